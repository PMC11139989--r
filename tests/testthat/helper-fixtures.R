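# Shared fixture builders; everything is generated in code.

# Brute-force all-pairs overlap oracle (half-open semantics), independent of
# the package's interval-index implementation.
brute_force_overlap <- function(query, subject) {
  pairs <- list()
  k <- 0L
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          query$start[i] < subject$end[j] &&
          subject$start[j] < query$end[i]) {
        k <- k + 1L
        pairs[[k]] <- c(i, j)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(query_idx = integer(0), subject_idx = integer(0)))
  }
  m <- do.call(rbind, pairs)
  out <- data.frame(query_idx = m[, 1], subject_idx = m[, 2])
  out <- out[order(out$query_idx, out$subject_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(200, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             name = sprintf("iv%d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# A tiny hand-built network: 3 enhancers on one chromosome.
tiny_network <- function() {
  enh <- data.frame(
    enhancer_id = c("e1", "e2", "e3"),
    chrom = "chr1",
    start = c(100, 1000, 5000),
    end = c(500, 2000, 6000),
    stringsAsFactors = FALSE)
  regulatory_network(
    enh,
    target_genes = list(e1 = c("gA", "gB"), e2 = c("gB", "gC", "gD"), e3 = c("gE", "gF")),
    binding_tfs = list(e1 = c("tX", "tY"), e2 = c("tX", "tZ"), e3 = c("tY", "tZ")))
}

# Planted linear instance for regression oracles: y = X w + b0 (no noise
# unless sigma > 0).
planted_linear <- function(n = 50, p = 5, sigma = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, mean = 5), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:p)))
  w <- runif(p, 0.5, 1.5) * sample(c(-1, 1), p, replace = TRUE)
  b0 <- runif(1, 2, 4)
  y <- drop(X %*% w) + b0 + rnorm(n, sd = sigma)
  list(X = X, y = y, w = w, b0 = b0)
}

# Closed-form least squares with intercept (the normal-equations oracle).
ols_oracle <- function(X, y) {
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  list(intercept = beta[1], coefficients = drop(beta[-1]))
}
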