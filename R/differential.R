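# Differential calling: empirical-Bayes moderated t-test and Wilcoxon
# rank-sum on (predicted) openness or expression, treated vs control, plus
# the threshold rules that define drug-responsive enhancers (diffEnhancers)
# and drug-perturbed genes.

# Newton inversion of the trigamma function (y = trigamma(x), y > 0).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

# Moment-matching estimate of the scaled inverse-chi-square prior
# (d0, s0^2) from per-feature sample variances s2 with residual df d,
# fitted on the log scale: log(s2) ~ log-F location/scale identities.
.estimate_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L) {
    warning("fewer than 10 positive residual variances; disabling shrinkage (d0 = 0)")
    return(list(d0 = 0, s0_sq = NA_real_))
  }
  z <- log(s2[ok])
  if (diff(range(z)) < 1e-12) {
    # all variances identical: the shrinkage target is that common value and
    # moderation leaves every statistic unchanged
    return(list(d0 = Inf, s0_sq = exp(z[1])))
  }
  e <- z - digamma(d / 2) + log(d / 2)
  n <- length(e)
  evar <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    # variances more concentrated than chi-square sampling alone: infinite
    # prior df, complete shrinkage to the common value
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

.split_groups <- function(matrix, condition_labels) {
  if (length(condition_labels) != ncol(matrix)) {
    stop("condition_labels must have one entry per sample column")
  }
  if (!all(condition_labels %in% c("control", "treated"))) {
    stop("condition labels must be 'control' or 'treated'")
  }
  it <- which(condition_labels == "treated")
  ic <- which(condition_labels == "control")
  if (length(it) < 2L || length(ic) < 2L) {
    stop("each condition needs >= 2 samples")
  }
  list(treated = matrix[, it, drop = FALSE], control = matrix[, ic, drop = FALSE])
}

#' Empirical-Bayes moderated t-test (two groups)
#'
#' Per-feature two-sample comparison with variance shrinkage: each feature's
#' pooled residual variance `s^2` (df `d = n_t + n_c - 2`) is combined with a
#' scaled inverse-chi-square prior `(d0, s0^2)` estimated from all features
#' by moment matching on `log s^2`, giving the posterior variance
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`. The moderated statistic
#' `t = logFC / (s_tilde * sqrt(1/n_t + 1/n_c))` is referred to a t
#' distribution with `d + d0` degrees of freedom. `prior_df = 0` disables
#' shrinkage and reproduces the ordinary pooled two-sample t-test.
#'
#' @param matrix Features x samples numeric matrix (assumed log-scale, so
#'   mean differences are log fold changes).
#' @param condition_labels Character vector (`"control"` / `"treated"`) per
#'   column.
#' @param prior_df `"auto"` (estimate d0 from the data) or a fixed
#'   non-negative number (0 = ordinary t-test).
#' @return data.frame with `feature_id`, `log_fc` (treated - control),
#'   `statistic`, `p_value`, `method`, `n_treated`, `n_control`.
#' @export
moderated_t_test <- function(matrix, condition_labels, prior_df = "auto") {
  if (anyNA(matrix) || !all(is.finite(matrix))) stop("non-finite values in input matrix")
  g <- .split_groups(matrix, condition_labels)
  nt <- ncol(g$treated); nc <- ncol(g$control)
  d <- nt + nc - 2
  mt <- rowMeans(g$treated); mc <- rowMeans(g$control)
  log_fc <- mt - mc
  rss <- rowSums((g$treated - mt)^2) + rowSums((g$control - mc)^2)
  s2 <- rss / d

  if (identical(prior_df, "auto")) {
    prior <- .estimate_variance_prior(s2, d)
  } else {
    prior_df <- as.numeric(prior_df)
    if (prior_df < 0) stop("prior_df must be >= 0")
    prior <- list(d0 = prior_df,
                  s0_sq = if (prior_df > 0) stats::median(s2) else NA_real_)
  }
  d0 <- prior$d0
  s_tilde_sq <- if (is.infinite(d0)) {
    rep(prior$s0_sq, length(s2))
  } else if (d0 > 0) {
    (d0 * prior$s0_sq + d * s2) / (d0 + d)
  } else {
    s2
  }
  se <- sqrt(s_tilde_sq * (1 / nt + 1 / nc))
  stat <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  df_total <- if (is.infinite(d0)) Inf else d + d0
  p <- 2 * stats::pt(-abs(stat), df = df_total)
  p[stat == 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(feature_id = rownames(matrix), log_fc = unname(log_fc),
             statistic = unname(stat), p_value = unname(p),
             method = "moderated_t", n_treated = nt, n_control = nc,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Exact two-sided rank-sum p-value by enumeration of all C(n, nt) group
# assignments on the observed (mid)ranks. Two-sided p doubles the smaller
# tail of the permutation distribution of the treated rank sum.
.wilcoxon_exact_p <- function(ranks, nt) {
  n <- length(ranks)
  w_obs <- sum(ranks[seq_len(nt)])
  combs <- utils::combn(n, nt)
  ws <- colSums(matrix(ranks[combs], nrow = nt))
  lo <- mean(ws <= w_obs + 1e-9)
  hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Normal approximation with midrank tie correction and continuity correction.
.wilcoxon_normal_p <- function(ranks, nt) {
  n <- length(ranks)
  nc <- n - nt
  w <- sum(ranks[seq_len(nt)])
  mu <- nt * (n + 1) / 2
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nt * nc / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum test (two groups, per feature)
#'
#' Two-sided rank-sum test with midranks for ties. When both groups have at
#' most `exact_max` samples the p-value is computed by full enumeration of
#' group assignments; otherwise a normal approximation with tie and
#' continuity correction is used. Features where every value is tied get
#' `p = 1`.
#'
#' @inheritParams moderated_t_test
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return data.frame as in [moderated_t_test()] with `statistic` = treated
#'   rank sum and `method = "wilcoxon"`.
#' @export
wilcoxon_test <- function(matrix, condition_labels, exact_max = 8L) {
  if (anyNA(matrix) || !all(is.finite(matrix))) stop("non-finite values in input matrix")
  g <- .split_groups(matrix, condition_labels)
  nt <- ncol(g$treated); nc <- ncol(g$control)
  exact <- nt <= exact_max && nc <= exact_max
  res <- t(vapply(seq_len(nrow(g$treated)), function(i) {
    vals <- c(g$treated[i, ], g$control[i, ])
    ranks <- rank(vals)
    w <- sum(ranks[seq_len(nt)])
    if (length(unique(vals)) == 1L) return(c(w, 1))
    p <- if (exact) .wilcoxon_exact_p(ranks, nt) else .wilcoxon_normal_p(ranks, nt)
    c(w, p)
  }, numeric(2)))
  data.frame(feature_id = rownames(matrix),
             log_fc = unname(rowMeans(g$treated) - rowMeans(g$control)),
             statistic = res[, 1], p_value = res[, 2],
             method = "wilcoxon", n_treated = nt, n_control = nc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call drug-responsive enhancers
#'
#' An enhancer is called when `|log_fc|` strictly exceeds `logfc_threshold`
#' and its p-value is strictly below `p_threshold` (defaults 0.5 and 0.001).
#'
#' @param results data.frame from [moderated_t_test()] or [wilcoxon_test()].
#' @param logfc_threshold,p_threshold Strict thresholds.
#' @param adjust `"none"` (default: raw p-values are gated) or `"bh"` for
#'   Benjamini-Hochberg adjustment before gating.
#' @return Sorted character vector of called feature ids.
#' @export
call_diff_enhancers <- function(results, logfc_threshold = 0.5,
                                p_threshold = 0.001, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  if (nrow(results) == 0L) return(character(0))
  p <- results$p_value
  if (adjust == "bh") p <- stats::p.adjust(p, method = "BH")
  called <- abs(results$log_fc) > logfc_threshold & p < p_threshold
  sort(results$feature_id[called])
}

#' Call drug-perturbed genes
#'
#' Genes with p-value strictly below `p_threshold` and `|log_fc|` strictly
#' above `abs_logfc_threshold` (defaults 0.05 and 0.8).
#'
#' @inheritParams call_diff_enhancers
#' @param abs_logfc_threshold Strict absolute log-fold-change threshold.
#' @return Sorted character vector of called gene ids.
#' @export
call_perturbed_genes <- function(results, p_threshold = 0.05,
                                 abs_logfc_threshold = 0.8) {
  if (nrow(results) == 0L) return(character(0))
  called <- results$p_value < p_threshold & abs(results$log_fc) > abs_logfc_threshold
  sort(results$feature_id[called])
}

#' Differential-openness pipeline for one drug / cell-line block
#'
#' Predicts per-enhancer openness for the control and treated expression
#' matrices with a fitted [fit_all()] collection, transforms predictions to
#' `log2(x + 1)` (so mean differences are log fold changes; `fc_scale =
#' "raw"` skips the transform), runs the chosen two-group test, and applies
#' the diffEnhancer thresholds. A condition with fewer than two samples
#' yields a skip record instead of results.
#'
#' @param models A `model_collection`.
#' @param expr_control,expr_treated Genes x samples expression matrices.
#' @param method `"moderated_t"` (default) or `"wilcoxon"`.
#' @param logfc_threshold,p_threshold Calling thresholds (defaults 0.5,
#'   0.001).
#' @param fc_scale `"log2p1"` (default) or `"raw"`.
#' @param adjust Multiple-testing adjustment passed to
#'   [call_diff_enhancers()].
#' @return list with `diff_enhancers` (called ids), `results` (full
#'   per-enhancer table), `skip_reason` (NULL unless skipped), and
#'   `active_fraction` (fraction of samples with >= 1 enhancer of predicted
#'   openness > 0).
#' @export
diff_pipeline <- function(models, expr_control, expr_treated,
                          method = c("moderated_t", "wilcoxon"),
                          logfc_threshold = 0.5, p_threshold = 0.001,
                          fc_scale = c("log2p1", "raw"),
                          adjust = "none") {
  method <- match.arg(method)
  fc_scale <- match.arg(fc_scale)
  stopifnot(inherits(models, "model_collection"))
  if (ncol(expr_control) < 2L || ncol(expr_treated) < 2L) {
    return(list(diff_enhancers = character(0), results = NULL,
                skip_reason = "fewer than 2 samples in a condition",
                active_fraction = NA_real_))
  }
  pc <- predict(models, expr_control)
  pt <- predict(models, expr_treated)
  pred <- cbind(pc, pt)
  active_fraction <- mean(apply(pred > 0, 2, any))
  if (fc_scale == "log2p1") pred <- log2(pred + 1)
  labels <- c(rep("control", ncol(pc)), rep("treated", ncol(pt)))
  results <- if (method == "moderated_t") {
    moderated_t_test(pred, labels)
  } else {
    wilcoxon_test(pred, labels)
  }
  list(diff_enhancers = call_diff_enhancers(results, logfc_threshold,
                                            p_threshold, adjust = adjust),
       results = results, skip_reason = NULL,
       active_fraction = active_fraction)
}
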