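# Moderated t, Wilcoxon rank-sum, and the diffEnhancer / perturbed-gene
# calling rules.

make_groups <- function(n_feat, n_t, n_c, shift = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * (n_t + n_c)), n_feat,
              dimnames = list(sprintf("f%d", 1:n_feat), NULL))
  labels <- c(rep("treated", n_t), rep("control", n_c))
  m[, labels == "treated"] <- m[, labels == "treated"] + shift
  list(m = m, labels = labels)
}

test_that("identical groups give zero logFC and p = 1", {
  m <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 4), nrow = 4,
              dimnames = list(sprintf("f%d", 1:4), NULL))
  labels <- rep(c("treated", "control"), each = 3)
  res <- moderated_t_test(m, labels)
  expect_equal(res$log_fc, rep(0, 4))
  expect_equal(res$p_value, rep(1, 4))
  resw <- wilcoxon_test(m, labels)
  expect_equal(resw$p_value, rep(1, 4))
})

test_that("with shrinkage disabled the moderated t is the textbook pooled t", {
  g <- make_groups(5, 6, 8, shift = 0.7, seed = 3)
  res <- moderated_t_test(g$m, g$labels, prior_df = 0)
  for (i in 1:5) {
    x <- g$m[i, g$labels == "treated"]
    y <- g$m[i, g$labels == "control"]
    oracle <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$statistic[i], unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], oracle$p.value, tolerance = 1e-12)
    expect_equal(res$log_fc[i], mean(x) - mean(y), tolerance = 1e-12)
  }
})

test_that("empirical-Bayes moderation agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(8)
  n_t <- 5; n_c <- 5
  m <- matrix(rnorm(400 * (n_t + n_c), sd = rep(runif(400, 0.5, 2), n_t + n_c)),
              nrow = 400, dimnames = list(sprintf("f%d", 1:400), NULL))
  labels <- c(rep("treated", n_t), rep("control", n_c))
  res <- moderated_t_test(m, labels)
  design <- cbind(1, as.integer(labels == "treated"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(res$statistic, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated and ordinary t coincide when all variances are equal", {
  # identical within-group deviations + per-feature mean shifts: every
  # feature has the same pooled s^2, so the shrinkage target equals it
  set.seed(5)
  dev <- rnorm(12)
  labels <- rep(c("treated", "control"), each = 6)
  shifts <- rnorm(30)
  m <- do.call(rbind, lapply(1:30, function(i) {
    dev + shifts[i] * (labels == "treated")
  }))
  rownames(m) <- sprintf("f%d", 1:30)
  res_auto <- moderated_t_test(m, labels)
  res_plain <- moderated_t_test(m, labels, prior_df = 0)
  expect_equal(res_auto$statistic, res_plain$statistic, tolerance = 1e-8)
})

test_that("p-values are invariant to feature order and label swap", {
  g <- make_groups(20, 5, 5, shift = 0.5, seed = 11)
  res <- moderated_t_test(g$m, g$labels)
  perm <- sample(20)
  res_perm <- moderated_t_test(g$m[perm, ], g$labels)
  expect_equal(res_perm$p_value, res$p_value[perm])
  swapped <- ifelse(g$labels == "treated", "control", "treated")
  res_swap <- moderated_t_test(g$m, swapped)
  expect_equal(res_swap$p_value, res$p_value)
  expect_equal(res_swap$log_fc, -res$log_fc)
})

test_that("group-size and finiteness preconditions are enforced", {
  g <- make_groups(3, 1, 5, seed = 2)
  expect_error(moderated_t_test(g$m, g$labels), ">= 2 samples")
  g2 <- make_groups(3, 3, 3, seed = 2)
  expect_error(moderated_t_test(g2$m[, 1:5], rep("treated", 5)), "control|>= 2")
  g2$m[1, 1] <- NA
  expect_error(moderated_t_test(g2$m, g2$labels), "non-finite")
})

test_that("wilcoxon exact path matches full enumeration semantics", {
  m <- matrix(c(4, 5, 6, 1, 2, 3), nrow = 1)
  rownames(m) <- "f1"
  labels <- rep(c("treated", "control"), each = 3)
  res <- wilcoxon_test(m, labels)
  # most extreme of the C(6,3) = 20 labelings, doubled: p = 2/20
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 4 + 5 + 6)

  # exact path equals wilcox.test's exact p on tie-free random instances
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(6); y <- rnorm(7) + 0.8
    m2 <- matrix(c(x, y), nrow = 1, dimnames = list("f1", NULL))
    res2 <- wilcoxon_test(m2, c(rep("treated", 6), rep("control", 7)))
    oracle <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(res2$p_value, oracle, tolerance = 1e-12,
                 info = sprintf("seed %d", seed))
  }
})

test_that("wilcoxon normal approximation tracks the exact path", {
  for (seed in 1:10) {
    set.seed(seed)
    vals <- rnorm(16)
    m <- matrix(vals, nrow = 1, dimnames = list("f1", NULL))
    labels <- rep(c("treated", "control"), each = 8)
    p_exact <- wilcoxon_test(m, labels, exact_max = 8)$p_value
    p_norm <- wilcoxon_test(m, labels, exact_max = 0)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("wilcoxon handles ties with midranks and flags all-tied features", {
  m <- rbind(f1 = c(1, 1, 2, 2, 3, 3, 1, 2), f2 = rep(5, 8))
  labels <- rep(c("treated", "control"), each = 4)
  res <- wilcoxon_test(m, labels)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(res$p_value[2], 1)
})

test_that("diffEnhancer calling applies strict thresholds", {
  results <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    log_fc = c(0.6, 0.5, -0.9, 2.0),
    statistic = 0, p_value = c(5e-4, 1e-6, 1e-4, 0.5),
    method = "moderated_t", n_treated = 10, n_control = 10)
  expect_equal(call_diff_enhancers(results), c("a", "c"))  # b: logFC == 0.5 excluded
  expect_equal(call_diff_enhancers(results[0, ]), character(0))

  gene_results <- data.frame(
    feature_id = c("g1", "g2", "g3"),
    log_fc = c(-0.9, 0.79, 2.0),
    statistic = 0, p_value = c(0.01, 1e-5, 0.06),
    method = "moderated_t", n_treated = 10, n_control = 10)
  expect_equal(call_perturbed_genes(gene_results), "g1")
})

test_that("null calling respects the nominal error rate", {
  g <- make_groups(4000, 10, 10, seed = 17)
  res <- moderated_t_test(g$m, g$labels)
  frac <- mean(res$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 0.015)
  # the logFC gate only reduces calls below the p gate alone
  called <- call_diff_enhancers(res, logfc_threshold = 0.5, p_threshold = 0.05)
  expect_lte(length(called), sum(res$p_value < 0.05))
})

test_that("diff_pipeline skips underpowered blocks and nulls call nothing", {
  gen <- generate_network(n_enhancers = 8, n_genes = 40, n_tfs = 6, seed = 61)
  tr <- generate_paired_training(gen, n_cells = 30, seed = 62)
  fit <- fit_all(gen$network, tr$expr, tr$openness, lambda = 0.05)
  pert <- generate_perturbation(gen, tr$truth, n_control = 10, n_treated = 10,
                                effect_size = 0, frac_responsive = 0.3, seed = 63)
  # effect 0: control and treated identically distributed; at p < 0.001 and
  # |logFC| > 0.5 nothing should be called on 8 enhancers
  res <- diff_pipeline(fit, pert$expr_control, pert$expr_treated)
  expect_length(res$diff_enhancers, 0)
  expect_true(res$active_fraction > 0.9)

  skip_res <- diff_pipeline(fit, pert$expr_control[, 1, drop = FALSE],
                            pert$expr_treated)
  expect_null(skip_res$results)
  expect_match(skip_res$skip_reason, "fewer than 2")

  ident <- diff_pipeline(fit, pert$expr_control, pert$expr_control)
  expect_length(ident$diff_enhancers, 0)
})
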