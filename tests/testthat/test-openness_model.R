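# Per-enhancer regression: feature assembly, fitting backends, prediction.

test_that("openness is the maximum DH bin value", {
  expect_equal(compute_openness(c(0.2, 1.7, 0.9)), 1.7)
  expect_equal(compute_openness(0), 0)
  for (x in c(0.01, 3.7, 100)) expect_equal(compute_openness(x), x)
  expect_error(compute_openness(numeric(0)), "empty")
  expect_error(compute_openness(c(1, -0.1)), ">= 0")
})

test_that("feature assembly orders TFs then TGs and applies gamma weights", {
  expr <- matrix(1:20, nrow = 5,
                 dimnames = list(c("t1", "t2", "gA", "gB", "gC"),
                                 sprintf("s%d", 1:4)))
  f <- assemble_features(c("t1", "t2"), c("gA", "gB", "gC"), expr)
  expect_equal(colnames(f$design),
               c("TF:t1", "TF:t2", "TG:gA", "TG:gB", "TG:gC"))
  expect_equal(nrow(f$design), 4)

  # gamma_T = 0 zeroes the TF block (target-gene-only limit)
  f0 <- assemble_features(c("t1", "t2"), c("gA", "gB"), expr, gamma_T = 0)
  expect_true(all(f0$design[, 1:2] == 0))
  expect_equal(f0$design[, "TG:gA"], expr["gA", ])

  # missing member dropped with warning; < 2 usable features -> NULL
  expect_warning(f2 <- assemble_features(c("t1"), c("gA", "ZZZ"), expr), "absent")
  expect_equal(ncol(f2$design), 2)
  expect_warning(f3 <- assemble_features("t1", "ZZZ", expr), "absent")
  expect_null(f3)

  # TGonly mode drops TFs entirely
  f4 <- assemble_features(c("t1", "t2"), c("gA", "gB"), expr, feature_mode = "TGonly")
  expect_equal(colnames(f4$design), c("TG:gA", "TG:gB"))
})

test_that("elastic net at lambda = 0 matches the normal-equations oracle", {
  for (seed in 1:10) {
    inst <- planted_linear(n = 50, p = 5, sigma = 0.3, seed = seed)
    m <- fit_enhancer_model(inst$X, inst$y, method = "elastic_net",
                            lambda = 0, zscore = FALSE)
    oracle <- ols_oracle(inst$X, inst$y)
    expect_equal(unname(m$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-6, info = sprintf("seed %d", seed))
    expect_equal(m$intercept, oracle$intercept, tolerance = 1e-6)
  }
})

test_that("noiseless planted data is recovered exactly at lambda = 0", {
  inst <- planted_linear(n = 50, p = 5, sigma = 0, seed = 3)
  m <- fit_enhancer_model(inst$X, inst$y, method = "elastic_net",
                          lambda = 0, zscore = FALSE)
  expect_equal(unname(m$coefficients), unname(inst$w), tolerance = 1e-6)
  pred <- predict(m, inst$X)
  expect_equal(unname(pred), unname(inst$y), tolerance = 1e-6)
})

test_that("heavy regularization shrinks to the training mean", {
  inst <- planted_linear(n = 40, p = 4, sigma = 0.2, seed = 9)
  m <- fit_enhancer_model(inst$X, inst$y, method = "elastic_net", lambda = 1e6)
  expect_true(all(abs(m$coefficients) < 1e-6))
  pred <- predict(m, inst$X, clip = FALSE)
  expect_equal(unname(pred), rep(mean(inst$y), 40), tolerance = 1e-6)
})

test_that("aggregate coefficient L1 norm is non-increasing in lambda", {
  inst <- planted_linear(n = 60, p = 6, sigma = 0.5, seed = 11)
  lambdas <- c(0, 0.01, 0.1, 0.5, 1, 5, 50)
  norms <- vapply(lambdas, function(l) {
    m <- fit_enhancer_model(inst$X, inst$y, method = "elastic_net", lambda = l)
    sum(abs(m$coefficients))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("constant targets give a flagged intercept-only model", {
  inst <- planted_linear(n = 20, p = 3, seed = 2)
  y <- rep(4.2, 20)
  m <- fit_enhancer_model(inst$X, y, method = "elastic_net", lambda = 0)
  expect_true(m$degenerate)
  expect_equal(unname(predict(m, inst$X)), rep(4.2, 20))
})

test_that("missing values are rejected, never imputed", {
  inst <- planted_linear(n = 20, p = 3, seed = 2)
  Xna <- inst$X; Xna[3, 2] <- NA
  expect_error(fit_enhancer_model(Xna, inst$y), "missing")
  m <- fit_enhancer_model(inst$X, inst$y, lambda = 0)
  expect_error(predict(m, Xna), "missing")
})

test_that("negative linear predictions clip to zero; backends stay finite", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- pmax(drop(X %*% c(2, -1, 1)), 0)
  for (method in c("elastic_net", "random_forest", "svm")) {
    m <- fit_enhancer_model(X, y, method = method, lambda = 0.1, seed = 1)
    Xnew <- matrix(rnorm(30, sd = 3), 10, 3, dimnames = list(NULL, colnames(X)))
    pred <- predict(m, Xnew)
    expect_true(all(is.finite(pred)) && all(pred >= 0), info = method)
  }
  # unclipped linear output can go negative; clipped never does
  m <- fit_enhancer_model(X, y - 10, method = "elastic_net", lambda = 0)
  raw <- predict(m, X, clip = FALSE)
  expect_true(any(raw < 0))
  expect_true(all(predict(m, X) >= 0))
})

test_that("random forest predictions stay within the training target range", {
  inst <- planted_linear(n = 40, p = 4, sigma = 0.5, seed = 6)
  m <- fit_enhancer_model(inst$X, inst$y, method = "random_forest", seed = 1)
  Xnew <- matrix(rnorm(40, mean = 5, sd = 5), 10, 4,
                 dimnames = list(NULL, colnames(inst$X)))
  pred <- predict(m, Xnew, clip = FALSE)
  expect_true(all(pred >= min(inst$y) & pred <= max(inst$y)))
})

test_that("prediction errors name missing features", {
  inst <- planted_linear(n = 20, p = 3, seed = 8)
  m <- fit_enhancer_model(inst$X, inst$y, lambda = 0)
  expect_error(predict(m, inst$X[, 1:2, drop = FALSE]), "f3")
})

test_that("fit_all fits every fittable enhancer and reports skips", {
  gen <- generate_network(n_enhancers = 10, n_genes = 40, n_tfs = 8, seed = 21)
  tr <- generate_paired_training(gen, n_cells = 30, seed = 22)
  fit <- fit_all(gen$network, tr$expr, tr$openness, lambda = 0.05, seed = 1)
  expect_length(fit$models, 10)
  expect_equal(nrow(fit$skip_report), 0)

  # removing one enhancer's features from the expression matrix skips it
  victim <- gen$network$enhancers$enhancer_id[1]
  drop_feats <- c(gen$network$binding_tfs[[victim]],
                  gen$network$target_genes[[victim]])
  keep_rows <- setdiff(rownames(tr$expr), drop_feats)
  fit2 <- fit_all(gen$network, tr$expr[keep_rows, ], tr$openness,
                  lambda = 0.05, seed = 1)
  expect_equal(fit2$skip_report$enhancer_id, victim)
  expect_length(fit2$models, 9)

  expect_error(fit_all(gen$network, tr$expr[, 1:5],
                       tr$openness[, 6:10, drop = FALSE]),
               "share no samples")
})

test_that("fitting is deterministic given the seed", {
  gen <- generate_network(n_enhancers = 6, n_genes = 30, n_tfs = 6, seed = 31)
  tr <- generate_paired_training(gen, n_cells = 25, seed = 32)
  for (method in c("elastic_net", "random_forest")) {
    f1 <- fit_all(gen$network, tr$expr, tr$openness, method = method, seed = 7)
    f2 <- fit_all(gen$network, tr$expr, tr$openness, method = method, seed = 7)
    p1 <- predict(f1, tr$expr)
    p2 <- predict(f2, tr$expr)
    expect_identical(p1, p2, info = method)
    if (method == "elastic_net") {
      expect_identical(lapply(f1$models, `[[`, "coefficients"),
                       lapply(f2$models, `[[`, "coefficients"))
    }
  }
})

test_that("model collection serializes a readable manifest", {
  gen <- generate_network(n_enhancers = 4, n_genes = 20, n_tfs = 6, seed = 41)
  tr <- generate_paired_training(gen, n_cells = 15, seed = 42)
  fit <- fit_all(gen$network, tr$expr, tr$openness, lambda = 0.1)
  dir <- withr::local_tempdir()
  write_model_collection(fit, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(manifest$models, 4)
  expect_equal(manifest$config$method, "elastic_net")
  expect_true(file.exists(file.path(dir, paste0(names(fit$models)[1], "_coef.tsv"))))
})
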