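# Per-enhancer openness regression.
#
# One independent model per enhancer predicts that enhancer's openness
# (max DH signal over its genome bins) across samples from the expression of
# its binding TFs (E_T) and associated target genes (E_G). The linear backend
# minimizes
#     || O - a0 - gamma_T * sum_p alpha_p TF_p - gamma_G * sum_q beta_q TG_q ||^2
#       + lambda * penalty(alpha, beta)
# which with gamma_T = gamma_G is an elastic net; random-forest and
# support-vector backends learn the same feature -> openness mapping with
# their own regularization.

#' Openness of an enhancer from per-bin DH signal
#'
#' An enhancer's openness is the maximum DNase I hypersensitivity signal over
#' the genome bins spanning it.
#'
#' @param dh_bins Numeric vector of per-bin DH values (all `>= 0`, length
#'   `>= 1`).
#' @return The maximum bin value.
#' @examples
#' compute_openness(c(0.2, 1.7, 0.9)) # 1.7
#' @export
compute_openness <- function(dh_bins) {
  if (length(dh_bins) == 0L) stop("empty bin list: an enhancer needs >= 1 DH bin")
  if (anyNA(dh_bins)) stop("missing DH bin values")
  if (any(dh_bins < 0)) stop("DH signal must be >= 0")
  max(dh_bins)
}

#' Detect whether an expression matrix is already log-scaled
#'
#' Heuristic used by the default preprocessing: values above 50 indicate a
#' linear-scale matrix that should get a log2(x + 1) transform.
#'
#' @param expr Numeric matrix.
#' @return TRUE when the matrix looks linear-scale (needs log transform).
#' @keywords internal
needs_log_transform <- function(expr) {
  any(expr > 50, na.rm = TRUE)
}

# Resolve preprocessing mode to (log?, zscore?) flags against a training
# matrix. "auto" log-transforms only when the matrix looks linear-scale.
.resolve_preprocess <- function(preprocess, expr) {
  preprocess <- match.arg(preprocess, c("auto", "none", "log", "log_zscore"))
  switch(preprocess,
    auto = list(log = needs_log_transform(expr), zscore = TRUE),
    none = list(log = FALSE, zscore = FALSE),
    log = list(log = TRUE, zscore = FALSE),
    log_zscore = list(log = TRUE, zscore = TRUE)
  )
}

#' Assemble the per-enhancer design matrix
#'
#' Columns are ordered TFs first (each scaled by `gamma_T`) then target genes
#' (scaled by `gamma_G`). Feature-set members absent from the expression
#' matrix are dropped with a warning; an enhancer keeping fewer than two
#' usable features is unfittable. `feature_mode = "TGonly"` drops the TF
#' block entirely (the target-gene-only baseline).
#'
#' @param tfs,tgs Character vectors: the enhancer's binding TFs and target
#'   genes.
#' @param expr Genes x samples expression matrix (rownames = gene symbols).
#' @param gamma_T,gamma_G Fixed group weights multiplying the TF and TG
#'   columns.
#' @param feature_mode `"TFandTG"` (default) or `"TGonly"`.
#' @return A list with `design` (samples x features), `tf_features`,
#'   `tg_features`, `dropped` — or `NULL` when < 2 usable features remain.
#' @export
assemble_features <- function(tfs, tgs, expr, gamma_T = 1, gamma_G = 1,
                              feature_mode = c("TFandTG", "TGonly")) {
  feature_mode <- match.arg(feature_mode)
  if (feature_mode == "TGonly") tfs <- character(0)
  have <- rownames(expr)
  use_tf <- intersect(tfs, have)
  use_tg <- intersect(tgs, have)
  dropped <- setdiff(c(tfs, tgs), have)
  if (length(dropped)) {
    warning(sprintf("%d feature(s) absent from expression matrix: %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
  }
  if (length(use_tf) + length(use_tg) < 2L) return(NULL)
  # a gene acting as both TF and TG contributes two columns (disambiguated names)
  design <- cbind(
    if (length(use_tf)) t(expr[use_tf, , drop = FALSE]) * gamma_T,
    if (length(use_tg)) t(expr[use_tg, , drop = FALSE]) * gamma_G
  )
  colnames(design) <- c(if (length(use_tf)) paste0("TF:", use_tf),
                        if (length(use_tg)) paste0("TG:", use_tg))
  list(design = design, tf_features = use_tf, tg_features = use_tg,
       dropped = dropped)
}

# Decreasing lambda path through `target`, so glmnet solves the target value
# as part of a warm-started path (accurate down to lambda = 0).
.lambda_path <- function(x, y, target) {
  n <- nrow(x)
  lmax <- max(abs(crossprod(x, y - mean(y)))) / (0.5 * n)
  lmax <- max(lmax, target * 1.001, 1e-3)
  path <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 40))
  path <- sort(unique(c(path[path > target], target)), decreasing = TRUE)
  path
}

#' Fit one enhancer's openness model
#'
#' `method = "elastic_net"` minimizes squared error plus an equal-mix L1/L2
#' penalty weighted by `lambda` (glmnet with `alpha = 0.5` on glmnet's
#' `1/(2N)` loss scale; `lambda = 0` is ordinary least squares).
#' `lambda = "cv"` selects lambda per enhancer by internal 5-fold
#' cross-validation. Random-forest (100 trees, `mtry = ceiling(sqrt(p))`) and
#' SVM (radial kernel) backends fit the same mapping. The design matrix is
#' standardized internally with training statistics; the fitted model stores
#' everything needed for standalone prediction.
#'
#' @param design Samples x features numeric matrix (from
#'   [assemble_features()]).
#' @param y Numeric openness vector aligned with the design rows.
#' @param method One of `"elastic_net"`, `"random_forest"`, `"svm"`.
#' @param lambda `"cv"` or a single non-negative number (elastic net only).
#' @param seed Integer seed fixing CV folds and stochastic backends.
#' @param zscore Standardize columns with training mean/sd (default TRUE).
#' @return An object of class `enhancer_model`.
#' @export
fit_enhancer_model <- function(design, y,
                               method = c("elastic_net", "random_forest", "svm"),
                               lambda = "cv", seed = 1L, zscore = TRUE) {
  method <- match.arg(method)
  if (anyNA(design) || anyNA(y)) {
    stop("missing values in training data; impute or drop samples explicitly upstream")
  }
  if (!all(is.finite(design)) || !all(is.finite(y))) stop("non-finite training values")
  n <- nrow(design)
  if (n != length(y)) stop("design rows and openness vector lengths differ")
  if (n < 3L) stop("need >= 3 training samples")
  p <- ncol(design)

  center <- if (zscore) colMeans(design) else rep(0, p)
  scl <- if (zscore) apply(design, 2, stats::sd) else rep(1, p)
  scl[!is.finite(scl) | scl == 0] <- 1   # constant columns pass through unscaled
  x <- sweep(sweep(design, 2, center, "-"), 2, scl, "/")

  model <- structure(list(
    method = method, feature_names = colnames(design),
    center = center, scale = scl, zscore = zscore,
    train_mean = mean(y), train_range = range(y),
    degenerate = FALSE, lambda = NA_real_,
    coefficients = NULL, intercept = NULL, fit = NULL
  ), class = "enhancer_model")

  if (stats::sd(y) == 0) {
    # constant target: intercept-only model, flagged degenerate
    model$degenerate <- TRUE
    model$intercept <- y[1]
    model$coefficients <- stats::setNames(rep(0, p), colnames(design))
    model$lambda <- if (is.numeric(lambda)) lambda else NA_real_
    return(model)
  }

  if (method == "elastic_net") {
    if (identical(lambda, "cv")) {
      set.seed(seed)
      foldid <- sample(rep_len(seq_len(5L), n))
      cv <- glmnet::cv.glmnet(x, y, alpha = 0.5, foldid = foldid,
                              standardize = FALSE, thresh = 1e-10)
      lam <- cv$lambda.min
      fit <- glmnet::glmnet(x, y, alpha = 0.5, lambda = .lambda_path(x, y, lam),
                            standardize = FALSE, thresh = 1e-10)
    } else {
      lam <- as.numeric(lambda)
      if (lam < 0) stop("lambda must be >= 0")
      fit <- glmnet::glmnet(x, y, alpha = 0.5, lambda = .lambda_path(x, y, lam),
                            standardize = FALSE, thresh = 1e-12, maxit = 1e6)
    }
    # the target lambda is a knot of the fitted path, so no interpolation
    idx <- which.min(abs(fit$lambda - lam))
    cf <- c(unname(fit$a0[idx]), as.numeric(fit$beta[, idx]))
    model$intercept <- cf[1]
    model$coefficients <- stats::setNames(cf[-1], colnames(design))
    model$lambda <- lam
  } else if (method == "random_forest") {
    set.seed(seed)
    model$fit <- randomForest::randomForest(
      x = x, y = y, ntree = 100L, mtry = max(1L, ceiling(sqrt(p))))
  } else {
    model$fit <- e1071::svm(x = x, y = y, kernel = "radial")
  }
  model
}

#' Predict openness for one enhancer model
#'
#' Applies the training-time standardization to the supplied design matrix
#' and evaluates the fitted regressor. Negative raw outputs of the linear and
#' SVM backends are clipped to 0 by default, since openness is a nonnegative
#' DH-derived quantity.
#'
#' @param object An `enhancer_model`.
#' @param design Samples x features matrix with the model's feature columns
#'   (same construction as training, e.g. via [assemble_features()]).
#' @param clip Clip negative predictions to 0 (default TRUE).
#' @param ... Unused.
#' @return Named numeric vector of per-sample predicted openness.
#' @export
predict.enhancer_model <- function(object, design, clip = TRUE, ...) {
  missing_feats <- setdiff(object$feature_names, colnames(design))
  if (length(missing_feats)) {
    stop(sprintf("feature(s) missing at prediction time: %s",
                 paste(missing_feats, collapse = ", ")))
  }
  design <- design[, object$feature_names, drop = FALSE]
  if (anyNA(design)) stop("missing values in prediction input")
  x <- sweep(sweep(design, 2, object$center, "-"), 2, object$scale, "/")
  pred <- if (object$degenerate) {
    rep(object$intercept, nrow(x))
  } else if (object$method == "elastic_net") {
    drop(x %*% object$coefficients) + object$intercept
  } else if (object$method == "random_forest") {
    unname(stats::predict(object$fit, newdata = x))
  } else {
    unname(stats::predict(object$fit, newdata = x))
  }
  if (clip) pred <- pmax(pred, 0)
  stats::setNames(as.numeric(pred), rownames(design))
}

#' @export
print.enhancer_model <- function(x, ...) {
  cat(sprintf("<enhancer_model> method=%s, %d features%s\n", x$method,
              length(x$feature_names),
              if (x$degenerate) " (degenerate: constant target)" else ""))
  invisible(x)
}

#' Fit openness models for every enhancer in a network
#'
#' Runs the full training stage: resolves preprocessing on the expression
#' matrix (optional log2(x + 1), per-feature z-scoring with training
#' statistics), assembles each enhancer's TF/TG design matrix, and fits one
#' model per enhancer. Enhancers with fewer than two usable features, or
#' absent from the openness matrix, go to the skip report instead.
#'
#' @param network A `regulatory_network` (typically after
#'   [filter_by_degree()]).
#' @param expr Genes x samples expression matrix.
#' @param openness Enhancers x samples openness matrix sharing sample ids
#'   with `expr`.
#' @param method Regression backend, see [fit_enhancer_model()].
#' @param lambda `"cv"` or fixed non-negative value (elastic net).
#' @param gamma_T,gamma_G TF and TG group weights of the model (defaults 1).
#' @param feature_mode `"TFandTG"` or `"TGonly"` (target-gene-only baseline).
#' @param seed Integer seed (CV folds, random forest).
#' @param preprocess `"auto"`, `"none"`, `"log"`, or `"log_zscore"`.
#' @return A `model_collection`: named list of models plus config, training
#'   sample ids, and a skip report (`enhancer_id`, `reason`).
#' @export
fit_all <- function(network, expr, openness,
                    method = c("elastic_net", "random_forest", "svm"),
                    lambda = "cv", gamma_T = 1, gamma_G = 1,
                    feature_mode = c("TFandTG", "TGonly"),
                    seed = 1L, preprocess = "auto") {
  method <- match.arg(method)
  feature_mode <- match.arg(feature_mode)
  stopifnot(inherits(network, "regulatory_network"))
  common <- intersect(colnames(expr), colnames(openness))
  if (length(common) == 0L) stop("expression and openness matrices share no samples")
  expr <- expr[, common, drop = FALSE]
  openness <- openness[, common, drop = FALSE]
  pp <- .resolve_preprocess(preprocess, expr)
  if (pp$log) expr <- log2(expr + 1)

  ids <- network$enhancers$enhancer_id
  models <- list()
  skip <- data.frame(enhancer_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  note_skip <- function(id, why) {
    rbind(skip, data.frame(enhancer_id = id, reason = why, stringsAsFactors = FALSE))
  }
  for (id in ids) {
    if (!id %in% rownames(openness)) {
      skip <- note_skip(id, "no openness row")
      next
    }
    feats <- withCallingHandlers(
      assemble_features(network$binding_tfs[[id]], network$target_genes[[id]],
                        expr, gamma_T, gamma_G, feature_mode),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(feats)) {
      skip <- note_skip(id, "fewer than 2 usable features")
      next
    }
    m <- fit_enhancer_model(feats$design, openness[id, ], method = method,
                            lambda = lambda, seed = seed, zscore = pp$zscore)
    m$enhancer_id <- id
    m$tf_features <- feats$tf_features
    m$tg_features <- feats$tg_features
    models[[id]] <- m
  }
  structure(list(
    models = models,
    sample_ids = common,
    skip_report = skip,
    config = list(method = method, lambda = lambda, gamma_T = gamma_T,
                  gamma_G = gamma_G, feature_mode = feature_mode, seed = seed,
                  preprocess = preprocess, log_applied = pp$log,
                  zscore = pp$zscore)
  ), class = "model_collection")
}

#' @export
print.model_collection <- function(x, ...) {
  cat(sprintf("<model_collection> %d models (%s), %d skipped, %d training samples\n",
              length(x$models), x$config$method, nrow(x$skip_report),
              length(x$sample_ids)))
  invisible(x)
}

#' Predict openness for every model in a collection
#'
#' Applies the collection's training-time preprocessing (log transform flag
#' learned on the training matrix, per-feature standardization stored in each
#' model) to a new expression matrix and stacks per-enhancer predictions.
#'
#' @param object A `model_collection` from [fit_all()].
#' @param expr Genes x samples expression matrix containing the model
#'   features.
#' @param clip Clip negative predictions to 0 (default TRUE).
#' @param ... Unused.
#' @return Enhancers x samples matrix of predicted openness.
#' @export
predict.model_collection <- function(object, expr, clip = TRUE, ...) {
  if (object$config$log_applied) expr <- log2(expr + 1)
  samples <- colnames(expr)
  out <- matrix(NA_real_, nrow = length(object$models), ncol = length(samples),
                dimnames = list(names(object$models), samples))
  for (id in names(object$models)) {
    m <- object$models[[id]]
    feats <- assemble_features(m$tf_features, m$tg_features, expr,
                               object$config$gamma_T, object$config$gamma_G,
                               object$config$feature_mode)
    if (is.null(feats)) stop(sprintf("features missing at prediction time for enhancer '%s'", id))
    out[id, ] <- predict(m, feats$design, clip = clip)
  }
  out
}

#' Serialize a model collection to a directory
#'
#' Writes a JSON manifest (config, per-model feature lists and preprocessing
#' state, skip report) plus one coefficient TSV per linear model. Opaque
#' random-forest / SVM fits are not serialized to text; collections using
#' those backends must be refit from data (the manifest records enough to do
#' so deterministically).
#'
#' @param collection A `model_collection`.
#' @param dir Output directory (created if needed).
#' @export
write_model_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "model_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = collection$config,
    sample_ids = collection$sample_ids,
    skip_report = collection$skip_report,
    models = lapply(collection$models, function(m) {
      list(enhancer_id = m$enhancer_id, method = m$method,
           tf_features = m$tf_features, tg_features = m$tg_features,
           feature_names = m$feature_names,
           center = as.list(stats::setNames(m$center, m$feature_names)),
           scale = as.list(stats::setNames(m$scale, m$feature_names)),
           lambda = m$lambda, degenerate = m$degenerate,
           intercept = m$intercept)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (m in collection$models) {
    if (m$method == "elastic_net") {
      utils::write.table(
        data.frame(feature = m$feature_names, coefficient = unname(m$coefficients)),
        file.path(dir, paste0(m$enhancer_id, "_coef.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
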