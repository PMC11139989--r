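# Evaluation statistics for predicted openness, DH-property
# characterization, and the predictability filter.

# Pearson correlation that returns NA (an explicit "undefined" marker)
# instead of erroring/warning when either vector is constant.
.safe_pcc <- function(a, b) {
  if (length(a) < 2L) return(NA_real_)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (is.na(sa) || is.na(sb) || sa == 0 || sb == 0) return(NA_real_)
  stats::cor(a, b)
}

.check_same_shape <- function(O, Ohat) {
  if (!all(dim(O) == dim(Ohat))) stop("matrices differ in shape")
  if (!is.null(rownames(O)) && !is.null(rownames(Ohat)) &&
      !identical(rownames(O), rownames(Ohat))) {
    stop("row (enhancer) orderings differ")
  }
  if (!is.null(colnames(O)) && !is.null(colnames(Ohat)) &&
      !identical(colnames(O), colnames(Ohat))) {
    stop("column (sample) orderings differ")
  }
}

#' Cross-cell correlation (per enhancer)
#'
#' Pearson correlation between measured and predicted openness of each
#' enhancer across samples. Enhancers where either vector is constant get an
#' `NA` marker and are excluded from summary statistics rather than
#' zero-filled.
#'
#' @param O,Ohat Enhancers x samples matrices (measured, predicted) with
#'   matching shapes and orderings.
#' @return Named numeric vector, one entry per enhancer (`NA` = undefined).
#' @export
cross_cell_correlation <- function(O, Ohat) {
  .check_same_shape(O, Ohat)
  out <- vapply(seq_len(nrow(O)), function(m) .safe_pcc(O[m, ], Ohat[m, ]), numeric(1))
  stats::setNames(out, rownames(O))
}

#' Cross-enhancer correlation (per sample)
#'
#' Pearson correlation between measured and predicted openness within each
#' sample across enhancers; constant vectors yield `NA`.
#'
#' @inheritParams cross_cell_correlation
#' @return Named numeric vector, one entry per sample.
#' @export
cross_enhancer_correlation <- function(O, Ohat) {
  .check_same_shape(O, Ohat)
  out <- vapply(seq_len(ncol(O)), function(n) .safe_pcc(O[, n], Ohat[, n]), numeric(1))
  stats::setNames(out, colnames(O))
}

#' Normalized squared prediction error
#'
#' Total squared prediction error divided by the total squared deviation of
#' the measured openness from its grand mean:
#' `sum((O - Ohat)^2) / sum((O - mean(O))^2)`. Equals 0 for a perfect
#' prediction and 1 for the constant grand-mean predictor.
#'
#' @inheritParams cross_cell_correlation
#' @return A single non-negative number.
#' @export
squared_prediction_error <- function(O, Ohat) {
  .check_same_shape(O, Ohat)
  denom <- sum((O - mean(O))^2)
  if (denom == 0) stop("measured openness is constant: error normalization undefined")
  sum((O - Ohat)^2) / denom
}

#' Full evaluation of a prediction
#'
#' @inheritParams cross_cell_correlation
#' @return A list of class `evaluation_result` with `cross_cell_pcc`,
#'   `cross_enhancer_pcc`, `squared_error`, and counts of defined
#'   correlations.
#' @export
evaluate_predictions <- function(O, Ohat) {
  cc <- cross_cell_correlation(O, Ohat)
  ce <- cross_enhancer_correlation(O, Ohat)
  structure(list(
    cross_cell_pcc = cc,
    cross_enhancer_pcc = ce,
    squared_error = squared_prediction_error(O, Ohat),
    n_defined_cc = sum(!is.na(cc)),
    n_defined_ce = sum(!is.na(ce))
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_result> median cross-cell PCC %.3f (%d defined), ",
                     "median cross-enhancer PCC %.3f (%d defined), error %.4f\n"),
              stats::median(x$cross_cell_pcc, na.rm = TRUE), x$n_defined_cc,
              stats::median(x$cross_enhancer_pcc, na.rm = TRUE), x$n_defined_ce,
              x$squared_error))
  invisible(x)
}

#' Per-enhancer DH-signal properties
#'
#' Three predictability covariates per enhancer: spread = number of samples
#' with DH > 0 (strict), variation = sample standard deviation of DH across
#' samples, specificity = number of distinct cell types with at least one
#' sample where DH > 2 (strict).
#'
#' @param O Enhancers x samples openness matrix.
#' @param cell_type_of_sample Named character vector mapping every sample id
#'   to a cell type; when NULL each sample is its own type (with a warning).
#' @return data.frame with columns `enhancer_id`, `spread`, `variation`,
#'   `specificity`.
#' @export
dh_properties <- function(O, cell_type_of_sample = NULL) {
  samples <- colnames(O)
  if (is.null(cell_type_of_sample)) {
    warning("no cell-type labels supplied; treating each sample as its own type")
    cell_type_of_sample <- stats::setNames(samples, samples)
  }
  unmapped <- setdiff(samples, names(cell_type_of_sample))
  if (length(unmapped)) {
    stop(sprintf("sample(s) without a cell type: %s", paste(unmapped, collapse = ", ")))
  }
  types <- cell_type_of_sample[samples]
  spread <- rowSums(O > 0)
  variation <- apply(O, 1, stats::sd)
  specificity <- apply(O, 1, function(row) {
    length(unique(types[row > 2]))
  })
  data.frame(enhancer_id = rownames(O), spread = as.integer(spread),
             variation = variation, specificity = as.integer(specificity),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter enhancers by predictability covariates
#'
#' Retains enhancers with spread strictly above `min_spread`, variation
#' strictly above the `variation_quantile`-quantile of the cohort's
#' variations, and specificity strictly above `min_specificity`. The
#' variation quantile is computed on the full input cohort before any other
#' filtering. Defaults: spread > 100 samples, variation above the lower
#' quartile, specificity > 10 cell types.
#'
#' @param props data.frame from [dh_properties()].
#' @param min_spread,min_specificity Strict lower bounds (defaults 100, 10).
#' @param variation_quantile Cohort quantile the variation must exceed
#'   (default 0.25).
#' @param strict Use strict inequalities (default TRUE).
#' @return Character vector of retained enhancer ids.
#' @export
filter_predictable <- function(props, min_spread = 100L,
                               variation_quantile = 0.25,
                               min_specificity = 10L, strict = TRUE) {
  if (nrow(props) == 0L) return(character(0))
  vq <- stats::quantile(props$variation, variation_quantile, names = FALSE)
  cmp <- if (strict) `>` else `>=`
  keep <- cmp(props$spread, min_spread) &
    cmp(props$variation, vq) &
    cmp(props$specificity, min_specificity)
  props$enhancer_id[keep]
}

#' Prediction accuracy stratified by DH properties
#'
#' Bins enhancers by each DH property, summarizes the per-bin median
#' cross-cell PCC, and reports the Spearman rank correlation (with p-value)
#' of each property with per-enhancer PCC. Enhancers with undefined PCC are
#' excluded.
#'
#' @param cross_cell_pcc Named per-enhancer PCC vector (NA = undefined).
#' @param props data.frame from [dh_properties()] on the same enhancers.
#' @param n_bins Number of quantile bins per property (default 4).
#' @return list with `bins` (per-property, per-bin medians and counts) and
#'   `spearman` (property, rho, p_value; NA when the correlation is
#'   undefined).
#' @export
stratified_performance <- function(cross_cell_pcc, props, n_bins = 4L) {
  props <- props[match(names(cross_cell_pcc), props$enhancer_id), , drop = FALSE]
  ok <- !is.na(cross_cell_pcc)
  pcc <- cross_cell_pcc[ok]
  props <- props[ok, , drop = FALSE]
  properties <- c("spread", "variation", "specificity")
  bins <- list(); rho <- numeric(0); pval <- numeric(0)
  for (pr in properties) {
    v <- props[[pr]]
    edges <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    grp <- if (length(edges) > 1) {
      cut(v, breaks = edges, include.lowest = TRUE)
    } else {
      factor(rep("all", length(v)))
    }
    bins[[pr]] <- data.frame(
      bin = levels(grp),
      n = as.integer(table(grp)),
      median_pcc = as.numeric(tapply(pcc, grp, stats::median)),
      stringsAsFactors = FALSE)
    if (length(unique(v)) > 1 && length(v) > 2) {
      ct <- suppressWarnings(stats::cor.test(v, pcc, method = "spearman"))
      rho[pr] <- unname(ct$estimate); pval[pr] <- ct$p.value
    } else {
      rho[pr] <- NA_real_; pval[pr] <- NA_real_
    }
  }
  list(bins = bins,
       spearman = data.frame(property = properties, rho = unname(rho[properties]),
                             p_value = unname(pval[properties]),
                             stringsAsFactors = FALSE))
}

#' Leave-one-out evaluation driver
#'
#' For each sample, refits all enhancer models on the remaining samples and
#' predicts the held-out one; predictions are pooled into a matrix and
#' evaluated with [evaluate_predictions()]. This is the protocol behind the
#' cross-validated benchmark comparisons; it refits M models N times, so use
#' it at moderate problem sizes.
#'
#' @inheritParams fit_all
#' @return list with `predictions` (enhancers x samples) and `evaluation`
#'   (an `evaluation_result`).
#' @export
evaluate_loo <- function(network, expr, openness, method = "elastic_net",
                         lambda = "cv", gamma_T = 1, gamma_G = 1,
                         feature_mode = "TFandTG", seed = 1L,
                         preprocess = "auto") {
  common <- intersect(colnames(expr), colnames(openness))
  expr <- expr[, common, drop = FALSE]
  openness <- openness[, common, drop = FALSE]
  pred <- NULL
  for (i in seq_along(common)) {
    fit <- fit_all(network, expr[, -i, drop = FALSE], openness[, -i, drop = FALSE],
                   method = method, lambda = lambda, gamma_T = gamma_T,
                   gamma_G = gamma_G, feature_mode = feature_mode, seed = seed,
                   preprocess = preprocess)
    p <- predict(fit, expr[, i, drop = FALSE])
    if (is.null(pred)) {
      pred <- matrix(NA_real_, nrow = nrow(p), ncol = length(common),
                     dimnames = list(rownames(p), common))
    }
    pred[rownames(p), i] <- p[, 1]
  }
  keep <- rownames(pred)[rowSums(is.na(pred)) == 0]
  pred <- pred[keep, , drop = FALSE]
  list(predictions = pred,
       evaluation = evaluate_predictions(openness[keep, , drop = FALSE], pred))
}

#' Write the per-enhancer evaluation report
#'
#' @param eval_result An `evaluation_result`.
#' @param props data.frame from [dh_properties()].
#' @param retained Character vector of ids kept by [filter_predictable()].
#' @param path Output TSV path.
#' @return The report data.frame, invisibly written to `path` when given.
#' @export
evaluation_report <- function(eval_result, props, retained = character(0),
                              path = NULL) {
  df <- data.frame(
    enhancer_id = names(eval_result$cross_cell_pcc),
    cross_cell_pcc = unname(eval_result$cross_cell_pcc),
    stringsAsFactors = FALSE)
  df <- merge(df, props, by = "enhancer_id", all.x = TRUE, sort = FALSE)
  df$retained <- df$enhancer_id %in% retained
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
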