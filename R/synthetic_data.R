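# Synthetic inputs with known ground truth.
#
# The generators emulate the structure of the pipeline's real inputs: a
# prior network of enhancers with target genes and binding TFs, paired
# expression/openness training data across cell types, control/treated
# perturbation expression for one drug and cell line, and an eQTL-style
# variant table. Every stage is deterministic given (parameters, seed), and
# the returned ground truth is sufficient to score model recovery,
# differential calling, and annotation without re-reading generator
# internals.
#
# Scale conventions (documented in the methods vignette): expression is
# log2-like — per-gene baseline ~ U(2, 10), cell-type effect ~ N(0, 0.7),
# within-type noise ~ N(0, 1). Planted openness is the linear model
#   raw = b0 + sum_j w_j (x_j - xbar_j)
# with coefficients w ~ +/- U(0.5, 1.5); b0 = 2.5 x sd(raw - b0) keeps
# truncation at zero rare while leaving fold changes detectable.

.TYPE_EFFECT_SD <- 0.7
.WITHIN_NOISE_SD <- 1.0
.INTERCEPT_SD_MULT <- 2.5

# Deterministic slicing of a shuffled, recycled pool: members are disjoint
# across enhancers whenever the universe is large enough, and reuse is
# spread evenly otherwise.
.sample_member_sets <- function(universe, n_sets, per_set) {
  need <- n_sets * per_set
  pool <- character(0)
  while (length(pool) < need) pool <- c(pool, sample(universe))
  lapply(seq_len(n_sets), function(i) {
    sort(pool[((i - 1) * per_set + 1):(i * per_set)])
  })
}

#' Generate a synthetic regulatory network
#'
#' Places non-overlapping enhancer intervals on one toy chromosome and
#' assigns each enhancer `genes_per_enhancer` target genes and
#' `tfs_per_enhancer` binding TFs (disjoint across enhancers when the
#' universes are large enough). One binding-site interval per (enhancer, TF)
#' pair is emitted inside the enhancer, so rebuilding the TF-enhancer
#' network from the sites reproduces the planted TF sets.
#'
#' @param n_enhancers,n_genes,n_tfs Universe sizes.
#' @param genes_per_enhancer,tfs_per_enhancer Set sizes per enhancer (both
#'   `>= 2`).
#' @param genome_length Length of the toy chromosome in bp.
#' @param seed Integer seed.
#' @return list with `network` (a `regulatory_network`), `tf_sites`
#'   (BED4-style data.frame), and `association_table`.
#' @export
generate_network <- function(n_enhancers = 100L, n_genes = 400L, n_tfs = 30L,
                             genes_per_enhancer = 3L, tfs_per_enhancer = 3L,
                             genome_length = 1e7, seed = 1L) {
  if (genes_per_enhancer < 2L || tfs_per_enhancer < 2L) {
    stop("genes_per_enhancer and tfs_per_enhancer must both be >= 2")
  }
  set.seed(seed)
  widths <- round(stats::runif(n_enhancers, 1000, 5000))
  if (sum(widths) + n_enhancers * 200 > genome_length) {
    stop("cannot pack enhancers into genome_length without overlap")
  }
  gaps <- stats::runif(n_enhancers)
  gaps <- gaps / sum(gaps) * (genome_length - sum(widths) - 200 * n_enhancers)
  starts <- cumsum(c(0, widths[-n_enhancers])) +
    cumsum(round(gaps) + 200)
  enh <- data.frame(
    enhancer_id = sprintf("enh%03d", seq_len(n_enhancers)),
    chrom = "chrS",
    start = starts,
    end = starts + widths,
    stringsAsFactors = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  tfs <- sprintf("tf%03d", seq_len(n_tfs))
  tg_sets <- .sample_member_sets(genes, n_enhancers, genes_per_enhancer)
  tf_sets <- .sample_member_sets(tfs, n_enhancers, tfs_per_enhancer)
  names(tg_sets) <- names(tf_sets) <- enh$enhancer_id

  site_rows <- do.call(rbind, lapply(seq_len(n_enhancers), function(i) {
    w <- enh$end[i] - enh$start[i]
    site_start <- enh$start[i] + floor(stats::runif(tfs_per_enhancer, 0, w - 20))
    data.frame(chrom = "chrS", start = site_start, end = site_start + 15,
               name = tf_sets[[i]], stringsAsFactors = FALSE)
  }))
  rownames(site_rows) <- NULL
  network <- regulatory_network(enh, tg_sets, tf_sets)
  assoc <- data.frame(
    enhancer_id = rep(enh$enhancer_id, lengths(tg_sets)),
    chrom = rep(enh$chrom, lengths(tg_sets)),
    start = rep(enh$start, lengths(tg_sets)),
    end = rep(enh$end, lengths(tg_sets)),
    gene = unlist(tg_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(network = network, tf_sites = site_rows, association_table = assoc)
}

# Expression for all genes and TFs: baseline + cell-type block effect +
# within-type noise.
.simulate_expression <- function(feature_ids, baselines, type_of_sample,
                                 type_effects, within_sd) {
  n <- length(type_of_sample)
  vals <- matrix(stats::rnorm(length(feature_ids) * n, sd = within_sd),
                 nrow = length(feature_ids),
                 dimnames = list(feature_ids, names(type_of_sample)))
  vals <- vals + baselines[feature_ids]
  vals + type_effects[feature_ids, type_of_sample, drop = FALSE]
}

#' Generate paired expression/openness training data
#'
#' Expression follows a cell-type block model; openness is the planted
#' linear model of each enhancer's TF and TG expression (coefficients
#' `+/- U(0.5, 1.5)`, single intercept) plus Gaussian noise, truncated at
#' zero. At `noise_sd = 0` openness equals the planted linear map wherever
#' truncation does not bind (pre-truncation values are kept in the ground
#' truth).
#'
#' @param net A list from [generate_network()] (or a bare
#'   `regulatory_network`).
#' @param n_cells Number of paired samples (`>= 3`).
#' @param n_cell_types Number of cell types in the block structure.
#' @param noise_sd Openness noise standard deviation; interpreted relative
#'   to each enhancer's planted signal sd when `noise_relative = TRUE`
#'   (default, so 0.1 means 10% of signal sd).
#' @param noise_relative Interpret `noise_sd` as a fraction of per-enhancer
#'   signal sd (default TRUE).
#' @param seed Integer seed.
#' @return list with `expr` ((genes+TFs) x cells), `openness`
#'   (enhancers x cells), `cell_types` (named vector sample -> type), and
#'   `truth` (class `perd_truth`: planted coefficients, intercepts, feature
#'   means, per-enhancer noise sd, pre-truncation openness, expression
#'   baselines).
#' @export
generate_paired_training <- function(net, n_cells = 120L, n_cell_types = 10L,
                                     noise_sd = 0.1, noise_relative = TRUE,
                                     seed = 1L) {
  network <- if (inherits(net, "regulatory_network")) net else net$network
  if (n_cells < 3L) stop("n_cells must be >= 3")
  set.seed(seed)
  samples <- sprintf("cell%03d", seq_len(n_cells))
  types <- sprintf("type%02d", seq_len(n_cell_types))
  type_of_sample <- stats::setNames(
    sample(rep_len(types, n_cells)), samples)
  feats <- sort(unique(c(network$gene_universe, network$tf_universe)))
  baselines <- stats::setNames(stats::runif(length(feats), 2, 10), feats)
  type_effects <- matrix(stats::rnorm(length(feats) * n_cell_types,
                                      sd = .TYPE_EFFECT_SD),
                         nrow = length(feats),
                         dimnames = list(feats, types))
  expr <- .simulate_expression(feats, baselines, type_of_sample, type_effects,
                               .WITHIN_NOISE_SD)

  ids <- network$enhancers$enhancer_id
  coefficients <- list(); intercepts <- numeric(0)
  feature_means <- list(); enhancer_noise_sd <- numeric(0)
  raw <- matrix(0, nrow = length(ids), ncol = n_cells,
                dimnames = list(ids, samples))
  for (id in ids) {
    members <- c(paste0("TF:", network$binding_tfs[[id]]),
                 paste0("TG:", network$target_genes[[id]]))
    feat_genes <- sub("^T[FG]:", "", members)
    w <- stats::runif(length(members), 0.5, 1.5) *
      sample(c(-1, 1), length(members), replace = TRUE)
    names(w) <- members
    x <- expr[feat_genes, , drop = FALSE]
    mu <- rowMeans(x)
    centered <- drop(crossprod(x - mu, w))
    b0 <- .INTERCEPT_SD_MULT * stats::sd(centered)
    raw[id, ] <- b0 + centered
    sd_noise <- if (noise_relative) noise_sd * stats::sd(centered) else noise_sd
    coefficients[[id]] <- w
    intercepts[id] <- b0
    feature_means[[id]] <- stats::setNames(mu, members)
    enhancer_noise_sd[id] <- sd_noise
  }
  noise <- matrix(stats::rnorm(length(raw)), nrow = nrow(raw)) * enhancer_noise_sd
  openness <- pmax(raw + noise, 0)
  dimnames(openness) <- dimnames(raw)

  truth <- structure(list(
    coefficients = coefficients,
    intercepts = intercepts,
    feature_means = feature_means,
    noise_sd = enhancer_noise_sd,
    raw_openness = raw,
    expr_baselines = baselines,
    expr_grand_means = rowMeans(expr),
    within_noise_sd = .WITHIN_NOISE_SD
  ), class = "perd_truth")
  list(expr = expr, openness = openness, cell_types = type_of_sample,
       truth = truth)
}

#' Generate control/treated perturbation expression for one drug
#'
#' Emulates a perturbation experiment in a single cell line: control
#' expression sits at each gene's training-time mean (plus a fixed per-gene
#' context offset) with within-line noise of sd 1; in treated samples the
#' target genes of the designated responsive enhancers are shifted by
#' `effect_size * sign(beta_q)` expression units, so `effect_size` is the
#' per-gene shift in units of the expression noise sd and each responsive
#' enhancer's planted openness shifts by `effect_size * sum(|beta_q|)`.
#' Ground truth records the realized per-gene shifts and recomputes the
#' responsive enhancer set from them, so target genes shared between
#' enhancers are accounted for.
#'
#' @param net [generate_network()] result (or bare network).
#' @param truth `perd_truth` from [generate_paired_training()].
#' @param drug_name Drug label for the metadata.
#' @param n_control,n_treated Sample counts per condition.
#' @param effect_size Per-gene expression shift in noise-sd units
#'   (default 2; 0 gives a null experiment).
#' @param frac_responsive Fraction of enhancers designated responsive
#'   (in (0, 1)).
#' @param cell_line Cell-line label for the metadata.
#' @param seed Integer seed.
#' @return list with `expr_control`, `expr_treated`, `metadata`
#'   (sample_id/cell_line/drug/condition), and `truth` extended with
#'   `drug`, `responsive_enhancers`, `designated_responsive`,
#'   `perturbed_genes`, `gene_shifts`, `openness_shift`.
#' @export
generate_perturbation <- function(net, truth, drug_name = "drugA",
                                  n_control = 20L, n_treated = 20L,
                                  effect_size = 2, frac_responsive = 0.3,
                                  cell_line = "CL1", seed = 1L) {
  network <- if (inherits(net, "regulatory_network")) net else net$network
  if (frac_responsive <= 0 || frac_responsive >= 1) {
    stop("frac_responsive must lie in (0, 1)")
  }
  set.seed(seed)
  ids <- network$enhancers$enhancer_id
  n_resp <- max(1L, round(frac_responsive * length(ids)))
  designated <- sort(sample(ids, n_resp))

  feats <- names(truth$expr_grand_means)
  context_offset <- stats::setNames(stats::runif(length(feats), -0.5, 0.5), feats)
  control_means <- truth$expr_grand_means + context_offset

  gene_shifts <- stats::setNames(numeric(length(feats)), feats)
  for (id in designated) {
    w <- truth$coefficients[[id]]
    tg_members <- grep("^TG:", names(w), value = TRUE)
    tg_genes <- sub("^TG:", "", tg_members)
    gene_shifts[tg_genes] <- gene_shifts[tg_genes] +
      effect_size * sign(w[tg_members])
  }

  # realized openness shift per enhancer, from final gene shifts (covers
  # target genes shared between enhancers)
  openness_shift <- vapply(ids, function(id) {
    w <- truth$coefficients[[id]]
    sum(w * gene_shifts[sub("^T[FG]:", "", names(w))])
  }, numeric(1))
  responsive <- ids[abs(openness_shift) > 1e-12]

  sample_ids <- c(sprintf("%s_ctl%02d", drug_name, seq_len(n_control)),
                  sprintf("%s_trt%02d", drug_name, seq_len(n_treated)))
  condition <- c(rep("control", n_control), rep("treated", n_treated))
  simulate_block <- function(n, shifted) {
    means <- control_means + if (shifted) gene_shifts else 0
    means + matrix(stats::rnorm(length(feats) * n, sd = truth$within_noise_sd),
                   nrow = length(feats))
  }
  expr_control <- simulate_block(n_control, FALSE)
  expr_treated <- simulate_block(n_treated, TRUE)
  dimnames(expr_control) <- list(feats, sample_ids[condition == "control"])
  dimnames(expr_treated) <- list(feats, sample_ids[condition == "treated"])

  metadata <- data.frame(
    sample_id = sample_ids, cell_line = cell_line,
    drug = ifelse(condition == "treated", drug_name, ""),
    condition = condition, stringsAsFactors = FALSE)

  truth$drug <- drug_name
  truth$designated_responsive <- designated
  truth$responsive_enhancers <- responsive
  truth$perturbed_genes <- sort(names(gene_shifts)[gene_shifts != 0])
  truth$gene_shifts <- gene_shifts[gene_shifts != 0]
  truth$openness_shift <- openness_shift
  list(expr_control = expr_control, expr_treated = expr_treated,
       metadata = metadata, truth = truth)
}

#' Generate an eQTL-style variant table with planted consistent variants
#'
#' Plants one significant variant inside each responsive enhancer, with its
#' associated gene drawn from that enhancer's perturbed target genes (so the
#' full evidence chain holds by construction), then adds three flavours of
#' decoy: significant variants outside every enhancer (associated with
#' perturbed genes — the gene-linked tier), significant variants inside
#' responsive enhancers but associated with unperturbed genes, and
#' non-significant variants (`q >= 0.05`) inside responsive enhancers with
#' perturbed genes.
#'
#' @param net [generate_network()] result (or bare network).
#' @param truth Perturbation-extended `perd_truth`.
#' @param n_decoys Total decoy count (split across the three flavours).
#' @param seed Integer seed.
#' @return list with `variants` (data.frame: variant_id, chrom, pos, gene,
#'   qvalue) and `planted` (data.frame of the planted consistent
#'   variant/gene/enhancer triples).
#' @export
generate_variant_table <- function(net, truth, n_decoys = 30L, seed = 1L) {
  network <- if (inherits(net, "regulatory_network")) net else net$network
  if (is.null(truth$responsive_enhancers)) {
    stop("truth lacks perturbation fields; run generate_perturbation first")
  }
  set.seed(seed)
  enh <- network$enhancers
  resp <- truth$responsive_enhancers
  rows <- list(); planted <- list(); k <- 0L
  next_id <- function() { k <<- k + 1L; sprintf("var%04d", k) }

  for (id in resp) {
    e <- enh[enh$enhancer_id == id, ]
    tg <- network$target_genes[[id]]
    ptg <- intersect(tg, truth$perturbed_genes)
    if (length(ptg) == 0L) next
    pos <- sample((e$start + 1):e$end, 1L)  # 1-based position inside
    vid <- next_id()
    gene <- if (length(ptg) == 1L) ptg else sample(ptg, 1L)
    rows[[vid]] <- data.frame(variant_id = vid, chrom = e$chrom, pos = pos,
                              gene = gene,
                              qvalue = stats::runif(1, 0.001, 0.04),
                              stringsAsFactors = FALSE)
    planted[[vid]] <- data.frame(variant_id = vid, gene = gene,
                                 enhancer_id = id, stringsAsFactors = FALSE)
  }

  outside_positions <- function(n) {
    # midpoints of inter-enhancer gaps are guaranteed outside all enhancers
    gaps_start <- c(1, enh$end + 50)
    gaps_end <- c(enh$start - 50, max(enh$end) + 5000)
    ok <- gaps_end > gaps_start
    idx <- sample(which(ok), n, replace = TRUE)
    vapply(idx, function(i) sample(gaps_start[i]:gaps_end[i], 1L), numeric(1))
  }
  n_each <- ceiling(n_decoys / 3)
  # (a) outside any enhancer, perturbed gene, significant
  if (length(truth$perturbed_genes)) {
    for (pos in outside_positions(n_each)) {
      vid <- next_id()
      rows[[vid]] <- data.frame(variant_id = vid, chrom = "chrS", pos = pos,
                                gene = sample(truth$perturbed_genes, 1L),
                                qvalue = stats::runif(1, 0.001, 0.04),
                                stringsAsFactors = FALSE)
    }
  }
  unperturbed <- setdiff(network$gene_universe, truth$perturbed_genes)
  inside_resp_pos <- function() {
    id <- if (length(resp) == 1L) resp else sample(resp, 1L)
    e <- enh[enh$enhancer_id == id, ]
    sample((e$start + 1):e$end, 1L)
  }
  # (b) inside a responsive enhancer, unperturbed gene, significant
  if (length(unperturbed)) {
    for (i in seq_len(n_each)) {
      vid <- next_id()
      rows[[vid]] <- data.frame(variant_id = vid, chrom = "chrS",
                                pos = inside_resp_pos(),
                                gene = sample(unperturbed, 1L),
                                qvalue = stats::runif(1, 0.001, 0.04),
                                stringsAsFactors = FALSE)
    }
  }
  # (c) inside, perturbed gene, but q >= 0.05
  if (length(truth$perturbed_genes)) {
    for (i in seq_len(n_decoys - 2 * n_each)) {
      vid <- next_id()
      rows[[vid]] <- data.frame(variant_id = vid, chrom = "chrS",
                                pos = inside_resp_pos(),
                                gene = sample(truth$perturbed_genes, 1L),
                                qvalue = stats::runif(1, 0.05, 1),
                                stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(variant_id = character(0), gene = character(0),
               enhancer_id = character(0))
  rownames(planted) <- NULL
  list(variants = variants, planted = planted)
}

#' Write a complete simulated dataset to a directory
#'
#' Runs the generators at one of three presets and writes every file in the
#' formats the rest of the pipeline reads, plus a `truth.json` manifest of
#' the ground truth (coefficients, responsive enhancers, perturbed genes,
#' planted variant triples).
#'
#' @param dir Output directory.
#' @param preset `"training"` (network + paired data), `"perturbation"`
#'   (training plus one drug block), or `"full"` (perturbation plus
#'   variants and motif sites).
#' @param seed Integer seed; stage seeds are derived from it.
#' @param n_enhancers,n_cells,n_control,n_treated,effect_size,frac_responsive
#'   Key sizes forwarded to the generators.
#' @return Invisibly, a list of the generated in-memory objects.
#' @export
write_simulation <- function(dir, preset = c("full", "training", "perturbation"),
                             seed = 1L, n_enhancers = 100L, n_cells = 120L,
                             n_control = 20L, n_treated = 20L,
                             effect_size = 2, frac_responsive = 0.3) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_network(n_enhancers = n_enhancers, seed = seed)
  utils::write.table(gen$association_table, file.path(dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(gen$tf_sites, file.path(dir, "tf_sites.bed"))
  train <- generate_paired_training(gen, n_cells = n_cells, seed = seed + 1L)
  write_matrix_tsv(train$expr, file.path(dir, "expr_train.tsv"), "gene")
  write_matrix_tsv(train$openness, file.path(dir, "openness_train.tsv"), "enhancer")
  utils::write.table(
    data.frame(sample_id = names(train$cell_types),
               cell_type = unname(train$cell_types)),
    file.path(dir, "cell_types.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(network = gen, training = train)

  truth_json <- list(
    coefficients = lapply(train$truth$coefficients, as.list),
    intercepts = as.list(train$truth$intercepts)
  )
  if (preset %in% c("perturbation", "full")) {
    pert <- generate_perturbation(gen, train$truth, n_control = n_control,
                                  n_treated = n_treated,
                                  effect_size = effect_size,
                                  frac_responsive = frac_responsive,
                                  seed = seed + 2L)
    write_matrix_tsv(pert$expr_control, file.path(dir, "expr_control.tsv"), "gene")
    write_matrix_tsv(pert$expr_treated, file.path(dir, "expr_treated.tsv"), "gene")
    utils::write.table(pert$metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth_json$responsive_enhancers <- pert$truth$responsive_enhancers
    truth_json$perturbed_genes <- pert$truth$perturbed_genes
    out$perturbation <- pert
  }
  if (preset == "full") {
    vt <- generate_variant_table(gen, out$perturbation$truth, seed = seed + 3L)
    utils::write.table(vt$variants, file.path(dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # motif sites: reuse the TF binding-site intervals under motif names
    motif <- gen$tf_sites
    motif$name <- paste0(motif$name, "_motif")
    write_bed(motif, file.path(dir, "motif_sites.bed"))
    truth_json$planted_variants <- vt$planted
    out$variants <- vt
  }
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
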