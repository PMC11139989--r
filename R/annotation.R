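# Evidence chain for called diffEnhancers: motif sites overlapping them,
# target genes that are also drug-perturbed, and regulatory variants whose
# position falls inside them. A variant is "consistent" when its associated
# gene is both a target gene of the enhancer and a drug-perturbed gene.

# diffEnhancer ids -> coordinate data.frame rows of the network
.enhancer_coords <- function(network, enhancer_ids) {
  enh <- network$enhancers
  missing_ids <- setdiff(enhancer_ids, enh$enhancer_id)
  if (length(missing_ids)) {
    stop(sprintf("enhancer id(s) not in network: %s", paste(missing_ids, collapse = ", ")))
  }
  out <- enh[match(enhancer_ids, enh$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count motif sites overlapping each diffEnhancer
#'
#' @param network A `regulatory_network` carrying enhancer coordinates.
#' @param diff_enhancers Character vector of called enhancer ids.
#' @param motif_sites data.frame with `chrom`, `start`, `end`, `name` (motif
#'   identifier; BED4 as read by [read_bed()]).
#' @return data.frame with `enhancer_id`, `motif_count`, and a `motifs`
#'   list-column of overlapping motif names; enhancers with zero hits are
#'   still reported.
#' @export
annotate_motifs <- function(network, diff_enhancers, motif_sites) {
  coords <- .enhancer_coords(network, diff_enhancers)
  hits <- bulk_overlap(coords, motif_sites)
  motifs <- replicate(length(diff_enhancers), character(0), simplify = FALSE)
  names(motifs) <- diff_enhancers
  if (nrow(hits) > 0L) {
    by_enh <- split(motif_sites$name[hits$subject_idx],
                    diff_enhancers[hits$query_idx])
    for (id in names(by_enh)) motifs[[id]] <- sort(by_enh[[id]])
  }
  out <- data.frame(enhancer_id = diff_enhancers,
                    motif_count = lengths(motifs),
                    stringsAsFactors = FALSE)
  out$motifs <- unname(motifs)
  out
}

#' Target genes of diffEnhancers that are drug-perturbed
#'
#' Intersects each called enhancer's associated gene set with the
#' drug-perturbed gene set.
#'
#' @param network A `regulatory_network`.
#' @param diff_enhancers Character vector of called enhancer ids.
#' @param perturbed_genes Character vector from
#'   [call_perturbed_genes()].
#' @return Named list (by enhancer id) of concordant gene vectors.
#' @export
concordant_perturbed_genes <- function(network, diff_enhancers, perturbed_genes) {
  .enhancer_coords(network, diff_enhancers)  # validates ids
  out <- lapply(diff_enhancers, function(id) {
    sort(intersect(network$target_genes[[id]], perturbed_genes))
  })
  stats::setNames(out, diff_enhancers)
}

#' Significant variants located inside diffEnhancers
#'
#' Keeps variants with q-value strictly below `q_threshold`, then assigns
#' each to every called enhancer whose (0-based half-open) interval contains
#' its 1-based position — i.e. the position lies within the printed
#' 1-based inclusive enhancer range.
#'
#' @param network A `regulatory_network`.
#' @param diff_enhancers Character vector of called enhancer ids.
#' @param variants data.frame with `variant_id`, `chrom`, `pos` (1-based),
#'   `gene`, `qvalue` (see [read_variant_table()]).
#' @param q_threshold Strict significance cutoff (default 0.05).
#' @return Named list (by enhancer id) of variant data.frames.
#' @export
variants_in_enhancers <- function(network, diff_enhancers, variants,
                                  q_threshold = 0.05) {
  coords <- .enhancer_coords(network, diff_enhancers)
  variants <- variants[variants$qvalue < q_threshold, , drop = FALSE]
  out <- stats::setNames(
    replicate(length(diff_enhancers), variants[0, , drop = FALSE], simplify = FALSE),
    diff_enhancers)
  if (nrow(variants) > 0L && length(diff_enhancers) > 0L) {
    # 1-based point as a 0-based half-open interval of width 1
    vq <- data.frame(chrom = variants$chrom, start = variants$pos - 1,
                     end = variants$pos)
    hits <- bulk_overlap(vq, coords)
    if (nrow(hits) > 0L) {
      by_enh <- split(hits$query_idx, diff_enhancers[hits$subject_idx])
      for (id in names(by_enh)) {
        v <- variants[by_enh[[id]], , drop = FALSE]
        out[[id]] <- v[order(v$variant_id), , drop = FALSE]
      }
    }
  }
  out
}

#' Assemble the full evidence chain for called diffEnhancers
#'
#' Composes motif overlap, perturbed-gene concordance, and
#' variant-in-enhancer annotation for one (drug, cell line) context. A
#' variant is *consistent* when its associated gene is both a target gene of
#' the enhancer and drug-perturbed. Variants passing the q filter whose gene
#' is perturbed but which lie outside every called enhancer are reported
#' separately in a gene-linked tier (gene-body pharmacogenomic variants).
#'
#' @param network A `regulatory_network`.
#' @param diff_enhancers Character vector of called enhancer ids.
#' @param perturbed_genes Character vector of drug-perturbed genes.
#' @param variants Variant data.frame (see [read_variant_table()]).
#' @param motif_sites Optional motif-site data.frame (`chrom`, `start`,
#'   `end`, `name`); NULL for no motif annotation.
#' @param q_threshold Strict variant q-value cutoff (default 0.05).
#' @return list with `records` (per-enhancer data.frame: `enhancer_id`,
#'   `motif_count`, list-columns `concordant_genes`, `variant_ids`,
#'   `consistent_variant_ids`), `gene_linked` (variants matched by perturbed
#'   gene outside enhancers), and `summary` (drug-level tallies).
#' @export
build_evidence_chain <- function(network, diff_enhancers, perturbed_genes,
                                 variants, motif_sites = NULL,
                                 q_threshold = 0.05) {
  conc <- concordant_perturbed_genes(network, diff_enhancers, perturbed_genes)
  vin <- variants_in_enhancers(network, diff_enhancers, variants, q_threshold)
  motif_count <- rep(NA_integer_, length(diff_enhancers))
  motifs <- NULL
  if (!is.null(motif_sites)) {
    mm <- annotate_motifs(network, diff_enhancers, motif_sites)
    motif_count <- mm$motif_count
    motifs <- mm$motifs
  }
  consistent <- lapply(diff_enhancers, function(id) {
    v <- vin[[id]]
    v[v$gene %in% conc[[id]], , drop = FALSE]
  })
  names(consistent) <- diff_enhancers

  records <- data.frame(enhancer_id = diff_enhancers,
                        motif_count = motif_count,
                        stringsAsFactors = FALSE)
  records$concordant_genes <- unname(conc)
  records$variant_ids <- unname(lapply(vin, function(v) v$variant_id))
  records$consistent_variant_ids <- unname(lapply(consistent, function(v) v$variant_id))
  if (!is.null(motifs)) records$motifs <- motifs

  sig <- variants[variants$qvalue < q_threshold, , drop = FALSE]
  in_any <- unique(unlist(lapply(vin, function(v) v$variant_id)))
  gene_linked <- sig[sig$gene %in% perturbed_genes &
                       !(sig$variant_id %in% in_any), , drop = FALSE]
  rownames(gene_linked) <- NULL

  summary <- data.frame(
    n_diff_enhancers = length(diff_enhancers),
    n_with_motif = if (is.null(motifs)) NA_integer_ else sum(motif_count > 0),
    n_with_concordant_gene = sum(lengths(conc) > 0),
    n_with_variant = sum(vapply(vin, nrow, integer(1)) > 0),
    n_with_consistent_variant = sum(vapply(consistent, nrow, integer(1)) > 0))
  list(records = records, gene_linked = gene_linked, summary = summary)
}

#' Write an evidence-chain annotation table
#'
#' Flattens the list-columns of [build_evidence_chain()] records to
#' comma-separated strings and writes a TSV.
#'
#' @param chain Result of [build_evidence_chain()].
#' @param path Output TSV path.
#' @export
write_annotation_table <- function(chain, path) {
  rec <- chain$records
  flat <- data.frame(
    enhancer_id = rec$enhancer_id,
    motif_count = rec$motif_count,
    concordant_genes = vapply(rec$concordant_genes, paste, "", collapse = ","),
    variant_ids = vapply(rec$variant_ids, paste, "", collapse = ","),
    consistent_variant_ids = vapply(rec$consistent_variant_ids, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
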