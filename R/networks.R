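# Prior regulatory networks: enhancer -> target genes (from a curated
# association table) and TF -> enhancer (from binding-site intervals).

#' Construct a regulatory network object
#'
#' @param enhancers data.frame with columns `enhancer_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param target_genes Named list (by enhancer_id) of character vectors: each
#'   enhancer's associated gene set.
#' @param binding_tfs Named list (by enhancer_id) of character vectors: each
#'   enhancer's binding TF set.
#' @return An object of class `regulatory_network` with fields `enhancers`,
#'   `target_genes`, `binding_tfs`, `gene_universe`, `tf_universe`.
#' @export
regulatory_network <- function(enhancers, target_genes, binding_tfs = NULL) {
  stopifnot(all(c("enhancer_id", "chrom", "start", "end") %in% names(enhancers)))
  if (anyDuplicated(enhancers$enhancer_id)) stop("enhancer_id must be unique")
  ids <- enhancers$enhancer_id
  if (is.null(binding_tfs)) {
    binding_tfs <- stats::setNames(replicate(length(ids), character(0), simplify = FALSE), ids)
  }
  target_genes <- target_genes[ids]
  names(target_genes) <- ids
  target_genes <- lapply(target_genes, function(g) sort(unique(as.character(g))))
  binding_tfs <- binding_tfs[ids]
  names(binding_tfs) <- ids
  binding_tfs <- lapply(binding_tfs, function(t) {
    if (is.null(t)) character(0) else sort(unique(as.character(t)))
  })
  structure(list(
    enhancers = enhancers,
    target_genes = target_genes,
    binding_tfs = binding_tfs,
    gene_universe = sort(unique(unlist(target_genes, use.names = FALSE))),
    tf_universe = sort(unique(unlist(binding_tfs, use.names = FALSE)))
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d enhancers, %d genes, %d TFs\n",
              nrow(x$enhancers), length(x$gene_universe), length(x$tf_universe)))
  cat(sprintf("  median |E_G| = %s, median |E_T| = %s\n",
              stats::median(lengths(x$target_genes)),
              stats::median(lengths(x$binding_tfs))))
  invisible(x)
}

#' Build the enhancer-gene network from an association table
#'
#' One record per distinct enhancer id; its gene set is the union of all
#' listed genes (duplicate rows collapse). The same enhancer id appearing
#' with two different intervals is a hard error — coordinates are part of the
#' enhancer's identity.
#'
#' @param association_table data.frame with columns `enhancer_id`, `chrom`,
#'   `start`, `end`, `gene` (coordinates 0-based half-open), or a path to
#'   such a TSV.
#' @return A [regulatory_network()] with empty TF sets.
#' @export
build_enhancer_gene_network <- function(association_table) {
  if (is.character(association_table)) {
    association_table <- utils::read.delim(association_table, stringsAsFactors = FALSE)
  }
  df <- association_table
  need <- c("enhancer_id", "chrom", "start", "end", "gene")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("association table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(df$start < 0 | df$end <= df$start)) {
    stop("invalid enhancer coordinates (need start >= 0, end > start)")
  }
  coords <- unique(df[c("enhancer_id", "chrom", "start", "end")])
  if (anyDuplicated(coords$enhancer_id)) {
    bad <- coords$enhancer_id[duplicated(coords$enhancer_id)][1]
    stop(sprintf("conflicting coordinates for enhancer '%s'", bad))
  }
  genes <- split(as.character(df$gene), df$enhancer_id)
  coords <- coords[order(match(coords$enhancer_id, unique(df$enhancer_id))), , drop = FALSE]
  rownames(coords) <- NULL
  regulatory_network(coords, genes[coords$enhancer_id])
}

#' Attach TFs to enhancers from binding-site intervals
#'
#' A TF is associated with an enhancer when at least one of its binding-site
#' intervals overlaps the enhancer region; multiple sites of one TF inside
#' one enhancer count once. `mode = "containment"` requires the site to lie
#' fully inside the enhancer instead (stricter reading of "located in").
#'
#' @param network A `regulatory_network`.
#' @param tf_sites data.frame with columns `chrom`, `start`, `end`, `name`
#'   (TF symbol; BED4 as read by [read_bed()]).
#' @param mode `"overlap"` (any >= 1 bp overlap, default) or `"containment"`.
#' @return The network with `binding_tfs` replaced by the derived sets.
#' @export
build_tf_enhancer_network <- function(network, tf_sites, mode = c("overlap", "containment")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "regulatory_network"))
  enh <- network$enhancers
  tfs_by_enh <- stats::setNames(
    replicate(nrow(enh), character(0), simplify = FALSE), enh$enhancer_id)
  if (nrow(tf_sites) > 0L) {
    hits <- bulk_overlap(enh, tf_sites)
    if (mode == "containment" && nrow(hits) > 0L) {
      keep <- tf_sites$start[hits$subject_idx] >= enh$start[hits$query_idx] &
        tf_sites$end[hits$subject_idx] <= enh$end[hits$query_idx]
      hits <- hits[keep, , drop = FALSE]
    }
    if (nrow(hits) > 0L) {
      assoc <- split(tf_sites$name[hits$subject_idx], enh$enhancer_id[hits$query_idx])
      for (id in names(assoc)) tfs_by_enh[[id]] <- sort(unique(assoc[[id]]))
    }
  }
  regulatory_network(enh, network$target_genes, tfs_by_enh)
}

#' Keep enhancers with enough associated genes and binding TFs
#'
#' Retains enhancers with `|E_G| >= min_genes` and `|E_T| >= min_tfs`
#' (at-least-two defaults). Both thresholds are parameters so a strict
#' greater-than reading is one increment away.
#'
#' @param network A `regulatory_network`.
#' @param min_genes,min_tfs Minimum set sizes, both `>= 1`; defaults 2.
#' @return The filtered network; the number of removed enhancers is reported
#'   via `message()`.
#' @export
filter_by_degree <- function(network, min_genes = 2L, min_tfs = 2L) {
  stopifnot(inherits(network, "regulatory_network"), min_genes >= 1L, min_tfs >= 1L)
  keep <- lengths(network$target_genes) >= min_genes &
    lengths(network$binding_tfs) >= min_tfs
  removed <- sum(!keep)
  message(sprintf("filter_by_degree: removed %d of %d enhancers (|E_G| >= %d, |E_T| >= %d)",
                  removed, length(keep), min_genes, min_tfs))
  enh <- network$enhancers[keep, , drop = FALSE]
  rownames(enh) <- NULL
  regulatory_network(enh,
                     network$target_genes[keep],
                     network$binding_tfs[keep])
}

#' Export the network as an edge list
#'
#' @param network A `regulatory_network`.
#' @param path Optional TSV path; when given the edge list is written there.
#' @return data.frame with columns `enhancer_id`, `partner`, `role`
#'   (`"TF"` or `"TG"`).
#' @export
network_edge_list <- function(network, path = NULL) {
  stopifnot(inherits(network, "regulatory_network"))
  ids <- network$enhancers$enhancer_id
  tg <- data.frame(
    enhancer_id = rep(ids, lengths(network$target_genes)),
    partner = unlist(network$target_genes, use.names = FALSE),
    role = "TG", stringsAsFactors = FALSE)
  tf <- data.frame(
    enhancer_id = rep(ids, lengths(network$binding_tfs)),
    partner = unlist(network$binding_tfs, use.names = FALSE),
    role = "TF", stringsAsFactors = FALSE)
  out <- rbind(tf, tg)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write a network's association table
#'
#' Inverse of [build_enhancer_gene_network()] plus a BED4 file of TF sites is
#' not recoverable; this writes the gene association TSV only.
#'
#' @param network A `regulatory_network`.
#' @param path Output TSV path.
#' @export
write_association_table <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  enh <- network$enhancers
  n_genes <- lengths(network$target_genes)
  out <- data.frame(
    enhancer_id = rep(enh$enhancer_id, n_genes),
    chrom = rep(enh$chrom, n_genes),
    start = rep(enh$start, n_genes),
    end = rep(enh$end, n_genes),
    gene = unlist(network$target_genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
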