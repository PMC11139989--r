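# Interval arithmetic and on-disk formats.
#
# All intervals are stored 0-based half-open (BED-native). Coordinates that
# arrive as human-readable text ("chr12:12713282-12727320") are treated as
# 1-based inclusive and converted on parse, so printed coordinates round-trip.

#' Construct a genomic interval
#'
#' Intervals are stored 0-based half-open: `start` is the 0-based position of
#' the first base, `end` is one past the last base. This matches BED and lets
#' abutting intervals (end == start of the next) be non-overlapping.
#'
#' @param chrom Chromosome name (non-empty string; treated as an opaque label,
#'   no assembly is assumed).
#' @param start 0-based inclusive start, `>= 0`.
#' @param end Exclusive end, `> start`.
#' @return An object of class `genomic_interval` with fields `chrom`, `start`,
#'   `end`.
#' @examples
#' genomic_interval("chr1", 100, 200)
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) || !nzchar(chrom)) {
    stop("'chrom' must be a non-empty string")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("'start' and 'end' must be single non-missing numbers")
  }
  if (start < 0) stop("'start' must be >= 0")
  if (end <= start) stop("'end' must be > 'start'")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s\n", format_text_coordinate(x)))
  invisible(x)
}

#' Parse a printed genomic coordinate
#'
#' Accepts the loose formats coordinates are printed in:
#' `"chr12:12713282-12727320"` or `"chr20: 44, 640, 672-44, 653, 156"` —
#' hyphen or en-dash separators, optional spaces and thousands commas. The
#' text range is read as 1-based inclusive and converted to the internal
#' 0-based half-open convention, i.e. `chrN:a-b` becomes `[a-1, b)`.
#'
#' @param s A single coordinate string.
#' @return A [genomic_interval()].
#' @examples
#' parse_text_coordinate("chr12:12713282-12727320")
#' @export
parse_text_coordinate <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop("coordinate must be a single string")
  }
  x <- gsub("[ ,]", "", s)
  # en-dash (U+2013) and minus (U+2212) are accepted alongside ASCII hyphen
  x <- gsub("\u2013|\u2212", "-", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse coordinate string '%s' (expected chrom:start-end)", s))
  }
  start1 <- as.numeric(m[3])
  end1 <- as.numeric(m[4])
  if (start1 < 1 || end1 < start1) {
    stop(sprintf("invalid 1-based range in '%s'", s))
  }
  genomic_interval(m[2], start1 - 1, end1)
}

#' Format an interval as a 1-based inclusive coordinate string
#'
#' Inverse of [parse_text_coordinate()]: an interval parsed from text formats
#' back to the same (normalized) coordinate string.
#'
#' @param iv A `genomic_interval`.
#' @return A string `"chrom:start-end"` with 1-based inclusive positions.
#' @export
format_text_coordinate <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  sprintf("%s:%d-%d", iv$chrom, as.integer(iv$start) + 1L, as.integer(iv$end))
}

#' Read a BED3/BED4 file
#'
#' Native BED semantics: 0-based half-open, tab-separated, `track`/`browser`
#' and `#` comment lines skipped, input order preserved. Column 4, when
#' present, is the feature name (else a `feature_<i>` placeholder).
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  out_chrom <- character(0); out_start <- numeric(0)
  out_end <- numeric(0); out_name <- character(0)
  kept <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (grepl("^(track|browser|#)", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("line %d: expected >= 3 tab-separated columns", i))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("line %d: non-integer coordinate", i))
    }
    if (start < 0) stop(sprintf("line %d: start < 0", i))
    if (end <= start) stop(sprintf("end <= start at line %d", i))
    kept <- kept + 1L
    out_chrom[kept] <- f[1]
    out_start[kept] <- start
    out_end[kept] <- end
    out_name[kept] <- if (length(f) >= 4L && nzchar(f[4])) f[4] else sprintf("feature_%d", kept)
  }
  data.frame(chrom = out_chrom, start = out_start, end = out_end,
             name = out_name, stringsAsFactors = FALSE)
}

#' Write intervals as BED4
#'
#' @param df data.frame with `chrom`, `start`, `end`, `name` (0-based
#'   half-open).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                       as.integer(df$end), df$name), con)
  }
  invisible(path)
}

#' Read a numeric matrix from TSV or GCT 1.2
#'
#' TSV layout: header row of sample ids, row ids in column 1. GCT 1.2 layout:
#' `#1.2` version line, a `rows<TAB>cols` dimension line, then a table whose
#' first two columns are NAME and Description. Missing values (`NA`, empty
#' cells) are kept as `NA`, never zero-filled; model fitting rejects them
#' explicitly downstream.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`; default guesses from the extension.
#' @return Numeric matrix with unique rownames (features) and colnames
#'   (samples).
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3L || !grepl("^#1\\.2", lines[[1]])) {
      stop("not a GCT 1.2 file (missing '#1.2' header)")
    }
    dims <- as.integer(strsplit(lines[[2]], "\t", fixed = TRUE)[[1]][1:2])
    body <- lines[-(1:2)]
    mat <- .parse_matrix_lines(body, id_cols = 2L)
    if (!is.na(dims[1]) && nrow(mat) != dims[1]) {
      stop(sprintf("GCT declares %d rows but body has %d", dims[1], nrow(mat)))
    }
    if (!is.na(dims[2]) && ncol(mat) != dims[2]) {
      stop(sprintf("GCT declares %d columns but body has %d", dims[2], ncol(mat)))
    }
    mat
  } else {
    .parse_matrix_lines(lines, id_cols = 1L)
  }
}

# Shared TSV-body parser: first row is the header, `id_cols` leading columns
# are identifiers (row id first), the rest numeric.
.parse_matrix_lines <- function(lines, id_cols) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty matrix file")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-seq_len(id_cols)]
  # tolerate headers that omit the row-id column label
  if (length(lines) > 1L) {
    first_body <- strsplit(lines[[2]], "\t", fixed = TRUE)[[1]]
    if (length(header) == length(first_body) - 1L && id_cols == 1L) {
      sample_ids <- header
    }
  }
  if (anyDuplicated(sample_ids)) stop("duplicate column (sample) identifiers")
  n <- length(lines) - 1L
  if (n == 0L) stop("matrix has a header but no data rows")
  row_ids <- character(n)
  vals <- matrix(NA_real_, nrow = n, ncol = length(sample_ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(f) != id_cols + length(sample_ids)) {
      stop(sprintf("ragged row at data line %d: %d fields, expected %d",
                   i, length(f), id_cols + length(sample_ids)))
    }
    row_ids[i] <- f[1]
    body <- f[-seq_len(id_cols)]
    body[body %in% c("", "NA", "NaN", "nan")] <- NA
    v <- suppressWarnings(as.numeric(body))
    bad <- !is.na(body) & is.na(v)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' at data line %d", body[which(bad)[1]], i))
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(row_ids)) {
    stop(sprintf("duplicate row identifier: %s", row_ids[duplicated(row_ids)][1]))
  }
  dimnames(vals) <- list(row_ids, sample_ids)
  vals
}

#' Write a matrix as TSV (row ids in column 1)
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_label Label for the row-id column header.
#' @export
write_matrix_tsv <- function(mat, path, id_label = "id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_label, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r) paste(formatC(r, format = "g", digits = 15), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a variant table
#'
#' Expected TSV columns: `variant_id`, `chrom`, `pos` (1-based), `gene`,
#' `qvalue`. Used for eQTL and pharmacogenomic variant inputs.
#'
#' @param path TSV path with a header row.
#' @return data.frame with those five columns; `pos` numeric, `qvalue` in
#'   `[0, 1]`.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "gene", "qvalue")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("variant table missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- df[need]
  if (any(df$pos < 1)) stop("variant positions must be 1-based (>= 1)")
  if (any(df$qvalue < 0 | df$qvalue > 1)) stop("qvalue must lie in [0, 1]")
  df
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `cell_line`, `drug`, `condition`
#' (control/treated) and optional `dose`. Treated samples must carry a drug
#' name.
#'
#' @param path TSV path.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "drug", "condition")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("sample metadata missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$condition %in% c("control", "treated"))) {
    stop("condition must be 'control' or 'treated'")
  }
  treated <- df$condition == "treated"
  if (any(treated & (is.na(df$drug) | !nzchar(df$drug)))) {
    stop("treated samples must carry a drug name")
  }
  df
}

#' Do two intervals overlap?
#'
#' Half-open semantics: true iff same chromosome and
#' `a$start < b$end && b$start < a$end`. Abutting intervals do not overlap.
#'
#' @param a,b `genomic_interval` objects.
#' @return Logical scalar.
#' @export
overlaps <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Is a 1-based point inside an interval?
#'
#' Tests whether a 1-based position (the convention variants and printed
#' coordinates use) lies within a 0-based half-open interval, i.e.
#' `iv$start < pos <= iv$end`. This makes both endpoints of the printed
#' 1-based inclusive range count as inside.
#'
#' @param chrom Chromosome of the point.
#' @param pos_1based 1-based position, `>= 1`.
#' @param iv A `genomic_interval`.
#' @return Logical scalar.
#' @export
point_in_interval <- function(chrom, pos_1based, iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  if (pos_1based < 1) stop("'pos_1based' must be >= 1")
  chrom == iv$chrom && iv$start < pos_1based && pos_1based <= iv$end
}

# data.frame(chrom,start,end) -> GRanges; 0-based half-open to 1-based closed
.df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end))
  )
}

#' All overlapping pairs between two interval sets
#'
#' Finds every (query, subject) pair with >= 1 bp overlap under half-open
#' semantics, using an interval-index join. Output is sorted by query index,
#' then subject index.
#'
#' @param query,subject data.frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame with integer columns `query_idx`, `subject_idx`.
#' @export
bulk_overlap <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query_idx = integer(0), subject_idx = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(.df_to_granges(query), .df_to_granges(subject))
  out <- data.frame(query_idx = S4Vectors::queryHits(hits),
                    subject_idx = S4Vectors::subjectHits(hits))
  out <- out[order(out$query_idx, out$subject_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
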