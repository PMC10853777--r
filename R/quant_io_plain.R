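#' Read plain tab-delimited quantifications
#'
#' Fallback dialect for quantifications that did not come from Salmon or
#' kallisto: a tab-delimited counts table with a header row of sample
#' identifiers and a first column of transcript identifiers, plus optionally
#' one bootstrap table per sample in the same layout (first column transcript
#' id, remaining columns the B resamples). Malformed rows are reported with
#' their line number.
#'
#' @param counts_path Path to the counts table.
#' @param bootstrap_paths Optional character vector, one bootstrap table per
#'   sample, in sample order. Omit for a counts-only bundle (B = 0), usable
#'   for the raw-count pipeline only.
#' @return A [quant_bundle()].
#' @export
read_plain <- function(counts_path, bootstrap_paths = NULL) {
  parsed <- parse_tsv_numeric(counts_path, header = TRUE)
  ids <- parsed$ids
  counts <- parsed$values
  colnames(counts) <- parsed$header
  n <- ncol(counts)
  boots <- NULL
  if (!is.null(bootstrap_paths)) {
    if (length(bootstrap_paths) != n)
      stop("expected ", n, " bootstrap files (one per sample), got ",
           length(bootstrap_paths))
    boots <- lapply(bootstrap_paths, function(p) {
      bp <- parse_tsv_numeric(p, header = FALSE)
      if (length(bp$ids) != length(ids) || !setequal(bp$ids, ids))
        stop("transcript ids in ", p, " do not match the counts table")
      bp$values[match(ids, bp$ids), , drop = FALSE]
    })
  }
  quant_bundle(counts = counts, transcript_ids = ids, bootstraps = boots,
               sample_ids = colnames(counts),
               provenance = list(dialect = "plain", paths = counts_path))
}

# Strict TSV parser reporting the offending line on error.
parse_tsv_numeric <- function(path, header) {
  if (!file.exists(path)) stop("missing file ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file ", path)
  first_data <- 1L
  hdr <- NULL
  if (header) {
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    # drop a leading id-column name if present
    first_data <- 2L
  }
  rows <- strsplit(lines[first_data:length(lines)], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged row in ", path, " at line ", bad + first_data - 1L)
  }
  nc <- widths[1L] - 1L
  if (nc < 1L) stop("no data columns in ", path)
  if (header) {
    if (length(hdr) == nc + 1L) hdr <- hdr[-1L]
    if (length(hdr) != nc)
      stop("header of ", path, " has ", length(hdr),
           " sample columns but rows have ", nc)
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(nc)))
  vals <- matrix(vals, ncol = length(rows))  # nc x nrow, guard nc == 1
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    stop("non-numeric cell in ", path, " at line ", bad + first_data - 1L)
  }
  list(ids = ids, values = t(vals), header = hdr)
}
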