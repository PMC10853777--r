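#' Per-sample transcript quantifications with bootstrap resamples
#'
#' A `QuantBundle` holds the output of a transcript quantifier for a set of
#' samples: the matrix of (fractional) estimated read counts `y_ti`, the
#' per-sample bootstrap resample matrices `u_tib`, transcript annotation
#' carried along from the quantifier, and per-sample library sizes
#' `N_i = sum_t y_ti`.
#'
#' @param counts Numeric matrix, transcripts x samples. Fractional values are
#'   allowed and are never rounded.
#' @param transcript_ids Character vector of transcript identifiers, one per
#'   row of `counts`.
#' @param bootstraps List with one element per sample: a numeric matrix of
#'   dimension transcripts x B_i holding bootstrap counts, or `NULL`/a
#'   zero-column matrix when the sample carries no resamples.
#' @param sample_ids Character vector of sample identifiers, one per column.
#' @param lengths Integer transcript lengths in bp (optional).
#' @param effective_lengths Numeric matrix transcripts x samples of effective
#'   lengths (optional; carried for export, unused by the estimator).
#' @param provenance List of free-form provenance records (source dialect,
#'   resample type, paths).
#'
#' @return An object of class `QuantBundle`.
#' @export
quant_bundle <- function(counts, transcript_ids = rownames(counts),
                         bootstraps = NULL, sample_ids = colnames(counts),
                         lengths = NULL, effective_lengths = NULL,
                         provenance = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  T <- nrow(counts)
  n <- ncol(counts)
  if (is.null(transcript_ids)) transcript_ids <- paste0("tx", seq_len(T))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  transcript_ids <- as.character(transcript_ids)
  sample_ids <- as.character(sample_ids)
  if (length(transcript_ids) != T)
    stop("transcript_ids length does not match nrow(counts)")
  if (length(sample_ids) != n)
    stop("sample_ids length does not match ncol(counts)")
  if (anyDuplicated(transcript_ids))
    stop("duplicated transcript identifiers")
  if (is.null(bootstraps)) bootstraps <- rep(list(NULL), n)
  if (length(bootstraps) != n)
    stop("bootstraps must have one element per sample")
  bootstraps <- lapply(bootstraps, function(b) {
    if (is.null(b)) return(matrix(numeric(0), nrow = T, ncol = 0))
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    if (nrow(b) != T) stop("bootstrap matrix row count does not match counts")
    b
  })
  names(bootstraps) <- sample_ids
  dimnames(counts) <- list(transcript_ids, sample_ids)
  if (!is.null(effective_lengths)) {
    effective_lengths <- as.matrix(effective_lengths)
    storage.mode(effective_lengths) <- "double"
    if (!all(dim(effective_lengths) == c(T, n)))
      stop("effective_lengths dimensions do not match counts")
    dimnames(effective_lengths) <- dimnames(counts)
  }
  if (!is.null(lengths)) {
    if (length(lengths) != T) stop("lengths must have one entry per transcript")
    lengths <- as.integer(round(lengths))
  }
  obj <- structure(
    list(counts = counts,
         transcript_ids = transcript_ids,
         sample_ids = sample_ids,
         bootstraps = bootstraps,
         lengths = lengths,
         effective_lengths = effective_lengths,
         library_sizes = colSums(counts),
         provenance = provenance),
    class = "QuantBundle")
  validate_quant_bundle(obj)
  obj
}

#' Validate a QuantBundle's invariants
#'
#' Checks non-negativity and finiteness of counts and bootstraps, dimension
#' agreement, and that stored library sizes equal column sums of counts to a
#' relative tolerance of 1e-8.
#'
#' @param x A `QuantBundle`.
#' @return `x` invisibly; errors on violation.
#' @export
validate_quant_bundle <- function(x) {
  stopifnot(inherits(x, "QuantBundle"))
  if (!all(is.finite(x$counts)) || any(x$counts < 0))
    stop("counts must be finite and non-negative")
  for (b in x$bootstraps) {
    if (length(b) && (!all(is.finite(b)) || any(b < 0)))
      stop("bootstrap counts must be finite and non-negative")
  }
  cs <- colSums(x$counts)
  tol <- 1e-8 * pmax(1, abs(cs))
  if (any(abs(cs - x$library_sizes) > tol))
    stop("library_sizes do not match column sums of counts")
  invisible(x)
}

#' Number of bootstrap resamples per sample
#'
#' @param x A `QuantBundle`.
#' @return Integer vector `B_i`, named by sample.
#' @export
n_bootstraps <- function(x) {
  stopifnot(inherits(x, "QuantBundle"))
  vapply(x$bootstraps, ncol, integer(1))
}

#' @export
print.QuantBundle <- function(x, ...) {
  B <- n_bootstraps(x)
  cat(sprintf("QuantBundle: %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  bootstraps per sample: %s\n",
              paste(B, collapse = ", ")))
  cat(sprintf("  library sizes: %s\n",
              paste(signif(x$library_sizes, 4), collapse = ", ")))
  if (!is.null(x$provenance$dialect))
    cat(sprintf("  source: %s\n", x$provenance$dialect))
  invisible(x)
}

#' @export
dim.QuantBundle <- function(x) dim(x$counts)

#' Subset a QuantBundle by transcript and/or sample
#'
#' @param x A `QuantBundle`.
#' @param i Transcript index (integer, logical, or character).
#' @param j Sample index.
#' @param ... Ignored.
#' @return A `QuantBundle` restricted to the selected transcripts and samples.
#' @export
`[.QuantBundle` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$transcript_ids)
  if (is.character(j)) j <- match(j, x$sample_ids)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  quant_bundle(
    counts = x$counts[i, j, drop = FALSE],
    transcript_ids = x$transcript_ids[i],
    bootstraps = lapply(x$bootstraps[j], function(b) b[i, , drop = FALSE]),
    sample_ids = x$sample_ids[j],
    lengths = x$lengths[i],
    effective_lengths = if (!is.null(x$effective_lengths))
      x$effective_lengths[i, j, drop = FALSE],
    provenance = x$provenance)
}
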