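#' Count dataset for differential transcript expression
#'
#' Container for the (scaled or raw) count matrix together with library
#' sizes, TMM normalization factors, the design matrix, and a provenance
#' record of what has been done to the counts.
#'
#' @param counts Numeric matrix, transcripts x samples; non-negative,
#'   fractional values allowed.
#' @param group Optional factor of sample group labels.
#' @param design Optional numeric design matrix (samples x coefficients) with
#'   full column rank. If omitted and `group` is given, `model.matrix(~group)`
#'   is used.
#' @param lib_sizes Library sizes; default column sums of `counts`.
#' @param norm_factors Normalization factors with geometric mean 1; default
#'   all 1.
#' @param provenance List recording scaling/filtering applied.
#' @return An object of class `DTEDataset`.
#' @export
dte_dataset <- function(counts, group = NULL, design = NULL,
                        lib_sizes = NULL, norm_factors = NULL,
                        provenance = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0) || !all(is.finite(counts)))
    stop("counts must be finite and non-negative")
  n <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("tx", seq_len(nrow(counts)))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(norm_factors)) norm_factors <- rep(1, n)
  if (length(lib_sizes) != n || length(norm_factors) != n)
    stop("lib_sizes/norm_factors length must equal the number of samples")
  if (any(norm_factors <= 0)) stop("norm_factors must be positive")
  gm <- exp(mean(log(norm_factors)))
  if (abs(gm - 1) > 1e-8)
    stop("norm_factors must have geometric mean 1")
  if (!is.null(group)) group <- as.factor(group)
  if (is.null(design) && !is.null(group))
    design <- stats::model.matrix(~group)
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != n) stop("design must have one row per sample")
    if (qr(design)$rank < ncol(design))
      stop("design matrix is not of full column rank")
  }
  structure(list(counts = counts, lib_sizes = lib_sizes,
                 norm_factors = norm_factors, design = design,
                 group = group, provenance = provenance),
            class = "DTEDataset")
}

#' @export
print.DTEDataset <- function(x, ...) {
  cat(sprintf("DTEDataset: %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$group))
    cat("  groups:", paste(levels(x$group), collapse = ", "), "\n")
  if (isTRUE(x$provenance$scaled)) cat("  counts are RTA-scaled\n")
  if (!is.null(x$provenance$filtered))
    cat(sprintf("  filtered: %d of %d transcripts kept\n",
                x$provenance$filtered$kept, x$provenance$filtered$total))
  invisible(x)
}

#' @export
dim.DTEDataset <- function(x) dim(x$counts)

# effective library sizes = lib size x TMM factor
effective_lib_sizes <- function(ds) ds$lib_sizes * ds$norm_factors
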