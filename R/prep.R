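#' Filter transcripts by expression level
#'
#' Keeps a transcript if its counts-per-million exceed a cutoff in enough
#' samples and its total count is large enough. The CPM cutoff is
#' `min_count / median(lib_sizes) * 1e6`, i.e. `min_count` reads in a library
#' of median depth; the required number of passing samples is
#' `min_prop * (smallest group size)`, compared with a 1e-14 tolerance so
#' that e.g. 0.7 x 3 = 2.1 requires 3 passing samples while an exact 2.0
#' requires 2. Groups come from `group` labels or, failing that, from the
#' distinct rows of the design matrix. The filter is idempotent and preserves
#' transcript order.
#'
#' @param ds A [dte_dataset()] with group labels or a design.
#' @param min_count Reads required at median library depth; default 10.
#' @param min_total Minimum total count across samples; default 15.
#' @param min_prop Proportion of the smallest group that must pass the CPM
#'   cutoff; default 0.7.
#' @return The filtered `DTEDataset`.
#' @export
filter_by_expression <- function(ds, min_count = 10, min_total = 15,
                                 min_prop = 0.7) {
  stopifnot(inherits(ds, "DTEDataset"))
  grp <- ds$group
  if (is.null(grp)) {
    if (is.null(ds$design))
      stop("group labels or a design matrix are required for filtering")
    grp <- factor(apply(ds$design, 1L, paste, collapse = ","))
  }
  min_group <- min(table(grp))
  k <- min_prop * min_group
  cutoff <- min_count / stats::median(ds$lib_sizes) * 1e6
  cpm_mat <- t(t(ds$counts) / ds$lib_sizes) * 1e6
  n_pass <- rowSums(cpm_mat >= cutoff)
  keep <- (n_pass >= k - 1e-14) & (rowSums(ds$counts) >= min_total)
  if (!any(keep))
    stop("all ", nrow(ds$counts), " transcripts removed by expression filter")
  prov <- ds$provenance
  prov$filtered <- list(total = nrow(ds$counts), kept = sum(keep),
                        cpm_cutoff = cutoff, min_samples = k,
                        min_total = min_total)
  dte_dataset(ds$counts[keep, , drop = FALSE], group = ds$group,
              design = ds$design, lib_sizes = ds$lib_sizes,
              norm_factors = ds$norm_factors, provenance = prov)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes a composition-correcting factor per sample from the doubly
#' trimmed, precision-weighted mean of log2 expression ratios (M-values)
#' against a reference sample. The reference is the sample whose upper
#' quartile of depth-scaled counts is closest to the mean upper quartile.
#' For each sample, transcripts with a zero in either sample are dropped,
#' the remaining M-values are trimmed by `trim_logratio` at each end and by
#' `trim_abs` on absolute expression (A-values), and the surviving M-values
#' are averaged with inverse-variance (binomial delta method) weights.
#' Factors are rescaled to geometric mean 1, so a pure depth difference
#' (already absorbed by the library size) yields factors of 1.
#'
#' @param ds A [dte_dataset()] with at least two samples.
#' @param trim_logratio Two-sided trim fraction on M-values; default 0.3.
#' @param trim_abs Two-sided trim fraction on A-values; default 0.05.
#' @return The dataset with `norm_factors` filled in.
#' @export
tmm_norm_factors <- function(ds, trim_logratio = 0.3, trim_abs = 0.05) {
  stopifnot(inherits(ds, "DTEDataset"))
  y <- ds$counts
  lib <- ds$lib_sizes
  if (ncol(y) < 2L) stop("TMM needs at least two samples")
  if (any(lib <= 0)) stop("sample with zero library size")
  # reference: upper quartile of depth-scaled counts closest to the mean
  uq <- apply(y, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(i) {
    tmm_pair_factor(y[, i], y[, ref], lib[i], lib[ref],
                    trim_logratio, trim_abs)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  dte_dataset(y, group = ds$group, design = ds$design,
              lib_sizes = lib, norm_factors = f, provenance = ds$provenance)
}

# One TMM factor of sample `obs` against reference `ref`.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            trim_logratio, trim_abs) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & is.finite(w) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (!n) return(1)
  if (max(abs(M)) < 1e-6) return(1)  # columns proportional: no composition shift
  loM <- floor(n * trim_logratio) + 1L
  hiM <- n + 1L - loM
  loA <- floor(n * trim_abs) + 1L
  hiA <- n + 1L - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Counts per million
#'
#' CPM on effective library sizes (library size times normalization factor).
#' The log version damps low counts with a library-size-proportional prior
#' count before taking log2, so zeros map to finite values.
#'
#' @param ds A [dte_dataset()].
#' @param log If `TRUE`, return log2-CPM with prior-count damping.
#' @param prior_count Average prior count added before the log; default 2.
#' @return A matrix of (log-)CPM values.
#' @export
cpm <- function(ds, log = FALSE, prior_count = 2) {
  stopifnot(inherits(ds, "DTEDataset"))
  eff <- effective_lib_sizes(ds)
  if (!log) return(t(t(ds$counts) / eff) * 1e6)
  pc <- prior_count * eff / mean(eff)
  log2(t((t(ds$counts) + pc) / (eff + 2 * pc)) * 1e6)
}

#' Average log2 counts per million per transcript
#'
#' Abundance summary used as the covariate for dispersion trends: log2 of the
#' average (over samples) damped CPM.
#'
#' @param ds A [dte_dataset()].
#' @param prior_count Prior count; default 2.
#' @return Numeric vector, one value per transcript.
#' @export
ave_log_cpm <- function(ds, prior_count = 2) {
  stopifnot(inherits(ds, "DTEDataset"))
  eff <- effective_lib_sizes(ds)
  pc <- prior_count * eff / mean(eff)
  log2(rowMeans(t((t(ds$counts) + pc) / (eff + 2 * pc))) * 1e6)
}
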