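#' Run the full differential transcript expression pipeline
#'
#' Composes the stages of the scaled-count DTE analysis on a quantification
#' bundle: (optionally) estimate and moderate the RTA overdispersion from the
#' bootstraps and scale the counts, then filter low-expression transcripts,
#' compute TMM factors, estimate the dispersion trend, fit the NB model and
#' apply quasi-likelihood F-tests with Benjamini-Hochberg adjustment. With
#' `scale = FALSE` the identical code path runs on the raw counts, which is
#' the natural baseline comparison.
#'
#' @param bundle A [quant_bundle()].
#' @param group Factor of sample groups (two-group designs); either `group`
#'   or `design` must be given.
#' @param design Optional design matrix (samples x coefficients).
#' @param contrast Numeric contrast vector; defaults to testing the last
#'   coefficient.
#' @param scale If `TRUE` (default), divide the RTA overdispersion out of the
#'   counts before testing; requires bootstraps.
#' @param prior_df Prior degrees of freedom for overdispersion moderation.
#' @param min_count,min_total,min_prop Filtering parameters, see
#'   [filter_by_expression()].
#' @return A `DTEResult` data frame (see [ql_ftest()]) with attribute
#'   `pipeline` carrying the intermediate objects (`overdispersion`,
#'   `dataset`, `dispersion_fit`, `fit`).
#' @export
run_dte <- function(bundle, group = NULL, design = NULL, contrast = NULL,
                    scale = TRUE, prior_df = 3,
                    min_count = 10, min_total = 15, min_prop = 0.7) {
  stopifnot(inherits(bundle, "QuantBundle"))
  if (is.null(group) && is.null(design))
    stop("either group labels or a design matrix are required")
  od <- NULL
  if (scale) {
    if (min(n_bootstraps(bundle)) < 2L)
      stop("scaling requires bootstrap resamples; rerun with scale = FALSE ",
           "or quantify with bootstraps")
    od <- moderate_overdispersion(estimate_overdispersion(bundle),
                                  prior_df = prior_df)
    ds <- scale_counts(bundle, od)
    ds <- dte_dataset(ds$counts, group = group, design = design,
                      provenance = ds$provenance)
  } else {
    ds <- dte_dataset(bundle$counts, group = group, design = design)
  }
  ds <- filter_by_expression(ds, min_count = min_count,
                             min_total = min_total, min_prop = min_prop)
  ds <- tmm_norm_factors(ds)
  dfit <- estimate_trended_dispersion(ds)
  fit <- fit_nb_glm(ds, dispersion = dfit$trended_dispersion)
  if (is.null(contrast)) {
    contrast <- rep(0, ncol(fit$design))
    contrast[length(contrast)] <- 1
  }
  res <- ql_ftest(ds, fit, contrast)
  attr(res, "pipeline") <- list(overdispersion = od, dataset = ds,
                                dispersion_fit = dfit, fit = fit)
  res
}
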