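#' Estimate an abundance-dependent NB dispersion trend
#'
#' Per-transcript dispersions are first estimated by the Pearson moment
#' method: starting from a Poisson fit of the design, \eqn{\phi_t} solves
#' \deqn{\sum_i \frac{(y_{ti}-\hat\mu_{ti})^2}{\hat\mu_{ti}(1+\phi_t\hat\mu_{ti})}
#'       = n - p,}
#' by a few Newton steps (the left side is decreasing in \eqn{\phi}).
#' Transcripts are then binned by average log2-CPM (up to 20 bins), bin
#' medians are smoothed by lowess, and the smooth is evaluated at each
#' transcript's abundance and floored at zero. With a single bin the trend
#' is constant.
#'
#' @param ds A [dte_dataset()] with a design.
#' @param nbins Maximum number of abundance bins; default 20.
#' @return An object of class `DispersionFit`: `trended_dispersion`,
#'   `dispersion_raw` (per-transcript moment estimates, floored at 0),
#'   `ave_log_cpm`, plus QL fields filled by [ql_ftest()].
#' @export
estimate_trended_dispersion <- function(ds, nbins = 20L) {
  stopifnot(inherits(ds, "DTEDataset"))
  if (is.null(ds$design)) stop("a design matrix is required")
  n <- ncol(ds$counts); p <- ncol(ds$design)
  if (n - p < 1L) stop("no residual degrees of freedom")
  alc <- ave_log_cpm(ds)
  fit0 <- fit_nb_glm(ds, dispersion = 0)
  mu <- pmax(fit0$fitted, 1e-8)
  r2 <- (ds$counts - mu)^2
  phi <- pearson_moment_dispersion(r2, mu, n - p)
  trend <- smooth_dispersion_trend(phi, alc, nbins)
  structure(list(trended_dispersion = trend,
                 dispersion_raw = pmax(phi, 0),
                 ave_log_cpm = alc,
                 ql_dispersion_raw = NULL, ql_dispersion_shrunk = NULL,
                 prior_df_ql = NULL, residual_df = n - p),
            class = "DispersionFit")
}

# Solve sum r2/(mu(1+phi mu)) = df for phi >= 0, vectorized Newton.
pearson_moment_dispersion <- function(r2, mu, df) {
  X2_0 <- rowSums(r2 / mu)
  phi <- pmax((X2_0 - df) / pmax(rowSums(mu), 1e-8) / df, 0)  # crude start
  for (k in seq_len(20L)) {
    denom <- 1 + phi * mu
    f <- rowSums(r2 / (mu * denom)) - df
    fp <- -rowSums(r2 / denom^2)
    step <- f / fp
    step[!is.finite(step)] <- 0
    phi <- pmin(pmax(phi - step, 0), 100)
  }
  phi[X2_0 <= df] <- 0
  phi
}

smooth_dispersion_trend <- function(phi, alc, nbins) {
  T <- length(phi)
  nb <- max(1L, min(as.integer(nbins), floor(T / 20)))
  if (nb <= 1L || length(unique(alc)) < 2L)
    return(rep(max(stats::median(phi), 0), T))
  qs <- unique(stats::quantile(alc, probs = seq(0, 1, length.out = nb + 1L)))
  if (length(qs) < 3L) return(rep(max(stats::median(phi), 0), T))
  bins <- cut(alc, qs, include.lowest = TRUE)
  mids <- tapply(alc, bins, stats::median)
  meds <- tapply(phi, bins, stats::median)
  ok <- is.finite(mids) & is.finite(meds)
  if (sum(ok) < 2L) return(rep(max(stats::median(phi), 0), T))
  sm <- stats::lowess(mids[ok], meds[ok], f = 0.5)
  out <- stats::approx(sm$x, sm$y, xout = alc, rule = 2L)$y
  pmax(out, 0)
}

#' Squeeze sample variances toward an abundance-dependent trend
#'
#' Empirical Bayes moderation of per-transcript quasi-dispersions by
#' F-distribution moment matching on the log scale. A lowess trend of
#' log variances against the covariate sets the prior location; the excess of
#' the observed spread of log variances over the chi-square sampling spread
#' (via trigamma moments) determines the prior degrees of freedom. The
#' posterior value is the degrees-of-freedom weighted average of prior and
#' observation, as in standard limma-style variance shrinkage.
#'
#' @param s2 Observed variances (one per transcript), each on `df` degrees of
#'   freedom.
#' @param df Residual degrees of freedom (scalar or vector).
#' @param covariate Abundance covariate for the trend; `NULL` for a constant
#'   prior.
#' @return List with `var_post`, `var_prior` (vector along the trend),
#'   `df_prior` (possibly `Inf`).
#' @export
squeeze_var <- function(s2, df, covariate = NULL) {
  n <- length(s2)
  df <- rep_len(df, n)
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) stop("too few positive variances to moderate")
  z <- log(s2[ok])
  # bias-correct: E log(s2) = log(true) + digamma(df/2) - log(df/2)
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (!is.null(covariate) && length(unique(covariate[ok])) > 2L) {
    sm <- stats::lowess(covariate[ok], e, f = 0.4)
    emean <- stats::approx(sm$x, sm$y, xout = covariate, rule = 2L,
                           ties = "ordered")$y
  } else {
    emean <- rep(mean(e), n)
  }
  resid <- e - emean[ok]
  evar <- sum(resid^2) / (sum(ok) - 1L)
  evar <- evar - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  s2c <- ifelse(is.finite(s2), pmax(s2, 0), 0)
  var_post <- if (is.infinite(df_prior)) var_prior
              else (df_prior * var_prior + df * s2c) / (df_prior + df)
  list(var_post = var_post, var_prior = var_prior, df_prior = df_prior)
}

# Inverse of the trigamma function by Newton iteration on 1/psi'(y).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (k in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}
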