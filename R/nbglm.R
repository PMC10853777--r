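#' Fit negative binomial GLMs with log link to every transcript
#'
#' Fits, by Fisher scoring (IRLS), the log-linear model
#' \eqn{\log\mu_{ti} = o_i + x_i'\beta_t} at fixed per-transcript dispersion
#' \eqn{\phi_t}, with offsets \eqn{o_i} the log effective library sizes.
#' The score equations involve only means and variances, so fractional
#' counts are handled by the continuous generalization of the NB likelihood;
#' the reported deviance uses the continuous NB deviance, which is valid for
#' real-valued `y`. Dispersion 0 gives the Poisson limit. Convergence is
#' declared when the relative deviance change falls below 1e-8 (at most 50
#' iterations); transcripts that fail to converge are flagged, not fatal.
#'
#' @param ds A [dte_dataset()] with a design matrix.
#' @param dispersion Scalar or per-transcript NB dispersion \eqn{\phi_t}.
#' @param design Optional design matrix overriding `ds$design` (used
#'   internally for reduced-model fits).
#' @return List with `coefficients` (transcripts x p, natural log scale),
#'   `fitted` (mean matrix), `deviance`, `df_residual`, `dispersion`,
#'   `converged`, `design`, `offset`.
#' @export
fit_nb_glm <- function(ds, dispersion = 0, design = NULL) {
  stopifnot(inherits(ds, "DTEDataset"))
  if (is.null(design)) design <- ds$design
  if (is.null(design)) stop("a design matrix is required")
  X <- as.matrix(design)
  y <- ds$counts
  T <- nrow(y); n <- ncol(y); p <- ncol(X)
  if (nrow(X) != n) stop("design rows must match samples")
  offset <- log(effective_lib_sizes(ds))
  phi <- rep_len(dispersion, T)

  # start from an unweighted least squares fit on shifted log counts
  z0 <- sweep(log(pmax(y, 0.5)), 2L, offset)
  beta <- z0 %*% X %*% solve(crossprod(X))

  dev_old <- rep(Inf, T)
  converged <- rep(FALSE, T)
  for (iter in seq_len(50L)) {
    eta <- sweep(beta %*% t(X), 2L, offset, `+`)
    eta <- pmin(pmax(eta, -50), 50)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, phi)
    converged <- abs(dev - dev_old) <= 1e-8 * (abs(dev) + 0.1)
    if (all(converged)) break
    dev_old <- dev
    w <- mu / (1 + phi * mu)
    zw <- w * (eta - rep(offset, each = T) + (y - mu) / mu)
    xtwz <- zw %*% X
    beta <- batch_wls(w, X, xtwz, beta)
  }
  if (!all(converged)) {  # report fit at the final coefficients
    eta <- pmin(pmax(sweep(beta %*% t(X), 2L, offset, `+`), -50), 50)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, phi)
  }
  dimnames(beta) <- list(rownames(y), colnames(X))
  list(coefficients = beta, fitted = mu, deviance = dev,
       df_residual = n - p, dispersion = phi, converged = converged,
       design = X, offset = offset)
}

# Solve the per-transcript weighted least squares systems X'WX b = X'Wz.
# w: T x n weights, X: n x p, xtwz: T x p. Closed form for p <= 2, direct
# solve otherwise.
batch_wls <- function(w, X, xtwz, beta_fallback) {
  p <- ncol(X)
  if (p == 1L) {
    s11 <- w %*% (X[, 1L]^2)
    out <- xtwz / as.vector(s11)
    bad <- !is.finite(out)
    out[bad] <- beta_fallback[bad]
    return(out)
  }
  if (p == 2L) {
    s11 <- as.vector(w %*% (X[, 1L]^2))
    s12 <- as.vector(w %*% (X[, 1L] * X[, 2L]))
    s22 <- as.vector(w %*% (X[, 2L]^2))
    det <- s11 * s22 - s12^2
    b1 <- (s22 * xtwz[, 1L] - s12 * xtwz[, 2L]) / det
    b2 <- (s11 * xtwz[, 2L] - s12 * xtwz[, 1L]) / det
    out <- cbind(b1, b2)
    bad <- !is.finite(out[, 1L]) | !is.finite(out[, 2L])
    out[bad, ] <- beta_fallback[bad, ]
    return(out)
  }
  T <- nrow(w)
  out <- beta_fallback
  for (t in seq_len(T)) {
    xtwx <- crossprod(X, X * w[t, ])
    bt <- try(solve(xtwx, xtwz[t, ]), silent = TRUE)
    if (!inherits(bt, "try-error") && all(is.finite(bt))) out[t, ] <- bt
  }
  out
}

# Continuous NB residual deviance per transcript; phi = 0 is Poisson.
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  ylogy <- y * log(ifelse(y > 0, y / mu, 1))
  pois <- phi == 0
  out <- numeric(nrow(y))
  if (any(pois)) {
    yy <- y[pois, , drop = FALSE]
    out[pois] <- 2 * rowSums(ylogy[pois, , drop = FALSE] -
                             (yy - mu[pois, , drop = FALSE]))
  }
  if (any(!pois)) {
    ph <- phi[!pois]
    yy <- y[!pois, , drop = FALSE]
    mm <- mu[!pois, , drop = FALSE]
    r <- 1 / ph  # recycles down rows
    out[!pois] <- 2 * rowSums(ylogy[!pois, , drop = FALSE] -
                              (yy + r) * log((yy + r) / (mm + r)))
  }
  pmax(out, 0)
}
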