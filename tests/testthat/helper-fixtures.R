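# Shared fixture builders: everything is generated in code at test time.

# A small random bundle with fractional counts and bootstraps.
random_bundle <- function(T = 10, n = 2, B = 5, seed = 1) {
  set.seed(seed)
  counts <- matrix(round(runif(T * n, 0, 500) + runif(T * n), 4), T, n)
  boots <- lapply(seq_len(n), function(i)
    matrix(round(rpois(T * B, 50) + runif(T * B), 4), T, B))
  quant_bundle(counts,
               transcript_ids = sprintf("ENST%08d.%d", seq_len(T),
                                        rep_len(1:3, T)),
               bootstraps = if (B > 0) boots,
               sample_ids = paste0("s", seq_len(n)),
               lengths = sample(200:3000, T, replace = TRUE))
}

# Bundle whose bootstraps are iid Poisson (true RTA overdispersion 1).
poisson_bundle <- function(T = 2000, n = 4, B = 100, lambda = c(5, 50),
                           seed = 1) {
  set.seed(seed)
  lam <- rep_len(lambda, T)
  boots <- lapply(seq_len(n), function(i)
    matrix(rpois(T * B, rep(lam, B)), T, B))
  quant_bundle(vapply(boots, rowMeans, numeric(T)), bootstraps = boots)
}

expect_same_bundle <- function(a, b, tol = 1e-9) {
  expect_identical(a$transcript_ids, b$transcript_ids)
  expect_equal(a$counts, b$counts, tolerance = tol, ignore_attr = TRUE)
  expect_equal(unname(n_bootstraps(a)), unname(n_bootstraps(b)))
  for (i in seq_along(a$bootstraps))
    expect_equal(a$bootstraps[[i]], b$bootstraps[[i]], tolerance = tol,
                 ignore_attr = TRUE)
}
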