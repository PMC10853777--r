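test_that("transcriptome skeleton has the promised class structure", {
  tr0 <- make_transcriptome(100, isoforms_per_gene = 1, ambiguity = 0.9,
                            seed = 1)
  # single-isoform genes are unique-only regardless of ambiguity
  expect_true(all(tr0$shared_weight == 0))
  expect_equal(sum(tr0$baseline_expression), 1)

  tr1 <- make_transcriptome(50, isoforms_per_gene = 2, ambiguity = 1,
                            seed = 2)
  expect_true(all(tr1$shared_weight == 1))
  expect_identical(length(tr1$transcript_ids), 100L)

  tr2 <- make_transcriptome(200, ambiguity = 0.5, seed = 3)
  expect_true(all(tr2$shared_weight %in% c(0, 0.5)))
  expect_true(all(tr2$shared_weight[tr2$n_isoforms == 1] == 0))
})

test_that("expression draws have the stated CV and fold change", {
  tr <- make_transcriptome(600, isoforms_per_gene = 1, seed = 4)
  tr$bcv2[] <- 0.09  # CV 0.3
  n <- 2000
  pis <- draw_expression(tr, n, seed = 5)
  cv <- apply(pis, 1, sd) / rowMeans(pis)
  expect_equal(median(cv), 0.3, tolerance = 0.05)

  # zero-dispersion limit: proportions constant across samples
  tr0 <- tr; tr0$bcv2[] <- 0
  p0 <- draw_expression(tr0, 3, seed = 6)
  expect_equal(p0[, 1], p0[, 2])

  # group-2 mean over group-1 mean recovers the fold change
  trd <- set_de_transcripts(tr, n_de = 20, fc = 2)
  g <- rep(c(1, 2), each = 500)
  pd <- draw_expression(trd, 1000, group = g, seed = 7)
  up <- trd$de_labels == 1
  ratio <- rowMeans(pd[, 501:1000]) / rowMeans(pd[, 1:500])
  expect_equal(median(ratio[up]), 2, tolerance = 0.1)
  expect_equal(median(ratio[trd$de_labels == 0]), 1, tolerance = 0.05)
  # de labels split up/down within one of half
  expect_lte(abs(sum(trd$de_labels == 1) - sum(trd$de_labels == -1)), 1)
})

test_that("counts and bootstraps conserve reads and have Poisson baseline", {
  set.seed(8)
  tr <- make_transcriptome(400, isoforms_per_gene = 1, ambiguity = 0, seed = 8)
  pis <- draw_expression(tr, 3)
  libs <- c(2e5, 5e5, 2e5)
  b <- draw_counts_and_bootstraps(tr, pis, libs, B = 50)
  # column sums near the target library sizes (Poisson totals)
  expect_equal(unname(colSums(b$counts)), libs, tolerance = 0.02)
  # every bootstrap redistributes exactly the realized total
  for (i in 1:3)
    expect_true(all(abs(colSums(b$bootstraps[[i]]) -
                        sum(b$counts[, i])) < 1e-6))
  # without ambiguity the bootstrap var/mean ratio is ~1
  disp <- estimate_overdispersion(b)
  expect_equal(median(disp$sigma2_hat, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("brute-force true overdispersion is 1 without sharing, ~2 for the
           canonical two-isoform case, and monotone in ambiguity", {
  set.seed(9)
  libs <- rep(2e5, 2)
  tr0 <- make_transcriptome(300, isoforms_per_gene = 2, ambiguity = 0)
  s0 <- true_sigma2(tr0, draw_expression(tr0, 2), libs, n_mc = 300)
  expect_equal(median(s0, na.rm = TRUE), 1, tolerance = 0.05)

  tr2 <- make_transcriptome(300, isoforms_per_gene = 2, ambiguity = 2 / 3)
  s2 <- true_sigma2(tr2, draw_expression(tr2, 2), libs, n_mc = 300)
  expect_gt(median(s2, na.rm = TRUE), 1.5)
  expect_lt(median(s2, na.rm = TRUE), 2.5)

  meds <- vapply(c(0, 0.3, 0.6, 0.9), function(a) {
    tra <- make_transcriptome(200, isoforms_per_gene = 3, ambiguity = a)
    median(true_sigma2(tra, draw_expression(tra, 2), libs, n_mc = 200),
           na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("the generative chain reproduces the two-component variance model", {
  # var(y) ~ sigma2*mu + phi*mu^2 across biological replicates
  set.seed(10)
  tr <- make_transcriptome(500, isoforms_per_gene = 2, ambiguity = 0.6)
  tr$bcv2[] <- 0.04
  n <- 200
  pis <- draw_expression(tr, n)
  libs <- rep(3e5, n)
  b <- draw_counts_and_bootstraps(tr, pis, libs, B = 0)
  s2 <- true_sigma2(tr, draw_expression(tr, 4), rep(3e5, 4), n_mc = 300)
  mu <- rowMeans(b$counts)
  v <- apply(b$counts, 1, var)
  keep <- mu > 20 & is.finite(s2)
  pred <- s2[keep] * mu[keep] + 0.04 * mu[keep]^2
  fitq <- summary(lm(v[keep] ~ 0 + pred))
  expect_gt(fitq$r.squared, 0.9)
  expect_equal(unname(coef(fitq)[1, 1]), 1, tolerance = 0.15)
})

test_that("estimator recovery closes the loop against the brute-force truth", {
  set.seed(12)
  tr <- make_transcriptome(250, isoforms_per_gene = 3, ambiguity = 0.7)
  pis <- draw_expression(tr, 4)
  libs <- rep(2e5, 4)
  b <- draw_counts_and_bootstraps(tr, pis, libs, B = 100)
  est <- estimate_overdispersion(b)
  ts2 <- true_sigma2(tr, pis, libs, n_mc = 400)
  ok <- is.finite(ts2) & est$df > 0 & rowMeans(b$counts) > 5
  expect_gt(sum(ok), 400)
  ratio <- est$sigma2_hat[ok] / ts2[ok]
  expect_gt(median(ratio), 0.9)
  expect_lt(median(ratio), 1.1)
})

test_that("scenarios are reproducible bit-for-bit from one seed", {
  s1 <- build_scenario("de", n_per_group = 2, n_genes = 80, n_de = 10,
                       B = 10, seed = 42)
  s2 <- build_scenario("de", n_per_group = 2, n_genes = 80, n_de = 10,
                       B = 10, seed = 42)
  expect_identical(s1$bundle$counts, s2$bundle$counts)
  expect_identical(s1$bundle$bootstraps, s2$bundle$bootstraps)
  expect_identical(s1$truth$fold_change, s2$truth$fold_change)
  s3 <- build_scenario("de", n_per_group = 2, n_genes = 80, n_de = 10,
                       B = 10, seed = 43)
  expect_false(identical(s1$bundle$counts, s3$bundle$counts))

  # scenario invariants
  null <- build_scenario("null", n_per_group = 2, n_genes = 50, B = 0,
                         seed = 1)
  expect_true(all(null$truth$de_labels == 0))
  expect_true(all(null$truth$fold_change == 1))
  de <- build_scenario("de", n_per_group = 2, n_genes = 100, n_de = 25,
                       B = 0, seed = 1)
  expect_identical(sum(de$truth$de_labels != 0), 25L)
  # unbalanced library pattern
  expect_equal(unname(de$bundle$library_sizes) > 5e5,
               rep(c(FALSE, TRUE), 2))
})

test_that("score_run computes power, FDR and type I with stated conventions", {
  truth <- structure(list(transcript_ids = paste0("t", 1:10),
                          de_labels = c(rep(1L, 3), rep(0L, 7))),
                     class = "SimTruth")
  res <- data.frame(transcript_id = paste0("t", 1:10),
                    p_value = c(1e-5, 1e-4, 0.2, 0.5, 0.03, rep(0.9, 5)),
                    fdr = c(1e-4, 1e-3, 0.4, 0.6, 0.2, rep(0.95, 5)))
  m <- score_run(res, truth)
  expect_equal(m$power, 2 / 3)
  expect_equal(m$observed_fdr, 0)
  expect_equal(m$type1, 1 / 7)
  # no calls: 0/0 convention gives fdr 0
  res2 <- res; res2$fdr[] <- 1
  expect_equal(score_run(res2, truth)$observed_fdr, 0)
  # perfect caller
  res3 <- res; res3$fdr <- c(0, 0, 0, rep(1, 7))
  expect_equal(score_run(res3, truth)$power, 1)
  expect_equal(score_run(res3, truth)$observed_fdr, 0)
  # unknown ids are fatal
  res4 <- res; res4$transcript_id[1] <- "zzz"
  expect_error(score_run(res4, truth), "missing")
  # uniform p-values give type1 ~ alpha
  set.seed(31)
  tbig <- structure(list(transcript_ids = paste0("u", 1:20000),
                         de_labels = rep(0L, 20000)), class = "SimTruth")
  rbig <- data.frame(transcript_id = paste0("u", 1:20000),
                     p_value = runif(20000), fdr = 1)
  expect_equal(score_run(rbig, tbig)$type1, 0.05, tolerance = 0.1)
})
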