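test_that("Salmon dialect round-trips exactly, including fractional counts", {
  b <- random_bundle(T = 10, n = 2, B = 5, seed = 3)
  dir <- withr::local_tempdir()
  dirs <- write_salmon_fixture(b, dir)
  rb <- read_salmon(dirs, sample_ids = b$sample_ids)
  expect_same_bundle(b, rb)
  # fractional NumReads preserved at full precision
  expect_equal(rb$counts, b$counts, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rb$library_sizes), unname(colSums(b$counts)))
})

test_that("Salmon reader aligns samples whose transcript order differs", {
  b <- random_bundle(T = 8, n = 3, B = 4, seed = 11)
  dir <- withr::local_tempdir()
  dirs <- write_salmon_fixture(b, dir)
  # permute the second sample's rows on disk
  perm <- c(3, 1, 2, 8, 7, 4, 5, 6)
  b_perm <- b[perm, 2]
  b_perm$sample_ids <- b$sample_ids[2]
  write_salmon_fixture(b_perm, dir)  # overwrites sample 2 dir
  rb <- read_salmon(dirs, sample_ids = b$sample_ids)
  expect_same_bundle(b, rb)
})

test_that("Salmon reader handles B = 0, Gibbs draws, and error cases", {
  b0 <- random_bundle(T = 5, n = 2, B = 0, seed = 5)
  dir <- withr::local_tempdir()
  dirs <- write_salmon_fixture(b0, dir)
  rb <- read_salmon(dirs)
  expect_identical(unname(n_bootstraps(rb)), c(0L, 0L))
  expect_error(estimate_overdispersion(rb), "bootstrap resamples required")

  bg <- random_bundle(T = 5, n = 1, B = 3, seed = 6)
  gdir <- withr::local_tempdir()
  gd <- write_salmon_fixture(bg, gdir, samp_type = "gibbs")
  expect_warning(rg <- read_salmon(gd), "Gibbs")
  expect_identical(rg$provenance$resample_type, "gibbs")
  expect_equal(rg$bootstraps[[1]], bg$bootstraps[[1]], ignore_attr = TRUE)

  expect_error(read_salmon(file.path(dir, "no_such")), "quant.sf")
})

test_that("Salmon integer bootstrap streams are auto-detected", {
  b <- random_bundle(T = 6, n = 1, B = 4, seed = 8)
  b$bootstraps[[1]][] <- round(b$bootstraps[[1]])
  dir <- withr::local_tempdir()
  d <- write_salmon_fixture(b, dir)
  # rewrite the stream as 4-byte little-endian integers
  gz <- file.path(d, "aux_info", "bootstrap", "bootstraps.gz")
  con <- gzfile(gz, "wb")
  writeBin(as.integer(b$bootstraps[[1]]), con, size = 4L, endian = "little")
  close(con)
  rb <- read_salmon(d)
  expect_equal(rb$bootstraps[[1]], b$bootstraps[[1]], ignore_attr = TRUE)
  # a stream matching neither layout is fatal
  con <- gzfile(gz, "wb")
  writeBin(raw(13), con)
  close(con)
  expect_error(read_salmon(d), "consistent with neither")
})

test_that("samples quantified against different transcript sets are fatal", {
  b <- random_bundle(T = 6, n = 2, B = 2, seed = 9)
  dir <- withr::local_tempdir()
  dirs <- write_salmon_fixture(b, dir)
  b2 <- b[, 2]
  b2$transcript_ids[1] <- "ENST_other"
  rownames(b2$counts)[1] <- "ENST_other"
  write_salmon_fixture(b2, dir)
  expect_error(read_salmon(dirs), "transcript sets differ")
})

test_that("kallisto dialect round-trips exactly", {
  b <- random_bundle(T = 4, n = 2, B = 2, seed = 21)
  dir <- withr::local_tempdir()
  dirs <- write_kallisto_fixture(b, dir)
  rb <- read_kallisto(dirs, sample_ids = b$sample_ids)
  expect_same_bundle(b, rb, tol = 0)  # doubles stored natively

  # fractional est_counts preserved exactly, no rounding
  bf <- quant_bundle(matrix(c(2.5, 0.25, 7.75), 3, 1),
                     transcript_ids = c("a", "b", "c"))
  df <- withr::local_tempdir()
  rb2 <- read_kallisto(write_kallisto_fixture(bf, df))
  expect_identical(as.vector(rb2$counts), c(2.5, 0.25, 7.75))
  expect_identical(unname(n_bootstraps(rb2)), 0L)

  expect_error(read_kallisto(file.path(dir, "absent")), "abundance.h5")
})

test_that("kallisto reader copes with h5py-written files and bad metadata", {
  # independent oracle: build abundance.h5 with python/h5py (fixed-length
  # strings, the layout kallisto itself uses) and with a corrupted
  # num_bootstrap
  py <- Sys.which("python")
  dir <- withr::local_tempdir()
  script <- file.path(dir, "make.py")
  writeLines(c(
    "import h5py, numpy as np, sys",
    "d = sys.argv[1]",
    "f = h5py.File(d + '/abundance.h5', 'w')",
    "f['est_counts'] = np.array([1.5, 2.0, 3.25])",
    "f['aux/ids'] = np.array([b'txA', b'txB', b'txC'], dtype='S4')",
    "f['aux/lengths'] = np.array([100.0, 200.0, 300.0])",
    "f['aux/eff_lengths'] = np.array([80.0, 180.0, 280.0])",
    "f['aux/num_bootstrap'] = np.array([2], dtype='i4')",
    "f['bootstrap/bs0'] = np.array([1.0, 2.0, 3.0])",
    "if sys.argv[2] == 'ok':",
    "    f['bootstrap/bs1'] = np.array([2.0, 2.5, 3.5])",
    "f.close()"), script)
  okdir <- file.path(dir, "ok"); dir.create(okdir)
  status <- system2(py, c(script, okdir, "ok"))
  expect_identical(status, 0L)
  rb <- read_kallisto(okdir)
  expect_identical(rb$transcript_ids, c("txA", "txB", "txC"))
  expect_identical(as.vector(rb$counts), c(1.5, 2.0, 3.25))
  expect_identical(rb$bootstraps[[1]][, 2], c(2.0, 2.5, 3.5))

  baddir <- file.path(dir, "bad"); dir.create(baddir)
  system2(py, c(script, baddir, "bad"))
  expect_error(read_kallisto(baddir), "declares 2")
})

test_that("plain dialect reads counts and bootstrap tables", {
  dir <- withr::local_tempdir()
  cpath <- file.path(dir, "counts.tsv")
  writeLines(c("id\tsampleA\tsampleB",
               "tx1\t10\t20",
               "tx2\t0.5\t1.5",
               "tx3\t7\t0"), cpath)
  bpaths <- file.path(dir, c("bootA.tsv", "bootB.tsv"))
  for (p in bpaths)
    writeLines(c("tx1\t9\t11\t10\t10", "tx2\t1\t0\t1\t0.5",
                 "tx3\t6\t8\t7\t7"), p)
  b <- read_plain(cpath, bpaths)
  expect_identical(dim(b$counts), c(3L, 2L))
  expect_identical(unname(n_bootstraps(b)), c(4L, 4L))
  expect_identical(b$counts["tx2", "sampleB"], 1.5)

  b0 <- read_plain(cpath)
  expect_identical(unname(n_bootstraps(b0)), c(0L, 0L))

  # malformed inputs name the line
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("id\ts1", "tx1\t5", "tx2\t1\t9"), bad)
  expect_error(read_plain(bad), "line 3")
  writeLines(c("id\ts1", "tx1\tfive"), bad)
  expect_error(read_plain(bad), "non-numeric.*line 2")
  # bootstrap table with a missing transcript id
  writeLines(c("tx1\t1\t2", "txX\t0\t0", "tx3\t1\t1"), bpaths[1])
  expect_error(read_plain(cpath, bpaths), "do not match")
})

test_that("version-suffix stripping is opt-in", {
  b <- random_bundle(T = 4, n = 2, B = 0, seed = 33)
  dir <- withr::local_tempdir()
  dirs <- write_salmon_fixture(b, dir)
  rb <- read_salmon(dirs, strip_versions = TRUE)
  expect_false(any(grepl("\\.\\d+$", rb$transcript_ids)))
  rb2 <- read_salmon(dirs)
  expect_identical(rb2$transcript_ids, b$transcript_ids)
})
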