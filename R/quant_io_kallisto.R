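#' Read kallisto quantification directories
#'
#' Imports estimated counts and bootstrap resamples from `abundance.h5` files.
#' Each file must contain the datasets `/est_counts`, `/aux/ids`,
#' `/aux/eff_lengths`, `/aux/lengths` and `/aux/num_bootstrap`; bootstrap
#' resamples live in `/bootstrap/bs0 ... bs{B-1}` and are assembled in index
#' order. A `num_bootstrap` value disagreeing with the number of `bs*`
#' datasets present is an error. Fractional estimated counts are preserved
#' exactly; nothing is rounded.
#'
#' @inheritParams read_salmon
#' @param dirs Character vector of kallisto output directories (each
#'   containing `abundance.h5`).
#' @return A [quant_bundle()].
#' @export
read_kallisto <- function(dirs, sample_ids = basename(dirs),
                          strip_versions = FALSE) {
  if (length(dirs) < 1L) stop("no directories given")
  per <- lapply(dirs, function(dir) {
    h5 <- file.path(dir, "abundance.h5")
    if (!file.exists(h5)) stop("missing abundance.h5 in ", dir)
    raw <- .Call(C_h5_read_kallisto, h5)
    list(ids = raw$ids, lengths = raw$lengths,
         eff_lengths = raw$eff_lengths, counts = raw$est_counts,
         boots = raw$bootstraps,
         resample_type = if (raw$num_bootstrap > 0) "bootstrap" else "none")
  })
  assemble_bundle(per, sample_ids, dialect = "kallisto",
                  strip_versions = strip_versions, paths = dirs)
}

#' Write a kallisto-dialect fixture directory tree
#'
#' Emits one `abundance.h5` per sample with the datasets [read_kallisto()]
#' consumes. `read_kallisto(write_kallisto_fixture(x))` reproduces counts and
#' bootstraps exactly (doubles are stored natively).
#'
#' @param bundle A [quant_bundle()].
#' @param dir Parent directory; one subdirectory per sample is created.
#' @return Character vector of the per-sample directories, invisibly.
#' @export
write_kallisto_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "QuantBundle"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create directory ", dir)
  T <- nrow(bundle$counts)
  lens <- if (is.null(bundle$lengths)) rep(1000, T) else as.double(bundle$lengths)
  out <- character(0)
  for (i in seq_along(bundle$sample_ids)) {
    sdir <- file.path(dir, bundle$sample_ids[i])
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    eff <- if (is.null(bundle$effective_lengths)) pmax(lens - 200, 1)
           else bundle$effective_lengths[, i]
    .Call(C_h5_write_kallisto, file.path(sdir, "abundance.h5"),
          bundle$transcript_ids, as.double(lens), as.double(eff),
          as.double(bundle$counts[, i]), bundle$bootstraps[[i]])
    out <- c(out, sdir)
  }
  invisible(out)
}
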