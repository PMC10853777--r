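#' Read Salmon quantification directories
#'
#' Imports transcript counts (the `NumReads` column of `quant.sf`) and, when
#' present, the bootstrap resamples stored under `aux_info/bootstrap/` of each
#' Salmon output directory. Bootstrap streams are decoded as a gzip-compressed
#' sequence of `num_bootstraps` records of T little-endian doubles; streams
#' whose byte length instead matches T 4-byte integers per record (emitted by
#' some Salmon versions) are decoded as integers. Transcript order is
#' reconciled across samples by identifier; directories quantified against
#' different transcript sets are an error.
#'
#' Directories holding posterior Gibbs samples instead of bootstraps are
#' accepted with a warning and the draws are treated as bootstrap resamples;
#' the choice is recorded in the bundle's provenance.
#'
#' @param dirs Character vector of Salmon output directories (each containing
#'   `quant.sf`).
#' @param sample_ids Sample names; defaults to `basename(dirs)`.
#' @param strip_versions If `TRUE`, strip trailing `.N` version suffixes from
#'   transcript identifiers before reconciling samples. Default `FALSE`:
#'   silent coercion can hide annotation mismatches.
#' @return A [quant_bundle()].
#' @export
read_salmon <- function(dirs, sample_ids = basename(dirs),
                        strip_versions = FALSE) {
  if (length(dirs) < 1L) stop("no directories given")
  per <- lapply(dirs, read_salmon_one)
  assemble_bundle(per, sample_ids, dialect = "salmon",
                  strip_versions = strip_versions, paths = dirs)
}

read_salmon_one <- function(dir) {
  qf <- file.path(dir, "quant.sf")
  if (!file.exists(qf))
    stop("missing quant.sf in ", dir)
  quant <- utils::read.delim(qf, header = TRUE, sep = "\t",
                             colClasses = c("character", "numeric", "numeric",
                                            "numeric", "numeric"))
  need <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  if (!all(need %in% names(quant)))
    stop("quant.sf in ", dir, " lacks columns: ",
         paste(setdiff(need, names(quant)), collapse = ", "))
  ids <- quant$Name
  T <- length(ids)

  boots <- matrix(numeric(0), nrow = T, ncol = 0)
  resample_type <- "none"
  meta_path <- file.path(dir, "aux_info", "meta_info.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    nboot <- meta$num_bootstraps
    if (is.null(nboot)) nboot <- 0L
    nboot <- as.integer(nboot)
    samp_type <- meta$samp_type
    if (!is.null(samp_type) && identical(tolower(samp_type), "gibbs") &&
        nboot > 0L) {
      warning("directory ", dir, " holds Gibbs posterior samples; ",
              "treating them as bootstrap resamples")
      resample_type <- "gibbs"
    } else if (nboot > 0L) {
      resample_type <- "bootstrap"
    }
    if (nboot > 0L) {
      bs_path <- file.path(dir, "aux_info", "bootstrap", "bootstraps.gz")
      nm_path <- file.path(dir, "aux_info", "bootstrap", "names.tsv.gz")
      if (!file.exists(bs_path))
        stop("meta_info.json declares ", nboot,
             " bootstraps but ", bs_path, " is missing")
      boot_ids <- read_gz_ids(nm_path)
      if (length(boot_ids) != T)
        stop("names.tsv.gz in ", dir, " lists ", length(boot_ids),
             " transcripts but quant.sf has ", T)
      raw <- read_gz_stream(bs_path)
      nb <- length(raw)
      if (nb == 8L * T * nboot) {
        vals <- readBin(raw, what = "double", n = T * nboot, size = 8L,
                        endian = "little")
      } else if (nb == 4L * T * nboot) {
        vals <- as.double(readBin(raw, what = "integer", n = T * nboot,
                                  size = 4L, endian = "little"))
      } else {
        stop("bootstrap stream in ", dir, " has ", nb,
             " bytes, consistent with neither ", 8L * T * nboot,
             " (doubles) nor ", 4L * T * nboot, " (integers)")
      }
      boots <- matrix(vals, nrow = T, ncol = nboot)
      # stream order may differ from quant.sf order
      m <- match(ids, boot_ids)
      if (anyNA(m))
        stop("bootstrap transcript names in ", dir,
             " do not match quant.sf")
      boots <- boots[m, , drop = FALSE]
    }
  }
  list(ids = ids, lengths = quant$Length, eff_lengths = quant$EffectiveLength,
       counts = quant$NumReads, boots = boots, resample_type = resample_type)
}

# Read an entire gzip-compressed byte stream.
read_gz_stream <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    chunk <- readBin(con, what = "raw", n = 1048576L)
    if (!length(chunk)) break
    chunks[[length(chunks) + 1L]] <- chunk
  }
  do.call(c, chunks)
}

read_gz_ids <- function(path) {
  if (!file.exists(path)) stop("missing ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  line <- readLines(con, warn = FALSE)
  unlist(strsplit(line, "\t", fixed = TRUE))
}

# Align per-sample reads on the first sample's transcript order and build the
# bundle. Shared by the Salmon and kallisto readers.
assemble_bundle <- function(per, sample_ids, dialect, strip_versions, paths) {
  canon <- function(ids) if (strip_versions) sub("\\.\\d+$", "", ids) else ids
  ref_ids <- canon(per[[1L]]$ids)
  T <- length(ref_ids)
  n <- length(per)
  counts <- matrix(0, T, n)
  eff <- matrix(0, T, n)
  boots <- vector("list", n)
  for (i in seq_len(n)) {
    ids_i <- canon(per[[i]]$ids)
    if (length(ids_i) != T || !setequal(ids_i, ref_ids))
      stop("transcript sets differ between samples 1 and ", i)
    m <- match(ref_ids, ids_i)
    counts[, i] <- per[[i]]$counts[m]
    eff[, i] <- per[[i]]$eff_lengths[m]
    boots[[i]] <- per[[i]]$boots[m, , drop = FALSE]
  }
  quant_bundle(
    counts = counts, transcript_ids = ref_ids, bootstraps = boots,
    sample_ids = sample_ids, lengths = per[[1L]]$lengths,
    effective_lengths = eff,
    provenance = list(
      dialect = dialect, paths = paths,
      resample_type = vapply(per, `[[`, character(1), "resample_type"),
      strip_versions = strip_versions))
}

#' Write a Salmon-dialect fixture directory tree
#'
#' Emits, for each sample of the bundle, a directory in the exact dialect that
#' [read_salmon()] consumes: `quant.sf` with Name/Length/EffectiveLength/TPM/
#' NumReads columns at full double precision, `aux_info/meta_info.json` with
#' `num_bootstraps`, and gzipped `bootstraps.gz` / `names.tsv.gz` streams.
#' `read_salmon(write_salmon_fixture(x))` reproduces all numeric fields to
#' better than 1e-9.
#'
#' @param bundle A [quant_bundle()].
#' @param dir Parent directory; one subdirectory per sample is created.
#' @param samp_type Value for the `samp_type` metadata key (`"bootstrap"` by
#'   default; `"gibbs"` exercises the Gibbs-sample warning path).
#' @return Character vector of the per-sample directories, invisibly.
#' @export
write_salmon_fixture <- function(bundle, dir, samp_type = "bootstrap") {
  stopifnot(inherits(bundle, "QuantBundle"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create directory ", dir)
  T <- nrow(bundle$counts)
  lens <- if (is.null(bundle$lengths)) rep(1000L, T) else bundle$lengths
  out <- character(0)
  for (i in seq_along(bundle$sample_ids)) {
    sdir <- file.path(dir, bundle$sample_ids[i])
    dir.create(file.path(sdir, "aux_info", "bootstrap"),
               recursive = TRUE, showWarnings = FALSE)
    eff <- if (is.null(bundle$effective_lengths)) pmax(lens - 200, 1)
           else bundle$effective_lengths[, i]
    y <- bundle$counts[, i]
    tpm_raw <- ifelse(eff > 0, y / eff, 0)
    tpm <- if (sum(tpm_raw) > 0) tpm_raw / sum(tpm_raw) * 1e6 else tpm_raw
    tab <- data.frame(Name = bundle$transcript_ids,
                      Length = lens,
                      EffectiveLength = sprintf("%.17g", eff),
                      TPM = sprintf("%.17g", tpm),
                      NumReads = sprintf("%.17g", y),
                      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(sdir, "quant.sf"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    b <- bundle$bootstraps[[i]]
    B <- ncol(b)
    meta <- list(num_bootstraps = B, samp_type = samp_type,
                 num_valid_targets = T)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
               file.path(sdir, "aux_info", "meta_info.json"))
    if (B > 0L) {
      con <- gzfile(file.path(sdir, "aux_info", "bootstrap", "bootstraps.gz"),
                    "wb")
      # B consecutive records of T little-endian doubles
      writeBin(as.vector(b), con, size = 8L, endian = "little")
      close(con)
      con <- gzfile(file.path(sdir, "aux_info", "bootstrap", "names.tsv.gz"),
                    "wt")
      writeLines(paste(bundle$transcript_ids, collapse = "\t"), con)
      close(con)
    }
    out <- c(out, sdir)
  }
  invisible(out)
}
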