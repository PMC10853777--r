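#' Build a synthetic transcriptome with controlled read-assignment ambiguity
#'
#' Generates genes with 1..K isoforms and an equivalence-class structure that
#' mimics what a lightweight quantifier sees: a fraction `ambiguity` of each
#' transcript's read mass falls into a class shared by all isoforms of its
#' gene, the rest into a transcript-unique class. Single-isoform genes are
#' fully unique. Baseline relative expression is drawn from a gamma
#' distribution (heavy right tail, as in real transcriptomes) and normalized
#' to sum to one; the generative NB dispersion follows a decreasing abundance
#' trend \eqn{\phi_t = \phi_0 + c/\mu_t} evaluated at the reference depth.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Either a single integer (constant isoform count)
#'   or a probability vector over 1..K isoforms.
#' @param ambiguity Fraction of read mass in the gene-shared class, in
#'   \[0, 1\].
#' @param bcv2_base Asymptotic squared biological coefficient of variation;
#'   default 0.04 (BCV 0.2, typical of cell-line experiments).
#' @param bcv2_slope Low-abundance inflation constant `c` in
#'   \eqn{\phi_0 + c/\mu}; default 2.
#' @param baseline_shape Shape of the gamma distribution for baseline
#'   relative expression; default 0.5.
#' @param ref_depth Reference library size at which the dispersion trend is
#'   evaluated; default 5e5.
#' @param seed Optional RNG seed.
#' @return An object of class `SimTruth`.
#' @export
make_transcriptome <- function(n_genes,
                               isoforms_per_gene = c(0.40, 0.22, 0.14, 0.09,
                                                     0.06, 0.04, 0.03, 0.02),
                               ambiguity = 0.7,
                               bcv2_base = 0.04, bcv2_slope = 2,
                               baseline_shape = 0.5, ref_depth = 5e5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ambiguity >= 0, ambiguity <= 1, n_genes >= 1)
  k <- if (length(isoforms_per_gene) == 1L)
    rep(as.integer(isoforms_per_gene), n_genes)
  else
    sample.int(length(isoforms_per_gene), n_genes, replace = TRUE,
               prob = isoforms_per_gene)
  gene_index <- rep(seq_len(n_genes), k)
  T <- length(gene_index)
  transcript_ids <- sprintf("tx%05d", seq_len(T))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  n_isoforms <- k[gene_index]
  # shared-class weight per transcript; single-isoform genes are unique-only
  alpha <- ifelse(n_isoforms > 1L, ambiguity, 0)
  pi0 <- stats::rgamma(T, shape = baseline_shape, scale = 1)
  pi0 <- pmax(pi0, 1e-8)
  pi0 <- pi0 / sum(pi0)
  mu_ref <- pi0 * ref_depth
  bcv2 <- bcv2_base + bcv2_slope / pmax(mu_ref, 1)
  structure(
    list(transcript_ids = transcript_ids,
         gene_map = data.frame(transcript_id = transcript_ids,
                               gene_id = gene_ids[gene_index],
                               stringsAsFactors = FALSE),
         gene_index = gene_index,
         n_isoforms = n_isoforms,
         shared_weight = alpha,
         baseline_expression = pi0,
         bcv2 = bcv2,
         de_labels = rep(0L, T),
         fold_change = rep(1, T),
         true_sigma2 = rep(NA_real_, T)),
    class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d transcripts in %d genes\n",
              length(x$transcript_ids), max(x$gene_index)))
  cat(sprintf("  shared-class weight: %s; DE transcripts: %d\n",
              paste(unique(signif(x$shared_weight, 3)), collapse = "/"),
              sum(x$de_labels != 0L)))
  invisible(x)
}

#' Mark transcripts as differentially expressed
#'
#' Picks `n_de` random transcripts and splits them as evenly as possible into
#' up- and down-regulated at fold change `fc` (applied to the second group).
#'
#' @param truth A `SimTruth`.
#' @param n_de Number of DE transcripts.
#' @param fc Fold change (> 1).
#' @return The updated `SimTruth`.
#' @export
set_de_transcripts <- function(truth, n_de, fc = 2) {
  stopifnot(inherits(truth, "SimTruth"), fc > 0)
  T <- length(truth$transcript_ids)
  if (n_de > T) stop("n_de exceeds the number of transcripts")
  idx <- sample.int(T, n_de)
  up <- idx[seq_len(ceiling(n_de / 2))]
  dn <- setdiff(idx, up)
  truth$de_labels[] <- 0L
  truth$fold_change[] <- 1
  truth$de_labels[up] <- 1L
  truth$de_labels[dn] <- -1L
  truth$fold_change[up] <- fc
  truth$fold_change[dn] <- 1 / fc
  truth
}

#' Draw per-sample true expression proportions
#'
#' Biological replicate variation: each sample's transcript proportion is a
#' gamma draw with mean `baseline * fold_change^(group == 2)` and shape
#' `1/bcv2`, renormalized within the sample. Counts generated from these
#' proportions follow an NB distribution across replicates with dispersion
#' equal to the reciprocal of the gamma shape. A zero dispersion gives
#' constant proportions.
#'
#' @param truth A `SimTruth`.
#' @param n_samples Number of samples.
#' @param group Integer/factor of length `n_samples` with levels 1 and 2;
#'   defaults to all group 1.
#' @param seed Optional RNG seed.
#' @return Matrix transcripts x samples of proportions (columns sum to 1).
#' @export
draw_expression <- function(truth, n_samples, group = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "SimTruth"))
  if (is.null(group)) group <- rep(1L, n_samples)
  group <- as.integer(as.factor(group))
  T <- length(truth$baseline_expression)
  pis <- matrix(0, T, n_samples)
  for (i in seq_len(n_samples)) {
    mean_i <- truth$baseline_expression *
      (if (group[i] == 2L) truth$fold_change else rep(1, T))
    shape <- 1 / truth$bcv2
    x <- ifelse(truth$bcv2 > 0,
                stats::rgamma(T, shape = shape, scale = mean_i / shape),
                mean_i)
    pis[, i] <- x / sum(x)
  }
  rownames(pis) <- truth$transcript_ids
  pis
}

# Class rates for one sample: unique-class rate per transcript and
# shared-class rate per gene (zero for unique-only genes).
class_rates <- function(truth, pi_i, lib_size) {
  uniq <- lib_size * pi_i * (1 - truth$shared_weight)
  shared <- rowsum(lib_size * pi_i * truth$shared_weight,
                   truth$gene_index, reorder = TRUE)[, 1L]
  list(uniq = uniq, shared = shared)
}

# Assign class counts to transcripts: unique counts go to their owner; each
# gene-shared class is split in proportion to the bootstrap's own unique
# evidence (one EM fixed-point pass from abundance-proportional
# initialization, which for this class topology is already the converged EM).
# Genes with no unique evidence in a draw fall back to the true-abundance
# split.
assign_classes <- function(a, s_gene, gene_index, fallback_frac) {
  A <- rowsum(a, gene_index, reorder = TRUE)
  ratio <- a / A[gene_index, , drop = FALSE]
  nan <- is.nan(ratio)
  if (any(nan)) {
    fb <- matrix(fallback_frac, nrow(a), ncol(a))
    ratio[nan] <- fb[nan]
  }
  a + s_gene[gene_index, , drop = FALSE] * ratio
}

#' Draw transcript counts and bootstrap resamples
#'
#' The technical layer of the simulator. Per sample: equivalence-class read
#' counts are Poisson with the class rates implied by the sample's
#' proportions; point-estimate transcript counts come from the EM fixed-point
#' assignment of each shared class to its members. Each bootstrap resamples
#' the class counts (multinomial over classes at the realized total, i.e.
#' read-bootstrap semantics) and re-runs the same assignment, so transcripts
#' in shared classes acquire genuine extra-Poisson variation while unique
#' transcripts stay Poisson.
#'
#' @param truth A `SimTruth`.
#' @param pis Proportion matrix from [draw_expression()].
#' @param lib_sizes Target library sizes, one per sample.
#' @param B Number of bootstrap resamples per sample.
#' @param seed Optional RNG seed.
#' @return A [quant_bundle()] (fractional counts; provenance records the
#'   generator settings).
#' @export
draw_counts_and_bootstraps <- function(truth, pis, lib_sizes, B = 100L,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "SimTruth"))
  n <- ncol(pis)
  if (length(lib_sizes) != n) stop("one library size per sample required")
  T <- length(truth$transcript_ids)
  gidx <- truth$gene_index
  w <- truth$shared_weight
  counts <- matrix(0, T, n)
  boots <- vector("list", n)
  for (i in seq_len(n)) {
    cr <- class_rates(truth, pis[, i], lib_sizes[i])
    W <- rowsum(pis[, i] * w, gidx, reorder = TRUE)[, 1L]
    fallback <- ifelse(W[gidx] > 0, pis[, i] * w / W[gidx], 0)
    a0 <- stats::rpois(T, cr$uniq)
    s0 <- stats::rpois(length(cr$shared), cr$shared)
    counts[, i] <- assign_classes(cbind(a0), cbind(s0), gidx, fallback)[, 1L]
    if (B > 0L) {
      tot <- sum(a0) + sum(s0)
      probs <- c(a0, s0) / tot
      m <- stats::rmultinom(B, tot, probs)
      boots[[i]] <- assign_classes(m[seq_len(T), , drop = FALSE],
                                   m[-seq_len(T), , drop = FALSE],
                                   gidx, fallback)
    }
  }
  quant_bundle(counts, transcript_ids = truth$transcript_ids,
               bootstraps = if (B > 0L) boots else NULL,
               sample_ids = sprintf("sim%02d", seq_len(n)),
               provenance = list(dialect = "simulated", B = B))
}

#' Brute-force ground-truth RTA overdispersion
#'
#' Monte-Carlo oracle: at fixed proportions, repeat the technical process
#' (class draw + assignment) `n_mc` times per sample and pool the Pearson
#' statistic var/mean over samples, exactly the quantity the bootstrap-based
#' estimator targets. Unique-only transcripts give values near 1; shared
#' transcripts are inflated by the noisy assignment.
#'
#' @param truth A `SimTruth`.
#' @param pis Proportion matrix from [draw_expression()].
#' @param lib_sizes Library sizes.
#' @param n_mc Monte-Carlo draws per sample; default 500.
#' @param seed Optional RNG seed.
#' @return Per-transcript true overdispersion (NA for transcripts with zero
#'   expected count everywhere).
#' @export
true_sigma2 <- function(truth, pis, lib_sizes, n_mc = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "SimTruth"))
  T <- length(truth$transcript_ids)
  gidx <- truth$gene_index
  w <- truth$shared_weight
  ss <- numeric(T)
  df <- numeric(T)
  for (i in seq_len(ncol(pis))) {
    cr <- class_rates(truth, pis[, i], lib_sizes[i])
    W <- rowsum(pis[, i] * w, gidx, reorder = TRUE)[, 1L]
    fallback <- ifelse(W[gidx] > 0, pis[, i] * w / W[gidx], 0)
    rates <- c(cr$uniq, cr$shared)
    tot <- round(sum(rates))
    m <- stats::rmultinom(n_mc, tot, rates / sum(rates))
    u <- assign_classes(m[seq_len(T), , drop = FALSE],
                        m[-seq_len(T), , drop = FALSE], gidx, fallback)
    lam <- rowMeans(u)
    pos <- lam > 0
    dev <- u[pos, , drop = FALSE] - lam[pos]
    ss[pos] <- ss[pos] + rowSums(dev * dev) / lam[pos]
    df[pos] <- df[pos] + (n_mc - 1)
  }
  ifelse(df > 0, ss / df, NA_real_)
}

#' Build a complete simulation scenario
#'
#' Desk-scale counterpart of a two-group RNA-seq benchmark: ~5000 transcripts
#' by default, a random subset differentially expressed at 2-fold change
#' (split up/down), 100 bootstrap resamples per sample, and unbalanced
#' library sizes alternating between 0.25 and 1 million reads (the published
#' 25M/100M pattern scaled down 1:100). The null scenario is identical with
#' no fold changes.
#'
#' @param name `"de"` or `"null"`.
#' @param n_per_group Samples per group; default 5.
#' @param n_genes Number of genes; default 1980 (about 5000 transcripts under
#'   the default isoform distribution).
#' @param n_de Number of DE transcripts (`"de"` scenario); default 300.
#' @param fc Fold change; default 2.
#' @param B Bootstrap resamples per sample; default 100.
#' @param lib_sizes Library sizes; default alternating 2.5e5 and 1e6.
#' @param ambiguity Shared-class weight; default 0.7.
#' @param isoforms_per_gene Isoform count distribution, see
#'   [make_transcriptome()].
#' @param seed RNG seed (single seed drives the entire scenario).
#' @return List with elements `bundle` (a [quant_bundle()]), `truth`
#'   (a `SimTruth`), `group` (factor), and `pis`.
#' @export
build_scenario <- function(name = c("de", "null"), n_per_group = 5L,
                           n_genes = 1980L, n_de = 300L, fc = 2,
                           B = 100L, lib_sizes = NULL, ambiguity = 0.7,
                           isoforms_per_gene = c(0.40, 0.22, 0.14, 0.09,
                                                 0.06, 0.04, 0.03, 0.02),
                           seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  n <- 2L * n_per_group
  if (is.null(lib_sizes)) lib_sizes <- rep(c(2.5e5, 1e6), length.out = n)
  truth <- make_transcriptome(n_genes, isoforms_per_gene = isoforms_per_gene,
                              ambiguity = ambiguity,
                              ref_depth = stats::median(lib_sizes))
  if (name == "de") truth <- set_de_transcripts(truth, n_de = n_de, fc = fc)
  group <- factor(rep(c(1L, 2L), each = n_per_group))
  pis <- draw_expression(truth, n_samples = n, group = group)
  bundle <- draw_counts_and_bootstraps(truth, pis, lib_sizes, B = B)
  list(bundle = bundle, truth = truth, group = group, pis = pis)
}

#' Score a DTE result against simulation truth
#'
#' @param results A `DTEResult` data frame (from [ql_ftest()] or
#'   [run_dte()]).
#' @param truth The `SimTruth` the data came from.
#' @param alpha Nominal threshold; default 0.05.
#' @return List with `power` (true positives over true DE among tested
#'   transcripts), `observed_fdr` (false positives over calls at
#'   `fdr <= alpha`; 0 when nothing is called), and `type1` (fraction of
#'   null transcripts with raw p below `alpha`).
#' @export
score_run <- function(results, truth, alpha = 0.05) {
  stopifnot(inherits(truth, "SimTruth"))
  m <- match(results$transcript_id, truth$transcript_ids)
  if (anyNA(m)) stop("result transcripts missing from truth")
  is_de <- truth$de_labels[m] != 0L
  called <- results$fdr <= alpha
  tp <- sum(called & is_de)
  fp <- sum(called & !is_de)
  power <- if (any(is_de)) tp / sum(is_de) else NA_real_
  list(power = power,
       observed_fdr = fp / max(1L, sum(called)),
       type1 = mean(results$p_value[!is_de] < alpha))
}
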