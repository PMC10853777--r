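---
title: "Dividing read-to-transcript-ambiguity overdispersion out of transcript counts"
author: "rtadte developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dividing read-to-transcript-ambiguity overdispersion out of transcript counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtadte)
```

## The variance model

For an experiment with $n$ samples and $T$ annotated transcripts, let
$y_{ti}$ be the fractional number of reads a quantifier assigns to
transcript $t$ in sample $i$, $N_i$ the library size and $\pi_{ti}$ the
(unobserved) proportion of cDNA fragments originating from $t$. Conditional
on $\pi_{ti}$, gene-level counts are classically Poisson; transcript-level
counts are not, because reads compatible with several isoforms are assigned
only probabilistically. The assignment error depends on annotation topology
— how much transcript $t$ overlaps its sibling isoforms — which is
transcript-specific but sample-independent, and both the mean and the
variance of $y_{ti}$ must stay proportional to $N_i\pi_{ti}$. That forces a
quasi-Poisson form,

$$\mathrm{var}(y_{ti} \mid \pi_{ti}) = \sigma^2_t \, \mu_{ti},
  \qquad \mu_{ti} = N_i \pi_{ti}, \qquad \sigma^2_t \ge 1 .$$

Letting $\pi_{ti}$ vary across biological replicates with constant squared
coefficient of variation $\phi_t$ gives, by the law of total variance,

$$\mathrm{var}(y_{ti}) = \sigma^2_t\mu_{ti} + \phi_t\mu_{ti}^2 .$$

The technical factor $\sigma^2_t$ is neither additive nor multiplicative to
the NB variance function, so it cannot be absorbed as observation weights
in a linear model. The way out is to *divide it out*: the scaled count
$z_{ti} = y_{ti}/\sigma^2_t$ satisfies
$\mathrm{var}(z_{ti}) = \nu_{ti} + \phi_t\nu_{ti}^2$ with
$\nu_{ti} = \mu_{ti}/\sigma^2_t$ — an ordinary NB mean-variance
relationship — while all fold changes are preserved. Scaling deliberately
*reduces* the effective number of reads: a transcript with $\sigma^2_t = 7$
carries the information of one seventh of its nominal reads.

## Estimating $\sigma^2_t$ from bootstraps

Quantifier bootstraps resample reads at the level of equivalence classes,
which are unambiguous; the resample is then re-quantified. Hence all
extra-Poisson scatter among the bootstrap counts $u_{ti1},\dots,u_{tiB_i}$
is assignment uncertainty, and the Pearson-residual moment estimator

$$\hat\sigma^2_t = \frac{1}{d_t}\sum_{i}\sum_{b}
  \frac{(u_{tib}-\hat\lambda_{ti})^2}{\hat\lambda_{ti}},
  \qquad \hat\lambda_{ti} = \tfrac{1}{B_i}\sum_b u_{tib},$$

is unbiased (mean 1) under pure Poisson resampling. A sample whose
bootstrap mean $\hat\lambda_{ti}$ is zero carries no information about
transcript $t$; it contributes to neither the numerator nor the degrees of
freedom, so $d_t = \sum_{i\,:\,\hat\lambda_{ti}>0}(B_i-1)$, which reduces
to $n(B-1)$ when every sample is expressed with a common $B$. Unequal $B_i$
across samples are supported for the same reason.

**Empirical Bayes moderation.** With $d_t$ typically in the hundreds the
raw estimator is already precise, but lowly expressed transcripts benefit
from light shrinkage toward a global prior
$\hat\sigma^2_0 = \max\{1,\; Q_2(\hat\sigma^2_t)/Q_2(F_{d_\mathrm{med},d_0})\}$,
where both medians are taken over *expressed* transcripts (here: $d_t > 0$
and a finite raw estimate; zero-count transcripts carry no information) and
$Q_2(F_{d_\mathrm{med},d_0})$ is the median of an F distribution whose
numerator degrees of freedom $d_\mathrm{med}$ is the median $d_t$. Dividing
by the F median removes the downward bias of a median of scaled-$\chi^2$
draws. The moderated value is the df-weighted combination
$\tilde\sigma^2_t = \max\{1, (d_0\hat\sigma^2_0 + d_t\hat\sigma^2_t)/(d_0+d_t)\}$,
clamped at 1 because probabilistic assignment can only add variance. The
prior degrees of freedom default to $d_0 = 3$; the value is conventional
rather than derived, so it is an exposed parameter (`prior_df`) everywhere,
including the CLI. $d_\mathrm{med}$ is computed *after* excluding
zero-mean samples — the other order is defensible but changes $d_t$ only
for partially expressed transcripts.

Counts stay continuous end to end. Quantifier estimates are fractional by
nature and the downstream NB machinery uses a continuous generalization of
the NB deviance, so nothing is ever rounded.

## The DTE engine

The pipeline after scaling is deliberately a standard quasi-NB analysis so
that the scaled-vs-raw comparison isolates the effect of scaling. The
stages, with every rule pinned here rather than delegated:

* **Expression filter.** Keep transcript $t$ if its CPM exceeds
  $c = \mathrm{min\_count}/\mathrm{median}(N_i)\times 10^6$ in at least
  $k = \mathrm{min\_prop}\times(\text{smallest group size})$ samples
  (compared with a $10^{-14}$ tolerance, so $k = 2.1$ requires 3 passing
  samples while an exact $k = 2$ requires 2) *and* its total count is at
  least `min_total`. Defaults 10 / 0.7 / 15. Filtering operates on the
  scaled counts when scaling was applied, mirroring the pipeline order.
  The filter is idempotent and order-preserving.
* **TMM normalization.** Composition factors from the doubly trimmed
  (30% on M, 5% on A), precision-weighted mean of log2 ratios against the
  sample whose upper quartile is closest to the mean upper quartile;
  factors rescaled to geometric mean 1. Zeros in either sample are dropped
  pairwise. Exact scale invariance does not hold (the binomial precision
  weights involve the library size) but deviations are at the third
  decimal; the implementation agrees with the reference TMM implementation
  to $10^{-3}$ on random data.
* **Dispersion trend.** Per-transcript Pearson moment estimates of
  $\phi_t$ (solving $\sum_i (y-\hat\mu)^2/[\hat\mu(1+\phi\hat\mu)] = n-p$
  by Newton steps from a Poisson start), binned by average log2-CPM (up to
  20 quantile bins), bin medians smoothed by lowess ($f = 0.5$) and floored
  at zero. A single bin degenerates to a constant trend.
* **Quasi-likelihood F-tests.** NB GLMs with log link and log effective
  library sizes as offsets are fitted by Fisher scoring at the trended
  dispersion (relative deviance tolerance $10^{-8}$, 50 iterations,
  per-transcript convergence flags; batched closed-form solves for up to
  two coefficients). The raw quasi-dispersion is residual deviance over
  residual df; it is squeezed toward a lowess trend in abundance by
  F-moment matching on the log scale (trigamma inversion by Newton), giving
  a prior df. Contrasts are tested by the deviance difference between the
  full fit and a refit on the null-space-reduced design — an F construction,
  not Wald — with
  $F = (\Delta\mathrm{dev}/q)\,/\,s^2_\mathrm{shrunk}$ referred to
  $F_{q,\,d_\mathrm{res}+d_\mathrm{prior}}$. Zero residual df with an
  infinite prior falls back to $\chi^2$ p-values with a warning.
  Benjamini-Hochberg is implemented directly (and property-tested against a
  brute-force step-up).

This QL procedure is *a* pinned, fully documented variant, not a
bit-for-bit reimplementation of any other package's internals (which have
their own bias adjustments and legacy/new modes); correctness is assessed
by statistical properties — null calibration, FDR control, power ordering —
which the test suite checks by simulation.

## What the simulator emulates

The generator reproduces, at the count level, the statistical structure the
method relies on, with ground truth that read-level simulation cannot give
without running an aligner:

1. **Topology.** Genes receive $1..K$ isoforms (default distribution with
   mean ≈ 2.5, up to 8). Each transcript of a multi-isoform gene sends a
   fraction `ambiguity` of its read mass to a class shared by all isoforms
   of its gene and the rest to a unique class; single-isoform genes are
   fully unique. This star topology is the simplest structure with the two
   ingredients that matter: unambiguous evidence and shared mass.
2. **Biology.** Baseline relative expression is gamma with shape 0.5
   (heavy right tail); replicate proportions are gamma with squared CV
   $\phi_t = 0.04 + 2/\mu_t$ evaluated at the reference depth — a BCV of
   0.2 for abundant transcripts, inflated at low abundance, typical of
   designed experiments on cell lines or inbred animals. Counts generated
   from these proportions are NB across replicates with dispersion equal to
   the reciprocal gamma shape.
3. **Technics.** Class counts are Poisson at rates $N_i \times$ (class
   mass). Bootstraps resample the realized class counts (multinomial at
   the realized total — read-bootstrap semantics). Assignment of a shared
   class splits it in proportion to the draw's *own* unique-class counts:
   one EM fixed-point pass from abundance-proportional initialization,
   which for the star topology is already the converged EM. Because the
   unique evidence is itself noisy, shared transcripts acquire genuine
   extra-Poisson variance whose size grows with the shared-to-unique
   ratio — overdispersion rises with isoform count and ambiguity, with
   $\sigma^2 \approx 1$ for unique transcripts, $\approx 2$ at two isoforms
   with ambiguity $2/3$, and $5{-}10$ at ten isoforms with ambiguity 0.9.
   A gene with *no* unique evidence in a draw has a flat EM likelihood; the
   generator then falls back to the true-abundance split, which makes the
   fully shared case essentially Poisson rather than inflated — full
   sharing is unidentifiable for any assignment procedure, deterministic
   splits cannot inflate variance, and real annotations practically always
   leave some unique sequence. The brute-force oracle `true_sigma2()`
   replays the technical layer afresh many times at fixed proportions, so
   estimator-recovery tests close the loop against the mechanism itself,
   not against a formula.
4. **Scenarios.** `build_scenario()` assembles ~5000 transcripts, 300 DE
   at 2-fold (split up/down) or a null with no fold changes, 5 samples per
   group, $B = 100$ bootstraps, and unbalanced library sizes alternating
   0.25M/1M — the published benchmark's 25M/100M pattern scaled down 1:100
   so that a full scenario simulates and analyses in seconds. One seed
   drives everything; identical seeds give bit-identical bundles.

What a green simulation test does **not** establish: behaviour under real
annotation topologies (nested and partially overlapping classes rather than
a star), quantifier-specific bias models, fragment-length or GC effects,
Gibbs-sampler posterior draws (accepted by the readers with a warning, but
their variance need not equal bootstrap variance), or read-length effects —
those require read-level simulation through an actual quantifier.

## Numerical choices and degenerate inputs

* Bootstrap streams: auto-detect 8-byte doubles vs 4-byte integers by byte
  count; doubles preferred on (impossible-in-practice) ambiguity; the
  choice lands in provenance.
* Transcript reconciliation across samples is by exact identifier;
  version-suffix stripping is opt-in (`strip_versions`), never silent.
* GLM safeguards: $\eta$ clipped to $\pm 50$, singular per-transcript
  systems keep the previous iterate and are reported as non-converged
  (never fatal).
* `sigma2_hat` is `NA` when $d_t = 0$; moderation then returns
  $\max(1, \hat\sigma^2_0)$.
* Ties in BH are handled by the cummin step-up; `fdr >= p` always.
* Fold-change preservation under scaling is exact in real arithmetic and
  verified at $10^{-12}$ relative tolerance (floating-point division
  forbids a bitwise claim).
* The overdispersion moderation uses the F quantile with possibly
  non-integer $d_\mathrm{med}$ (continuous df are well-defined).

## Known limitations

* The QL engine matches reference implementations in behaviour, not in
  bits; users comparing against other toolchains should expect p-values to
  differ in the third decimal while rankings agree.
* TMM factors are only approximately invariant to rescaling a column
  (inherited from the precision weights of the original method).
* The simulator's star-shaped class topology understates the variety of
  real equivalence-class graphs; its $\sigma^2$ range (≈1–10 at the
  defaults) covers the realistic regime but is not calibrated to any
  particular annotation.
* Long-read data, where ambiguity is nearly absent, is handled trivially
  (estimates near 1, scaling a no-op); no long-read-specific modelling is
  attempted.
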