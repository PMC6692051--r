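---
title: "Primacy coding of odors: model, statistics, and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primacy coding of odors: model, statistics, and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(primacode)
```

## The model

An odor is a concentration vector $c = (c_1, \dots, c_{N_L})$ over the
$N_L$ ligand species the receptor repertoire can detect; typical odors
contain only tens of ligands, so most entries are zero.  Each of the
$N_R$ receptor types (represented at the level of its glomerulus) responds
linearly,
$$ e_n = \sum_{i=1}^{N_L} S_{ni}\, c_i , $$
with a sensitivity matrix $S_{ni}$ whose entries are broadly distributed.
Under *primacy coding* the odor identity is carried by the set of the
$N_C$ receptor types with the largest excitations — the primacy set —
encoded as a binary activity vector $a$ with exactly $N_C$ ones.  Because
multiplying $c$ by a constant scales all excitations (and the implied
threshold $\gamma$) alike, the primacy set is independent of the odor
intensity: only relative excitations matter.  The alternatives implemented
for comparison are *binary coding* ($a_n = 1$ iff $e_n > \gamma$ for a
fixed $\gamma$) and *normalized coding* ($a_n = 1$ iff
$e_n > \alpha \bar e$), whose sparsity, unlike primacy coding's, depends
on the odor statistics.

Since the map from odor to pattern is deterministic, the information the
pattern carries about the odor is the output entropy
$I = -\sum_a P(a) \log_2 P(a)$, bounded by the capacity
$I_{\max}(N_C, N_R) = \log_2 \binom{N_R}{N_C}$, which is attained when all
primacy sets are equiprobable.  $I$ grows roughly linearly in $N_C$ but
only logarithmically in $N_R$ — halving the repertoire costs about $N_C$
bits — which is why repertoire lesions are predicted to matter little in
large arrays.

## Stochastic ingredients

**Odor environment.**  Ligand $i$ is present with probability
$p = s/N_L$ (independently; co-occurrence correlations are out of scope),
and a present ligand draws its concentration from a log-normal with
*distribution* mean $\mu$ and standard deviation $\sigma$.  The defaults
($N_L = 512$, $s = 16$, $\mu = \sigma = 1$) are the reference conditions
used throughout the information experiments.  Note the parameterization
asymmetry, which is deliberate and documented on every constructor: for
concentrations, $(\mu, \sigma)$ are moments of the distribution itself
(underlying normal parameters are obtained by moment matching), whereas
the sensitivity width $\lambda$ is the standard deviation of the
*underlying* normal, so that $\mathrm{var}(S)/\bar S^2 = e^{\lambda^2}-1
\approx 1.72$ at the default $\lambda = 1$.  A log-uniform sensitivity
family is provided as well, parameterized by its variance ratio (a ratio
of 7 corresponds to a support of about 7 decades); primacy-coding results
are insensitive to this choice, and to the overall sensitivity scale
$\bar S$, which the tests verify.

**Ensemble convention.**  Sensitivity matrices are redrawn for every
Monte Carlo trial (ensemble averages over sensitivity matrices), and for
entropy estimates a fresh odor *and* a fresh matrix are drawn per sample.
Per-receptor sensitivity factors $\xi_n$, in contrast, are a persistent
property of one receptor array: they are held fixed across all samples of
one entropy estimate, and heterogeneity statements average the resulting
information over independently drawn factor vectors.  Redrawing $\xi$ per
sample would restore exchangeability across receptors and destroy the
very effect being measured.

**Zero odors.**  An odor with no present ligand has no primacy set; such
draws are resampled and counted (`n_resampled` attribute).  At the
reference conditions ($s = 16$) the event is vanishingly rare; the choice
only matters for sparse environments.

## Statistical theory

For a given odor the excitations across receptor types are approximately
log-normal with scale-invariant log-width
$$ \zeta(c) = \tfrac12 \ln\!\Big[ 1 + (e^{\lambda^2}-1)
   \frac{\sum_i c_i^2}{(\sum_i c_i)^2} \Big]. $$
The theory works with the unit-mean log-normal CDF $G(x;\zeta)$
(`excitation_cdf()`), for which the mean primacy threshold is
$\langle\gamma\rangle = \langle e_n\rangle\, G^{-1}(1 - N_C/N_R;\zeta)$ —
equivalently, primacy coding is normalized coding whose inhibition
strength $\alpha = G^{-1}(1-N_C/N_R;\zeta)$ adapts to the width of the
excitation distribution.

For the environment as a whole, the concentration ratio in $\zeta$ is
replaced by its ensemble value $(1+\sigma^2/\mu^2)/s$.  This substitution
treats the mixture size as exactly $s$ and the denominator as
concentrated (a ratio-of-moments evaluation); the per-odor ratio is
bounded by 1, so the substitution is an approximation that is excellent
for large mixtures and is *not* an unbiased expectation of the per-odor
ratio at small $s$.  The tests verify it in its moment-matched reading
and, directly, at large $s$.

```{r}
zeta_from_env(mixture_size = 16, conc_cv = 1, log_width = 1)
```

**Discrimination.**  For two odors of a scenario (target added to a
single-ligand or multi-ligand background; two mixtures sharing part of
their ligands) the expected Hamming distance between the primacy sets is
obtained by quadrature over threshold-crossing probabilities
(`expected_distance()`), with the thresholds of the two odors estimated
from their respective excitation statistics.  The mapping from distance
to the detection probability,
$\eta(d) = 1 - (1 - d/2N_C)^{N_C}$, models the distance as binomial over
$\{0, 2, \dots, 2N_C\}$.  Two accuracy remarks, quantified in the test
suite: the quadrature $d$ agrees with simulation to a few percent
mid-curve but overestimates by $\sim$14% for very dilute targets, and the
binomial mapping deviates from the simulated $\eta$ by up to $\sim$0.06
at intermediate $\eta$ (it is tight at both ends).  Both the analytic and
the Monte Carlo $\eta$ (fraction of trials with $d > 0$) are therefore
always reported side by side.  For uncorrelated odors
$d_* = 2N_C(1 - N_C/N_R)$, giving the near-certain bound
$\eta_* = 1 - (N_C/N_R)^{N_C}$.

**Order statistics.**  The robustness of the primacy set is controlled by
the excitation gap at the primacy boundary, i.e. between the ranked
excitations $e_{(N_R-N_C)}$ and $e_{(N_R-N_C+1)}$ (strongest inactive vs
weakest active type).  `order_stat_model()` exposes rank densities, the
gap density, and mean gaps by quadrature; for heavy-tailed excitation
distributions the boundary gap grows with $N_R$, which is why *larger*
repertoires can make dilute targets *harder* to detect.  The
implementation uses the verbal rank convention above; exponential order
statistics (mean gap $1/(N_R - r + 1)$) serve as the closed-form oracle
in the tests.

## Numerical choices

* **Monte Carlo kernels** (pattern sampling, discrimination trials,
  scheme comparison) are compiled (Rcpp) and draw through R's RNG, so a
  single `set.seed()`/`seed` argument makes every experiment bit
  reproducible.  Pattern codes are receptor bitmasks, which caps the
  entropy pipelines at $N_R \le 30$ — ample for entropy estimation, which
  needs $n \gg \binom{N_R}{N_C}$ anyway.
* **Entropy estimation** uses the plug-in estimator with a delta-method
  standard error; the Miller–Madow correction is reported alongside, and
  a warning fires when $n < 50\,K$ for $K$ observed patterns.  The
  negative bias $\approx (K-1)/(2n\ln 2)$ bits is the reason desk-scale
  information experiments use $(N_R, N_C)$ like $(16, 4)$ or $(20, 4)$,
  where $10^6$ samples put the bias below $0.005$ bits.
* **Problem sizes.**  Default trial counts are desk-scale: $10^4$ trials
  per discrimination grid point, $10^5$ for headline detection numbers,
  $10^6$ patterns per entropy point, and 16 array realizations for
  distributed-heterogeneity averages (62\,500 samples each).  All are
  arguments, so paper-scale runs ($10^5$/$10^7$) are one flag away.
* **Quadrature** uses adaptive integration with tolerance $10^{-9}$;
  failures re-raise with the scenario parameters attached.  Binomial
  coefficients are evaluated in log space throughout (`lchoose`,
  `lgamma`), so $N_R = 1000$ poses no overflow risk, and the
  identification bound $\binom{N_R-N_C}{d/2}$ is interpolated
  continuously in $d$ for curves (round-half-to-even when an integral
  count is requested).
* **Ties** at the primacy boundary go to the lower receptor index — a
  probability-zero event for continuous sensitivities, made deterministic
  for testability.  The recorded threshold is the largest excluded
  excitation, making the activity rule hold with strict inequality.
* **Calibration** of the alternative schemes (binary $\gamma$, normalized
  $\alpha$) is a monotone root solve on a fixed single-ligand ensemble
  (common random numbers), so both schemes activate a prescribed mean
  number of glomeruli for single ligands; the same convention is applied
  to both schemes for comparability since no absolute threshold value is
  canonical.

## Worked example

Information transmitted by a small array, next to its capacity:

```{r}
run_information_experiment(n_receptors = 16, n_primacy = c(2, 4, 6),
                           n_samples = 20000, seed = 1)
```

Detection of a weak target on a single-ligand background, Monte Carlo
against theory:

```{r}
sc <- mixture_scenario("target_in_single_background", target_conc = 0.2)
run_discrimination_experiment(sc, tibble::tibble(target_conc = c(0.1, 0.2, 0.4)),
                              n_trials = 2000, n_receptors = 300,
                              n_primacy = 8, seed = 1)
```

A receptor type 1.5 times more sensitive than its peers transmits less
information than no receptor at all:

```{r}
het <- run_heterogeneity_experiment("single_factor",
                                    grid = c(0, 1, 1.5, 2),
                                    n_samples = 20000, seed = 1)
het[het$metric == "information", c("xi1", "value", "se")]
```

## What the generator does and does not emulate

The synthetic environment reproduces the statistical skeleton real odor
scenes are usually reduced to — sparse ligand occupancy, broad
(log-normal) concentrations, broad receptor sensitivities — and nothing
more.  It omits co-occurrence correlations between ligands, per-ligand
heterogeneity of $(p_i, \mu_i, \sigma_i)$, receptor nonlinearities,
antagonism and saturation, and all temporal structure (rank and latency
information).  Passing tests therefore validate the coding-theoretic
claims under these idealized statistics; they do not certify performance
on measured receptor data, though measured sensitivity matrices can be
injected through the CSV interface.  All identification results are
perfect-decoder counting bounds: upper limits, not predictions of
realized behavioral performance.

## Known limitations

* Entropy pipelines require $N_R \le 30$ (bitmask codes); capacity-based
  quantities have no such limit.
* The analytic $\eta$ inherits the accuracy limits quantified above;
  treat the Monte Carlo columns as ground truth where they disagree.
* The Stirling form of the capacity is within 5% of exact only once
  $N_C$ itself is moderately large (e.g. $N_C = 8$ at $N_R = 1000$, or
  $N_C \ge 12$ at $N_R/N_C = 50$); use `method = "exact"` unless a
  closed form is needed.
* `heterogeneity_crossing()` interpolates linearly on the sweep grid; its
  resolution is the grid spacing.
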