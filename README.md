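# primacode

Simulation and statistical theory of **primacy coding** in olfactory
receptor arrays.

The olfactory system must recognize what an odor is independently of how
strong it is.  Primacy coding proposes that the odor identity is carried
by the identities of the `N_C` receptor types (glomeruli) that respond
most strongly — the *primacy set* — a sparse, concentration-invariant
combinatorial code.  `primacode` implements a complete, seeded pipeline
around this idea for computational-neuroscience use:

* a parametric **odor environment** (Bernoulli ligand presence with mean
  mixture size `s`, log-normal concentrations) and deterministic mixture
  scenarios (target in a background, ligand added to a mixture, pairs of
  mixtures sharing ligands);
* **receptor sensitivity ensembles**: i.i.d. log-normal (width `λ`, so
  `var(S)/S̄² = e^{λ²}−1`) or log-uniform matrices, with per-receptor
  sensitivity factors `ξ_n` for modeling overly sensitive or silenced
  receptor types, plus CSV import of measured matrices;
* **coding schemes**: primacy (`e = S c`, top-`N_C` rule), binary
  (fixed threshold), and normalized (threshold `α·mean(e)`) codes, with
  calibration utilities;
* **information metrics**: plug-in/Miller–Madow entropy of the pattern
  ensemble, the capacity `I_max = log2 C(N_R, N_C)`, grouped-code
  information for heterogeneous receptors, and perfect-decoder
  identification bounds (`C(N_L, s) < C(N_R, N_C)`);
* the **closed-form statistical theory**: log-normal excitation
  statistics with scale-invariant width
  `ζ = ½ ln[1 + (e^{λ²}−1) Σc²/(Σc)²]`, mean primacy thresholds
  `⟨γ⟩ = ⟨e⟩ G⁻¹(1−N_C/N_R; ζ)`, order-statistics gap distributions, and
  quadrature predictions of the expected code distance `d` and the
  discriminability `η(d) = 1 − (1 − d/2N_C)^{N_C}`;
* tidy, seeded **experiment pipelines** (`run_*` functions returning
  tibbles with standard errors, `autoplot()` methods, `tidy()`/`glance()`
  for entropy results) and a thin **CLI**
  (`inst/cli/primacode.R`, or `run_cli()` from R).

Monte Carlo inner loops are compiled (Rcpp) and draw through R's RNG, so
every result is reproducible from its configuration plus one seed.

## Worked example

```r
library(primacode)

# Information transmitted by a 16-type array vs its capacity
run_information_experiment(n_receptors = 16, n_primacy = c(2, 4),
                           n_samples = 20000, seed = 1)
#>   n_receptors n_primacy metric      value        se n_trials  seed
#> 1          16         2 information  6.90  0.000741    20000     1
#> 2          16         2 capacity     6.91 NA              NA     1
#> 3          16         4 information 10.8   0.00299     20000     1
#> 4          16         4 capacity    10.8  NA              NA     1
```

The transmitted information sits just below the capacity
`log2 C(16, N_C)` — the primacy code uses the receptor types nearly
uniformly (the residual gap at `N_C = 4` is plug-in estimator bias).

```r
# Can adding a target ligand at 20% of a background ligand's
# concentration be detected?  (human-scale repertoire, N_R = 300)
sc <- mixture_scenario("target_in_single_background", target_conc = 0.2)
run_discrimination_experiment(sc, tibble::tibble(target_conc = c(0.1, 0.2, 0.4)),
                              n_trials = 2000, n_receptors = 300,
                              n_primacy = 8, seed = 1)
#>   target_conc     metric value      se
#> 1         0.1        eta 0.240 0.00954
#> 2         0.1 eta_theory 0.238      NA
#> 3         0.2        eta 0.497 0.01118
#> 4         0.2 eta_theory 0.454      NA
#> 5         0.4        eta 0.849 0.00801
#> 6         0.4 eta_theory 0.787      NA
```

A target at one fifth of the background concentration changes the
primacy set in about half the trials (`eta ≈ 0.5`), Monte Carlo and
analytic prediction side by side.  Two closed-form anchors:

```r
100 * discriminability(2 * 4 * (1 - 4/50), 4)  # uncorrelated odors, N_C=4, N_R=50
#> 99.9959                                      # percent: nearly always distinct
max_mixture_size(300, 8, 1000)                 # identifiable mixture size, 1000-ligand library
#> 6
```

From the shell:

```sh
Rscript inst/cli/primacode.R detect --nr 300 --nc 8 \
  --grid 0.05:1.0:20 --trials 10000 --seed 1 --out detection.csv
```

writes a tidy CSV (Monte Carlo `eta` ± SE next to the theory columns)
plus a JSON metadata sidecar.

## Further reading

The methods vignette (`vignettes/primacy-coding.Rmd`) documents the
model assumptions, the ensemble conventions (when sensitivity matrices
are redrawn, when sensitivity factors are held fixed), the accuracy of
the analytic approximations, and all numerical choices and limitations.
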