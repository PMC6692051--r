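#' Monte Carlo sample of primacy patterns
#'
#' Draws `n_samples` primacy-set patterns under the odor environment: for
#' every sample a fresh odor and a fresh sensitivity matrix are drawn
#' (ensemble average over sensitivity matrices), the excitations are
#' computed and the top `n_primacy` receptor types are recorded as a
#' bitmask code.  Per-receptor sensitivity factors `factors` are a fixed
#' property of the array: they persist across all samples (heterogeneity
#' across arrays is modeled by calling this function once per drawn
#' factor vector and averaging the resulting information).  Odors with
#' zero present ligands are redrawn; the number of redraws is available
#' as `attr(codes, "n_resampled")`.
#'
#' @param n_samples number of patterns to draw.
#' @param n_receptors repertoire size (at most 30, so patterns fit an
#'   integer bitmask).
#' @param n_primacy primacy dimension.
#' @param env an [odor_environment()].
#' @param log_width sensitivity width `lambda`.
#' @param factors fixed per-receptor sensitivity factors (default all 1).
#' @return Integer vector of pattern bitmask codes (bit `n - 1` set iff
#'   receptor `n` is in the primacy set).
#' @examples
#' env <- odor_environment(n_ligands = 64, mean_mixture_size = 4)
#' codes <- simulate_primacy_patterns(1000, 8, 2, env)
#' entropy_from_samples(codes, n_primacy = 2, n_receptors = 8)
#' @export
simulate_primacy_patterns <- function(n_samples, n_receptors, n_primacy,
                                      env = odor_environment(),
                                      log_width = 1, factors = NULL) {
  stopifnot(inherits(env, "odor_env"), n_receptors <= 30,
            n_primacy >= 1, n_primacy <= n_receptors)
  if (env$presence_prob <= 0) stop("presence probability is zero")
  lp <- lognormal_from_moments(env$conc_mean, env$conc_sd^2)
  if (is.null(factors)) factors <- rep(1, n_receptors)
  stopifnot(length(factors) == n_receptors)
  cpp_primacy_pattern_codes(
    as.integer(n_samples), as.integer(n_receptors), as.integer(n_primacy),
    env$n_ligands, env$presence_prob,
    lp$meanlog, lp$sdlog,
    as.numeric(factors),
    -log_width^2 / 2, log_width
  )
}

#' Per-receptor activation frequency of a pattern sample
#'
#' @param codes integer bitmask codes from [simulate_primacy_patterns()].
#' @param n_receptors repertoire size.
#' @return Numeric vector: fraction of samples in which each receptor is
#'   part of the primacy set.
#' @export
receptor_activity_freq <- function(codes, n_receptors) {
  vapply(seq_len(n_receptors) - 1L, function(bit) {
    mean(bitwAnd(codes, bitwShiftL(1L, bit)) != 0L)
  }, numeric(1))
}

#' Monte Carlo discrimination of a mixture scenario
#'
#' Estimates, by trials with freshly drawn sensitivity matrices, the
#' probability `eta` that the two odors of a scenario produce different
#' primacy sets, together with the mean Hamming distance between the
#' sets.  `eta` is the fraction of trials with distance > 0.
#'
#' @param scenario a [mixture_scenario()].
#' @param n_trials number of Monte Carlo trials.
#' @param n_receptors,n_primacy code dimensions.
#' @param params sensitivity ensemble; defaults to a log-normal with
#'   `log_width = 1`.  (`factors` are not supported here.)
#' @return A one-row tibble with `eta`, `eta_se` (binomial), `d_mean`,
#'   `d_se` and `n_trials`.
#' @examples
#' sc <- mixture_scenario("target_in_single_background", target_conc = 0.5)
#' simulate_discrimination(sc, 500, n_receptors = 50, n_primacy = 4)
#' @export
simulate_discrimination <- function(scenario, n_trials, n_receptors,
                                    n_primacy, params = NULL) {
  stopifnot(inherits(scenario, "mixture_scenario"), n_trials >= 1)
  if (is.null(params)) {
    params <- sensitivity_params(n_receptors, n_ligands = 1L)
  }
  lp <- sens_base_logparams(params)
  cp <- scenario_conc_pair(scenario)
  jitter <- scenario$conc_cv > 0
  jp <- if (jitter) lognormal_from_moments(1, scenario$conc_cv^2) else
    list(meanlog = 0, sdlog = 0)
  d <- cpp_discrimination_distances(
    as.integer(n_trials), as.integer(n_receptors), as.integer(n_primacy),
    cp$conc_a, cp$conc_b,
    lp$family, lp$meanlog, lp$sdlog, lp$log_lo, lp$log_hi,
    jp$meanlog, jp$sdlog, jitter
  )
  changed <- d > 0
  eta <- mean(changed)
  tibble::tibble(
    eta = eta,
    eta_se = sqrt(eta * (1 - eta) / n_trials),
    d_mean = mean(d),
    d_se = sd(d) / sqrt(n_trials),
    n_trials = as.integer(n_trials)
  )
}
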