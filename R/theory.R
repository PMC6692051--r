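#' Unit-mean log-normal excitation distribution
#'
#' The statistical theory describes the scaled excitation `e / <e>` of a
#' glomerulus by a log-normal with mean 1 and variance `exp(2 zeta) - 1`,
#' where `zeta` is the (scale-invariant) log-width.  Its CDF is
#' `G(x; zeta) = 1/2 + 1/2 erf((zeta + ln x) / (2 sqrt(zeta)))`, i.e. a
#' log-normal with underlying normal parameters `(-zeta, sqrt(2 zeta))`.
#'
#' @param x excitation ratio (> 0; values <= 0 map to CDF 0 / density 0).
#' @param q probability in `(0, 1)`.
#' @param zeta log-width of the excitation distribution (> 0).
#' @return CDF value, density, or quantile respectively.
#' @examples
#' excitation_cdf(exp(-0.5), zeta = 0.5)  # median: 0.5
#' @export
excitation_cdf <- function(x, zeta) {
  stopifnot(zeta > 0)
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- plnorm(x[pos], meanlog = -zeta, sdlog = sqrt(2 * zeta))
  out
}

#' @rdname excitation_cdf
#' @export
excitation_pdf <- function(x, zeta) {
  stopifnot(zeta > 0)
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- dlnorm(x[pos], meanlog = -zeta, sdlog = sqrt(2 * zeta))
  out
}

#' @rdname excitation_cdf
#' @export
excitation_quantile <- function(q, zeta) {
  stopifnot(zeta > 0, all(q > 0), all(q < 1))
  qlnorm(q, meanlog = -zeta, sdlog = sqrt(2 * zeta))
}

#' Excitation log-width zeta
#'
#' For a concrete odor `c` and sensitivity width `lambda`, the excitation
#' distribution across receptor types has
#' `zeta = 1/2 ln(1 + (e^(lambda^2) - 1) * sum(c^2) / sum(c)^2)`; the
#' ratio `sum(c^2)/sum(c)^2` makes `zeta` invariant under rescaling of
#' `c`.  The environment form substitutes the ensemble-averaged ratio
#' `(1 + (sigma/mu)^2) / s`.
#'
#' @param conc concentration vector with positive total.
#' @param log_width sensitivity width `lambda`.
#' @param mixture_size mean mixture size `s`.
#' @param conc_cv concentration coefficient of variation `sigma/mu`.
#' @return `zeta` (dimensionless, >= 0).
#' @examples
#' zeta_from_conc(c(1), log_width = 1)          # lambda^2 / 2 = 0.5
#' zeta_from_env(16, conc_cv = 1, log_width = 1)  # ~ 0.097
#' @export
zeta_from_conc <- function(conc, log_width = 1) {
  stopifnot(all(conc >= 0))
  tot <- sum(conc)
  if (tot <= 0) stop("zero odor: total concentration must be positive")
  ratio <- sum(conc^2) / tot^2
  0.5 * log1p(expm1(log_width^2) * ratio)
}

#' @rdname zeta_from_conc
#' @export
zeta_from_env <- function(mixture_size, conc_cv = 1, log_width = 1) {
  stopifnot(mixture_size > 0, conc_cv >= 0)
  ratio <- (1 + conc_cv^2) / mixture_size
  0.5 * log1p(expm1(log_width^2) * ratio)
}

zeta_from_ratio <- function(var_over_mean2) 0.5 * log1p(var_over_mean2)

#' Mean primacy threshold and equivalent inhibition strength
#'
#' The constraint of exactly `n_primacy` active glomeruli implies a mean
#' activity `n_primacy / n_receptors`, so the ensemble-mean threshold is
#' `gamma = <e> * G^{-1}(1 - N_C/N_R; zeta)`.  The scale-free factor
#' `alpha = gamma / <e>` is the inhibition strength of the equivalent
#' normalized code: primacy coding acts as global inhibition whose
#' strength adapts to the width of the excitation distribution.
#'
#' @param n_primacy,n_receptors code dimensions (`0 < N_C < N_R`).
#' @param zeta excitation log-width.
#' @param mean_excitation mean excitation `<e>` (sets the scale of
#'   `gamma`).
#' @return A list with elements `gamma` and `alpha`.
#' @export
mean_threshold <- function(n_primacy, n_receptors, zeta, mean_excitation = 1) {
  stopifnot(n_primacy >= 1, n_primacy < n_receptors, mean_excitation > 0)
  alpha <- excitation_quantile(1 - n_primacy / n_receptors, zeta)
  list(gamma = mean_excitation * alpha, alpha = alpha)
}

#' Excitation statistics of a mixture scenario
#'
#' Mean, variance and log-width `zeta` of the glomerular excitation
#' contributed by each part of a [mixture_scenario()], under the
#' sensitivity ensemble with width `log_width` (mean sensitivity set to
#' 1).  The variance-to-mean-squared ratio of an `s`-ligand part is
#' `(e^(lambda^2) - 1) (1 + conc_cv^2) / s`; a single-ligand target has
#' mean `c_t/c_b` times and variance `(c_t/c_b)^2` times the single-ligand
#' background values, while a target added to an `s`-mixture has mean and
#' variance both `1/s` of the background's.
#'
#' @param scenario a [mixture_scenario()].
#' @param log_width sensitivity width `lambda`.
#' @return For target scenarios, a list with elements `background`,
#'   `target` and `combined`; for shared pairs, elements `shared`,
#'   `distinct` and `combined`.  Each is a list `(mean, var, zeta)`.
#' @export
scenario_excitation_stats <- function(scenario, log_width = 1) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  v1 <- expm1(log_width^2) * (1 + scenario$conc_cv^2)  # single-ligand ratio
  s <- scenario$background_size
  cb <- scenario$background_conc
  part <- function(mean, ratio) {
    list(mean = mean, var = ratio * mean^2,
         zeta = if (mean > 0) zeta_from_ratio(ratio) else NA_real_)
  }
  if (scenario$kind == "shared_ligand_pair") {
    sb <- scenario$shared_count
    shared <- if (sb > 0) part(sb * cb, v1 / sb) else part(0, NA_real_)
    distinct <- if (sb < s) part((s - sb) * cb, v1 / (s - sb)) else part(0, NA_real_)
    combined <- part(s * cb, v1 / s)
    list(shared = shared, distinct = distinct, combined = combined)
  } else {
    background <- part(s * cb, v1 / s)
    ct <- scenario$target_conc
    target <- if (ct > 0) part(ct, v1) else part(0, NA_real_)
    combined <- list(
      mean = background$mean + target$mean,
      var = background$var + target$var,
      zeta = zeta_from_ratio((background$var + target$var) /
                               (background$mean + target$mean)^2)
    )
    list(background = background, target = target, combined = combined)
  }
}

# Density of an excitation with the given mean and log-width.
scaled_excitation_pdf <- function(x, mean, zeta) {
  excitation_pdf(x / mean, zeta) / mean
}

#' Discriminability from the expected code distance
#'
#' Modeling the distance between two primacy sets as binomial over
#' `{0, 2, ..., 2 N_C}` with mean `d`, the probability that the sets
#' differ at all is `eta = 1 - (1 - d / (2 N_C))^N_C` (which tends to
#' `1 - exp(-d/2)` for large `N_C`).  `p_correct` maps `eta` to the
#' expected fraction of correct answers in a two-alternative task:
#' `eta + (1 - eta) / 2`.
#'
#' @param d expected Hamming distance, in `[0, 2 * n_primacy]`.
#' @param n_primacy primacy dimension.
#' @param eta discriminability in `[0, 1]`.
#' @return Probability.
#' @examples
#' discriminability(0, 8)       # 0: identical primacy sets
#' p_correct(0)                 # 0.5: chance level
#' @export
discriminability <- function(d, n_primacy) {
  stopifnot(all(d >= -1e-9), all(d <= 2 * n_primacy + 1e-9))
  d <- pmin(pmax(d, 0), 2 * n_primacy)
  1 - (1 - d / (2 * n_primacy))^n_primacy
}

#' @rdname discriminability
#' @export
p_correct <- function(eta) {
  stopifnot(all(eta >= 0), all(eta <= 1))
  eta + (1 - eta) / 2
}

#' Analytic expected code distance for a mixture scenario
#'
#' Closed-form (quadrature) prediction of the expected Hamming distance
#' `d` between the primacy sets of the two odors of a scenario, and the
#' derived discriminability.  For target scenarios,
#' `d = N_R (p_on + p_off)` where `p_on` / `p_off` are the probabilities
#' that the target perturbation moves a glomerulus into / out of the
#' primacy set; the thresholds of the background and the perturbed odor
#' are estimated from the mean-threshold formula under their respective
#' excitation statistics.  For shared-ligand pairs, `d = 2 N_R p_xor`
#' with the shared part playing the role of the background.  The
#' uncorrelated-odor bound `d_star = 2 N_C (1 - N_C / N_R)` is attached
#' for reference.
#'
#' @param scenario a [mixture_scenario()].
#' @param n_primacy,n_receptors code dimensions.
#' @param log_width sensitivity width `lambda`.
#' @return A one-row tibble (`distance_result`) with columns `d`, `p_on`,
#'   `p_off`, `p_xor`, `eta`, `p_correct`, `d_star` and the scenario
#'   parameters.
#' @examples
#' sc <- mixture_scenario("target_in_single_background", target_conc = 0.2)
#' expected_distance(sc, n_primacy = 8, n_receptors = 300)
#' @export
expected_distance <- function(scenario, n_primacy, n_receptors,
                              log_width = 1) {
  stopifnot(n_primacy >= 1, n_primacy < n_receptors)
  stats <- scenario_excitation_stats(scenario, log_width)
  q <- 1 - n_primacy / n_receptors
  p_on <- p_off <- p_xor <- NA_real_

  if (scenario$kind == "shared_ligand_pair") {
    sb <- scenario$shared_count
    s <- scenario$background_size
    tot <- stats$combined
    gamma <- mean_threshold(n_primacy, n_receptors, tot$zeta, tot$mean)$gamma
    if (sb == s) {
      p_xor <- 0
    } else if (sb == 0) {
      gd <- 1 - excitation_cdf(gamma / stats$distinct$mean, stats$distinct$zeta)
      p_xor <- gd * (1 - gd)
    } else {
      B <- stats$shared
      D <- stats$distinct
      integrand <- function(x) {
        gd <- excitation_cdf((gamma - x) / D$mean, D$zeta)
        gd * (1 - gd) * scaled_excitation_pdf(x, B$mean, B$zeta)
      }
      p_xor <- quad_safe(integrand, 0, gamma, scenario)
    }
    d <- 2 * n_receptors * p_xor
  } else {
    bg <- stats$background
    tg <- stats$target
    if (scenario$target_conc == 0) {
      p_on <- p_off <- 0
    } else {
      comb <- stats$combined
      gamma1 <- mean_threshold(n_primacy, n_receptors, bg$zeta, bg$mean)$gamma
      gamma2 <- mean_threshold(n_primacy, n_receptors, comb$zeta, comb$mean)$gamma
      dens_b <- function(x) scaled_excitation_pdf(x, bg$mean, bg$zeta)
      p_on <- quad_safe(function(x) {
        (1 - excitation_cdf((gamma2 - x) / tg$mean, tg$zeta)) * dens_b(x)
      }, 0, gamma1, scenario)
      p_off <- if (gamma2 > gamma1) {
        quad_safe(function(x) {
          excitation_cdf((gamma2 - x) / tg$mean, tg$zeta) * dens_b(x)
        }, gamma1, gamma2, scenario)
      } else {
        0
      }
    }
    d <- n_receptors * (p_on + p_off)
  }

  d <- min(max(d, 0), 2 * n_primacy)
  eta <- discriminability(d, n_primacy)
  out <- tibble::tibble(
    kind = scenario$kind,
    background_size = scenario$background_size,
    background_conc = scenario$background_conc,
    target_conc = scenario$target_conc,
    shared_count = scenario$shared_count,
    conc_cv = scenario$conc_cv,
    d = d, p_on = p_on, p_off = p_off, p_xor = p_xor,
    eta = eta, p_correct = p_correct(eta),
    d_star = 2 * n_primacy * (1 - n_primacy / n_receptors)
  )
  class(out) <- c("distance_result", class(out))
  out
}

# Adaptive quadrature with scenario diagnostics on failure.
quad_safe <- function(f, lower, upper, scenario) {
  if (upper <= lower) return(0)
  res <- tryCatch(
    integrate(f, lower, upper, abs.tol = 1e-9, rel.tol = 1e-9,
              subdivisions = 400L),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    stop("quadrature failed for scenario ", scenario$kind,
         " (s = ", scenario$background_size,
         ", c_t = ", scenario$target_conc,
         ", s_B = ", scenario$shared_count, "): ", conditionMessage(res))
  }
  res$value
}
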