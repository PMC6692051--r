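#' Figure-class experiment pipelines
#'
#' Each `run_*` function reproduces one class of experiment as a seeded
#' pipeline returning a tidy tibble (one row per sweep point and metric)
#' with columns `metric`, `value`, `se` (`NA` for deterministic theory
#' values), `n_trials` and `seed`, plus the sweep parameters.  Identical
#' configuration and seed give identical output.
#'
#' @name experiments
NULL

as_result_table <- function(df, experiment) {
  class(df) <- c("primacy_results", class(df))
  attr(df, "experiment") <- experiment
  df
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

#' Transmitted information across code dimensions
#'
#' Estimates the transmitted information `I` (plug-in entropy of the
#' primacy-pattern ensemble) for a sweep over the primacy dimension, next
#' to the capacity `i_max`.  Optional fixed sensitivity factors make this
#' the single-deviant-receptor heterogeneity experiment.
#'
#' @param n_receptors repertoire size (<= 30).
#' @param n_primacy vector of primacy dimensions to sweep.
#' @param env odor environment.
#' @param log_width sensitivity width `lambda`.
#' @param n_samples patterns per sweep point.
#' @param factors fixed sensitivity factors passed to
#'   [simulate_primacy_patterns()].
#' @param seed RNG seed recorded in the output.
#' @return A `primacy_results` tibble with metrics `information` and
#'   `capacity`.
#' @examples
#' run_information_experiment(n_receptors = 12, n_primacy = 2:3,
#'                            n_samples = 5000, seed = 1)
#' @rdname experiments
#' @export
run_information_experiment <- function(n_receptors = 16, n_primacy = 2:8,
                                       env = odor_environment(),
                                       log_width = 1, n_samples = 100000,
                                       factors = NULL, seed = NULL) {
  set_seed_if(seed)
  rows <- purrr::map(n_primacy, function(nc) {
    codes <- simulate_primacy_patterns(n_samples, n_receptors, nc, env,
                                       log_width, factors)
    info <- entropy_from_samples(codes, n_primacy = nc,
                                 n_receptors = n_receptors)
    tibble::tibble(
      n_receptors = n_receptors, n_primacy = nc,
      metric = c("information", "capacity"),
      value = c(info$information, info$capacity),
      se = c(info$se, NA_real_),
      n_trials = c(info$n_samples, NA_integer_)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  as_result_table(out, "information")
}

#' Capacity lost when half the receptor types are removed
#'
#' Analytic lesion curves: `i_max(N_C, N_R) - i_max(N_C, N_R / 2)` for a
#' sweep over the primacy dimension, one curve per repertoire size (about
#' `N_C` bits in large repertoires).
#'
#' @param n_receptors repertoire sizes (each halved by the lesion).
#' @param n_primacy primacy dimensions to sweep.
#' @return A `primacy_results` tibble with metrics `capacity_loss` and
#'   `capacity_loss_relative`.
#' @rdname experiments
#' @export
run_lesion_curve <- function(n_receptors = c(50, 300, 1000),
                             n_primacy = 1:16) {
  grid <- tidyr::expand_grid(n_receptors = n_receptors,
                             n_primacy = n_primacy)
  grid <- grid[grid$n_primacy <= grid$n_receptors / 2, , drop = FALSE]
  full <- i_max(grid$n_primacy, grid$n_receptors)
  lesioned <- i_max(grid$n_primacy, floor(grid$n_receptors / 2))
  out <- dplyr::bind_rows(
    dplyr::mutate(grid, metric = "capacity_loss", value = full - lesioned),
    dplyr::mutate(grid, metric = "capacity_loss_relative",
                  value = (full - lesioned) / full)
  )
  out$se <- NA_real_
  out$n_trials <- NA_integer_
  out$seed <- NA_integer_
  as_result_table(out, "lesion")
}

#' Discrimination sweep for a family of mixture scenarios
#'
#' Monte Carlo discriminability with the matching analytic prediction for
#' a grid of scenarios.  `sweep` is a tibble (or data frame) whose
#' columns override fields of the base scenario (`target_conc`,
#' `background_size`, `shared_count`, `conc_cv`); each row is one grid
#' point.
#'
#' @param scenario base [mixture_scenario()].
#' @param sweep tibble of scenario-field overrides, one row per point.
#' @param n_trials Monte Carlo trials per point.
#' @param n_receptors,n_primacy code dimensions.
#' @param params optional [sensitivity_params()] (family, width).
#' @param log_width sensitivity width used for the theory columns (taken
#'   from `params` if given).
#' @param theory include analytic columns (log-normal theory).
#' @param seed RNG seed.
#' @return A `primacy_results` tibble with metrics `eta`, `d`,
#'   `p_correct` (Monte Carlo; with `se`) and `eta_theory`, `d_theory`,
#'   `p_correct_theory` (no `se`).
#' @rdname experiments
#' @export
run_discrimination_experiment <- function(scenario, sweep, n_trials = 10000,
                                          n_receptors = 300, n_primacy = 8,
                                          params = NULL, log_width = 1,
                                          theory = TRUE, seed = NULL) {
  set_seed_if(seed)
  sweep <- tibble::as_tibble(sweep)
  if (!is.null(params)) log_width <- params$log_width
  rows <- purrr::map(seq_len(nrow(sweep)), function(i) {
    sc <- scenario
    for (field in names(sweep)) sc[[field]] <- sweep[[field]][i]
    mc <- simulate_discrimination(sc, n_trials, n_receptors, n_primacy,
                                  params)
    point <- sweep[i, , drop = FALSE]
    res <- dplyr::bind_cols(
      point,
      tibble::tibble(
        metric = c("eta", "d", "p_correct"),
        value = c(mc$eta, mc$d_mean, p_correct(mc$eta)),
        se = c(mc$eta_se, mc$d_se, mc$eta_se / 2),
        n_trials = as.integer(n_trials)
      )
    )
    if (theory) {
      th <- expected_distance(sc, n_primacy, n_receptors, log_width)
      res <- dplyr::bind_rows(res, dplyr::bind_cols(
        point,
        tibble::tibble(
          metric = c("eta_theory", "d_theory", "p_correct_theory"),
          value = c(th$eta, th$d, th$p_correct),
          se = NA_real_, n_trials = NA_integer_
        )
      ))
    }
    res
  })
  out <- dplyr::bind_rows(rows)
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  as_result_table(out, "discrimination")
}

#' Primacy versus binary and normalized coding
#'
#' For each mixture size `s`, measures the probability that adding one
#' ligand (all concentrations equal, `sigma = 0`) changes the activity
#' pattern, and the background sparsity (mean active count), under the
#' three schemes.  The binary threshold `gamma` and the inhibition
#' strength `alpha` are calibrated so that a single ligand activates
#' `target_single_active` glomeruli on average.
#'
#' @param mixture_sizes sweep over the background mixture size `s`.
#' @param n_receptors,n_primacy code dimensions (primacy scheme).
#' @param target_single_active calibration target for the alternative
#'   schemes.
#' @param n_trials trials per sweep point.
#' @param log_width sensitivity width `lambda`.
#' @param seed RNG seed.
#' @return A `primacy_results` tibble with a `scheme` column and metrics
#'   `eta` and `active_mean`.
#' @rdname experiments
#' @export
run_scheme_comparison <- function(mixture_sizes = c(1, 2, 4, 8, 16, 32),
                                  n_receptors = 300, n_primacy = 8,
                                  target_single_active = 8,
                                  n_trials = 2000, log_width = 1,
                                  seed = NULL) {
  set_seed_if(seed)
  sp <- sensitivity_params(n_receptors, n_ligands = 1L,
                           log_width = log_width)
  alpha <- calibrate_alpha(sp, target_single_active)
  gamma <- calibrate_gamma(sp, target_single_active)
  lp <- sens_base_logparams(sp)
  rows <- purrr::map(mixture_sizes, function(s) {
    tr <- cpp_scheme_trials(as.integer(n_trials), as.integer(n_receptors),
                            as.integer(n_primacy), as.integer(s),
                            as.numeric(gamma), as.numeric(alpha),
                            lp$meanlog, lp$sdlog)
    schemes <- c("primacy", "binary", "normalized")
    eta <- colMeans(tr[, 1:3, drop = FALSE])
    act <- colMeans(tr[, 4:6, drop = FALSE])
    act_se <- apply(tr[, 4:6, drop = FALSE], 2, sd) / sqrt(n_trials)
    tibble::tibble(
      mixture_size = s,
      scheme = rep(schemes, 2),
      metric = rep(c("eta", "active_mean"), each = 3),
      value = c(eta, act),
      se = c(sqrt(eta * (1 - eta) / n_trials), act_se),
      n_trials = as.integer(n_trials)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "alpha") <- as.numeric(alpha)
  attr(out, "gamma") <- as.numeric(gamma)
  as_result_table(out, "scheme_comparison")
}

#' Heterogeneous sensitivity factors
#'
#' Two variants of the receptor-heterogeneity experiment:
#' `kind = "single_factor"` sweeps the sensitivity factor `xi_1` of the
#' first receptor type (all others at 1), including the silenced array
#' `xi_1 = 0`; `kind = "distributed"` sweeps the squared coefficient of
#' variation of log-normal factors.  In the distributed variant each
#' ensemble member is a receptor array with its own fixed factor vector
#' (heterogeneity is a persistent property of the array, not odor noise):
#' `n_arrays` factor vectors are drawn per grid point, the pattern
#' entropy is estimated for each array with `n_samples / n_arrays`
#' samples, and the mean information across arrays is reported with its
#' standard error.
#'
#' @param kind `"single_factor"` or `"distributed"`.
#' @param grid values of `xi_1` (single factor) or `var(xi)/mean(xi)^2`
#'   (distributed).
#' @param n_receptors,n_primacy code dimensions.
#' @param env odor environment.
#' @param log_width sensitivity width `lambda`.
#' @param n_samples patterns per grid point (split across arrays for the
#'   distributed variant).
#' @param n_arrays factor-vector realizations per grid point
#'   (distributed variant).
#' @param seed RNG seed.
#' @return A `primacy_results` tibble with metric `information` (and the
#'   sweep column `xi1` or `factor_cv2`).
#' @rdname experiments
#' @export
run_heterogeneity_experiment <- function(kind = c("single_factor",
                                                  "distributed"),
                                         grid = NULL,
                                         n_receptors = 16, n_primacy = 4,
                                         env = odor_environment(),
                                         log_width = 1, n_samples = 100000,
                                         n_arrays = 8, seed = NULL) {
  kind <- match.arg(kind)
  set_seed_if(seed)
  if (is.null(grid)) {
    grid <- if (kind == "single_factor") c(0, seq(0.5, 2, by = 0.25))
            else c(0, 0.25, 0.5, 1)
  }
  rows <- purrr::map(grid, function(g) {
    if (kind == "single_factor") {
      codes <- simulate_primacy_patterns(n_samples, n_receptors, n_primacy,
                                         env, log_width,
                                         factors = c(g, rep(1, n_receptors - 1)))
      info <- entropy_from_samples(codes, n_primacy = n_primacy,
                                   n_receptors = n_receptors)
      value <- info$information
      se <- info$se
      n_used <- info$n_samples
    } else if (g == 0) {
      codes <- simulate_primacy_patterns(n_samples, n_receptors, n_primacy,
                                         env, log_width)
      info <- entropy_from_samples(codes, n_primacy = n_primacy,
                                   n_receptors = n_receptors)
      value <- info$information
      se <- info$se
      n_used <- info$n_samples
    } else {
      per_array <- ceiling(n_samples / n_arrays)
      flp <- lognormal_from_moments(1, g)
      info_arrays <- vapply(seq_len(n_arrays), function(a) {
        xi <- rlnorm(n_receptors, flp$meanlog, flp$sdlog)
        codes <- simulate_primacy_patterns(per_array, n_receptors,
                                           n_primacy, env, log_width,
                                           factors = xi)
        # per-array plug-in bias ~ (K-1)/(2 n ln 2) bits is negligible
        # against the heterogeneity effect measured here
        suppressWarnings(entropy_from_samples(codes)$information)
      }, numeric(1))
      value <- mean(info_arrays)
      se <- sd(info_arrays) / sqrt(n_arrays)
      n_used <- per_array * n_arrays
    }
    tibble::tibble(
      n_receptors = n_receptors, n_primacy = n_primacy,
      metric = "information", value = value, se = se,
      n_trials = as.integer(n_used)
    )
  })
  out <- dplyr::bind_rows(rows)
  out[[if (kind == "single_factor") "xi1" else "factor_cv2"]] <- grid
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  as_result_table(out, paste0("heterogeneity_", kind))
}

#' Crossover factor where a hot receptor is worse than none
#'
#' From a `single_factor` heterogeneity table containing `xi1 = 0`,
#' locates (by linear interpolation on the grid) the `xi_1` value at
#' which the information first falls below the silenced-receptor value
#' `I(xi_1 = 0)`.
#'
#' @param results output of
#'   `run_heterogeneity_experiment(kind = "single_factor")`.
#' @return The interpolated crossing `xi_1`.
#' @export
heterogeneity_crossing <- function(results) {
  stopifnot(all(c("xi1", "metric", "value") %in% names(results)))
  df <- results[results$metric == "information", c("xi1", "value")]
  df <- df[order(df$xi1), ]
  if (df$xi1[1] != 0) stop("the grid must contain xi1 = 0")
  i0 <- df$value[1]
  df <- df[df$xi1 >= 1, , drop = FALSE]
  below <- which(df$value < i0)
  if (length(below) == 0) stop("information never falls below I(xi1 = 0) on the grid")
  j <- below[1]
  if (j == 1) return(df$xi1[1])
  x0 <- df$xi1[j - 1]; y0 <- df$value[j - 1]
  x1 <- df$xi1[j]; y1 <- df$value[j]
  x0 + (y0 - i0) / (y0 - y1) * (x1 - x0)
}

#' @export
print.primacy_results <- function(x, ...) {
  cat("<primacy_results:", attr(x, "experiment"), "experiment>\n")
  NextMethod()
}
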