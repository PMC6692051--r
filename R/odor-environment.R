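#' Parametric odor environment
#'
#' Defines the distribution `P_env(c)` from which odors are drawn: each of
#' the `n_ligands` possible ligands is present independently with
#' probability `p`, and a present ligand receives a concentration from a
#' log-normal distribution.  The log-normal is parameterized by its
#' *distribution* mean `conc_mean` and standard deviation `conc_sd` (the
#' underlying normal parameters are obtained by moment matching; this is a
#' different convention from the sensitivity width `log_width`, which is
#' the standard deviation of the underlying normal).
#'
#' The presence probability can be given either directly via
#' `presence_prob` or through the mean mixture size
#' `mean_mixture_size = p * n_ligands`.
#'
#' @param n_ligands number of ligand species the receptors can detect.
#' @param mean_mixture_size expected number of ligands per odor
#'   (`s = p * n_ligands`).  Ignored when `presence_prob` is given.
#' @param conc_mean,conc_sd mean and standard deviation of the
#'   concentration distribution of a present ligand (`conc_sd = 0` gives
#'   fixed concentrations).
#' @param presence_prob per-ligand presence probability `p`; overrides
#'   `mean_mixture_size`.
#'
#' @return An object of class `odor_env`.
#' @examples
#' env <- odor_environment(n_ligands = 512, mean_mixture_size = 16)
#' environment_moments(env)
#' @export
odor_environment <- function(n_ligands = 512, mean_mixture_size = 16,
                             conc_mean = 1, conc_sd = 1,
                             presence_prob = NULL) {
  stopifnot(n_ligands >= 1, conc_mean > 0, conc_sd >= 0)
  if (is.null(presence_prob)) {
    stopifnot(mean_mixture_size > 0, mean_mixture_size <= n_ligands)
    presence_prob <- mean_mixture_size / n_ligands
  } else {
    stopifnot(presence_prob >= 0, presence_prob <= 1)
    mean_mixture_size <- presence_prob * n_ligands
  }
  structure(
    list(
      n_ligands = as.integer(n_ligands),
      presence_prob = presence_prob,
      conc_mean = conc_mean,
      conc_sd = conc_sd,
      mean_mixture_size = mean_mixture_size
    ),
    class = "odor_env"
  )
}

#' @export
print.odor_env <- function(x, ...) {
  cat("Odor environment: N_L =", x$n_ligands,
      " p =", signif(x$presence_prob, 4),
      " (s =", signif(x$mean_mixture_size, 4), ")\n",
      "ligand concentration: log-normal mean =", x$conc_mean,
      " sd =", x$conc_sd, "\n")
  invisible(x)
}

#' Moments of the odor environment
#'
#' Per-ligand concentration mean `p * mu` and variance
#' `(p - p^2) mu^2 + p sigma^2` (over all ligands, counting absent ones as
#' zero), together with the ensemble-averaged concentration ratio
#' `E[sum(c^2) / sum(c)^2] = (1 + sigma^2/mu^2) / s`, which controls the
#' width of the excitation distribution.
#'
#' @param env an [odor_environment()].
#' @return A one-row tibble with columns `conc_mean`, `conc_var` and
#'   `conc_ratio`.
#' @export
environment_moments <- function(env) {
  stopifnot(inherits(env, "odor_env"))
  p <- env$presence_prob
  mu <- env$conc_mean
  sigma <- env$conc_sd
  tibble::tibble(
    conc_mean = p * mu,
    conc_var = (p - p^2) * mu^2 + p * sigma^2,
    conc_ratio = (1 + (sigma / mu)^2) / env$mean_mixture_size
  )
}

#' Sample odors from the environment
#'
#' Draws `n` odors: ligand presence is Bernoulli with probability `p`,
#' concentrations of present ligands are log-normal with the environment's
#' distribution mean and standard deviation.  Odors in which no ligand is
#' present are redrawn (the primacy set is undefined for a zero odor); the
#' number of redraws is reported in the `n_resampled` attribute.
#'
#' @param env an [odor_environment()].
#' @param n number of odors to draw.
#' @return A tibble with columns `odor_id`, `ligand` (1-based index) and
#'   `concentration`, one row per present ligand.
#' @examples
#' env <- odor_environment(n_ligands = 64, mean_mixture_size = 4)
#' odors <- sample_odors(env, n = 3)
#' @export
sample_odors <- function(env, n = 1) {
  stopifnot(inherits(env, "odor_env"), n >= 1)
  if (env$presence_prob <= 0) {
    stop("presence probability is zero: every odor would be empty")
  }
  lp <- lognormal_from_moments(env$conc_mean, env$conc_sd^2)
  n_resampled <- 0L
  counts <- rbinom(n, env$n_ligands, env$presence_prob)
  while (any(counts == 0L)) {
    zero <- counts == 0L
    n_resampled <- n_resampled + sum(zero)
    counts[zero] <- rbinom(sum(zero), env$n_ligands, env$presence_prob)
  }
  ligand <- unlist(lapply(counts, function(k) sort(sample.int(env$n_ligands, k))),
                   use.names = FALSE)
  out <- tibble::tibble(
    odor_id = rep(seq_len(n), counts),
    ligand = ligand,
    concentration = rlnorm(sum(counts), lp$meanlog, lp$sdlog)
  )
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Expand a tidy odor to a dense concentration vector
#'
#' @param odors a tibble as returned by [sample_odors()] (a single odor or
#'   one selected by `odor_id`).
#' @param n_ligands length of the concentration vector.
#' @param id which `odor_id` to extract (default: the first present).
#' @return Numeric vector of length `n_ligands`.
#' @export
odor_concentration_vector <- function(odors, n_ligands, id = NULL) {
  if (is.null(id)) id <- odors$odor_id[1]
  odors <- odors[odors$odor_id == id, , drop = FALSE]
  stopifnot(all(odors$ligand >= 1), all(odors$ligand <= n_ligands))
  conc <- numeric(n_ligands)
  conc[odors$ligand] <- odors$concentration
  conc
}

#' Mixture scenarios for discrimination tasks
#'
#' Constructs the deterministic two-odor scenarios used throughout the
#' discrimination analyses:
#' \describe{
#'   \item{`target_in_single_background`}{a single background ligand at
#'     concentration `background_conc` versus background plus one target
#'     ligand at `target_conc`.}
#'   \item{`ligand_added_to_mixture`}{a background mixture of
#'     `background_size` ligands, all at `background_conc`, versus the
#'     same mixture plus one target ligand at `target_conc`.}
#'   \item{`shared_ligand_pair`}{two mixtures of `background_size` ligands
#'     each, sharing exactly `shared_count` ligand indices, all at
#'     `background_conc`.}
#' }
#' If `conc_cv > 0`, every ligand concentration is multiplied by an
#' independent log-normal jitter factor with unit mean and coefficient of
#' variation `conc_cv` when the scenario is realized (the factor is shared
#' between the two odors for shared ligands).
#'
#' @param kind scenario kind, see above.
#' @param background_size number of background ligands `s`.
#' @param background_conc concentration of each background ligand.
#' @param target_conc concentration of the added target ligand.
#' @param shared_count ligands shared between the pair
#'   (`shared_ligand_pair` only).
#' @param conc_cv per-ligand concentration jitter `sigma/mu` (0 = fixed).
#' @return An object of class `mixture_scenario`.
#' @export
mixture_scenario <- function(kind = c("target_in_single_background",
                                      "ligand_added_to_mixture",
                                      "shared_ligand_pair"),
                             background_size = 1, background_conc = 1,
                             target_conc = 0, shared_count = NULL,
                             conc_cv = 0) {
  kind <- match.arg(kind)
  stopifnot(background_size >= 1, background_conc > 0, target_conc >= 0,
            conc_cv >= 0)
  if (kind == "target_in_single_background") background_size <- 1L
  if (kind == "shared_ligand_pair") {
    stopifnot(!is.null(shared_count), shared_count >= 0,
              shared_count <= background_size)
  } else {
    shared_count <- NA_integer_
  }
  structure(
    list(
      kind = kind,
      background_size = as.integer(background_size),
      background_conc = background_conc,
      target_conc = target_conc,
      shared_count = as.integer(shared_count),
      conc_cv = conc_cv
    ),
    class = "mixture_scenario"
  )
}

# Concentration vectors of the two odors over the minimal shared ligand
# index space.  Ligand identities are exchangeable under the sensitivity
# ensemble, so consecutive indices are used.
scenario_conc_pair <- function(scenario) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  s <- scenario$background_size
  cb <- scenario$background_conc
  switch(scenario$kind,
    target_in_single_background = ,
    ligand_added_to_mixture = list(
      conc_a = c(rep(cb, s), 0),
      conc_b = c(rep(cb, s), scenario$target_conc)
    ),
    shared_ligand_pair = {
      sb <- scenario$shared_count
      len <- 2L * s - sb
      a <- b <- numeric(len)
      a[seq_len(s)] <- cb
      b[c(seq_len(sb), s + seq_len(s - sb))] <- cb
      list(conc_a = a, conc_b = b)
    }
  )
}

#' Materialize a scenario as a pair of odors
#'
#' Draws the ligand indices of a [mixture_scenario()] without replacement
#' from `1:n_ligands` and applies concentration jitter if requested.
#'
#' @param scenario a [mixture_scenario()].
#' @param n_ligands size of the ligand space the indices are drawn from.
#' @return A tibble with columns `odor` (`"A"` background / `"B"`
#'   perturbed), `ligand` and `concentration`.
#' @export
scenario_odor_pair <- function(scenario, n_ligands = 512) {
  cp <- scenario_conc_pair(scenario)
  len <- length(cp$conc_a)
  if (len > n_ligands) {
    stop("ligand space too small: scenario needs ", len,
         " distinct ligands but n_ligands = ", n_ligands)
  }
  ligand <- sample.int(n_ligands, len)
  jitter <- rep(1, len)
  if (scenario$conc_cv > 0) {
    lp <- lognormal_from_moments(1, scenario$conc_cv^2)
    jitter <- rlnorm(len, lp$meanlog, lp$sdlog)
  }
  a <- cp$conc_a * jitter
  b <- cp$conc_b * jitter
  dplyr::bind_rows(
    tibble::tibble(odor = "A", ligand = ligand[a > 0], concentration = a[a > 0]),
    tibble::tibble(odor = "B", ligand = ligand[b > 0], concentration = b[b > 0])
  )
}
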