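#' Order statistics of the excitation distribution
#'
#' Tools for the distribution of ranked excitations
#' `e_(1) < e_(2) < ... < e_(NR)` of `n_receptors` i.i.d. draws from a
#' continuous distribution with CDF `cdf` and density `pdf`.  The model
#' object simply bundles the two functions and the sample size; the
#' default is the unit-mean log-normal excitation distribution with
#' log-width `zeta`.
#'
#' @param n_receptors number of i.i.d. excitations.
#' @param cdf,pdf distribution functions of a single excitation.  Default:
#'   the unit-mean log-normal with log-width `zeta`.
#' @param zeta log-width used for the default distribution.
#' @return An object of class `order_stat_model`.
#' @export
order_stat_model <- function(n_receptors, cdf = NULL, pdf = NULL,
                             zeta = 0.1) {
  stopifnot(n_receptors >= 2)
  if (is.null(cdf) != is.null(pdf)) {
    stop("supply both cdf and pdf, or neither")
  }
  if (is.null(cdf)) {
    force(zeta)
    cdf <- function(x) excitation_cdf(x, zeta)
    pdf <- function(x) excitation_pdf(x, zeta)
  }
  structure(list(n_receptors = as.integer(n_receptors), cdf = cdf, pdf = pdf),
            class = "order_stat_model")
}

#' Density of the excitation at a given rank
#'
#' `f_{E(r)}(e) = NR! / ((r-1)! (NR-r)!) F(e)^(r-1) (1-F(e))^(NR-r) f(e)`,
#' evaluated stably through the beta density.
#'
#' @param model an [order_stat_model()].
#' @param e evaluation points.
#' @param rank rank `r` (1 = smallest, `n_receptors` = largest).
#' @return Density values.
#' @export
rank_density <- function(model, e, rank) {
  nr <- model$n_receptors
  stopifnot(rank >= 1, rank <= nr)
  dbeta(model$cdf(e), rank, nr - rank + 1) * model$pdf(e)
}

#' @rdname rank_density
#' @param lower,upper integration support of the excitation distribution.
#' @export
rank_mean <- function(model, rank, lower = 0, upper = Inf) {
  integrate(function(e) e * rank_density(model, e, rank), lower, upper,
            rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 400L)$value
}

#' Gap between consecutive ranked excitations
#'
#' `gap_density()` evaluates the density of `delta = e_(r) - e_(r-1)` by
#' integrating the joint density of the two consecutive order statistics;
#' `mean_gap()` returns its expectation, computed as the difference of the
#' two rank means.  `primacy_boundary_gap()` is the mean gap at the
#' primacy boundary — between the strongest excited *inactive* receptor
#' type (rank `NR - NC`) and the weakest *active* one (rank
#' `NR - NC + 1`) — which controls how easily a perturbation reshuffles
#' the primacy set; it typically grows with the repertoire size because a
#' heavy-tailed excitation distribution develops larger gaps between its
#' top values.
#'
#' @param model an [order_stat_model()].
#' @param delta gap values (> 0) at which to evaluate the density.
#' @param rank upper rank `r` of the pair `(r-1, r)`; `2 <= r <= NR`.
#' @param lower,upper integration support of the excitation distribution.
#' @return Density values / mean gap.
#' @examples
#' m <- order_stat_model(32, zeta = 0.1)
#' mean_gap(m, rank = 29)  # boundary gap for N_C = 4
#' @export
gap_density <- function(model, delta, rank, lower = 0, upper = Inf) {
  nr <- model$n_receptors
  stopifnot(rank >= 2, rank <= nr, all(delta >= 0))
  log_coef <- lgamma(nr + 1) - lgamma(rank - 1) - lgamma(nr - rank + 1)
  vapply(delta, function(dd) {
    integrand <- function(y) {
      fy <- model$cdf(y)
      fz <- model$cdf(y + dd)
      exp(log_coef + (rank - 2) * log(pmax(fy, 1e-300)) +
            (nr - rank) * log(pmax(1 - fz, 1e-300))) *
        model$pdf(y) * model$pdf(y + dd)
    }
    integrate(integrand, lower, upper, rel.tol = 1e-9, abs.tol = 1e-12,
              subdivisions = 400L)$value
  }, numeric(1))
}

#' @rdname gap_density
#' @export
mean_gap <- function(model, rank, lower = 0, upper = Inf) {
  stopifnot(rank >= 2, rank <= model$n_receptors)
  rank_mean(model, rank, lower, upper) - rank_mean(model, rank - 1, lower, upper)
}

#' @rdname gap_density
#' @param n_primacy primacy dimension.
#' @export
primacy_boundary_gap <- function(model, n_primacy) {
  stopifnot(n_primacy >= 1, n_primacy < model$n_receptors)
  mean_gap(model, model$n_receptors - n_primacy + 1)
}
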