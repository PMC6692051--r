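#' Moment matching for the log-normal distribution
#'
#' Returns the location and scale of the underlying normal such that
#' `exp(Normal(meanlog, sdlog))` has the requested distribution mean and
#' variance.  `variance = 0` yields a degenerate point mass
#' (`sdlog = 0`).
#'
#' @param mean distribution mean (> 0).
#' @param variance distribution variance (>= 0).
#' @return A list with elements `meanlog` and `sdlog`.
#' @examples
#' lognormal_from_moments(1, exp(1) - 1)  # meanlog -0.5, sdlog 1
#' @export
lognormal_from_moments <- function(mean, variance) {
  stopifnot(mean > 0)
  if (variance < 0) stop("variance must be nonnegative")
  sdlog <- sqrt(log1p(variance / mean^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Half-width w (in natural log units) of a log-uniform distribution with
# var(X)/E[X]^2 equal to `ratio`: X = exp(U), U uniform on [m-w, m+w].
# The ratio depends only on w: sinh(2w)/(2w) * (w/sinh(w))^2 - 1.
loguniform_halfwidth <- function(ratio) {
  stopifnot(ratio > 0)
  f <- function(w) sinh(2 * w) / (2 * w) * (w / sinh(w))^2 - 1 - ratio
  uniroot(f, c(1e-8, 50), tol = 1e-12)$root
}

#' Receptor sensitivity ensemble parameters
#'
#' Describes the random ensemble of sensitivity matrices `S[n, i]`: i.i.d.
#' entries from a log-normal (width `log_width`, the standard deviation of
#' the *underlying* normal) or log-uniform family, followed by scaling row
#' `n` with a per-receptor sensitivity factor `xi[n]`.  The log-uniform
#' family is parameterized by its variance ratio `var(S)/mean(S)^2`
#' (default: matched to the log-normal value `exp(log_width^2) - 1`); the
#' implied half-width of the uniform support in decades is exposed as
#' `decade_span`.
#'
#' The overall scale `mean_sensitivity` is provably irrelevant for primacy
#' coding (only relative excitations matter) and defaults to 1; it is kept
#' as a parameter for binary-threshold coding where absolute scale matters.
#'
#' @param n_receptors,n_ligands matrix dimensions.
#' @param mean_sensitivity ensemble mean of an entry.
#' @param log_width standard deviation `lambda` of the underlying normal
#'   (log-normal family).
#' @param family `"log_normal"` or `"log_uniform"`.
#' @param factors per-receptor sensitivity factors `xi` (default: all 1).
#' @param factor_cv2 if given, `factors` are drawn fresh from a unit-mean
#'   log-normal with `var(xi)/mean(xi)^2 = factor_cv2` each time a matrix
#'   is sampled.
#' @param var_ratio variance ratio for the log-uniform family.
#' @return An object of class `sens_params`.
#' @export
sensitivity_params <- function(n_receptors, n_ligands,
                               mean_sensitivity = 1, log_width = 1,
                               family = c("log_normal", "log_uniform"),
                               factors = NULL, factor_cv2 = NULL,
                               var_ratio = NULL) {
  family <- match.arg(family)
  stopifnot(n_receptors >= 1, n_ligands >= 1, mean_sensitivity > 0,
            log_width > 0)
  if (!is.null(factors)) {
    stopifnot(length(factors) == n_receptors, all(factors >= 0))
  }
  if (!is.null(factor_cv2)) stopifnot(factor_cv2 >= 0)
  if (is.null(var_ratio)) var_ratio <- expm1(log_width^2)
  halfwidth <- if (family == "log_uniform") loguniform_halfwidth(var_ratio) else NA_real_
  structure(
    list(
      n_receptors = as.integer(n_receptors),
      n_ligands = as.integer(n_ligands),
      mean_sensitivity = mean_sensitivity,
      log_width = log_width,
      family = family,
      factors = factors,
      factor_cv2 = factor_cv2,
      var_ratio = var_ratio,
      log_halfwidth = halfwidth,
      decade_span = 2 * halfwidth / log(10)
    ),
    class = "sens_params"
  )
}

#' @export
print.sens_params <- function(x, ...) {
  cat("Sensitivity ensemble:", x$n_receptors, "receptors x", x$n_ligands,
      "ligands\n  family:", x$family,
      if (x$family == "log_normal") paste0("(lambda = ", x$log_width, ")")
      else paste0("(var ratio = ", signif(x$var_ratio, 3), ", span ~",
                  signif(x$decade_span, 3), " decades)"),
      "\n  mean sensitivity:", x$mean_sensitivity, "\n")
  if (!is.null(x$factor_cv2)) {
    cat("  factors: log-normal, var(xi)/<xi>^2 =", x$factor_cv2, "\n")
  } else if (!is.null(x$factors)) {
    cat("  factors: fixed vector (", paste(signif(head(x$factors, 4), 3),
                                           collapse = ", "),
        if (x$n_receptors > 4) ", ..." else "", ")\n", sep = "")
  }
  invisible(x)
}

# Underlying-normal parameters of the base (unit-factor) entry
# distribution, used by the Monte Carlo kernels.
sens_base_logparams <- function(params) {
  if (params$family == "log_normal") {
    list(
      family = 0L,
      meanlog = log(params$mean_sensitivity) - params$log_width^2 / 2,
      sdlog = params$log_width,
      log_lo = 0, log_hi = 0
    )
  } else {
    w <- params$log_halfwidth
    m <- log(params$mean_sensitivity * w / sinh(w))
    list(family = 1L, meanlog = 0, sdlog = 0, log_lo = m - w, log_hi = m + w)
  }
}

#' Sample a sensitivity matrix
#'
#' Draws an `n_receptors x n_ligands` matrix of i.i.d. sensitivities from
#' the ensemble described by `params` and multiplies row `n` by the
#' sensitivity factor `xi[n]` (drawn fresh if `factor_cv2` was given).
#'
#' @param params a [sensitivity_params()] object.
#' @return A positive matrix with attributes `factors` and `params`.
#' @examples
#' sp <- sensitivity_params(n_receptors = 8, n_ligands = 16)
#' S <- sample_sensitivity_matrix(sp)
#' @export
sample_sensitivity_matrix <- function(params) {
  stopifnot(inherits(params, "sens_params"))
  lp <- sens_base_logparams(params)
  n <- params$n_receptors * params$n_ligands
  S <- if (params$family == "log_normal") {
    matrix(rlnorm(n, lp$meanlog, lp$sdlog), params$n_receptors)
  } else {
    matrix(exp(runif(n, lp$log_lo, lp$log_hi)), params$n_receptors)
  }
  factors <- params$factors
  if (!is.null(params$factor_cv2)) {
    flp <- lognormal_from_moments(1, params$factor_cv2)
    factors <- rlnorm(params$n_receptors, flp$meanlog, flp$sdlog)
  }
  if (!is.null(factors)) S <- S * factors
  attr(S, "factors") <- if (is.null(factors)) rep(1, params$n_receptors) else factors
  attr(S, "params") <- params
  S
}

#' Read and write sensitivity matrices as CSV
#'
#' The CSV layout is receptors as rows and ligands as columns, with a
#' header row of ligand indices (`L1`, `L2`, ...), so measured
#' sensitivities can be injected in place of sampled ones.
#'
#' @param S sensitivity matrix.
#' @param path file path.
#' @return `read_sensitivity_csv` returns a numeric matrix;
#'   `write_sensitivity_csv` returns `path` invisibly.
#' @export
write_sensitivity_csv <- function(S, path) {
  df <- as.data.frame(S)
  names(df) <- paste0("L", seq_len(ncol(S)))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_sensitivity_csv
#' @export
read_sensitivity_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  S <- as.matrix(df)
  dimnames(S) <- NULL
  stopifnot(all(S > 0))
  S
}

#' Read and write tidy odor tables as CSV
#'
#' Columns: `odor_id`, `ligand`, `concentration`.
#'
#' @param odors tibble as produced by [sample_odors()].
#' @param path file path.
#' @export
write_odors_csv <- function(odors, path) {
  stopifnot(all(c("odor_id", "ligand", "concentration") %in% names(odors)))
  readr::write_csv(odors, path)
  invisible(path)
}

#' @rdname write_odors_csv
#' @export
read_odors_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    odor_id = readr::col_integer(),
                    ligand = readr::col_integer(),
                    concentration = readr::col_double()
                  ))
}
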