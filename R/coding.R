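#' Glomerular excitations
#'
#' Linear excitation `e = S %*% c`: glomerulus `n` accumulates the
#' sensitivity-weighted concentrations of all present ligands.  Only the
#' support of `conc` is touched.
#'
#' @param S sensitivity matrix (`n_receptors x n_ligands`).
#' @param conc concentration vector of length `n_ligands` (nonnegative).
#' @return Numeric vector of excitations, length `n_receptors`.
#' @examples
#' excitations(matrix(1:4, 2, byrow = TRUE), c(1, 1))  # c(3, 7)
#' @export
excitations <- function(S, conc) {
  stopifnot(is.matrix(S), length(conc) == ncol(S))
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  support <- which(conc > 0)
  if (length(support) == 0) return(numeric(nrow(S)))
  drop(S[, support, drop = FALSE] %*% conc[support])
}

new_activity_pattern <- function(bits, n_primacy = NA_integer_,
                                 threshold = NA_real_, gap = NA_real_) {
  structure(as.integer(bits), class = "activity_pattern",
            n_primacy = n_primacy, threshold = threshold, gap = gap)
}

#' @export
print.activity_pattern <- function(x, ...) {
  cat("Activity pattern (", sum(unclass(x)), "/", length(x), " active): ",
      paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Primacy coding
#'
#' The primacy set is formed by the `n_primacy` glomeruli with the largest
#' excitations; exactly `n_primacy` bits are active.  The recorded
#' threshold `gamma` is the largest excluded excitation (any value in the
#' open gap is equivalent), and `gap` is the excitation difference between
#' the weakest member of the primacy set and the strongest excluded
#' glomerulus.  Ties at the boundary are broken toward the lower receptor
#' index (probability zero for continuous sensitivities; determinism aids
#' testing).  The pattern is invariant under rescaling of the odor: only
#' relative excitations matter.
#'
#' @param e excitation vector.
#' @param n_primacy primacy dimension `N_C`.
#' @return An `activity_pattern` (0/1 integer vector) with attributes
#'   `n_primacy`, `threshold` and `gap`.
#' @examples
#' primacy_code(c(3, 7, 5, 1), 2)  # pattern 0110
#' @export
primacy_code <- function(e, n_primacy) {
  n_r <- length(e)
  stopifnot(n_primacy >= 1, n_primacy <= n_r)
  if (sum(e > 0) < n_primacy) {
    stop("degenerate input: fewer than n_primacy strictly positive excitations")
  }
  ord <- order(e, decreasing = TRUE)  # stable: ties go to the lower index
  active <- ord[seq_len(n_primacy)]
  bits <- integer(n_r)
  bits[active] <- 1L
  threshold <- if (n_primacy < n_r) e[ord[n_primacy + 1L]] else 0
  new_activity_pattern(bits, n_primacy = as.integer(n_primacy),
                       threshold = threshold,
                       gap = e[ord[n_primacy]] - threshold)
}

#' Binary-threshold coding
#'
#' A glomerulus is active iff its excitation exceeds the fixed threshold
#' `gamma`; there is no constraint on the number of active glomeruli, so
#' the sparsity grows with the odor intensity.
#'
#' @param e excitation vector.
#' @param gamma fixed threshold (>= 0).
#' @return An `activity_pattern`.
#' @export
binary_code <- function(e, gamma) {
  stopifnot(gamma >= 0)
  new_activity_pattern(e > gamma, threshold = gamma)
}

#' Normalized (global-inhibition) coding
#'
#' A glomerulus is active iff its excitation exceeds `alpha` times the
#' mean excitation.  The pattern is concentration-invariant, but its
#' sparsity still depends on the odor statistics (larger mixtures give
#' narrower excitation distributions and hence fewer active glomeruli).
#'
#' @param e excitation vector (not all zero).
#' @param alpha inhibition strength (> 0).
#' @return An `activity_pattern`.
#' @export
normalized_code <- function(e, alpha) {
  stopifnot(alpha > 0)
  if (all(e == 0)) stop("degenerate input: all excitations are zero")
  gamma <- alpha * mean(e)
  new_activity_pattern(e > gamma, threshold = gamma)
}

#' Hamming distance between activity patterns
#'
#' Number of glomeruli with different activities.  For two primacy
#' patterns of equal dimension the result is even and at most
#' `2 * n_primacy`.
#'
#' @param a,b activity patterns (or plain 0/1 vectors) of equal length.
#' @return Nonnegative integer.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("patterns differ in length")
  sum(unclass(a) != unclass(b))
}

# Single-ligand excitation ensemble: n_trials x n_receptors matrix of
# i.i.d. base sensitivities times `conc`.  Used for threshold calibration.
single_ligand_excitations <- function(n_trials, params, conc = 1) {
  lp <- sens_base_logparams(params)
  n <- n_trials * params$n_receptors
  E <- if (lp$family == 0L) {
    matrix(rlnorm(n, lp$meanlog, lp$sdlog), n_trials)
  } else {
    matrix(exp(runif(n, lp$log_lo, lp$log_hi)), n_trials)
  }
  E * conc
}

#' Calibrate the inhibition strength of the normalized code
#'
#' Finds `alpha` such that the mean number of glomeruli activated by a
#' single ligand equals `target_mean_active`, by a monotone root solve on
#' a fixed Monte Carlo ensemble of single-ligand excitation vectors
#' (common random numbers, so the count is a deterministic nonincreasing
#' step function of `alpha`).
#'
#' @param params a [sensitivity_params()] object.
#' @param target_mean_active desired mean active count, in
#'   `(0, n_receptors)`.
#' @param n_trials ensemble size used for the calibration.
#' @return `alpha` with the achieved mean active count as attribute
#'   `achieved`.
#' @export
calibrate_alpha <- function(params, target_mean_active, n_trials = 10000) {
  stopifnot(target_mean_active > 0, target_mean_active < params$n_receptors)
  E <- single_ligand_excitations(n_trials, params)
  m <- rowMeans(E)
  count <- function(alpha) mean(rowSums(E > alpha * m))
  f <- function(alpha) count(alpha) - target_mean_active
  lo <- 1e-6
  hi <- max(E / m) + 1
  if (f(lo) < 0) stop("calibration error: target mean active count unreachable")
  alpha <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  structure(alpha, achieved = count(alpha))
}

#' Calibrate the fixed threshold of the binary code
#'
#' Same convention as [calibrate_alpha()]: `gamma` is chosen such that a
#' single ligand at concentration `conc` activates `target_mean_active`
#' glomeruli on average.
#'
#' @inheritParams calibrate_alpha
#' @param conc concentration of the calibration ligand.
#' @return `gamma` with attribute `achieved`.
#' @export
calibrate_gamma <- function(params, target_mean_active, conc = 1,
                            n_trials = 10000) {
  stopifnot(target_mean_active > 0, target_mean_active < params$n_receptors)
  E <- single_ligand_excitations(n_trials, params, conc = conc)
  count <- function(gamma) mean(rowSums(E > gamma))
  f <- function(gamma) count(gamma) - target_mean_active
  hi <- max(E) + 1
  if (f(1e-12) < 0) stop("calibration error: target mean active count unreachable")
  gamma <- uniroot(f, c(1e-12, hi), tol = 1e-10)$root
  structure(gamma, achieved = count(gamma))
}
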