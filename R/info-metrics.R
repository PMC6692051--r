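#' Coding capacity of a fixed-sparsity binary code
#'
#' `log2 choose(n_receptors, n_primacy)`: the entropy attained when all
#' primacy sets of size `n_primacy` are equiprobable.  The `"stirling"`
#' method returns the large-repertoire approximation
#' `n_primacy / ln 2 + n_primacy * log2(n_receptors / n_primacy)`.
#'
#' @param n_primacy primacy dimension `N_C`.
#' @param n_receptors repertoire size `N_R`.
#' @param method `"exact"` (log-space binomial) or `"stirling"`.
#' @return Capacity in bits.
#' @examples
#' i_max(4, 50)  # log2(230300) ~ 17.81 bits
#' @export
i_max <- function(n_primacy, n_receptors, method = c("exact", "stirling")) {
  method <- match.arg(method)
  stopifnot(all(n_primacy >= 1), all(n_primacy <= n_receptors))
  if (method == "exact") {
    lchoose(n_receptors, n_primacy) / log(2)
  } else {
    n_primacy / log(2) + n_primacy * log2(n_receptors / n_primacy)
  }
}

# Pattern codes -> counts.  Accepts an integer vector of bitmask codes
# (from the simulation kernels), a 0/1 matrix with one pattern per row,
# or a list of activity patterns.
pattern_counts <- function(x) {
  if (is.matrix(x)) {
    x <- apply(x, 1, paste, collapse = "")
  } else if (is.list(x)) {
    x <- vapply(x, function(p) paste(unclass(p), collapse = ""), character(1))
  }
  table(x)
}

#' Plug-in entropy of an observed pattern ensemble
#'
#' Empirical (maximum-likelihood) entropy of the distribution of activity
#' patterns, in bits, with the Miller-Madow bias correction reported
#' alongside.  The plug-in estimator underestimates the true entropy by
#' roughly `(K - 1) / (2 n ln 2)` bits for `K` observed patterns; a
#' warning is raised when `n_samples < 50 * K`.
#'
#' @param x observed patterns: integer bitmask codes (as returned by
#'   [simulate_primacy_patterns()]), a 0/1 matrix with one pattern per
#'   row, or a list of activity patterns.
#' @param n_primacy,n_receptors optional code dimensions; when given, the
#'   capacity `i_max(n_primacy, n_receptors)` and the number of
#'   distinguishable signals `2^I` are attached.
#' @return An object of class `info_result` with fields `information`
#'   (plug-in, bits), `information_mm` (Miller-Madow), `se` (delta-method
#'   standard error), `n_samples`, `n_patterns`, `capacity`, `n_signals`.
#' @examples
#' codes <- c(3L, 3L, 5L, 6L)  # patterns {1,2}, {1,2}, {1,3}, {2,3}
#' entropy_from_samples(codes)$information
#' @export
entropy_from_samples <- function(x, n_primacy = NULL, n_receptors = NULL) {
  counts <- as.numeric(pattern_counts(x))
  n <- sum(counts)
  if (n < 1) stop("at least one sample is required")
  k <- length(counts)
  p <- counts / n
  info <- -sum(p * log2(p))
  # delta-method standard error of the plug-in estimate
  v <- sum(p * log2(p)^2) - info^2
  se <- sqrt(max(v, 0) / n)
  if (n < 50 * k) {
    warning("entropy may be biased: ", n, " samples for ", k,
            " observed patterns (undersampling)")
  }
  capacity <- if (!is.null(n_primacy) && !is.null(n_receptors)) {
    i_max(n_primacy, n_receptors)
  } else {
    NA_real_
  }
  structure(
    list(
      information = info,
      information_mm = info + (k - 1) / (2 * n * log(2)),
      se = se,
      n_samples = n,
      n_patterns = k,
      capacity = capacity,
      n_signals = 2^info
    ),
    class = "info_result"
  )
}

#' @export
print.info_result <- function(x, ...) {
  cat("Transmitted information: ", signif(x$information, 6), " bits",
      if (!is.na(x$capacity)) paste0(" (capacity ", signif(x$capacity, 6), ")"),
      "\n  Miller-Madow: ", signif(x$information_mm, 6),
      ";  n = ", x$n_samples, ", ", x$n_patterns, " patterns\n", sep = "")
  invisible(x)
}

#' @rdname entropy_from_samples
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.info_result <- function(x, ...) {
  tibble::tibble(
    information = x$information,
    information_mm = x$information_mm,
    se = x$se,
    capacity = x$capacity,
    n_signals = x$n_signals,
    n_samples = x$n_samples,
    n_patterns = x$n_patterns
  )
}

#' @rdname entropy_from_samples
#' @exportS3Method generics::glance
glance.info_result <- function(x, ...) tidy.info_result(x, ...)

#' Information of a grouped pattern code
#'
#' When the primacy sets can be partitioned into groups whose members are
#' equiprobable, the entropy is `I = -sum_m p_m log2(p_m / M_m)` for group
#' probabilities `p_m` and group sizes `M_m`.
#'
#' @param group_probs probability of each group (sums to 1).
#' @param group_sizes number of patterns in each group.
#' @param log2_sizes optionally, `log2(group_sizes)` directly (for sizes
#'   too large to represent exactly).
#' @return Information in bits.
#' @export
grouped_information <- function(group_probs, group_sizes = NULL,
                                log2_sizes = NULL) {
  if (is.null(log2_sizes)) {
    stopifnot(!is.null(group_sizes), all(group_sizes >= 1))
    log2_sizes <- log2(group_sizes)
  }
  stopifnot(length(group_probs) == length(log2_sizes),
            all(group_probs >= 0),
            abs(sum(group_probs) - 1) < 1e-8)
  pos <- group_probs > 0
  p <- group_probs[pos]
  -sum(p * (log2(p) - log2_sizes[pos]))
}

#' Two-group code for one deviant receptor type
#'
#' Partition of the primacy sets by whether they contain receptor type 1,
#' whose mean activity `a1_mean` deviates from the symmetric value
#' `n_primacy / n_receptors`: group 1 (receptor 1 active) has
#' `choose(N_R - 1, N_C - 1)` members with total probability `a1_mean`,
#' group 2 the rest.  At `a1_mean = n_primacy / n_receptors` this
#' reproduces `i_max(n_primacy, n_receptors)` exactly; at `a1_mean = 0` it
#' reduces to `i_max(n_primacy, n_receptors - 1)` and at `a1_mean = 1` to
#' `i_max(n_primacy - 1, n_receptors - 1)`.
#'
#' @param a1_mean mean activity of the deviant receptor type, in `[0, 1]`.
#' @param n_primacy,n_receptors code dimensions.
#' @return Information in bits.
#' @export
two_group_information <- function(a1_mean, n_primacy, n_receptors) {
  stopifnot(a1_mean >= 0, a1_mean <= 1, n_primacy >= 1,
            n_primacy < n_receptors)
  log2_sizes <- c(
    lchoose(n_receptors - 1, n_primacy - 1),
    lchoose(n_receptors - 1, n_primacy)
  ) / log(2)
  grouped_information(c(a1_mean, 1 - a1_mean), log2_sizes = log2_sizes)
}

#' Critical activity of a deviant receptor type
#'
#' The mean activity `p1_max` of a single overly active receptor type
#' above which the array transmits less information than with that type
#' removed entirely.  `method = "numeric"` solves
#' `two_group_information(p1) = i_max(n_primacy, n_receptors - 1)` on
#' `(n_primacy / n_receptors, 1)`; `method = "asymptotic"` returns the
#' large-repertoire leading order `e * n_primacy / n_receptors`.
#'
#' @param n_primacy,n_receptors code dimensions.
#' @param method `"numeric"` or `"asymptotic"`.
#' @return Activity probability.
#' @examples
#' p1_max(8, 1000, method = "asymptotic")  # ~ 0.0217
#' @export
p1_max <- function(n_primacy, n_receptors, method = c("numeric", "asymptotic")) {
  method <- match.arg(method)
  if (method == "asymptotic") {
    return(exp(1) * n_primacy / n_receptors)
  }
  target <- i_max(n_primacy, n_receptors - 1)
  f <- function(p1) two_group_information(p1, n_primacy, n_receptors) - target
  lo <- n_primacy / n_receptors
  if (f(1) > 0) stop("no crossing found in (n_primacy/n_receptors, 1)")
  uniroot(f, c(lo, 1), tol = 1e-12)$root
}

# log2 of the generalized binomial coefficient, continuous in k.
log2_choose_cont <- function(n, k) {
  (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)) / log(2)
}

#' Perfect-decoder identification bounds
#'
#' All equal-concentration mixtures of `s` ligands drawn from a library of
#' `n_library` ligands map to distinct primacy sets only if
#' `choose(n_library, s) < choose(n_receptors, n_primacy)`.
#' `mixture_capacity()` returns the largest library size for a given
#' mixture size, `max_mixture_size()` the largest mixture size for a given
#' library.  Binomial coefficients are evaluated in log space.
#'
#' @param n_receptors,n_primacy code dimensions.
#' @param mixture_size number of ligands per mixture `s`.
#' @param n_library library size `N_L`.
#' @return A count (returned as a double; can exceed integer range).
#' @examples
#' max_mixture_size(300, 8, 1000)  # 6
#' @export
mixture_capacity <- function(n_receptors, n_primacy, mixture_size) {
  stopifnot(mixture_size >= 1)
  cap <- lchoose(n_receptors, n_primacy)
  if (mixture_size == 1) return(round(choose(n_receptors, n_primacy)) - 1)
  f <- function(log_nl) lchoose(exp(log_nl), mixture_size) - cap
  if (f(log(mixture_size)) >= 0) return(mixture_size - 1)
  upper <- log(mixture_size)
  while (f(upper) < 0) upper <- upper + 5
  nl <- floor(exp(uniroot(f, c(log(mixture_size), upper), tol = 1e-12)$root))
  # adjust for the strict inequality at the boundary
  while (lchoose(nl, mixture_size) >= cap) nl <- nl - 1
  while (lchoose(nl + 1, mixture_size) < cap) nl <- nl + 1
  nl
}

#' @rdname mixture_capacity
#' @export
max_mixture_size <- function(n_receptors, n_primacy, n_library) {
  cap <- lchoose(n_receptors, n_primacy)
  s <- 0
  while (s < n_library && lchoose(n_library, s + 1) < cap) s <- s + 1
  s
}

#' Number of identifiable target ligands at a given code distance
#'
#' When adding a target changes the primacy set by an expected Hamming
#' distance `d`, about `d / 2` of the previously inactive
#' `n_receptors - n_primacy` types become active, so roughly
#' `choose(n_receptors - n_primacy, d / 2)` targets can be told apart.
#' Evaluated continuously in `d` via log-gamma for curves; with
#' `integer = TRUE` the half-distance is rounded half-to-even and an
#' integral count is returned.
#'
#' @param n_receptors,n_primacy code dimensions.
#' @param d expected Hamming distance, in `[0, 2 * n_primacy]`.
#' @param integer round `d / 2` to an integer count.
#' @return Estimated number of distinguishable targets.
#' @export
identifiable_targets <- function(n_receptors, n_primacy, d, integer = FALSE) {
  stopifnot(all(d >= 0), all(d <= 2 * n_primacy))
  k <- if (integer) round(d / 2) else d / 2
  2^log2_choose_cont(n_receptors - n_primacy, k)
}
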