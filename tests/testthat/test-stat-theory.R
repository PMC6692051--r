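test_that("unit-mean log-normal building block G", {
  # median of the matched log-normal is exp(-zeta)
  for (z in c(0.1, 0.5, 2)) {
    expect_equal(excitation_cdf(exp(-z), z), 0.5, tolerance = 1e-12)
  }
  expect_equal(excitation_quantile(0.5, 0.5), exp(-0.5), tolerance = 1e-12)

  # mean 1 and variance exp(2 zeta) - 1, by numerical integration
  z <- 0.3
  m1 <- integrate(function(x) x * excitation_pdf(x, z), 0, Inf,
                  rel.tol = 1e-10)$value
  m2 <- integrate(function(x) x^2 * excitation_pdf(x, z), 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(m1, 1, tolerance = 1e-8)
  expect_equal(m2 - m1^2, exp(2 * z) - 1, tolerance = 1e-7)

  # quantile/CDF round trip
  q <- c(0.001, 0.1, 0.5, 0.9, 0.999)
  for (z in c(0.097, 0.5, 1)) {
    expect_lt(max(abs(excitation_cdf(excitation_quantile(q, z), z) - q)),
              1e-10)
  }
})

test_that("excitation width zeta", {
  # a single ligand gives zeta = lambda^2 / 2
  expect_equal(zeta_from_conc(1, log_width = 1), 0.5, tolerance = 1e-12)
  # the Fig-2-class environment: s = 16, sigma/mu = 1, lambda = 1
  expect_equal(zeta_from_env(16, 1, 1), 0.0973, tolerance = 1e-3)
  # scale invariance of the concrete-odor form
  set.seed(501)
  conc <- rlnorm(12)
  expect_equal(zeta_from_conc(conc), zeta_from_conc(1e3 * conc),
               tolerance = 1e-12)
  expect_error(zeta_from_conc(c(0, 0)), "zero odor")
})

test_that("mean threshold and the equivalent inhibition strength", {
  # at half sparsity the threshold sits at the median exp(-zeta)
  th <- mean_threshold(8, 16, zeta = 0.3, mean_excitation = 5)
  expect_equal(th$gamma, 5 * exp(-0.3), tolerance = 1e-10)
  expect_equal(th$alpha, exp(-0.3), tolerance = 1e-10)

  # alpha does not depend on the excitation scale
  expect_equal(mean_threshold(4, 50, 0.2, 1)$alpha,
               mean_threshold(4, 50, 0.2, 1000)$alpha)

  # Monte Carlo: fraction of excitations above gamma is N_C/N_R
  set.seed(502)
  z <- 0.5
  th2 <- mean_threshold(8, 64, z)
  e <- rlnorm(2e5, -z, sqrt(2 * z))
  frac <- mean(e > th2$gamma)
  expect_lt(abs(frac - 8 / 64), 4 * sqrt(0.125 * 0.875 / 2e5))
})

test_that("scenario excitation statistics follow the mixture rules", {
  # single background: target scales mean by ct/cb, variance by (ct/cb)^2
  sc <- mixture_scenario("target_in_single_background",
                         background_conc = 2, target_conc = 1)
  st <- scenario_excitation_stats(sc, log_width = 1)
  expect_equal(st$target$mean, 0.5 * st$background$mean)
  expect_equal(st$target$var, 0.25 * st$background$var)

  # equal-concentration mixture: mean and variance both 1/s of background
  sc2 <- mixture_scenario("ligand_added_to_mixture", background_size = 4,
                          background_conc = 1, target_conc = 1)
  st2 <- scenario_excitation_stats(sc2, log_width = 1)
  expect_equal(st2$target$mean, st2$background$mean / 4)
  expect_equal(st2$target$var, st2$background$var / 4)
  # the target is itself a single ligand: its variance ratio is e^1 - 1
  expect_equal(st2$target$var / st2$target$mean^2, expm1(1),
               tolerance = 1e-12)

  # a vanishing target perturbs nothing
  sc3 <- mixture_scenario("ligand_added_to_mixture", background_size = 10,
                          target_conc = 0)
  d3 <- expected_distance(sc3, 8, 300)
  expect_equal(d3$d, 0)
  expect_equal(d3$eta, 0)
})

test_that("expected distance recovers the uncorrelated and identical limits", {
  d_star <- 2 * 8 * (1 - 8 / 300)
  un <- expected_distance(
    mixture_scenario("shared_ligand_pair", background_size = 30,
                     shared_count = 0), 8, 300)
  expect_equal(un$d, d_star, tolerance = 1e-9)
  expect_equal(un$d_star, d_star)

  id <- expected_distance(
    mixture_scenario("shared_ligand_pair", background_size = 30,
                     shared_count = 30), 8, 300)
  expect_equal(id$d, 0)
  expect_equal(id$eta, 0)
  expect_equal(id$p_correct, 0.5)

  # d decreases monotonically with the shared fraction
  ds <- vapply(c(0, 10, 20, 25, 29), function(sb) {
    expected_distance(mixture_scenario("shared_ligand_pair",
                                       background_size = 30,
                                       shared_count = sb), 8, 300)$d
  }, numeric(1))
  expect_true(all(diff(ds) < 0))
})

test_that("discriminability maps distances to detection probabilities", {
  expect_equal(discriminability(0, 8), 0)
  expect_equal(discriminability(16, 8), 1)
  expect_equal(p_correct(0), 0.5)
  expect_equal(p_correct(1), 1)

  # uncorrelated bound at N_C = 4, N_R = 50
  d_star <- 2 * 4 * (1 - 4 / 50)
  eta <- discriminability(d_star, 4)
  expect_equal(eta, 1 - (4 / 50)^4, tolerance = 1e-12)
  expect_gt(eta, 0.9999)

  # monotone nondecreasing in d
  d <- seq(0, 16, by = 0.25)
  expect_true(all(diff(discriminability(d, 8)) >= 0))
  expect_error(discriminability(17, 8))
})

test_that("theory tracks Monte Carlo along a detection curve", {
  # the quadrature d agrees with simulation to a few percent; eta (the
  # paper's binomial mapping) agrees tightly at the curve ends and to
  # ~0.06 in the middle
  set.seed(503)
  for (ct in c(0.05, 0.2, 0.8)) {
    sc <- mixture_scenario("target_in_single_background", target_conc = ct)
    mc <- simulate_discrimination(sc, 10000, 300, 8)
    th <- expected_distance(sc, 8, 300)
    expect_lt(abs(th$d - mc$d_mean), 0.05 + 0.05 * mc$d_mean)
    expect_lt(abs(th$eta - mc$eta), 0.05)
  }
  # curve ends: tight agreement
  sc_lo <- mixture_scenario("target_in_single_background", target_conc = 0.02)
  mc_lo <- simulate_discrimination(sc_lo, 10000, 300, 8)
  th_lo <- expected_distance(sc_lo, 8, 300)
  expect_lt(abs(th_lo$eta - mc_lo$eta), 3 * mc_lo$eta_se + 0.005)
})

test_that("probabilities and distances stay in their ranges", {
  set.seed(504)
  grid <- expand.grid(ct = c(0.01, 0.1, 1, 10), s = c(1, 4, 16))
  for (i in seq_len(nrow(grid))) {
    sc <- mixture_scenario("ligand_added_to_mixture",
                           background_size = grid$s[i],
                           target_conc = grid$ct[i])
    th <- expected_distance(sc, 8, 300)
    expect_gte(th$d, 0)
    expect_lte(th$d, 16)
    expect_gte(th$eta, 0)
    expect_lte(th$eta, 1)
    expect_gte(th$p_on, 0)
    expect_lte(th$p_on, 1)
    expect_gte(th$p_off, 0)
    expect_lte(th$p_off, 1)
  }
})
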