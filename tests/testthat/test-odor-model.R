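test_that("environment invariants and derived mixture size", {
  env <- odor_environment(n_ligands = 512, mean_mixture_size = 16)
  expect_equal(env$presence_prob, 16 / 512)
  expect_equal(env$mean_mixture_size, env$presence_prob * env$n_ligands)

  env2 <- odor_environment(n_ligands = 100, presence_prob = 0.05)
  expect_equal(env2$mean_mixture_size, 5)

  expect_error(odor_environment(n_ligands = 10, mean_mixture_size = 20))
  expect_error(odor_environment(conc_mean = -1))
  expect_error(sample_odors(odor_environment(presence_prob = 0), 1))
})

test_that("sampled presence count matches the mean mixture size", {
  set.seed(101)
  env <- odor_environment(n_ligands = 512, mean_mixture_size = 16)
  n <- 20000
  odors <- sample_odors(env, n)
  counts <- tabulate(odors$odor_id, nbins = n)
  s_hat <- mean(counts)
  se <- sd(counts) / sqrt(n)
  expect_lt(abs(s_hat - 16), 4 * se)
  expect_true(all(counts >= 1))
})

test_that("concentrations are moment-matched log-normal", {
  set.seed(102)
  env <- odor_environment(n_ligands = 64, mean_mixture_size = 8,
                          conc_mean = 2, conc_sd = 3)
  odors <- sample_odors(env, 5000)
  x <- odors$concentration
  expect_lt(abs(mean(x) - 2), 4 * sd(x) / sqrt(length(x)))
  # log-concentrations are normal with the matched underlying parameters
  lp <- lognormal_from_moments(2, 9)
  ks <- suppressWarnings(
    stats::ks.test(log(x), "pnorm", lp$meanlog, lp$sdlog)
  )
  expect_gt(ks$p.value, 0.01)

  # degenerate distribution: every present ligand at exactly conc_mean
  env0 <- odor_environment(n_ligands = 32, mean_mixture_size = 4,
                           conc_mean = 1.5, conc_sd = 0)
  odors0 <- sample_odors(env0, 50)
  expect_true(all(odors0$concentration == 1.5))
})

test_that("per-ligand moments follow the presence/concentration model", {
  set.seed(103)
  env <- odor_environment(n_ligands = 512, mean_mixture_size = 16,
                          conc_mean = 1, conc_sd = 1)
  m <- environment_moments(env)
  p <- 16 / 512
  expect_equal(m$conc_mean, p * 1)
  expect_equal(m$conc_var, (p - p^2) * 1 + p * 1)
  expect_equal(m$conc_ratio, 2 / 16)

  n <- 20000
  odors <- sample_odors(env, n)
  # mean over ALL ligand slots, absent ligands counting as zero
  c_mean_hat <- sum(odors$concentration) / (n * env$n_ligands)
  c2_mean_hat <- sum(odors$concentration^2) / (n * env$n_ligands)
  var_hat <- c2_mean_hat - c_mean_hat^2
  expect_lt(abs(c_mean_hat - m$conc_mean) / m$conc_mean, 0.05)
  expect_lt(abs(var_hat - m$conc_var) / m$conc_var, 0.05)
})

test_that("concentration-ratio formula matches the fixed-size moment ratio", {
  # The theory uses E[sum c^2] / (E[sum c])^2 with the mixture size held
  # at exactly s; verify that reading by Monte Carlo on the concentration
  # distribution for a grid of (s, sigma/mu).
  set.seed(104)
  for (s in c(1, 4, 16)) {
    for (cv in c(0, 1, 3)) {
      env <- odor_environment(n_ligands = 512, mean_mixture_size = s,
                              conc_mean = 1, conc_sd = cv)
      formula <- environment_moments(env)$conc_ratio
      n <- 20000
      lp <- lognormal_from_moments(1, cv^2)
      c_mat <- matrix(rlnorm(n * s, lp$meanlog, lp$sdlog), n, s)
      num <- rowSums(c_mat^2)
      den <- rowSums(c_mat)
      est <- mean(num) / mean(den)^2
      # delta-method error on the ratio of the two moment estimates
      se <- est * sqrt(var(num) / (n * mean(num)^2) +
                         4 * var(den) / (n * mean(den)^2))
      expect_lt(abs(est - formula), 4 * se + 1e-12)
    }
  }
  # for large mixtures the per-odor ratio itself approaches the formula
  env <- odor_environment(n_ligands = 512, mean_mixture_size = 64,
                          conc_sd = 1)
  odors <- sample_odors(env, 3000)
  ratios <- vapply(split(odors$concentration, odors$odor_id),
                   function(cc) sum(cc^2) / sum(cc)^2, numeric(1))
  expect_lt(abs(mean(ratios) - environment_moments(env)$conc_ratio) /
              environment_moments(env)$conc_ratio, 0.10)
})

test_that("scenario pairs realize the declared ligand structure", {
  set.seed(105)
  sc <- mixture_scenario("target_in_single_background",
                         background_conc = 1, target_conc = 0.2)
  pair <- scenario_odor_pair(sc, n_ligands = 32)
  a <- pair[pair$odor == "A", ]
  b <- pair[pair$odor == "B", ]
  expect_equal(nrow(a), 1)
  expect_equal(nrow(b), 2)
  added <- dplyr::anti_join(b, a, by = "ligand")
  expect_equal(nrow(added), 1)
  expect_equal(added$concentration, 0.2)

  # identical mixtures when all ligands are shared
  sc2 <- mixture_scenario("shared_ligand_pair", background_size = 30,
                          shared_count = 30)
  pair2 <- scenario_odor_pair(sc2, n_ligands = 64)
  a2 <- pair2[pair2$odor == "A", c("ligand", "concentration")]
  b2 <- pair2[pair2$odor == "B", c("ligand", "concentration")]
  expect_equal(a2, b2)

  # total concentrations for a mixture-addition scenario
  sc3 <- mixture_scenario("ligand_added_to_mixture", background_size = 10,
                          background_conc = 1, target_conc = 1)
  pair3 <- scenario_odor_pair(sc3, n_ligands = 64)
  expect_equal(sum(pair3$concentration[pair3$odor == "A"]), 10)
  expect_equal(sum(pair3$concentration[pair3$odor == "B"]), 11)

  # shared ligands keep identical jittered concentrations in both odors
  sc4 <- mixture_scenario("shared_ligand_pair", background_size = 6,
                          shared_count = 3, conc_cv = 1)
  pair4 <- scenario_odor_pair(sc4, n_ligands = 64)
  shared <- dplyr::inner_join(pair4[pair4$odor == "A", ],
                              pair4[pair4$odor == "B", ], by = "ligand")
  expect_equal(nrow(shared), 3)
  expect_equal(shared$concentration.x, shared$concentration.y)

  expect_error(scenario_odor_pair(sc2, n_ligands = 10),
               "ligand space too small")
  expect_error(mixture_scenario("shared_ligand_pair", background_size = 5,
                                shared_count = 6))
})

test_that("odor tables round-trip through CSV", {
  set.seed(106)
  env <- odor_environment(n_ligands = 32, mean_mixture_size = 4)
  odors <- sample_odors(env, 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_odors_csv(odors, path)
  back <- read_odors_csv(path)
  expect_equal(back$odor_id, odors$odor_id)
  expect_equal(back$ligand, odors$ligand)
  expect_equal(back$concentration, odors$concentration)
})
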