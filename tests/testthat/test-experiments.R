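test_that("information tracks capacity across primacy dimensions", {
  res <- run_information_experiment(n_receptors = 16, n_primacy = c(2, 4),
                                    n_samples = 50000, seed = 601)
  info <- res[res$metric == "information", ]
  cap <- res[res$metric == "capacity", ]
  # close to but below capacity, with the gap within a few percent
  expect_true(all(info$value < cap$value))
  expect_true(all((cap$value - info$value) / cap$value < 0.03))
  # stochastic rows carry standard errors, theory rows do not
  expect_true(all(!is.na(info$se)))
  expect_true(all(is.na(cap$se)))
  expect_true(all(res$seed == 601L))

  # a single observation carries no information
  res1 <- suppressWarnings(
    run_information_experiment(n_receptors = 8, n_primacy = 2,
                               n_samples = 1, seed = 602))
  expect_equal(res1$value[res1$metric == "information"], 0)
})

test_that("halving the repertoire costs about N_C bits of capacity", {
  res <- run_lesion_curve(n_receptors = 1000, n_primacy = c(4, 8))
  loss <- res[res$metric == "capacity_loss", ]
  expect_equal(loss$value, loss$n_primacy, tolerance = 0.01)
  rel <- res[res$metric == "capacity_loss_relative", ]
  expect_true(all(rel$value > 0 & rel$value < 1))
})

test_that("experiments are reproducible from config plus seed", {
  a <- run_information_experiment(n_receptors = 12, n_primacy = 3,
                                  n_samples = 5000, seed = 603)
  b <- run_information_experiment(n_receptors = 12, n_primacy = 3,
                                  n_samples = 5000, seed = 603)
  expect_identical(as.data.frame(a), as.data.frame(b))

  sc <- mixture_scenario("target_in_single_background", target_conc = 0.3)
  d1 <- run_discrimination_experiment(sc, tibble::tibble(target_conc = c(0.2, 0.5)),
                                      n_trials = 500, n_receptors = 50,
                                      n_primacy = 4, seed = 604)
  d2 <- run_discrimination_experiment(sc, tibble::tibble(target_conc = c(0.2, 0.5)),
                                      n_trials = 500, n_receptors = 50,
                                      n_primacy = 4, seed = 604)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})

test_that("discrimination sweep pairs Monte Carlo with theory columns", {
  sc <- mixture_scenario("target_in_single_background")
  res <- run_discrimination_experiment(
    sc, tibble::tibble(target_conc = c(0.1, 0.4)),
    n_trials = 2000, n_receptors = 50, n_primacy = 4, seed = 605)
  expect_setequal(unique(res$metric),
                  c("eta", "d", "p_correct",
                    "eta_theory", "d_theory", "p_correct_theory"))
  mc <- res[res$metric == "eta", ]
  th <- res[res$metric == "eta_theory", ]
  expect_true(all(!is.na(mc$se)))
  expect_true(all(is.na(th$se)))
  # detection improves with target concentration in both columns
  expect_lt(mc$value[1], mc$value[2])
  expect_lt(th$value[1], th$value[2])
  # p_correct is the chance-corrected eta
  pc <- res[res$metric == "p_correct", ]
  expect_equal(pc$value, mc$value + (1 - mc$value) / 2, tolerance = 1e-12)
})

test_that("scheme comparison: only primacy keeps its sparsity", {
  res <- run_scheme_comparison(mixture_sizes = c(1, 4, 16),
                               n_receptors = 64, n_primacy = 4,
                               target_single_active = 4,
                               n_trials = 1500, seed = 606)
  act <- tidyr::pivot_wider(res[res$metric == "active_mean", ],
                            id_cols = "mixture_size",
                            names_from = "scheme", values_from = "value")
  # primacy sparsity is exactly N_C for every mixture size
  expect_true(all(act$primacy == 4))
  # binary grows with s, normalized shrinks with s
  expect_true(all(diff(act$binary) > 0))
  expect_true(all(diff(act$normalized) < 0))
  # at s = 1 the calibrated schemes hit the target mean active count
  expect_lt(abs(act$normalized[act$mixture_size == 1] - 4), 0.5)
  expect_lt(abs(act$binary[act$mixture_size == 1] - 4), 0.5)
  # every stochastic cell carries a standard error
  expect_true(all(!is.na(res$se)))
})

test_that("a single hot receptor dominates; information peaks at xi1 = 1", {
  res <- run_heterogeneity_experiment(
    "single_factor", grid = c(0, 0.5, 1, 2),
    n_receptors = 16, n_primacy = 4, n_samples = 30000, seed = 607)
  info <- res$value
  names(info) <- res$xi1
  # maximum at the homogeneous point
  expect_gt(info[["1"]], info[["0"]])
  expect_gt(info[["1"]], info[["0.5"]])
  expect_gt(info[["1"]], info[["2"]])
  # an overly sensitive receptor is worse than a silenced one
  expect_lt(info[["2"]], info[["0"]])
})

test_that("distributed heterogeneity degrades the information", {
  res <- run_heterogeneity_experiment(
    "distributed", grid = c(0, 0.5), n_receptors = 16, n_primacy = 4,
    n_samples = 80000, n_arrays = 4, seed = 608)
  expect_lt(res$value[res$factor_cv2 == 0.5],
            res$value[res$factor_cv2 == 0])
})

test_that("autoplot produces ggplot objects for each result type", {
  res <- run_information_experiment(n_receptors = 10, n_primacy = 2:3,
                                    n_samples = 2000, seed = 609)
  expect_s3_class(autoplot(res), "ggplot")
  sc <- mixture_scenario("target_in_single_background")
  disc <- run_discrimination_experiment(
    sc, tibble::tibble(target_conc = c(0.2, 0.6)), n_trials = 200,
    n_receptors = 30, n_primacy = 3, seed = 610)
  expect_s3_class(autoplot(disc), "ggplot")
  les <- run_lesion_curve(n_receptors = 100, n_primacy = 2:6)
  expect_s3_class(autoplot(les), "ggplot")
})
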