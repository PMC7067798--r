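# Lifetime, Poisson-count and slope estimators, and genotype assembly.

test_that("retraction rates are inverse mean lifetimes by class", {
  tr <- data.frame(t_birth_min = rep(0, 4),
                   t_death_min = c(2, 2, 2, 12))
  est <- estimate_retraction_rates(tr)
  expect_equal(est$c2_sF, 0.5)
  expect_equal(est$c2_lF, 1 / 12)
  expect_equal(est$n_short, 3L)
  expect_equal(est$n_censored, 0L)

  # censored tracks are excluded but counted
  tr$t_death_min[2] <- NA
  est2 <- estimate_retraction_rates(tr)
  expect_equal(est2$n_censored, 1L)
  expect_equal(est2$n_short, 2L)

  expect_error(estimate_retraction_rates(
    data.frame(t_birth_min = 0, t_death_min = 3)), "long-lived")
  expect_error(estimate_retraction_rates(
    data.frame(t_birth_min = 0, t_death_min = 9)), "short-lived")
  expect_error(estimate_retraction_rates(tr, cutoff = -1), "positive")
})

test_that("exponential lifetimes recover their rate by the law of large numbers", {
  set.seed(7)
  life <- rexp(10000, 0.25)
  life <- life[life < 8]                      # keep within the short class
  tr <- data.frame(t_birth_min = 0, t_death_min = c(life, 20))
  est <- estimate_retraction_rates(tr)
  # truncated exponential mean: (1/r) - cutoff*exp(-r*cutoff)/(1-exp(-r*cutoff))
  r <- 0.25; cutoff <- 8
  m_trunc <- 1 / r - cutoff * exp(-r * cutoff) / (1 - exp(-r * cutoff))
  expect_equal(est$c2_sF, 1 / m_trunc, tolerance = 0.05)
})

test_that("lambda is the exact sample mean with a dispersion diagnostic", {
  sn <- data.frame(t_min = 1:3, sF = c(2, 2, 2))
  est <- estimate_lambda(sn, "sF")
  expect_identical(est$lambda, 2)
  expect_identical(est$dispersion, 0)

  set.seed(3)
  big <- data.frame(t_min = 1:10000, sF = rpois(10000, 3.4))
  est2 <- estimate_lambda(big, "sF")
  expect_equal(est2$lambda, 3.4, tolerance = 0.02)
  expect_equal(est2$dispersion, 1, tolerance = 0.1)
  expect_equal(est2$lambda, mean(big$sF))      # exact closed form

  one <- data.frame(t_min = 0, sF = 5)
  expect_identical(estimate_lambda(one, "sF")$lambda, 5)
  expect_error(estimate_lambda(sn, "bogus"), "unknown")
})

test_that("generation rate follows the stationary relation and guards the drive", {
  expect_equal(estimate_generation_rate(2, 0.5, 1), 1)
  expect_equal(estimate_generation_rate(0, 0.5, 1), 0)
  expect_error(estimate_generation_rate(2, 0.5, 0), "f_F")
  expect_error(estimate_generation_rate(2, 0.5, eval_f_F(1200)), "f_F")
})

test_that("c6 slope arithmetic is exact (1/132 for the control inputs)", {
  expect_equal(estimate_c6(5, 600, 1.1), 5 / 660)
  expect_equal(estimate_c6(5, 600, 1.1), 1 / 132)
  expect_equal(estimate_c6(0, 600, 1.1), 0)
  expect_equal(estimate_c6(6, 100, 2), 0.03)
  expect_error(estimate_c6(5, 0, 1.1), "positive")
  expect_error(estimate_c6(5, 600, 0), "positive")

  tab <- data.frame(stage = c(40, 50, 60, 70),
                    synapses = c(0, 1, 6, 9))
  sl <- steepest_synapse_slope(tab)
  expect_equal(sl$delta_S, 5)
  expect_equal(sl$delta_t, 600)
  expect_equal(sl$from, 50)
})

test_that("full estimation chain recovers the generating parameters", {
  truth <- list(lambda_sF = 6, lambda_lF = 9, c2_sF = 1 / 3, c2_lF = 1 / 15,
                c5 = 0.03138528, B50 = 2, r3 = 0.02183574)
  syn <- gen_track_table(truth$lambda_sF, truth$lambda_lF, truth$c2_sF,
                         truth$c2_lF, duration = 600, n_terminals = 8,
                         seed = 11)
  bo <- gen_bulb_observations(truth$r3, 1 / 120, truth$c5, 5 / 660,
                              truth$B50, total_time = 120000,
                              sample_dt = 20, N = 8, seed = 12)
  fit <- estimate_genotype(syn$tracks, syn$snapshots,
                           bulb_obs = list(sB = bo$sB, synB = bo$synB),
                           genotype_label = "recovery")
  est <- coef(fit)
  expect_equal(unname(est["c2_sF"]), truth$c2_sF, tolerance = 0.10)
  expect_equal(unname(est["c2_lF"]), truth$c2_lF, tolerance = 0.10)
  expect_equal(unname(est["lambda_sF"]), truth$lambda_sF, tolerance = 0.05)
  expect_equal(unname(est["lambda_lF"]), truth$lambda_lF, tolerance = 0.05)
  expect_equal(unname(est["c1_sF"]), truth$lambda_sF * truth$c2_sF,
               tolerance = 0.15)
  expect_equal(unname(est["c1_lF"]), truth$lambda_lF * truth$c2_lF,
               tolerance = 0.15)
  expect_equal(unname(est["c5"]), truth$c5, tolerance = 0.25)
  expect_equal(unname(est["r3"]), truth$r3, tolerance = 0.25)
  expect_equal(unname(est["B50"]), truth$B50, tolerance = 0.25)
  expect_equal(unname(est["c4"]), 1 / 120)       # fixed, not fitted
  # c3 closes the factorization at P60
  f_FB_P60 <- eval_f_FB(1200, 1000)
  expect_equal(unname(est["c3"]),
               est[["r3"]] / ((est[["lambda_sF"]] + est[["lambda_lF"]]) *
                                f_FB_P60), tolerance = 1e-10)

  # determinism: identical inputs give identical estimates
  fit2 <- estimate_genotype(syn$tracks, syn$snapshots,
                            bulb_obs = list(sB = bo$sB, synB = bo$synB),
                            genotype_label = "recovery")
  expect_identical(coef(fit), coef(fit2))
})

test_that("missing bulb observations leave the triple unestimated", {
  syn <- gen_track_table(4, 6, 1 / 3, 1 / 12, duration = 120,
                         n_terminals = 4, seed = 2)
  fit <- estimate_genotype(syn$tracks, syn$snapshots)
  expect_true(is.na(coef(fit)["c5"]))
  expect_match(fit$report$bulb_triple, "unestimated")
  expect_match(fit$report$c4, "fixed")
})

test_that("bootstrap intervals cover the point estimates", {
  syn <- gen_track_table(5, 7, 1 / 3, 1 / 12, duration = 300,
                         n_terminals = 6, seed = 8)
  bb <- bootstrap_estimate(syn$tracks, "c2", B = 80, seed = 4)
  est <- estimate_retraction_rates(syn$tracks)
  expect_true(bb$c2_sF[1] <= est$c2_sF && est$c2_sF <= bb$c2_sF[2])
  bl <- bootstrap_estimate(syn$snapshots, "lambda", category = "sF",
                           B = 80, seed = 4)
  lam <- estimate_lambda(syn$snapshots, "sF")$lambda
  expect_true(bl$lambda[1] <= lam && lam <= bl$lambda[2])
})
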