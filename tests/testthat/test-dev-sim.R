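# Exact stochastic simulation of the developmental model.

test_that("all-zero rates produce an empty trajectory that stops early", {
  p <- dev_params()
  tr <- simulate_developmental(p, 0, 100, seed = 1)
  expect_length(tr$times, 0)
  expect_equal(final_state(tr),
               c(sF = 0L, lF = 0L, sB = 0L, synB = 0L, S = 0L))
  expect_match(attr(tr, "stopped_early"), "propensities")
})

test_that("trajectories are reproducible per seed and differ across seeds", {
  p <- const_drive_params(c1_sF = 0.5, c2_sF = 0.25, c1_lF = 0.1,
                          c2_lF = 0.05, c3 = 0.02, c5 = 0.01,
                          c6 = 0.01, B50 = 2, t_half = 300)
  a <- simulate_developmental(p, 0, 500, seed = 42)
  b <- simulate_developmental(p, 0, 500, seed = 42)
  expect_identical(a, b)
  c <- simulate_developmental(p, 0, 500, seed = 43)
  expect_false(identical(a$times, c$times))
})

test_that("every event applies exactly its reaction stoichiometry and S never decreases", {
  p <- const_drive_params(c1_sF = 0.8, c2_sF = 0.3, c1_lF = 0.3,
                          c2_lF = 0.05, c3 = 0.05, c5 = 0.05,
                          c6 = 0.02, B50 = 2, t_half = 200)
  tr <- simulate_developmental(p, 0, 800, seed = 5)
  expect_gt(length(tr$times), 100)
  expect_true(all(diff(tr$times) > 0))

  stoich <- rbind(
    R1_sF = c(1, 0, 0, 0, 0), R2_sF = c(-1, 0, 0, 0, 0),
    R1_lF = c(0, 1, 0, 0, 0), R2_lF = c(0, -1, 0, 0, 0),
    R3 = c(0, 0, 1, 0, 0), R4 = c(0, 0, -1, 0, 0),
    R5 = c(0, 0, -1, 1, 0), R6 = c(0, 0, 0, -1, 1))
  diffs <- diff(rbind(c(0, 0, 0, 0, 0), tr$states))
  expect_equal(unname(diffs), unname(stoich[tr$reactions, ]))
  expect_true(all(tr$states >= 0))
  expect_true(all(diff(tr$states[, "S"]) >= 0))
  expect_equal(final_state(tr)[["S"]], sum(tr$reactions == "R6"))
})

test_that("stationary filopodium counts are Poisson with mean c1/c2", {
  p <- const_drive_params(c1_sF = 1, c2_sF = 0.25)
  tr <- simulate_developmental(p, 0, 11000, seed = 11)
  sn <- snapshot_counts(tr, seq(1000, 11000, by = 1))
  lam_hat <- mean(sn$sF)
  expect_equal(lam_hat, 4, tolerance = 0.05)
  disp <- var(sn$sF) / lam_hat
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)
})

test_that("thinning and piecewise-constant schemes agree on a time-dependent case", {
  # quadratic ramp drive plus the f_FB switch; compare mean sF over many
  # short replicates between the two samplers
  p <- dev_params(c1_sF = 1, c2_sF = 0.2, t_half = 400,
                  poly_coeffs = c(0.2, 1e-3, 5e-7, 0, 0, 0))
  grid <- seq(150, 300, by = 5)
  mean_traj <- function(method) {
    mean(vapply(1:80, function(k) {
      tr <- simulate_developmental(p, 0, 300, seed = 100 + k,
                                   method = method)
      mean(snapshot_counts(tr, grid)$sF)
    }, numeric(1)))
  }
  m_thin <- mean_traj("thinning")
  m_pw <- mean_traj("piecewise")
  expect_equal(m_thin, m_pw, tolerance = 0.1)
  # and both near the deterministic immigration-death mean trajectory
  ode_mean <- local({
    tt <- seq(0, 300, by = 0.05)
    drv <- eval_f_F(tt, p$poly_coeffs)
    m <- numeric(length(tt))
    for (k in seq_along(tt)[-1]) {
      m[k] <- m[k - 1] + 0.05 * (drv[k] * p$c1_sF - p$c2_sF * m[k - 1])
    }
    mean(m[tt >= 150])
  })
  expect_equal(m_thin, ode_mean, tolerance = 0.1)
})

test_that("snapshots use the right-continuous convention", {
  p <- const_drive_params(c1_sF = 0.5, c2_sF = 0.2)
  tr <- simulate_developmental(p, 0, 300, seed = 2)
  expect_gt(length(tr$times), 3)
  # before the first event: initial state
  t_before <- tr$times[1] / 2
  expect_equal(snapshot_counts(tr, t_before)$sF, 0L)
  # exactly at an event: the post-event state
  k <- 3L
  expect_equal(unname(unlist(
    snapshot_counts(tr, tr$times[k])[, c("sF", "lF", "sB", "synB", "S")])),
    unname(tr$states[k, ]))
  expect_error(snapshot_counts(tr, 301), "horizon")
})

test_that("with stabilization off, concurrent bulbs match the M/M/inf mean r3/c4", {
  # frozen filopodium pool (no generation/retraction), early-saturating
  # f_FB, so bulb influx is constant: r3 = c3 * sF0
  p <- const_drive_params(c3 = 0.02, c4 = 0.05, t_half = 0.01)
  ini <- dev_state(t = 0, sF = 10)
  tr <- simulate_developmental(p, 0, 6000, initial = ini, seed = 9)
  st <- concurrent_bulb_stats(tr, window = c(500, 6000))
  r3 <- 0.02 * 10
  expect_equal(st$mean_concurrent, r3 / 0.05, tolerance = 0.1)
})

test_that("bulb lifetimes and stability classification are bookkept correctly", {
  p <- const_drive_params(c3 = 0.05, c4 = 1 / 30, t_half = 0.01)
  ini <- dev_state(t = 0, sF = 5)
  tr <- simulate_developmental(p, 0, 4000, initial = ini, seed = 4)
  st <- concurrent_bulb_stats(tr, window = c(0, 4000))
  lt <- st$lifetimes
  expect_gt(nrow(lt), 50)
  expect_true(all(lt$lifetime >= 0))
  # uncensored mean lifetime ~ 1/c4 = 30 min
  expect_equal(mean(lt$lifetime[!lt$censored]), 30, tolerance = 0.15)
  # stability flag is the > threshold rule
  expect_identical(lt$stable, lt$lifetime > st$stable_min)
  expect_error(concurrent_bulb_stats(tr, window = c(10, 10)), "interval")
})

test_that("frozen-rate stationary sB marginal matches the independent eigen solve", {
  # c5 = 0: bulbs form at constant r3 and retract at c4; compare the
  # simulated occupancy of sB with the truncated-generator stationary law
  p <- const_drive_params(c3 = 0.03, c4 = 0.04, t_half = 0.01)
  ini <- dev_state(t = 0, sF = 4)
  tr <- simulate_developmental(p, 0, 1e5, initial = ini, seed = 21)
  sn <- snapshot_counts(tr, seq(1000, 1e5, by = 5))
  N <- 12L
  emp <- tabulate(pmin(sn$sB, N) + 1L, nbins = N + 1L) / nrow(sn)
  m <- marginal_densities(stationary_distribution(
    build_generator(0.03 * 4, 0.04, 0, 0.01, 2, N)))
  expect_lt(0.5 * sum(abs(emp - m$sB)), 0.02)   # total-variation distance
})
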