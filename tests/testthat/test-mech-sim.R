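# Winner-takes-all seed-pool model.

test_that("pool initialization uses the round-half-up convention", {
  expect_identical(init_pool(120, 1.0), 120L)
  expect_identical(init_pool(120, 1.1), 132L)
  expect_identical(init_pool(120, 1.004), 120L)   # 120.48 rounds down
  expect_identical(init_pool(120, 3.5), 420L)
  expect_error(init_pool(120, 0), "positive")
})

test_that("per-reaction propensities follow the competition rules", {
  p <- mech_params()
  pr <- mech_propensities(pool = 10, seeds = 4L, p)
  expect_equal(pr$emergence, p$g1)
  expect_equal(pr$accumulate, 10 * 0.07)
  expect_equal(pr$release, 1.5)
  expect_equal(pr$retract, 0.25)

  # empty roster: only emergence
  pr0 <- mech_propensities(10, integer(0), p)
  expect_length(pr0$accumulate, 0)
  expect_equal(pr0$emergence, p$g1)

  # seedless filopodium: no release, retraction hazard 1 (1/max(i,1))
  pr1 <- mech_propensities(10, 0L, p)
  expect_equal(pr1$release, 0)
  expect_equal(pr1$retract, 1)

  # at the cap accumulation is blocked
  prc <- mech_propensities(10, p$n, p)
  expect_equal(prc$accumulate, 0)

  # upregulated mode: retraction is seed-independent and equals c4
  pu <- mech_params(mode = "upregulated")
  for (i in c(0L, 4L, 60L, 120L)) {
    expect_equal(mech_propensities(10, i, pu)$retract, 1 / 120)
  }
})

test_that("seeds are conserved exactly and stay within [0, n] all run long", {
  p <- mech_params(n = 40, mean_bulbs_P60 = 1.5, g1 = 0.05)
  h <- simulate_mechanistic(p, steps = 5000, seed = 6)
  expect_equal(h$pool0, 60L)
  # replay seed totals from the log
  held <- integer(0); names(held) <- character(0)
  for (r in seq_len(nrow(h$event_log))) {
    id <- as.character(h$event_log$filo_id[r])
    ev <- h$event_log$event[r]
    if (ev == "retract") held <- held[names(held) != id]
    else held[id] <- h$event_log$seeds_after[r]
  }
  expect_true(all(h$pool >= 0))
  expect_true(all(h$event_log$seeds_after <= p$n))
  expect_equal(h$pool[h$steps] + sum(held), h$pool0)
  expect_true(all(diff(h$time) > 0))
})

test_that("with no accumulation the pool is frozen and no bulbs form", {
  p <- mech_params(c_in = 0, g1 = 0.5, n = 20, mean_bulbs_P60 = 1)
  h <- simulate_mechanistic(p, steps = 2000, seed = 3)
  expect_true(all(h$pool == h$pool0))
  expect_true(all(h$event_log$seeds_after <= 0))
  expect_true(all(h$n_bulbs == 0))
})

test_that("runs are reproducible per seed", {
  p <- mech_params(mean_bulbs_P60 = 1.1)
  a <- simulate_mechanistic(p, steps = 3000, seed = 9)
  b <- simulate_mechanistic(p, steps = 3000, seed = 9)
  expect_identical(a, b)
  c <- simulate_mechanistic(p, steps = 3000, seed = 10)
  expect_false(identical(a$time, c$time))
})

test_that("a larger seed pool yields more concurrent bulbous tips", {
  small <- analyze_bulbs(simulate_mechanistic(
    mech_params(mean_bulbs_P60 = 1.1), steps = 40000, seed = 12))
  large <- analyze_bulbs(simulate_mechanistic(
    mech_params(mean_bulbs_P60 = 3.5), steps = 40000, seed = 12))
  expect_gt(large$mean_bulbs, small$mean_bulbs)
})

test_that("bulb classification threshold and episode bookkeeping are correct", {
  p <- mech_params()
  expect_identical(p$bulb_threshold, 30L)           # ceiling(120/4)
  h <- simulate_mechanistic(mech_params(n = 24, mean_bulbs_P60 = 2,
                                        g1 = 0.05),
                            steps = 30000, seed = 2)
  st <- analyze_bulbs(h)
  expect_true(all(st$lifetimes$lifetime >= 0))
  expect_true(abs(sum(st$count_distribution) - 1) < 1e-12)
  # filopodia that never reach threshold contribute no episodes
  reached <- unique(h$event_log$filo_id[
    h$event_log$seeds_after >= h$params$bulb_threshold])
  expect_true(all(st$lifetimes$filo_id %in% reached))
  expect_error(analyze_bulbs(h, burn_in_fraction = 1), "burn-in")
})

test_that("competitive mode produces longer-lived bulbs than upregulated at matched pool", {
  comp <- analyze_bulbs(simulate_mechanistic(
    mech_params(mean_bulbs_P60 = 1.1), steps = 50000, seed = 5))
  upr <- analyze_bulbs(simulate_mechanistic(
    mech_params(mean_bulbs_P60 = 1.1, mode = "upregulated"),
    steps = 50000, seed = 5))
  expect_gt(mean(comp$lifetimes$lifetime), mean(upr$lifetimes$lifetime))
})

test_that("upregulated filopodium lifetimes are exponential with the constant hazard", {
  p <- mech_params(mode = "upregulated", n = 20, mean_bulbs_P60 = 2,
                   g1 = 0.5, upregulated_const = 0.05)
  h <- simulate_mechanistic(p, steps = 60000, seed = 8)
  log <- h$event_log
  born <- log$time[log$event == "emergence"]
  names(born) <- log$filo_id[log$event == "emergence"]
  died <- log$time[log$event == "retract"]
  names(died) <- log$filo_id[log$event == "retract"]
  common <- intersect(names(born), names(died))
  expect_gt(length(common), 500)
  lt <- died[common] - born[common]
  ks <- suppressWarnings(ks.test(lt, "pexp", 0.05))
  expect_gt(ks$p.value, 0.01)
})
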