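# Generator construction, stationary solve, marginals, KL and the fit.

test_that("N = 1 generator matches the hand-enumerated transition list", {
  r3 <- 0.7; c4 <- 0.3; c5 <- 0.2; c6 <- 0.11; B50 <- 2
  g <- build_generator(r3, c4, c5, c6, B50, N = 1)
  # states in order: [0,0], [1,0], [0,1], [1,1]; f1(0)=1, f1(1)=2/3
  f1_1 <- 2 / 3
  expected <- matrix(0, 4, 4)
  expected[1, 2] <- r3                       # [0,0] -> [1,0] birth
  expected[2, 1] <- c4                       # [1,0] -> [0,0] death
  expected[2, 3] <- c5                       # [1,0] -> [0,1] stabilize
  expected[3, 1] <- c6                       # [0,1] -> [0,0] mature
  expected[3, 4] <- r3 * f1_1                # [0,1] -> [1,1] birth
  expected[4, 2] <- c6                       # [1,1] -> [1,0] mature
  expected[4, 3] <- c4                       # [1,1] -> [0,1] death
  # stabilization [1,1] -> [0,2] is blocked by the reflecting boundary
  diag(expected) <- -rowSums(expected)
  expect_equal(g$matrix, expected, tolerance = 1e-14)
})

test_that("rows of the generator always sum to zero", {
  for (k in 1:5) {
    g <- build_generator(r3 = 0.01 * k, c4 = 0.02, c5 = 0.004 * k,
                         c6 = 0.007, B50 = k, N = 4 + k)
    expect_lt(max(abs(rowSums(g$matrix))), 1e-12)
    offdiag <- g$matrix; diag(offdiag) <- 0
    expect_true(all(offdiag >= 0))
  }
})

test_that("as-printed stabilization differs from reaction-consistent unless c5 = 0", {
  gA <- build_generator(0.05, 0.02, 0, 0.01, 2, N = 6,
                        generator_mode = "reaction_consistent")
  gB <- build_generator(0.05, 0.02, 0, 0.01, 2, N = 6,
                        generator_mode = "as_printed")
  expect_equal(gA$matrix, gB$matrix)
  mA <- marginal_densities(stationary_distribution(gA))
  mB <- marginal_densities(stationary_distribution(gB))
  expect_equal(mA$sB, mB$sB, tolerance = 1e-10)

  gC <- build_generator(0.05, 0.02, 0.03, 0.01, 2, N = 6,
                        generator_mode = "as_printed")
  gD <- build_generator(0.05, 0.02, 0.03, 0.01, 2, N = 6)
  expect_false(isTRUE(all.equal(gC$matrix, gD$matrix)))
})

test_that("stationary solve recovers eigenvalue zero and the birth-death law", {
  # with c5 = 0 the recurrent class is the j = 0 slice: a birth-death
  # chain with birth r3 and death i*c4, stationary truncated Poisson
  r3 <- 0.06; c4 <- 0.012
  g <- build_generator(r3, c4, 0, 0.01, 3, N = 14)
  v <- stationary_distribution(g)
  expect_lt(abs(v$eigenvalue), 1e-10)
  expect_lt(v$residual, 1e-10)
  expect_equal(sum(v$pi), 1, tolerance = 1e-12)
  pois <- dpois(0:14, r3 / c4); pois <- pois / sum(pois)
  expect_equal(unname(marginal_densities(v)$sB), pois, tolerance = 1e-8)
})

test_that("a reducible generator is reported with its components", {
  # c5 = c6 = 0 freezes j: each slice is its own communicating class
  g <- build_generator(0.05, 0.01, 0, 0, 2, N = 3)
  expect_error(stationary_distribution(g), "reducible")
  expect_error(stationary_distribution(g), "4 disconnected")
})

test_that("marginalization recovers point masses and product factors exactly", {
  N <- 3L
  P0 <- matrix(0, N + 1, N + 1); P0[1, 1] <- 1
  m0 <- marginal_densities(forge_stationary(P0))
  expect_equal(unname(m0$sB), c(1, 0, 0, 0))
  expect_equal(unname(m0$synB), c(1, 0, 0, 0))

  u <- matrix(1 / 4, 2, 2)
  mu <- marginal_densities(forge_stationary(u))
  expect_equal(unname(mu$sB), c(0.5, 0.5))
  expect_equal(unname(mu$synB), c(0.5, 0.5))

  a <- c(0.5, 0.3, 0.15, 0.05); b <- c(0.1, 0.2, 0.3, 0.4)
  mp <- marginal_densities(forge_stationary(outer(a, b)))
  expect_equal(unname(mp$sB), a, tolerance = 1e-14)
  expect_equal(unname(mp$synB), b, tolerance = 1e-14)
})

test_that("KL divergence: zero iff equal, hand value, infinity warning", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(kl_divergence(p, p), 0, tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1), pseudocount = 0),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1), pseudocount = 0),
               0.5108256, tolerance = 1e-6)
  expect_warning(v <- kl_divergence(c(0.5, 0.5), c(1, 0), pseudocount = 0),
                 "zero probability")
  expect_identical(v, Inf)
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.3, 0.2)), "support")
  # non-negativity over random pairs
  set.seed(1)
  for (k in 1:20) {
    a <- proportions(runif(6)); b <- proportions(runif(6))
    expect_gte(kl_divergence(a, b), 0)
  }
})

test_that("the KL fit returns the truth when observations equal the model", {
  truth <- c(c5 = 0.03, B50 = 2, r3 = 0.02)
  N <- 8L
  m <- marginal_densities(stationary_distribution(
    build_generator(truth["r3"], 1 / 120, truth["c5"], 5 / 660,
                    truth["B50"], N)))
  fit <- fit_bulbs(m$sB, m$synB, c4 = 1 / 120, c6 = 5 / 660, N = N)
  expect_lt(fit$objective, 1e-5)
  co <- coef(fit)
  expect_equal(unname(co["c5"]), 0.03, tolerance = 0.05)
  expect_equal(unname(co["r3"]), 0.02, tolerance = 0.05)
  expect_equal(unname(co["B50"]), 2, tolerance = 0.25)
  # refitting the fitted marginals reproduces the optimum (self-consistency)
  expect_lt(kl_divergence(m$sB, fit$model$sB) +
              kl_divergence(m$synB, fit$model$synB), 1e-5)
})

test_that("synB mass at zero with Poisson sB drives c5 to the boundary", {
  N <- 8L
  pois <- dpois(0:N, 0.06 / 0.02); pois <- pois / sum(pois)
  at_zero <- c(1, rep(0, N))
  fit <- fit_bulbs(pois, at_zero, c4 = 0.02, c6 = 0.01, N = N)
  expect_lt(coef(fit)[["c5"]], 1e-3)
  expect_equal(coef(fit)[["r3"]], 0.06, tolerance = 0.1)
})

test_that("degenerate all-zero observations are flagged unidentifiable", {
  N <- 4L
  z <- c(1, rep(0, N))
  expect_warning(fit <- fit_bulbs(z, z, N = N), "unidentifiable")
  expect_true(fit$unidentifiable)
})

test_that("truncation choice is insensitive once the boundary mass is negligible", {
  co8 <- {
    m <- marginal_densities(stationary_distribution(
      build_generator(0.02, 1 / 120, 0.03, 5 / 660, 2, 8)))
    coef(fit_bulbs(m$sB, m$synB, N = 8))
  }
  co12 <- {
    m <- marginal_densities(stationary_distribution(
      build_generator(0.02, 1 / 120, 0.03, 5 / 660, 2, 12)))
    coef(fit_bulbs(m$sB, m$synB, N = 12))
  }
  expect_equal(unname(co8), unname(co12), tolerance = 0.05)
  N <- choose_truncation(0.02, 1 / 120, 0.03, 5 / 660, 2)
  v <- stationary_distribution(build_generator(0.02, 1 / 120, 0.03,
                                               5 / 660, 2, N))
  expect_lt(with(v$states, sum(v$pi[pmax(i, j) >= N - 1])), 1e-6)
})
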