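test_that("k_deff is K_R*E_R/K_F and linear in E_R", {
  expect_equal(k_deff(lux_params(K_F = 1, K_R = 1), 1), 1)
  expect_equal(k_deff(lux_params(K_F = 4, K_R = 2), 6), 3)
  p <- asym_lux()
  for (er in c(0.1, 1, 7.3))
    expect_equal(k_deff(p, 2 * er), 2 * k_deff(p, er))
  expect_error(lux_params(K_F = 0), "positive")
  expect_error(k_deff(lux_params(), -1), ">= 0")
})

test_that("steady-state product saturates with half-point K_deff", {
  p <- asym_lux()
  kd <- k_deff(p, E_R = 2)
  expect_equal(steady_state_product(p, E_F = kd, E_R = 2), p$S_T / 2)
  expect_equal(steady_state_product(p, E_F = 0, E_R = 2), 0)
  expect_equal(steady_state_product(p, E_F = 9 * kd, E_R = 2), 0.9 * p$S_T)
  # E_R = 0 with E_F > 0: analytic limit S_T, flagged
  lim <- steady_state_product(p, E_F = 1, E_R = 0)
  expect_equal(as.numeric(lim), p$S_T)
  expect_true(attr(lim, "limit"))
})

test_that("steady-state product is monotone in each enzyme", {
  p <- asym_lux()
  ef <- log_grid(1e-2, 1e2, 40)
  expect_true(all(diff(steady_state_product(p, ef, 1)) > 0))
  er <- log_grid(1e-2, 1e2, 40)
  expect_true(all(diff(steady_state_product(p, 1, er)) < 0))
})

test_that("bioluminescence signal follows the steady-state model", {
  expect_equal(bioluminescence_signal(lux_params(), 1, 1), 0.5)
  expect_equal(bioluminescence_signal(lux_params(), 0, 1), 0)
  expect_equal(bioluminescence_signal(lux_params(), 1, 0), 0)
  p <- asym_lux()
  # at fixed E_F/K_deff ratio, doubling E_R doubles the output
  er <- 1.5
  ratio <- 3  # E_F = ratio * K_deff
  i1 <- bioluminescence_signal(p, ratio * k_deff(p, er), er)
  i2 <- bioluminescence_signal(p, ratio * k_deff(p, 2 * er), 2 * er)
  expect_equal(i2, 2 * i1)
  # strictly increasing in E_F at fixed E_R
  ef <- log_grid(1e-2, 1e2, 50)
  expect_true(all(diff(bioluminescence_signal(p, ef, 2)) > 0))
})

test_that("half-plateau forward-enzyme level equals k_deff", {
  # the E_F at which the signal reaches half its E_F -> Inf plateau is the
  # detection threshold; raising E_R raises both threshold and intensity
  p <- asym_lux()
  for (er in c(0.5, 1, 4)) {
    plateau <- bioluminescence_signal(p, 1e12, er)
    kd <- k_deff(p, er)
    expect_equal(bioluminescence_signal(p, kd, er), plateau / 2,
                 tolerance = 1e-9)
  }
  expect_true(bioluminescence_signal(p, 1e12, 4) >
                bioluminescence_signal(p, 1e12, 0.5))
  expect_true(k_deff(p, 4) > k_deff(p, 0.5))
})

test_that("reaction ODE conserves the pool and matches the closed form", {
  p <- asym_lux()
  tg <- seq(0, 40, length.out = 100)
  cases <- list(c(E_F = 2, E_R = 1.5), c(E_F = 0.3, E_R = 3),
                c(E_F = 5, E_R = 0.2))
  for (cs in cases) {
    sim <- simulate_reaction(p, cs[["E_F"]], cs[["E_R"]], P0 = 0, t_grid = tg)
    expect_lt(max(abs(sim$S + sim$P - p$S_T)) / p$S_T, 1e-8)
    oracle <- closed_form_P(p, cs[["E_F"]], cs[["E_R"]], tg)
    rel <- abs(sim$P[-1] - oracle[-1]) / pmax(oracle[-1], 1e-300)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("trajectory reaches the steady state after ~10 relaxation times", {
  p <- asym_lux()
  E_F <- 1.2; E_R <- 0.8
  lambda <- p$K_F * E_F + p$K_R * E_R
  tg <- seq(0, 10 / lambda, length.out = 50)
  sim <- simulate_reaction(p, E_F, E_R, P0 = 0, t_grid = tg)
  Pinf <- steady_state_product(p, E_F, E_R)
  expect_equal(sim$P[nrow(sim)], Pinf, tolerance = 1e-4)
})

test_that("degenerate reaction inputs behave as limits or errors", {
  p <- default_lux()
  sim <- simulate_reaction(p, E_F = 0, E_R = 1, P0 = 0, t_grid = 0:20)
  expect_true(all(sim$P == 0))
  expect_true(all(sim$I == 0))
  expect_error(simulate_reaction(p, 1, 1, P0 = -0.1, t_grid = 0:5), "P0")
  expect_error(simulate_reaction(p, 1, 1, P0 = 2, t_grid = 0:5), "P0")
  expect_error(simulate_reaction(p, 1, 1, P0 = 0, t_grid = c(1, 1)),
               "increasing")
})
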