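test_that("stress response reproduces the delayed rise-and-decay model", {
  katg <- biosensor_params("katG", X0 = 1000)
  # direct arithmetic oracle at t = 20: X0*(1-e^-1)*(e^-1 + beta) + c
  expect_equal(stress_response(katg, c(0, 20))$I[2],
               1000 * (1 - exp(-1)) * (exp(-1) + 0.02) + 2000,
               tolerance = 1e-12)
  expect_equal(stress_response(katg, c(0, 20))$I[2], 2245.187,
               tolerance = 1e-6)
  # delayed activation: flat at baseline before tau_D1
  na <- biosensor_params("recA_NA")
  tc <- stress_response(na, 0:600)
  expect_true(all(tc$I[tc$t_min < 60] == na$c))
  # long-time plateau X0*beta + c
  far <- stress_response(na, c(0, 1e6))
  expect_equal(far$I[2], na$X0 * na$beta + na$c, tolerance = 1e-9)
  # continuity at the delay points (1-min grid, no jumps)
  expect_lt(max(abs(diff(tc$I))), na$X0 * 0.1)
})

test_that("shifting both delays translates the response", {
  p0 <- stress_params(X0 = 500, tau1 = 30, tau_eff = 25, tau_D1 = 10,
                      tau_D2 = 50, beta = 0.1, c = 100)
  delta <- 40
  p1 <- stress_params(X0 = 500, tau1 = 30, tau_eff = 25,
                      tau_D1 = 10 + delta, tau_D2 = 50 + delta,
                      beta = 0.1, c = 100)
  t <- 0:500
  a <- stress_response(p0, t)$I - p0$c
  b <- stress_response(p1, t + delta)$I - p1$c
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("summed responses keep one baseline and add linearly", {
  t <- 0:600
  comps <- recA_components()
  single <- combined_response(comps[1], t)
  expect_equal(single$I, stress_response(comps[[1]], t)$I)
  dup <- combined_response(list(comps[[1]], comps[[1]]), t)
  expect_equal(dup$I - comps[[1]]$c,
               2 * (single$I - comps[[1]]$c), tolerance = 1e-12)
  expect_error(combined_response(list(), t), "at least one")
})

test_that("recA crosstalk by summation yields exactly two maxima", {
  t <- 0:600
  both <- combined_response(recA_components(), t)
  strict_max <- which(diff(sign(diff(both$I))) == -2) + 1
  expect_identical(length(strict_max), 2L)
  # first peak near the fast H2O2 component, second near the NA component
  expect_lt(t[strict_max[1]], 80)
  expect_gt(t[strict_max[2]], 90)
  expect_identical(as.integer(count_peaks(both)), 2L)
})

test_that("TetR course is the delayed, normalized AHL proxy", {
  katg <- biosensor_params("katG")
  t <- 0:600
  ip0 <- iffl_params(tau_delay = 0)
  tetr0 <- tetr_course(katg, ip0, t)
  ahl <- stress_response(katg, t)$I - katg$c
  expect_equal(tetr0$I, ahl / max(ahl), tolerance = 1e-12)
  ip60 <- iffl_params(tau_delay = 60)
  tetr60 <- tetr_course(katg, ip60, t)
  expect_equal(t[which.max(tetr60$I)], t[which.max(tetr0$I)] + 60)
  expect_true(all(tetr60$I[t < 60] == 0))
  # silent sender
  silent <- stress_params(X0 = 0, tau1 = 20, tau_eff = 20)
  expect_true(all(tetr_course(silent, ip60, t)$I == 0))
})

test_that("P_tetO repression follows the TetR Hill curve", {
  expect_equal(ptet_activity(0), 1)
  expect_equal(ptet_activity(0.2), 0.5)
  expect_equal(ptet_activity(0.4), 0.2)
  expect_error(ptet_activity(-0.1), ">= 0")
})

test_that("IFFL peak count equals the number of chemicals present", {
  expect_identical(as.integer(count_peaks(iffl_simulate(character(0),
                                                        c_basal = 5))), 0L)
  expect_identical(as.integer(count_peaks(iffl_simulate("NA"))), 1L)
  expect_identical(as.integer(count_peaks(iffl_simulate("H2O2"))), 1L)
  both <- iffl_simulate(c("NA", "H2O2"))
  k <- count_peaks(both)
  expect_identical(as.integer(k), 2L)
  # two peaks separated by a repression trough
  pt <- attr(k, "peak_times")
  i1 <- which(both$t_min == pt[1]); i2 <- which(both$t_min == pt[2])
  trough <- min(both$I[i1:i2])
  expect_lt(trough, 0.5 * min(both$I[i1], both$I[i2]))
})

test_that("empty dose set gives a flat basal trace", {
  tc <- iffl_simulate(character(0), c_basal = 42)
  expect_true(all(tc$I == 42))
  expect_error(iffl_simulate("arsenic"), "subset")
})

test_that("receiver implements NIMPLY: ON only for stress without AHL", {
  tt <- receiver_truth_table()
  expect_gt(tt$I10, 5 * max(tt$I00, tt$I01, tt$I11))
  # stress off -> leak-level output regardless of AHL
  expect_lt(tt$I00 / tt$I10, 0.1)
  # saturating AHL represses the stressed state to near the leak
  expect_lt(tt$I11, 2 * tt$I00 + 0.05 * tt$I10)
})

test_that("peak counting respects prominence", {
  t <- 0:300
  mono <- time_course(t, 1 + t / 300)
  expect_identical(as.integer(count_peaks(mono)), 0L)
  bump <- time_course(t, exp(-(t - 150)^2 / 400))
  expect_identical(as.integer(count_peaks(bump)), 1L)
  two <- time_course(t, exp(-(t - 80)^2 / 300) +
                       0.8 * exp(-(t - 220)^2 / 300))
  k <- count_peaks(two)
  expect_identical(as.integer(k), 2L)
  expect_equal(attr(k, "peak_times"), c(80, 220))
  # a tiny ripple is not a prominent peak
  ripple <- time_course(t, exp(-(t - 150)^2 / 400) +
                          0.01 * sin(t / 3))
  expect_identical(as.integer(count_peaks(ripple)), 1L)
  expect_error(count_peaks(time_course(0:1, c(1, 2))), "3 samples")
})
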