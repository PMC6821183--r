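test_that("promoter activity has the Hill form with basal leak", {
  p <- promoter_params(vmax = 3, K = 5, n = 2, basal = 0)
  expect_equal(promoter_activity(p, 0), 0)
  expect_equal(promoter_activity(p, 5), 1.5)
  expect_equal(promoter_activity(p, 1e9), 3, tolerance = 1e-6)
  pb <- promoter_params(vmax = 2, K = 1, n = 1, basal = 0.02)
  expect_equal(promoter_activity(pb, 0), 2 * 0.02)
  expect_error(promoter_activity(p, -1), ">= 0")
  grid <- log_grid(1e-3, 1e3, 50)
  expect_true(all(diff(promoter_activity(pb, grid)) > 0))
})

test_that("soft minimum is sandwiched between min/2 and min", {
  expect_equal(soft_min(1, 1), 0.5)
  expect_equal(soft_min(0, 7), 0)
  expect_equal(soft_min(3, 6), 2)
  expect_equal(soft_min(0, 0), 0)
  set.seed(11)
  a <- 10^runif(300, -3, 3); b <- 10^runif(300, -3, 3)
  s <- soft_min(a, b)
  m <- pmin(a, b)
  expect_true(all(s <= m))
  expect_true(all(s >= m / 2))
})

test_that("wild-type operon response is a bounded power law", {
  x <- log_grid(1e-3, 1e3, 200)
  dr <- wildtype_operon_response(x)
  expect_true(all(diff(dr$output) > 0))
  sl <- local_loglog_slope(dr)
  expect_true(all(sl > 1 & sl < 2))
  # analytic local exponent: 1 + 1/(1 + gamma x), gamma = K_F sF/(K_R sR)
  inner <- x[-c(1, length(x))]
  expect_equal(sl, 1 + 1 / (1 + inner), tolerance = 1e-3)
  expect_gt(sl[1], 1.99)          # -> 2 as x -> 0
  expect_lt(sl[length(sl)], 1.01) # -> 1 as x -> Inf
})

test_that("wild-type slope formula holds for asymmetric scales", {
  p <- asym_lux()
  sF <- 2.5; sR <- 0.4
  gamma <- p$K_F * sF / (p$K_R * sR)
  x <- log_grid(1e-4, 1e4, 150)
  dr <- wildtype_operon_response(x, p, scale_F = sF, scale_R = sR)
  sl <- local_loglog_slope(dr)
  inner <- x[-c(1, length(x))]
  expect_equal(sl, 1 + 1 / (1 + gamma * inner), tolerance = 1e-3)
})

test_that("local log-log slope recovers exact power laws", {
  x <- log_grid(0.1, 100, 30)
  dr <- dose_response(x, 2 * x^1.45)
  expect_equal(local_loglog_slope(dr), rep(1.45, 28))
  flat <- dose_response(x, rep(3, 30))
  expect_equal(local_loglog_slope(flat), rep(0, 28))
  expect_error(local_loglog_slope(dose_response(x, c(-1, rep(1, 29)))),
               "positive")
})

test_that("MIN gate output is bounded by the smaller promoter activity", {
  p_arab <- promoter_params(vmax = 2, K = 1, basal = 0.01)
  p_ahl <- promoter_params(vmax = 2, K = 10, basal = 0.01)
  # both off: soft_min of the basal levels
  expect_equal(min_gate_output(0, 0, p_arab, p_ahl),
               soft_min(0.02, 0.02))
  # symmetric promoters at saturation: h/2
  h <- promoter_activity(p_arab, 1e9)
  expect_equal(min_gate_output(1e9, 1e9, p_arab, promoter_params(
    vmax = 2, K = 1, basal = 0.01)), h / 2, tolerance = 1e-6)
  set.seed(3)
  for (i in 1:20) {
    a <- 10^runif(1, -2, 3); b <- 10^runif(1, -2, 3)
    out <- min_gate_output(a, b, p_arab, p_ahl)
    expect_lte(out, min(promoter_activity(p_arab, a),
                        promoter_activity(p_ahl, b)))
  }
})

test_that("protein-protein gate is the bilinear product over K_AB", {
  p <- promoter_params(vmax = 1, K = 1, basal = 0)
  expect_equal(pp_gate_output(0, 10, p, p), 0)
  h <- promoter_activity(p, 1e9)
  expect_equal(pp_gate_output(1e9, 1e9, p, p, pp_gate_params(1)), h^2,
               tolerance = 1e-6)
  # scaling both activities by s scales the output by s^2
  p2 <- promoter_params(vmax = 3, K = 1, basal = 0)
  expect_equal(pp_gate_output(5, 5, p2, p2), 9 * pp_gate_output(5, 5, p, p))
})

test_that("output dynamic range is the worst-case ON/OFF separation", {
  expect_equal(odr(gate_truth_table(1, 1, 1, 1)), 0)
  expect_equal(odr(gate_truth_table(1, 1, 1, 10)), 1)
  expect_equal(odr(gate_truth_table(1, 1, 50, 100)), log10(2))
  expect_error(gate_truth_table(0, 1, 1, 1), "> 0")
  # invariance under global intensity rescaling
  set.seed(5)
  for (i in 1:20) {
    v <- 10^runif(4, -1, 3)
    s <- 10^runif(1, -2, 2)
    t1 <- gate_truth_table(v[1], v[2], v[3], v[4])
    t2 <- gate_truth_table(s * v[1], s * v[2], s * v[3], s * v[4])
    expect_equal(odr(t1), odr(t2))
  }
})

test_that("detection threshold is the half-span input", {
  x <- log_grid(1e-2, 1e5, 80)
  hill <- dose_response(x, x / (x + 30))
  expect_equal(detection_threshold(hill), 30, tolerance = 0.02)
  # reparameterization: inputs scaled by 10 scale the threshold by 10
  hill10 <- dose_response(10 * x, x / (x + 30))
  expect_equal(detection_threshold(hill10), 10 * detection_threshold(hill),
               tolerance = 1e-6)
  expect_error(detection_threshold(dose_response(x, rep(1, 80))),
               "undefined")
  expect_error(detection_threshold(dose_response(x, rev(x / (x + 30)))),
               "undefined")
})

test_that("comparator threshold rises with AHL in both designs", {
  arab <- log_grid(1e-3, 1e3, 120)
  for (d in c("luxCDE-luxAB", "luxA-luxC")) {
    curves <- lapply(c(0.1, 0.3, 1, 3, 10), function(a)
      comparator_transfer(arab, a, d))
    thr <- threshold_series(curves)
    expect_true(all(diff(thr$threshold) > 0))
    # at saturating Arabinose the plateau is proportional-to-increasing E_R
    plateaus <- vapply(curves, function(cv) max(cv$output), numeric(1))
    expect_true(all(diff(plateaus) > 0))
  }
})

test_that("luxA-luxC ON/OFF fold change is AHL-independent", {
  # in the design's operating regime the forward drive (luxA on a medium
  # plasmid with weak constitutive LuxB) stays below the reverse capacity
  # (luxCDE on a high-copy plasmid) for every AHL level; the signal is then
  # proportional to K_F*E_F at both plateau and leak, and the fixed
  # fractional basal leak cancels, leaving fold ~ 1/basal at every AHL
  arab <- log_grid(1e-4, 1e4, 150)
  p_arab <- promoter_params(vmax = 1, K = 1, basal = 0.02)
  p_ahl <- promoter_params(vmax = 20, K = 1, basal = 0.02)
  folds <- vapply(c(0.1, 1, 10), function(a) {
    cv <- comparator_transfer(arab, a, "luxA-luxC", p_arab, p_ahl,
                              luxB_const = 0.1)
    max(cv$output) / min(cv$output)
  }, numeric(1))
  expect_lt(max(folds) / min(folds), 1.05)
  expect_equal(folds, rep(1 / 0.02, 3), tolerance = 0.1)
})
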