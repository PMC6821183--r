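# Temporal model of stress-responsive promoters, crosstalk-by-summation,
# the sender/receiver incoherent feedforward loop, NIMPLY logic, and
# peak-count classification.

rise_decay <- function(p, t) {
  rise <- ifelse(t < p$tau_D1, 0, 1 - exp(-(t - p$tau_D1) / p$tau_eff))
  dec <- ifelse(t < p$tau_D2, 1, exp(-(t - p$tau_D2) / p$tau1)) + p$beta
  p$X0 * rise * dec
}

#' Stress-promoter bioluminescence time course
#'
#' The delayed rise-and-decay model
#' `I(t) = X0 * rise(t) * decay(t) + c`, where
#' `rise(t) = 1 - exp(-(t - tau_D1)/tau_eff)` (0 before the activation delay
#' `tau_D1`) and `decay(t) = exp(-(t - tau_D2)/tau1) + beta` with the
#' exponential clamped to 1 before the consumption delay `tau_D2`. The
#' non-degradable chemical fraction `beta` leaves a persistent plateau
#' `X0*beta + c` as `t -> Inf`. Both clamps make `I` continuous at the delay
#' points and give `I(0) = c` whenever `tau_D1 > 0`.
#'
#' @param p a [stress_params()] object.
#' @param t_grid increasing sample times (min).
#' @return A [time_course()].
#' @export
#' @examples
#' tc <- stress_response(biosensor_params("katG"), 0:240)
stress_response <- function(p, t_grid) {
  stopifnot(inherits(p, "stress_params"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be increasing")
  time_course(t_grid, rise_decay(p, t_grid) + p$c)
}

#' Summed multi-chemical stress response
#'
#' Crosstalk of a promiscuous promoter (e.g. recA responding to both
#' nalidixic acid and H2O2) modelled as the sum of the per-chemical
#' rise-and-decay components over one shared instrument baseline (the `c`
#' of the first component; baselines are not summed).
#'
#' @param components non-empty list of [stress_params()], one per chemical.
#' @param t_grid increasing sample times (min).
#' @return A [time_course()].
#' @export
combined_response <- function(components, t_grid) {
  if (length(components) < 1) stop("need at least one component")
  lapply(components, function(p) stopifnot(inherits(p, "stress_params")))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be increasing")
  I <- Reduce(`+`, lapply(components, rise_decay, t = t_grid))
  time_course(t_grid, I + components[[1]]$c)
}

#' TetR repressor time course of the sender/receiver loop
#'
#' The sender detects H2O2 through katG and emits AHL; the AHL proxy is the
#' baseline-subtracted katG response normalized to peak `sender_scale`. The
#' receiver expresses TetR proportionally to the delayed AHL level:
#' `TetR(t) = AHL(t - tau_delay)`, 0 before the delay.
#'
#' @param katg_params [stress_params()] of the katG (sender) response.
#' @param ip an [iffl_params()] object.
#' @param t_grid increasing sample times (min).
#' @return A [time_course()] of the TetR level (AHL-proxy units).
#' @export
tetr_course <- function(katg_params, ip = iffl_params(), t_grid) {
  stopifnot(inherits(katg_params, "stress_params"),
            inherits(ip, "iffl_params"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be increasing")
  ahl <- rise_decay(katg_params, t_grid)
  pk <- max(ahl)
  if (pk == 0) return(time_course(t_grid, rep(0, length(t_grid))))
  ahl <- ahl / pk * ip$sender_scale
  shifted <- t_grid - ip$tau_delay
  tetr <- approx(x = t_grid, y = ahl, xout = shifted,
                 yleft = 0, yright = ahl[length(ahl)])$y
  tetr[shifted < t_grid[1]] <- 0
  time_course(t_grid, tetr)
}

#' P_tetO promoter activity under TetR repression
#'
#' The repression transfer function of the receiver's luciferase promoter:
#' `1 / (1 + (TetR/K_tetr)^h_tetr)`, with defaults `K_tetr = 0.2` and
#' `h_tetr = 2`.
#'
#' @param tetr TetR level (>= 0, vectorized, AHL-proxy units).
#' @param ip an [iffl_params()] object supplying `K_tetr`, `h_tetr`.
#' @return Expression fraction in `(0, 1]`.
#' @export
#' @examples
#' ptet_activity(0.2)  # 0.5
ptet_activity <- function(tetr, ip = iffl_params()) {
  if (any(!is.finite(tetr)) || any(tetr < 0)) stop("TetR level must be >= 0")
  1 / (1 + (tetr / ip$K_tetr)^ip$h_tetr)
}

#' Simulate the crosstalk-compensating (IFFL) biosensor
#'
#' The incoherent feedforward loop: recA activates the reverse enzymes
#' (luxCDE) in response to every chemical present, while katG — responding
#' to H2O2 only — drives, via the delayed TetR repressor, a transient
#' shutdown of the forward enzymes (luxAB under P_tetO). The output is the
#' steady-state signal model evaluated along the enzyme time courses, so
#' each chemical contributes one separated bioluminescent peak.
#'
#' `E_R(t)` is the baseline-subtracted sum of the recA components of the
#' chemicals present, scaled by `er_scale`; `E_F(t)` is the P_tetO activity
#' (identically 1 when H2O2 is absent, since katG stays silent and TetR = 0).
#'
#' @param doses character subset of `c("NA", "H2O2")`; chemicals present.
#' @param recA_params named list with elements `NA.` and `H2O2`
#'   ([stress_params()]), the recA response components per chemical.
#' @param katg_params [stress_params()] of the katG sender response.
#' @param ip an [iffl_params()] object.
#' @param params a [lux_params()] object.
#' @param t_grid increasing sample times (min); default 1-min grid 0..600.
#' @param er_scale scaling from recA amplitude units to reverse-enzyme
#'   units. The default 1e-5 places the unrepressed forward drive (1) above
#'   the peak reverse drive (~0.5 at the default amplitudes) and the
#'   repressed forward drive (~0.04) below it — the regime in which the
#'   reverse pathway is rate-limiting and TetR gates the recA signal.
#' @param c_basal additive basal bioluminescence of the output (a.u.).
#' @return A [time_course()].
#' @export
iffl_simulate <- function(doses,
                          recA_params = list("NA." = biosensor_params("recA_NA"),
                                             H2O2 = biosensor_params("recA_H2O2")),
                          katg_params = biosensor_params("katG"),
                          ip = iffl_params(),
                          params = lux_params(),
                          t_grid = 0:600,
                          er_scale = 1e-5,
                          c_basal = 0) {
  doses <- as.character(doses)
  if (!all(doses %in% c("NA", "H2O2")))
    stop("doses must be a subset of c(\"NA\", \"H2O2\")")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be increasing")
  nt <- length(t_grid)

  key <- ifelse(doses == "NA", "NA.", "H2O2")
  E_R <- if (length(doses) == 0) rep(0, nt) else {
    comps <- recA_params[key]
    er_scale * Reduce(`+`, lapply(comps, rise_decay, t = t_grid))
  }

  E_F <- if ("H2O2" %in% doses) {
    tetr <- tetr_course(katg_params, ip, t_grid)$I
    ptet_activity(tetr, ip)
  } else {
    rep(1, nt)  # katG silent, TetR == 0, P_tetO fully active
  }

  I <- bioluminescence_signal(params, E_F = E_F, E_R = E_R) + c_basal
  time_course(t_grid, I)
}

#' Steady-state receiver output at one logic corner
#'
#' The receiver circuit with constant inputs: the stress input sets the
#' reverse-enzyme drive (recA-controlled luxCDE, basal leak when off) and an
#' externally supplied AHL level sets TetR, repressing the forward enzymes.
#' High output requires stress AND NOT AHL — a NIMPLY gate.
#'
#' @param stress_on logical; whether the stress chemical is present.
#' @param ahl external AHL level in normalized TetR-drive units
#'   (1 = saturating).
#' @param p_stress [promoter_params()] of the recA drive (its `basal` sets
#'   the OFF-state leak).
#' @param ip an [iffl_params()] object.
#' @param params a [lux_params()] object.
#' @return Signal intensity (a.u., scalar).
#' @export
receiver_output <- function(stress_on, ahl,
                            p_stress = promoter_params(basal = 0.02),
                            ip = iffl_params(),
                            params = lux_params()) {
  stopifnot(is.logical(stress_on), length(stress_on) == 1)
  if (!is.finite(ahl) || ahl < 0) stop("ahl must be >= 0")
  E_R <- if (stress_on) p_stress$vmax else p_stress$vmax * p_stress$basal
  E_F <- ptet_activity(ahl * ip$sender_scale, ip)
  bioluminescence_signal(params, E_F = E_F, E_R = E_R)
}

#' Receiver NIMPLY truth table
#'
#' Evaluates [receiver_output()] at the four (stress, AHL) corners.
#' `I10` (stress on, AHL off) is the ON state.
#'
#' @inheritParams receiver_output
#' @return A [gate_truth_table()] with first index = stress, second = AHL.
#' @export
receiver_truth_table <- function(p_stress = promoter_params(basal = 0.02),
                                 ip = iffl_params(),
                                 params = lux_params()) {
  gate_truth_table(
    I00 = receiver_output(FALSE, 0, p_stress, ip, params),
    I01 = receiver_output(FALSE, 1, p_stress, ip, params),
    I10 = receiver_output(TRUE, 0, p_stress, ip, params),
    I11 = receiver_output(TRUE, 1, p_stress, ip, params))
}

find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) == -2) + 1  # strict local maxima
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- y[i]
    # walk outwards to the nearest sample at least as high; the key col is
    # the lowest point passed on the way (topographic prominence)
    lo_l <- {
      j <- i - 1; m <- h
      while (j >= 1 && y[j] < h) { m <- min(m, y[j]); j <- j - 1 }
      m
    }
    lo_r <- {
      j <- i + 1; m <- h
      while (j <= n && y[j] < h) { m <- min(m, y[j]); j <- j + 1 }
      m
    }
    h - max(lo_l, lo_r)
  }, numeric(1))
  cand[prom > min_prominence]
}

#' Count prominent peaks in a time course
#'
#' Strict local maxima whose topographic prominence exceeds
#' `min_prominence_frac` times the trace's global range. Prominence of a
#' peak is its height above the higher of the two lowest points separating
#' it from equal-or-higher terrain on either side.
#'
#' @param tc a [time_course()] (or data frame with columns `t_min`, `I`)
#'   with at least 3 samples.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   global max - min (default 0.05).
#' @return Integer peak count, with attribute `peak_times` (minutes).
#' @export
count_peaks <- function(tc, min_prominence_frac = 0.05) {
  if (!all(c("t_min", "I") %in% names(tc)))
    stop("tc must have columns t_min and I")
  y <- tc$I
  if (length(y) < 3) stop("need at least 3 samples")
  rng <- max(y) - min(y)
  idx <- find_peaks(y, min_prominence = min_prominence_frac * rng)
  structure(length(idx), peak_times = tc$t_min[idx])
}
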