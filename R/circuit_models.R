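# Promoter layer and split-operon circuit topologies: wild-type operon
# reporter, MIN fuzzy lattice (AND), protein-protein gate, comparator, and
# the output-dynamic-range statistic.

#' Hill-type promoter activity
#'
#' `vmax * (basal + (1 - basal) * c^n / (c^n + K^n))`. With `n = 1` this is
#' the Michaelis-Menten form; `basal` is the leaky (uninduced) fraction.
#'
#' @param p a [promoter_params()] object.
#' @param inducer inducer concentration (>= 0, vectorized).
#' @return Expression level(s), monotone increasing in the inducer.
#' @export
promoter_activity <- function(p, inducer) {
  stopifnot(inherits(p, "promoter_params"))
  if (any(!is.finite(inducer)) || any(inducer < 0))
    stop("inducer concentration must be >= 0")
  cn <- inducer^p$n
  p$vmax * (p$basal + (1 - p$basal) * cn / (cn + p$K^p$n))
}

#' Wild-type operon transfer function
#'
#' All five lux genes share one promoter, so their levels track a common
#' drive `x`. Luciferase is the LuxA.LuxB heterodimer, hence
#' `E_F = scale_F * x^2`; the reverse enzymes are monomeric, hence
#' `E_R = scale_R * x`. The resulting signal is a power law `I ~ x^n` with
#' local exponent `n = 1 + 1/(1 + gamma*x)` (gamma = K_F*scale_F/(K_R*scale_R)),
#' strictly between 1 and 2.
#'
#' @param x_grid strictly increasing positive drive levels.
#' @param params a [lux_params()] object.
#' @param scale_F,scale_R proportionality of `E_F = scale_F * x^2` and
#'   `E_R = scale_R * x`.
#' @return A [dose_response()] with the drive as input.
#' @export
wildtype_operon_response <- function(x_grid, params = lux_params(),
                                     scale_F = 1, scale_R = 1) {
  if (any(!is.finite(x_grid)) || any(x_grid <= 0))
    stop("x_grid must be strictly positive")
  I <- bioluminescence_signal(params, E_F = scale_F * x_grid^2,
                              E_R = scale_R * x_grid)
  dose_response(x_grid, I,
                metadata = list(model = "wildtype_operon",
                                scale_F = scale_F, scale_R = scale_R))
}

#' Local log-log slope of a dose-response curve
#'
#' Central differences of `log(output)` against `log(input)`: the local
#' power-law exponent at each interior grid point.
#'
#' @param dr a [dose_response()] with strictly positive inputs and outputs.
#' @return Numeric vector of length `nrow(dr) - 2`.
#' @export
local_loglog_slope <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  x <- dr$input; y <- dr$output
  if (any(x <= 0) || any(y <= 0))
    stop("log-log slope requires strictly positive inputs and outputs")
  if (length(x) < 3) stop("need at least 3 points")
  diff(log(y), lag = 2) / diff(log(x), lag = 2)
}

#' Soft minimum
#'
#' The conjunction operator `a*b/(a + b)`, bounded between `min(a, b)/2` and
#' `min(a, b)`; the continuous (fuzzy) AND realized by the split lux operon.
#'
#' @param a,b non-negative levels (vectorized).
#' @return `a*b/(a+b)`, with 0 where both are 0.
#' @export
#' @examples
#' soft_min(3, 6)  # 2
soft_min <- function(a, b) {
  if (any(!is.finite(a)) || any(a < 0) || any(!is.finite(b)) || any(b < 0))
    stop("soft_min requires non-negative arguments")
  s <- a + b
  ifelse(s == 0, 0, a * b / s)
}

#' MIN fuzzy-lattice gate output
#'
#' The split-operon AND gate: Arabinose drives the forward enzymes (luxAB),
#' AHL drives the reverse enzymes (luxCDE), and the cassette output is the
#' steady-state signal — a soft minimum of the two drives scaled by the
#' reaction constants.
#'
#' @param arab,ahl inducer concentrations (>= 0, vectorized).
#' @param p_arab,p_ahl [promoter_params()] for the Arabinose- and
#'   AHL-inducible promoters.
#' @param params a [lux_params()] object supplying the Eq-of-state constants.
#' @return Signal intensity (a.u.).
#' @export
min_gate_output <- function(arab, ahl, p_arab, p_ahl, params = lux_params()) {
  E_F <- promoter_activity(p_arab, arab)
  E_R <- promoter_activity(p_ahl, ahl)
  bioluminescence_signal(params, E_F = E_F, E_R = E_R)
}

#' Protein-protein interaction AND gate output
#'
#' The split-luxAB gate: LuxA and LuxB are driven by the two promoters and
#' active luciferase forms by heterodimerization, `Out = LuxA*LuxB/K_AB` —
#' a product, not a minimum.
#'
#' @inheritParams min_gate_output
#' @param gp a [pp_gate_params()] object.
#' @return Gate output (a.u.).
#' @export
pp_gate_output <- function(arab, ahl, p_arab, p_ahl, gp = pp_gate_params()) {
  la <- promoter_activity(p_arab, arab)
  lb <- promoter_activity(p_ahl, ahl)
  la * lb / gp$K_AB
}

#' Evaluate a two-input gate at the four logic corners
#'
#' Logic "0" is zero added inducer (basal leak only); logic "1" is
#' `hi_factor` times the promoter's half-activation constant, i.e.
#' effectively saturating induction.
#'
#' @param gate_fun function of `(arab, ahl)` returning an intensity.
#' @param p_arab,p_ahl the two [promoter_params()] (used to place the "1"
#'   corners at `hi_factor * K`).
#' @param hi_factor multiple of `K` defining the induced state (default 100).
#' @return A [gate_truth_table()].
#' @export
evaluate_truth_table <- function(gate_fun, p_arab, p_ahl, hi_factor = 100) {
  lo_a <- 0; hi_a <- hi_factor * p_arab$K
  lo_b <- 0; hi_b <- hi_factor * p_ahl$K
  gate_truth_table(I00 = gate_fun(lo_a, lo_b),
                   I01 = gate_fun(lo_a, hi_b),
                   I10 = gate_fun(hi_a, lo_b),
                   I11 = gate_fun(hi_a, hi_b))
}

#' Output dynamic range of a logic gate
#'
#' The worst-case ON/OFF separation in orders of magnitude:
#' `min{log10(I11/I00), log10(I11/I01), log10(I11/I10)}`.
#'
#' @param t a [gate_truth_table()].
#' @return ODR in orders of magnitude (can be negative for a broken gate).
#' @export
odr <- function(t) {
  stopifnot(inherits(t, "gate_truth_table"))
  min(log10(t$I11 / t$I00), log10(t$I11 / t$I01), log10(t$I11 / t$I10))
}

#' Comparator transfer function
#'
#' Arabinose-to-bioluminescence transfer function at a fixed AHL level, for
#' the two split-operon comparator designs:
#'
#' * `"luxCDE-luxAB"`: P_BAD drives luxAB (so `E_F` is the square of the
#'   P_BAD activity, LuxA.LuxB dimerization) and P_lux drives all three
#'   reverse genes (`E_R` proportional to P_lux activity).
#' * `"luxA-luxC"`: only luxA and luxC are inducible; LuxB is constitutive,
#'   so `E_F = P_BAD activity * luxB_const / K_AB`, and with LuxD/LuxE
#'   constitutive and in excess the reverse rate is set by LuxC alone,
#'   `E_R` proportional to the P_lux activity.
#'
#' Raising AHL raises `E_R`, hence the detection threshold `K_deff`, in both
#' designs; in the second the ON/OFF fold change is AHL-independent.
#'
#' @param arab_grid strictly increasing Arabinose concentrations.
#' @param ahl fixed AHL concentration.
#' @param design `"luxCDE-luxAB"` or `"luxA-luxC"`.
#' @param p_arab,p_ahl [promoter_params()] for P_BAD and P_lux.
#' @param params a [lux_params()] object.
#' @param luxB_const constitutive LuxB level (design `"luxA-luxC"`).
#' @param gp [pp_gate_params()] with the LuxA-LuxB dissociation constant.
#' @return A [dose_response()] with metadata recording `ahl` and `design`.
#' @export
comparator_transfer <- function(arab_grid, ahl,
                                design = c("luxCDE-luxAB", "luxA-luxC"),
                                p_arab = promoter_params(basal = 0.02),
                                p_ahl = promoter_params(basal = 0.02),
                                params = lux_params(),
                                luxB_const = 1, gp = pp_gate_params()) {
  design <- match.arg(design)
  act_arab <- promoter_activity(p_arab, arab_grid)
  act_ahl <- promoter_activity(p_ahl, ahl)
  if (design == "luxCDE-luxAB") {
    E_F <- act_arab^2
    E_R <- act_ahl
  } else {
    E_F <- act_arab * luxB_const / gp$K_AB
    E_R <- act_ahl
  }
  I <- bioluminescence_signal(params, E_F = E_F, E_R = E_R)
  dose_response(arab_grid, I, metadata = list(ahl = ahl, design = design))
}

#' Detection threshold of a monotone dose-response curve
#'
#' The input value at which the output reaches half of its span,
#' `min + (max - min)/2`, located by linear interpolation in log-input
#' space (dose grids are log-spaced). The curve must be monotone
#' non-decreasing and span at least a 2-fold output range; otherwise the
#' threshold is undefined and an error is raised.
#'
#' @param dr a [dose_response()] with strictly positive inputs.
#' @return Threshold concentration (scalar).
#' @export
detection_threshold <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  x <- dr$input; y <- dr$output
  if (any(x <= 0)) stop("inputs must be strictly positive")
  if (length(x) < 2) stop("need at least 2 points")
  tol <- 1e-9 * max(abs(y))
  if (any(diff(y) < -tol))
    stop("threshold undefined: response is not monotone non-decreasing")
  if (max(y) < 2 * min(y))
    stop("threshold undefined: output span is below 2-fold")
  target <- min(y) + (max(y) - min(y)) / 2
  exp(approx(x = y, y = log(x), xout = target, ties = "ordered")$y)
}
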