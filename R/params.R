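#' Rate and pool constants of the lux forward/reverse reaction
#'
#' Bundles the constants of the two-enzyme metabolic model of the luxCDABE
#' cassette: the luciferase-catalysed forward reaction (aldehyde -> fatty
#' acid, light-emitting) and the reductase/transferase/synthetase-catalysed
#' reverse reaction (fatty acid -> aldehyde).
#'
#' Concentrations are in arbitrary consistent units and time is in minutes.
#' The overall proportionality constant of the signal model is `I_scale`
#' (default 1), so reported intensities are in arbitrary units.
#'
#' @param K_F forward rate constant (per concentration per minute).
#' @param K_R reverse rate constant (per concentration per minute).
#' @param K_d dissociation constant of the reduced cofactor binding the
#'   reverse enzymes (concentration).
#' @param S_T total substrate + product pool (concentration).
#' @param Y_T initial reduced-cofactor pool (concentration).
#' @param I_scale global proportionality constant of the signal model.
#' @return An object of class `lux_params`.
#' @export
#' @examples
#' p <- lux_params()
#' k_deff(p, E_R = 2)
lux_params <- function(K_F = 1, K_R = 1, K_d = 1, S_T = 1, Y_T = 1,
                       I_scale = 1) {
  vals <- c(K_F = K_F, K_R = K_R, K_d = K_d, S_T = S_T, Y_T = Y_T,
            I_scale = I_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all lux reaction parameters must be finite and strictly positive")
  structure(as.list(vals), class = "lux_params")
}

#' Hill-type promoter activity parameters
#'
#' @param vmax maximal expression level (expression units, > 0).
#' @param K half-activation inducer concentration (> 0).
#' @param n Hill coefficient (n = 1 gives the Michaelis-Menten form).
#' @param basal leaky expression as a fraction of `vmax`, in `[0, 1)`.
#' @return An object of class `promoter_params`.
#' @export
promoter_params <- function(vmax = 1, K = 1, n = 1, basal = 0) {
  if (!is.finite(vmax) || vmax <= 0) stop("vmax must be > 0")
  if (!is.finite(K) || K <= 0) stop("K must be > 0")
  if (!is.finite(n) || n <= 0) stop("n must be > 0")
  if (!is.finite(basal) || basal < 0 || basal >= 1)
    stop("basal must be in [0, 1)")
  structure(list(vmax = vmax, K = K, n = n, basal = basal),
            class = "promoter_params")
}

#' Protein-protein AND gate parameter
#'
#' The LuxA-LuxB heterodimerization constant of the split-luxAB gate, where
#' active luciferase forms as LuxA.LuxB / K_AB.
#'
#' @param K_AB binding dissociation constant (expression units, > 0).
#' @return An object of class `pp_gate_params`.
#' @export
pp_gate_params <- function(K_AB = 1) {
  if (!is.finite(K_AB) || K_AB <= 0) stop("K_AB must be > 0")
  structure(list(K_AB = K_AB), class = "pp_gate_params")
}

#' Stress-promoter response parameters
#'
#' Parameters of the delayed rise-and-decay model of a stress-responsive
#' promoter (recA, katG): the reporter level rises with an effective protein
#' half-life constant after an activation delay, while the inducing chemical
#' is consumed exponentially after a consumption delay, leaving a
#' non-degradable fraction `beta`.
#'
#' @param X0 response amplitude (a.u.).
#' @param tau1 chemical consumption time constant (min, > 0).
#' @param tau_eff effective protein half-life constant (min, > 0).
#' @param tau_D1 activation delay (min, >= 0).
#' @param tau_D2 consumption delay (min, >= 0).
#' @param beta non-degradable basal chemical fraction (>= 0).
#' @param c basal bioluminescence (a.u., >= 0).
#' @return An object of class `stress_params`.
#' @export
#' @examples
#' stress_params(X0 = 1000, tau1 = 20, tau_eff = 20, beta = 0.02, c = 2000)
stress_params <- function(X0 = 1000, tau1 = 20, tau_eff = 20,
                          tau_D1 = 0, tau_D2 = 0, beta = 0, c = 0) {
  if (!is.finite(X0) || X0 < 0) stop("X0 must be >= 0")
  if (!is.finite(tau1) || tau1 <= 0) stop("tau1 must be > 0")
  if (!is.finite(tau_eff) || tau_eff <= 0) stop("tau_eff must be > 0")
  if (!is.finite(tau_D1) || tau_D1 < 0) stop("tau_D1 must be >= 0")
  if (!is.finite(tau_D2) || tau_D2 < 0) stop("tau_D2 must be >= 0")
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0")
  if (!is.finite(c) || c < 0) stop("c must be >= 0")
  structure(list(X0 = X0, tau1 = tau1, tau_eff = tau_eff, tau_D1 = tau_D1,
                 tau_D2 = tau_D2, beta = beta, c = c),
            class = "stress_params")
}

#' Fitted stress-promoter parameter sets for the model biosensors
#'
#' Returns the rise-and-decay parameter sets used for the katG oxidative
#' stress response (to H2O2) and the two components of the recA DNA-damage
#' response (to nalidixic acid and to H2O2). Amplitudes `X0` are taken equal
#' across components; baselines are in raw instrument units. The default
#' amplitude corresponds to a roughly 10-fold peak induction over the recA
#' baseline, typical of stress-responsive lux fusions.
#'
#' @param which one of `"katG"`, `"recA_NA"`, `"recA_H2O2"`.
#' @param X0 response amplitude assigned to the component (a.u.).
#' @return A [stress_params()] object.
#' @export
biosensor_params <- function(which = c("katG", "recA_NA", "recA_H2O2"),
                             X0 = 50000) {
  which <- match.arg(which)
  switch(which,
    katG = stress_params(X0 = X0, tau1 = 20, tau_eff = 20,
                         tau_D1 = 0, tau_D2 = 0, beta = 0.02, c = 2000),
    recA_NA = stress_params(X0 = X0, tau1 = 60, tau_eff = 25,
                            tau_D1 = 60, tau_D2 = 100, beta = 0.10, c = 9000),
    recA_H2O2 = stress_params(X0 = X0, tau1 = 30, tau_eff = 30,
                              tau_D1 = 0, tau_D2 = 40, beta = 0.25, c = 9000))
}

#' Incoherent feedforward loop (sender/receiver) parameters
#'
#' @param tau_delay sender-to-repressor delay (min, >= 0). The TetR level
#'   follows the AHL proxy shifted by this delay.
#' @param K_tetr TetR level at half repression of the P_tetO promoter
#'   (dimensionless, in AHL-proxy units).
#' @param h_tetr repression Hill coefficient (>= 1).
#' @param sender_scale normalization of the AHL proxy; the proxy peak equals
#'   this value.
#' @return An object of class `iffl_params`.
#' @export
iffl_params <- function(tau_delay = 60, K_tetr = 0.2, h_tetr = 2,
                        sender_scale = 1) {
  if (!is.finite(tau_delay) || tau_delay < 0) stop("tau_delay must be >= 0")
  if (!is.finite(K_tetr) || K_tetr <= 0) stop("K_tetr must be > 0")
  if (!is.finite(h_tetr) || h_tetr < 1) stop("h_tetr must be >= 1")
  if (!is.finite(sender_scale) || sender_scale <= 0)
    stop("sender_scale must be > 0")
  structure(list(tau_delay = tau_delay, K_tetr = K_tetr, h_tetr = h_tetr,
                 sender_scale = sender_scale),
            class = "iffl_params")
}

#' Dose-response container
#'
#' A data frame with strictly increasing `input` (inducer concentration) and
#' `output` (signal intensity, a.u.), plus free-form metadata recording the
#' fixed co-inputs the curve was measured under.
#'
#' @param inputs strictly increasing inducer concentrations.
#' @param outputs signal intensities, same length as `inputs`.
#' @param metadata named list of fixed co-inputs / provenance.
#' @return A data frame of class `dose_response`.
#' @export
dose_response <- function(inputs, outputs, metadata = list()) {
  if (length(inputs) != length(outputs))
    stop("inputs and outputs must have equal length")
  if (length(inputs) >= 2 && any(diff(inputs) <= 0))
    stop("inputs must be strictly increasing")
  structure(data.frame(input = inputs, output = outputs),
            metadata = metadata,
            class = c("dose_response", "data.frame"))
}

#' Time-course container
#'
#' @param t sample times (min, strictly increasing).
#' @param I signal (a.u.), same length as `t`.
#' @return A data frame of class `time_course` with columns `t_min`, `I`.
#' @export
time_course <- function(t, I) {
  if (length(t) != length(I)) stop("t and I must have equal length")
  if (length(t) >= 2 && any(diff(t) <= 0))
    stop("t must be strictly increasing")
  structure(data.frame(t_min = t, I = I),
            class = c("time_course", "data.frame"))
}

#' Logic-gate truth table
#'
#' Signal intensities at the four logic corners; `Ixy` is the output with the
#' first input at level x and the second at level y. All entries must be
#' strictly positive (basal leak guarantees positivity in the models here).
#'
#' @param I00,I01,I10,I11 corner intensities (a.u., > 0).
#' @return An object of class `gate_truth_table`.
#' @export
gate_truth_table <- function(I00, I01, I10, I11) {
  vals <- c(I00 = I00, I01 = I01, I10 = I10, I11 = I11)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all truth-table intensities must be finite and > 0")
  structure(as.list(vals), class = "gate_truth_table")
}
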