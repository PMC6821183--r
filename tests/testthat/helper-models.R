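# shared fixtures: parameter sets and small generators used across tests

default_lux <- function() lux_params()

asym_lux <- function() lux_params(K_F = 0.7, K_R = 1.3, K_d = 2,
                                  S_T = 2, Y_T = 0.5)

recA_components <- function(X0 = 50000)
  list(biosensor_params("recA_NA", X0 = X0),
       biosensor_params("recA_H2O2", X0 = X0))

# closed-form relaxation of the linear reaction ODE, used as an independent
# oracle for the numeric integrator: P(t) = Pinf * (1 - exp(-lambda t))
closed_form_P <- function(params, E_F, E_R, t) {
  lambda <- params$K_F * E_F + params$K_R * E_R
  f <- params$K_F * E_F
  Pinf <- if (lambda == 0) 0 else params$S_T * f / lambda
  Pinf * (1 - exp(-lambda * t))
}

log_grid <- function(lo, hi, n) 10^seq(log10(lo), log10(hi), length.out = n)
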