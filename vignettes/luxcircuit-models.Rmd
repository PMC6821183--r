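---
title: "Modelling the luxCDABE cassette: kinetics, logic gates, and the crosstalk-compensating biosensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the luxCDABE cassette}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxcircuit)
```

## The system

Bacterial bioluminescence is produced by the five-gene *luxCDABE* operon:
*luxAB* encode luciferase, which oxidizes a long-chain aldehyde to the
corresponding fatty acid and emits light (the *forward* reaction), while
*luxCDE* encode the reductase/transferase/synthetase complex that
regenerates the aldehyde from the fatty acid (the *reverse* reaction).
Because the two directions of the same metabolic cycle can be placed under
independent transcriptional control, the cassette is more than a reporter:
it is a computational element whose transfer function is set by the
interplay of enzyme expression and reaction kinetics. This package
implements the kinetic model of that cycle and the circuit topologies built
on it — an intact-operon reporter, soft-minimum (AND) gates, a comparator
with a programmable detection threshold, and a two-strain incoherent
feedforward loop that converts chemical identity into a bioluminescent
peak count — together with the fitting and peak-classification procedures
used to interpret them.

## The reaction model

With $S$ the aldehyde pool, $P$ the fatty-acid pool ($S + P = S_T$
conserved), and $E_F$, $E_R$ the forward/reverse enzyme levels,

$$\frac{dP}{dt} = K_F E_F S - K_R E_R P .$$

The system is linear, so $P(t)$ relaxes exponentially with rate
$\lambda = K_F E_F + K_R E_R$ to

$$P_\infty = S_T\,\frac{E_F/K_\mathrm{deff}}{1 + E_F/K_\mathrm{deff}},
\qquad K_\mathrm{deff} \equiv \frac{K_R E_R}{K_F} ,$$

a Michaelis–Menten-like saturation in $E_F$ whose half-point
$K_\mathrm{deff}$ acts as a *detection threshold* controlled by the reverse
pathway. Light is proportional to the forward flux through the cofactor
turnover; at steady state

$$I \propto \frac{S_T Y_T K_R}{K_d}\, E_R\,
\frac{E_F/K_\mathrm{deff}}{1 + E_F/K_\mathrm{deff}}
 = \frac{S_T Y_T}{K_d}\,
 \frac{(K_F E_F)(K_R E_R)}{K_F E_F + K_R E_R},$$

the second, symmetric form making explicit that the cassette computes a
**soft minimum** $ab/(a+b)$ of the two drives. Raising $E_R$ therefore
raises *both* the threshold and the saturation intensity — the property the
comparator exploits. `simulate_reaction()` integrates the ODE
(`deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$; accuracy is cheap for a
linear system and the closed form is used as an independent oracle in the
tests), and `steady_state_product()`, `bioluminescence_signal()`,
`k_deff()` evaluate the algebra directly.

**Units and degenerate inputs.** Time is in minutes; concentrations and
expression levels are in arbitrary consistent units; all rate and pool
constants default to 1 and the global proportionality constant `I_scale`
is configurable (absolute parameter values for the cassette are not
available, so the package works throughout in these reduced units — every
claim checked here is a structural one, invariant to the overall scales).
The $E_R = 0$, $E_F > 0$ limit returns the analytic limits ($P = S_T$,
$I = 0$) rather than dividing by zero, and the cofactor pool is assumed
non-depleting ($Y_T \gg Y^*$) with no correction modelled.

## The wild-type operon: a power-law reporter

In the intact operon all five genes track one drive $x$: luciferase is the
LuxA·LuxB heterodimer ($E_F \propto x^2$) while the reverse enzymes are
monomeric ($E_R \propto x$). Substituting into the signal model gives a
local log–log slope

$$n(x) = 1 + \frac{1}{1 + \gamma x}, \qquad
\gamma = \frac{K_F\,\mathrm{scale}_F}{K_R\,\mathrm{scale}_R},$$

strictly inside $(1, 2)$, approaching 2 at low drive and 1 at high drive.
`wildtype_operon_response()` and `local_loglog_slope()` reproduce this on
the package's canonical dose grid — 200 log-spaced points spanning
$10^{-3}$ to $10^{3}$, wide enough to cover both asymptotic regimes:

```{r wildtype}
x <- 10^seq(-3, 3, length.out = 200)
sl <- local_loglog_slope(wildtype_operon_response(x))
range(sl)
```

## Logic gates and the ODR statistic

Splitting the operon so that Arabinose drives *luxAB* and AHL drives
*luxCDE* yields the **MIN fuzzy lattice** (`min_gate_output()`): the output
is the soft minimum of the two promoter activities, sandwiched between
$\min(a,b)/2$ and $\min(a,b)$, and acts as an AND gate when the inputs are
discretized. The alternative **protein–protein gate**
(`pp_gate_output()`) splits *luxA*/*luxB* under the two inducers and forms
luciferase by dimerization, giving a *product* $\mathrm{LuxA}\cdot
\mathrm{LuxB}/K_{AB}$ instead.

Gate quality is summarized by the **output dynamic range**
(`odr()`): the worst-case ON/OFF separation
$\min_k \log_{10}(I_{11}/I_k)$ over the three OFF corners, invariant to
global intensity rescaling. Logic corners are evaluated at zero added
inducer ("0": basal leak only; the default leak is 2% of $v_\max$, a
conventional figure for inducible promoters, since the OFF states are
visibly nonzero but unquantified) and at $100\times K$ ("1": effectively
saturating without requiring infinite inputs). Copy-number effects
(low/medium/high-copy plasmids) are folded into $v_\max$ scale factors
(defaults 1/5/20, configurable) — no quantitative copy numbers are
available. The measured ODR values of the physical gates derive from
plate-reader data that exist only as figures, so the package asserts the
model-level gate properties and does not attempt to reproduce those
numbers.

## The comparator

`comparator_transfer()` implements the two threshold-programmable designs.
In `luxCDE-luxAB`, P~BAD~ drives the forward pair (so $E_F$ is the square
of the P~BAD~ activity) and P~lux~ drives all three reverse genes. In
`luxA-luxC`, only *luxA* and *luxC* are inducible; LuxB is constitutive
and LuxD/LuxE are taken non-limiting, so the reverse rate is set by LuxC
alone — the simplest model consistent with the construct. In both, raising
AHL raises $K_\mathrm{deff}$ and hence the Arabinose threshold
(`detection_threshold()`: the half-span input, interpolated in log-input
space because dose grids are log-spaced; flat or non-monotone curves are
rejected as having no defined threshold). In the `luxA-luxC` design's
operating regime — forward drive below the reverse capacity at every AHL —
the fixed fractional leak cancels in the ON/OFF ratio and the fold change
becomes AHL-independent, which is the design's selling point.

## Stress-promoter dynamics and crosstalk

A stress-responsive promoter (recA for DNA damage, katG for oxidative
stress) is modelled phenomenologically as

$$I(t) = X_0 \left(1 - e^{-(t-\tau_{D1})/\tau_\mathrm{eff}}\right)
\left(e^{-(t-\tau_{D2})/\tau_1} + \beta\right) + c,$$

with the rise term zeroed before the activation delay $\tau_{D1}$ and the
decay exponential clamped to 1 before the consumption delay $\tau_{D2}$
(clamping the rise term as well as the decay term is required for
$I(0) = c$ and continuity; the $\beta$ offset — the non-degradable chemical
fraction — applies throughout, giving the long-time plateau
$X_0\beta + c$). The fitted time constants used as defaults are, in
minutes: katG/H2O2 $\tau_1 = \tau_\mathrm{eff} = 20$, no delays,
$\beta = 0.02$, $c = 2000$; recA/NA $\tau_1 = 60$, $\tau_\mathrm{eff} =
25$, $\tau_{D1} = 60$, $\tau_{D2} = 100$, $\beta = 0.10$; recA/H2O2
$\tau_1 = 30$, $\tau_\mathrm{eff} = 30$, $\tau_{D2} = 40$, $\beta = 0.25$
(recA baseline $c = 9000$).

recA's promiscuity is modelled by **summation**
(`combined_response()`): the per-chemical components add over a single
shared baseline (summing baselines would double-count the instrument
floor). With equal amplitudes the NA + H2O2 sum has exactly two strict
maxima on a 1-min grid over 0–600 min — but the early H2O2 peak is small
and rides on the full baseline, which is why simple summation is a poor
classifier in practice.

**Amplitudes.** The per-chemical $X_0$ are not published. The package
defaults to an amplitude giving a ~10-fold peak induction over the recA
baseline ($X_0 = 5\times10^4$ against $c = 9000$), the typical range for
stress-responsive lux fusions; all structural claims (peak counts, delays,
plateaus) are invariant to this choice, but the noise-robustness of peak
counting is not — at signal-to-background near 1 the early peak drowns in
realistic measurement noise, consistent with the observation that the
small first peak is fragile.

## The crosstalk-compensating circuit (IFFL)

`iffl_simulate()` wires the incoherent feedforward loop: recA activates
the reverse enzymes for every chemical present
($E_R(t) = \mathrm{er\_scale}\times$ the baseline-subtracted summed recA
components), while katG — specific to H2O2 — drives the sender's AHL
production; the receiver converts delayed AHL into TetR
($\mathrm{TetR}(t) = \mathrm{AHL}(t - \tau_\mathrm{delay})$, with the AHL
proxy taken as the normalized katG response shape rather than an explicit
LuxI synthesis/diffusion ODE) and represses the forward enzymes through

$$\mathrm{luxAB} = \frac{1}{1 + (\mathrm{TetR}/0.2)^2}.$$

Two normalizations are deliberate model choices. The delay
$\tau_\mathrm{delay}$ is not published ("synchronized with the NA
kinetics"); the default 60 min places the repression window over the
H2O2-driven early response so the two peaks separate cleanly. The scale
linking recA amplitude units to reverse-enzyme units is likewise
unpublished; the default (`er_scale` $= 10^{-5}$, i.e. a peak reverse
drive of ~0.5) puts the circuit in its working regime: the unrepressed
forward drive (1) exceeds the reverse drive, so the output tracks the
recA signal, while the repressed forward drive (~0.04) falls below it,
so TetR gates the output. Under these defaults the peak count equals the
number of chemicals present: 0/1/1/2 for none/NA/H2O2/both.

At steady state with external AHL the receiver is a **NIMPLY gate**
(`receiver_truth_table()`): high output only for stress without AHL, with
the ON corner at least 5-fold above every other corner under the defaults.

**Peak counting** (`count_peaks()`) uses strict local maxima filtered by
topographic prominence — a peak's height above the higher of the two
lowest points separating it from equal-or-higher terrain — with a default
threshold of 5% of the trace's global range. Prominence, unlike a height
threshold, is invariant to baseline shifts and robust to shallow ripple;
the 1-min simulation grid is fine enough that discretization never merges
the peaks of interest.

## Synthetic plate-reader data

`generate_dose_response()` and `generate_time_course()` emulate the
structure of plate-reader measurements: triplicate wells, a per-well OD600
drawn uniformly within 10% of 0.4, multiplicative lognormal noise with
unit mean (CV configurable, default 10% — a noise *law* is not published,
only triplicate s.e.m. values, so lognormal is chosen as the standard
model for positive multiplicative measurement error), a 15-min sampling
cadence and a 4-h default horizon. OD normalization (`od_normalize()`)
recovers the generating model value in expectation. What the generator
does **not** emulate: growth dynamics (OD is a per-well scalar, not a
curve), toxicity, instrument saturation, or stochastic gene expression —
so passing tests demonstrate correctness of the analysis chain under the
stated noise model, not robustness to every pathology of real plate data.

## Fitting

`fit_hill()` performs least squares on log-transformed outputs (signals
span orders of magnitude; log-space residuals weight the decades evenly)
of $v_\max(\mathrm{basal} + (1-\mathrm{basal})\,x^n/(x^n + K^n))$,
reporting both $(K, n)$ and the aggregate form $x^n/(x^n + \hat K)$,
$\hat K = K^n$, the conventional reporting form for these transfer
functions. Initialization is data-driven — $K$ from the half-max crossing,
$n$ from the sub-half-max log–log slope, $v_\max$ from the maximum —
because naive starts ($n = 1$, $K$ at the grid's geometric median)
converge to a spurious local optimum of the log-space objective on wide
grids; five seeded perturbed restarts are used only on convergence
failure, so fits are deterministic given data. Whether the original
transfer-function fits used basal offsets or weighting is unknown; basal
is fixed at 0 unless requested. `fit_power_law()` is ordinary least
squares of $\log y$ on $\log x$.

A consistency check ties the pieces together: composing the GFP transfer
function $x/(x+11)$ with the reporter power law $I \propto
\mathrm{GFP}^{1.45}$ and Hill-fitting the composition on the canonical
wide grid yields $n \approx 1.42$, $\hat K \approx 33.6$ — bracketing the
directly fitted bioluminescence curve $x^{1.5}/(x^{1.5} + 30)$. The
composition is not exactly a Hill function, so the fitted values depend on
the fitting window; the wide grid is the package's standard choice because
it covers the low-dose power-law regime (whose exact asymptote is
$n = 1.45$, $\hat K = 11^{1.45} \approx 32.4$) as well as saturation. This
check is documented as approximate, not asserted as an equality.

## Problem sizes and limitations

The analyses run at modest sizes chosen for statistical adequacy: 200-point
dose grids, 1-min simulation grids over 10 h, 200-trial Monte-Carlo
recovery and 100-trial robustness studies; each completes in seconds.
Known limitations: no spatial AHL diffusion or sender:receiver population
dynamics (the strain ratio is an experimental condition, not modelled); no
stochastic chemical kinetics (noise enters only through the measurement
model); no resource competition or host burden; and the experimentally
measured gate ODRs and the GFP-vs-lux power-law exponent are
figure-derived quantities that the package treats as given parameters, not
as targets to re-estimate.
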