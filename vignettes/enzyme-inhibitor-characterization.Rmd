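---
title: "Characterizing reversible enzyme inhibitors: kinetics, quenching, thermodynamics and FRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing reversible enzyme inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinquench)
```

## Scope

`kinquench` implements the complete in-vitro characterization workflow for
a reversible small-molecule enzyme inhibitor, of the kind applied to
yeast α-glucosidase (EC 3.2.1.20) assayed with the chromogenic substrate
pNPG (p-nitrophenyl-α-D-glucopyranoside, product detected at 405 nm):

1. initial rates and relative activity from progress curves;
2. IC50 by four-parameter logistic regression;
3. Michaelis–Menten / Lineweaver–Burk analysis across inhibitor levels,
   secondary replots, a global mixed-model fit for $K_i$ and $K_i'$, and
   mechanism classification;
4. reversibility from $v$ vs $[E]$ lines;
5. first-order inactivation kinetics and the transition free energy
   $\Delta\Delta G^\circ = -RT\ln k$;
6. Stern–Volmer fluorescence quenching, the double-logarithmic binding
   fit, Van 't Hoff thermodynamics and Ross–Subramanian force
   classification;
7. synchronous-fluorescence peak shifts;
8. Förster resonance energy transfer distances.

A seeded simulator generates every input with known ground truth, so the
full pipeline is testable without instrument data.

## Models and assumptions

### Rate extraction

Initial velocities are ordinary-least-squares slopes of product
concentration vs time over an early window.  The automatic window grows
from the first three points while the linear fit keeps $R^2 \ge 0.99$
and, when the extinction coefficient is known, while no more than
`max_depletion_frac` (default 5%) of the substrate has been consumed.
The cap matters more than the $R^2$ rule on clean data: a chord fitted
over a span in which a fraction $f$ of substrate disappears
underestimates the $t\to 0$ tangent by roughly $f/2$ at substrate
concentrations near $K_m$, so a 10% window would already bias $K_m$ by
several percent.  Five percent conversion is the stricter of the
conventional "initial velocity" criteria and keeps that bias near 1%.

### Inhibition mechanism

All four classical reversible mechanisms are nested in
$$v = \frac{V_{max} S}{K_m\left(1 + [I]/K_i\right) + S\left(1 + [I]/K_i'\right)}.$$
The analysis mirrors practice: per-level Lineweaver–Burk lines, then
secondary replots of LB slope and LB intercept against $[I]$, whose
negated x-intercepts estimate $K_i$ and $K_i'$.  Because the
double-reciprocal transform amplifies noise, the replots are treated as
diagnostics (their linearity is the "single class of sites" check) and
the reported constants come from a global Levenberg–Marquardt fit of the
rate law above, started at the replot values and parameterized in
$1/K$ so zero is an admissible bound.

A replot slope is declared *indistinguishable from zero* — the
corresponding constant infinite — when its 95% CI covers zero, when it
is non-positive, or when its contribution across the tested $[I]$ range
is under 1% of the replot intercept.  The last rule is needed on
noise-free data, where optimizer-level jitter yields tiny nonzero slopes
with even tinier standard errors.

Classification uses the $K_i/K_i'$ pattern: $K_i' = \infty$ competitive,
$K_i = \infty$ uncompetitive, $|K_i - K_i'| \le 0.15\,\min(K_i, K_i')$
non-competitive, otherwise mixed.  The 0.15 default separates pairs like
34.2/35.4 µM (non-competitive) from 78.3/132.4 µM (mixed).

### Dose–response

Activity normalized to the uninhibited control is fitted with a
four-parameter logistic whose top is fixed at 100% (the normalization
makes it definitional), bottom bounded at zero, Hill slope free, and
IC50 fitted on the log10 scale.  The optimizer is `minpack.lm::nls.lm`
called directly: full-inhibition data push the bottom onto its zero
bound, where the `nls`-object construction inside `nlsLM` fails on a
degenerate numeric derivative.  Standard errors come from the
Gauss–Newton Hessian, inverting only the block of parameters off their
bounds.  Fits that never cross 50% inside the tested range carry an
`extrapolated` flag.

### Reversibility

A reversible inhibitor reduces the slope of $v$ vs $[E]$ without moving
the lines off the origin; an irreversible one titrates enzyme away,
shifting the x-intercept right.  The verdict is `reversible` iff every
per-level intercept's 95% CI covers zero and the slopes strictly
decrease with $[I]$.

### Inactivation kinetics

Activity decays are fitted as
$A(t) = A_\infty + (A_0 - A_\infty) e^{-kt}$ with a free plateau
$A_\infty$ — time courses in this assay family level off at 60–80% of
control, so forcing $A_\infty = 0$ would bias $k$.  A fit is called
monophasic when the semilog residuals of $\ln(A - \hat A_\infty)$ show
no systematic curvature (runs-test $p > 0.05$) and the semilog line has
$R^2 \ge 0.98$.  $\Delta\Delta G^\circ = -RT\ln k / 1000$ kJ/mol with
$R = 8.314$ J mol$^{-1}$ K$^{-1}$; the 37 °C assay corresponds to
$T = 310$ K.

Identifiability deserves emphasis: a three-parameter exponential with
$k \approx 2.8\times10^{-4}$ s$^{-1}$ is only determined when sampling
covers several time constants.  The simulator's default grid therefore
spans 0–21600 s (six time constants, 300 s steps); truncating at one
time constant leaves $k$ and $A_\infty$ so correlated that 2% noise
produces order-50% errors in $k$.

### Fluorescence quenching and binding

The Stern–Volmer fit regresses $F_0/F$ on $[Q]$ with a free intercept,
flagging deviations of more than 5% from 1 (an intercept forced through
1 is available via `force_intercept`).  $K_q = K_{sv}/\tau_0$ exactly,
with $\tau_0 = 10^{-8}$ s by default (the conventional intrinsic-protein
fluorescence lifetime, which makes $K_q = K_{sv}\times10^8$).
Mechanism classification across temperatures: $K_{sv}$ rising with $T$
and $K_q$ above the diffusion-controlled limit
($2\times10^{10}$ M$^{-1}$s$^{-1}$) is combined static–dynamic quenching;
rising with collisional-scale $K_q$ is dynamic; falling $K_{sv}$ is
static (the temperature trend is the decisive static signature, so the
falling branch does not further condition on $K_q$); a non-monotone
trend is reported as inconclusive rather than forced into a class.

Binding constants come from the double-logarithmic plot
$\log_{10}\frac{F_0-F}{F} = \log_{10} K_a + n \log_{10}[Q]$.  Because
the intercept sits many decades from the data, this estimator is only
well conditioned when the quench fraction dominates the intensity noise
at *every* titration point: at 1% noise, points quenched by only ~6%
carry a noise multiplier $F_0/(F_0-F) \approx 17$ in log space and a
Jensen-type bias of several percent in $K_a$.  Recovery tests therefore
use titrations whose shallowest point is quenched by >20%.  The fit
itself stays unweighted OLS, matching field practice.

Van 't Hoff analysis regresses $\ln K_a$ (absolute M$^{-1}$) on $1/T$:
$\Delta H^\circ = -R\,\text{slope}$,
$\Delta S^\circ = R\,\text{intercept}$, and
$\Delta G^\circ(T) = \Delta H^\circ - T\Delta S^\circ$.  Note that
$\Delta S^\circ$ from the intercept inherits the full extrapolation
uncertainty of the regression and is sensitive to the concentration
scale of $K_a$; $\Delta H^\circ$ is scale-invariant.  Force
classification follows the Ross–Subramanian sign rules:
$\Delta H^\circ>0,\Delta S^\circ>0$ hydrophobic;
both negative van der Waals / hydrogen bonding;
$\Delta H^\circ<0,\Delta S^\circ>0$ electrostatic; the remaining
quadrant is reported `unclassified`.

### Synchronous fluorescence

Peaks are localized by three-point parabolic interpolation around the
grid maximum, so shifts are not limited to the wavelength-grid
resolution.  A shift beyond the threshold (default 1 nm) from first to
last titration step is called red (longer wavelength, increased polarity
around the probed residues — tyrosine at $\Delta\lambda = 15$ nm,
tryptophan at 60 nm) or blue.

### FRET

The overlap integral uses the standard Förster form
$J = \int F(\lambda)\,\varepsilon(\lambda)\,\lambda^4 d\lambda \,/\,
\int F(\lambda) d\lambda$ with $\lambda$ in cm (J in M$^{-1}$cm$^3$),
trapezoidal integration on the finer of the two grids restricted to the
300–500 nm window, and
$R_0^6 = 8.79\times10^{-25}\,\kappa^2 n^{-4} \Phi J$ (cm$^6$).
$\kappa^2 = 2/3$, $n = 1.336$ and $\Phi = 0.118$ are
literature-conventional defaults and explicitly assumptions — they are
configuration fields, not measured quantities.  $E = 1 - F/F_0$ at the
reference stoichiometry, $r = R_0((1-E)/E)^{1/6}$, and distances below
7 nm are flagged as the regime where non-radiative transfer is
plausible.

## The simulator, and what passing tests do not show

`simulation_scenario()` fixes every ground-truth parameter; defaults
mirror the α-glucosidase assay: 0.075 µM enzyme, 0.25–2.5 mM substrate,
$K_m = 0.48$ mM, $k_{cat} = 3.89$ s$^{-1}$, a mixed-type inhibitor with
$K_i = 78.3$, $K_i' = 132.4$ µM, emission band at 337 nm,
Stern–Volmer / binding constants in the $10^5$–$10^6$ M$^{-1}$ range at
298/304/310 K, and 1% multiplicative noise (plate-reader CV behavior).
Progress curves integrate the rate law with substrate depletion
(adaptive LSODA, rtol $10^{-8}$); all generators are byte-deterministic
under a fixed seed and embed their truth as an attribute.

The simulator does *not* emulate inner-filter effects, photobleaching,
lamp drift, pipetting error structure, tight-binding depletion of free
inhibitor, or substrate inhibition.  Recovery of generating parameters
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to every artifact of real spectrofluorometer
data.

## Numerical choices and degenerate inputs

* Unweighted least squares throughout, matching the source methodology.
* Nonlinear fits are Levenberg–Marquardt (`minpack.lm`) with bound
  constraints and replot- or transform-based starting values.
* Typed conditions: schema errors name the missing column; validation,
  domain, insufficient-data and no-inhibition errors carry distinct
  classes so callers can branch.
* Degenerate cases are flags, not silent numbers: non-decaying
  inactivation series (`no_inactivation`), dose–response without a 50%
  crossing (`extrapolated`), non-monotone $K_{sv}(T)$ (inconclusive),
  disjoint FRET spectra ($J = 0$ with a warning), $E$ at 0 or 1
  (domain error).
* Units: molar, seconds, kelvin internally; $K_m$ in mM, $K_i$ in µM,
  kJ/mol only at reporting boundaries.  The decimal separator is always
  ".".
* The extinction coefficient of the detected product has no privileged
  default — it is assay-dependent — so `assay_config()` requires it
  explicitly; simulated fixtures use $10^4$ M$^{-1}$cm$^{-1}$.

## Problem sizes used in the test suite

Synthetic studies are sized to mirror the assay design while keeping the
suite fast: 6 substrate × 5 inhibitor levels (×5 replicates for noisy
recovery), 16 parameter sets for the mechanism sweep, 50 replicate
titrations for quenching recovery, and 100 seeded runs for inactivation
recovery.

## Known limitations

* No tight-binding (Morrison) correction and no substrate-inhibition
  term in the rate law.
* No inner-filter correction of fluorescence intensities.
* Modified Stern–Volmer (Lehrer) and sphere-of-action quenching models
  are out of scope.
* CD spectral deconvolution is out of scope; only generic spectrum I/O
  is provided for such data.
* Reported $\Delta S^\circ$ carries the caveat above; interpret the
  force classification from the signs jointly with the fit diagnostics.
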