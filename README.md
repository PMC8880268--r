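# kinquench

Characterization of reversible enzyme inhibitors from plate-reader
progress curves and fluorescence titrations, in one tested R package.

The workflow it implements is the standard one for small-molecule
glycosidase inhibitors (the shipped reference constants describe
magnolol, luteolin and acarbose acting on yeast α-glucosidase assayed
with pNPG at 405 nm), and every stage runs equally on simulated data
with known ground truth:

* **Kinetics** — initial rates with a depletion-capped automatic fit
  window; relative activity; four-parameter logistic IC50
  (top fixed at 100%); Michaelis–Menten and Lineweaver–Burk fits;
  secondary replots of LB slope / intercept vs [I]; a global fit of

  $$v = \frac{V_{max} S}{K_m(1 + [I]/K_i) + S(1 + [I]/K_i')}$$

  for $K_i$ and $K_i'$; mechanism classification (competitive /
  non-competitive / mixed / uncompetitive); catalytic efficiency
  $k_{cat}/K_m$ and potency ratios; reversibility from $v$ vs $[E]$
  lines.
* **Inactivation** — first-order decay fits with a free plateau,
  monophasicity diagnostics (semilog $R^2$ + runs test), and
  $\Delta\Delta G^\circ = -RT \ln k$.
* **Binding spectroscopy** — Stern–Volmer ($F_0/F = 1 + K_{sv}[Q]$,
  $K_q = K_{sv}/\tau_0$) with static/dynamic/combined classification
  against the diffusion limit; the double-log binding fit
  ($\log\frac{F_0-F}{F} = \log K_a + n\log[Q]$); Van 't Hoff
  thermodynamics ($\Delta H^\circ$, $\Delta S^\circ$,
  $\Delta G^\circ(T)$) with Ross–Subramanian binding-force
  classification; synchronous-fluorescence peak shifts (Δλ = 15/60 nm).
* **FRET** — overlap integral $J$, Förster radius $R_0$, efficiency
  $E = 1 - F/F_0$, donor–acceptor distance
  $r = R_0((1-E)/E)^{1/6}$, and the r < 7 nm plausibility flag.
* **Simulators** — seeded, byte-deterministic generators for progress
  curves (ODE integration with substrate depletion), inactivation time
  courses, quench titrations, FRET spectra and synchronous series, each
  embedding its ground truth.

## Worked example

```r
library(kinquench)

cfg <- assay_config(epsilon_product = 1e4)   # M^-1 cm^-1 for the product
sc  <- simulation_scenario(mechanism = "mixed", noise_frac = 0.01, seed = 1)
ds  <- simulate_progress_curves(sc, cfg)     # 6 substrate x 5 inhibitor levels
fit <- fit_inhibition_model(rate_table(ds, config = cfg), enzyme_M = 7.5e-8)
fit
#> <inhibition_fit> mechanism = mixed; Ki = 77.14 uM, Ki' = 135.6 uM; Km = 0.4889 mM, Vmax = 2.913e-07 M/s
#>   replot linearity: slope R^2 = 0.9996, y-intercept R^2 = 0.9997
```

The generating truth was $K_i = 78.3$ µM, $K_i' = 132.4$ µM,
$K_m = 0.48$ mM: at 1% noise the global fit lands within a few percent
of each, the near-unity replot $R^2$ supports a single class of binding
sites, and the finite, unequal constants give the mixed-type call.

Binding thermodynamics from a temperature series of binding constants:

```r
th <- vant_hoff(c(2.97e5, 4.54e5, 5.48e5), c(298, 304, 310))
th$dH_kJ_mol
#> [1] 39.29953
th$force_class
#> [1] "hydrophobic"
```

A positive $\Delta H^\circ$ with positive $\Delta S^\circ$ marks an
entropy-driven, hydrophobically stabilized association.  And the
inactivation free energy from a first-order rate constant at 310 K:

```r
transition_free_energy(2.78e-4, 310)
#> [1] 21.10297   # kJ/mol
```

A command-line wrapper with subcommands (`simulate`, `rates`, `ic50`,
`mechanism`, `inactivation`, `quench`, `thermo`, `fret`, `shift`,
`all`) is installed at `system.file("cli", "kinquench", package = "kinquench")`;
`run_characterization()` is the equivalent R entry point and writes one
JSON report per stage plus a summary.

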