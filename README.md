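# nldfs — dynamic force spectroscopy under nonlinear loading

Dynamic force spectroscopy (DFS) pulls on a single receptor–ligand bond
with a force that grows in time and reads the bond's kinetic identity —
the bond length *x*<sub>b</sub> and the thermal off-rate
*k*<sub>off</sub><sup>th</sup> — out of the distribution of rupture
forces. The classical analysis requires a constant loading rate *r*, in
which case the most probable rupture force obeys

F\* = (k<sub>B</sub>T / x<sub>b</sub>) · ln[ r·x<sub>b</sub> /
(k<sub>off</sub><sup>th</sup>·k<sub>B</sub>T) ].

Real experiments often violate that requirement: worm-like-chain tethers,
bacterial adhesion pili, elastic polymers and nonlinear probes all load
the bond nonlinearly. This package implements the generalization to any
continuous, strictly increasing force protocol. With Bell kinetics
k<sub>off</sub>(F) = k<sub>off</sub><sup>th</sup>·exp(F·x<sub>b</sub>/k<sub>B</sub>T),
the peak force satisfies the implicit condition

F\* = (k<sub>B</sub>T / x<sub>b</sub>) · ln[ ( r(t\*)·x<sub>b</sub>/k<sub>B</sub>T −
d ln r/dt (t\*) ) / k<sub>off</sub><sup>th</sup> ],

which collapses to the classical formula whenever d ln r/dt = 0. The
package is aimed at single-molecule biophysicists using AFM or optical
tweezers who want to analyze pulls through nonlinear tethers without a
force-feedback loop.

It provides:

* **Protocols** — constant rate, power law (F = a(vt)ⁿ), inelastic
  worm-like chain, and tabulated force–distance curves
  (`linear_protocol()`, `power_law_protocol()`, `wlc_protocol()`,
  `tabulated_protocol()`), all exposing F(t), r(t) and d ln r/dt.
* **Kinetics** — survival, cumulative hazard, and the analytic
  rupture-force density (`survival()`, `cumulative_hazard()`,
  `rupture_density_force()`).
* **Peak forces** — closed form, implicit solver, and an independent
  density-maximization oracle (`peak_force_linear()`,
  `peak_force_nonlinear()`, `peak_force_density_oracle()`).
* **Simulation** — exact inverse-hazard Monte Carlo rupture draws with
  mandatory seeds (`sample_rupture_forces()`, `rupture_sampler()`).
* **Spectra** — Gaussian-kernel rupture spectra and peak identification
  (`kde_spectrum()`, `find_peak()`).
* **Estimation** — recovery of (x<sub>b</sub>, k<sub>off</sub><sup>th</sup>)
  from (velocity, peak force) pairs by Nelder–Mead least squares, plus a
  sample-size error study (`fit_parameters()`, `error_study()`).
* **Tooling** — plain-text I/O with metadata headers, YAML run configs, a
  synthetic fixture generator, and an `exec/nldfs` command line with
  `simulate`, `spectrum`, `peak`, `fit`, `errorstudy` and `fixtures`
  subcommands.

## Worked example

An adhesion bond (x<sub>b</sub> = 0.70 nm, k<sub>off</sub><sup>th</sup> =
10⁻⁴ /s) on a worm-like-chain tether (persistence length 3 nm, contour
length 10 µm), pulled at 10–10⁴ nm/s:

```r
library(nldfs)
bp  <- bond_parameters(xb = 0.70, koff_th = 1e-4)
fam <- wlc_family(persistence_length = 3, contour_length = 10)
v   <- c(0.01, 0.1, 1, 10)   # um/s

round(predict_peak_forces(bp, fam, v), 2)
#> [1] 41.55 58.61 74.49 89.81
```

These are the analytic most-probable rupture forces per velocity. A
synthetic experiment with 50 rupture measurements per velocity, 3 pN
spectrum kernel:

```r
peaks <- vapply(v, function(vv) {
  d <- sample_rupture_forces(bp, fam(vv), n = 50, seed = round(1e3 * vv))
  as.numeric(find_peak(kde_spectrum(d, sigma = 3)))
}, numeric(1))
round(peaks, 2)
#> [1] 40.98 57.59 69.92 90.24

fit_parameters(v, peaks, fam)
#> NLDFS parameter fit
#>   bond length xb  : 0.7079 nm
#>   thermal off-rate: 0.0001094 1/s
#>   mean sq. error  : 3.596 pN^2 (converged, 95 evaluations)
#>   per-velocity predicted peaks (pN):
#>  v_um_s predicted residual
#>    0.01    40.334   -0.646
#>    0.10    57.279   -0.316
#>    1.00    73.014    3.099
#>   10.00    88.180   -2.065
```

The fit recovers the bond length to ~1% from just 200 simulated
measurements; the off-rate, which the peak forces constrain only
logarithmically, lands within ~10% here but typically scatters by ~50% at
this sample size (see `error_study()` and the methods vignette).

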