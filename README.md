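# sheetvoid

Sheet-and-void porous-media models of the brain interstitial space (ISS).

Diffusion measurements characterise brain tissue by two porous-media
numbers: the porosity φ (ISS volume fraction, typically ≈ 0.2) and the
geometrical tortuosity τ_g = √(D/D*) (typically ≈ 1.6, where D and D*
are the free and effective diffusivities of a small probe molecule). A
lattice of uniformly spaced convex cells cannot produce that tortuosity —
its maximum, from τ_g = √((3−φ)/2) + 0.07φ(1−φ), is √(3/2) ≈ 1.225 —
so the ISS must contain *dead spaces*. `sheetvoid` is for researchers in
brain biophysics and porous-media transport who want to build and
interrogate the two minimal dead-space geometries that do reproduce the
measurements:

* **CCV** — cubic cells of half-width *a* with cubic voids of width *b*
  at every corner, wrapped in ISS sheets of half-width *w*;
* **ETV** — the corner cubes plus square tunnels along all 12 cell
  edges (the "sheets and tunnels" picture from serial-EM
  reconstructions).

The package provides:

* the closed-form calculus linking φ, *w*, *a*, *b* and the
  void-to-sheet volume ratio Ω = V_v/V_s (`cell_dims`,
  `scale_factor_A`, `ccv_void_width`, `etv_void_width`, …);
* a compiled reflecting Brownian random-walk simulator that releases
  molecules from a point source in a periodic ensemble and measures
  τ_g(t) = √(D/D*) with D* = ⟨r²⟩/6t (`build_ensemble`, `run_walk`,
  `detect_steady_state`, `gaussianity_r2`);
* fitting and inversion of the structure–transport laws
  τ_g² = τ_g0² + m₁Ω (+ m₂Ω² + m₃Ω³ + m₄Ω⁴) (`fit_tau_omega`,
  `omega_at_tau`, `solve_geometry_table`);
* the asleep/awake two-state porosity analysis
  (`sleepwake_analysis`).

## Worked example

Which CCV cell produces the experimentally measured τ_g = 1.6 at
φ = 0.2 with 40 nm sheets? Invert the linear law (fitted slope
m₁ = 0.722, anchor τ_g0² = 1.399) and resolve the geometry:

```r
library(sheetvoid)
fit <- tau_omega_fit(1.399, 0.722, phi = 0.2)
omega_at_tau(fit, 1.6)
#> [1] 1.608033
cell_dims("ccv", phi = 0.2, w = 0.020, omega = 1.608)
#> <cell_dims> CCV model, phi = 0.2
#>   a = 0.742 um, b = 0.3793 um, w = 0.02 um, p = 0.762 um
#>   Omega = 1.608  (A = a/w = 37.1, B = b/a = 0.5112)
#>   volumes [um^3]: V_a = 3.269, V_p = 3.54, V_s = 0.2715, V_v = 0.4366
```

So a 1.48 µm cell with 0.76 µm corner voids, spaced 40 nm apart, has the
measured porosity *and* tortuosity. The two-state analysis runs the same
logic for the asleep (φ = 0.234) and awake (φ = 0.141) brain at a shared
τ = 1.55, anchoring each state's line with the analytic zero-void
tortuosity and one simulated trial point:

```r
sleepwake_analysis()
#> <sleepwake> shared tau = 1.55
#>   sleep: phi = 0.234, tau0 = 1.1886, m = 0.6599, Omega = 1.5000, A = 30.03, B = 0.5371
#>   awake: phi = 0.141, tau0 = 1.2041, m = 0.8248, Omega = 1.1550, A = 43.84, B = 0.4324
#>   constant bounding cube (p = 0.6206 um): awake w = 13.8417 nm, a = 0.6068, b = 0.2624 um
```

The constant-bounding-cube row is the physiologically plausible
scenario: the tissue neither swells nor shrinks on waking, the sheets
thin from 20 nm to 13.8 nm and the voids shrink while the cells swell
slightly.

To measure a tortuosity rather than assume a law, build an ensemble and
run the walker (a desk-scale run; takes a few minutes):

```r
dims <- cell_dims("ccv", phi = 0.2, w = 0.020, a = 0.416)
ens  <- build_ensemble(build_cell(dims), 32)
cfg  <- sim_config(d_cm2_s = 7.71e-6, duration_s = 4e-3,
                   n_molecules = 2000, preset = "custom")
tc   <- run_walk(ens, cfg)
mean(tc$tau_g[tc$t_s >= 2e-3])   # plateau tortuosity, ~1.33
```

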