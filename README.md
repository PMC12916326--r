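# bandratchet

Mechanics of unilateral cytokinesis: a viscoelastic contractile-band
simulator and the in vivo cytoplasmic microrheology pipeline behind it.

Large yolk-anchored embryonic cells (the first zebrafish blastomeres) do
not divide with a closed actomyosin ring: an **open-ended contractile
band** forms on one side and ingresses into the cytoplasm. An open band
under tension should collapse by retracting its free ends — unless the
surrounding cytoplasm anchors it. `bandratchet` implements the
*mechanical ratchet* account of how division still succeeds: in
interphase the microtubule-aster-filled cytoplasm is stiff and anchors
the growing band; in M-phase the cytoplasm fluidizes, the band ingresses
fast but shortens; the alternation repeats until the cell is cut.

The package provides:

* **Jeffreys rheology** — the three-parameter viscoelastic material
  (spring *k* ∥ dashpot γ₁, in series with dashpot γ₂): pulse response,
  recovery fraction
  *a* = 1 − 1/(1 + γ₂/(k·t_p)·(1 − e^(−k·t_p/γ₁))),
  model fitting, and the analytic complex modulus.
* **A contractile-band mesh simulator** — a volumetric ball of Jeffreys
  edges (bulk cytoplasm, not a hollow shell) with an exact equatorial
  spring ring; the band grows at
  *g* = 25 µm/min per end with line tension λᵢ = Λ·pᵢ, and vertices are
  relaxed to force balance (max force < 10⁻⁵) at every dt = 0.01 min
  step through a 15 min interphase + 10 min M-phase cycle.
* **Magnetic-tweezers analysis** — Stokes-drag force calibration
  (f(x) = a₁e^(−k₁x) + a₂e^(−k₂x)), 5 s-on/15 s-off pulse segmentation,
  drift correction, per-pulse normalized displacement and recovery,
  embryo averaging, weighted Welch tests and weighted bootstrap CIs.
* **Creep → complex modulus** — J(t) = 6πR·x(t)/f(t), the
  phenomenological tail fit b + a·t + c·e^(−d·t) (J(0) = b + c,
  η = 1/a), the discrete direct conversion to G*(ω), and fractional
  Kelvin–Voigt spectrum fits G* = c_α(iω)^α + c_β(iω)^β.
* **Laser-ablation kinematics** — recoil fits y = A(1 − e^(−x/x₀)) + c
  with initial recoil velocity A/x₀, band-end detection from PIV flow
  profiles, and the end-velocity/flow/growth decomposition.
* **Seeded synthetic-data generators** for every input above, each a
  closure test for its consuming pipeline.

## Worked example

Phase-specific cytoplasm mechanics, straight from the closed forms:

```r
library(bandratchet)

jeffreys_recovery(interphase_params(), tp = 5)
#> [1] 0.5252432
jeffreys_recovery(mphase_params(), tp = 5)
#> [1] 0.2765745
```

A 5-s, 40-pN bead pulse in interphase cytoplasm displaces the bead by
2.22 µm and recovers 53% of it after release; the same pulse in M-phase
recovers only 28% — the cytoplasm has fluidized.

Fit the Jeffreys model to a (here synthetic, noiseless) pulse and get the
material back:

```r
pulse_t <- seq(0, 20, by = 0.1)
pulse <- pulse_response(pulse_t,
                        jeffreys_displacement(interphase_params(), 40, 5, pulse_t),
                        F0 = 40, tp = 5)
fit_jeffreys(pulse)
#> Jeffreys pulse fit
#> Jeffreys material: k = 32.4 pN/um, gamma1 = 56.1 pN s/um, gamma2 = 189.8 pN s/um
#>   (KV relaxation time gamma1/k = 1.73 s)
#>   recovery a = 0.525, residual norm = 9.31e-16 um
```

Run a short, coarse ratchet cycle (2 min of each phase on a 140-µm mesh;
the full configuration below takes minutes, not seconds):

```r
cfg <- sim_config(target_edge_length = 140, interphase_duration = 2,
                  mphase_duration = 2, record_every = 50)
res <- run_cycle(cfg)
as.data.frame(res)
#>   time_min      phase ingression_um band_length_um
#> 1      0.5 interphase     0.7224092       24.87174
#> 2      1.0 interphase     2.4745375       49.08735
#> 3      1.5 interphase     5.1193814       72.02842
#> 4      2.0 interphase     8.4545859       93.02034
#> 5      2.5    M-phase    21.2862454       87.86773
#> 6      3.0    M-phase    33.1546653       50.98705
#> 7      3.5    M-phase    45.4969336       18.68560
#> 8      4.0    M-phase    46.6936900       43.01737
```

Even on this toy 129-vertex mesh the ratchet signature is visible: the
band (length Σ pᵢ·lᵢ) grows and barely ingresses in the stiff interphase
cytoplasm, then ingresses several-fold faster while shortening once the
M-phase material takes over.

## Package layout

| Module | Files |
|---|---|
| Jeffreys + creep + fractional KV rheology | `R/rheology-*.R` |
| Mesh + ratchet simulator | `R/mesh.R`, `R/simulate.R`, `src/relax.cpp` |
| Magnetic-tweezers pipeline | `R/tweezers.R`, `R/weighted-stats.R` |
| Ablation + band kinematics | `R/ablation.R` |
| Synthetic data | `R/synthetic.R` |
| I/O (tracks, manifests, spectra, configs) | `R/io.R` |

The methods vignette (`vignettes/mechanical-ratchet.Rmd`) documents the
models, the numerical choices (volumetric lattice-ball mesh, Newton-CG
force-balance relaxation, smooth edge-length regularisation), and what
the synthetic generators do and do not emulate.
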