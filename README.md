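# threephoton

Quantitative comparison of 920-nm two-photon (2PM) and 1320-nm three-photon
(3PM) calcium imaging in the scattering mouse brain: photon budgets for
reliable transient detection, excitation scaling with depth, Monte Carlo
light transport and Pennes bio-heat simulation of brain heating, the
signal-to-background depth limit, a calcium-trace measurement pipeline, and
a planner that turns the constraints into concrete imaging parameters.
Synthetic-data generators stand in for the in vivo recordings so every
pipeline stage is testable end to end.

## The models at the core

**Detection fidelity.** A single calcium transient recorded at baseline
photon rate F0 with indicator parameters ΔF/F and τ1/e has shot-noise
discriminability

    d' = (ΔF/F) sqrt(F0 τ1/e / 2) / sqrt(1 + 1/SBR)

For GCaMP6s (ΔF/F = 0.30, τ1/e = 2 s), d' = 3 needs F0 ≈ 100 photons/s and
gives 93% true / 7% false positives under the midpoint Gaussian decision
rule; background at SBR = 1 costs a factor √2 in d'.

**Excitation.** n-photon signal per pulse scales as Cn (P/f)^n / τ^(n−1);
ballistic power decays as exp(−z/EAL) (EAL ≈ 154 µm at 920 nm, ≈ 293 µm at
1320 nm), so the surface pulse energy for fixed focal signal grows as
exp(z/EAL) and the 2P/3P curves cross in the deep cortex. Three-photon
saturation follows Pr = 1 − exp(−gp(3) σ3 Φ³/τ²) with
Φ = E·π·NA²/(hcλ).

**Heating.** Weighted Monte Carlo transport (Henyey–Greenstein scattering,
implicit-capture absorption, underfilled-objective launch, scanned FOV)
produces the absorbed power density that drives the Pennes bio-heat
equation ρc ∂T/∂t = k∇²T + ρb cb wb (TA − T) + Sh + qm, solved on an
axisymmetric grid with a cranial-window-cooled surface.

**Depth limit.** For binary staining with inhomogeneity χ (≈ 50 for ~2%
labelled vasculature), the ratio of in-focus n-photon excitation to
out-of-focus cone plus scattered-halo background falls with depth; the 2P
SBR reaches 1 near 4.5–4.7 EALs while 3P stays orders of magnitude higher.

## Worked example

```r
library(threephoton)

ind <- gcamp6s()
min_baseline_rate(ind, 3)            # photons/s for d' = 3
#> [1] 100
detection_rates(3)
#>   d_prime       tpr       fpr
#> 1       3 0.9331928 0.0668072
dprime(ind, 100) / dprime(ind, 100, sbr = 1)   # background penalty at SBR = 1
#> [1] 1.414214

# light transport at 1 mm depth, 230 um FOV, 1320 nm
beam <- beam_geometry(z_focus_um = 1000, fov_diameter_um = 230)
ag <- simulate_transport(beam, tissue_optics(1320), n_photons = 2e5, seed = 421)
ag
#> <absorption_grid> 2e+05 photons, focus 1000 um, FOV 230 um
#>   fates: heating 62.4%, window 11.5%, skull 6.2%, escaped 20.0%

# brain heating versus average power after the objective
sw <- power_sweep(ag, c(50, 100, 150))
sw$table
#>   power_mw   tmax_c
#> 1       50 36.69465
#> 2      100 37.37698
#> 3      150 39.82191
round(sw$slope_c_per_50mw, 2)        # deg C per 50 mW above the onset
#> [1] 2.44

# two-photon depth limit for staining inhomogeneity 50
round(sbr_unity_depth(2, staining_model(chi = 50)), 2)  # in EALs
#> [1] 4.51
```

The interpretation: 62% of 1320-nm photons delivered for imaging at 1 mm
are absorbed in the tissue; the hottest ~10⁷ µm³ warms by ≈2.4 °C per
additional 50 mW once heating outpaces window cooling (crossing 37 °C
near 90 mW after the objective here); and densely labelled 2PM runs out of
contrast (SBR = 1) at ≈4.5 attenuation lengths, where 3PM still has
SBR ≈ 100.

## Analysis scripts

`analysis/01_photon_budget.R` … `06_imaging_plans.R` are thin numbered
drivers over the package that regenerate the study's analyses (photon
budgets, EAL fits and cross-over, photon fates and heating curves, SBR
depth profiles, paired-channel trace measurements, imaging plans) and
write their tables under `results/`.

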