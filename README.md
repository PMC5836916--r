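# bloodwalk

Monte-Carlo simulation and measurement analysis of water diffusion in
blood, for diffusion-weighted MRI and intravoxel incoherent motion
(IVIM) modelling.

Blood is a two-compartment system: plasma and red blood cells (RBCs)
separated by permeable membranes. The apparent diffusion coefficient
(ADC) that a diffusion-weighted sequence reports for blood therefore
depends on hematocrit (HCT), on the diffusion time `T`, and on the
gradient waveform — monopolar (MP) or flow-compensated (FC). IVIM
perfusion quantification needs the blood self-diffusion constant `D_b`
as an input, and this package provides both halves of its
characterization:

* **Simulation** — a random walk of water molecules in a periodic unit
  cell containing an oblate-cylinder RBC (diameter/height = 8.00/1.75 um,
  scaled to the MCV), with compartment diffusivities `D_p = 2.75`,
  `D_e = 1.00` um²/ms, membrane transmission `P = 2 d_s κ_i / D_i`
  calibrated by the intracellular pre-exchange lifetime
  `τ_e = 12 ms` via `κ_e = (V/S)/τ_e`. Phases accrue per Eq.
  `φ = φ'√b = γ g · Σ_k Δt_k x_cm,k (−1)^k` from per-interval trajectory
  centers of mass, and the estimators are
  `ADC_b = −(1/b) ln |⟨e^{iφ'√b}⟩|`, `ADC_0 = ⟨φ'²⟩/2`,
  `K_app = ⟨φ'⁴⟩/⟨φ'²⟩² − 3`, linked by
  `ADC_b = ADC_0 − (b/6) ADC_0² K_app + O(b²)`.
* **Analysis** — sum-of-squares noise-floor correction
  `S_c = √(S_m² − 6σ²)`, the `√60·σ` (SNR < √10 ≈ 3.2) exclusion rule,
  three-b-value ADC fits, mono-exponential T2 fits, Pearson correlation
  with the `|r| > r_crit` gate, paired MP-vs-FC comparison, and the
  blood-count calibration
  `ADC_FC = 1.545 + (0.42 − HCT)·2.169`,
  `ADC_MP = 1.307 + (0.42 − HCT)·2.846` (plus HGB analogues and the
  covariate-free constants 1.54/1.30 um²/ms).

The walker's hot loop is C++ (Rcpp) with an internal seeded RNG, so runs
are fast and bit-reproducible.

## Worked example

```r
library(bloodwalk)

cell <- build_unit_cell(hct = 0.43, mcv = 87.7)
cell$gap                    # 0.8566122  -> 1% step = 8.57 nm
cell$surface_to_volume      # 1.644508   um^-1

params <- compartment_params(cell)   # D_p 2.75, D_e 1.00, tau_e 12 ms
params$f                    # 0.35727  intracellular water fraction
params$kappa_e              # 0.05067  um/ms

profs <- list(switch_times("MP", T_ms = 40, TE_ms = 120),
              switch_times("FC", T_ms = 100, TE_ms = 120))
rec  <- simulate_walk(cell, params, profs, n_particles = 2000,
                      step_fraction = 0.05, seed = 1)
dirs <- isotropic_directions(2000, seed = 1)
adc_from_phases(phases(rec, 2, dirs, b_s_mm2 = 400))
#> Diffusion statistics at b = 0.4 ms/um^2 (2000 particles x 2000 directions)
#>   ADC_b  = 1.4335 +/- 0.0291 um^2/ms
#>   ADC_0  = 1.4812 +/- 0.0308 um^2/ms
#>   K_app  = 0.3172 +/- 0.0633
```

ADC_b is the coefficient a two-point (b = 0, 400 s/mm²) measurement
would report for this flow-compensated encoding at HCT 0.43; it sits
below ADC_0 because the phase distribution has positive excess kurtosis
(restricted, exchanging compartments). Sweeping hematocrit shows the
calibration-relevant trend — higher HCT, lower ADC:

```r
adc_sweep(hct = c(0.36, 0.43, 0.47), T_mp = 40, T_fc = 100,
          n_particles = 2000, step_fraction = 0.05, seed = 1)
```

On the measurement side:

```r
predict_Db("FC", hct = 0.42)   # 1.545 um^2/ms
noise_correct(10, 1)           # 9.69536 = sqrt(94)
```

A command-line wrapper over the same functions lives at
`inst/cli/bloodwalk.R` (subcommands `waveform`, `simulate`, `sweep`,
`analyze`, `fixtures`, `acceptance`).

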