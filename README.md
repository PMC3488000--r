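# lovscreen

Screening analytics for directed evolution of flavin-binding fluorescent
proteins (FbFPs).

FbFPs are small LOV-domain reporters whose fluorescence comes from a
noncovalently bound FMN chromophore; they work without oxygen, which makes
them attractive reporters for anaerobic biology, but wild-type proteins are
dim. Brighter variants are found by site-saturation mutagenesis: replace one
chromophore-proximal codon with a degenerate NNK triplet (32 codons, all 20
amino acids plus one stop), screen ~180 colonies per site by plate
fluorescence spectroscopy, confirm hits in shake flasks and as purified
protein, and characterize them by relative quantum yield, holoprotein
fraction and oligomeric state.

`lovscreen` implements the quantitative machinery of that campaign:

* **Library design** — degenerate codon expansion, amino-acid
  distributions, exact/Monte-Carlo complete-coverage probabilities
  (inclusion–exclusion over variant subsets), required clone counts for a
  target confidence, oversampling factors, and NNK mutagenic primer
  construction and validation.
* **Site selection** — minimum heavy-atom residue–ligand distances from a
  PDB structure, with 0.3 nm / 0.4 nm proximity shells.
* **Spectral screening** — background subtraction, order-3 frame-5
  Savitzky–Golay smoothing, peak metrics, beneficial / neutral /
  deleterious calling (≥2-fold brighter and/or ≥10 nm shifted; ≤0.5-fold is
  deleterious) with three-tier confirmation and library summary tables.
* **Photophysics** — relative quantum yield against the FMN standard
  (QY = 0.27), `QY = (F_s/A_s)/(F_ref/A_ref) · QY_ref`, and Beer–Lambert
  holoprotein fractions, `C_holo = A450/(ε·l)` with ε = 12500 M⁻¹cm⁻¹,
  both with propagated uncertainties.
* **SEC oligomeric state** — log₁₀(mass) vs elution-volume calibration and
  nearest-integer oligomer labels (monomer mass 16.3 kDa by default).
* **Synthetic data** — a seeded generator for every input above with known
  ground truth, so the whole pipeline is validated by parameter recovery.

## Worked example

```r
library(lovscreen)

# How well does a 180-colony screen cover an NNK site?
lib <- degenerate_library("NNK")
oversampling_factor(180, lib)
#> [1] 5.625
coverage_probability(180, lib$variant_probs)
#> <coverage_result> n = 180: P(complete) = 0.89887 [exact]
required_clones(lib$variant_probs, confidence = 0.95)
#> [1] 203

# Call hits on a simulated 180-clone plate screen with known ground truth
sim  <- simulate_screen(generator_config(seed = 42))
recs <- screen_records(process_plate_scans(sim$scans))
mean(recs$final_class == sim$truth$true_class[match(recs$clone, sim$truth$clone)])
#> [1] 0.9888889

# Photophysics of a bright mutant: quantum yield vs the FMN standard
ph <- generate_photophysics_series(true_qy = 0.30, true_f_holo = 0.49,
                                   noise_fraction = 0.01)
quantum_yield(ph$sample, ph$standard)
#> <qy_estimate> QY = 0.301 +/- 0.002 (mean_ratio; n = 5 vs 5 standard)

# Oligomeric state from a size-exclusion run
run <- generate_sec_run(true_state = 1.81, noise_sd_ml = 0)
sec_oligomer_table(fit_calibration(run$standards), run$samples)
#> # A tibble: 1 × 5
#>   name   elution_volume_ml net_mass_kda state_value state_label
#> 1 sample              15.9         29.5        1.81 dimer
```

Reading the numbers: 180 colonies oversample the 32-codon space 5.6-fold
(reported as "≈6-fold"), but the probability that *every* codon appears is
only ~0.90 — 203 colonies are needed for 95%. On synthetic plates at the
default 3% noise, ~99% of clones get their true class back. The
quantum-yield estimator recovers a true QY of 0.30 within its reported
uncertainty, and a 29.5 kDa species over a 16.3 kDa monomer is a dimer
(state 1.81).

A small command-line wrapper over the same functions is installed as
`exec/lovscreen` (subcommands `coverage`, `design`, `sites`, `screen`,
`sec`, `simulate`).

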