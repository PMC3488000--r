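---
title: "Quantitative analytics for FbFP site-saturation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analytics for FbFP site-saturation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovscreen)
```

## The problem

Flavin-binding fluorescent proteins (FbFPs) are small LOV-domain reporters
whose fluorescence comes from a noncovalently bound FMN cofactor. Unlike
GFP-family proteins they need no molecular oxygen, which makes them the
reporter of choice in anaerobic systems — but the wild-type proteins are
dim. A practical route to brighter variants is site-saturation mutagenesis
of chromophore-proximal residues: replace one codon at a time with a
degenerate NNK triplet, screen a few plates of colonies by fluorescence
spectroscopy, and characterize the confirmed hits biochemically.

`lovscreen` covers the quantitative side of such a campaign end to end:

1. **Library design** — degenerate codon enumeration, amino-acid
   distributions, coverage statistics and mutagenic primer construction.
2. **Site selection** — chromophore-proximity shells from a PDB structure.
3. **Screening** — hit calling from plate emission scans with three-tier
   confirmation.
4. **Photophysics** — relative quantum yield and holoprotein fraction.
5. **Oligomeric state** — SEC mass calibration.
6. **Synthetic data** — a generator with known ground truth that stands in
   for the wet lab, so every stage is validated by parameter recovery.

## Degenerate libraries and coverage

An NNK codon (N = any base, K = G or T) expands to $4 \times 4 \times 2 =
32$ codons encoding all 20 amino acids plus a single stop (TAG):

```{r}
lib <- degenerate_library("NNK")
length(lib$codons)
amino_acid_distribution("NNK")[["*"]]
```

How many colonies must be screened so that, with confidence $c$, every
variant appears at least once? For $n$ i.i.d. draws from variant
probabilities $p_1,\dots,p_k$ the complete-coverage probability is the
inclusion–exclusion sum

$$P(\text{all } k \text{ seen}) \;=\; \sum_{S \subseteq \{1..k\}} (-1)^{|S|}
\Bigl(1 - \sum_{i \in S} p_i\Bigr)^{n},$$

which collapses to $\sum_j (-1)^j \binom{k}{j} \bigl((k-j)/k\bigr)^n$ when
all variants are equiprobable. The package evaluates the equiprobable form
in closed form for any $k$, the general subset sum up to 20 variants
(cost $2^k$), and a seeded Monte-Carlo estimator (default $10^5$
replicates) beyond that. `required_clones()` inverts the monotone coverage
curve by doubling plus bisection and always returns the smallest qualifying
$n$.

```{r}
coverage_probability(180, lib$variant_probs)
required_clones(lib$variant_probs, confidence = 0.95)
oversampling_factor(180, lib)
```

Two conventions deserve a note, because screens are sized differently
depending on them:

* **Codon vs amino-acid level.** The default works at codon level (32
  variants, matching the "32 possible mutations" arithmetic used to size
  such screens); `degenerate_library(level = "amino_acid", include_stop =
  FALSE)` switches to the 20-residue view. Both are exposed because sizing
  tools in this field do not agree on the convention.
* **Stop codons count as variants at codon level.** A TAG draw is a clone
  on the plate even though it covers no residue; excluding it is exactly
  the amino-acid view.

Screening 180 colonies covers the 32-codon space about six-fold, yet the
exact complete-coverage probability at $n = 180$ is just below 90%; the
smallest $n$ reaching 95% is a little above 200. Six-fold oversampling and
"95% of libraries fully covered" are close but not interchangeable
statements, and the package computes both so the trade-off is explicit.

## Mutagenic primers

`build_mutagenic_primer()` concatenates concrete flanks around the
degenerate codon and `validate_primer()` is the reverse QC step: it locates
the unique 3-nt degenerate block (anything else — zero blocks, several
blocks, a block of the wrong length — is an error). The shipped panel of
nine FbFP NNK primers round-trips through both:

```{r}
spec <- read_library_spec(system.file("extdata", "fbfp_nnk_primers.tsv",
                                      package = "lovscreen"))
spec[spec$name == "FbFP_F37Xmut", c("name", "sequence", "degenerate_start")]
```

Primer thermodynamics (melting temperature, hairpins) are deliberately out
of scope.

## Selecting chromophore-proximal sites

Given a structure with the FMN cofactor, candidate positions are residues
whose minimum heavy-atom distance to any ligand atom falls within a shell.
Distances are minimum heavy-atom distances (hydrogens excluded, the
standard reading when a cutoff "from the chromophore" is quoted without
naming atoms), computed in Angstrom and reported in nm. Alternate locations
keep the first conformer; only the first model of a multi-model file is
used.

```{r}
pdb <- generate_toy_structure(c(rep(2.8, 3), rep(2.95, 3), 3.3, 3.7, 3.9, 6))
model <- parse_structure(pdb)
proximity_shells(model, inner_nm = 0.3, outer_nm = 0.4)
```

The tool annotates distances; it does not decide targets. Positions picked
for mechanistic reasons despite lying outside the shells (as happens in
real campaigns) are a manual choice.

## Calling hits from plate scans

Emission scans (470–600 nm, 1 nm steps, excitation 450 nm) are processed
per plate and tier:

1. the **background** is the mean spectrum of the background wells
   (uninduced cells) and is subtracted pointwise — negative values are
   retained for honest statistics, and only the fold-change numerator is
   floored at zero;
2. spectra are smoothed with an order-3, frame-5 **Savitzky–Golay** filter.
   Edges use mirror padding (the filter literature offers several
   conventions; mirror padding keeps the grid unchanged and its bias is
   confined to the two outermost points, which is why the
   polynomial-exactness property is asserted on interior points);
3. the **peak** is the argmax over the full scan window — not a fixed
   495 nm readout, since a fixed wavelength would miss exactly the
   spectrally shifted hits the screen is looking for — with ties broken
   toward the shorter wavelength;
4. a clone is **beneficial** if its peak intensity reaches twice the
   wild-type reference (boundary inclusive) and/or its peak is shifted by
   10 nm or more; **deleterious** if the fold change drops to 0.5 or below
   (the symmetric criterion on a log scale; screens report only "greatly
   diminished", so this is a configurable default); **neutral** otherwise —
   "identical to wild type" is implemented as this residual band, not as an
   equality test;
5. a clone is finally beneficial only if it meets the criteria in **every
   tier** screened (plate, shake flask, purified protein).

```{r}
sim <- simulate_screen(generator_config(seed = 1, clones_per_library = 60L))
records <- screen_records(process_plate_scans(sim$scans))
summarize_library(records)
```

## Quantum yield and holoprotein fraction

The relative quantum yield against free FMN ($QY_{FMN} = 0.27$) ratios
integrated emission per unit absorbance:

$$QY = \frac{\int F_s \, d\lambda / A_s}{\int F_{ref} \, d\lambda /
A_{ref}} \; QY_{ref}.$$

Each concentration series is reduced to a single $F/A$ before the ratio is
formed — by default the mean of per-sample $F/A$ values, with a
through-origin regression of $F$ on $A$ available as an option (both agree
on proportional data; the mean is more robust when the series spans a wide
absorbance range with heteroscedastic noise). Uncertainties are standard
deviations propagated to first order. No refractive-index correction is
applied: samples and standard are measured in the same aqueous buffer, so
the factor cancels.

Only the FMN-bound holoprotein absorbs at 450 nm, so Beer–Lambert gives its
concentration, $C_{holo} = A_{450}/(\varepsilon l)$ with $\varepsilon =
12500\ \mathrm{M^{-1} cm^{-1}}$, and dividing by the Bradford total protein
concentration gives the holoprotein fraction $f_{holo}$. Fractions
marginally above 1 (≤ 5% relative excess, ordinary measurement noise) are
clamped to 1 with a warning; larger excess is treated as inconsistent
input, not data. Free-FMN corrections are omitted — purified preparations
carry negligible free cofactor.

```{r}
ph <- generate_photophysics_series(true_qy = 0.30, true_f_holo = 0.49,
                                   noise_fraction = 0.01, seed = 7)
quantum_yield(ph$sample, ph$standard)
mean(holo_fraction(holoprotein_concentration(ph$sample$absorbance_450),
                   ph$sample$concentration))
```

Fold enhancements between variants propagate uncertainty by the delta
method and are rounded to two significant figures only at the reporting
layer (`format_fold()`); full precision is kept internally.

## Oligomeric state by SEC

Gel-filtration calibration is ordinary least squares of $\log_{10}$(mass)
on elution volume — the semi-logarithmic straight line of column
calibration plots. The fit refuses a non-negative slope (larger proteins
must elute earlier), requires three distinct standards, and warns on
extrapolation. Calibration against volume rather than the partition
coefficient $K_{av}$ is a deliberate simplification: it matches how
single-column calibrations are usually reported, and the inputs are
already-called peak elution volumes, not chromatograms. The net mass
divided by the 16.3 kDa monomer mass gives the oligomeric state; labels
follow the nearest integer (a state of 1.81 is a dimer).

```{r}
run <- generate_sec_run(true_state = 1.81, noise_sd_ml = 0)
cal <- fit_calibration(run$standards)
cal
sec_oligomer_table(cal, run$samples)
```

## What the generator emulates — and what it does not

The synthetic generator defines the study conditions under which the
pipeline is validated: a 180-clone NNK screen in 96-well format (each plate
carrying its own background and wild-type reference wells), emission peaked
at 495 nm with a red-skewed asymmetric-Gaussian line shape (red width 1.6×
the blue width — only peak position and intensity drive the analysis, so no
physical vibronic model is attempted), a 5%-of-peak autofluorescence
background, and additive Gaussian noise of 3% of the wild-type peak at
plate level, shrinking at the flask and purified tiers as real measurements
do. Ground-truth classes default to 1% beneficial / 40% deleterious / 59%
neutral — the composition observed at chromophore-critical positions —
with true folds drawn uniformly on [2, 3] (beneficial), normally around 1
(sd 0.05, neutral) and uniformly on [0.05, 0.45] (deleterious).
Photophysics readings carry multiplicative 1–2% noise (additive on
spectra, multiplicative on meter readings: the simplest models with
analytic recovery bounds), and SEC volumes carry 0.05 mL of Gaussian
jitter on a Superdex-200-like calibration line. One global seed feeds
per-stream substreams, so each stage can be regenerated independently and
every artifact is byte-reproducible.

What passing recovery tests on these data does **not** show: robustness to
growth-rate differences between wells (no optical-density normalization is
modeled), plate edge effects, spectral shapes beyond a shifted/scaled
unimodal peak, FMN dissociation kinetics, or colony-level image screening.
Those belong to the wet lab, not to this model of it.

Under the defaults the screening pipeline recovers the ground-truth class
of ≥95% of clones aggregated over 100 seeded replicates, quantum yields
are recovered within ±0.01 and SEC states within ±0.05 — these are exactly
the checks in the test suite and the acceptance script, run at those
problem sizes (100 × 180 clones in the tests; 50 × 180 in the script)
because they give stable aggregates at negligible cost.

Clones with a true fold sitting exactly on the inclusive two-fold boundary
are recalled perfectly only in the noiseless limit; with any measurement
noise a boundary clone's measured fold falls below threshold with
appreciable probability. The suite therefore checks boundary inclusivity
at zero noise and overall accuracy at the default noise, rather than
pretending boundary recall survives noise.

## Numerical notes and known limitations

* The alternating inclusion–exclusion sum loses absolute accuracy around
  $10^{-13}$ when the true coverage probability is itself that small
  (e.g. 32 variants, 32 draws); results are clamped to [0, 1] and the
  comparison against Monte-Carlo uses a $10^{-9}$ floating-point floor.
* Exact subset inclusion–exclusion is capped at 20 unequal-probability
  variants ($2^{20}$ subset sums); beyond that the Monte-Carlo path (seed
  20121024, $10^5$ replicates by default) keeps results reproducible.
* `required_clones()` errors on zero-probability variants (coverage is
  unreachable) rather than returning infinity.
* Savitzky–Golay mirror padding biases the two edge points of each scan;
  peak calling is unaffected in practice because emission peaks sit well
  inside the 470–600 nm window.
* The screen classifies on smoothed, background-subtracted peak intensity
  only; integrated brightness is deliberately reserved for the purified
  photophysics stage.
* Dual-excitation plate data (450 and 500 nm) can be stored in the scan
  format, but classification uses the 450 nm excitation scans.
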