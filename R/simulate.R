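#' Configuration for the synthetic screening-data generator
#'
#' Defines the study conditions emulated by the generator: a 180-clone NNK
#' site-saturation screen in 96-well format of a flavin-binding fluorescent
#' protein whose emission peaks at 495 nm, with a small beneficial class and
#' a large deleterious class (the shape observed at chromophore-critical
#' positions), plate autofluorescence background, and additive Gaussian
#' detection noise that shrinks in the later (shake-flask, purified) tiers.
#'
#' @param seed Global seed; every generator derives independent substreams
#'   from it, so stages can be regenerated independently.
#' @param class_proportions Probabilities of the beneficial / deleterious /
#'   neutral ground-truth classes (must sum to 1).
#' @param beneficial_fold_range True-fold support for beneficial clones
#'   (uniform; >= 2).
#' @param neutral_fold_sd SD of the neutral true fold around 1 (clamped well
#'   inside the classification band).
#' @param deleterious_fold_range True-fold support for deleterious clones
#'   (uniform; <= 0.5).
#' @param peak_center_nm Wild-type emission peak (default 495 nm).
#' @param peak_width_nm Blue-side Gaussian width of the emission peak; the
#'   red side is 1.6x wider (broad red tail).
#' @param wt_amplitude Wild-type peak intensity, a.u.
#' @param noise_sd_fraction Plate-tier noise SD as a fraction of the
#'   wild-type peak (default 0.03).
#' @param tier_noise_scale Multipliers applied to the noise SD per tier.
#' @param background_level Autofluorescence background as a fraction of the
#'   wild-type peak.
#' @param clones_per_library Clones screened per library (default 180).
#' @param wells_per_plate Plate format (default 96).
#' @param n_background_wells,n_reference_wells Background / wild-type
#'   reference wells per plate-tier.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 20121024L,
                             class_proportions = c(beneficial = 0.01,
                                                   deleterious = 0.40,
                                                   neutral = 0.59),
                             beneficial_fold_range = c(2.0, 3.0),
                             neutral_fold_sd = 0.05,
                             deleterious_fold_range = c(0.05, 0.45),
                             peak_center_nm = 495,
                             peak_width_nm = 12,
                             wt_amplitude = 1000,
                             noise_sd_fraction = 0.03,
                             tier_noise_scale = c(plate = 1, flask = 2 / 3,
                                                  purified = 1 / 3),
                             background_level = 0.05,
                             clones_per_library = 180L,
                             wells_per_plate = 96L,
                             n_background_wells = 8L,
                             n_reference_wells = 8L) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (!all(sort(names(class_proportions)) ==
           c("beneficial", "deleterious", "neutral"))) {
    stop("class proportions must be named beneficial/deleterious/neutral",
         call. = FALSE)
  }
  if (any(class_proportions < 0) || noise_sd_fraction < 0) {
    stop("proportions and noise must be non-negative", call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

# Derived per-stream seed, kept below 2^31.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * stream) %% 2147483647)
}

#' Generate a ground-truth library
#'
#' Draws `clones_per_library` clones i.i.d. from the uniform codon
#' distribution of a degenerate scheme, assigns each a ground-truth
#' phenotype class per the configured proportions and a true brightness
#' fold consistent with that class under the default screening thresholds.
#'
#' @param config A [generator_config()].
#' @param scheme Degenerate codon scheme (default `"NNK"`).
#' @param n_clones Number of clones (defaults to
#'   `config$clones_per_library`).
#' @return Tibble with `clone`, `codon`, `residue`, `true_class`,
#'   `true_fold`, `true_peak_nm`.
#' @export
generate_library <- function(config = generator_config(), scheme = "NNK",
                             n_clones = config$clones_per_library) {
  stopifnot(inherits(config, "generator_config"))
  codons <- expand_degenerate_codon(scheme)
  with_local_seed(substream_seed(config$seed, 1L), {
    codon <- sample(codons, n_clones, replace = TRUE)
    cls <- sample(names(config$class_proportions), n_clones, replace = TRUE,
                  prob = config$class_proportions)
    fold <- numeric(n_clones)
    fold[cls == "beneficial"] <- runif(sum(cls == "beneficial"),
                                       config$beneficial_fold_range[1],
                                       config$beneficial_fold_range[2])
    fold[cls == "neutral"] <- pmin(pmax(
      rnorm(sum(cls == "neutral"), 1, config$neutral_fold_sd), 0.6), 1.9)
    fold[cls == "deleterious"] <- runif(sum(cls == "deleterious"),
                                        config$deleterious_fold_range[1],
                                        config$deleterious_fold_range[2])
    tibble::tibble(
      clone = sprintf("clone_%04d", seq_len(n_clones)),
      codon = codon,
      residue = unname(Biostrings::GENETIC_CODE[codon]),
      true_class = cls,
      true_fold = fold,
      true_peak_nm = config$peak_center_nm
    )
  })
}

# Asymmetric Gaussian emission line shape on a wavelength grid: blue-side
# width `width`, red-side width 1.6x (broad red tail), unit peak height.
emission_shape <- function(wavelengths, peak_nm, width_nm) {
  w <- ifelse(wavelengths <= peak_nm, width_nm, 1.6 * width_nm)
  exp(-(wavelengths - peak_nm)^2 / (2 * w^2))
}

#' Generate one synthetic emission spectrum
#'
#' Smooth asymmetric-Gaussian peak at the clone's true peak wavelength,
#' scaled by its true fold times the wild-type amplitude, plus the
#' autofluorescence background and i.i.d. Gaussian noise.
#'
#' @param truth One-row data frame (or list) with `true_fold` and
#'   `true_peak_nm`, e.g. a row of [generate_library()].
#' @param config A [generator_config()].
#' @param tier Screening tier (sets the noise scale).
#' @param noise Add noise? Set `FALSE` for a noiseless spectrum.
#' @param wavelengths Grid (default 470:600 nm).
#' @return An [emission_spectrum()].
#' @export
generate_emission_spectrum <- function(truth, config = generator_config(),
                                       tier = "plate", noise = TRUE,
                                       wavelengths = 470:600) {
  amp <- config$wt_amplitude
  signal <- amp * truth$true_fold *
    emission_shape(wavelengths, truth$true_peak_nm, config$peak_width_nm) +
    config$background_level * amp
  if (noise) {
    sd <- config$noise_sd_fraction * amp * config$tier_noise_scale[[tier]]
    signal <- signal + rnorm(length(wavelengths), 0, sd)
  }
  emission_spectrum(wavelengths, signal, tier = tier,
                    clone = if (!is.null(truth$clone)) truth$clone else NA_character_)
}

#' Simulate a full multi-tier screening run
#'
#' Generates a ground-truth library and long-format plate scans for each
#' requested tier, including background wells (autofluorescence only) and
#' wild-type reference wells, laid out on 96-well plates. The output feeds
#' directly into [process_plate_scans()].
#'
#' @param config A [generator_config()].
#' @param scheme Degenerate codon scheme (default `"NNK"`).
#' @param tiers Tiers to simulate (default all three).
#' @return List with `truth` (tibble) and `scans` (long-format tibble with
#'   columns `plate`, `well`, `role`, `tier`, `clone`, `excitation_nm`,
#'   `wavelength_nm`, `intensity`).
#' @export
simulate_screen <- function(config = generator_config(), scheme = "NNK",
                            tiers = c("plate", "flask", "purified")) {
  truth <- generate_library(config, scheme)
  wavelengths <- 470:600
  amp <- config$wt_amplitude
  scans <- lapply(seq_along(tiers), function(ti) {
    tier <- tiers[ti]
    with_local_seed(substream_seed(config$seed, 10L + ti), {
      n_bg <- config$n_background_wells
      n_ref <- config$n_reference_wells
      per_plate <- config$wells_per_plate - n_bg - n_ref
      if (per_plate < 1L) stop("plate too small for controls", call. = FALSE)
      n_plates <- ceiling(nrow(truth) / per_plate)
      # every plate carries its own background and reference wells
      roles <- character(0); clones <- character(0)
      folds <- numeric(0); peaks <- numeric(0); plate_no <- integer(0)
      for (pl in seq_len(n_plates)) {
        idx <- ((pl - 1L) * per_plate + 1L):min(pl * per_plate, nrow(truth))
        roles <- c(roles, rep("background", n_bg), rep("wt_reference", n_ref),
                   rep("sample", length(idx)))
        clones <- c(clones, rep(NA_character_, n_bg + n_ref), truth$clone[idx])
        folds <- c(folds, rep(0, n_bg), rep(1, n_ref), truth$true_fold[idx])
        peaks <- c(peaks, rep(config$peak_center_nm, n_bg + n_ref),
                   truth$true_peak_nm[idx])
        plate_no <- c(plate_no, rep(pl, n_bg + n_ref + length(idx)))
      }
      n_wells <- length(roles)
      shape <- vapply(seq_len(n_wells), function(i) {
        amp * folds[i] * emission_shape(wavelengths, peaks[i],
                                        config$peak_width_nm)
      }, numeric(length(wavelengths)))
      sd <- config$noise_sd_fraction * amp * config$tier_noise_scale[[tier]]
      intens <- shape + config$background_level * amp +
        matrix(rnorm(length(shape), 0, sd), nrow = length(wavelengths))
      pos <- unlist(lapply(rle(plate_no)$lengths, seq_len)) - 1L
      well <- sprintf("%s%02d", LETTERS[pos %/% 12L + 1L], pos %% 12L + 1L)
      tibble::tibble(
        plate = rep(paste0("plate", plate_no), each = length(wavelengths)),
        well = rep(well, each = length(wavelengths)),
        role = rep(roles, each = length(wavelengths)),
        tier = tier,
        clone = rep(clones, each = length(wavelengths)),
        excitation_nm = 450,
        wavelength_nm = rep(wavelengths, times = n_wells),
        intensity = as.vector(intens)
      )
    })
  })
  list(truth = truth, scans = dplyr::bind_rows(scans))
}

#' Generate a synthetic photophysics concentration series
#'
#' Emulates paired quantum-yield / holoprotein measurements: absorbance at
#' 450 nm proportional to the true holoprotein fraction times the total
#' protein concentration (Beer-Lambert), and integrated emission
#' proportional to the true quantum yield times the absorbance, both with
#' multiplicative Gaussian noise. A matching FMN standard series (quantum
#' yield 0.27, fully chromophore-bound) is generated alongside.
#'
#' @param true_qy True quantum yield of the protein.
#' @param true_f_holo True holoprotein fraction.
#' @param concentrations Total protein concentrations, molar (default five
#'   points spanning 0.1-1 mg/mL of a 16.3 kDa protein).
#' @param standard_concentrations FMN standard concentrations, molar
#'   (default five points spanning 6.2-25 uM).
#' @param noise_fraction Multiplicative noise SD (default 0.01).
#' @param epsilon,path_length_cm Beer-Lambert parameters (defaults 12500
#'   per M per cm, 1 cm).
#' @param gain Instrument gain linking absorbed light to integrated
#'   emission (cancels in the quantum-yield ratio).
#' @param seed Seed for the noise stream.
#' @return List with tibbles `sample` and `standard` (columns
#'   `concentration`, `absorbance_450`, `integrated_emission`,
#'   `path_length_cm`) plus the true parameters.
#' @export
generate_photophysics_series <- function(true_qy, true_f_holo,
                                         concentrations =
                                           seq(0.1, 1, length.out = 5) / 16.3e3,
                                         standard_concentrations =
                                           seq(6.2e-6, 25e-6, length.out = 5),
                                         noise_fraction = 0.01,
                                         epsilon = 12500, path_length_cm = 1,
                                         gain = 1e8, seed = 20121024L) {
  stopifnot(all(concentrations > 0), all(standard_concentrations > 0))
  with_local_seed(seed, {
    series <- function(conc, f_holo, qy) {
      a450 <- f_holo * conc * epsilon * path_length_cm *
        (1 + rnorm(length(conc), 0, noise_fraction))
      emission <- gain * qy * a450 * (1 + rnorm(length(conc), 0, noise_fraction))
      tibble::tibble(concentration = conc, absorbance_450 = a450,
                     integrated_emission = emission,
                     path_length_cm = path_length_cm)
    }
    list(sample = series(concentrations, true_f_holo, true_qy),
         standard = series(standard_concentrations, 1, 0.27),
         true_qy = true_qy, true_f_holo = true_f_holo, epsilon = epsilon)
  })
}

#' Generate a synthetic size-exclusion chromatography run
#'
#' Places the four classic gel-filtration standards exactly on a log-linear
#' calibration line and derives a sample elution volume from a true
#' oligomeric state (sample volume = calibration inverse of state x monomer
#' mass, plus Gaussian volume noise).
#'
#' @param true_state True oligomeric state (e.g. 1.81 for a partially
#'   compact dimer).
#' @param monomer_kda Monomer mass (default 16.3 kDa).
#' @param intercept,slope Calibration line `log10(kDa) = intercept + slope
#'   * V_ml` (defaults emulate a Superdex 200 analytical column).
#' @param standard_masses Named standard masses in kDa.
#' @param noise_sd_ml SD of the sample elution volume, mL (default 0.05).
#' @param seed Seed for the noise stream.
#' @return List with `standards` and `samples` tibbles (CSV-ready) and the
#'   true parameters.
#' @export
generate_sec_run <- function(true_state = 1.81, monomer_kda = 16.3,
                             intercept = 4.5, slope = -0.19,
                             standard_masses = c(thyroglobulin = 670,
                                                 gamma_globulin = 158,
                                                 ovalbumin = 44,
                                                 myoglobin = 17),
                             noise_sd_ml = 0.05, seed = 20121024L) {
  if (slope >= 0) stop("calibration slope must be negative", call. = FALSE)
  stopifnot(true_state > 0, monomer_kda > 0)
  vol_of_mass <- function(m) (log10(m) - intercept) / slope
  with_local_seed(seed, {
    v_sample <- vol_of_mass(true_state * monomer_kda) +
      rnorm(1, 0, noise_sd_ml)
    list(
      standards = tibble::tibble(name = names(standard_masses),
                                 mass_kda = unname(standard_masses),
                                 elution_volume_ml = vol_of_mass(unname(standard_masses))),
      samples = tibble::tibble(name = "sample",
                               elution_volume_ml = v_sample),
      true_state = true_state, monomer_kda = monomer_kda
    )
  })
}

#' Generate a toy PDB structure with prescribed ligand distances
#'
#' Writes a valid fixed-column PDB in which a single-atom ligand sits at the
#' origin and each requested residue is placed along its own direction so
#' that its nearest heavy atom lies at exactly the prescribed distance from
#' the ligand (to coordinate precision, 1e-3 Angstrom). Each residue gets
#' three backbone/side-chain atoms (CB at the target distance, CA and N
#' farther out). Used as a stand-in fixture for chromophore-proximity
#' selection; it is synthetic, not a real protein fold.
#'
#' @param distances Data frame with columns `resno` and `distance_ang`
#'   (optionally `resname`, `chain`), or a numeric vector of distances in
#'   Angstrom (residues numbered sequentially).
#' @param ligand_name Ligand residue name (default `"FMN"`).
#' @return A single string of PDB text.
#' @export
generate_toy_structure <- function(distances, ligand_name = "FMN") {
  if (is.numeric(distances)) {
    distances <- tibble::tibble(resno = seq_along(distances),
                                distance_ang = as.numeric(distances))
  }
  distances <- tibble::as_tibble(distances)
  if (!all(c("resno", "distance_ang") %in% names(distances))) {
    stop("`distances` needs columns resno and distance_ang", call. = FALSE)
  }
  if (any(distances$distance_ang <= 0)) {
    stop("infeasible distance spec: distances must be positive", call. = FALSE)
  }
  if (!"resname" %in% names(distances)) distances$resname <- "ALA"
  if (!"chain" %in% names(distances)) distances$chain <- "A"

  n <- nrow(distances)
  # deterministic golden-spiral directions so residues never collide
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / max(n, 2)
  theta <- i * 2.399963229728653
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(theta), r * sin(theta), z)

  fmt_atom <- function(record, serial, name, resname, chain, resno, xyz, elem) {
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, sprintf(" %-3s", name), resname, chain, resno,
            xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
  }
  lines <- character(0)
  serial <- 1L
  for (j in seq_len(n)) {
    d <- distances$distance_ang[j]
    u <- dirs[j, ]
    atoms <- list(CB = d * u, CA = (d + 1.5) * u, N = (d + 2.4) * u)
    elems <- c(CB = "C", CA = "C", N = "N")
    for (a in names(atoms)) {
      lines <- c(lines, fmt_atom("ATOM", serial, a, distances$resname[j],
                                 distances$chain[j], distances$resno[j],
                                 round(atoms[[a]], 3), elems[[a]]))
      serial <- serial + 1L
    }
  }
  lines <- c(lines, "TER",
             fmt_atom("HETATM", serial, "C1", ligand_name, "L", 1L,
                      c(0, 0, 0), "C"),
             "END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write every simulated input the pipeline consumes
#'
#' Materializes one full synthetic campaign under `dir`: plate scans CSV,
#' ground-truth TSV, photophysics CSV, SEC standards/samples CSVs and a toy
#' PDB. All outputs are deterministic under the config seed.
#'
#' @param dir Output directory (created if needed).
#' @param config A [generator_config()].
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_inputs <- function(dir, config = generator_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scans = file.path(dir, "plate_scans.csv"),
             truth = file.path(dir, "ground_truth.tsv"),
             photophysics = file.path(dir, "photophysics.csv"),
             sec_standards = file.path(dir, "sec_standards.csv"),
             sec_samples = file.path(dir, "sec_samples.csv"),
             pdb = file.path(dir, "toy_structure.pdb"))
  sim <- simulate_screen(config)
  utils::write.csv(sim$scans, paths[["scans"]], row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ph <- generate_photophysics_series(true_qy = 0.30, true_f_holo = 0.49,
                                     seed = substream_seed(config$seed, 21L))
  ph_tab <- rbind(cbind(role = "protein", ph$sample),
                  cbind(role = "fmn_standard", ph$standard))
  utils::write.csv(ph_tab, paths[["photophysics"]], row.names = FALSE)
  sec <- generate_sec_run(seed = substream_seed(config$seed, 22L))
  utils::write.csv(sec$standards, paths[["sec_standards"]], row.names = FALSE)
  utils::write.csv(sec$samples, paths[["sec_samples"]], row.names = FALSE)
  writeLines(generate_toy_structure(c(2.9, 2.5, 3.5, 4.2)), paths[["pdb"]])
  invisible(paths)
}
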