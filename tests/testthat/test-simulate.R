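test_that("generation is fully deterministic under a fixed seed", {
  cfg <- generator_config(seed = 77, clones_per_library = 30L)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$scans, b$scans)

  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_simulated_inputs(d1, cfg)
  p2 <- write_simulated_inputs(d2, cfg)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("library draws respect the codon set and configured proportions", {
  cfg <- generator_config(seed = 123, clones_per_library = 10000L)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib), 10000L)
  nnk <- expand_degenerate_codon("NNK")
  expect_true(all(lib$codon %in% nnk))
  expect_identical(unname(Biostrings::GENETIC_CODE[lib$codon]), lib$residue)

  # codon frequencies within 3 binomial SEs of 1/32
  freq <- table(factor(lib$codon, levels = nnk)) / nrow(lib)
  se <- sqrt((1 / 32) * (31 / 32) / nrow(lib))
  expect_true(all(abs(freq - 1 / 32) <= 3 * se))

  # class frequencies within 3 binomial SEs of the configured proportions
  for (cl in names(cfg$class_proportions)) {
    p <- cfg$class_proportions[[cl]]
    se_cl <- sqrt(p * (1 - p) / nrow(lib))
    expect_lte(abs(mean(lib$true_class == cl) - p), 3 * se_cl)
  }

  # folds consistent with their class under the default thresholds
  th <- screen_thresholds()
  expect_true(all(lib$true_fold[lib$true_class == "beneficial"] >=
                    th$beneficial_fold))
  expect_true(all(lib$true_fold[lib$true_class == "deleterious"] <=
                    th$deleterious_fold))
  neut <- lib$true_fold[lib$true_class == "neutral"]
  expect_true(all(neut > th$deleterious_fold & neut < th$beneficial_fold))
})

test_that("single-class configurations degenerate correctly", {
  cfg <- generator_config(seed = 9, clones_per_library = 50L,
                          class_proportions = c(beneficial = 0,
                                                deleterious = 0, neutral = 1))
  lib <- generate_library(cfg)
  expect_true(all(lib$true_class == "neutral"))
  expect_true(all(abs(lib$true_fold - 1) < 0.4))
  expect_error(generator_config(class_proportions = c(beneficial = 0.5,
                                                      deleterious = 0.2,
                                                      neutral = 0.2)),
               "sum to 1")
})

test_that("noiseless spectra round-trip through the screen metrics", {
  cfg <- generator_config()
  bg <- generate_emission_spectrum(list(true_fold = 0, true_peak_nm = 495),
                                   cfg, noise = FALSE)
  wt <- generate_emission_spectrum(list(true_fold = 1, true_peak_nm = 495),
                                   cfg, noise = FALSE)
  mut <- generate_emission_spectrum(list(true_fold = 2, true_peak_nm = 495),
                                    cfg, noise = FALSE)
  wt_pm <- peak_metrics(subtract_background(wt, bg))
  mut_pm <- peak_metrics(subtract_background(mut, bg))
  expect_equal(wt_pm$peak_wavelength_nm, 495)
  rec <- classify_clone(mut_pm, wt_pm)
  expect_equal(rec$fold_change, 2)
  expect_identical(rec$class, "beneficial")  # inclusive twofold boundary
})

test_that("boundary-fold clones are recalled perfectly without noise", {
  cfg <- generator_config(seed = 55, clones_per_library = 25L,
                          noise_sd_fraction = 0,
                          class_proportions = c(beneficial = 1,
                                                deleterious = 0, neutral = 0),
                          beneficial_fold_range = c(2, 2))
  sim <- simulate_screen(cfg)
  recs <- screen_records(process_plate_scans(sim$scans))
  expect_true(all(recs$final_class == "beneficial"))
})

test_that("generated artifacts parse through their readers without warnings", {
  cfg <- generator_config(seed = 31, clones_per_library = 12L)
  dir <- tempfile()
  paths <- write_simulated_inputs(dir, cfg)
  expect_no_warning(scans <- read_plate_scans(paths[["scans"]]))
  expect_no_warning(recs <- screen_records(process_plate_scans(scans)))
  expect_equal(nrow(recs), 12L)
  expect_no_warning(model <- parse_structure(paths[["pdb"]]))
  expect_s3_class(model, "structure_model")
  expect_no_warning({
    std <- utils::read.csv(paths[["sec_standards"]])
    cal <- fit_calibration(std)
  })
  ph <- utils::read.csv(paths[["photophysics"]])
  expect_no_warning(
    quantum_yield(ph[ph$role == "protein", ], ph[ph$role == "fmn_standard", ]))
  unlink(dir, recursive = TRUE)
})

test_that("noiseless photophysics and SEC wiring return the true parameters", {
  ph <- generate_photophysics_series(true_qy = 0.27, true_f_holo = 0.33,
                                     noise_fraction = 0)
  expect_equal(quantum_yield(ph$sample, ph$standard)$value, 0.27)
  f <- holo_fraction(holoprotein_concentration(ph$sample$absorbance_450),
                     ph$sample$concentration)
  expect_equal(f, rep(0.33, 5))

  run <- generate_sec_run(true_state = 2, noise_sd_ml = 0)
  tab <- sec_oligomer_table(fit_calibration(run$standards), run$samples)
  expect_equal(tab$state_value, 2, tolerance = 1e-9)
  expect_identical(tab$state_label, "dimer")

  run181 <- generate_sec_run(true_state = 1.81, noise_sd_ml = 0)
  tab181 <- sec_oligomer_table(fit_calibration(run181$standards),
                               run181$samples)
  expect_equal(tab181$state_value, 1.81, tolerance = 1e-9)
  expect_identical(tab181$state_label, "dimer")
})

test_that("infeasible structure specs are rejected", {
  expect_error(generate_toy_structure(c(2.5, -1)), "infeasible")
  expect_error(generate_toy_structure(data.frame(resno = 1)), "distance_ang")
})
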