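pm <- function(wl, int) structure(list(peak_wavelength_nm = wl,
                                       peak_intensity = int),
                                  class = "peak_metrics")

test_that("classification thresholds are boundary-inclusive", {
  ref <- pm(495, 100)
  expect_identical(classify_clone(pm(495, 100), ref)$class, "neutral")
  expect_identical(classify_clone(pm(495, 200), ref)$class, "beneficial")
  expect_identical(classify_clone(pm(495, 199.9), ref)$class, "neutral")
  expect_identical(classify_clone(pm(507, 100), ref)$class, "beneficial")
  expect_identical(classify_clone(pm(505, 100), ref)$class, "beneficial")
  expect_identical(classify_clone(pm(504, 100), ref)$class, "neutral")
  expect_identical(classify_clone(pm(485, 100), ref)$class, "beneficial")
  expect_identical(classify_clone(pm(495, 50), ref)$class, "deleterious")
  expect_identical(classify_clone(pm(495, 51), ref)$class, "neutral")
  expect_identical(classify_clone(pm(495, -5), ref)$class, "deleterious")
  expect_error(classify_clone(pm(495, 100), pm(495, 0)), "positive")
})

test_that("self-comparison is neutral and fold/shift are recorded", {
  rec <- classify_clone(pm(495, 123.4), pm(495, 123.4))
  expect_identical(rec$class, "neutral")
  expect_equal(rec$fold_change, 1)
  expect_equal(rec$peak_shift_nm, 0)
})

test_that("threshold configuration is validated", {
  expect_error(screen_thresholds(beneficial_fold = 0.9), "deleterious_fold < 1")
  expect_error(screen_thresholds(sg_window = 4), "odd")
})

test_that("tier confirmation requires beneficial calls in every screen", {
  expect_identical(confirm_across_tiers(c(plate = "beneficial",
                                          flask = "beneficial",
                                          purified = "beneficial")),
                   "beneficial")
  expect_identical(confirm_across_tiers(c(plate = "beneficial",
                                          flask = "neutral")), "neutral")
  expect_identical(confirm_across_tiers(c(plate = "deleterious")),
                   "deleterious")
  expect_identical(confirm_across_tiers(c(plate = "neutral",
                                          flask = "beneficial")), "neutral")
  expect_error(confirm_across_tiers(character(0)), "no tier")
  expect_error(confirm_across_tiers(c(flask = "beneficial")), "plate")
})

test_that("class counts partition the record set", {
  withr::with_seed(5, {
    recs <- tibble::tibble(
      final_class = sample(c("beneficial", "deleterious", "neutral"), 250,
                           replace = TRUE, prob = c(0.05, 0.4, 0.55)))
  })
  s <- summarize_library(recs)
  expect_equal(s$beneficial + s$deleterious + s$neutral, nrow(recs))
  expect_equal(s$pct_beneficial + s$pct_deleterious + s$pct_neutral, 100)
  single <- summarize_library(tibble::tibble(final_class = "beneficial"))
  expect_equal(single$beneficial, 1)
  expect_equal(single$neutral, 0)
})

test_that("aggregating the published screen counts reproduces the class fractions", {
  counts <- utils::read.delim(system.file("extdata", "fbfp_screen_counts.tsv",
                                          package = "lovscreen"))
  tolerant <- summarize_counts(counts[counts$library %in%
                                        c("D52X", "R54X", "Q57X", "R70X",
                                          "W94X", "Y112X"), ])
  expect_equal(round(tolerant$pct_neutral), 82)

  sensitive <- summarize_counts(counts[counts$library %in%
                                         c("F37X", "A53X", "N85X"), ])
  expect_equal(round(sensitive$pct_neutral), 40)
  expect_equal(round(sensitive$pct_deleterious), 60)
})

test_that("summaries reject unknown classes and empty inputs", {
  expect_error(summarize_library(tibble::tibble(final_class = "odd")),
               "unknown class")
  expect_error(summarize_library(tibble::tibble(final_class = character(0))),
               "no records")
  expect_error(summarize_counts(data.frame(beneficial = 1)), "missing columns")
})

test_that("the plate pipeline round-trips written scans and partitions clones", {
  sim <- simulate_screen(generator_config(seed = 314, clones_per_library = 40L),
                         tiers = "plate")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(sim$scans, path, row.names = FALSE)
  scans <- read_plate_scans(path)
  recs <- screen_records(process_plate_scans(scans))
  expect_equal(nrow(recs), 40L)
  s <- summarize_library(recs)
  expect_equal(s$total, 40)
})
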