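#' Screening thresholds for hit calling
#'
#' Criteria for classifying a clone against the wild-type reference:
#' beneficial if its peak intensity is at least `beneficial_fold` times the
#' reference (boundary inclusive) and/or its emission peak is shifted by at
#' least `beneficial_shift_nm`; deleterious if the fold change drops to
#' `deleterious_fold` or below; neutral otherwise. The deleterious default
#' of 0.5 is the symmetric counterpart of the two-fold beneficial criterion
#' on a log scale.
#'
#' @param beneficial_fold Fold-change threshold for a brightness hit
#'   (default 2).
#' @param beneficial_shift_nm Peak-shift threshold in nm (default 10).
#' @param deleterious_fold Fold change at or below which a clone is called
#'   deleterious (default 0.5).
#' @param sg_order,sg_window Savitzky-Golay smoothing parameters used by the
#'   plate pipeline (defaults 3 and 5).
#' @return A `screen_thresholds` list.
#' @export
screen_thresholds <- function(beneficial_fold = 2, beneficial_shift_nm = 10,
                              deleterious_fold = 0.5,
                              sg_order = 3L, sg_window = 5L) {
  if (!(deleterious_fold < 1 && 1 < beneficial_fold)) {
    stop("need deleterious_fold < 1 < beneficial_fold", call. = FALSE)
  }
  if (sg_window %% 2L != 1L || sg_window <= sg_order) {
    stop("`sg_window` must be odd and exceed `sg_order`", call. = FALSE)
  }
  structure(list(beneficial_fold = beneficial_fold,
                 beneficial_shift_nm = beneficial_shift_nm,
                 deleterious_fold = deleterious_fold,
                 sg_order = sg_order, sg_window = sg_window),
            class = "screen_thresholds")
}

#' Classify a clone against the wild-type reference
#'
#' @param sample_metrics,reference_metrics [peak_metrics()] of the clone and
#'   of the wild-type reference (background-subtracted, smoothed).
#' @param thresholds A [screen_thresholds()] object.
#' @return One-row tibble with `class` (`"beneficial"`, `"neutral"`,
#'   `"deleterious"`), `fold_change` and `peak_shift_nm`.
#' @export
classify_clone <- function(sample_metrics, reference_metrics,
                           thresholds = screen_thresholds()) {
  if (!is.finite(reference_metrics$peak_intensity) ||
      reference_metrics$peak_intensity <= 0) {
    stop("reference peak intensity must be positive", call. = FALSE)
  }
  fold <- max(0, sample_metrics$peak_intensity) / reference_metrics$peak_intensity
  shift <- sample_metrics$peak_wavelength_nm - reference_metrics$peak_wavelength_nm
  class <- if (fold >= thresholds$beneficial_fold ||
               abs(shift) >= thresholds$beneficial_shift_nm) {
    "beneficial"
  } else if (fold <= thresholds$deleterious_fold) {
    "deleterious"
  } else {
    "neutral"
  }
  tibble::tibble(class = class, fold_change = fold, peak_shift_nm = shift)
}

#' Confirm a classification across screening tiers
#'
#' A clone is finally beneficial only if it meets the beneficial criteria in
#' every tier in which it was screened (96-well plate, shake flask, purified
#' protein); it is deleterious if the plate tier called it deleterious, and
#' neutral otherwise.
#'
#' @param tier_classes Named character vector/list of per-tier classes; must
#'   contain a `"plate"` entry.
#' @return Final class string.
#' @examples
#' confirm_across_tiers(c(plate = "beneficial", flask = "neutral")) # "neutral"
#' @export
confirm_across_tiers <- function(tier_classes) {
  tier_classes <- unlist(tier_classes)
  if (length(tier_classes) == 0L) stop("no tier classes supplied", call. = FALSE)
  if (!"plate" %in% names(tier_classes)) {
    stop("the plate tier is required", call. = FALSE)
  }
  if (all(tier_classes == "beneficial")) {
    "beneficial"
  } else if (tier_classes[["plate"]] == "deleterious") {
    "deleterious"
  } else {
    "neutral"
  }
}

#' Process long-format plate scans into per-tier screen records
#'
#' Runs the plate pipeline on a long-format scan table (columns `plate`,
#' `well`, `role`, `tier`, `clone`, `excitation_nm`, `wavelength_nm`,
#' `intensity`): per plate and tier, the background is the mean spectrum of
#' all background-role wells and the reference is the mean background-
#' subtracted spectrum of the wild-type reference wells; every sample clone
#' is background-subtracted, Savitzky-Golay smoothed, reduced to peak
#' metrics over the full scan window and classified.
#'
#' @param scans Data frame of long-format scans (see above), e.g. from
#'   [read_plate_scans()] or [simulate_screen()].
#' @param thresholds A [screen_thresholds()] object.
#' @return Tibble with one row per clone and tier: `clone`, `tier`, `class`,
#'   `fold_change`, `peak_shift_nm`.
#' @export
process_plate_scans <- function(scans, thresholds = screen_thresholds()) {
  needed <- c("plate", "well", "role", "tier", "clone", "wavelength_nm",
              "intensity")
  missing <- setdiff(needed, names(scans))
  if (length(missing) > 0L) {
    stop("scan table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(tibble::as_tibble(scans),
                  list(scans$plate, scans$tier), drop = TRUE)
  dplyr::bind_rows(lapply(groups, process_one_plate, thresholds = thresholds))
}

process_one_plate <- function(scan, thresholds) {
  tier <- scan$tier[1L]
  grid <- sort(unique(scan$wavelength_nm))
  mean_spectrum <- function(rows, role) {
    m <- tapply(rows$intensity, rows$wavelength_nm, mean)
    emission_spectrum(as.numeric(names(m)), as.numeric(m), role = role,
                      tier = tier)
  }
  bg_rows <- scan[scan$role == "background", , drop = FALSE]
  ref_rows <- scan[scan$role == "wt_reference", , drop = FALSE]
  if (nrow(bg_rows) == 0L || nrow(ref_rows) == 0L) {
    stop("each plate needs background and wt_reference wells", call. = FALSE)
  }
  background <- mean_spectrum(bg_rows, "background")
  reference <- mean_spectrum(ref_rows, "wt_reference") |>
    subtract_background(background) |>
    savitzky_golay(order = thresholds$sg_order, window = thresholds$sg_window)
  ref_metrics <- peak_metrics(reference)

  samples <- scan[scan$role == "sample", , drop = FALSE]
  per_clone <- split(samples, samples$clone)
  recs <- lapply(names(per_clone), function(cl) {
    rows <- per_clone[[cl]]
    rows <- rows[order(rows$wavelength_nm), , drop = FALSE]
    sp <- emission_spectrum(rows$wavelength_nm, rows$intensity,
                            clone = cl, role = "sample", tier = tier) |>
      subtract_background(background) |>
      savitzky_golay(order = thresholds$sg_order, window = thresholds$sg_window)
    cls <- classify_clone(peak_metrics(sp), ref_metrics, thresholds)
    dplyr::mutate(cls, clone = cl, tier = tier)
  })
  dplyr::bind_rows(recs)[, c("clone", "tier", "class", "fold_change",
                             "peak_shift_nm")]
}

#' Collapse per-tier records into final confirmed screen records
#'
#' @param tier_records Tibble from [process_plate_scans()].
#' @return One row per clone with the per-tier classes, the plate-tier fold
#'   change and peak shift, and `final_class` from
#'   [confirm_across_tiers()].
#' @export
screen_records <- function(tier_records) {
  per_clone <- split(tibble::as_tibble(tier_records), tier_records$clone)
  recs <- lapply(per_clone, function(rows) {
    classes <- setNames(rows$class, rows$tier)
    plate <- rows[rows$tier == "plate", , drop = FALSE]
    if (nrow(plate) == 0L) stop("clone ", rows$clone[1L],
                                " has no plate-tier record", call. = FALSE)
    tibble::tibble(
      clone = rows$clone[1L],
      fold_change = plate$fold_change[1L],
      peak_shift_nm = plate$peak_shift_nm[1L],
      plate_class = classes[["plate"]],
      flask_class = if ("flask" %in% names(classes)) classes[["flask"]] else NA_character_,
      purified_class = if ("purified" %in% names(classes)) classes[["purified"]] else NA_character_,
      final_class = confirm_across_tiers(classes)
    )
  })
  dplyr::bind_rows(recs)
}

#' Summarize a library screen into per-class counts and fractions
#'
#' @param records Tibble with a class column (default `final_class`), e.g.
#'   from [screen_records()].
#' @param class_col Name of the class column.
#' @return One-row tibble with `beneficial`, `deleterious`, `neutral`
#'   counts, `total`, and percentage columns `pct_beneficial`,
#'   `pct_deleterious`, `pct_neutral`.
#' @export
summarize_library <- function(records, class_col = "final_class") {
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  cls <- records[[class_col]]
  if (is.null(cls)) stop("column '", class_col, "' not found", call. = FALSE)
  bad <- setdiff(unique(cls), c("beneficial", "deleterious", "neutral"))
  if (length(bad) > 0L) stop("unknown class: ", paste(bad, collapse = ", "),
                             call. = FALSE)
  counts <- c(beneficial = sum(cls == "beneficial"),
              deleterious = sum(cls == "deleterious"),
              neutral = sum(cls == "neutral"))
  summarize_counts(tibble::as_tibble(as.list(counts)))
}

#' Aggregate classification count tables
#'
#' Sums per-library beneficial/deleterious/neutral counts (one row per
#' library target) and reports totals with percentage fractions — the form
#' in which site-saturation screens are usually tabulated. The package ships
#' the published FbFP site-saturation screen counts as
#' `system.file("extdata", "fbfp_screen_counts.tsv", package = "lovscreen")`.
#'
#' @param counts Data frame with numeric columns `beneficial`,
#'   `deleterious`, `neutral` (extra columns are ignored).
#' @return One-row tibble of summed counts, `total`, and `pct_*`
#'   percentages.
#' @export
summarize_counts <- function(counts) {
  needed <- c("beneficial", "deleterious", "neutral")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0L) {
    stop("count table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tot <- vapply(counts[needed], sum, numeric(1))
  total <- sum(tot)
  if (total == 0) stop("no clones in count table", call. = FALSE)
  tibble::tibble(
    beneficial = tot[["beneficial"]],
    deleterious = tot[["deleterious"]],
    neutral = tot[["neutral"]],
    total = total,
    pct_beneficial = 100 * tot[["beneficial"]] / total,
    pct_deleterious = 100 * tot[["deleterious"]] / total,
    pct_neutral = 100 * tot[["neutral"]] / total
  )
}

#' Read long-format plate scans from CSV
#'
#' @param path CSV with columns `plate`, `well`, `role`, `tier`, `clone`,
#'   `excitation_nm`, `wavelength_nm`, `intensity`.
#' @return Tibble of scans.
#' @export
read_plate_scans <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
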