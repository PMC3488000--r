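#' Fit a size-exclusion chromatography mass calibration
#'
#' Ordinary least squares of `log10(mass_kda)` on elution volume for a set
#' of globular protein standards — the semi-logarithmic calibration line of
#' a gel-filtration column. The slope must be negative (larger proteins
#' elute earlier); at least three standards with distinct volumes are
#' required.
#'
#' @param standards Data frame with columns `mass_kda` and
#'   `elution_volume_ml` (a `name` column is carried along if present).
#' @return A `sec_calibration` with `slope`, `intercept`, `r_squared` and
#'   the standards used.
#' @export
fit_calibration <- function(standards) {
  standards <- tibble::as_tibble(standards)
  needed <- c("mass_kda", "elution_volume_ml")
  missing <- setdiff(needed, names(standards))
  if (length(missing) > 0L) {
    stop("standards table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(standards) < 3L) {
    stop("at least 3 standards are required", call. = FALSE)
  }
  if (anyDuplicated(standards$elution_volume_ml)) {
    stop("duplicate elution volumes among standards", call. = FALSE)
  }
  if (any(standards$mass_kda <= 0) || any(standards$elution_volume_ml <= 0)) {
    stop("standard masses and volumes must be positive", call. = FALSE)
  }
  fit <- stats::lm(log10(mass_kda) ~ elution_volume_ml, data = standards)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) {
    stop("calibration slope must be negative (larger proteins elute earlier)",
         call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log10(standards$mass_kda) - mean(log10(standards$mass_kda)))^2)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
         r_squared = 1 - ss_res / ss_tot, standards = standards),
    class = "sec_calibration"
  )
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("<sec_calibration> log10(kDa) = %.4f %+.4f * V_ml (r^2 = %.4f, %d standards)\n",
              x$intercept, x$slope, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Predict molecular mass from an elution volume
#'
#' Inverts the calibration: `mass = 10^(intercept + slope * V)`. A warning
#' is issued when `V` lies outside the calibrated volume range
#' (extrapolation).
#'
#' @param calibration A [fit_calibration()] result.
#' @param elution_volume_ml Elution volume(s) in mL.
#' @return Net molecular mass in kDa.
#' @export
mass_from_elution <- function(calibration, elution_volume_ml) {
  stopifnot(inherits(calibration, "sec_calibration"))
  rng <- range(calibration$standards$elution_volume_ml)
  if (any(elution_volume_ml < rng[1] | elution_volume_ml > rng[2])) {
    warning("elution volume outside the calibrated range; extrapolating")
  }
  10^(calibration$intercept + calibration$slope * elution_volume_ml)
}

#' Oligomeric state from a net molecular mass
#'
#' Divides the net (SEC-derived) mass by the monomer mass and labels the
#' nearest integer state: values in [1.5, 2.5) are dimers, and so on. An
#' FbFP monomer is 16.3 kDa, so a 29.5 kDa species has state 1.81 (dimer).
#'
#' @param net_mass_kda Net mass in kDa (> 0).
#' @param monomer_mass_kda Monomer mass in kDa (default 16.3).
#' @return An `oligomer_estimate` with `net_mass_kda`, `monomer_mass_kda`,
#'   `state_value` and `state_label`.
#' @examples
#' oligomeric_state(29.5)$state_label # "dimer"
#' @export
oligomeric_state <- function(net_mass_kda, monomer_mass_kda = 16.3) {
  if (any(net_mass_kda <= 0) || any(monomer_mass_kda <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  value <- net_mass_kda / monomer_mass_kda
  k <- pmax(1L, as.integer(floor(value + 0.5)))
  labels <- c("monomer", "dimer", "trimer", "tetramer", "pentamer", "hexamer")
  label <- ifelse(k <= length(labels), labels[pmin(k, length(labels))],
                  paste0(k, "-mer"))
  structure(list(net_mass_kda = net_mass_kda,
                 monomer_mass_kda = monomer_mass_kda,
                 state_value = value, state_label = label),
            class = "oligomer_estimate")
}

#' @export
print.oligomer_estimate <- function(x, ...) {
  cat(sprintf("<oligomer_estimate> %.1f kDa / %.1f kDa = %.2f (%s)\n",
              x$net_mass_kda[1L], x$monomer_mass_kda[1L],
              x$state_value[1L], x$state_label[1L]))
  invisible(x)
}

#' Oligomeric states for a table of SEC runs
#'
#' Convenience wrapper: fits nothing, just applies an existing calibration
#' to sample elution volumes and derives oligomeric states.
#'
#' @param calibration A [fit_calibration()] result.
#' @param samples Data frame with columns `name` and `elution_volume_ml`.
#' @param monomer_mass_kda Monomer mass in kDa (default 16.3).
#' @return Tibble with `name`, `elution_volume_ml`, `net_mass_kda`,
#'   `state_value`, `state_label`.
#' @export
sec_oligomer_table <- function(calibration, samples, monomer_mass_kda = 16.3) {
  samples <- tibble::as_tibble(samples)
  mass <- mass_from_elution(calibration, samples$elution_volume_ml)
  est <- oligomeric_state(mass, monomer_mass_kda)
  tibble::tibble(name = samples$name,
                 elution_volume_ml = samples$elution_volume_ml,
                 net_mass_kda = mass,
                 state_value = est$state_value,
                 state_label = est$state_label)
}
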