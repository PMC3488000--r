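#' Integrate an emission spectrum
#'
#' Trapezoidal integral of the intensities over a wavelength interval
#' (default the full 470-600 nm FbFP emission window) — the quantity F used
#' when ratioing emission per unit absorbance against a quantum-yield
#' standard.
#'
#' @param spectrum An `emission_spectrum`.
#' @param interval Length-2 interval in nm; must lie within the scan.
#' @return Integral in intensity-units x nm.
#' @export
integrate_emission <- function(spectrum, interval = c(470, 600)) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelengths
  if (length(interval) != 2L || interval[1] >= interval[2]) {
    stop("`interval` must be an increasing length-2 range", call. = FALSE)
  }
  if (interval[1] < min(wl) || interval[2] > max(wl)) {
    stop("integration interval extends outside the scan", call. = FALSE)
  }
  keep <- wl >= interval[1] & wl <= interval[2]
  pracma::trapz(wl[keep], spectrum$intensities[keep])
}

#' One photophysics measurement
#'
#' Pairs the integrated emission of a sample with its absorbance at 450 nm
#' (and optionally its total protein concentration from a Bradford assay and
#' the cuvette path length) for quantum-yield and holoprotein-fraction
#' calculations.
#'
#' @param integrated_emission Integrated emission, a.u. x nm.
#' @param absorbance_450 Absorbance at 450 nm (>= 0).
#' @param total_protein_conc Total protein concentration, molar (optional).
#' @param path_length_cm Cuvette path length in cm (default 1).
#' @return One-row tibble.
#' @export
photophysics_sample <- function(integrated_emission, absorbance_450,
                                total_protein_conc = NA_real_,
                                path_length_cm = 1) {
  if (any(absorbance_450 < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(path_length_cm <= 0)) stop("path length must be > 0", call. = FALSE)
  tibble::tibble(integrated_emission = integrated_emission,
                 absorbance_450 = absorbance_450,
                 total_protein_conc = total_protein_conc,
                 path_length_cm = path_length_cm)
}

#' Relative fluorescence quantum yield against a standard
#'
#' Estimates the quantum yield of a sample from paired (integrated emission
#' F, absorbance A) readings by ratioing against a standard of known quantum
#' yield (free FMN, QY = 0.27, for FbFPs):
#' `QY = (F_s/A_s) / (F_ref/A_ref) * QY_ref`.
#' Each concentration series is aggregated before the ratio is formed:
#' either as the mean of per-sample F/A values (default) or as the slope of
#' a through-origin regression of F on A. The standard deviation follows by
#' first-order (delta-method) propagation of the standard errors of the two
#' aggregated F/A values; it is 0 when both series have a single point.
#'
#' @param samples,standard_samples Data frames with columns
#'   `integrated_emission` and `absorbance_450` (see
#'   [photophysics_sample()]); all absorbances must be positive.
#' @param standard_qy Known quantum yield of the standard (default 0.27,
#'   free FMN).
#' @param method `"mean_ratio"` (default) or `"slope"` (through-origin
#'   regression of F on A).
#' @return A `qy_estimate` with `value`, `sd`, sample sizes and `method`.
#' @export
quantum_yield <- function(samples, standard_samples, standard_qy = 0.27,
                          method = c("mean_ratio", "slope")) {
  method <- match.arg(method)
  if (standard_qy <= 0 || standard_qy > 1) {
    stop("`standard_qy` must lie in (0, 1]", call. = FALSE)
  }
  agg <- function(df, label) {
    if (nrow(df) == 0L) stop("empty ", label, " series", call. = FALSE)
    if (any(df$absorbance_450 <= 0)) {
      stop(label, " series contains non-positive absorbance", call. = FALSE)
    }
    if (method == "mean_ratio") {
      r <- df$integrated_emission / df$absorbance_450
      se <- if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else 0
      list(value = mean(r), se = se, n = length(r))
    } else {
      if (nrow(df) == 1L) {
        list(value = df$integrated_emission / df$absorbance_450, se = 0, n = 1L)
      } else {
        fit <- stats::lm(integrated_emission ~ 0 + absorbance_450, data = df)
        s2 <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
        list(value = unname(stats::coef(fit)[1L]),
             se = sqrt(s2 / sum(df$absorbance_450^2)), n = nrow(df))
      }
    }
  }
  s <- agg(tibble::as_tibble(samples), "sample")
  r <- agg(tibble::as_tibble(standard_samples), "standard")
  value <- s$value / r$value * standard_qy
  sd <- value * sqrt((s$se / s$value)^2 + (r$se / r$value)^2)
  structure(list(value = value, sd = sd, n_sample = s$n, n_standard = r$n,
                 standard_qy = standard_qy, method = method),
            class = "qy_estimate")
}

#' @export
print.qy_estimate <- function(x, ...) {
  cat(sprintf("<qy_estimate> QY = %.3f +/- %.3f (%s; n = %d vs %d standard)\n",
              x$value, x$sd, x$method, x$n_sample, x$n_standard))
  invisible(x)
}

#' Holoprotein concentration from 450 nm absorbance (Beer-Lambert)
#'
#' Only the FMN-bound holoprotein absorbs at 450 nm, so its concentration is
#' `C_holo = A450 / (epsilon * l)` with the molar absorptivity of FMN
#' (12500 per M per cm) and the cuvette path length.
#'
#' @param absorbance_450 Absorbance at 450 nm (>= 0); vectorized.
#' @param epsilon Molar absorptivity, per M per cm (default 12500).
#' @param path_length_cm Path length in cm (default 1).
#' @return Concentration in mol/L.
#' @examples
#' holoprotein_concentration(0.125) # 1e-5 M = 10 uM
#' @export
holoprotein_concentration <- function(absorbance_450, epsilon = 12500,
                                      path_length_cm = 1) {
  if (any(epsilon <= 0) || any(path_length_cm <= 0)) {
    stop("epsilon and path length must be positive", call. = FALSE)
  }
  if (any(absorbance_450 < 0)) stop("absorbance must be >= 0", call. = FALSE)
  absorbance_450 / (epsilon * path_length_cm)
}

#' Fraction of fluorescent holoprotein
#'
#' Ratio of the Beer-Lambert holoprotein concentration to the total protein
#' concentration (Bradford). Ratios marginally above 1 (up to `tolerance`
#' relative excess, default 5%) are clamped to 1 with a warning; anything
#' larger signals inconsistent measurements and is an error. Vectorized.
#'
#' @param c_holo Holoprotein concentration, molar.
#' @param total_protein_conc Total protein concentration, molar (> 0).
#' @param tolerance Allowed relative excess over 1 before erroring
#'   (default 0.05).
#' @return Numeric fraction(s) in [0, 1].
#' @export
holo_fraction <- function(c_holo, total_protein_conc, tolerance = 0.05) {
  if (any(total_protein_conc <= 0)) {
    stop("total protein concentration must be > 0", call. = FALSE)
  }
  f <- c_holo / total_protein_conc
  if (any(f > 1 + tolerance)) {
    stop(sprintf("holoprotein fraction %.3f exceeds 1 + %.0f%%: inconsistent measurements",
                 max(f), 100 * tolerance), call. = FALSE)
  }
  over <- f > 1
  if (any(over)) {
    warning(sprintf("%d holoprotein fraction(s) marginally above 1 clamped to 1",
                    sum(over)))
    f[over] <- 1
  }
  f
}

#' Fold enhancement with propagated uncertainty
#'
#' Ratio of two uncertain values with the first-order (delta-method)
#' standard deviation under independence:
#' `sd = ratio * sqrt((sd_a/a)^2 + (sd_b/b)^2)`. Reported fold values are
#' conventionally rounded to 2 significant figures via [format_fold()];
#' full precision is kept here.
#'
#' @param a,b Values (numerator, denominator); `b` must be positive.
#' @param a_sd,b_sd Their standard deviations (default 0).
#' @return List with `value` and `sd`.
#' @examples
#' fold_with_error(0.30, 0.17, 0.01, 0.0)$value # 1.7647
#' @export
fold_with_error <- function(a, b, a_sd = 0, b_sd = 0) {
  if (any(b <= 0)) stop("denominator must be positive", call. = FALSE)
  value <- a / b
  sd <- value * sqrt((a_sd / a)^2 + (b_sd / b)^2)
  list(value = value, sd = sd)
}

#' Round a fold enhancement for reporting
#'
#' @param fold A [fold_with_error()] result or a numeric value.
#' @param digits Significant figures (default 2).
#' @return Numeric value rounded to `digits` significant figures.
#' @export
format_fold <- function(fold, digits = 2L) {
  v <- if (is.list(fold)) fold$value else fold
  signif(v, digits)
}
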