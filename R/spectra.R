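#' Construct an emission spectrum
#'
#' The unit all spectral operations flow through: a strictly increasing
#' wavelength grid (by convention 470-600 nm at 1 nm steps for FbFP
#' screening, excitation 450 nm) with matching intensities and acquisition
#' metadata.
#'
#' @param wavelengths Strictly increasing numeric grid, nm.
#' @param intensities Finite intensities (arbitrary units), same length.
#' @param excitation_nm Excitation wavelength (default 450).
#' @param well,clone Optional well / clone identifiers.
#' @param role One of `"sample"`, `"wt_reference"`, `"background"`.
#' @param tier One of `"plate"`, `"flask"`, `"purified"`.
#' @return An `emission_spectrum` object.
#' @export
emission_spectrum <- function(wavelengths, intensities, excitation_nm = 450,
                              well = NA_character_, clone = NA_character_,
                              role = c("sample", "wt_reference", "background"),
                              tier = c("plate", "flask", "purified")) {
  role <- match.arg(role)
  tier <- match.arg(tier)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities differ in length", call. = FALSE)
  }
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         excitation_nm = excitation_nm, well = well, clone = clone,
         role = role, tier = tier),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %g-%g nm (%d points), ex %g nm, role %s, tier %s\n",
              min(x$wavelengths), max(x$wavelengths), length(x$wavelengths),
              x$excitation_nm, x$role, x$tier))
  invisible(x)
}

#' Subtract a background spectrum
#'
#' Pointwise subtraction on identical wavelength grids (e.g. removal of the
#' autofluorescence measured in uninduced cells). Negative differences are
#' retained, not clipped. Metadata is carried from the sample.
#'
#' @param sample,background `emission_spectrum` objects on the same grid.
#' @return The background-subtracted `emission_spectrum`.
#' @export
subtract_background <- function(sample, background) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(background, "emission_spectrum"))
  if (length(sample$wavelengths) != length(background$wavelengths) ||
      any(sample$wavelengths != background$wavelengths)) {
    stop("wavelength grids differ between sample and background", call. = FALSE)
  }
  out <- sample
  out$intensities <- sample$intensities - background$intensities
  out
}

#' Savitzky-Golay smoothing of an emission spectrum
#'
#' Local least-squares polynomial smoothing with the central projection row
#' of the Savitzky-Golay matrix (order 3, frame 5 by default, the standard
#' choice for 1 nm plate-reader scans). Edges are handled by mirror padding:
#' the signal is reflected about its end points, so the output grid is
#' unchanged. Interior points of any polynomial of degree <= `order` are
#' reproduced exactly.
#'
#' @param spectrum An `emission_spectrum`.
#' @param order Polynomial order (default 3).
#' @param window Odd frame size > `order` (default 5).
#' @return The smoothed `emission_spectrum`.
#' @export
savitzky_golay <- function(spectrum, order = 3L, window = 5L) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  if (window <= order) stop("`window` must exceed `order`", call. = FALSE)
  x <- spectrum$intensities
  n <- length(x)
  if (n < window) stop("scan shorter than the smoothing window", call. = FALSE)
  coefs <- as.matrix(signal::sgolay(p = order, n = window))[(window + 1L) / 2L, ]
  h <- (window - 1L) / 2L
  padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  sm <- stats::filter(padded, coefs, method = "convolution", sides = 2L)
  out <- spectrum
  out$intensities <- as.numeric(sm[(h + 1L):(h + n)])
  out
}

#' Peak wavelength and intensity of a spectrum
#'
#' Argmax and max of the intensities over a wavelength search range; ties
#' are broken toward the shorter wavelength.
#'
#' @param spectrum An `emission_spectrum` (usually background-subtracted and
#'   smoothed).
#' @param search_range Length-2 numeric interval in nm, or `NULL` for the
#'   full scan.
#' @return A `peak_metrics` list with `peak_wavelength_nm` and
#'   `peak_intensity`.
#' @export
peak_metrics <- function(spectrum, search_range = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelengths
  keep <- if (is.null(search_range)) {
    rep(TRUE, length(wl))
  } else {
    if (length(search_range) != 2L || search_range[1] > search_range[2]) {
      stop("`search_range` must be an increasing length-2 interval", call. = FALSE)
    }
    wl >= search_range[1] & wl <= search_range[2]
  }
  if (!any(keep)) stop("empty search range", call. = FALSE)
  idx <- which(keep)
  i <- idx[which.max(spectrum$intensities[idx])]  # first max = shortest wavelength
  structure(list(peak_wavelength_nm = wl[i],
                 peak_intensity = spectrum$intensities[i]),
            class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf("<peak_metrics> %g nm, intensity %.4g\n",
              x$peak_wavelength_nm, x$peak_intensity))
  invisible(x)
}
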