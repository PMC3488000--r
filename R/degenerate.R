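#' Expand a degenerate IUPAC codon into its concrete triplets
#'
#' A degenerate codon such as `"NNK"` (N = any base, K = G or T) stands for
#' the set of concrete codons obtained by taking the Cartesian product of the
#' per-position IUPAC expansions. `"NNK"` expands to 4 x 4 x 2 = 32 codons,
#' the building block of site-saturation mutagenesis.
#'
#' @param codon A length-3 string of IUPAC nucleotide codes
#'   (`A C G T R Y S W K M B D H V N`).
#' @return Character vector of concrete triplets, sorted lexicographically.
#' @examples
#' length(expand_degenerate_codon("NNK")) # 32
#' expand_degenerate_codon("ATG")         # "ATG"
#' @export
expand_degenerate_codon <- function(codon) {
  chars <- check_degenerate_codon(codon)
  sets <- strsplit(unname(Biostrings::IUPAC_CODE_MAP[chars]), "", fixed = TRUE)
  grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(paste0(grid[[1]], grid[[2]], grid[[3]]))
}

check_degenerate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    stop("`codon` must be a single string", call. = FALSE)
  }
  codon <- toupper(codon)
  if (nchar(codon) != 3L) {
    stop("degenerate codon must have exactly 3 characters, got ",
         nchar(codon), call. = FALSE)
  }
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC nucleotide code '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  chars
}

#' Amino-acid distribution encoded by a degenerate codon
#'
#' Translates every concrete codon in the expansion with the standard genetic
#' code and returns the induced probability of each residue (codons are
#' equiprobable draws from the degenerate scheme). Stop codons appear as
#' `"*"`; with `include_stop = FALSE` they are removed and the remaining
#' probabilities renormalized.
#'
#' @param codon Degenerate IUPAC triplet.
#' @param include_stop Keep stop codons (`"*"`) in the distribution?
#' @return Named numeric vector of probabilities summing to 1.
#' @examples
#' amino_acid_distribution("NNK")[["*"]] # 1/32 (TAG)
#' @export
amino_acid_distribution <- function(codon, include_stop = TRUE) {
  codons <- expand_degenerate_codon(codon)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  probs <- table(aa) / length(codons)
  probs <- setNames(as.numeric(probs), names(probs))
  if (!include_stop && "*" %in% names(probs)) {
    probs <- probs[names(probs) != "*"]
    if (length(probs) == 0L) {
      stop("degenerate codon encodes only stop codons", call. = FALSE)
    }
    probs <- probs / sum(probs)
  }
  probs[order(names(probs))]
}

#' Construct a degenerate-codon library
#'
#' Bundles a degenerate codon scheme with its expanded variant set and the
#' probability of each variant under unbiased synthesis (every concrete codon
#' equiprobable). At `level = "codon"` the variants are the concrete codons
#' (stop codons count as variants); at `level = "amino_acid"` they are the
#' encoded residues, optionally excluding stops.
#'
#' @param scheme Degenerate IUPAC triplet, e.g. `"NNK"`.
#' @param level Variant level, `"codon"` (default) or `"amino_acid"`.
#' @param include_stop At amino-acid level, keep the stop "residue"?
#' @return A `degenerate_library` object with elements `scheme`, `codons`,
#'   `level`, `include_stop` and `variant_probs`.
#' @examples
#' lib <- degenerate_library("NNK")
#' length(lib$codons) # 32
#' @export
degenerate_library <- function(scheme, level = c("codon", "amino_acid"),
                               include_stop = TRUE) {
  level <- match.arg(level)
  codons <- expand_degenerate_codon(scheme)
  variant_probs <- if (level == "codon") {
    setNames(rep(1 / length(codons), length(codons)), codons)
  } else {
    amino_acid_distribution(scheme, include_stop = include_stop)
  }
  stopifnot(abs(sum(variant_probs) - 1) < 1e-12)
  structure(
    list(scheme = toupper(scheme), codons = codons, level = level,
         include_stop = include_stop, variant_probs = variant_probs),
    class = "degenerate_library"
  )
}

#' @export
print.degenerate_library <- function(x, ...) {
  cat(sprintf("<degenerate_library> scheme %s: %d codons, %d variants at %s level\n",
              x$scheme, length(x$codons), length(x$variant_probs), x$level))
  invisible(x)
}
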