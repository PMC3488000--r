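#' Build a mutagenic primer around a degenerate codon
#'
#' Concatenates concrete DNA flanks around a degenerate triplet, the layout
#' of a site-saturation (e.g. QuikChange-style NNK) mutagenic oligo. The
#' flanks must be plain A/C/G/T; degeneracy is allowed only at the target
#' codon.
#'
#' @param upstream_flank,downstream_flank Concrete DNA strings, each at least
#'   `min_flank` nucleotides.
#' @param scheme Degenerate IUPAC triplet placed between the flanks.
#' @param min_flank Minimum flank length (default 10 nt).
#' @return A `mutagenic_primer` with `sequence`, 0-based `degenerate_start`,
#'   `scheme` and the flanks.
#' @examples
#' p <- build_mutagenic_primer("CGTCAACCCGGCC", "NNK", "GAGCGCCTGACC")
#' p$sequence
#' @export
build_mutagenic_primer <- function(upstream_flank, scheme, downstream_flank,
                                   min_flank = 10L) {
  upstream_flank <- check_concrete_flank(upstream_flank, "upstream", min_flank)
  downstream_flank <- check_concrete_flank(downstream_flank, "downstream", min_flank)
  check_degenerate_codon(scheme)
  scheme <- toupper(scheme)
  primer <- structure(
    list(sequence = paste0(upstream_flank, scheme, downstream_flank),
         degenerate_start = nchar(upstream_flank),
         scheme = scheme,
         upstream_flank = upstream_flank,
         downstream_flank = downstream_flank),
    class = "mutagenic_primer"
  )
  # self-check: a degenerate scheme must validate back to the same codon
  # (a concrete scheme is legal but has nothing to locate)
  if (grepl("[^ACGT]", scheme)) {
    v <- validate_primer(primer$sequence)
    stopifnot(v$degenerate_start == primer$degenerate_start, v$scheme == scheme)
  }
  primer
}

check_concrete_flank <- function(flank, side, min_flank) {
  if (!is.character(flank) || length(flank) != 1L || is.na(flank)) {
    stop(sprintf("%s flank must be a single string", side), call. = FALSE)
  }
  flank <- toupper(flank)
  if (grepl("[^ACGT]", flank)) {
    stop(sprintf("%s flank contains non-A/C/G/T characters; degeneracy is only allowed at the target codon",
                 side), call. = FALSE)
  }
  if (nchar(flank) < min_flank) {
    stop(sprintf("%s flank shorter than %d nt", side, min_flank), call. = FALSE)
  }
  flank
}

#' @export
print.mutagenic_primer <- function(x, ...) {
  cat(sprintf("<mutagenic_primer> %s (%s at 0-based offset %d)\n",
              x$sequence, x$scheme, x$degenerate_start))
  invisible(x)
}

#' Validate a mutagenic primer and locate its degenerate codon
#'
#' Scans an IUPAC nucleotide string for runs of degenerate (non-A/C/G/T)
#' characters. A valid mutagenic primer contains exactly one such run of
#' length 3 — the target codon.
#'
#' @param primer_sequence IUPAC nucleotide string.
#' @return List with the 0-based `degenerate_start` and the `scheme` triplet.
#' @examples
#' validate_primer("CGTCAACCCGGCCNNKGAGCGCCTGACC")
#' @export
validate_primer <- function(primer_sequence) {
  if (!is.character(primer_sequence) || length(primer_sequence) != 1L ||
      is.na(primer_sequence) || nchar(primer_sequence) == 0L) {
    stop("`primer_sequence` must be a single non-empty string", call. = FALSE)
  }
  seq <- toupper(primer_sequence)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC nucleotide code '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  degen <- !chars %in% c("A", "C", "G", "T")
  runs <- rle(degen)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  which_degen <- which(runs$values)
  if (length(which_degen) == 0L) {
    stop("no degenerate block found: primer is a concrete oligo", call. = FALSE)
  }
  if (length(which_degen) > 1L) {
    stop(sprintf("multiple degenerate blocks found (%d); expected exactly one",
                 length(which_degen)), call. = FALSE)
  }
  len <- runs$lengths[which_degen]
  if (len != 3L) {
    stop(sprintf("degenerate block has length %d; expected a 3-nt codon", len),
         call. = FALSE)
  }
  start <- starts[which_degen]
  list(degenerate_start = start - 1L,
       scheme = substr(seq, start, start + 2L))
}

#' Read a degenerate-library primer specification table
#'
#' Reads a TSV with columns `name`, `target_codon_index_1based`, `scheme`,
#' `upstream_flank`, `downstream_flank` and assembles the mutagenic primer
#' for each row. The package ships the FbFP NNK site-saturation panel as an
#' example (`system.file("extdata", "fbfp_nnk_primers.tsv", package =
#' "lovscreen")`).
#'
#' @param path Path to the TSV file.
#' @param min_flank Passed to [build_mutagenic_primer()].
#' @return Tibble with the input columns plus `sequence` and
#'   `degenerate_start`.
#' @export
read_library_spec <- function(path, min_flank = 10L) {
  spec <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "target_codon_index_1based", "scheme",
              "upstream_flank", "downstream_flank")
  missing <- setdiff(needed, names(spec))
  if (length(missing) > 0L) {
    stop("library spec missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  built <- lapply(seq_len(nrow(spec)), function(i) {
    build_mutagenic_primer(spec$upstream_flank[i], spec$scheme[i],
                           spec$downstream_flank[i], min_flank = min_flank)
  })
  tibble::as_tibble(spec) |>
    dplyr::mutate(
      sequence = vapply(built, `[[`, character(1), "sequence"),
      degenerate_start = vapply(built, `[[`, integer(1), "degenerate_start")
    )
}

#' Write primers to FASTA (degenerate IUPAC letters preserved)
#'
#' @param primers Tibble from [read_library_spec()] (needs `name` and
#'   `sequence` columns) or a list of `mutagenic_primer` objects.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_primers_fasta <- function(primers, path) {
  if (is.data.frame(primers)) {
    seqs <- primers$sequence
    nms <- primers$name
  } else {
    seqs <- vapply(primers, `[[`, character(1), "sequence")
    nms <- paste0("primer_", seq_along(primers))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nms
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
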