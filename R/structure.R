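#' Parse a PDB structure with a bound ligand
#'
#' Reads fixed-column ATOM/HETATM records (via `bio3d`) and splits them into
#' protein atoms and the atoms of a named ligand (e.g. the FMN chromophore).
#' Hydrogens and deuteriums are dropped — chromophore-proximity distances are
#' conventionally measured between heavy atoms — and for atoms with
#' alternate locations only the first conformer is kept. Only the first
#' model of a multi-model file is used.
#'
#' @param pdb Path to a PDB file, or the PDB text itself (detected by an
#'   embedded newline or a character vector of record lines).
#' @param ligand_name Residue name of the ligand (default `"FMN"`).
#' @return A `structure_model` with tibbles `protein` and `ligand` (columns
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`) and the
#'   `ligand_name`.
#' @export
parse_structure <- function(pdb, ligand_name = "FMN") {
  path <- pdb
  if (length(pdb) > 1L || any(grepl("\n", pdb, fixed = TRUE))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
    on.exit(unlink(path), add = TRUE)
  }
  obj <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("malformed PDB input: ", conditionMessage(e),
                             call. = FALSE)
  )
  at <- obj$atom
  # heavy atoms only
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- gsub("[^A-Za-z].*", "",
                                         at$elety[is.na(elem) | elem == ""])
  at <- at[!toupper(trimws(elem)) %in% c("H", "D"), , drop = FALSE]
  # first-conformer rule for altlocs
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""

  lig <- at[at$resid == ligand_name, , drop = FALSE]
  prot <- at[at$type == "ATOM" & at$resid != ligand_name, , drop = FALSE]
  if (nrow(lig) == 0L) {
    stop("no ligand atoms with residue name '", ligand_name, "'", call. = FALSE)
  }
  if (nrow(prot) == 0L) {
    stop("no protein (ATOM) residues in structure", call. = FALSE)
  }
  keep <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  if (any(!is.finite(as.matrix(prot[, c("x", "y", "z")]))) ||
      any(!is.finite(as.matrix(lig[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure", call. = FALSE)
  }
  structure(
    list(protein = tibble::as_tibble(prot[, keep]),
         ligand = tibble::as_tibble(lig[, keep]),
         ligand_name = ligand_name),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d protein atoms in %d residues; ligand %s (%d atoms)\n",
              nrow(x$protein),
              length(unique(paste(x$protein$chain, x$protein$resno, x$protein$insert))),
              x$ligand_name, nrow(x$ligand)))
  invisible(x)
}

# Minimum heavy-atom distance (Angstrom) from each protein residue to the
# ligand, over all (residue atom, ligand atom) pairs.
residue_ligand_distances <- function(model) {
  pc <- as.matrix(model$protein[, c("x", "y", "z")])
  lc <- as.matrix(model$ligand[, c("x", "y", "z")])
  d2 <- outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * pc %*% t(lc)
  atom_min <- sqrt(pmax(0, apply(d2, 1L, min)))
  key <- paste(model$protein$chain, model$protein$resno, model$protein$insert,
               sep = "\r")
  res_min <- tapply(atom_min, key, min)
  first <- !duplicated(key)
  info <- model$protein[first, c("chain", "resno", "insert", "resid")]
  tibble::tibble(
    chain = info$chain, resno = info$resno, insert = info$insert,
    resname = info$resid,
    min_distance_nm = as.numeric(res_min[paste(info$chain, info$resno,
                                               info$insert, sep = "\r")]) / 10
  )
}

#' Residues within a cutoff distance of the ligand
#'
#' For every protein residue, computes the minimum heavy-atom Euclidean
#' distance to any ligand atom and returns the residues whose minimum
#' distance does not exceed `cutoff_nm`, sorted by distance. Coordinates are
#' Angstrom internally (PDB convention); distances are reported in nm
#' (1 nm = 10 Angstrom) to match how chromophore-proximity shells (0.3 nm,
#' 0.4 nm) are usually quoted.
#'
#' @param model A [parse_structure()] result.
#' @param cutoff_nm Distance cutoff in nm (> 0).
#' @return Tibble with `chain`, `resno`, `insert`, `resname`,
#'   `min_distance_nm`, ascending by distance.
#' @export
residues_within <- function(model, cutoff_nm) {
  stopifnot(inherits(model, "structure_model"))
  if (length(cutoff_nm) != 1L || !is.finite(cutoff_nm) || cutoff_nm <= 0) {
    stop("`cutoff_nm` must be a single positive number", call. = FALSE)
  }
  d <- residue_ligand_distances(model)
  d <- d[d$min_distance_nm <= cutoff_nm, , drop = FALSE]
  d[order(d$min_distance_nm), , drop = FALSE]
}

#' Annotate chromophore-proximity shells around the ligand
#'
#' Residues within `outer_nm` of the ligand, labelled `"inner"` when inside
#' `inner_nm` and `"outer"` otherwise — the two shells (0.3 nm target shell
#' and 0.4 nm extended shell) used when picking site-saturation targets
#' around a buried chromophore.
#'
#' @inheritParams residues_within
#' @param inner_nm,outer_nm Shell radii in nm; `inner_nm <= outer_nm`.
#' @return Tibble as [residues_within()] plus a `shell` column.
#' @export
proximity_shells <- function(model, inner_nm = 0.3, outer_nm = 0.4) {
  if (inner_nm > outer_nm) stop("`inner_nm` must not exceed `outer_nm`",
                                call. = FALSE)
  hits <- residues_within(model, outer_nm)
  hits$shell <- ifelse(hits$min_distance_nm <= inner_nm, "inner", "outer")
  hits
}
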