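#' Build a peptide/MHC complex structure object
#'
#' A `complex_structure` wraps an atom table (one row per non-hydrogen atom)
#' together with the chain identifiers of the 9-residue peptide and the MHC
#' heavy chain whose residues 1-180 form the peptide-binding groove.
#'
#' @param atoms tibble with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z` (Å) and optionally `altloc`.
#' @param peptide_chain,heavy_chain single chain identifiers.
#' @param id label for the structure (PDB ID or decoy index).
#' @param validate check invariants (peptide is a nonamer numbered 1-9 with a
#'   Cα per residue).
#' @return object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, peptide_chain, heavy_chain, id = "structure",
                              validate = TRUE) {
  atoms <- as_tibble(atoms)
  required <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  atoms$resno <- as.integer(atoms$resno)
  x <- structure(
    list(atoms = atoms, peptide_chain = peptide_chain,
         heavy_chain = heavy_chain, id = id),
    class = "complex_structure"
  )
  if (validate) validate_complex(x)
  x
}

validate_complex <- function(x) {
  atoms <- x$atoms
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("non-finite coordinates in atom table")
  }
  for (ch in c(x$peptide_chain, x$heavy_chain)) {
    if (!ch %in% atoms$chain) abort(paste0("chain not found: '", ch, "'"))
  }
  pep <- atoms[atoms$chain == x$peptide_chain, ]
  pep_res <- sort(unique(pep$resno))
  if (length(pep_res) != 9 || !identical(pep_res, 1:9)) {
    abort(paste0(
      "not a nonamer: peptide chain '", x$peptide_chain, "' has residues ",
      paste(pep_res, collapse = ","), " (need 1-9)"
    ))
  }
  bad <- setdiff(unique(atoms$resname), AA3)
  if (length(bad) > 0) {
    abort(paste0("non-standard residue(s): ", paste(bad, collapse = ", ")))
  }
  by_res <- unique(atoms[, c("chain", "resno")])
  ca <- unique(atoms[atoms$atom == "CA", c("chain", "resno")])
  if (nrow(by_res) != nrow(ca)) abort("residue without a CA atom present")
  groove <- sort(unique(atoms$resno[atoms$chain == x$heavy_chain & atoms$atom == "CA"]))
  covered <- intersect(groove, 1:180)
  if (length(covered) < 180) {
    warn(paste0(
      "heavy chain '", x$heavy_chain, "' has Calpha for only ", length(covered),
      " of groove residues 1-180"
    ))
  }
  invisible(x)
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> ", x$id, "\n", sep = "")
  cat("  peptide chain ", x$peptide_chain, " (", peptide_sequence(x), "), heavy chain ",
      x$heavy_chain, ", ", nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

#' Peptide sequence of a complex as one-letter codes
#' @param structure a `complex_structure`.
#' @return 9-character string.
#' @export
peptide_sequence <- function(structure) {
  pep <- structure$atoms[structure$atoms$chain == structure$peptide_chain &
                           structure$atoms$atom == "CA", ]
  pep <- pep[order(pep$resno), ]
  paste(AA1[pep$resname], collapse = "")
}

#' Read a PDB coordinate file into a complex structure
#'
#' Parses fixed-width `ATOM` records. Hydrogens are dropped (crystal
#' references generally lack them and all RMSDs here are heavy-atom), only
#' the first alternate-location conformer is kept, and waters/heteroatoms
#' (`HETATM`) are excluded. Author residue numbering is preserved; the
#' peptide chain must number its residues 1-9 unless `renumber_peptide` is
#' set, in which case residues are renumbered 1-9 in order of appearance.
#'
#' @param path PDB file path.
#' @param peptide_chain,heavy_chain chain identifiers in the file.
#' @param id structure label (defaults to the file name).
#' @param renumber_peptide renumber peptide residues to 1-9.
#' @return a [complex_structure()].
#' @export
read_pdb <- function(path, peptide_chain = "P", heavy_chain = "A",
                     id = NULL, renumber_peptide = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ")
  idx <- which(is_atom)
  if (length(idx) == 0) abort(paste0("no ATOM records in ", path))
  rec <- lines[idx]

  fw <- function(from, to) trimws(substr(rec, from, to))
  xs <- suppressWarnings(as.numeric(fw(31, 38)))
  ys <- suppressWarnings(as.numeric(fw(39, 46)))
  zs <- suppressWarnings(as.numeric(fw(47, 54)))
  resno <- suppressWarnings(as.integer(fw(23, 26)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs) | is.na(resno))
  if (length(bad) > 0) {
    abort(paste0("unreadable ATOM record at line ", idx[bad[1]], " of ", path))
  }

  atoms <- tibble(
    chain = fw(22, 22),
    resno = resno,
    resname = fw(18, 20),
    atom = fw(13, 16),
    altloc = fw(17, 17),
    x = xs, y = ys, z = zs
  )
  atoms$element <- {
    elem <- fw(77, 78)
    ifelse(elem == "", element_from_name(atoms$atom), toupper(elem))
  }
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", ]
  # first alt-loc wins (file order)
  atoms <- atoms[!duplicated(atoms[, c("chain", "resno", "atom")]), ]
  atoms$altloc <- ""

  if (!peptide_chain %in% atoms$chain) {
    abort(paste0("chain not found: '", peptide_chain, "'"))
  }
  if (!heavy_chain %in% atoms$chain) {
    abort(paste0("chain not found: '", heavy_chain, "'"))
  }
  if (renumber_peptide) {
    pep_sel <- atoms$chain == peptide_chain
    old <- unique(atoms$resno[pep_sel])
    if (length(old) != 9) {
      abort(paste0("not a nonamer: peptide chain '", peptide_chain, "' has ",
                   length(old), " residues"))
    }
    atoms$resno[pep_sel] <- match(atoms$resno[pep_sel], old)
  }
  complex_structure(
    atoms[, c("chain", "resno", "resname", "atom", "element", "x", "y", "z", "altloc")],
    peptide_chain = peptide_chain, heavy_chain = heavy_chain,
    id = id %||% sub("\\.pdb$", "", basename(path))
  )
}

#' Write a complex structure to a PDB file
#'
#' Emits standard fixed-width `ATOM` records (coordinates to 3 decimals) with
#' `TER` records between chains, so [read_pdb()] of the output reproduces the
#' input coordinates to PDB precision (1e-3 Å).
#'
#' @param structure a [complex_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  atoms <- structure$atoms
  if (nrow(atoms) == 0) abort("nothing to write: empty atom list")
  ord <- order(
    match(atoms$chain, unique(atoms$chain)), atoms$resno,
    mapply(atom_order_index, atoms$resname, atoms$atom)
  )
  atoms <- atoms[ord, ]
  name4 <- ifelse(nchar(atoms$atom) >= 4, atoms$atom, paste0(" ", atoms$atom))
  recs <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
    seq_len(nrow(atoms)), name4, atoms$resname, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$element
  )
  # TER after each chain
  out <- character(0)
  for (ch in unique(atoms$chain)) {
    out <- c(out, recs[atoms$chain == ch], "TER")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Select atoms from a complex structure
#'
#' Returns the atoms of one chain (optionally restricted to a residue range)
#' belonging to a named atom class, in deterministic
#' (residue number, canonical atom-name) order regardless of input record
#' order.
#'
#' Atom classes: `"CA"` = α-carbons only; `"heavy"` = all non-hydrogen atoms;
#' `"backbone"` = N, CA, C, O (plus OXT when `include_oxt`); `"sidechain"` =
#' heavy minus backbone. Backbone and sidechain partition heavy exactly.
#'
#' @param structure a [complex_structure()].
#' @param chain chain identifier.
#' @param residue_range optional `c(lo, hi)` inclusive author-numbered range.
#' @param atom_class one of `"CA"`, `"heavy"`, `"backbone"`, `"sidechain"`.
#' @param include_oxt count a terminal OXT as backbone (default TRUE).
#' @return tibble of atoms (same columns as the structure's atom table).
#' @export
select_atoms <- function(structure, chain, residue_range = NULL,
                         atom_class = c("heavy", "CA", "backbone", "sidechain"),
                         include_oxt = TRUE) {
  atom_class <- match.arg(atom_class)
  atoms <- structure$atoms[structure$atoms$chain == chain, ]
  if (!is.null(residue_range)) {
    atoms <- atoms[atoms$resno >= residue_range[1] & atoms$resno <= residue_range[2], ]
  }
  bb <- if (include_oxt) BACKBONE_ATOMS else BACKBONE_ATOMS[1:4]
  keep <- switch(atom_class,
    CA = atoms$atom == "CA",
    heavy = rep(TRUE, nrow(atoms)),
    backbone = atoms$atom %in% bb,
    sidechain = !(atoms$atom %in% bb)
  )
  atoms <- atoms[keep, ]
  if (nrow(atoms) == 0) abort("no atoms matched selection")
  atoms[order(atoms$resno, mapply(atom_order_index, atoms$resname, atoms$atom)), ]
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}
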