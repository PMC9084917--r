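# Standard amino-acid heavy-atom topology and element/radius tables.
# Side-chain atom names are listed in canonical PDB order; backbone order is
# N, CA, C, O (OXT last when present at a chain terminus).

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

AA3 <- names(SIDECHAIN_ATOMS)
AA1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1_TO_3 <- setNames(names(AA1), unname(AA1))

#' Van der Waals radii used for solvent accessible surface area
#'
#' Heavy-atom van der Waals radii in angstroms (Bondi-type values:
#' C 1.70, N 1.55, O 1.52, S 1.80). The exact table used by any particular
#' scoring suite differs slightly; [shrake_rupley()] accepts a replacement
#' table, so numeric parity with a specific external program is a matter of
#' supplying its radii.
#'
#' @return named numeric vector of radii (Å) keyed by element symbol.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

# element symbol from a PDB atom name (heavy atoms of standard residues)
element_from_name <- function(atom_name) {
  sub("^([A-Z]).*$", "\\1", sub("^[0-9]+", "", toupper(atom_name)))
}

# canonical within-residue ordering index for an atom name
atom_order_index <- function(residue_name, atom_name) {
  canon <- c(
    BACKBONE_ATOMS[1:4],
    SIDECHAIN_ATOMS[[residue_name]] %||% character(0),
    "OXT"
  )
  idx <- match(atom_name, canon)
  ifelse(is.na(idx), length(canon) + 1L, idx)
}

heavy_atom_names <- function(residue_name, oxt = FALSE) {
  c(
    BACKBONE_ATOMS[1:4],
    SIDECHAIN_ATOMS[[residue_name]],
    if (oxt) "OXT"
  )
}
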