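# Deterministic golden-spiral (Fibonacci) sphere points; no RNG, so SASA is
# bit-reproducible for a given n.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Solvent accessible surface area by Shrake-Rupley sphere sampling
#'
#' Rolls a spherical probe (default radius 1.4 Å, the conventional water
#' probe) over every heavy atom of the complex, sampling each expanded sphere
#' at `n_points` deterministically placed points. SASA is computed on the
#' full complex — peptide in groove — so peptide residue areas describe the
#' bound state. Hydrophobic SASA (hSASA) sums the areas of atoms satisfying
#' `hydrophobic` (default: carbon and sulfur).
#'
#' @param structure a [complex_structure()].
#' @param probe probe radius, Å.
#' @param n_points sampling points per atom sphere (>= 100; quadrature error
#'   scales roughly as 1/n).
#' @param radii named vector of van der Waals radii by element; see
#'   [default_vdw_radii()].
#' @param hydrophobic function mapping an element-symbol vector to a logical
#'   vector marking hydrophobic atoms.
#' @return a `sasa_result`: list with `atoms` (tibble: chain, resno, atom,
#'   element, area), `residues` (tibble for the peptide chain: `position`,
#'   `sasa`, `hsasa`, Å²), `total_area`, `probe_radius`, `n_points`.
#' @export
shrake_rupley <- function(structure, probe = 1.4, n_points = 960,
                          radii = default_vdw_radii(),
                          hydrophobic = function(el) el %in% c("C", "S")) {
  if (n_points < 100) abort("n_points must be >= 100")
  atoms <- structure$atoms
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown) > 0) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  xyz <- coords_matrix(atoms)
  rad <- radii[atoms$element] + probe
  n <- nrow(atoms)
  sphere <- golden_spiral_points(n_points)
  area <- numeric(n)
  # neighbor lists from pairwise distances (structures here are small)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    pts <- sphere * rad[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
        (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  atom_tbl <- tibble(chain = atoms$chain, resno = atoms$resno,
                     atom = atoms$atom, element = atoms$element, area = area)
  pep <- atom_tbl[atom_tbl$chain == structure$peptide_chain, ]
  hydro <- hydrophobic(pep$element)
  residues <- pep |>
    mutate(h = ifelse(hydro, .data$area, 0)) |>
    group_by(position = .data$resno) |>
    summarise(sasa = sum(.data$area), hsasa = sum(.data$h), .groups = "drop")
  residues <- left_join(tibble(position = 1:9), residues, by = "position")
  residues$sasa[is.na(residues$sasa)] <- 0
  residues$hsasa[is.na(residues$hsasa)] <- 0
  structure(
    list(atoms = atom_tbl, residues = residues, total_area = sum(area),
         probe_radius = probe, n_points = as.integer(n_points)),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> total", format(x$total_area, digits = 6), "Å² (probe",
      x$probe_radius, "Å,", x$n_points, "points)\n")
  invisible(x)
}

#' @rdname shrake_rupley
#' @param x a `sasa_result`.
#' @param ... unused.
#' @export
tidy.sasa_result <- function(x, ...) x$residues
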