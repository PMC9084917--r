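#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the least-squares optimal proper rotation and translation mapping
#' `mobile` onto `reference`, pairing points positionally. Reflections are
#' excluded by the usual determinant sign correction, so `det(rotation)` is
#' +1 to machine precision.
#'
#' @param mobile,reference n x 3 coordinate matrices (Å), equal length, n >= 3,
#'   not collinear.
#' @return a `superposition`: list with `rotation` (3 x 3, applied to row
#'   vectors as `x %*% rotation`), `translation` (length-3), and `fit_rmsd`
#'   (Å over the fitted set).
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) abort("need at least 3 points to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  am <- sweep(mobile, 2, cm); ar <- sweep(reference, 2, cr)
  if (sum(svd(am)$d > 1e-8) < 2 || sum(svd(ar)$d > 1e-8) < 2) {
    abort("degenerate (collinear) point set: superposition is not unique")
  }
  h <- crossprod(am, ar)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- as.numeric(cr - cm %*% rot)
  fitted <- mobile %*% rot + matrix(trans, n, 3, byrow = TRUE)
  structure(
    list(rotation = rot, translation = trans,
         fit_rmsd = sqrt(mean(rowSums((fitted - reference)^2)))),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 matrix.
#' @param sp a `superposition` from [kabsch_fit()].
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  xyz <- as.matrix(xyz)
  xyz %*% sp$rotation + matrix(sp$translation, nrow(xyz), 3, byrow = TRUE)
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> fit RMSD", format(x$fit_rmsd, digits = 4), "Å\n")
  invisible(x)
}

#' Superpose a crystal structure onto a decoy via the binding groove
#'
#' Fits ONLY the Cα atoms of heavy-chain residues 1-180 (the class I MHC
#' peptide-binding groove) and moves the whole crystal structure into the
#' decoy frame. Peptide atoms are never part of the fit, so subsequent
#' peptide RMSDs measure modeling error, not alignment slack. If either
#' structure is missing groove residues, the common subset is used with a
#' warning.
#'
#' @param crystal,decoy [complex_structure()] objects.
#' @param groove_range residue range of the groove on the heavy chain.
#' @return the transformed crystal structure, with the fitted
#'   `superposition` attached as attribute `"superposition"`.
#' @export
groove_superpose <- function(crystal, decoy, groove_range = c(1L, 180L)) {
  ca_c <- select_atoms(crystal, crystal$heavy_chain, groove_range, "CA")
  ca_d <- select_atoms(decoy, decoy$heavy_chain, groove_range, "CA")
  common <- intersect(ca_c$resno, ca_d$resno)
  if (length(common) < 3) abort("fewer than 3 common groove residues")
  n_groove <- diff(groove_range) + 1L
  if (length(common) < n_groove) {
    warn(paste0("groove superposition uses ", length(common), " of ",
                n_groove, " residues (missing residues skipped)"))
  }
  sp <- kabsch_fit(
    coords_matrix(ca_c[match(common, ca_c$resno), ]),
    coords_matrix(ca_d[match(common, ca_d$resno), ])
  )
  out <- crystal
  xyz <- apply_superposition(coords_matrix(out$atoms), sp)
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  attr(out, "superposition") <- sp
  out
}

# Pair peptide atoms of two structures by (residue number, atom name) for a
# given atom class. A terminal OXT is compared only when present in both
# structures; other unpaired atoms are skipped with a warning and the
# comparison fails when more than `max_unpaired` of the class is unpaired.
paired_peptide_atoms <- function(crystal, decoy, atom_class, max_unpaired = 0.1) {
  a <- select_atoms(crystal, crystal$peptide_chain, c(1L, 9L), atom_class)
  b <- select_atoms(decoy, decoy$peptide_chain, c(1L, 9L), atom_class)
  a$key <- paste(a$resno, a$atom); b$key <- paste(b$resno, b$atom)
  oxt_keys <- paste(9, "OXT")
  a <- a[!(a$key %in% oxt_keys & !(a$key %in% b$key)), ]
  b <- b[!(b$key %in% oxt_keys & !(b$key %in% a$key)), ]
  common <- intersect(a$key, b$key)
  n_union <- length(union(a$key, b$key))
  n_unpaired <- n_union - length(common)
  if (n_unpaired > 0) {
    if (n_unpaired / n_union > max_unpaired) {
      abort(paste0("atom-name mismatch: ", n_unpaired, " of ", n_union,
                   " ", atom_class, " atoms unpaired"))
    }
    warn(paste0(n_unpaired, " unpaired ", atom_class, " atom(s) skipped"))
  }
  ia <- match(common, a$key); ib <- match(common, b$key)
  list(
    ref = coords_matrix(b[ib, ]), mob = coords_matrix(a[ia, ]),
    position = a$resno[ia]
  )
}

#' Peptide RMSD after groove superposition
#'
#' Root-mean-square deviation over the peptide atoms of a given class,
#' computed after superposing the crystal onto the decoy via the groove Cα
#' atoms only — there is no re-fitting on the peptide, so the value reports
#' how far the modeled peptide sits from the experimentally determined one in
#' the frame of the MHC groove. Atoms are paired by name within each residue.
#'
#' @param crystal,decoy [complex_structure()] objects.
#' @param atom_class `"heavy"` (HA RMSD), `"CA"`, `"backbone"` or
#'   `"sidechain"`.
#' @param superpose run [groove_superpose()] first (set `FALSE` only if the
#'   structures are already in a common frame).
#' @param max_unpaired maximum tolerated fraction of unpaired atom names.
#' @return RMSD in Å.
#' @export
peptide_rmsd <- function(crystal, decoy,
                         atom_class = c("heavy", "CA", "backbone", "sidechain"),
                         superpose = TRUE, max_unpaired = 0.1) {
  atom_class <- match.arg(atom_class)
  if (superpose) crystal <- groove_superpose(crystal, decoy)
  p <- paired_peptide_atoms(crystal, decoy, atom_class, max_unpaired)
  sqrt(mean(rowSums((p$mob - p$ref)^2)))
}

#' Per-position stratified peptide RMSD report
#'
#' Computes global and per-position (1-9) peptide RMSDs for all four atom
#' classes in one pass, after a single groove superposition. The global
#' heavy-atom value satisfies the aggregation identity
#' `ha^2 * n_ha = sum_p ha_p^2 * n_p` exactly.
#'
#' @inheritParams peptide_rmsd
#' @return an `rmsd_report`: list with `global` (tibble: `atom_class`,
#'   `rmsd`, `n_atoms`) and `per_position` (tibble: `position`, `atom_class`,
#'   `rmsd`, `n_atoms`; positions with no atoms of a class, e.g. glycine side
#'   chains, have `n_atoms = 0` and `rmsd = NA`).
#' @export
stratified_rmsd <- function(crystal, decoy, superpose = TRUE, max_unpaired = 0.1) {
  if (superpose) crystal <- groove_superpose(crystal, decoy)
  classes <- c("CA", "heavy", "backbone", "sidechain")
  per_pos <- list(); glob <- list()
  for (cl in classes) {
    p <- tryCatch(
      paired_peptide_atoms(crystal, decoy, cl, max_unpaired),
      rlang_error = function(e) {
        if (grepl("no atoms matched", conditionMessage(e))) NULL else stop(e)
      }
    )
    sq <- if (is.null(p)) numeric(0) else rowSums((p$mob - p$ref)^2)
    pos <- if (is.null(p)) integer(0) else p$position
    per <- vapply(1:9, function(i) {
      v <- sq[pos == i]
      c(rmsd = if (length(v)) sqrt(mean(v)) else NA_real_, n = length(v))
    }, numeric(2))
    per_pos[[cl]] <- tibble(position = 1:9, atom_class = cl,
                            rmsd = per["rmsd", ], n_atoms = as.integer(per["n", ]))
    glob[[cl]] <- tibble(atom_class = cl,
                         rmsd = if (length(sq)) sqrt(mean(sq)) else NA_real_,
                         n_atoms = length(sq))
  }
  structure(
    list(global = bind_rows(glob), per_position = bind_rows(per_pos),
         id = decoy$id),
    class = "rmsd_report"
  )
}

#' @export
print.rmsd_report <- function(x, ...) {
  g <- x$global
  cat("<rmsd_report> ", x$id, ": ", sep = "")
  cat(paste0(g$atom_class, " ", format(g$rmsd, digits = 3), " Å", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname stratified_rmsd
#' @param x an `rmsd_report`.
#' @param ... unused.
#' @export
tidy.rmsd_report <- function(x, ...) x$per_position

#' @rdname stratified_rmsd
#' @export
glance.rmsd_report <- function(x, ...) {
  g <- x$global
  tibble(
    ca_rmsd = g$rmsd[g$atom_class == "CA"],
    ha_rmsd = g$rmsd[g$atom_class == "heavy"],
    backbone_rmsd = g$rmsd[g$atom_class == "backbone"],
    sidechain_rmsd = g$rmsd[g$atom_class == "sidechain"]
  )
}
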