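#' Theoretical maximum solvent accessibility per residue type
#'
#' Theoretical maximum accessible surface areas (Gly-X-Gly context, in
#' square Angstroms) used as the denominator of relative SASA, following the
#' widely used table of Tien and co-workers (2013).
#'
#' @format Named numeric vector, one entry per standard amino acid
#'   (3-letter code).
#' @export
max_sasa_reference <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# van der Waals radii (A) by element; unknown elements fall back to carbon.
vdw_radius <- function(element) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10, D = 1.10,
             P = 1.80, SE = 1.90, FE = 1.80, ZN = 1.39, MG = 1.73)
  r <- radii[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Near-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by test points on each atom's solvent-expanded sphere;
#' a point is accessible if outside every neighbor's expanded sphere.
#' Hydrogens and HETATM records are excluded from both the computation and
#' the occlusion set.
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param model Model number (default: first).
#' @param probe_radius Solvent probe radius in Angstroms (default 1.4).
#' @param n_points Test points per atom (default 120).
#' @return The heavy-atom subset of `atoms` with an added `sasa` column
#'   (square Angstroms).
#' @export
atom_sasa <- function(atoms, model = NULL, probe_radius = 1.4, n_points = 120) {
  if (probe_radius <= 0) abort("probe_radius must be > 0")
  atoms <- as_pdb_atoms(atoms)
  model <- model %||% min(atoms$model)
  heavy <- atoms |>
    filter(.data$model == !!model, !.data$hydrogen, !.data$het)
  if (nrow(heavy) == 0) abort("no heavy atoms in selected model")
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  rad <- vdw_radius(heavy$element) + probe_radius
  sphere <- fibonacci_sphere(n_points)
  n <- nrow(xyz)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & d2 > 1e-12)
    pts <- sweep(sphere * rad[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 > rad[j]^2
    }
    sasa[i] <- 4 * pi * rad[i]^2 * sum(accessible) / n_points
  }
  heavy$sasa <- sasa
  heavy
}

#' Per-residue absolute and relative solvent accessibility
#'
#' Sums heavy-atom SASA per residue and normalizes by the theoretical
#' maximum for the residue type ([max_sasa_reference]), yielding the
#' relative accessibility used to decide solvent exposure (e.g. for docking
#' active-residue selection).
#'
#' @inheritParams atom_sasa
#' @return Tibble with `chain`, `resno`, `resname`, `sasa` (absolute, A^2)
#'   and `rel_sasa` (fraction of the type reference; `NA` with a warning for
#'   residue types without a reference value).
#' @export
relative_accessibility <- function(atoms, model = NULL, probe_radius = 1.4,
                                   n_points = 120) {
  per_atom <- atom_sasa(atoms, model = model, probe_radius = probe_radius,
                        n_points = n_points)
  out <- per_atom |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(sasa = sum(.data$sasa), .groups = "drop") |>
    mutate(rel_sasa = .data$sasa / unname(max_sasa_reference[.data$resname])) |>
    arrange(.data$chain, .data$resno)
  unknown <- unique(out$resname[is.na(out$rel_sasa)])
  if (length(unknown)) {
    warn(sprintf("no reference accessibility for residue type(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  out
}
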