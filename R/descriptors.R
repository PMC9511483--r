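# Per-conformer 3D descriptors: 3D polar surface area by numerical
# integration over a deterministic sphere lattice, radius of gyration,
# voxelized van der Waals volume, and least-squares superposition RMSD.

#' Radius of gyration
#'
#' Root-mean-square distance of the atoms from the molecular center of
#' mass: `Rgyr = sqrt(sum(w_i * |r_i - c|^2) / sum(w_i))` with `w_i` the
#' atomic mass (default) or 1 (`weighting = "unit"`). The center `c` is
#' always the weighted centroid under the same weights.
#'
#' @param conf a [conformer()].
#' @param mol the parent [molecule()] (supplies atomic masses).
#' @param weighting `"mass"` (default) or `"unit"`.
#' @return length in Angstrom.
#' @export
radius_of_gyration <- function(conf, mol, weighting = c("mass", "unit")) {
  weighting <- match.arg(weighting)
  x <- conf$coords
  w <- if (weighting == "mass") atomic_mass(mol$elements) else rep(1, nrow(x))
  ctr <- colSums(x * w) / sum(w)
  sqrt(sum(w * rowSums((x - matrix(ctr, nrow(x), 3, byrow = TRUE))^2)) / sum(w))
}

# Deterministic Fibonacci sphere lattice: n near-uniform points on the unit
# sphere, no RNG, so surface areas are bit-for-bit reproducible.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' 3D polar surface area of a conformer
#'
#' Numerical molecular-surface integration: for every polar atom, points
#' are placed on its sphere of radius `r + probe`; a point is exposed iff
#' it lies outside every other atom's sphere (same probe inflation). The
#' summed exposed area `4*pi*(r+probe)^2 * exposed fraction` over the polar
#' set is returned. With the default `probe = 0` this is the polar part of
#' the van der Waals surface.
#'
#' @param conf a [conformer()].
#' @param psa_atoms polar atom indices from [assign_psa_atoms()].
#' @param mol the parent [molecule()] (supplies elements).
#' @param radii named radii set, see [bondi_radii()].
#' @param probe probe radius in Angstrom (>= 0); 1.4 gives the
#'   solvent-accessible variant.
#' @param points_per_atom sphere lattice size (>= 32); the default 1024
#'   resolves drug-like surfaces to well under 1%.
#' @return area in Angstrom^2 (0 for an empty polar set).
#' @export
psa_3d <- function(conf, psa_atoms, mol, radii = bondi_radii(), probe = 0,
                   points_per_atom = 1024L) {
  if (probe < 0) stop("probe radius must be >= 0", call. = FALSE)
  if (points_per_atom < 32L) stop("points_per_atom must be >= 32", call. = FALSE)
  if (!length(psa_atoms)) return(0)
  x <- conf$coords
  r <- radius_for(mol$elements, radii) + probe
  unit <- fibonacci_sphere(as.integer(points_per_atom))
  total <- 0
  for (a in psa_atoms) {
    ra <- r[a]
    d_ab <- sqrt(colSums((t(x) - x[a, ])^2))
    blockers <- which(d_ab > 1e-9 & d_ab < ra + r)
    if (!length(blockers)) { total <- total + 4 * pi * ra^2; next }
    pts <- unit * ra + matrix(x[a, ], points_per_atom, 3, byrow = TRUE)
    exposed <- rep(TRUE, points_per_atom)
    for (b in blockers) {
      if (!any(exposed)) break
      idx <- which(exposed)
      d2 <- (pts[idx, 1] - x[b, 1])^2 + (pts[idx, 2] - x[b, 2])^2 +
            (pts[idx, 3] - x[b, 3])^2
      exposed[idx[d2 < r[b]^2 - 1e-12]] <- FALSE
    }
    total <- total + 4 * pi * ra^2 * mean(exposed)
  }
  total
}

#' Voxelized van der Waals volume
#'
#' Union-of-spheres volume on a cubic grid: every voxel whose center falls
#' inside at least one atomic sphere contributes `grid_step^3`. Converges
#' to the exact union volume as the step shrinks.
#'
#' @param conf a [conformer()].
#' @param mol the parent [molecule()].
#' @param radii named radii set, see [bondi_radii()].
#' @param grid_step voxel edge in Angstrom (must be <= 0.3).
#' @return volume in Angstrom^3.
#' @export
vdw_volume <- function(conf, mol, radii = bondi_radii(), grid_step = 0.2) {
  if (grid_step > 0.3) stop("grid_step must be <= 0.3 Angstrom", call. = FALSE)
  x <- conf$coords
  r <- radius_for(mol$elements, radii)
  lo <- apply(x, 2, min) - max(r) - grid_step
  hi <- apply(x, 2, max) + max(r) + grid_step
  gx <- seq(lo[1] + grid_step / 2, hi[1], by = grid_step)
  gy <- seq(lo[2] + grid_step / 2, hi[2], by = grid_step)
  gz <- seq(lo[3] + grid_step / 2, hi[3], by = grid_step)
  inside <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  for (a in seq_len(nrow(x))) {
    ix <- which(abs(gx - x[a, 1]) <= r[a])
    iy <- which(abs(gy - x[a, 2]) <= r[a])
    iz <- which(abs(gz - x[a, 3]) <= r[a])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - x[a, 1])^2
    dy2 <- (gy[iy] - x[a, 2])^2
    dz2 <- (gz[iz] - x[a, 3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r[a]^2
    inside[ix, iy, iz] <- inside[ix, iy, iz] | sub
  }
  sum(inside) * grid_step^3
}

#' Least-squares superposition RMSD
#'
#' Optimal rigid-body (rotation + translation) superposition of two
#' conformers over an atom subset (Kabsch algorithm: SVD of the
#' cross-covariance with a reflection guard), returning the residual RMSD
#' at full precision.
#'
#' @param a,b [conformer()]s sharing a topology.
#' @param subset atom indices used for fit and RMSD; defaults to all heavy
#'   atoms of `mol`, or all atoms when `mol` is NULL.
#' @param mol optional parent [molecule()] (only used for the heavy-atom
#'   default subset).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b, subset = NULL, mol = NULL) {
  if (nrow(a$coords) != nrow(b$coords))
    stop("topology mismatch: conformers differ in atom count", call. = FALSE)
  if (is.null(subset))
    subset <- if (is.null(mol)) seq_len(nrow(a$coords)) else heavy_atoms(mol)
  if (!length(subset)) stop("atom subset must be nonempty", call. = FALSE)
  A <- scale(a$coords[subset, , drop = FALSE], scale = FALSE)
  B <- scale(b$coords[subset, , drop = FALSE], scale = FALSE)
  s <- svd(t(B) %*% A)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

#' Per-conformer descriptor table for an ensemble
#'
#' Computes 3D PSA, Rgyr and IMHB count (and optionally van der Waals
#' volume) for every conformer of an ensemble.
#'
#' @param ens an [ensemble()].
#' @param psa_mode polar-atom mode for [assign_psa_atoms()].
#' @param radii radii set.
#' @param probe probe radius (Angstrom) for [psa_3d()].
#' @param points_per_atom lattice size for [psa_3d()].
#' @param weighting Rgyr weighting, see [radius_of_gyration()].
#' @param criteria IMHB criteria from [hbond_criteria()].
#' @param volume also compute [vdw_volume()] (slower); otherwise `NA`.
#' @return data frame with columns `conformer_id`, `solvent`, `psa3d`,
#'   `rgyr`, `volume`, `imhb_count`, `energy`.
#' @export
conformer_records <- function(ens, psa_mode = "NO", radii = bondi_radii(),
                              probe = 0, points_per_atom = 1024L,
                              weighting = "mass",
                              criteria = hbond_criteria(),
                              volume = FALSE) {
  stopifnot(inherits(ens, "molcham_ens"))
  mol <- ens$molecule
  pa <- assign_psa_atoms(mol, psa_mode)
  roles <- assign_hbond_roles(mol)
  dmat <- bond_distance_matrix(mol)
  rows <- lapply(ens$conformers, function(cf) {
    data.frame(
      conformer_id = cf$id,
      solvent = ens$solvent,
      psa3d = psa_3d(cf, pa, mol, radii, probe, points_per_atom),
      rgyr = radius_of_gyration(cf, mol, weighting),
      volume = if (volume) vdw_volume(cf, mol, radii) else NA_real_,
      imhb_count = nrow(detect_imhbs(cf, roles, criteria, mol,
                                     dist_matrix = dmat)),
      energy = if (is.null(cf$energy)) NA_real_ else cf$energy)
  })
  do.call(rbind, rows)
}

#' Write a descriptor table as TSV
#'
#' @param records data frame from [conformer_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
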