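# Synthetic data generation. Two families: (1) analytic toy-chain
# geometries with controllable intramolecular H-bond formation, polar-atom
# burial and Rgyr contrast, for which expected descriptor orderings are
# knowable in closed form; (2) seeded Gaussian property clouds for the
# density-map machinery. A thin adapter to an external distance-geometry
# engine embeds real structures.

#' Toy-chain fixture specification
#'
#' Describes an omega-hydroxy aldehyde chain `HO-(CH2)k-CHO`: the hydroxyl
#' is the IMHB donor, the aldehyde carbonyl the acceptor, separated by the
#' whole backbone so the topological-separation filter never rejects the
#' contact. Folded geometries place the backbone on a circular arc whose
#' radius is solved so the donor hydrogen sits exactly `fold_distance`
#' from the acceptor oxygen at a linear donor-H-acceptor angle; extended
#' geometries are a standard zigzag. A small seeded coordinate jitter
#' makes ensemble statistics nondegenerate.
#'
#' @param n_chain number of backbone carbons including the carbonyl
#'   carbon (>= 4).
#' @param fold_distance H...acceptor distance in the folded form
#'   (Angstrom).
#' @param fraction_folded fraction of nonpolar-ensemble conformers folded.
#' @param n_conformers conformers per ensemble.
#' @param jitter coordinate noise standard deviation (Angstrom).
#' @param seed RNG seed.
#' @return list of class `molcham_toyspec`.
#' @export
toy_chain_spec <- function(n_chain = 8L, fold_distance = 2.0,
                           fraction_folded = 0.8, n_conformers = 30L,
                           jitter = 0.05, seed = 1L) {
  if (n_chain < 4L) stop("n_chain must be >= 4", call. = FALSE)
  if (fold_distance <= 0) stop("fold_distance must be > 0", call. = FALSE)
  if (fraction_folded < 0 || fraction_folded > 1)
    stop("fraction_folded must lie in [0, 1]", call. = FALSE)
  structure(list(n_chain = as.integer(n_chain),
                 fold_distance = fold_distance,
                 fraction_folded = fraction_folded,
                 n_conformers = as.integer(n_conformers),
                 jitter = jitter, seed = as.integer(seed)),
            class = "molcham_toyspec")
}

# idealized internal coordinates
.toy_geom <- list(cc = 1.54, co = 1.43, oh = 0.96, c_dbl_o = 1.22,
                  ch = 1.09, angle = 112 * pi / 180)

toy_chain_molecule <- function(n_chain) {
  # atom order: O_d, C1..Ck (Ck = carbonyl C), O_a, H(O_d), H(C_co),
  # then 2 H per CH2 carbon (C1..C_{k-1})
  k <- n_chain
  el <- c("O", rep("C", k), "O", "H", "H", rep("H", 2L * (k - 1L)))
  bonds <- data.frame(i = 1L, j = 2L, order = 1L)                 # O_d-C1
  for (q in seq_len(k - 1L))
    bonds <- rbind(bonds, data.frame(i = q + 1L, j = q + 2L, order = 1L))
  io_a <- k + 2L; ih_d <- k + 3L; ih_co <- k + 4L
  bonds <- rbind(bonds,
                 data.frame(i = k + 1L, j = io_a, order = 2L),    # C=O
                 data.frame(i = 1L, j = ih_d, order = 1L),        # O-H
                 data.frame(i = k + 1L, j = ih_co, order = 1L))   # CHO H
  hidx <- ih_co
  for (q in seq_len(k - 1L)) {
    bonds <- rbind(bonds,
                   data.frame(i = q + 1L, j = hidx + 1L, order = 1L),
                   data.frame(i = q + 1L, j = hidx + 2L, order = 1L))
    hidx <- hidx + 2L
  }
  molecule(el, bonds, name = sprintf("toy-chain-%d", k))
}

toy_backbone_extended <- function(k) {
  # zigzag in the xy-plane: O_d, C1..Ck, then the carbonyl O continues it
  half <- (pi - .toy_geom$angle) / 2
  dirs <- list(c(cos(half), sin(half), 0), c(cos(half), -sin(half), 0))
  lens <- c(.toy_geom$co, rep(.toy_geom$cc, k - 1L), .toy_geom$c_dbl_o)
  pos <- matrix(0, k + 2L, 3L)
  for (q in seq_len(k + 1L))
    pos[q + 1L, ] <- pos[q, ] + lens[q] * dirs[[1L + (q - 1L) %% 2L]]
  pos
}

toy_backbone_folded <- function(k, fold_distance) {
  m <- k + 1L                       # arc atoms: O_d, C1..Ck
  spacing <- 1.5
  target <- fold_distance + .toy_geom$oh + .toy_geom$c_dbl_o
  chord <- function(r) {
    delta <- 2 * asin(spacing / (2 * r))
    2 * r * abs(sin((m - 1L) * delta / 2))
  }
  f <- function(r) chord(r) - target
  lo <- spacing / 2 + 1e-6
  # the chord grows with r once the arc stops wrapping; bracket a root
  rs <- seq(lo + 0.05, 60, by = 0.05)
  vals <- vapply(rs, f, numeric(1))
  hit <- which(vals[-1] * vals[-length(vals)] <= 0 & diff(vals) > 0)
  if (!length(hit))
    stop(sprintf(
      "fold distance %.2f Angstrom is incompatible with a %d-carbon chain",
      fold_distance, k), call. = FALSE)
  r <- stats::uniroot(f, c(rs[hit[1]], rs[hit[1] + 1]))$root
  delta <- 2 * asin(spacing / (2 * r))
  ang <- (seq_len(m) - 1L) * delta
  arc <- cbind(r * cos(ang), r * sin(ang), 0)
  o_a <- arc[m, ] + .toy_geom$c_dbl_o *
    (arc[1L, ] - arc[m, ]) / sqrt(sum((arc[1L, ] - arc[m, ])^2))
  rbind(arc, o_a)
}

toy_conformer_coords <- function(k, folded, fold_distance) {
  bb <- if (folded) toy_backbone_folded(k, fold_distance)
        else toy_backbone_extended(k)
  o_d <- bb[1L, ]; c_co <- bb[k + 1L, ]; o_a <- bb[k + 2L, ]
  h_d <- if (folded) {
    o_d + .toy_geom$oh * (o_a - o_d) / sqrt(sum((o_a - o_d)^2))
  } else {
    o_d + .toy_geom$oh * c(-1, 0, 0)   # anti to the chain
  }
  h_co <- c_co + .toy_geom$ch * c(0, 0, 1)
  coords <- rbind(bb, h_d, h_co)
  for (q in seq_len(k - 1L)) {
    cc <- bb[q + 1L, ]
    coords <- rbind(coords,
                    cc + .toy_geom$ch * c(0, 0, 1),
                    cc + .toy_geom$ch * c(0, 0, -1))
  }
  coords
}

#' Analytic toy-chameleon ensemble pair
#'
#' Builds a polar ensemble of extended conformers (no IMHB, polar atoms
#' exposed, high Rgyr) and a nonpolar ensemble with the specified fraction
#' folded (a donor-H...acceptor contact at the specified distance and a
#' near-linear angle, partially occluded polar atoms, low Rgyr). Folded
#' conformers carry lower energies in the nonpolar ensemble. All output is
#' a deterministic function of the spec (including its seed).
#'
#' @param spec a [toy_chain_spec()].
#' @return list with elements `polar` and `nonpolar` ([ensemble()]s).
#' @export
toy_chameleon_ensembles <- function(spec = toy_chain_spec()) {
  stopifnot(inherits(spec, "molcham_toyspec"))
  mol <- toy_chain_molecule(spec$n_chain)
  base_ext <- toy_conformer_coords(spec$n_chain, FALSE, spec$fold_distance)
  base_fold <- toy_conformer_coords(spec$n_chain, TRUE, spec$fold_distance)
  n <- spec$n_conformers
  n_fold <- round(spec$fraction_folded * n)
  make <- function(base, energy_mu, id, rng_offset) {
    set.seed(spec$seed + rng_offset)
    coords <- base + matrix(stats::rnorm(length(base), 0, spec$jitter),
                            nrow(base), 3L)
    conformer(coords, energy = energy_mu + stats::rnorm(1, 0, 0.1), id = id)
  }
  polar <- lapply(seq_len(n), function(q)
    make(base_ext, -1, q, 1000L + q))
  nonpolar <- lapply(seq_len(n), function(q) {
    folded <- q <= n_fold
    make(if (folded) base_fold else base_ext,
         if (folded) -2 else 0, q, 2000L + q)
  })
  list(polar = ensemble(mol, polar, "polar", "toy-analytic"),
       nonpolar = ensemble(mol, nonpolar, "nonpolar", "toy-analytic"))
}

#' Rigid (non-chameleonic) control ensemble pair
#'
#' Same toy chain, but both solvents sample the extended form only: no
#' IMHBs, no property separation, near-total overlap. The expected verdict
#' is non-chameleonic.
#'
#' @param spec a [toy_chain_spec()] (its `fraction_folded` is ignored).
#' @return list with elements `polar` and `nonpolar`.
#' @export
toy_rigid_ensembles <- function(spec = toy_chain_spec()) {
  spec$fraction_folded <- 0
  toy_chameleon_ensembles(spec)
}

#' Seeded Gaussian-mixture property cloud
#'
#' @param means matrix (or list) of component means, columns (rgyr, psa).
#' @param sds per-component standard deviations (recycled; scalar or
#'   two-column matrix).
#' @param weights component weights summing to 1.
#' @param n number of points.
#' @param seed RNG seed.
#' @return n x 2 matrix of (rgyr, psa3d) points.
#' @export
property_cloud <- function(means, sds = 1, weights = NULL, n = 1000L,
                           seed = 1L) {
  if (is.list(means)) means <- do.call(rbind, means)
  means <- matrix(as.numeric(means), ncol = 2L)
  m <- nrow(means)
  sds <- matrix(as.numeric(sds), nrow = m, ncol = 2L)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  comp <- sample.int(m, n, replace = TRUE, prob = weights)
  cbind(rgyr = stats::rnorm(n, means[comp, 1L], sds[comp, 1L]),
        psa3d = stats::rnorm(n, means[comp, 2L], sds[comp, 2L]))
}

# ---- distance-geometry adapter -------------------------------------------

#' Generate a conformer ensemble with an external distance-geometry engine
#'
#' Thin adapter over RDKit's ETKDG embedding followed by MMFF94
#' minimization, driven through the bundled helper script. The same seed
#' reproduces the same coordinates bit-for-bit. Conformer generation
#' itself is deliberately delegated: this package analyzes ensembles, it
#' does not sample them.
#'
#' @param mol a [molecule()] with explicit hydrogens.
#' @param n number of conformers (>= 1).
#' @param seed integer embedding seed.
#' @param solvent label attached to the returned ensemble (the embedding
#'   itself is solvent-blind; labels matter downstream).
#' @param python python interpreter with RDKit available.
#' @return an [ensemble()] with per-conformer MMFF energies.
#' @export
generate_ensemble <- function(mol, n, seed = 1L,
                              solvent = c("polar", "nonpolar"),
                              python = Sys.which("python")) {
  solvent <- match.arg(solvent)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!nzchar(python))
    stop("no python interpreter found for the distance-geometry engine",
         call. = FALSE)
  script <- system.file("python", "gen_conformers.py", package = "molcham")
  if (!nzchar(script))
    stop("bundled gen_conformers.py not found", call. = FALSE)
  fin <- tempfile(fileext = ".sdf"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  # the engine needs one 3D-ish record; flat placeholder coordinates are
  # fine, embedding ignores them
  ph <- conformer(cbind(seq_len(mol$n_atoms) * 0.1, 0, 0))
  write_sdf(mol, ph, fin)
  res <- suppressWarnings(system2(python, c(script, fin, fout,
                                            as.character(as.integer(n)),
                                            as.character(as.integer(seed))),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(fout))
    stop(sprintf("conformer embedding failed for molecule '%s': %s",
                 mol$name %||% molecular_formula(mol),
                 paste(res, collapse = " | ")), call. = FALSE)
  parsed <- parse_structure(fout, format = "sdf")
  ensemble(mol, parsed$conformers, solvent, method = "rdkit-etkdg")
}

#' Bundled example structures
#'
#' Returns one of the structure records shipped with the package (explicit
#' hydrogens, V2000 SDF): `"pomalidomide"`, `"saquinavir"`,
#' `"cyclosporin_a"`, or `"cmp98_synthetic"` -- the last is a synthetic
#' stand-in for a polar VHL-based homo-PROTAC (two thiazole-bearing VHL
#' ligands joined by a PEG linker), constructed for integration testing,
#' not the published compound's exact structure.
#'
#' @param name structure name.
#' @return a [molecule()] (the single bundled conformer is attached as
#'   attribute `"conformer"`).
#' @export
example_molecule <- function(name = c("pomalidomide", "saquinavir",
                                      "cyclosporin_a", "cmp98_synthetic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".sdf"), package = "molcham")
  if (!nzchar(path))
    stop(sprintf("bundled structure '%s' not found", name), call. = FALSE)
  parsed <- parse_structure(path, format = "sdf")
  parsed$molecule$name <- name
  structure(parsed$molecule, conformer = parsed$conformers[[1L]])
}
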