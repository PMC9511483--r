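# Geometric intramolecular hydrogen-bond (IMHB) detection. A donor
# hydrogen H (bonded to N/O/S) contacts an acceptor A (N/O/S with a lone
# pair) when the H...A distance is within an ideal value plus a distance
# relaxation, the D-H...A angle is within an ideal value minus an angle
# relaxation, and donor heavy atom and acceptor are separated by enough
# bonds to exclude trivial 1,2-/1,3-geometry artifacts.

#' IMHB geometric criteria
#'
#' Defaults accept `H...A <= d0 + relax_d = 2.5` Angstrom and
#' `D-H...A >= theta0 - relax_theta = 130` degrees, using the widely
#' adopted relaxations of 0.4 Angstrom and 20 degrees around a single
#' ideal geometry (2.1 Angstrom, 150 degrees). Both thresholds are closed
#' (a contact exactly on the relaxed boundary is detected).
#'
#' @param d0 ideal H...acceptor distance (Angstrom).
#' @param theta0 ideal donor-H...acceptor angle (degrees).
#' @param relax_d distance relaxation (Angstrom, >= 0).
#' @param relax_theta angle relaxation (degrees, >= 0).
#' @param min_separation minimum donor-heavy-atom to acceptor topological
#'   separation in bonds (>= 2; default 3).
#' @return list of class `molcham_criteria`.
#' @export
hbond_criteria <- function(d0 = 2.1, theta0 = 150, relax_d = 0.4,
                           relax_theta = 20, min_separation = 3L) {
  if (d0 <= 0 || theta0 <= 0 || theta0 > 180)
    stop("d0 must be positive and theta0 in (0, 180]", call. = FALSE)
  if (relax_d < 0 || relax_theta < 0)
    stop("relaxations must be >= 0", call. = FALSE)
  if (min_separation < 2L)
    stop("min_separation must be >= 2 bonds", call. = FALSE)
  structure(list(d0 = d0, theta0 = theta0, relax_d = relax_d,
                 relax_theta = relax_theta,
                 min_separation = as.integer(min_separation)),
            class = "molcham_criteria")
}

#' Detect intramolecular hydrogen bonds in a conformer
#'
#' Each donor hydrogen is reported with at most its best (shortest
#' distance) qualifying acceptor, unless `all_acceptors = TRUE` returns
#' the full multi-acceptor list (bifurcated geometries).
#'
#' @param conf a [conformer()].
#' @param roles donor/acceptor sets from [assign_hbond_roles()].
#' @param criteria geometric criteria from [hbond_criteria()].
#' @param mol the parent [molecule()] (for topological separations).
#' @param dist_matrix optional precomputed [bond_distance_matrix()]
#'   (pass it when scanning many conformers of one molecule).
#' @param all_acceptors keep every qualifying acceptor per hydrogen.
#' @return data frame with columns `donor_heavy`, `donor_h`, `acceptor`,
#'   `distance` (Angstrom), `angle` (degrees); zero rows when nothing is
#'   detected.
#' @export
detect_imhbs <- function(conf, roles, criteria = hbond_criteria(), mol,
                         dist_matrix = NULL, all_acceptors = FALSE) {
  stopifnot(inherits(roles, "molcham_roles"),
            inherits(criteria, "molcham_criteria"))
  x <- conf$coords
  if (length(roles$donor_h) &&
      (max(roles$donor_h, roles$acceptors) > nrow(x)))
    stop("roles refer to atoms beyond the conformer's coordinates",
         call. = FALSE)
  empty <- data.frame(donor_heavy = integer(), donor_h = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  if (!length(roles$donor_h) || !length(roles$acceptors)) return(empty)
  if (is.null(dist_matrix)) dist_matrix <- bond_distance_matrix(mol)
  dmax <- criteria$d0 + criteria$relax_d
  amin <- criteria$theta0 - criteria$relax_theta
  out <- empty
  for (k in seq_along(roles$donor_h)) {
    h <- roles$donor_h[k]; dheavy <- roles$donor_heavy[k]
    acc <- roles$acceptors[roles$acceptors != dheavy]
    acc <- acc[dist_matrix[dheavy, acc] >= criteria$min_separation]
    if (!length(acc)) next
    dv <- sqrt(colSums((t(x[acc, , drop = FALSE]) - x[h, ])^2))
    keep <- which(dv <= dmax + 1e-12)
    if (!length(keep)) next
    hd <- x[dheavy, ] - x[h, ]
    ang <- vapply(keep, function(q) {
      ha <- x[acc[q], ] - x[h, ]
      cosv <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
      acos(max(-1, min(1, cosv))) * 180 / pi
    }, numeric(1))
    ok <- keep[ang >= amin - 1e-9]
    if (!length(ok)) next
    hits <- data.frame(donor_heavy = dheavy, donor_h = h,
                       acceptor = acc[ok], distance = dv[ok],
                       angle = ang[match(ok, keep)])
    if (!all_acceptors && nrow(hits) > 1L)
      hits <- hits[which.min(hits$distance), , drop = FALSE]
    out <- rbind(out, hits)
  }
  rownames(out) <- NULL
  out
}

imhb_counts <- function(ens, criteria = hbond_criteria()) {
  mol <- ens$molecule
  roles <- assign_hbond_roles(mol)
  dmat <- bond_distance_matrix(mol)
  vapply(ens$conformers, function(cf)
    nrow(detect_imhbs(cf, roles, criteria, mol, dist_matrix = dmat)),
    numeric(1))
}

imhb_pair_frequencies <- function(ens, criteria = hbond_criteria()) {
  mol <- ens$molecule
  roles <- assign_hbond_roles(mol)
  dmat <- bond_distance_matrix(mol)
  n <- length(ens$conformers)
  tallies <- new.env(parent = emptyenv())
  for (cf in ens$conformers) {
    hits <- detect_imhbs(cf, roles, criteria, mol, dist_matrix = dmat)
    # pair identity: donor heavy atom + acceptor, whichever hydrogen
    pairs <- unique(paste(hits$donor_heavy, hits$acceptor, sep = "-"))
    for (p in pairs) assign(p, (tallies[[p]] %||% 0) + 1, envir = tallies)
  }
  keys <- ls(tallies)
  if (!length(keys))
    return(data.frame(donor_heavy = integer(), acceptor = integer(),
                      frequency = numeric()))
  parts <- do.call(rbind, strsplit(keys, "-"))
  data.frame(donor_heavy = as.integer(parts[, 1]),
             acceptor = as.integer(parts[, 2]),
             frequency = vapply(keys, function(p) tallies[[p]] / n,
                                numeric(1)),
             row.names = NULL)
}

#' Cross-solvent IMHB profile of an ensemble pair
#'
#' Counts IMHBs in every conformer of the polar and nonpolar ensembles and
#' reports per-solvent mean and median together with
#' `delta_mean = mean(nonpolar) - mean(polar)` (the nonpolar-minus-water
#' convention: positive values mean more IMHBs in the nonpolar medium).
#' Per-pair occurrence frequencies feed [classify_imhb_persistence()].
#'
#' @param polar,nonpolar [ensemble()]s sharing one topology.
#' @param criteria geometric criteria from [hbond_criteria()].
#' @return list of class `molcham_imhb_profile` with `counts_polar`,
#'   `counts_nonpolar`, `mean_polar`, `mean_nonpolar`, `median_polar`,
#'   `median_nonpolar`, `delta_mean`, and a `pairs` data frame with
#'   per-pair frequencies `f_polar`, `f_nonpolar`.
#' @export
ensemble_imhb_profile <- function(polar, nonpolar,
                                  criteria = hbond_criteria()) {
  stopifnot(inherits(polar, "molcham_ens"), inherits(nonpolar, "molcham_ens"))
  if (polar$solvent != "polar" || nonpolar$solvent != "nonpolar")
    stop("arguments must be a polar and a nonpolar ensemble, in that order",
         call. = FALSE)
  if (!identical(polar$molecule$elements, nonpolar$molecule$elements) ||
      !identical(polar$molecule$bonds, nonpolar$molecule$bonds))
    stop("topology mismatch between polar and nonpolar ensembles",
         call. = FALSE)
  cp <- imhb_counts(polar, criteria)
  cn <- imhb_counts(nonpolar, criteria)
  fp <- imhb_pair_frequencies(polar, criteria)
  fn <- imhb_pair_frequencies(nonpolar, criteria)
  pairs <- merge(fp, fn, by = c("donor_heavy", "acceptor"),
                 all = TRUE, suffixes = c("_polar", "_nonpolar"))
  names(pairs)[names(pairs) == "frequency_polar"] <- "f_polar"
  names(pairs)[names(pairs) == "frequency_nonpolar"] <- "f_nonpolar"
  if (nrow(pairs)) {
    pairs$f_polar[is.na(pairs$f_polar)] <- 0
    pairs$f_nonpolar[is.na(pairs$f_nonpolar)] <- 0
  } else {
    pairs <- data.frame(donor_heavy = integer(), acceptor = integer(),
                        f_polar = numeric(), f_nonpolar = numeric())
  }
  structure(list(counts_polar = cp, counts_nonpolar = cn,
                 mean_polar = mean(cp), mean_nonpolar = mean(cn),
                 median_polar = stats::median(cp),
                 median_nonpolar = stats::median(cn),
                 delta_mean = mean(cn) - mean(cp),
                 pairs = pairs),
            class = "molcham_imhb_profile")
}

#' Classify IMHB persistence across solvents
#'
#' A donor-acceptor pair is `static` when it occurs with frequency at
#' least `tau` in both ensembles, `dynamic` when frequent only in the
#' nonpolar one, `polar-only` when frequent only in water, else `absent`.
#'
#' @param pairs data frame with `f_polar` and `f_nonpolar` columns (e.g.
#'   the `pairs` element of [ensemble_imhb_profile()]).
#' @param tau occupancy threshold in (0, 1); default 0.2.
#' @return the input data frame with an added `class` column.
#' @export
classify_imhb_persistence <- function(pairs, tau = 0.2) {
  if (inherits(pairs, "molcham_imhb_profile")) pairs <- pairs$pairs
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)", call. = FALSE)
  cls <- ifelse(pairs$f_polar >= tau & pairs$f_nonpolar >= tau, "static",
         ifelse(pairs$f_nonpolar >= tau, "dynamic",
         ifelse(pairs$f_polar >= tau, "polar-only", "absent")))
  pairs$class <- if (nrow(pairs)) cls else character()
  pairs
}

#' Write an IMHB contact table as TSV
#'
#' @param ens an [ensemble()].
#' @param path output path.
#' @param criteria geometric criteria.
#' @return `path`, invisibly.
#' @export
write_imhb_table <- function(ens, path, criteria = hbond_criteria()) {
  mol <- ens$molecule
  roles <- assign_hbond_roles(mol)
  dmat <- bond_distance_matrix(mol)
  rows <- lapply(ens$conformers, function(cf) {
    hits <- detect_imhbs(cf, roles, criteria, mol, dist_matrix = dmat)
    if (!nrow(hits)) return(NULL)
    cbind(conformer_id = cf$id, hits)
  })
  rows <- Filter(Negate(is.null), rows)
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(conformer_id = integer(), donor_heavy = integer(),
                  donor_h = integer(), acceptor = integer(),
                  distance = numeric(), angle = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
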