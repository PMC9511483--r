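# Chameleonicity assessment. A molecular chameleon adopts polar, open
# conformers in water and less polar, more compact conformers in nonpolar
# media, with interconverting populations. Three quantitative criteria are
# scored on the (Rgyr, 3D PSA) ensembles: (a) cross-solvent separation of
# the property distributions, (b) a congruent-conformer overlap region
# shared by both solvents, (c) attainment of the topological PSA by the
# most polar water conformers; solvent-specific (dynamic) IMHB formation
# completes the verdict.

#' Cross-solvent separation score of a property
#'
#' `(median(polar) - median(nonpolar)) / IQR(pooled values)`, computed for
#' 3D PSA and Rgyr. Positive PSA separation means the molecule is more
#' polar in water. Identical distributions score 0; a zero pooled IQR with
#' unequal medians returns a signed infinite sentinel with a warning.
#'
#' @param polar,nonpolar per-conformer descriptor data frames (columns
#'   `psa3d`, `rgyr`).
#' @return named numeric vector with elements `psa` and `rgyr`.
#' @export
polarity_separation <- function(polar, nonpolar) {
  if (nrow(polar) < 2L || nrow(nonpolar) < 2L)
    stop("need at least 2 records per solvent", call. = FALSE)
  one <- function(vp, vn) {
    dm <- stats::median(vp) - stats::median(vn)
    iqr <- stats::IQR(c(vp, vn))
    if (iqr == 0) {
      if (dm == 0) return(0)
      warning("zero pooled IQR with unequal medians: returning Inf sentinel",
              call. = FALSE)
      return(sign(dm) * Inf)
    }
    dm / iqr
  }
  c(psa = one(polar$psa3d, nonpolar$psa3d),
    rgyr = one(polar$rgyr, nonpolar$rgyr))
}

#' Congruent-conformer overlap between solvents
#'
#' Overlap coefficient of the two tiled property distributions on a shared
#' grid: `sum over tiles of min(freq_polar, freq_nonpolar)` with each
#' solvent's tile frequencies summing to 1. 1 means identical tile
#' occupancy, 0 fully disjoint property ranges. The grid must be built on
#' pooled bounds so both ensembles are binned identically.
#'
#' @param polar,nonpolar per-conformer descriptor data frames.
#' @param grid a [tile_density()] grid carrying the shared edges (only its
#'   edges are used); default builds a 25 x 25 grid on pooled bounds.
#' @return overlap in [0, 1].
#' @export
congruence_overlap <- function(polar, nonpolar, grid = NULL) {
  pooled <- rbind(polar[, c("rgyr", "psa3d")], nonpolar[, c("rgyr", "psa3d")])
  if (is.null(grid)) grid <- tile_density(pooled)
  bounds <- list(x = range(grid$x_edges), y = range(grid$y_edges))
  nt <- length(grid$x_edges) - 1L
  gp <- tile_density(polar[, c("rgyr", "psa3d")], bounds = bounds,
                     n_tiles = nt)
  gn <- tile_density(nonpolar[, c("rgyr", "psa3d")], bounds = bounds,
                     n_tiles = nt)
  sum(pmin(grid_frequencies(gp), grid_frequencies(gn)))
}

#' TPSA attainment ratio
#'
#' `MaxPSA(polar) / TPSA`: how close the most polar water conformer comes
#' to exposing the full fragment-based polar surface. Values near (or
#' above) 1 indicate the ensemble reaches its topological polarity.
#'
#' @param polar_summary summary from [summarize_ensemble()] of the polar
#'   ensemble.
#' @param tpsa_value topological PSA (Angstrom^2), must be > 0.
#' @return dimensionless ratio in [0, Inf).
#' @export
tpsa_attainment <- function(polar_summary, tpsa_value) {
  if (is.na(tpsa_value) || tpsa_value <= 0)
    stop("attainment ratio undefined for TPSA <= 0", call. = FALSE)
  polar_summary$max_psa / tpsa_value
}

#' Default chameleonicity thresholds
#'
#' The three criteria are stated qualitatively in the field; these numeric
#' operating points are declared package defaults: a separation of at
#' least half a pooled IQR (`s_min`), at least 5% congruent tile overlap
#' (`o_min`), and at least 90% TPSA attainment (`c_min`).
#'
#' @param s_min minimum PSA separation score.
#' @param o_min minimum congruence overlap.
#' @param c_min minimum TPSA attainment ratio.
#' @param tau IMHB persistence occupancy threshold, see
#'   [classify_imhb_persistence()].
#' @return named list.
#' @export
chameleon_thresholds <- function(s_min = 0.5, o_min = 0.05, c_min = 0.9,
                                 tau = 0.2) {
  list(s_min = s_min, o_min = o_min, c_min = c_min, tau = tau)
}

#' Assess chameleonicity of a polar/nonpolar ensemble pair
#'
#' Combines the separation, overlap and attainment criteria with the IMHB
#' profile into a scored verdict. The verdict is `chameleonic` iff all of:
#' criterion (a) PSA separation >= `s_min` with the nonpolar ensemble less
#' polar; (b) overlap >= `o_min`; (c) attainment >= `c_min`; and the IMHB
#' pattern is gainful and solvent-specific (`delta_mean > 0`, at least one
#' dynamic pair, static pairs not outnumbering dynamic ones). Missing
#' inputs produce an `indeterminate` verdict with a reason code rather
#' than an error. Reason codes enumerate every failed clause.
#'
#' @param polar_records,nonpolar_records per-conformer descriptor data
#'   frames (or NULL when unavailable).
#' @param tpsa_value topological PSA of the molecule (Angstrom^2).
#' @param imhb_profile an [ensemble_imhb_profile()] (or NULL).
#' @param thresholds list from [chameleon_thresholds()].
#' @return list of class `molcham_report` with scores, per-criterion
#'   flags, persistence tallies, `verdict` and `reasons`.
#' @export
assess_chameleonicity <- function(polar_records, nonpolar_records,
                                  tpsa_value, imhb_profile,
                                  thresholds = chameleon_thresholds()) {
  missing_in <- c(
    if (is.null(polar_records) || !nrow(polar_records)) "polar-ensemble",
    if (is.null(nonpolar_records) || !nrow(nonpolar_records)) "nonpolar-ensemble",
    if (is.null(tpsa_value) || is.na(tpsa_value)) "tpsa",
    if (is.null(imhb_profile)) "imhb-profile")
  if (length(missing_in)) {
    return(structure(list(
      separation = c(psa = NA_real_, rgyr = NA_real_),
      overlap = NA_real_, attainment = NA_real_, delta_mean_imhb = NA_real_,
      persistence = data.frame(),
      tallies = c(static = NA_integer_, dynamic = NA_integer_,
                  `polar-only` = NA_integer_, absent = NA_integer_),
      flags = c(a = NA, b = NA, c = NA, imhb = NA),
      thresholds = thresholds,
      verdict = "indeterminate",
      reasons = paste0("missing-", missing_in)), class = "molcham_report"))
  }
  sep <- polarity_separation(polar_records, nonpolar_records)
  ovl <- congruence_overlap(polar_records, nonpolar_records)
  att <- tpsa_attainment(summarize_ensemble(polar_records), tpsa_value)
  pers <- classify_imhb_persistence(imhb_profile$pairs, thresholds$tau)
  tal <- c(static = sum(pers$class == "static"),
           dynamic = sum(pers$class == "dynamic"),
           `polar-only` = sum(pers$class == "polar-only"),
           absent = sum(pers$class == "absent"))
  dm <- imhb_profile$delta_mean
  flag_a <- is.finite(sep["psa"]) && sep[["psa"]] >= thresholds$s_min
  flag_b <- ovl >= thresholds$o_min
  flag_c <- att >= thresholds$c_min
  imhb_gain <- dm > 0
  imhb_dynamic <- tal[["dynamic"]] >= 1L && tal[["static"]] <= tal[["dynamic"]]
  reasons <- c(
    if (!flag_a) "no-separation",
    if (!flag_b) "no-overlap",
    if (!flag_c) "low-tpsa-attainment",
    if (!imhb_gain) "no-imhb-gain",
    if (!imhb_dynamic) "static-imhb")
  verdict <- if (flag_a && flag_b && flag_c && imhb_gain && imhb_dynamic)
    "chameleonic" else "non-chameleonic"
  structure(list(
    separation = sep, overlap = ovl, attainment = att,
    delta_mean_imhb = dm, persistence = pers, tallies = tal,
    flags = c(a = flag_a, b = flag_b, c = flag_c,
              imhb = imhb_gain && imhb_dynamic),
    thresholds = thresholds,
    verdict = verdict, reasons = reasons), class = "molcham_report")
}

#' @export
print.molcham_report <- function(x, ...) {
  cat("<chameleonicity report>\n")
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (length(x$reasons)) paste0(" [", paste(x$reasons,
                                                        collapse = ", "), "]")
              else ""))
  if (!anyNA(x$flags)) {
    cat(sprintf("  (a) PSA separation %.3f (Rgyr %.3f)  (b) overlap %.3f  (c) attainment %.3f\n",
                x$separation[["psa"]], x$separation[["rgyr"]],
                x$overlap, x$attainment))
    cat(sprintf("  IMHB delta-mean (nonpolar - water): %.3f; pairs: %s\n",
                x$delta_mean_imhb,
                paste(names(x$tallies), x$tallies, sep = "=",
                      collapse = " ")))
  }
  invisible(x)
}

#' Serialize a chameleonicity report to JSON
#'
#' @param report a [assess_chameleonicity()] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    verdict = report$verdict,
    reasons = as.list(report$reasons),
    scores = list(
      psa_separation = report$separation[["psa"]],
      rgyr_separation = report$separation[["rgyr"]],
      overlap = report$overlap,
      tpsa_attainment = report$attainment,
      delta_mean_imhb = report$delta_mean_imhb),
    flags = as.list(report$flags),
    imhb_persistence = as.list(report$tallies),
    thresholds = report$thresholds)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
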