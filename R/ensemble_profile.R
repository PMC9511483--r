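# Ensemble-level summary statistics over per-conformer descriptors and
# cross-solvent delta metrics.

#' Summarize descriptor statistics of one ensemble
#'
#' Min and Max of 3D PSA and Rgyr are reported together with the ids of
#' the conformers realizing them (these are real ensemble members);
#' Average and Median are plain ensemble statistics and generally do not
#' correspond to any real conformer. The median of an even-sized set is
#' the midpoint of the central pair; ties for an extreme go to the lowest
#' conformer id.
#'
#' @param records data frame of per-conformer descriptors with columns
#'   `conformer_id`, `psa3d`, `rgyr` (see [conformer_records()]).
#' @return one-row data frame: `min_psa`, `max_psa`, `average_psa`,
#'   `median_psa`, `id_min_psa`, `id_max_psa`, and the Rgyr analogues.
#' @export
summarize_ensemble <- function(records) {
  if (is.null(records) || nrow(records) < 1L)
    stop("cannot summarize an empty ensemble", call. = FALSE)
  pick <- function(v, which_fun) {
    idx <- which(v == which_fun(v))
    records$conformer_id[idx[which.min(records$conformer_id[idx])]]
  }
  data.frame(
    n = nrow(records),
    min_psa = min(records$psa3d), max_psa = max(records$psa3d),
    average_psa = mean(records$psa3d),
    median_psa = stats::median(records$psa3d),
    id_min_psa = pick(records$psa3d, min),
    id_max_psa = pick(records$psa3d, max),
    min_rgyr = min(records$rgyr), max_rgyr = max(records$rgyr),
    average_rgyr = mean(records$rgyr),
    median_rgyr = stats::median(records$rgyr),
    id_min_rgyr = pick(records$rgyr, min),
    id_max_rgyr = pick(records$rgyr, max))
}

#' Cross-solvent polarity swing
#'
#' `MaxPSA(polar) - MinPSA(nonpolar)`: how much polar surface the molecule
#' can expose in water beyond what it can bury in the nonpolar medium.
#' Returned unclamped (a negative value means the nonpolar minimum exceeds
#' the polar maximum).
#'
#' @param polar,nonpolar summaries from [summarize_ensemble()].
#' @return area in Angstrom^2.
#' @export
delta_max_min <- function(polar, nonpolar) {
  polar$max_psa - nonpolar$min_psa
}

#' Lowest-energy conformer of an ensemble
#'
#' @param ens an [ensemble()] whose conformers all carry energies.
#' @return conformer id of the minimum-energy member (ties go to the
#'   lowest id).
#' @export
lowest_energy_conformer <- function(ens) {
  stopifnot(inherits(ens, "molcham_ens"))
  en <- vapply(ens$conformers, function(cf)
    if (is.null(cf$energy)) NA_real_ else as.numeric(cf$energy), numeric(1))
  if (anyNA(en))
    stop("all conformers must carry energies", call. = FALSE)
  ids <- vapply(ens$conformers, function(cf) cf$id, numeric(1))
  cand <- ids[en == min(en)]
  min(cand)
}

#' Bravais-Pearson correlation coefficient
#'
#' Standard product-moment correlation with explicit guards: both series
#' must have equal length of at least 3 and be nonconstant.
#'
#' @param x,y numeric series.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  stats::cor(x, y)
}

#' Export per-solvent summaries as JSON
#'
#' @param summaries named list of one-row data frames from
#'   [summarize_ensemble()] (e.g. `list(polar = ..., nonpolar = ...)`).
#' @param path output path.
#' @param extra optional named list merged into the JSON root (e.g. the
#'   cross-solvent delta).
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summaries, path, extra = list()) {
  payload <- c(lapply(summaries, function(s) as.list(s)), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
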