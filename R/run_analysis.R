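# End-to-end orchestration: from a pair of solvent-labeled ensembles to
# descriptor tables, summaries, density maps, representative conformers
# and the chameleonicity report.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the package defaults.
#' Unknown names are rejected up front, before any computation.
#'
#' @param ... overrides of the defaults (see Details in the package
#'   vignette): `psa_mode`, `probe`, `points_per_atom`, `rgyr_weighting`,
#'   `tpsa_mode`, `criteria` ([hbond_criteria()]), `thresholds`
#'   ([chameleon_thresholds()]), `n_tiles`, `convergence_multiple`,
#'   `volume`, `write_plots`, `seed`.
#' @return named list of class `molcham_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(psa_mode = "NO", probe = 0, points_per_atom = 1024L,
              rgyr_weighting = "mass", tpsa_mode = "NO",
              criteria = hbond_criteria(),
              thresholds = chameleon_thresholds(),
              n_tiles = 25L, convergence_multiple = 3,
              volume = FALSE, write_plots = FALSE, seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "molcham_config")
}

#' Load an analysis configuration from YAML
#'
#' Scalar keys map directly; `criteria` and `thresholds` may be given as
#' nested mappings of the respective constructor arguments.
#'
#' @param path YAML file.
#' @return a [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$criteria)) raw$criteria <- do.call(hbond_criteria, raw$criteria)
  if (!is.null(raw$thresholds))
    raw$thresholds <- do.call(chameleon_thresholds, raw$thresholds)
  do.call(analysis_config, raw)
}

#' Run the full chameleonicity analysis on an ensemble pair
#'
#' Computes per-conformer descriptors for both solvents, per-solvent
#' summaries with the cross-solvent polarity swing, the IMHB profile and
#' persistence classes, pooled density grids with mode detection and
#' representative conformers, and the chameleonicity verdict. All outputs
#' are written under `outdir` (TSV/JSON/SDF, plus PNG maps when
#' `write_plots`). With `nonpolar = NULL` a partial report is produced and
#' the verdict is `indeterminate`.
#'
#' @param polar polar [ensemble()].
#' @param nonpolar nonpolar [ensemble()] or NULL.
#' @param outdir output directory (created if needed); NULL writes nothing.
#' @param config a [analysis_config()].
#' @return list with `records`, `summaries`, `profile`, `grids`, `modes`,
#'   `representatives` and `report`.
#' @export
run_analysis <- function(polar, nonpolar = NULL, outdir = NULL,
                         config = analysis_config()) {
  stopifnot(inherits(polar, "molcham_ens"), inherits(config, "molcham_config"))
  mol <- polar$molecule
  recs <- function(ens) conformer_records(
    ens, psa_mode = config$psa_mode, probe = config$probe,
    points_per_atom = config$points_per_atom,
    weighting = config$rgyr_weighting, criteria = config$criteria,
    volume = config$volume)
  rp <- recs(polar)
  rn <- if (!is.null(nonpolar)) recs(nonpolar) else NULL
  tp <- tpsa(mol, config$tpsa_mode)
  profile <- if (!is.null(nonpolar))
    ensemble_imhb_profile(polar, nonpolar, config$criteria) else NULL
  summaries <- list(polar = summarize_ensemble(rp))
  if (!is.null(rn)) summaries$nonpolar <- summarize_ensemble(rn)
  report <- assess_chameleonicity(rp, rn, tp, profile, config$thresholds)

  pooled <- rbind(rp, rn)
  grid <- tile_density(pooled[, c("rgyr", "psa3d")], n_tiles = config$n_tiles)
  bounds <- list(x = range(grid$x_edges), y = range(grid$y_edges))
  grids <- list(polar = tile_density(rp[, c("rgyr", "psa3d")],
                                     bounds = bounds,
                                     n_tiles = config$n_tiles))
  if (!is.null(rn))
    grids$nonpolar <- tile_density(rn[, c("rgyr", "psa3d")], bounds = bounds,
                                   n_tiles = config$n_tiles)
  modes <- lapply(grids, find_modes,
                  convergence_multiple = config$convergence_multiple)
  reps <- list()
  for (sv in names(modes)) {
    md <- modes[[sv]]$modes
    if (nrow(md)) {
      rr <- if (sv == "polar") rp else rn
      reps[[sv]] <- representative_conformers(rr, md[1L, ])
    }
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_descriptor_table(pooled, file.path(outdir, "descriptors.tsv"))
    extra <- list(tpsa = tp)
    if (!is.null(rn))
      extra$delta_max_p_min_np <- delta_max_min(summaries$polar,
                                                summaries$nonpolar)
    write_summary_json(summaries, file.path(outdir, "summary.json"), extra)
    write_imhb_table(polar, file.path(outdir, "imhb_polar.tsv"),
                     config$criteria)
    if (!is.null(nonpolar)) {
      write_imhb_table(nonpolar, file.path(outdir, "imhb_nonpolar.tsv"),
                       config$criteria)
      utils::write.table(classify_imhb_persistence(profile$pairs,
                                                   config$thresholds$tau),
                         file.path(outdir, "imhb_persistence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (sv in names(grids)) {
      write_density_table(grids[[sv]],
                          file.path(outdir, sprintf("density_%s.tsv", sv)))
      if (isTRUE(config$write_plots))
        plot_density_map(grids[[sv]],
                         file.path(outdir, sprintf("density_%s.png", sv)),
                         main = sv,
                         border = if (sv == "polar") "blue" else "orange")
    }
    for (sv in names(reps)) {
      ens <- if (sv == "polar") polar else nonpolar
      ids <- vapply(ens$conformers, function(cf) cf$id, numeric(1))
      cf <- ens$conformers[[which(ids == reps[[sv]])[1L]]]
      write_sdf(mol, cf,
                file.path(outdir, sprintf("representative_%s.sdf", sv)))
    }
    write_report_json(report, file.path(outdir, "report.json"))
  }
  list(records = list(polar = rp, nonpolar = rn), summaries = summaries,
       tpsa = tp, profile = profile, grids = grids, modes = modes,
       representatives = reps, report = report)
}
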