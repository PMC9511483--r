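# Tiled 2D property-density analysis over (Rgyr, 3D PSA): histogram grid,
# mode (high-density cluster) detection with a convergence flag, and
# representative-conformer selection by closeness to a mode center.

#' Tile a 2D property cloud into a density grid
#'
#' Half-open bins `[low, high)`, lower edge inclusive; the top edge of
#' each axis is inclusive so every point is counted exactly once. Default
#' tile sizes split each axis range into 25 tiles; pass explicit
#' `tile_sizes`/`bounds` (e.g. computed on pooled two-solvent data) to
#' make grids comparable across ensembles.
#'
#' @param points two-column matrix or data frame of (rgyr, psa3d) points.
#' @param tile_sizes optional numeric pair: tile edge on each axis
#'   (Angstrom, Angstrom^2).
#' @param bounds optional list with `x` and `y` ranges (length-2 each).
#' @param n_tiles tiles per axis used when `tile_sizes` is NULL.
#' @return list of class `molcham_grid`: `x_edges`, `y_edges`, `counts`
#'   (matrix, x along rows), `n`.
#' @export
tile_density <- function(points, tile_sizes = NULL, bounds = NULL,
                         n_tiles = 25L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 1L) stop("need at least one point", call. = FALSE)
  bad <- which(!is.finite(pts[, 1]) | !is.finite(pts[, 2]))
  if (length(bad))
    stop(sprintf("non-finite point at index %d", bad[1L]), call. = FALSE)
  rng <- function(k) {
    r <- if (!is.null(bounds)) range(bounds[[k]]) else range(pts[, k])
    if (diff(r) == 0) r + c(-0.5, 0.5) else r
  }
  rx <- rng(1); ry <- rng(2)
  edges <- function(r, size) {
    if (is.null(size)) return(seq(r[1], r[2], length.out = n_tiles + 1L))
    if (size <= 0) stop("tile sizes must be positive", call. = FALSE)
    e <- seq(r[1], r[2] + size, by = size)
    if (utils::tail(e, 1) < r[2]) e <- c(e, utils::tail(e, 1) + size)
    e
  }
  xe <- edges(rx, tile_sizes[1]); ye <- edges(ry, tile_sizes[2])
  bin <- function(v, e) {
    k <- findInterval(v, e, rightmost.closed = TRUE)
    k[k < 1L | k > length(e) - 1L] <- NA_integer_
    k
  }
  bx <- bin(pts[, 1], xe); by <- bin(pts[, 2], ye)
  counts <- matrix(0L, length(xe) - 1L, length(ye) - 1L)
  ok <- !is.na(bx) & !is.na(by)
  for (k in which(ok)) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1L
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 n = sum(ok), n_dropped = sum(!ok)),
            class = "molcham_grid")
}

grid_frequencies <- function(grid) grid$counts / max(grid$n, 1L)

tile_centers <- function(grid) {
  list(x = (grid$x_edges[-1] + grid$x_edges[-length(grid$x_edges)]) / 2,
       y = (grid$y_edges[-1] + grid$y_edges[-length(grid$y_edges)]) / 2)
}

#' Find density modes (high-density clusters) in a grid
#'
#' A mode is an occupied tile whose count is not exceeded by any of its
#' 8-connected neighbors; competing nearby maxima are collapsed by
#' non-maximum suppression within a Chebyshev radius of
#' `suppression_radius` tiles (ties resolve to the higher count, then the
#' lower tile index, deterministically). A mode is `converged` when its
#' count reaches `convergence_multiple` times the mean count of occupied
#' tiles and also exceeds that mean by at least four Poisson standard
#' deviations -- the significance guard keeps sparse-count noise spikes
#' from registering as clusters. When no tile qualifies, the grid as a
#' whole is flagged non-converged, mirroring the dispersed
#' no-high-density-region pattern of poorly clustering ensembles.
#'
#' @param grid a [tile_density()] grid.
#' @param convergence_multiple threshold multiple of the mean occupied-tile
#'   density (default 3).
#' @param suppression_radius Chebyshev radius (tiles) for collapsing
#'   competing local maxima (default 2).
#' @return list of class `molcham_modes`: data frame `modes` (tile indices,
#'   center coordinates, count, converged flag, ranked by count) and
#'   logical `converged` (any converged mode).
#' @export
find_modes <- function(grid, convergence_multiple = 3,
                       suppression_radius = 2L) {
  cnt <- grid$counts
  occ <- which(cnt > 0L)
  if (!length(occ))
    return(structure(list(modes = data.frame(), converged = FALSE),
                     class = "molcham_modes"))
  mean_occ <- mean(cnt[occ])
  threshold <- max(convergence_multiple * mean_occ,
                   mean_occ + 4 * sqrt(mean_occ))
  nx <- nrow(cnt); ny <- ncol(cnt)
  is_cand <- matrix(FALSE, nx, ny)
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    v <- cnt[ix, iy]
    if (v == 0L) next
    nb <- cnt[max(1, ix - 1):min(nx, ix + 1), max(1, iy - 1):min(ny, iy + 1)]
    if (v >= max(nb)) is_cand[ix, iy] <- TRUE
  }
  cand <- which(is_cand, arr.ind = TRUE)
  # non-maximum suppression: strongest first; a later candidate within the
  # radius of a kept one is absorbed into it
  ord <- order(-cnt[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    kept <- which(keep)
    clash <- length(kept) > 0 &&
      any(abs(cand[kept, 1] - cand[k, 1]) <= suppression_radius &
          abs(cand[kept, 2] - cand[k, 2]) <= suppression_radius)
    keep[k] <- !clash
  }
  cand <- cand[keep, , drop = FALSE]
  ctr <- tile_centers(grid)
  modes <- data.frame(
    tile_x = cand[, 1], tile_y = cand[, 2],
    x = ctr$x[cand[, 1]], y = ctr$y[cand[, 2]],
    count = cnt[cand],
    converged = cnt[cand] >= threshold)
  rownames(modes) <- NULL
  structure(list(modes = modes, converged = any(modes$converged),
                 threshold = threshold),
            class = "molcham_modes")
}

#' Representative conformer closest to a density-mode center
#'
#' Distances are measured in z-scored property space (Angstrom and
#' Angstrom^2 are incommensurable): each axis is centered and scaled by
#' the mean and standard deviation of the supplied records. Ties go to
#' the lowest conformer id.
#'
#' @param records data frame with `conformer_id`, `rgyr`, `psa3d` columns.
#' @param mode one row of the `modes` table from [find_modes()] (needs
#'   `x` = Rgyr center and `y` = PSA center), or any list with `x`, `y`.
#' @return the selected `conformer_id`.
#' @export
representative_conformers <- function(records, mode) {
  if (nrow(records) < 1L) stop("need at least one record", call. = FALSE)
  mx <- mean(records$rgyr); sx <- stats::sd(records$rgyr)
  my <- mean(records$psa3d); sy <- stats::sd(records$psa3d)
  if (is.na(sx) || sx == 0) sx <- 1
  if (is.na(sy) || sy == 0) sy <- 1
  d2 <- ((records$rgyr - mode$x[1]) / sx)^2 +
        ((records$psa3d - mode$y[1]) / sy)^2
  hit <- which(d2 == min(d2))
  records$conformer_id[hit[which.min(records$conformer_id[hit])]]
}

#' Write a density grid as TSV (tile centers and counts)
#'
#' @param grid a [tile_density()] grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(grid, path) {
  ctr <- tile_centers(grid)
  df <- expand.grid(rgyr = ctr$x, psa3d = ctr$y)
  df$count <- as.vector(grid$counts)
  df$frequency <- as.vector(grid_frequencies(grid))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a density map to PNG
#'
#' Per-tile frequency color scale with optional solvent-colored perimeter.
#'
#' @param grid a [tile_density()] grid.
#' @param path output PNG path.
#' @param main plot title.
#' @param border perimeter color (e.g. blue for water, orange for the
#'   nonpolar solvent).
#' @return `path`, invisibly.
#' @export
plot_density_map <- function(grid, path, main = "", border = "blue") {
  ctr <- tile_centers(grid)
  grDevices::png(path, width = 900, height = 750, res = 130)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(ctr$x, ctr$y, grid_frequencies(grid), col = pal,
                  xlab = "Rgyr (Angstrom)", ylab = "3D PSA (Angstrom^2)",
                  main = main)
  graphics::box(col = border, lwd = 3)
  invisible(path)
}
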