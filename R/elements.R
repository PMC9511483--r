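# Element data used across the package: standard atomic weights (amu),
# Bondi van der Waals radii (Angstrom) and covalent radii (Angstrom, for
# bond inference from geometry when a format carries no connectivity).

.element_table <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S",
             "Cl", "K", "Ca", "Se", "Br", "I"),
  mass   = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
             28.085, 30.974, 32.06, 35.45, 39.098, 40.078, 78.971, 79.904,
             126.904),
  vdw    = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.27, 1.73, 2.10, 1.80,
             1.80, 1.75, 2.75, 2.31, 1.90, 1.85, 1.98),
  cov    = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.11, 1.07,
             1.05, 1.02, 2.03, 1.76, 1.20, 1.20, 1.39),
  stringsAsFactors = FALSE
)

normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

element_property <- function(symbols, what, context = "element") {
  idx <- match(normalize_element(symbols), .element_table$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop(sprintf("unknown %s symbol(s): %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  .element_table[[what]][idx]
}

#' Standard atomic weights
#'
#' @param symbols character vector of element symbols.
#' @return numeric vector of atomic masses (amu).
#' @export
atomic_mass <- function(symbols) element_property(symbols, "mass")

#' Bondi van der Waals radii set
#'
#' Returns the default radii set used by [psa_3d()] and [vdw_volume()]:
#' the Bondi compilation (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80
#' Angstrom, ...). Radii can be overridden entry-wise.
#'
#' @param ... named overrides, e.g. `bondi_radii(S = 1.85)`.
#' @return named numeric vector (Angstrom) with a `"name"` attribute.
#' @export
bondi_radii <- function(...) {
  r <- stats::setNames(.element_table$vdw, .element_table$symbol)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("radius overrides must be named by element symbol", call. = FALSE)
    r[normalize_element(names(dots))] <- as.numeric(unlist(dots))
  }
  if (any(r <= 0)) stop("all radii must be > 0", call. = FALSE)
  attr(r, "name") <- "bondi"
  r
}

radius_for <- function(symbols, radii) {
  idx <- match(normalize_element(symbols), names(radii))
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop(sprintf("no van der Waals radius for element(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  as.numeric(radii[idx])
}
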