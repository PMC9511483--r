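# Topological polar surface area from published fragment contributions
# (Ertl, Rohde & Selzer 2000): every polar atom is matched to a bonding
# environment and its tabulated surface contribution is summed. The result
# is conformation-independent and pairs with psa_3d() as its ensemble
# upper-envelope index.

# Environment keys: element | aromatic | charge | nH | counts of non-H
# single/double/triple bonds | aromatic bond count | in-3-ring flag.
.tpsa_env <- function(el, arom, chg, nH, s, d, t, na, ring3) {
  paste(el, as.integer(arom), chg, nH, s, d, t, na, as.integer(ring3),
        sep = "|")
}

.tpsa_table <- local({
  e <- function(el, arom, chg, nH, s, d, t, na, ring3, val)
    stats::setNames(val, .tpsa_env(el, arom, chg, nH, s, d, t, na, ring3))
  c(
    # nitrogen, non-aromatic, neutral
    e("N", 0, 0, 0, 3, 0, 0, 0, 0, 3.24),
    e("N", 0, 0, 0, 1, 1, 0, 0, 0, 12.36),
    e("N", 0, 0, 0, 0, 0, 1, 0, 0, 23.79),
    e("N", 0, 0, 0, 1, 2, 0, 0, 0, 11.68),
    e("N", 0, 0, 0, 0, 1, 1, 0, 0, 13.60),
    e("N", 0, 0, 0, 3, 0, 0, 0, 1, 3.01),
    e("N", 0, 0, 1, 2, 0, 0, 0, 0, 12.03),
    e("N", 0, 0, 1, 2, 0, 0, 0, 1, 21.94),
    e("N", 0, 0, 1, 0, 1, 0, 0, 0, 23.85),
    e("N", 0, 0, 2, 1, 0, 0, 0, 0, 26.02),
    # nitrogen, non-aromatic, cationic
    e("N", 0, 1, 0, 4, 0, 0, 0, 0, 0.00),
    e("N", 0, 1, 0, 2, 1, 0, 0, 0, 3.01),
    e("N", 0, 1, 0, 0, 0, 1, 0, 0, 4.36),
    e("N", 0, 1, 1, 3, 0, 0, 0, 0, 4.44),
    e("N", 0, 1, 1, 1, 1, 0, 0, 0, 13.97),
    e("N", 0, 1, 2, 2, 0, 0, 0, 0, 16.61),
    e("N", 0, 1, 2, 0, 1, 0, 0, 0, 25.59),
    e("N", 0, 1, 3, 1, 0, 0, 0, 0, 27.64),
    # nitrogen, aromatic
    e("N", 1, 0, 0, 0, 0, 0, 2, 0, 12.89),
    e("N", 1, 0, 0, 0, 0, 0, 3, 0, 4.41),
    e("N", 1, 0, 0, 1, 0, 0, 2, 0, 4.93),
    e("N", 1, 0, 0, 0, 1, 0, 2, 0, 8.39),
    e("N", 1, 0, 1, 0, 0, 0, 2, 0, 15.79),
    e("N", 1, 1, 0, 0, 0, 0, 3, 0, 4.10),
    e("N", 1, 1, 0, 1, 0, 0, 2, 0, 3.88),
    e("N", 1, 1, 1, 0, 0, 0, 2, 0, 14.14),
    # oxygen
    e("O", 0, 0, 0, 2, 0, 0, 0, 0, 9.23),
    e("O", 0, 0, 0, 2, 0, 0, 0, 1, 12.53),
    e("O", 0, 0, 0, 0, 1, 0, 0, 0, 17.07),
    e("O", 0, 0, 1, 1, 0, 0, 0, 0, 20.23),
    e("O", 0, -1, 0, 1, 0, 0, 0, 0, 23.06),
    e("O", 1, 0, 0, 0, 0, 0, 2, 0, 13.14),
    # sulfur (NOSP mode only)
    e("S", 0, 0, 0, 2, 0, 0, 0, 0, 25.30),
    e("S", 0, 0, 0, 0, 1, 0, 0, 0, 32.09),
    e("S", 0, 0, 0, 2, 1, 0, 0, 0, 19.21),
    e("S", 0, 0, 0, 2, 2, 0, 0, 0, 8.38),
    e("S", 0, 0, 1, 1, 0, 0, 0, 0, 38.80),
    e("S", 1, 0, 0, 0, 0, 0, 2, 0, 28.24),
    e("S", 1, 0, 0, 0, 1, 0, 2, 0, 21.70),
    # phosphorus (NOSP mode only)
    e("P", 0, 0, 0, 3, 0, 0, 0, 0, 13.59),
    e("P", 0, 0, 0, 1, 1, 0, 0, 0, 34.14),
    e("P", 0, 0, 0, 3, 1, 0, 0, 0, 9.81),
    e("P", 0, 0, 1, 2, 1, 0, 0, 0, 23.47)
  )
})

# generic per-element fallback when an environment is unparameterized
.tpsa_fallback <- c(N = 3.24, O = 9.23, S = 25.30, P = 13.59)

#' Topological polar surface area (fragment contributions)
#'
#' Sums published per-atom fragment contributions over the polar atoms.
#' `"NO"` mode (default) counts N and O environments only; `"NOSP"` adds
#' the S and P contributions. Hydrogen counts are taken from explicit
#' hydrogens in the graph, so molecules should carry them. Unparameterized
#' environments fall back on the plainest contribution of the same element
#' with a warning.
#'
#' @param mol a [molecule()].
#' @param mode `"NO"` or `"NOSP"`.
#' @return area in Angstrom^2.
#' @export
tpsa <- function(mol, mode = c("NO", "NOSP")) {
  mode <- match.arg(mode)
  targets <- if (mode == "NO") c("N", "O") else c("N", "O", "S", "P")
  polar <- which(mol$elements %in% targets)
  if (!length(polar)) return(0)
  arom <- perceive_aromaticity(mol)
  rings <- mol_rings(mol)
  in3 <- rep(FALSE, mol$n_atoms)
  for (rg in rings) if (length(rg) == 3L) in3[rg] <- TRUE
  total <- 0
  for (a in polar) {
    kb <- which(mol$bonds$i == a | mol$bonds$j == a)
    partners <- ifelse(mol$bonds$i[kb] == a, mol$bonds$j[kb], mol$bonds$i[kb])
    is_h <- mol$elements[partners] == "H"
    nH <- sum(is_h)
    ord <- mol$bonds$order[kb][!is_h]
    ar_bond <- arom$bonds[kb][!is_h]
    # explicit aromatic bond order (4) counts as an aromatic connection
    ar_bond <- ar_bond | ord == 4L
    s <- sum(ord == 1L & !ar_bond)
    d <- sum(ord == 2L & !ar_bond)
    t <- sum(ord == 3L & !ar_bond)
    na <- sum(ar_bond)
    key <- .tpsa_env(mol$elements[a], arom$atoms[a] && na >= 2L,
                     mol$charges[a], nH, s, d, t, na, in3[a])
    hit <- .tpsa_table[key]
    if (is.na(hit)) {
      warning(sprintf(
        "atom %d (%s): unparameterized polar environment '%s'; using generic %s contribution",
        a, mol$elements[a], key, mol$elements[a]), call. = FALSE)
      hit <- .tpsa_fallback[[mol$elements[a]]]
    }
    total <- total + as.numeric(hit)
  }
  total
}
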