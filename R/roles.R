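# Chemical role assignment: hydrogen-bond donors/acceptors and the polar
# atom set used for surface integration.

#' Assign hydrogen-bond donor and acceptor roles
#'
#' Donor hydrogens are hydrogens bonded to N, O or S; acceptors are N, O
#' or S atoms bearing at least one lone pair under a formal-charge /
#' connectivity rule: N is an acceptor iff its total degree is at most 3
#' and its formal charge is not positive; O and S are acceptors iff their
#' formal charge is not positive. A positively charged tetravalent N
#' (e.g. a quaternary ammonium) is therefore excluded.
#'
#' @param mol a [molecule()] with explicit hydrogens.
#' @return list of class `molcham_roles` with integer index sets
#'   `donor_h`, `donor_heavy` (parallel vectors: `donor_heavy[k]` is the
#'   heavy atom of `donor_h[k]`) and `acceptors`.
#' @export
assign_hbond_roles <- function(mol) {
  stopifnot(inherits(mol, "molcham_mol"))
  has_h <- any(mol$elements == "H")
  if (!has_h && any(mol$elements %in% c("N", "O", "S")))
    stop("explicit hydrogens are required to assign H-bond roles ",
         "(molecule contains N/O/S but no hydrogens)", call. = FALSE)
  adj <- adjacency_list(mol)
  degree <- lengths(adj)
  donor_h <- integer(); donor_heavy <- integer()
  for (h in which(mol$elements == "H")) {
    nb <- adj[[h]]
    if (length(nb) != 1L) next
    if (mol$elements[nb] %in% c("N", "O", "S")) {
      donor_h <- c(donor_h, h); donor_heavy <- c(donor_heavy, nb)
    }
  }
  acceptors <- which(
    (mol$elements == "N" & degree <= 3L & mol$charges <= 0L) |
    (mol$elements %in% c("O", "S") & mol$charges <= 0L))
  structure(list(donor_h = donor_h, donor_heavy = donor_heavy,
                 acceptors = as.integer(acceptors)),
            class = "molcham_roles")
}

#' Select the polar atoms contributing to polar surface area
#'
#' `"NO"` mode (default) selects all N and O atoms plus hydrogens bonded to
#' them; `"NOSP"` additionally includes S and P (and their hydrogens).
#'
#' @param mol a [molecule()] with explicit hydrogens.
#' @param mode `"NO"` or `"NOSP"`.
#' @return sorted integer vector of polar atom indices (possibly empty).
#' @export
assign_psa_atoms <- function(mol, mode = c("NO", "NOSP")) {
  mode <- match.arg(mode)
  heavy_set <- if (mode == "NO") c("N", "O") else c("N", "O", "S", "P")
  heavy <- which(mol$elements %in% heavy_set)
  if (length(heavy) && !any(mol$elements == "H") &&
      any(mol$elements %in% c("N", "O", "S")))
    stop("explicit hydrogens are required for polar-surface work", call. = FALSE)
  adj <- adjacency_list(mol)
  hs <- unlist(lapply(heavy, function(i) {
    nb <- adj[[i]]
    nb[mol$elements[nb] == "H"]
  }))
  sort(unique(c(heavy, hs)))
}

#' Basic 2D descriptors: nC, MW, NAR, nHAcc, nHDon
#'
#' Carbon count, molecular weight (standard atomic weights; explicit
#' hydrogens are summed as present in the graph), number of aromatic rings
#' (smallest rings whose members are all aromatic), and hydrogen-bond
#' acceptor / donor heavy-atom counts from [assign_hbond_roles()].
#'
#' @param mol a [molecule()].
#' @return one-row data frame with columns `nC`, `MW`, `NAR`, `nHAcc`,
#'   `nHDon`.
#' @export
basic_2d_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molcham_mol"))
  arom <- perceive_aromaticity(mol)
  roles <- if (any(mol$elements %in% c("N", "O", "S")))
    assign_hbond_roles(mol)
  else list(donor_heavy = integer(), acceptors = integer())
  data.frame(
    nC = sum(mol$elements == "C"),
    MW = sum(atomic_mass(mol$elements)),
    NAR = length(arom$aromatic_rings),
    nHAcc = length(roles$acceptors),
    nHDon = length(unique(roles$donor_heavy)))
}
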