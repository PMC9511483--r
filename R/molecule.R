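# Molecular data model: an element-typed atom graph (molecule), Cartesian
# coordinate sets (conformer) and solvent-labeled conformer collections
# (ensemble). Atom indices are 1-based throughout the R interface; file
# formats carrying 1-based indices map through unchanged, 0-based ones are
# translated at the parsing boundary.

#' Construct a molecule
#'
#' A molecule is the topology shared by all conformers of an ensemble:
#' element symbols, formal charges and a bond list. Hydrogens must be
#' explicit for hydrogen-bond and polar-surface work; no implicit-hydrogen
#' inference is performed on 3D structures.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param bonds data frame (or matrix) with columns `i`, `j`, `order`
#'   (1 single, 2 double, 3 triple, 4 aromatic), 1-based atom indices.
#' @param charges integer vector of formal charges (recycled from 0).
#' @param name optional molecule name.
#' @param check_connected error when the bond graph is disconnected
#'   (a single molecule record must be one connected component).
#' @return object of class `molcham_mol`.
#' @export
molecule <- function(elements, bonds, charges = 0L, name = NULL,
                     check_connected = TRUE) {
  elements <- normalize_element(as.character(elements))
  n <- length(elements)
  if (n < 1L) stop("molecule needs at least one atom", call. = FALSE)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    names(bonds)[1:3] <- c("i", "j", "order")
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond endpoint out of range", call. = FALSE)
    if (any(bonds$i == bonds$j))
      stop("bond endpoints must be distinct", call. = FALSE)
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  charges <- as.integer(rep_len(charges, n))
  m <- structure(list(elements = elements, bonds = bonds,
                      charges = charges, n_atoms = n, name = name),
                 class = "molcham_mol")
  if (check_connected && n > 1L) {
    comp <- graph_components(m)
    if (max(comp) > 1L)
      stop(sprintf("molecule%s has %d disconnected components",
                   if (is.null(name)) "" else paste0(" '", name, "'"),
                   max(comp)), call. = FALSE)
  }
  m
}

#' @export
print.molcham_mol <- function(x, ...) {
  cat(sprintf("<molecule%s: %d atoms, %d bonds, formula %s>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n_atoms, nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

molecular_formula <- function(mol) {
  tab <- sort(table(mol$elements))
  ord <- c(intersect(c("C", "H"), names(tab)),
           sort(setdiff(names(tab), c("C", "H"))))
  paste0(vapply(ord, function(e) {
    k <- tab[[e]]
    if (k == 1) e else paste0(e, k)
  }, ""), collapse = "")
}

#' Construct a conformer
#'
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param energy optional scalar energy (any consistent unit).
#' @param id optional identifier (defaults are assigned by [ensemble()]).
#' @return object of class `molcham_conf`.
#' @export
conformer <- function(coords, energy = NULL, id = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix", call. = FALSE)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("conformer coordinates must all be finite", call. = FALSE)
  structure(list(coords = coords, energy = energy, id = id),
            class = "molcham_conf")
}

#' Construct a solvent-labeled conformer ensemble
#'
#' @param molecule a [molecule()].
#' @param conformers list of [conformer()]s sharing the molecule's topology.
#' @param solvent `"polar"` or `"nonpolar"` (mandatory).
#' @param method free-text label of the generation method.
#' @return object of class `molcham_ens`.
#' @export
ensemble <- function(molecule, conformers, solvent = c("polar", "nonpolar"),
                     method = "") {
  solvent <- match.arg(solvent)
  stopifnot(inherits(molecule, "molcham_mol"))
  if (inherits(conformers, "molcham_conf")) conformers <- list(conformers)
  if (length(conformers) < 1L)
    stop("ensemble needs at least one conformer", call. = FALSE)
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    if (!inherits(cf, "molcham_conf"))
      stop("conformers must be molcham_conf objects", call. = FALSE)
    if (nrow(cf$coords) != molecule$n_atoms)
      stop(sprintf("conformer %d has %d coordinates for %d atoms",
                   k, nrow(cf$coords), molecule$n_atoms), call. = FALSE)
    if (is.null(cf$id)) conformers[[k]]$id <- k
  }
  structure(list(molecule = molecule, conformers = conformers,
                 solvent = solvent, method = method),
            class = "molcham_ens")
}

#' @export
print.molcham_ens <- function(x, ...) {
  cat(sprintf("<ensemble: %d conformers of %s in %s solvent (%s)>\n",
              length(x$conformers),
              if (is.null(x$molecule$name)) molecular_formula(x$molecule)
              else x$molecule$name,
              x$solvent,
              if (nzchar(x$method)) x$method else "unspecified method"))
  invisible(x)
}

# ---- graph utilities ------------------------------------------------------

adjacency_list <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

graph_components <- function(mol) {
  adj <- adjacency_list(mol)
  comp <- integer(mol$n_atoms)
  cur <- 0L
  for (s in seq_len(mol$n_atoms)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# All-pairs bond-count distances by BFS from every atom (molecules here are
# a few hundred atoms at most, so O(n * (n + m)) is cheap).
bond_distance_matrix <- function(mol) {
  n <- mol$n_atoms
  adj <- adjacency_list(mol)
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; queue <- c(queue, w)
      }
    }
    d[s, ] <- dist
  }
  d
}

heavy_atoms <- function(mol) which(mol$elements != "H")

h_neighbors <- function(mol) {
  # list: for each atom, indices of bonded hydrogens
  adj <- adjacency_list(mol)
  lapply(seq_len(mol$n_atoms), function(i) {
    nb <- adj[[i]]
    nb[mol$elements[nb] == "H"]
  })
}

# ---- ring perception ------------------------------------------------------

# Smallest ring through every bond (BFS on the graph with that bond
# removed), deduplicated. For fused polycycles this recovers the usual
# smallest-set-of-smallest-rings picture at drug-like sizes.
mol_rings <- function(mol, max_size = 8L) {
  n <- mol$n_atoms
  if (nrow(mol$bonds) < n) return(list())  # acyclic: bonds < atoms
  adj <- adjacency_list(mol)
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$i[k]; b <- mol$bonds$j[k]
    # shortest path a -> b avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n); dist[a] <- 0L
    queue <- a
    while (length(queue) && is.na(dist[b])) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; prev[w] <- v; queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[b]) || dist[b] + 1L > max_size) next
    path <- b
    while (path[1L] != a) path <- c(prev[path[1L]], path)
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  rings
}

# ---- aromaticity ----------------------------------------------------------

# Aromatic perception: explicit aromatic bond orders (SDF type 4) are
# honoured when a ring carries them consistently; otherwise a Hueckel-style
# pi-electron count on each smallest ring (endocyclic double bond -> 1 per
# atom, exocyclic double bond -> 0, saturated N/O/S lone pair -> 2,
# saturated carbon breaks aromaticity; aromatic iff pi == 6).
perceive_aromaticity <- function(mol) {
  rings <- mol_rings(mol)
  n <- mol$n_atoms
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  border <- mol$bonds$order
  atom_arom <- rep(FALSE, n)
  bond_arom <- rep(FALSE, length(border))
  aromatic_rings <- list()
  ring_members <- unique(unlist(rings))
  for (ring in rings) {
    sz <- length(ring)
    if (sz < 5L || sz > 7L) next
    if (!all(mol$elements[ring] %in% c("C", "N", "O", "S"))) next
    ring_bonds <- vapply(seq_len(sz), function(q) {
      i <- ring[q]; j <- ring[if (q == sz) 1L else q + 1L]
      match(paste(min(i, j), max(i, j)), bkey)
    }, integer(1))
    orders <- border[ring_bonds]
    aromatic <- FALSE
    if (all(orders == 4L)) {
      aromatic <- TRUE
    } else if (!any(orders == 4L) && !any(orders == 3L)) {
      pi <- 0L; ok <- TRUE
      for (a in ring) {
        dbl <- which((mol$bonds$i == a | mol$bonds$j == a) & border == 2L)
        if (length(dbl)) {
          partners <- ifelse(mol$bonds$i[dbl] == a, mol$bonds$j[dbl], mol$bonds$i[dbl])
          # a double bond into this ring, or into a fused neighboring ring,
          # places one pi electron here; an exocyclic double to an acyclic
          # atom (e.g. C=O) leaves the atom sp2 with no pi electron to give
          if (any(partners %in% ring) || any(partners %in% ring_members))
            pi <- pi + 1L
        } else if (mol$elements[a] %in% c("N", "O", "S") && mol$charges[a] <= 0L) {
          pi <- pi + 2L
        } else {
          ok <- FALSE; break  # saturated carbon
        }
      }
      aromatic <- ok && pi == 6L
    }
    if (aromatic) {
      atom_arom[ring] <- TRUE
      bond_arom[ring_bonds] <- TRUE
      aromatic_rings[[length(aromatic_rings) + 1L]] <- ring
    }
  }
  list(atoms = atom_arom, bonds = bond_arom, rings = rings,
       aromatic_rings = aromatic_rings)
}
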