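test_that("SDF parsing handles minimal records, multi-record files and round-trips", {
  w <- mk_water()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(w$mol, w$conf, path)
  parsed <- parse_structure(path)
  expect_equal(parsed$molecule$elements, c("O", "H", "H"))
  expect_equal(nrow(parsed$molecule$bonds), 2L)
  expect_length(parsed$conformers, 1L)
  expect_equal(parsed$conformers[[1]]$coords, unname(w$conf$coords),
               tolerance = 1e-4)

  # multi-record: two conformers, shared topology, energies round-trip
  c2 <- conformer(w$conf$coords + 1, energy = -3.25)
  write_sdf(w$mol, list(conformer(w$conf$coords, energy = 1.5), c2), path)
  p2 <- parse_structure(path)
  expect_length(p2$conformers, 2L)
  expect_equal(p2$conformers[[2]]$energy, -3.25)
})

test_that("malformed SDF input fails with a line-naming parse error", {
  w <- mk_water()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(w$mol, w$conf, path)
  lines <- readLines(path)
  # counts line promises more atoms than the record carries
  lines[4] <- sub("  3  2", "  5  2", lines[4])
  expect_error(parse_structure(text = lines, format = "sdf"),
               "line")
  expect_error(parse_structure(text = c("", "", "", "garbage"),
                               format = "sdf"), "counts line")
})

test_that("topology mismatch across SDF records is rejected", {
  w <- mk_water(); m <- mk_methane()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(w$mol, w$conf, path)
  lines1 <- readLines(path)
  write_sdf(m$mol, m$conf, path)
  lines2 <- readLines(path)
  expect_error(parse_structure(text = c(lines1, lines2), format = "sdf"),
               "topology mismatch")
})

test_that("formal charges survive the SDF round-trip", {
  tma <- mk_tetramethylammonium()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(tma, conformer(matrix(rnorm(3 * tma$n_atoms), ncol = 3)), path)
  parsed <- parse_structure(path)
  expect_equal(parsed$molecule$charges[1], 1L)
  expect_equal(sum(parsed$molecule$charges), 1L)
})

test_that("multi-model PDB yields one conformer per model with one topology", {
  w <- mk_water()
  path <- withr::local_tempfile(fileext = ".pdb")
  atom_line <- function(k, el, xyz)
    sprintf("ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            k, el, xyz[1], xyz[2], xyz[3], el)
  model <- function(m, shift) c(
    sprintf("MODEL     %4d", m),
    vapply(1:3, function(k) atom_line(k, c("O", "H", "H")[k],
                                      w$conf$coords[k, ] + shift), ""),
    "ENDMDL")
  writeLines(c(model(1, 0), model(2, 0.5), "END"), path)
  parsed <- parse_structure(path)
  expect_length(parsed$conformers, 2L)
  expect_equal(parsed$molecule$elements, c("O", "H", "H"))
  expect_equal(nrow(parsed$molecule$bonds), 2L)  # inferred O-H bonds
  expect_equal(parsed$conformers[[2]]$coords - parsed$conformers[[1]]$coords,
               matrix(0.5, 3, 3), tolerance = 1e-3)
})

test_that("concatenated XYZ frames parse with shared topology", {
  w <- mk_water()
  fr <- function(shift) c("3", "frame",
                          sprintf("%s %.4f %.4f %.4f",
                                  c("O", "H", "H"),
                                  w$conf$coords[, 1] + shift,
                                  w$conf$coords[, 2], w$conf$coords[, 3]))
  parsed <- parse_structure(text = c(fr(0), fr(1)), format = "xyz")
  expect_length(parsed$conformers, 2L)
  expect_equal(nrow(parsed$molecule$bonds), 2L)
  expect_error(parse_structure(text = c(fr(0), "x"), format = "xyz"),
               "malformed XYZ")
})

test_that("H-bond roles follow the N/O/S donor and lone-pair acceptor rules", {
  met <- mk_methanol()
  r <- assign_hbond_roles(met$mol)
  expect_equal(r$donor_h, 3L)          # only the hydroxyl H
  expect_equal(r$donor_heavy, 2L)
  expect_equal(r$acceptors, 2L)        # the oxygen

  thiol <- assign_hbond_roles(mk_methanethiol())
  expect_equal(thiol$donor_h, 3L)      # S-H hydrogen is a donor
  expect_equal(thiol$acceptors, 2L)    # S is an acceptor

  tma <- assign_hbond_roles(mk_tetramethylammonium())
  expect_length(tma$donor_h, 0L)       # methyl H are not donors
  expect_false(1L %in% tma$acceptors)  # charged tetravalent N: no lone pair

  bare <- molecule(c("N", "C", "C"),
                   data.frame(i = c(1, 2), j = c(2, 3), order = 1L))
  expect_error(assign_hbond_roles(bare), "explicit hydrogens")
})

test_that("PSA atom selection honours NO/NOSP modes", {
  b <- mk_benzene()
  expect_length(assign_psa_atoms(b$mol), 0L)
  met <- mk_methanol()
  expect_equal(assign_psa_atoms(met$mol), c(2L, 3L))   # O and its H
  th <- mk_thiazole()
  expect_equal(assign_psa_atoms(th, "NO"), 3L)         # ring N only
  expect_equal(assign_psa_atoms(th, "NOSP"), c(1L, 3L))
})

test_that("role assignment is invariant under atom re-indexing", {
  met <- mk_methanol()
  set.seed(11)
  for (rep in 1:5) {
    perm <- sample(met$mol$n_atoms)
    inv <- order(perm)
    b <- met$mol$bonds
    pm <- molecule(met$mol$elements[perm],
                   data.frame(i = inv[b$i], j = inv[b$j], order = b$order),
                   met$mol$charges[perm])
    r0 <- assign_hbond_roles(met$mol)
    rp <- assign_hbond_roles(pm)
    expect_setequal(perm[rp$acceptors], r0$acceptors)
    expect_setequal(perm[rp$donor_h], r0$donor_h)
    expect_setequal(perm[assign_psa_atoms(pm)], assign_psa_atoms(met$mol))
  }
})

test_that("every donor hydrogen's heavy neighbour is in the donor heavy set", {
  for (mol in list(mk_methanol()$mol, mk_methanethiol(),
                   example_molecule("saquinavir"))) {
    r <- assign_hbond_roles(mol)
    adj <- molcham:::adjacency_list(mol)
    for (k in seq_along(r$donor_h))
      expect_true(adj[[r$donor_h[k]]] == r$donor_heavy[k])
  }
})

test_that("2D descriptors: counts, weights and aromatic ring perception", {
  b <- basic_2d_descriptors(mk_benzene()$mol)
  expect_equal(b$nC, 6); expect_equal(b$NAR, 1)
  expect_equal(b$nHAcc, 0); expect_equal(b$nHDon, 0)

  w <- basic_2d_descriptors(mk_water()$mol)
  expect_equal(w$MW, 18.015, tolerance = 1e-3)

  expect_equal(basic_2d_descriptors(mk_naphthalene())$NAR, 2)
  expect_equal(basic_2d_descriptors(mk_thiazole())$NAR, 1)
})

test_that("disconnected atom sets are rejected as single molecules", {
  expect_error(molecule(c("C", "C"), no_bonds), "disconnected")
})
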