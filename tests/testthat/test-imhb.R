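test_that("probe geometries inside / outside the relaxed thresholds", {
  p <- mk_probe(2.1, 180)
  hits <- detect_imhbs(p$conf, p$roles, hbond_criteria(), p$mol)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 2.1, tolerance = 1e-9)
  expect_equal(hits$angle, 180, tolerance = 1e-6)

  far <- mk_probe(2.6, 180)   # beyond d0 + 0.4
  expect_equal(nrow(detect_imhbs(far$conf, far$roles, hbond_criteria(),
                                 far$mol)), 0L)
  bent <- mk_probe(2.1, 120)  # below theta0 - 20
  expect_equal(nrow(detect_imhbs(bent$conf, bent$roles, hbond_criteria(),
                                 bent$mol)), 0L)
})

test_that("thresholds are closed: the exact relaxed boundary is detected", {
  edge <- mk_probe(2.1 + 0.4, 150 - 20)
  hits <- detect_imhbs(edge$conf, edge$roles, hbond_criteria(), edge$mol)
  expect_equal(nrow(hits), 1L)
  # one epsilon beyond either boundary is not
  eps_d <- mk_probe(2.5 + 1e-6, 150)
  expect_equal(nrow(detect_imhbs(eps_d$conf, eps_d$roles, hbond_criteria(),
                                 eps_d$mol)), 0L)
  eps_a <- mk_probe(2.1, 130 - 1e-4)
  expect_equal(nrow(detect_imhbs(eps_a$conf, eps_a$roles, hbond_criteria(),
                                 eps_a$mol)), 0L)
})

test_that("1,2- and 1,3-contacts are excluded by topological separation", {
  # donor O and acceptor O separated by 2 bonds (O-C-O), perfect geometry
  el <- c("O", "C", "O", "H")
  b <- data.frame(i = c(1, 2, 1), j = c(2, 3, 4), order = c(1, 1, 1))
  mol <- molecule(el, b)
  h <- c(0.96, 0, 0)
  a <- h + 2.1 * c(1, 0, 0)
  conf <- conformer(rbind(c(0, 0, 0), c(0.5, -2, 0), a, h))
  roles <- assign_hbond_roles(mol)
  expect_equal(nrow(detect_imhbs(conf, roles, hbond_criteria(), mol)), 0L)
  relaxed_sep <- hbond_criteria(min_separation = 2L)
  expect_equal(nrow(detect_imhbs(conf, roles, relaxed_sep, mol)), 1L)
})

test_that("each donor hydrogen reports its best acceptor only (unless asked)", {
  # two acceptors at different distances straight ahead of the donor H
  el <- c("O", "C", "C", "C", "O", "O", "H")
  b <- data.frame(i = c(1, 2, 3, 4, 4, 1),
                  j = c(2, 3, 4, 5, 6, 7),
                  order = c(1, 1, 1, 2, 1, 1))
  mol <- molecule(el, b)
  h <- c(0.96, 0, 0)
  conf <- conformer(rbind(
    c(0, 0, 0), c(0, -3, 0), c(1.5, -3.5, 0), c(3, -3, 0),
    h + c(2.1, 0, 0), h + c(2.4, 0.1, 0), h))
  roles <- assign_hbond_roles(mol)
  best <- detect_imhbs(conf, roles, hbond_criteria(), mol)
  expect_equal(nrow(best), 1L)
  expect_equal(best$acceptor, 5L)
  all_acc <- detect_imhbs(conf, roles, hbond_criteria(), mol,
                          all_acceptors = TRUE)
  expect_equal(nrow(all_acc), 2L)
})

test_that("detection is superset-monotone in the relaxations", {
  set.seed(97)
  base <- hbond_criteria()
  for (rep in 1:200) {
    d <- runif(1, 1.5, 3.2)
    th <- runif(1, 100, 180)
    p <- mk_probe(d, th)
    n0 <- nrow(detect_imhbs(p$conf, p$roles, base, p$mol))
    wider <- hbond_criteria(relax_d = 0.4 + runif(1, 0, 0.8),
                            relax_theta = 20 + runif(1, 0, 40))
    n1 <- nrow(detect_imhbs(p$conf, p$roles, wider, p$mol))
    expect_gte(n1, n0)
  }
})

test_that("detection is invariant under atom re-indexing", {
  p <- mk_probe(2.2, 165)
  set.seed(5)
  for (rep in 1:5) {
    perm <- sample(p$mol$n_atoms)
    inv <- order(perm)
    b <- p$mol$bonds
    pm <- molecule(p$mol$elements[perm],
                   data.frame(i = inv[b$i], j = inv[b$j], order = b$order))
    pc <- conformer(p$conf$coords[perm, ])
    hits <- detect_imhbs(pc, assign_hbond_roles(pm), hbond_criteria(), pm)
    expect_equal(nrow(hits), 1L)
    expect_equal(perm[hits$acceptor], 5L)
  }
})

test_that("ensemble IMHB profile arithmetic and the nonpolar-minus-water sign", {
  p_in <- mk_probe(2.1, 175)    # forms the contact
  p_out <- mk_probe(4.0, 175)   # does not
  mk_ens <- function(confs, solvent)
    ensemble(p_in$mol, confs, solvent, "probe")
  polar <- mk_ens(list(conformer(p_out$conf$coords, id = 1),
                       conformer(p_out$conf$coords, id = 2)), "polar")
  nonpolar <- mk_ens(list(conformer(p_in$conf$coords, id = 1),
                          conformer(p_in$conf$coords, id = 2)), "nonpolar")
  prof <- ensemble_imhb_profile(polar, nonpolar)
  expect_equal(prof$delta_mean, 1)
  expect_equal(prof$median_nonpolar, 1)
  expect_equal(prof$pairs$f_nonpolar, 1)
  expect_equal(prof$pairs$f_polar, 0)

  ident <- ensemble_imhb_profile(
    mk_ens(list(conformer(p_in$conf$coords, id = 1)), "polar"),
    mk_ens(list(conformer(p_in$conf$coords, id = 1)), "nonpolar"))
  expect_equal(ident$delta_mean, 0)
})

test_that("delta-mean equals a brute-force recount on the toy fixture", {
  tc <- toy_chameleon_ensembles(toy_chain_spec(n_conformers = 12L, seed = 3))
  prof <- ensemble_imhb_profile(tc$polar, tc$nonpolar)
  recount <- function(ens) {
    mol <- ens$molecule
    roles <- assign_hbond_roles(mol)
    mean(vapply(ens$conformers, function(cf)
      nrow(detect_imhbs(cf, roles, hbond_criteria(), mol)), numeric(1)))
  }
  expect_equal(prof$delta_mean, recount(tc$nonpolar) - recount(tc$polar),
               tolerance = 1e-12)
})

test_that("persistence classes follow the occupancy thresholds", {
  pairs <- data.frame(donor_heavy = 1:3, acceptor = 4:6,
                      f_polar = c(0.9, 0.0, 0.1),
                      f_nonpolar = c(0.8, 0.6, 0.1))
  cls <- classify_imhb_persistence(pairs, tau = 0.2)$class
  expect_equal(cls, c("static", "dynamic", "absent"))
  polar_only <- data.frame(donor_heavy = 1, acceptor = 2,
                           f_polar = 0.5, f_nonpolar = 0.05)
  expect_equal(classify_imhb_persistence(polar_only, 0.2)$class, "polar-only")
  expect_error(classify_imhb_persistence(pairs, tau = 1.2), "tau")
})
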