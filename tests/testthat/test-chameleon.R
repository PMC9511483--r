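mk_rec <- function(psa, rgyr, ids = seq_along(psa))
  data.frame(conformer_id = ids, psa3d = psa, rgyr = rgyr)

test_that("separation score: zero for identical, one per pooled IQR, signed", {
  set.seed(4)
  a <- mk_rec(runif(20, 50, 100), runif(20, 2, 4))
  expect_equal(unname(polarity_separation(a, a)["psa"]), 0)

  # construct medians exactly one pooled IQR apart
  p <- mk_rec(c(10, 20, 30, 40), rep(1, 4))
  n <- mk_rec(c(10, 20, 30, 40) - stats::IQR(c(c(10, 20, 30, 40),
                                               c(10, 20, 30, 40))),
              rep(1, 4))
  sep <- polarity_separation(p, n)
  expect_gt(sep[["psa"]], 0)   # polar more polar: positive sign

  # fully ordered: polar strictly above nonpolar
  hi <- mk_rec(c(100, 110, 120), 1:3)
  lo <- mk_rec(c(10, 20, 30), 1:3)
  expect_gt(polarity_separation(hi, lo)[["psa"]], 0)
  expect_lt(polarity_separation(lo, hi)[["psa"]], 0)
})

test_that("zero pooled IQR with unequal medians returns an Inf sentinel", {
  p <- mk_rec(rep(10, 3), rep(1, 3))
  n <- mk_rec(rep(10, 3), rep(1, 3))
  expect_equal(unname(polarity_separation(p, n)["psa"]), 0)
  n2 <- mk_rec(rep(8, 97), rep(1, 97))
  p2 <- mk_rec(c(rep(8, 96), 10), rep(1, 97))  # IQR 0, medians equal -> 0
  expect_equal(unname(polarity_separation(p2, n2)["psa"]), 0)
  # pooled quartiles both sit on the dominant value, medians differ
  p3 <- mk_rec(rep(10, 10), rep(1, 10))
  n3 <- mk_rec(c(0, 0, 0, 10, 10), rep(1, 5))
  expect_warning(s <- polarity_separation(p3, n3), "Inf")
  expect_identical(unname(s["psa"]), Inf)
})

test_that("congruence overlap: identical = 1, disjoint = 0, symmetric", {
  set.seed(6)
  a <- mk_rec(runif(50, 50, 100), runif(50, 2, 4))
  expect_equal(congruence_overlap(a, a), 1)

  lo <- mk_rec(runif(50, 10, 40), runif(50, 1, 2))
  hi <- mk_rec(runif(50, 200, 300), runif(50, 5, 8))
  expect_equal(congruence_overlap(lo, hi), 0)
  expect_equal(congruence_overlap(lo, hi), congruence_overlap(hi, lo))
  ov <- congruence_overlap(a, rbind(a[1:25, ], hi[1:25, ]))
  expect_gt(ov, 0); expect_lt(ov, 1)
})

test_that("overlap matches an exhaustive per-tile min-sum on shifted blocks", {
  # two uniform blocks shifted by half their width on a known grid
  set.seed(21)
  a <- mk_rec(runif(400, 0, 100), runif(400, 0, 10))
  b <- mk_rec(runif(400, 50, 150), runif(400, 0, 10))
  pooled <- rbind(a[, c("rgyr", "psa3d")], b[, c("rgyr", "psa3d")])
  grid <- tile_density(pooled, n_tiles = 10L)
  got <- congruence_overlap(a, b, grid)
  # independent recomputation with cut()-based binning on the same edges
  binify <- function(r) {
    bx <- cut(r$rgyr, grid$x_edges, include.lowest = TRUE, right = FALSE)
    by <- cut(r$psa3d, grid$y_edges, include.lowest = TRUE, right = FALSE)
    table(bx, by) / nrow(r)
  }
  oracle <- sum(pmin(binify(a), binify(b)))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("TPSA attainment ratio and its degenerate cases", {
  s <- summarize_ensemble(mk_rec(c(100, 278), 1:2))
  expect_equal(tpsa_attainment(s, 278), 1.0)
  s0 <- summarize_ensemble(mk_rec(c(0, 0), 1:2))
  expect_equal(tpsa_attainment(s0, 100), 0)
  expect_error(tpsa_attainment(s, 0), "TPSA")
})

test_that("identical ensembles are non-chameleonic with a no-separation reason", {
  tc <- toy_chameleon_ensembles(toy_chain_spec(n_conformers = 10L, seed = 2))
  rec <- conformer_records(tc$polar)
  prof_self <- ensemble_imhb_profile(
    tc$polar,
    ensemble(tc$polar$molecule, tc$polar$conformers, "nonpolar", "copy"))
  rep0 <- assess_chameleonicity(rec, rec, tpsa(tc$polar$molecule), prof_self)
  expect_equal(rep0$verdict, "non-chameleonic")
  expect_true("no-separation" %in% rep0$reasons)
})

test_that("missing inputs give an indeterminate verdict, not an error", {
  tc <- toy_chameleon_ensembles(toy_chain_spec(n_conformers = 6L, seed = 2))
  rec <- conformer_records(tc$polar)
  rep <- assess_chameleonicity(rec, NULL, 37.3, NULL)
  expect_equal(rep$verdict, "indeterminate")
  expect_true(any(grepl("missing-nonpolar", rep$reasons)))
  expect_true(any(grepl("missing-imhb", rep$reasons)))
})

test_that("static-only IMHBs and disjoint ranges fail with those reasons", {
  p <- mk_rec(c(100, 110, 120, 130), c(5, 5.2, 5.4, 5.6))
  n <- mk_rec(c(10, 20, 30, 40), c(2, 2.2, 2.4, 2.6))
  prof <- structure(list(
    delta_mean = 0.5,
    pairs = data.frame(donor_heavy = 1, acceptor = 5,
                       f_polar = 0.9, f_nonpolar = 0.9)),
    class = "molcham_imhb_profile")
  rep <- assess_chameleonicity(p, n, 100, prof)
  expect_equal(rep$verdict, "non-chameleonic")
  expect_true(all(c("no-overlap", "static-imhb") %in% rep$reasons))
})

test_that("the verdict is a pure function of the stored report", {
  tc <- toy_chameleon_ensembles(toy_chain_spec(seed = 13))
  res <- run_analysis(tc$polar, tc$nonpolar)
  rep <- res$report
  # recompute the verdict from the stored flags
  again <- if (all(rep$flags)) "chameleonic" else "non-chameleonic"
  expect_equal(again, rep$verdict)
  expect_identical(length(rep$reasons) == 0L, rep$verdict == "chameleonic")
})

test_that("chameleon fixture and rigid control are classified across seeds", {
  ok_cham <- 0L; ok_rigid <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    a <- toy_chameleon_ensembles(toy_chain_spec(seed = s))
    ok_cham <- ok_cham +
      (run_analysis(a$polar, a$nonpolar)$report$verdict == "chameleonic")
    b <- toy_rigid_ensembles(toy_chain_spec(seed = s))
    ok_rigid <- ok_rigid +
      (run_analysis(b$polar, b$nonpolar)$report$verdict == "non-chameleonic")
  }
  expect_gte(ok_cham, 19L)
  expect_gte(ok_rigid, 19L)
})
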