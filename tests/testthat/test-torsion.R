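test_that("dihedral handles canonical plane and chirality cases", {
  # planar zig-zag: trans arrangement -> 180
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  # cis arrangement -> 0
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # mirror image flips the sign
  p <- list(c(0, 1, 0.3), c(0, 0, 0), c(1, 0, 0), c(1.2, -1, 0.8))
  m <- lapply(p, function(v) v * c(1, 1, -1))
  expect_equal(dihedral(m[[1]], m[[2]], m[[3]], m[[4]]),
               -dihedral(p[[1]], p[[2]], p[[3]], p[[4]]))
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral agrees with the brute-force oracle on random quadruples", {
  set.seed(11)
  for (i in 1:1000) {
    q <- matrix(stats::rnorm(12), 4, 3)
    a <- dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
    b <- brute_dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_lt(abs(.wrap180_test(a - b)), 1e-6)
  }
})

test_that("angular_delta is a metric with correct wraparound and symmetry", {
  expect_equal(angular_delta(170, -170), 20)
  expect_equal(angular_delta(45, 45), 0)
  expect_equal(angular_delta(90, -90, symmetry_order = 2), 0)
  # brute-force over 2-fold equivalents
  set.seed(7)
  for (i in 1:50) {
    a <- stats::runif(1, -180, 180); b <- stats::runif(1, -180, 180)
    brute <- min(abs(.wrap180_test(a - b)), abs(.wrap180_test(a - b + 180)),
                 abs(.wrap180_test(a - b - 180)))
    expect_equal(angular_delta(a, b, symmetry_order = 2), brute)
  }
  # metric axioms on sampled triples
  set.seed(8)
  for (i in 1:100) {
    abc <- stats::runif(3, -540, 540)
    d <- function(x, y) angular_delta(x, y)
    expect_equal(d(abc[1], abc[2]), d(abc[2], abc[1]))
    expect_gte(d(abc[1], abc[3]) + 1e-9, 0)
    expect_lte(d(abc[1], abc[2]), d(abc[1], abc[3]) + d(abc[3], abc[2]) + 1e-9)
  }
})

test_that("classify_omega partitions the circle with documented boundaries", {
  expect_equal(classify_omega(178), "trans")
  expect_equal(classify_omega(-165), "trans")
  expect_equal(classify_omega(5), "cis")
  expect_equal(classify_omega(120), "twisted")
  expect_equal(classify_omega(-100), "twisted")
  # boundary exactly 30 degrees from planar goes to the planar class
  expect_equal(classify_omega(30), "cis")
  expect_equal(classify_omega(150), "trans")
  expect_equal(classify_omega(c(30.001, 149.999)), c("twisted", "twisted"))
  # exhaustive partition on a fine grid
  grid <- seq(-179.9, 180, by = 0.1)
  cls <- classify_omega(grid)
  expect_true(all(cls %in% c("cis", "trans", "twisted")))
  expect_true(is.na(classify_omega(NA_real_)))
})

test_that("backbone torsions are absent at termini and recovered in helices", {
  x <- helix_structure(strrep("A", 8))
  bb <- backbone_torsions(x)
  expect_true(is.na(bb$phi[1]) && is.na(bb$omega[1]))
  expect_true(is.na(bb$psi[8]))
  expect_lt(max(abs(bb$phi[-1] + 57)), 1e-3)
  expect_lt(max(abs(bb$psi[-8] + 47)), 1e-3)
  expect_lt(max(abs(abs(bb$omega[-1]) - 180)), 1e-3)
})

test_that("chain breaks suppress torsions across the gap", {
  x <- build_peptide(peptide_spec(strrep("A", 10), phi = -120, psi = 130))
  x$atoms <- x$atoms[!(x$atoms$res_seq %in% 5), , drop = FALSE]
  bb <- backbone_torsions(x)
  expect_true(is.na(bb$phi[bb$res_seq == 6]))
  expect_true(is.na(bb$omega[bb$res_seq == 6]))
  expect_true(is.na(bb$psi[bb$res_seq == 4]))
  expect_false(is.na(bb$phi[bb$res_seq == 7]))
})

test_that("chi torsions follow residue-type definitions", {
  x <- helix_structure("AGSLV", chi1 = -60, chi2 = 170)
  ct <- chi_torsions(x)
  expect_equal(ct$n_chi, c(0L, 0L, 1L, 2L, 1L))
  expect_true(all(is.na(ct$chi1[1:2])))
  expect_true(is.na(ct$chi2[ct$res_type == "SER"]))
  leu <- ct[ct$res_type == "LEU", ]
  expect_lt(abs(leu$chi1 + 60), 1e-3)
  expect_lt(abs(leu$chi2 - 170), 1e-3)
})

test_that("prescribed-torsion round trip holds for every torsion type", {
  set.seed(42)
  seq_str <- "CDEFHIKLMNQRSTVWY"
  n <- nchar(seq_str)
  sp <- peptide_spec(seq_str,
                     phi = stats::runif(n, -180, 180),
                     psi = stats::runif(n, -180, 180),
                     omega = stats::runif(n, -180, 180),
                     chi1 = stats::runif(n, -180, 180),
                     chi2 = stats::runif(n, -180, 180))
  tt <- torsion_table(build_peptide(sp))
  chk <- function(meas, presc) max(abs(.wrap180_test(meas - presc)), na.rm = TRUE)
  expect_lt(chk(tt$phi[-1], sp$phi[-1]), 1e-3)
  expect_lt(chk(tt$psi[-n], sp$psi[-n]), 1e-3)
  expect_lt(chk(tt$omega[-1], sp$omega[-1]), 1e-3)
  m1 <- !is.na(tt$chi1)
  m2 <- !is.na(tt$chi2)
  expect_lt(chk(tt$chi1[m1], sp$chi1[m1]), 1e-3)
  expect_lt(chk(tt$chi2[m2], sp$chi2[m2]), 1e-3)
})

test_that("torsion_delta of identical structures is zero with no flags", {
  x <- helix_structure()
  td <- torsion_delta(x, x)
  expect_lt(max(td$d_phi, na.rm = TRUE), 1e-9)
  expect_lt(max(td$d_chi2, na.rm = TRUE), 1e-9)
  expect_false(any(td$omega_flip))
  expect_false(any(td$omega_twist))
})

test_that("target chis missing from the model count as 180 degrees", {
  target <- helix_structure("ALKLDEF")
  mutant <- helix_structure("ALKADEF")   # L4A mutation
  td <- torsion_delta(target, mutant)
  row <- td[td$res_seq == 4, ]
  expect_equal(row$d_chi1, 180)
  expect_equal(row$d_chi2, 180)
  expect_equal(row$n_chi, 2L)
  expect_true(row$mutated)
})

test_that("cis/trans flips and twists are flagged with raw omega deltas", {
  target <- build_peptide(peptide_spec(strrep("A", 8), omega = 179))
  model_spec <- peptide_spec(strrep("A", 8), omega = 179)
  model_spec$omega[4] <- 2
  model_spec$omega[6] <- 100
  model <- build_peptide(model_spec)
  td <- torsion_delta(target, model)
  expect_true(td$omega_flip[td$res_seq == 4])
  expect_equal(td$d_omega[td$res_seq == 4], 177, tolerance = 1e-6)
  expect_true(td$omega_twist[td$res_seq == 6])
  expect_false(td$omega_flip[td$res_seq == 6])
  expect_equal(sum(td$omega_flip), 1)
  expect_equal(sum(td$omega_twist), 1)
})

test_that("chi2 symmetry correction applies only to Asp/Phe/Tyr when on", {
  target <- helix_structure("ADFYL", chi2 = 90)
  model <- helix_structure("ADFYL", chi2 = -90)
  td_sym <- torsion_delta(target, model, chi_symmetry = TRUE)
  td_raw <- torsion_delta(target, model, chi_symmetry = FALSE)
  sym_rows <- td_sym$res_type %in% c("ASP", "PHE", "TYR")
  expect_lt(max(td_sym$d_chi2[sym_rows]), 1e-9)
  expect_equal(td_raw$d_chi2[sym_rows], rep(180, 3))
  expect_equal(td_sym$d_chi2[td_sym$res_type == "LEU"], 180)
})
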