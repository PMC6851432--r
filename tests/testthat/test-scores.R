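test_that("gamma_torsion matches its closed form and is monotone", {
  expect_equal(gamma_torsion(0), 0)
  expect_equal(gamma_torsion(90), 0.5)
  expect_equal(gamma_torsion(180), 1)
  expect_equal(gamma_torsion(60), 0.25)
  grid <- seq(0, 180, by = 1)
  expect_true(all(diff(gamma_torsion(grid)) > 0))
  expect_true(all(gamma_torsion(grid) >= 0 & gamma_torsion(grid) <= 1))
  expect_error(gamma_torsion(-5), "0, 180")
  expect_error(gamma_torsion(181), "0, 180")
})

test_that("backbone_score averages over the defined torsion subset", {
  expect_equal(backbone_score(0, 0, 0), 0)
  expect_equal(backbone_score(180, 180, 180), 1)
  expect_equal(backbone_score(90, 90, 90), 0.5)
  # terminus renormalization: mean of two defined terms
  expect_equal(backbone_score(90, 90, NA), 0.5)
  expect_equal(backbone_score(NA, 180, NA), 1)
  expect_true(is.na(backbone_score(NA, NA, NA)))
})

# Hand-built two-residue structure where residue 1 (LEU) has a
# controlled number of residue-2 heavy atoms within the 4 A cutoff.
leu_with_neighbors <- function(n_near, n_far = 3) {
  near <- seq_len(n_near)
  atoms <- rbind(
    data.frame(chain = "A", res_seq = 1, icode = "", res_type = "LEU",
               atom = c("N", "CA", "CB", "CG"), element = c("N", "C", "C", "C"),
               altloc = "", x = c(0, 1.5, 2.2, 3.0), y = 0, z = 0,
               occ = 1, b = 0),
    data.frame(chain = "A", res_seq = 2, icode = "", res_type = "GLY",
               atom = c(sprintf("X%d", near), sprintf("F%d", seq_len(n_far))),
               element = "C", altloc = "",
               x = c(rep(1.5, n_near), rep(50, n_far)),
               y = c(3 + 0.05 * near, rep(50, n_far)), z = 0,
               occ = 1, b = 0))
  structure_record(atoms)
}

test_that("burial counts neighbors and saturates per the closed form", {
  expect_equal(burial(leu_with_neighbors(0))$beta[1], 0)
  # Leu: n_sc = 4, so 6 close heavy atoms give beta = 6/12 = 0.5
  b6 <- burial(leu_with_neighbors(6))
  expect_equal(b6$n_close[1], 6L)
  expect_equal(b6$n_sc[1], 4L)
  expect_equal(b6$beta[1], 0.5)
  # saturation at 3 * n_sc
  expect_equal(burial(leu_with_neighbors(14))$beta[1], 1)
})

test_that("burial excludes waters and, optionally, hetero ligands", {
  x <- leu_with_neighbors(6)
  wat <- data.frame(chain = "A", res_seq = 50, icode = "", res_type = "HOH",
                    atom = "O", element = "O", altloc = "",
                    x = 1.5, y = 2.5, z = 0, occ = 1, b = 0,
                    is_polymer = FALSE, nonstandard = FALSE, res_uid = NA)
  x$atoms <- rbind(x$atoms, wat[names(x$atoms)])
  x <- structure_record(x$atoms)
  expect_equal(burial(x)$n_close[1], 6L)
  lig <- wat
  lig$res_type <- "LIG"
  lig$atom <- "C1"
  lig$element <- "C"
  y <- structure_record(rbind(x$atoms, lig[names(x$atoms)]))
  expect_equal(burial(y)$n_close[1], 7L)
  p <- score_params(burial_include_het = FALSE)
  expect_equal(burial(y, p)$n_close[1], 6L)
})

test_that("sidechain_score reproduces its worked values", {
  # chi1 perfect, chi2 maximally wrong -> exactly 1/3
  expect_equal(sidechain_score(0, 180, 2, 1), 1 / 3, tolerance = 1e-12)
  # both perfect -> 0; chi1 maximally wrong -> ~1
  expect_equal(sidechain_score(0, 0, 2, 1), 0, tolerance = 1e-12)
  expect_equal(sidechain_score(180, 0, 2, 1), 1, tolerance = 1e-10)
  # hand-evaluated midpoint: gamma(30) = 0.0669873, e^{-1} = 0.367879
  expect_equal(sidechain_score(30, 0, 2, 1), 0.2553650, tolerance = 1e-6)
  # single-chi branch scales gamma by beta
  expect_equal(sidechain_score(90, NA, 1, 0.5), 0.25)
  # beta weighting is linear
  expect_equal(sidechain_score(0, 180, 2, 0.4), 0.4 / 3, tolerance = 1e-12)
  expect_true(is.na(sidechain_score(90, 90, 0, 1)))
  expect_true(is.na(sidechain_score(90, 90, 2, NA)))
})

test_that("sidechain_score is monotone in both chi deltas", {
  grid <- seq(0, 180, by = 5)
  for (d2 in c(0, 60, 120, 180)) {
    s <- sidechain_score(grid, d2, 2, 1)
    expect_true(all(diff(s) > -1e-12))
  }
  for (d1 in c(0, 20, 40, 90, 180)) {
    s <- sidechain_score(d1, grid, 2, 1)
    expect_true(all(diff(s) > -1e-12))
  }
})

test_that("chi2 influence is negligible once chi1 is off by 50 degrees", {
  bound <- exp(-(50 / 30)^2) / 3
  expect_lt(bound, 0.021)
  for (d1 in seq(50, 180, by = 10)) {
    spread <- sidechain_score(d1, 180, 2, 1) - sidechain_score(d1, 0, 2, 1)
    expect_gte(spread, 0)
    expect_lte(spread, bound + 1e-12)
  }
})

test_that("score_model of a structure against itself is exactly zero", {
  x <- helix_structure()
  s <- score_model(x, x)
  expect_lt(s$summary$mean_backbone, 1e-12)
  expect_lt(s$summary$mean_sidechain, 1e-12)
  expect_equal(s$summary$n_flips, 0)
  expect_equal(s$summary$n_twists, 0)
  expect_equal(s$summary$n_residues_scored, 11)
  expect_true(all(s$residues$s_backbone >= 0 & s$residues$s_backbone <= 1,
                  na.rm = TRUE))
})

test_that("a known chi1 rotation scores beta * gamma for single-chi residues", {
  x <- helix_structure("ASVSTCV")   # only 0- or 1-chi residues
  pr <- perturb(x, perturbation_spec(chi1 = 180))
  s <- score_model(x, pr$structure)
  res <- s$residues
  one_chi <- which(res$n_chi == 1)
  expect_equal(res$s_sidechain[one_chi],
               res$beta[one_chi] * gamma_torsion(180), tolerance = 1e-9)
})

test_that("models missing residues are book-kept, not penalized per residue", {
  target <- helix_structure(strrep("L", 12))
  model <- target
  model$atoms <- model$atoms[!(model$atoms$res_seq %in% 1:6), , drop = FALSE]
  model$peptide_spec <- NULL
  s <- score_model(target, model)
  expect_equal(s$summary$n_residues_scored, 6)
  expect_equal(s$summary$n_target_residues, 12)
  expect_true(all(is.na(s$residues$s_backbone[s$residues$res_seq %in% 1:6])))
})

test_that("fully exposed residues contribute zero regardless of conformation", {
  # pull the two residues 100 A apart so neither has any neighbor
  isolate <- function(x) {
    far <- x$atoms$res_seq == 2
    x$atoms$x[far] <- x$atoms$x[far] + 100
    x
  }
  target <- isolate(build_peptide(peptide_spec("SL", phi = -120, psi = 130)))
  model <- isolate(build_peptide(peptide_spec("SL", phi = -120, psi = 130,
                                              chi1 = 60, chi2 = -60)))
  s <- score_model(target, model)
  expect_true(all(s$residues$beta == 0, na.rm = TRUE))
  expect_true(all(s$residues$s_sidechain == 0, na.rm = TRUE))
})

test_that("compare_template_model localizes an engineered improvement", {
  target <- helix_structure(strrep("L", 10))
  template <- perturb(target, perturbation_spec(phi = 40, residues = 6))$structure
  model <- target   # model fixes the template's error
  cmp <- compare_template_model(target, model, template)
  expect_equal(nrow(cmp), 10)
  expect_lt(max(abs(cmp$s_backbone_model), na.rm = TRUE), 1e-9)
  worse <- which(cmp$backbone_delta < -1e-6)
  expect_true(6 %in% cmp$res_seq[worse])
  expect_lt(max(abs(cmp$ca_dist_model), na.rm = TRUE), 1e-6)
  expect_true(all(cmp$ca_dist_template >= 0, na.rm = TRUE))
})

test_that("comparing identical template and model yields all-zero deltas", {
  target <- helix_structure()
  other <- perturb(target, perturbation_spec(chi1 = list(sd = 15), seed = 3))$structure
  cmp <- compare_template_model(target, other, other)
  expect_lt(max(abs(cmp$backbone_delta), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(cmp$sidechain_delta), na.rm = TRUE), 1e-9)
})

test_that("the comparison chart renders without error", {
  target <- helix_structure()
  model <- perturb(target, perturbation_spec(phi = list(sd = 15),
                                             chi1 = list(sd = 30),
                                             seed = 2))$structure
  cmp <- compare_template_model(target, model, target)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot_comparison(cmp))
})

test_that("residue score report writes the expected columns", {
  x <- helix_structure()
  s <- score_model(x, x)
  path <- withr::local_tempfile(fileext = ".csv")
  write_residue_scores(s, path)
  df <- utils::read.csv(path)
  expect_true(all(c("chain", "res_seq", "s_backbone", "s_sidechain",
                    "omega_flip") %in% names(df)))
  expect_equal(nrow(df), 11)
})
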