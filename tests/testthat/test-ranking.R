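test_that("adjusted_z reproduces small worked examples", {
  # mean 2, sample SD 1 -> (-1, 0, 1), nothing pruned, negatives clipped
  expect_equal(adjusted_z(c(1, 2, 3)), c(0, 0, 1))
  # degenerate population: SD 0 in pass one -> all zero
  expect_equal(adjusted_z(rep(7, 5)), rep(0, 5))
  # the low value sits at z1 = -1.79 (sample SD), above the -2 cutoff:
  # no pruning, so the four equal rows keep their positive pass-one z
  expect_equal(adjusted_z(c(0, 10, 10, 10, 10)),
               c(0, rep(2 / sqrt(20), 4)))
  # one more low row pushes the outlier below -2: pruned, and the
  # surviving population is degenerate -> everything 0
  expect_equal(adjusted_z(c(0, 10, 10, 10, 10, 10)), rep(0, 6))
})

test_that("adjusted_z equals the brute-force two-pass oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    v <- stats::rnorm(n, mean = 50, sd = stats::runif(1, 0.5, 20))
    if (i %% 3 == 0) v[1] <- v[1] - 100   # plant an outlier
    expect_equal(adjusted_z(v), brute_adjusted_z(v), tolerance = 1e-12)
    expect_equal(adjusted_z(v, higher_is_better = FALSE),
                 brute_adjusted_z(v, higher_is_better = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("adjusted_z is invariant under positive affine transformations", {
  set.seed(102)
  for (i in 1:50) {
    v <- stats::rnorm(sample(4:30, 1))
    a <- stats::runif(1, 0.1, 50)
    b <- stats::rnorm(1, 0, 100)
    expect_equal(adjusted_z(a * v + b), adjusted_z(v), tolerance = 1e-9)
  }
  # lower-is-better orientation equals negation
  v <- c(3, 9, 1, 4)
  expect_equal(adjusted_z(v, higher_is_better = FALSE), adjusted_z(-v))
})

test_that("adjusted_z handles NA, population SD, and short input", {
  expect_error(adjusted_z(5), "at least 2")
  z <- adjusted_z(c(1, NA, 3))
  expect_equal(z[2], 0)
  # population SD shrinks the denominator by sqrt((n-1)/n)
  zp <- adjusted_z(c(1, 2, 3), sd_type = "population")
  expect_equal(zp, c(0, 0, sqrt(3 / 2)), tolerance = 1e-12)
})

test_that("scheme weights match the printed coefficients and sum to one", {
  w <- scheme_weights("S_CASP12")
  expect_equal(unname(w[c("GDT_HA", "lDDT", "CADaa", "SG", "ASE")]),
               c(1 / 3, 1 / 9, 1 / 9, 1 / 9, 1 / 3))
  expect_equal(sum(w), 1)
  w2 <- scheme_weights("S_CASP12-ASE")
  expect_equal(unname(w2[c("GDT_HA", "lDDT")]), c(1 / 2, 1 / 6))
  expect_equal(sum(w2), 1)
  w3 <- scheme_weights("S_torsion")
  expect_equal(unname(w3[c("mean_backbone", "mean_sidechain")]),
               c(2 / 3, 1 / 3))
  w4 <- scheme_weights("S_geom")
  expect_equal(unname(w4[c("lDDT", "clashscore", "GDT_HA")]),
               c(1 / 16, 1 / 8, 1 / 4))
  expect_equal(sum(w4), 1)
  expect_error(scheme_weights("S_bogus"), "unknown scheme")
})

test_that("combine_z evaluates schemes linearly with zero for missing z", {
  expect_equal(combine_z(c(GDT_HA = 0, lDDT = 0, CADaa = 0, SG = 0, ASE = 0),
                         "S_CASP12"), 0)
  expect_equal(suppressMessages(combine_z(c(GDT_HA = 3), "S_CASP12")), 1)
  expect_equal(suppressMessages(
    combine_z(c(mean_backbone = 1.5), "S_torsion")), 1)
  # linearity
  z1 <- c(GDT_HA = 1, lDDT = 2, CADaa = 0.5, SG = 1, ASE = 0)
  z2 <- 2 * z1
  expect_equal(combine_z(z2, "S_CASP12-ASE"),
               2 * combine_z(z1, "S_CASP12-ASE"))
  # data frame form is vectorized
  df <- data.frame(GDT_HA = c(3, 0), lDDT = c(0, 9))
  expect_equal(suppressMessages(combine_z(df, "S_CASP12")), c(1, 1))
})

test_that("rank_groups follows strictly ordered metrics on one target", {
  tab <- data.frame(group = c("alpha", "beta", "gamma"),
                    target = "T1", model_index = 1,
                    GDT_HA = c(80, 60, 40), lDDT = c(80, 60, 40),
                    CADaa = c(80, 60, 40), SG = c(80, 60, 40),
                    ASE = c(80, 60, 40))
  r <- rank_groups(tab, "S_CASP12")
  expect_equal(r$groups$group, c("alpha", "beta", "gamma"))
  # negative-z clipping can tie the trailing groups at 0, but the order
  # must be non-increasing with the best group strictly ahead
  expect_true(all(diff(r$groups$score) <= 0))
  expect_gt(r$groups$score[1], r$groups$score[2])
})

test_that("rank_groups recovers a planted ordering", {
  tab <- synth_metric_table(n_groups = 6, n_targets = 20, effect = 3,
                            seed = 2024)
  truth <- attr(tab, "ground_truth")$group
  r <- rank_groups(tab, "S_CASP12", model_selection = "model_1")
  expect_equal(r$groups$group, truth)
  r5 <- rank_groups(tab, "S_CASP12", model_selection = "best_of_5")
  expect_equal(r5$groups$group[1], truth[1])
})

test_that("rank_groups is idempotent under duplicated rows and row order", {
  tab <- synth_metric_table(4, 5, seed = 9)
  r0 <- rank_groups(tab, "S_geom")
  dup <- rbind(tab, tab)
  expect_equal(rank_groups(dup, "S_geom")$groups, r0$groups)
  shuffled <- tab[sample(nrow(tab)), , drop = FALSE]
  expect_equal(rank_groups(shuffled, "S_geom")$groups, r0$groups)
})

test_that("lower-is-better metrics are oriented before z-scoring", {
  tab <- data.frame(group = rep(c("good", "bad"), each = 1),
                    target = "T1", model_index = 1,
                    mean_backbone = c(0.1, 0.4),
                    mean_sidechain = c(0.2, 0.5))
  r <- rank_groups(tab, "S_torsion")
  expect_equal(r$groups$group[1], "good")
})

test_that("metric tables survive a CSV/TSV round trip", {
  tab <- synth_metric_table(3, 3, seed = 5)
  p_csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, p_csv, row.names = FALSE)
  back <- read_metric_table(p_csv)
  expect_equal(back$GDT_HA, tab$GDT_HA, tolerance = 1e-12)
  p_tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, p_tsv, sep = "\t", row.names = FALSE)
  expect_equal(read_metric_table(p_tsv)$SG, tab$SG, tolerance = 1e-12)
  r <- rank_groups(back)
  p_out <- withr::local_tempfile(fileext = ".csv")
  write_ranking(r, groups_path = p_out)
  expect_equal(utils::read.csv(p_out)$group, r$groups$group)
})
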