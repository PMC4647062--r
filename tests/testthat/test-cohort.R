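make_table <- function(values_by_group, feature = "f", units = "u") {
  rows <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(cell_id = paste0(g, seq_along(v)), genotype = g,
               projection_class = "PT", compartment = "soma",
               distance_um = 0, feature = feature, value = v, units = units)
  }))
  feature_table(rows$cell_id, rows$genotype, rows$projection_class,
                rows$compartment, rows$distance_um, rows$feature,
                rows$value, rows$units)
}

test_that("group summaries compute mean and SEM by hand", {
  tab <- make_table(list(WT = c(1, 2, 3), KO = c(5, 5, 5)))
  s <- summarize_groups(tab, group_design("genotype"))
  wt <- s[s$group == "WT", ]
  expect_equal(wt$mean, 2)
  expect_equal(wt$sem, 0.5774, tolerance = 1e-3)
  expect_equal(s[s$group == "KO", "sem"], 0)
  expect_error(summarize_groups(make_table(list(WT = 1, KO = c(1, 2)))),
               "n < 2")
})

test_that("identical groups compare as a null result", {
  tab <- make_table(list(WT = c(1, 2, 3, 4), KO = c(1, 2, 3, 4)))
  cm <- compare_groups(tab, "f", group_design("genotype"))
  expect_equal(cm$effect_size, 0)
  expect_gt(cm$p_value, 0.99)
  expect_false(cm$significant)
})

test_that("empirical power matches the closed-form two-sample t power", {
  n <- 20; d <- 1
  power_expected <- stats::power.t.test(n = n, delta = d, sd = 1,
                                        sig.level = 0.05)$power
  set.seed(42)
  hits <- vapply(1:500, function(i) {
    tab <- make_table(list(WT = stats::rnorm(n), KO = stats::rnorm(n, d)))
    compare_groups(tab, "f", group_design("genotype"))$significant
  }, logical(1))
  expect_lt(abs(mean(hits) - power_expected), 0.05)
})

test_that("type-I error is nominal under the null", {
  set.seed(7)
  fp <- vapply(1:500, function(i) {
    tab <- make_table(list(WT = stats::rnorm(15), KO = stats::rnorm(15)))
    compare_groups(tab, "f", group_design("genotype"))$significant
  }, logical(1))
  expect_lt(abs(mean(fp) - 0.05), 0.02)
})

test_that("Bonferroni adjustment is monotone and never decreases p", {
  tab <- make_table(list(WT = c(1, 2, 3, 5), KO = c(2, 3, 4, 7)))
  p1 <- compare_groups(tab, "f", group_design(family_size = 1L))
  p5 <- compare_groups(tab, "f", group_design(family_size = 5L))
  p9 <- compare_groups(tab, "f", group_design(family_size = 9L))
  expect_gte(p1$p_adjusted, p1$p_value)
  expect_lte(p1$p_adjusted, p5$p_adjusted)
  expect_lte(p5$p_adjusted, p9$p_adjusted)
  expect_lte(p9$p_adjusted, 1)
})

test_that("Pearson correlation behaves at both extremes", {
  tab <- rbind(make_table(list(WT = 1:6), feature = "x"),
               make_table(list(WT = 2 * (1:6) + 1), feature = "y"))
  class(tab) <- c("feature_table", "data.frame")
  r <- correlate(tab, "x", "y")
  expect_equal(r$r_squared, 1)
  expect_error(correlate(rbind(make_table(list(WT = rep(1, 6)),
                                          feature = "x"), tab[7:12, ]),
                         "x", "y"), "variance")
  # under independence the p values are uniform
  set.seed(11)
  ps <- vapply(1:1000, function(i) {
    t2 <- rbind(make_table(list(WT = stats::rnorm(20)), feature = "x"),
                make_table(list(WT = stats::rnorm(20)), feature = "y"))
    class(t2) <- c("feature_table", "data.frame")
    correlate(t2, "x", "y")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("resonance is negatively correlated with input resistance in PT", {
  cells <- sample_cohort(cohort_spec("WT", "PT", n_cells = 12, seed = 21))
  rows <- do.call(rbind, lapply(seq_along(cells), function(i) {
    rn <- analytic_input_resistance(cells[[i]])
    fr <- zap_profile(run_chirp(cells[[i]]))$f_R_Hz
    data.frame(id = sprintf("c%02d", i), rn = rn, fr = fr)
  }))
  tab <- feature_table(rep(rows$id, 2), "WT", "PT", "soma", 0,
                       rep(c("R_N", "f_R"), each = nrow(rows)),
                       c(rows$rn, rows$fr), "u")
  r <- correlate(tab, "R_N", "f_R")
  expect_lt(r$r, 0)
})

test_that("direction summary maps signs and significance", {
  tab_up <- make_table(list(WT = c(1, 1.1, 0.9, 1), KO = c(3, 3.1, 2.9, 3)))
  tab_ns <- make_table(list(WT = c(1, 2, 3, 4), KO = c(1.1, 2, 3, 4.2)))
  cm_up <- compare_groups(tab_up, "f", group_design("genotype"))
  cm_ns <- compare_groups(tab_ns, "f", group_design("genotype"))
  d <- direction_summary(list(a = cm_up, b = cm_ns))
  expect_identical(d$direction, c("up", "unchanged"))
  # flipping the group means flips the arrow
  tab_dn <- make_table(list(WT = c(3, 3.1, 2.9, 3), KO = c(1, 1.1, 0.9, 1)))
  cm_dn <- compare_groups(tab_dn, "f", group_design("genotype"))
  expect_identical(direction_summary(list(cm_dn))$direction, "down")
})

test_that("the pipeline is deterministic and validates its config", {
  expect_error(run_pipeline(list(features = "nope")), "unknown feature")
  cfg <- list(n_cells = 3, seed = 5, features = "subthreshold",
              classes = "PT", family_size = 1)
  r1 <- suppressWarnings(run_pipeline(cfg))
  r2 <- suppressWarnings(run_pipeline(cfg))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write_feature_table(r1$feature_table, f1)
  write_feature_table(r2$feature_table, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(all(c("feature", "direction") %in% names(r1$directions)))
})

test_that("the calibrated WT PT cohort resonates where the class does", {
  cells <- sample_cohort(cohort_spec("WT", "PT", n_cells = 15, seed = 7))
  frs <- vapply(cells, function(cell)
    zap_profile(run_chirp(cell))$f_R_Hz, numeric(1))
  # printed class statistic: 4.11 +/- 0.32 Hz (mean +/- SEM)
  expect_lt(abs(mean(frs) - 4.11), 2 * 0.32)
  expect_true(all(frs > 2.2))  # every cell classifies as PT-like
})
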