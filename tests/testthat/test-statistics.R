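toy_table <- function(vl, vr, gender = "male") {
  n <- length(vl)
  rbind(
    data.frame(id = sprintf("S%02d", 1:n), gender = gender, age = 40,
               side = "left", volume_ml = vl, area_mm2 = 3800,
               depth_mm = 39, defect = "none"),
    data.frame(id = sprintf("S%02d", 1:n), gender = gender, age = 40,
               side = "right", volume_ml = vr, area_mm2 = 3800,
               depth_mm = 39, defect = "none"))
}

test_that("asymmetry screening flags strictly above 0.2 mL", {
  t <- toy_table(c(27.5, 25.0, 24.0), c(26.7, 25.2, 24.2))
  sc <- screen_asymmetry(t)
  expect_equal(sc$flagged_ids, "S01")  # |27.5 - 26.7| = 0.8 mL
  t2 <- toy_table(25, 25.2)
  expect_length(screen_asymmetry(t2)$flagged_ids, 0L)  # exactly 0.2 retained
  # partition exhaustive and disjoint
  sc3 <- screen_asymmetry(toy_table(rnorm(20, 25, 3), rnorm(20, 25, 3)))
  expect_equal(nrow(sc3$retained) + nrow(sc3$excluded), 40L)
  expect_length(intersect(sc3$retained$id, sc3$excluded$id), 0L)
  # scale consistency: mm^3 volumes with a 200 mm^3 threshold
  tmm <- toy_table(c(27.5, 25.0) * 1000, c(26.7, 25.2) * 1000)
  expect_equal(screen_asymmetry(tmm, threshold_ml = 200)$flagged_ids, "S01")
  expect_error(screen_asymmetry(t, threshold_ml = 0), "> 0")
})

test_that("normality test behaves as Shapiro-Wilk should", {
  expect_error(test_normality(rep(5, 10)), "constant")
  expect_error(test_normality(c(1, 2)), "at least 3")
  set.seed(1)
  rej <- mean(replicate(400, test_normality(rnorm(91))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
  pow <- mean(replicate(150, test_normality(rexp(91))$p < 0.05))
  expect_gt(pow, 0.95)
})

test_that("group comparisons match textbook forms and handle degeneracy", {
  # hand-checkable 2-point-per-group Welch t
  t <- rbind(toy_table(c(10, 12), c(10, 12), "male"),
             toy_table(c(20, 26), c(20, 26), "female"))
  r <- compare_groups(t, "volume_ml", "male_vs_female", side = "left")
  expect_equal(r$p_unpaired,
               t.test(c(10, 12), c(20, 26))$p.value, tolerance = 1e-12)
  # identical sides: paired differences all zero -> degenerate
  tid <- toy_table(c(24, 25, 26), c(24, 25, 26))
  expect_warning(r2 <- compare_groups(tid, "volume_ml", "left_vs_right"),
                 "zero variance")
  expect_true(is.na(r2$p_paired))
})

test_that("side and larger-smaller designs reproduce the expected pattern", {
  set.seed(42)
  ok <- replicate(25, {
    t <- screen_asymmetry(make_cohort(cohort_gen_params(
      n_male = 91, n_female = 0,
      rng_seed = sample.int(1e6, 1)))$table)$retained
    lvr <- compare_groups(t, "volume_ml", "left_vs_right", gender = "male")
    lvs <- compare_groups(t, "volume_ml", "larger_vs_smaller",
                          gender = "male")
    c(lvs_paired = lvs$p_paired < 1e-10, lvs_unpaired = lvs$p_unpaired > 0.1,
      lvr_unpaired = lvr$p_unpaired > 0.1)
  })
  expect_gte(mean(ok["lvs_paired", ]), 0.9)
  expect_gte(mean(ok["lvs_unpaired", ]), 0.9)
  expect_gte(mean(ok["lvr_unpaired", ]), 0.9)
})

test_that("unpaired test keeps its nominal size", {
  set.seed(7)
  rej <- replicate(300, {
    t <- rbind(toy_table(rnorm(91, 27, 3.5), rnorm(91, 27, 3.5), "male"),
               toy_table(rnorm(83, 27, 3.5), rnorm(83, 27, 3.5), "female"))
    compare_groups(t, "volume_ml", "male_vs_female")$p_unpaired < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("the volume model recovers a pure depth effect", {
  set.seed(3)
  n <- 60
  depth <- rnorm(2 * n, c(rep(40, n), rep(37, n)), 3)
  vol <- 2 + 0.9 * depth + rnorm(2 * n, 0, 1e-6)
  t <- data.frame(id = sprintf("S%03d", 1:(2 * n)),
                  gender = rep(c("male", "female"), each = n), age = 40,
                  side = "left", volume_ml = vol, area_mm2 = 3800,
                  depth_mm = depth, defect = "none")
  fit <- fit_volume_model(t, "left")
  cf <- fit$coefficients
  expect_lt(cf["Depth", 4], 1e-12)
  expect_gt(cf["Gender", 4], 0.05)
  expect_gt(cf["Gender:Depth", 4], 0.05)
  expect_equal(unname(cf["Depth", 1]), 0.9, tolerance = 1e-3)
  expect_error(fit_volume_model(t[1:4, ], "left"), "more than 4")
  expect_error(fit_volume_model(t[t$gender == "male", ], "left"),
               "both genders")
})

test_that("squared correlations are Pearson R2", {
  x <- seq(30, 45, length.out = 20)
  t <- rbind(
    data.frame(id = sprintf("M%02d", 1:20), gender = "male", age = 40,
               side = "left", volume_ml = 2 * x + 1, area_mm2 = 3 * x - 5,
               depth_mm = x, defect = "none"),
    data.frame(id = sprintf("M%02d", 1:20), gender = "male", age = 40,
               side = "right", volume_ml = 2 * x + 1, area_mm2 = 3 * x - 5,
               depth_mm = x, defect = "none"),
    data.frame(id = sprintf("F%02d", 1:20), gender = "female", age = 40,
               side = "left", volume_ml = 2 * x + 1, area_mm2 = 3 * x - 5,
               depth_mm = x, defect = "none"),
    data.frame(id = sprintf("F%02d", 1:20), gender = "female", age = 40,
               side = "right", volume_ml = 2 * x + 1, area_mm2 = 3 * x - 5,
               depth_mm = x, defect = "none"))
  r2 <- correlations(t)
  expect_true(all(abs(r2$r2 - 1) < 1e-12))
  # null distribution: mean R2 ~ 1/(n-1) for independent normals
  set.seed(5)
  r2null <- replicate(400, cor(rnorm(91), rnorm(91))^2)
  expect_lt(abs(mean(r2null) - 1 / 90), 0.004)
})

test_that("ICC matches the ANOVA oracle and discriminates forms", {
  set.seed(8)
  for (trial in 1:5) {
    m <- matrix(rnorm(10 * 6, mean = 25, sd = 3), 10, 6)
    expect_equal(icc(m), icc_aov(m), tolerance = 1e-10)
  }
  base <- rnorm(10, 25, 3)
  same <- matrix(rep(base, 6), 10, 6)
  expect_equal(icc(same), 1)
  offs <- same + rep(seq(0, 2.5, length.out = 6), each = 10)
  expect_lt(icc(offs, "agreement"), 1)
  expect_equal(icc(offs, "consistency"), 1, tolerance = 1e-12)
  expect_warning(r <- icc(matrix(5, 3, 3)), "degenerate")
  expect_true(is.nan(r))
  expect_error(icc(matrix(1:3, 3, 1)), "at least 2")
})

test_that("derived ratios reproduce the reference summary values", {
  ref <- reference_cohort_summary()
  gd <- summary_gender_difference(ref, "volume_ml")
  expect_equal(gd, 13.96, tolerance = 0.005)
  expect_equal(round(gd), 14)
  va <- summary_volume_area_ratio(ref)
  expect_equal(va$average, 0.738, tolerance = 0.001)
  expect_equal(round(va$average / 0.05) * 0.05, 0.75)
  # male left cell: 28.95 / 38.7868
  ml <- va$cells$ratio[va$cells$gender == "male" & va$cells$side == "left"]
  expect_equal(ml, 0.7464, tolerance = 1e-4)
})

test_that("cohort-level ratios behave on constructed tables", {
  t <- toy_table(c(25, 25), c(25, 25))
  t$gender <- rep(c("male", "female"), 2)  # equal means across genders
  expect_equal(unname(gender_volume_difference(t)), 0, tolerance = 1e-12)
  # a sphere of radius 22.5 mm has V/A = r/30 cm = 0.75 mL/cm^2
  r <- 22.5
  ts <- toy_table(4 / 3 * pi * r^3 / 1000, 4 / 3 * pi * r^3 / 1000)
  ts$area_mm2 <- 4 * pi * r^2
  expect_equal(volume_area_ratio(ts)$average, 0.75, tolerance = 1e-12)
  expect_error(volume_area_ratio(within(ts, area_mm2 <- 0)), "positive")
})

test_that("gender volume difference recovers ~14% on synthetic cohorts", {
  gd <- sapply(1:25, function(s) {
    r <- screen_asymmetry(make_cohort(cohort_gen_params(rng_seed = s))$table)
    gender_volume_difference(r$retained)
  })
  expect_lt(abs(mean(gd) - 14), 1.5)
  expect_true(all(abs(gd - 14) < 6))
})
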