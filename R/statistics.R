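#' Screen a cohort for left-right asymmetry
#'
#' Flags subjects whose left and right orbital volumes differ by strictly
#' more than the threshold (default 0.2 mL) and partitions the cohort into
#' retained and excluded tables. The partition is exhaustive and disjoint; a
#' difference of exactly the threshold is retained.
#'
#' @param table a `cohort_table` (long format, both sides per subject).
#' @param threshold_ml asymmetry threshold (mL), must be > 0.
#' @return List with `retained` and `excluded` cohort tables (both carry an
#'   `asymmetric_flag` column) and `flagged_ids`.
#' @export
screen_asymmetry <- function(table, threshold_ml = 0.2) {
  if (threshold_ml <= 0) stop("threshold_ml must be > 0")
  w <- cohort_wide(table, "volume_ml")
  if (any(!complete.cases(w[, c("left", "right")])))
    stop("volume missing for one side of subject(s): ",
         paste(w$id[!complete.cases(w[, c("left", "right")])],
               collapse = ", "))
  flagged <- w$id[abs(w$left - w$right) > threshold_ml]
  table$asymmetric_flag <- table$id %in% flagged
  retained <- table[!table$asymmetric_flag, , drop = FALSE]
  excluded <- table[table$asymmetric_flag, , drop = FALSE]
  class(retained) <- class(excluded) <- c("cohort_table", "data.frame")
  list(retained = retained, excluded = excluded, flagged_ids = flagged)
}

# wide subject x side layout for one parameter
cohort_wide <- function(table, parameter) {
  l <- table[table$side == "left", c("id", "gender", parameter)]
  r <- table[table$side == "right", c("id", parameter)]
  names(l)[3] <- "left"
  names(r)[2] <- "right"
  merge(l, r, by = "id", all = TRUE)
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric sample, `n >= 3`, non-constant.
#' @return List with `W` and `p`.
#' @export
test_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 observations")
  if (diff(range(values)) == 0) stop("constant sample: normality undefined")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}

# Shapiro-Wilk p per gender x side x parameter
normality_table <- function(table) {
  params <- c("volume_ml", "area_mm2", "depth_mm")
  grid <- expand.grid(gender = c("male", "female"),
                      side = c("left", "right"), parameter = params,
                      stringsAsFactors = FALSE)
  grid$p <- vapply(seq_len(nrow(grid)), function(i) {
    x <- table[table$gender == grid$gender[i] & table$side == grid$side[i],
               grid$parameter[i]]
    test_normality(x)$p
  }, 0)
  grid
}

#' Group comparisons of orbital parameters
#'
#' Three designs: `male_vs_female` (unpaired Welch t-test on per-side
#' pooled ... the comparison is run on the requested side's values),
#' `left_vs_right` (Welch unpaired plus within-subject paired t-test) and
#' `larger_vs_smaller` (per-subject maximum versus minimum over sides,
#' unpaired as if independent samples plus paired within subject).
#'
#' @param table a `cohort_table`.
#' @param parameter `"volume_ml"`, `"area_mm2"` or `"depth_mm"`.
#' @param design comparison design.
#' @param side for `male_vs_female`: which side to compare.
#' @param gender for the side-based designs: restrict to one gender
#'   (`NULL` pools).
#' @return List with `p_unpaired` and, for the paired designs, `p_paired`.
#' @export
compare_groups <- function(table, parameter = "volume_ml",
                           design = c("male_vs_female", "left_vs_right",
                                      "larger_vs_smaller"),
                           side = "left", gender = NULL) {
  design <- match.arg(design)
  if (design == "male_vs_female") {
    sub <- table[table$side == side, ]
    m <- sub[[parameter]][sub$gender == "male"]
    f <- sub[[parameter]][sub$gender == "female"]
    if (!length(m) || !length(f)) stop("empty gender group")
    return(list(p_unpaired = t.test(m, f)$p.value))
  }
  sub <- if (is.null(gender)) table else table[table$gender == gender, ]
  w <- cohort_wide(sub, parameter)
  w <- w[complete.cases(w[, c("left", "right")]), ]
  if (!nrow(w)) stop("no complete bilateral subjects")
  if (design == "left_vs_right") {
    a <- w$left; b <- w$right
  } else {
    a <- pmax(w$left, w$right); b <- pmin(w$left, w$right)
  }
  d <- a - b
  p_paired <- if (sd(d) == 0) {
    warning("paired differences have zero variance; paired test degenerate")
    NA_real_
  } else {
    t.test(a, b, paired = TRUE)$p.value
  }
  list(p_unpaired = t.test(a, b)$p.value, p_paired = p_paired)
}

#' Linear model of volume on gender, depth and their interaction
#'
#' Ordinary least squares fit of
#' `volume ~ 1 + gender + depth + gender:depth` on one side of the cohort,
#' with gender coded male = 1, female = 0. Reports the coefficient table
#' (estimate, t, p) for all four terms.
#'
#' @param table a `cohort_table`.
#' @param side `"left"` or `"right"`.
#' @return List with `fit` (the `lm` object) and `coefficients` (matrix with
#'   rows Intercept, Gender, Depth, Gender:Depth).
#' @export
fit_volume_model <- function(table, side = "left") {
  sub <- table[table$side == side, ]
  if (nrow(sub) <= 4) stop("need more than 4 observations")
  if (length(unique(sub$gender)) < 2) stop("both genders required")
  sub$gender_num <- as.numeric(sub$gender == "male")
  fit <- lm(volume_ml ~ gender_num * depth_mm, data = sub)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 4 || any(is.na(coef(fit))))
    stop("rank-deficient design")
  rownames(cf) <- c("Intercept", "Gender", "Depth", "Gender:Depth")
  list(fit = fit, coefficients = cf)
}

#' Squared correlations among depth, volume and area
#'
#' Squared Pearson correlations for volume x depth (VxL), area x depth
#' (AxL) and area x volume (AxV), per gender and side.
#'
#' @param table a `cohort_table`.
#' @return data.frame with columns `pair`, `gender`, `side`, `r2`.
#' @export
correlations <- function(table) {
  pairs <- list(VxL = c("volume_ml", "depth_mm"),
                AxL = c("area_mm2", "depth_mm"),
                AxV = c("area_mm2", "volume_ml"))
  grid <- expand.grid(pair = names(pairs), gender = c("male", "female"),
                      side = c("left", "right"), stringsAsFactors = FALSE)
  grid$r2 <- vapply(seq_len(nrow(grid)), function(i) {
    sub <- table[table$gender == grid$gender[i] &
                   table$side == grid$side[i], ]
    if (nrow(sub) < 3) stop("need at least 3 observations per cell")
    v <- pairs[[grid$pair[i]]]
    if (sd(sub[[v[1]]]) == 0 || sd(sub[[v[2]]]) == 0)
      stop("zero variance in correlation cell")
    cor(sub[[v[1]]], sub[[v[2]]])^2
  }, 0)
  grid
}

#' Intraclass correlation coefficient
#'
#' Single-measurement ICC from the two-way ANOVA decomposition of a
#' subjects-by-raters matrix. The default `"agreement"` form is the two-way
#' random-effects absolute-agreement ICC (ICC(A,1)); `"consistency"` gives
#' the two-way mixed consistency ICC (ICC(C,1)), which ignores systematic
#' rater offsets.
#'
#' @param measurements numeric matrix, subjects in rows, raters/runs in
#'   columns (at least 2 x 2).
#' @param form `"agreement"` or `"consistency"`.
#' @return ICC value in `[-1, 1]`.
#' @export
icc <- function(measurements, form = c("agreement", "consistency")) {
  form <- match.arg(form)
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  mu <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - mu)^2)
  ssc <- n * sum((cm - mu)^2)
  sse <- sum((m - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + mu)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- if (form == "agreement")
    msr + (k - 1) * mse + k * (msc - mse) / n
  else
    msr + (k - 1) * mse
  if (denom <= 0) {
    warning("degenerate ICC: no variance in measurements")
    return(NaN)
  }
  (msr - mse) / denom
}

#' Percent gender difference of a parameter
#'
#' `100 * (mean_male - mean_female) / mean_female` with side-averaged
#' per-gender means. Operates on a cohort table or, via
#' [summary_gender_difference()], directly on published summary statistics.
#'
#' @param table a `cohort_table`.
#' @param parameter column to compare.
#' @return Percent difference (positive when male larger).
#' @export
gender_volume_difference <- function(table, parameter = "volume_ml") {
  mm <- side_averaged_means(table, parameter)
  if (any(is.na(mm))) stop("empty gender group")
  100 * (mm["male"] - mm["female"]) / mm["female"]
}

side_averaged_means <- function(table, parameter) {
  agg <- aggregate(table[[parameter]],
                   list(gender = table$gender, side = table$side), mean)
  c(male = mean(agg$x[agg$gender == "male"]),
    female = mean(agg$x[agg$gender == "female"]))
}

#' @rdname gender_volume_difference
#' @param summary a summary table as from [reference_cohort_summary()].
#' @export
summary_gender_difference <- function(summary, parameter = "volume_ml") {
  m <- ref_cell(summary, parameter, "male")
  f <- ref_cell(summary, parameter, "female")
  100 * (m - f) / f
}

#' Volume to surface-area ratio
#'
#' Mean volume (mL) divided by mean surface area (cm^2) per gender and side,
#' plus the average over the four gender-by-side cells.
#'
#' @param table a `cohort_table` (areas in mm^2).
#' @return List with `cells` (data.frame gender, side, ratio) and `average`.
#' @export
volume_area_ratio <- function(table) {
  if (any(table$area_mm2 <= 0)) stop("areas must be positive")
  v <- aggregate(table$volume_ml,
                 list(gender = table$gender, side = table$side), mean)
  a <- aggregate(table$area_mm2,
                 list(gender = table$gender, side = table$side), mean)
  cells <- v
  names(cells)[3] <- "ratio"
  cells$ratio <- v$x / (a$x / 100)  # mm^2 -> cm^2
  list(cells = cells[, c("gender", "side", "ratio")],
       average = mean(cells$ratio))
}

#' @rdname volume_area_ratio
#' @param summary a summary table as from [reference_cohort_summary()].
#' @export
summary_volume_area_ratio <- function(summary) {
  grid <- expand.grid(gender = c("male", "female"),
                      side = c("left", "right"), stringsAsFactors = FALSE)
  grid$ratio <- vapply(seq_len(nrow(grid)), function(i) {
    rows <- function(p) summary$mean[summary$parameter == p &
                                       summary$gender == grid$gender[i] &
                                       summary$side == grid$side[i]]
    rows("volume_ml") / (rows("area_mm2") / 100)
  }, 0)
  list(cells = grid, average = mean(grid$ratio))
}

#' Full cohort statistics report
#'
#' Runs the complete statistical battery on a (screened) cohort table:
#' Shapiro-Wilk normality per gender x side x parameter, gender / side /
#' larger-versus-smaller comparisons per parameter, the volume ~ gender x
#' depth interaction model per side, squared correlations, the percent
#' gender volume difference and the volume/area ratio.
#'
#' @param table a `cohort_table` (typically `screen_asymmetry()$retained`).
#' @return An object of class `stats_report`.
#' @export
stats_report <- function(table) {
  params <- c("volume_ml", "depth_mm", "area_mm2")
  group_tests <- list()
  for (p in params) {
    group_tests[[p]] <- list(
      male_vs_female = list(
        left = compare_groups(table, p, "male_vs_female", side = "left"),
        right = compare_groups(table, p, "male_vs_female", side = "right")),
      left_vs_right = list(
        male = compare_groups(table, p, "left_vs_right", gender = "male"),
        female = compare_groups(table, p, "left_vs_right",
                                gender = "female")),
      larger_vs_smaller = list(
        male = compare_groups(table, p, "larger_vs_smaller",
                              gender = "male"),
        female = compare_groups(table, p, "larger_vs_smaller",
                                gender = "female")))
  }
  models <- list(left = fit_volume_model(table, "left")$coefficients,
                 right = fit_volume_model(table, "right")$coefficients)
  structure(list(
    n_subjects = length(unique(table$id)),
    normality = normality_table(table),
    group_tests = group_tests,
    model = models,
    r2 = correlations(table),
    gender_diff_pct = unname(gender_volume_difference(table)),
    va_ratio = volume_area_ratio(table)), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report> ", x$n_subjects, " subjects\n", sep = "")
  cat("  gender volume difference: ", signif(x$gender_diff_pct, 4),
      " %\n", sep = "")
  cat("  volume/area ratio (4-cell average): ",
      signif(x$va_ratio$average, 4), " mL/cm^2\n", sep = "")
  gm <- x$group_tests$volume_ml
  cat("  volume p: male vs female (left) ",
      format.pval(gm$male_vs_female$left$p_unpaired, digits = 3),
      ", left vs right paired (male) ",
      format.pval(gm$left_vs_right$male$p_paired, digits = 3),
      ",\n    larger vs smaller paired (male) ",
      format.pval(gm$larger_vs_smaller$male$p_paired, digits = 3),
      " / unpaired ",
      format.pval(gm$larger_vs_smaller$male$p_unpaired, digits = 3),
      "\n", sep = "")
  cat("  model (left) Depth p: ",
      format.pval(x$model$left["Depth", 4], digits = 3),
      ", Gender p: ", format.pval(x$model$left["Gender", 4], digits = 3),
      ", Gender:Depth p: ",
      format.pval(x$model$left["Gender:Depth", 4], digits = 3), "\n",
      sep = "")
  invisible(x)
}
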