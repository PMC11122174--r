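#' Reference adult orbit summary statistics
#'
#' Published per-gender, per-side summary statistics (mean, median, SD,
#' range) of orbital depth (mm), volume (mL) and surface area (mm^2) in a
#' screened adult cohort of 91 men and 83 women. These values parameterize
#' the default cohort simulator and anchor the derived summary ratios.
#'
#' @return data.frame with columns `parameter`, `gender`, `side`, `mean`,
#'   `median`, `sd`, `min`, `max`.
#' @export
reference_cohort_summary <- function() {
  read.csv(system.file("extdata", "reference_cohort_summary.csv",
                       package = "orbitometry"),
           stringsAsFactors = FALSE)
}

ref_cell <- function(summary, parameter, gender, stat = "mean") {
  rows <- summary$parameter == parameter & summary$gender == gender
  mean(summary[[stat]][rows])  # side-averaged
}

#' Cohort generator parameters
#'
#' Sampling targets for the synthetic bilateral cohort. Defaults reproduce
#' the reference adult cohort: per-gender means and SDs of depth, volume and
#' area, squared depth-volume and area-volume correlations, a within-subject
#' left-right volume difference SD, and the rate of anatomically asymmetric
#' or artifact-bearing subjects.
#'
#' Volume is coupled to depth as `V = alpha_gender + beta * depth + noise`
#' with a slope shared across genders (depth is the only structural
#' predictor of volume); area is coupled to volume the same way. Per-gender
#' noise SDs are set so the squared correlations hit their targets in
#' expectation.
#'
#' @param n_male,n_female subjects per gender.
#' @param depth_mean,depth_sd named numeric (`male`, `female`), mm.
#' @param volume_mean,volume_sd named numeric, mL.
#' @param area_mean,area_sd named numeric, mm^2.
#' @param r2_volume_depth,r2_area_volume named numeric targets in (0, 1).
#' @param lr_sd_volume_ml SD (mL) of the left-right volume difference in
#'   defect-free subjects.
#' @param lr_sd_depth_mm,lr_sd_area_mm2 analogous side-difference SDs.
#' @param asymmetry_defect_rate probability that a subject carries a
#'   unilateral defect or gross asymmetry exceeding the screening threshold.
#' @param age_mean,age_sd,age_range years.
#' @param shape_family cavity shape for emitted phantom specs.
#' @param rng_seed integer seed.
#' @return An object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_male = 91L, n_female = 83L,
                              depth_mean = NULL, depth_sd = NULL,
                              volume_mean = NULL, volume_sd = NULL,
                              area_mean = NULL, area_sd = NULL,
                              r2_volume_depth = c(male = 0.72,
                                                  female = 0.545),
                              r2_area_volume = c(male = 0.955,
                                                 female = 0.87),
                              lr_sd_volume_ml = 0.07,
                              lr_sd_depth_mm = 0.15,
                              lr_sd_area_mm2 = 10,
                              asymmetry_defect_rate = 12 / 186,
                              age_mean = 38.49, age_sd = 13.52,
                              age_range = c(18, 74),
                              shape_family = "paraboloid",
                              rng_seed = 1L) {
  ref <- reference_cohort_summary()
  pick <- function(given, parameter, stat) {
    if (!is.null(given)) return(given)
    c(male = ref_cell(ref, parameter, "male", stat),
      female = ref_cell(ref, parameter, "female", stat))
  }
  depth_mean <- pick(depth_mean, "depth_mm", "mean")
  depth_sd <- pick(depth_sd, "depth_mm", "sd")
  volume_mean <- pick(volume_mean, "volume_ml", "mean")
  volume_sd <- pick(volume_sd, "volume_ml", "sd")
  area_mean <- pick(area_mean, "area_mm2", "mean")
  area_sd <- pick(area_sd, "area_mm2", "sd")
  if (n_male < 0 || n_female < 0) stop("nonpositive group size")
  if (any(c(depth_sd, volume_sd, area_sd) <= 0)) stop("SDs must be > 0")
  if (any(r2_volume_depth <= 0 | r2_volume_depth > 1) ||
      any(r2_area_volume <= 0 | r2_area_volume > 1))
    stop("infeasible R^2 target (must be in (0, 1])")
  if (asymmetry_defect_rate < 0 || asymmetry_defect_rate > 1)
    stop("asymmetry_defect_rate must be a probability")
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 volume_mean = volume_mean, volume_sd = volume_sd,
                 area_mean = area_mean, area_sd = area_sd,
                 r2_volume_depth = r2_volume_depth,
                 r2_area_volume = r2_area_volume,
                 lr_sd_volume_ml = lr_sd_volume_ml,
                 lr_sd_depth_mm = lr_sd_depth_mm,
                 lr_sd_area_mm2 = lr_sd_area_mm2,
                 asymmetry_defect_rate = asymmetry_defect_rate,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 shape_family = shape_family,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_gen_params")
}

# depth->volume and volume->area coupling coefficients implied by the targets
cohort_coupling <- function(p) {
  g <- c("male", "female")
  beta_g <- sqrt(p$r2_volume_depth[g]) * p$volume_sd[g] / p$depth_sd[g]
  beta <- mean(beta_g)                 # shared slope across genders
  sd_v <- beta * p$depth_sd[g] / sqrt(p$r2_volume_depth[g])
  sigma_v <- sd_v * sqrt(1 - p$r2_volume_depth[g])
  alpha <- p$volume_mean[g] - beta * p$depth_mean[g]
  gamma_g <- sqrt(p$r2_area_volume[g]) * p$area_sd[g] / sd_v
  gamma <- mean(gamma_g)
  sigma_a <- gamma * sd_v * sqrt((1 - p$r2_area_volume[g]) /
                                   p$r2_area_volume[g])
  gamma0 <- p$area_mean[g] - gamma * p$volume_mean[g]
  list(beta = beta, alpha = alpha, sigma_v = sigma_v,
       gamma = gamma, gamma0 = gamma0, sigma_a = sigma_a)
}

#' Simulate a bilateral cohort with matching phantom geometry
#'
#' Draws per-subject depth from gender-specific normals, volume conditionally
#' on depth (shared slope, per-gender intercept and noise hitting the target
#' squared correlations), and area conditionally on volume; splits each
#' parameter into left/right values around the subject mean with small
#' within-subject differences. A random subset of subjects receives a
#' unilateral defect (lacrimal-channel segmentation error, wall fracture, or
#' gross anatomical asymmetry, in 5:3:4 proportions) that shifts that side's
#' measured volume beyond the asymmetry screening threshold.
#'
#' Alongside the metric table, one phantom specification pair per subject is
#' emitted whose closed-form depth and volume match the drawn side values
#' (phantom surface area is geometry-determined, so the table is the
#' authority for area statistics).
#'
#' @param params a [cohort_gen_params()].
#' @param voxel_spacing_mm spacing written into the emitted phantom specs.
#' @return List with `table` (class `cohort_table`: columns `id`, `gender`,
#'   `age`, `side`, `volume_ml`, `area_mm2`, `depth_mm`, `defect`) and
#'   `specs` (per subject, a list with `left` and `right` [phantom_spec()]).
#' @export
make_cohort <- function(params = cohort_gen_params(),
                        voxel_spacing_mm = c(0.5, 0.5, 0.5)) {
  stopifnot(inherits(params, "cohort_gen_params"))
  n <- params$n_male + params$n_female
  if (n == 0) {
    empty <- data.frame(id = character(0), gender = character(0),
                        age = numeric(0), side = character(0),
                        volume_ml = numeric(0), area_mm2 = numeric(0),
                        depth_mm = numeric(0), defect = character(0),
                        stringsAsFactors = FALSE)
    class(empty) <- c("cohort_table", "data.frame")
    return(list(table = empty, specs = list()))
  }
  cp <- cohort_coupling(params)
  with_seed(params$rng_seed, {
    gender <- rep(c("male", "female"), c(params$n_male, params$n_female))
    gi <- ifelse(gender == "male", 1L, 2L)
    depth <- rnorm(n, params$depth_mean[gi], params$depth_sd[gi])
    volume <- cp$alpha[gi] + cp$beta * depth + rnorm(n, 0, cp$sigma_v[gi])
    area <- cp$gamma0[gi] + cp$gamma * volume + rnorm(n, 0, cp$sigma_a[gi])
    volume <- pmax(volume, 5)
    area <- pmax(area, 500)
    age <- round(pmin(pmax(rnorm(n, params$age_mean, params$age_sd),
                           params$age_range[1]), params$age_range[2]))
    dv <- rnorm(n, 0, params$lr_sd_volume_ml)
    dd <- rnorm(n, 0, params$lr_sd_depth_mm)
    da <- rnorm(n, 0, params$lr_sd_area_mm2)
    has_defect <- runif(n) < params$asymmetry_defect_rate
    defect_kind <- ifelse(has_defect,
                          sample(c("lacrimal_channel", "wall_fracture",
                                   "anatomic_asymmetry"), n, replace = TRUE,
                                 prob = c(5, 3, 4) / 12), "none")
    defect_side <- sample(c("left", "right"), n, replace = TRUE)
    defect_delta <- ifelse(defect_kind == "anatomic_asymmetry",
                           sample(c(-1, 1), n, replace = TRUE) *
                             runif(n, 0.3, 1.5),
                           runif(n, 0.4, 1.2))
    spec_seeds <- sample.int(.Machine$integer.max, 2 * n)
  })
  side_val <- function(subj, delta, side)
    subj + (if (side == "left") delta / 2 else -delta / 2)
  rows <- lapply(c("left", "right"), function(s) {
    v <- side_val(volume, dv, s)
    d <- side_val(depth, dd, s)
    a <- side_val(area, da, s)
    dk <- ifelse(has_defect & defect_side == s, defect_kind, "none")
    v <- v + ifelse(dk != "none", defect_delta, 0)
    data.frame(id = sprintf("S%03d", seq_len(n)), gender = gender,
               age = age, side = s, volume_ml = v, area_mm2 = a,
               depth_mm = d, defect = dk, stringsAsFactors = FALSE)
  })
  table <- rbind(rows[[1]], rows[[2]])
  table <- table[order(table$id, table$side), ]
  rownames(table) <- NULL
  class(table) <- c("cohort_table", "data.frame")

  specs <- lapply(seq_len(n), function(i) {
    per_side <- function(s, si) {
      v <- rows[[si]]$volume_ml[i] - if (rows[[si]]$defect[i] != "none")
        defect_delta[i] else 0
      h <- rows[[si]]$depth_mm[i]
      a_mm <- switch(params$shape_family,
        paraboloid = sqrt(2 * v * 1000 / (pi * h)),  # V = pi a^2 h / 2
        cone = sqrt(3 * v * 1000 / (pi * h)),        # V = pi a^2 h / 3
        hemisphere = (3 * v * 1000 / (2 * pi))^(1 / 3))
      dk <- rows[[si]]$defect[i]
      phantom_spec(shape_family = params$shape_family, depth_mm = h,
                   aperture_radius_mm = a_mm,
                   voxel_spacing_mm = voxel_spacing_mm, side = s,
                   defect = if (dk %in% c("lacrimal_channel",
                                          "wall_fracture")) dk else "none",
                   rng_seed = spec_seeds[2 * (i - 1) + si])
    }
    list(left = per_side("left", 1L), right = per_side("right", 2L))
  })
  list(table = table, specs = specs)
}

#' @export
print.cohort_table <- function(x, ...) {
  ns <- length(unique(x$id))
  cat("<cohort_table> ", ns, " subjects (",
      sum(x$gender[!duplicated(x$id)] == "male"), " male, ",
      sum(x$gender[!duplicated(x$id)] == "female"), " female), ",
      nrow(x), " orbit rows, ", sum(x$defect != "none"),
      " defect side(s)\n", sep = "")
  NextMethod()
}

#' Write / read a cohort table as CSV
#'
#' @param table a `cohort_table`.
#' @param path CSV file path.
#' @return `path` (write) or the `cohort_table` (read).
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "gender", "side", "volume_ml", "area_mm2", "depth_mm")
  if (!all(need %in% names(t)))
    stop("cohort CSV must contain columns: ", paste(need, collapse = ", "))
  if (!"defect" %in% names(t)) t$defect <- "none"
  class(t) <- c("cohort_table", "data.frame")
  t
}
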