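#' Build a set of bilateral validation phantoms
#'
#' Draws a small defect-free cohort and voxelizes one phantom pair per
#' subject, mimicking the random selection of validation patients from a
#' screened cohort.
#'
#' @param n_subjects number of subjects (default 10).
#' @param voxel_spacing_mm phantom voxel spacing (mm).
#' @param rng_seed seed for the cohort draw.
#' @return List of subject entries, each `list(left = , right = )` holding
#'   [make_phantom()] results.
#' @export
validation_phantoms <- function(n_subjects = 10,
                                voxel_spacing_mm = c(0.5, 0.5, 0.5),
                                rng_seed = 1L) {
  nm <- ceiling(n_subjects / 2)
  params <- cohort_gen_params(n_male = nm, n_female = n_subjects - nm,
                              asymmetry_defect_rate = 0,
                              rng_seed = rng_seed)
  specs <- make_cohort(params, voxel_spacing_mm = voxel_spacing_mm)$specs
  lapply(specs, function(sp) list(left = make_phantom(sp$left),
                                  right = make_phantom(sp$right)))
}

#' Replay the multi-operator repeatability protocol
#'
#' Runs the full segmentation + morphometry pipeline `n_operators * n_runs`
#' times on each orbit of each subject (10 subjects x 2 sides x 6 operators
#' x 2 runs = 240 measurements at the defaults) and computes intraclass
#' correlation coefficients: `icc_intra` is the agreement of the two
#' consecutive runs across all subject-side-operator combinations and
#' `icc_inter` the agreement of the operators' (run-averaged) measurements
#' across orbits. With a deterministic pipeline both are exactly 1.
#'
#' Optional per-measurement volume jitter emulates operator-dependent
#' variation (e.g. manual interaction) and drives the ICCs below 1.
#'
#' @param phantoms output of [validation_phantoms()] (or a compatible list).
#' @param n_operators,n_runs protocol size.
#' @param config a [segmentation_config()].
#' @param operator_jitter_sd_ml SD (mL) of independent per-measurement
#'   jitter; 0 (default) leaves the pipeline deterministic.
#' @param jitter_seed seed for the jitter draws.
#' @param icc_form ICC form passed to [icc()].
#' @return An object of class `validation_result` with `icc_intra`,
#'   `icc_inter`, the per-side ICCs and the full measurement array
#'   (subject-side x operator x run).
#' @export
validation_harness <- function(phantoms, n_operators = 6L, n_runs = 2L,
                               config = segmentation_config(),
                               operator_jitter_sd_ml = 0,
                               jitter_seed = 1L,
                               icc_form = "agreement") {
  if (n_runs < 2) stop("intra-operator ICC undefined for n_runs < 2")
  if (n_operators < 2) stop("inter-operator ICC undefined for < 2 operators")
  sides <- c("left", "right")
  n_sub <- length(phantoms)
  meas <- array(NA_real_, c(n_sub * 2, n_operators, n_runs),
                dimnames = list(
                  paste(rep(seq_len(n_sub), each = 2), rep(sides, n_sub),
                        sep = "_"), NULL, NULL))
  for (s in seq_len(n_sub)) {
    for (d in 1:2) {
      ph <- phantoms[[s]][[sides[d]]]
      for (o in seq_len(n_operators)) {
        for (r in seq_len(n_runs)) {
          m <- measure_orbit(ph$volume, ph$truth$seed_voxel, config,
                             side = sides[d])
          meas[(s - 1) * 2 + d, o, r] <- m$volume_ml
        }
      }
    }
  }
  if (operator_jitter_sd_ml > 0) {
    jit <- with_seed(jitter_seed,
                     array(rnorm(length(meas), 0, operator_jitter_sd_ml),
                           dim(meas)))
    meas <- meas + jit
  }
  # intra: rows = orbit x operator, columns = consecutive runs
  intra_mat <- matrix(aperm(meas, c(2, 1, 3)), ncol = n_runs)
  icc_intra <- icc(intra_mat, icc_form)
  # inter: rows = orbits, columns = operators (run-averaged)
  inter_mat <- apply(meas, c(1, 2), mean)
  icc_inter <- icc(inter_mat, icc_form)
  side_idx <- rep(1:2, n_sub)
  per_side <- lapply(1:2, function(d) {
    sel <- side_idx == d
    list(icc_intra = icc(matrix(aperm(meas[sel, , , drop = FALSE],
                                      c(2, 1, 3)), ncol = n_runs),
                         icc_form),
         icc_inter = icc(apply(meas[sel, , , drop = FALSE], c(1, 2), mean),
                         icc_form))
  })
  names(per_side) <- sides
  structure(list(icc_intra = icc_intra, icc_inter = icc_inter,
                 per_side = per_side, measurements = meas,
                 n_measurements = length(meas)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result> ", x$n_measurements, " measurements\n", sep = "")
  cat("  ICC intra-operator: ", format(x$icc_intra, digits = 10), "\n",
      "  ICC inter-operator: ", format(x$icc_inter, digits = 10), "\n",
      sep = "")
  invisible(x)
}
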