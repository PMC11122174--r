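test_that("phantom truths match closed forms", {
  # hemisphere: V = (2/3) pi r^3
  sp <- phantom_spec("hemisphere", aperture_radius_mm = 20)
  ph <- make_phantom(sp)
  expect_equal(ph$truth$volume_ml, 2 / 3 * pi * 20^3 / 1000, tolerance = 1e-10)
  expect_equal(ph$truth$volume_ml, 16.755, tolerance = 1e-4)
  expect_equal(ph$truth$depth_mm, 20)
  expect_equal(ph$truth$area_lateral_mm2, 2 * pi * 400, tolerance = 1e-10)

  # cone: V = (1/3) pi a^2 h
  spc <- phantom_spec("cone", depth_mm = 40, aperture_radius_mm = 20)
  phc <- make_phantom(spc)
  expect_equal(phc$truth$volume_ml, pi * 400 * 40 / 3 / 1000,
               tolerance = 1e-10)
  expect_equal(phc$truth$volume_ml, 16.755, tolerance = 1e-4)
  expect_equal(phc$truth$depth_mm, 40)

  # paraboloid lateral area against numeric surface-of-revolution integral
  spp <- phantom_spec("paraboloid", depth_mm = 38, aperture_radius_mm = 21)
  php <- make_phantom(spp)
  a <- 21; h <- 38
  num <- integrate(function(r) 2 * pi * r * sqrt(1 + (2 * h * r / a^2)^2),
                   0, a, rel.tol = 1e-10)$value
  expect_equal(php$truth$area_lateral_mm2, num, tolerance = 1e-8)
  expect_equal(php$truth$volume_ml, pi * a^2 * h / 2 / 1000,
               tolerance = 1e-10)
})

test_that("voxelized cavity volume converges to the closed form", {
  for (fam in c("hemisphere", "cone", "paraboloid")) {
    errs <- sapply(c(1.0, 0.5), function(vx) {
      sp <- phantom_spec(fam, depth_mm = 35, aperture_radius_mm = 18,
                         voxel_spacing_mm = rep(vx, 3))
      ph <- make_phantom(sp)
      vox <- sum(ph$truth$cavity_mask) * vx^3 / 1000
      abs(vox - ph$truth$volume_ml) / ph$truth$volume_ml
    })
    expect_lt(errs[2], 0.02)      # < 2% at 0.5 mm
    expect_lt(errs[2], errs[1])   # refinement reduces the error
  }
})

test_that("an intact wall is a single 6-connected component", {
  sp <- phantom_spec("hemisphere", aperture_radius_mm = 15,
                     wall_gap_fraction = 0)
  ph <- make_phantom(sp)
  idx <- which(ph$truth$bone_mask) - 1L
  lab <- orbitometry:::cpp_components(as.integer(idx),
                                      dim(ph$truth$bone_mask), 6L)
  expect_equal(length(unique(lab)), 1L)
})

test_that("phantom generation is seed-reproducible", {
  sp <- phantom_spec("cone", depth_mm = 30, aperture_radius_mm = 15,
                     wall_gap_fraction = 0.05, rng_seed = 123)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$volume$values, b$volume$values)
  sp2 <- phantom_spec("cone", depth_mm = 30, aperture_radius_mm = 15,
                      wall_gap_fraction = 0.05, rng_seed = 124)
  expect_false(identical(make_phantom(sp2)$volume$values, a$volume$values))
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec("cone", depth_mm = -1), "depth")
  expect_error(phantom_spec("cone", wall_thickness_mm = 0.2,
                            voxel_spacing_mm = c(0.5, 0.5, 0.5)),
               "thinner than one voxel")
  expect_error(phantom_spec("cone", wall_gap_fraction = 1), "gap_fraction")
  expect_error(phantom_spec("cone",
                            material_hu = c(air = -1000, soft_tissue = 800,
                                            bone = 700)),
               "bone > soft_tissue > air")
  sp <- phantom_spec("hemisphere", aperture_radius_mm = 20)
  expect_error(make_phantom(sp, grid_dim = c(30, 30, 30)),
               "exceeds grid bounds")
})

test_that("defect injection records and reproduces the extra volume", {
  sp <- phantom_spec("paraboloid", depth_mm = 38, aperture_radius_mm = 21,
                     rng_seed = 2)
  ph <- make_phantom(sp)
  ident <- inject_defect(ph$volume, ph$truth, "none")
  expect_identical(ident$volume$values, ph$volume$values)

  spl <- phantom_spec("paraboloid", depth_mm = 38, aperture_radius_mm = 21,
                      defect = "lacrimal_channel", rng_seed = 2)
  phl <- make_phantom(spl)
  expect_equal(phl$truth$defect, "lacrimal_channel")
  # recorded extra volume is close to the constructed 0.6 mL pocket
  expect_gt(phl$truth$defect_extra_volume_ml, 0.5)
  expect_lt(phl$truth$defect_extra_volume_ml, 0.8)

  spf <- phantom_spec("paraboloid", depth_mm = 38, aperture_radius_mm = 21,
                      defect = "wall_fracture", rng_seed = 2)
  phf <- make_phantom(spf)
  expect_equal(phf$truth$defect, "wall_fracture")
  expect_gt(phf$truth$at_risk_volume_ml, 10)
})

test_that("cohort sample moments converge to the generator targets", {
  p <- cohort_gen_params(n_male = 5000, n_female = 5000, rng_seed = 7,
                         asymmetry_defect_rate = 0)
  t <- make_cohort(p)$table
  for (g in c("male", "female")) {
    gi <- if (g == "male") 1 else 2
    sub <- t[t$gender == g, ]
    expect_equal(mean(sub$depth_mm), p$depth_mean[[gi]], tolerance = 0.005)
    expect_equal(sd(sub$depth_mm), p$depth_sd[[gi]], tolerance = 0.03)
    expect_equal(mean(sub$volume_ml), p$volume_mean[[gi]],
                 tolerance = 0.005)
    expect_equal(mean(sub$area_mm2), p$area_mean[[gi]], tolerance = 0.005)
  }
})

test_that("cohort is seed-reproducible and empty for n = 0", {
  a <- make_cohort(cohort_gen_params(rng_seed = 5))
  b <- make_cohort(cohort_gen_params(rng_seed = 5))
  expect_identical(a$table, b$table)
  e <- make_cohort(cohort_gen_params(n_male = 0, n_female = 0))
  expect_equal(nrow(e$table), 0L)
  expect_length(e$specs, 0L)
})

test_that("emitted phantom specs match the drawn depth and volume", {
  co <- make_cohort(cohort_gen_params(n_male = 4, n_female = 4,
                                      asymmetry_defect_rate = 0,
                                      rng_seed = 9))
  for (i in seq_along(co$specs)) {
    for (s in c("left", "right")) {
      spec <- co$specs[[i]][[s]]
      row <- co$table[co$table$id == sprintf("S%03d", i) &
                        co$table$side == s, ]
      expect_equal(spec$depth_mm, row$depth_mm)
      # paraboloid closed form recovers the drawn volume
      expect_equal(pi * spec$aperture_radius_mm^2 * spec$depth_mm / 2 / 1000,
                   row$volume_ml, tolerance = 1e-10)
    }
  }
})

test_that("flagged subjects match the binomial defect expectation", {
  # defect rate 12/186 applied to 186 subjects: mean flagged close to 12
  fl <- sapply(1:60, function(s) {
    p <- cohort_gen_params(n_male = 95, n_female = 91, rng_seed = s)
    length(screen_asymmetry(make_cohort(p)$table)$flagged_ids)
  })
  expect_equal(mean(fl), 12, tolerance = 0.12)  # within ~1.5 subjects
})

test_that("generator recovers the area-volume R2 target", {
  p <- cohort_gen_params(n_male = 5000, n_female = 5000, rng_seed = 11,
                         asymmetry_defect_rate = 0,
                         r2_area_volume = c(male = 0.95, female = 0.95))
  t <- make_cohort(p)$table
  sub <- t[t$gender == "male" & t$side == "left", ]
  expect_equal(cor(sub$area_mm2, sub$volume_ml)^2, 0.95, tolerance = 0.03)
})
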