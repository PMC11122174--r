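# one enclosed voxel with an open top face: the minimal meshable cavity
single_voxel_cavity <- function() {
  dims <- c(5L, 5L, 5L)
  mask <- array(FALSE, dims)
  mask[3, 3, 3] <- TRUE
  bone <- array(FALSE, dims)
  bone[2:4, 2:4, 2:4] <- TRUE
  bone[3, 3, 3] <- FALSE
  bone[3, 3, 2] <- FALSE  # open one face (aperture at -z)
  cavity_from_mask(mask, bone)
}

test_that("a unit voxel decomposes into 6 tetrahedra of exact volume", {
  cav <- single_voxel_cavity()
  cl <- build_closures(cav)
  mesh <- tetrahedralize(cav, cl)
  expect_equal(nrow(mesh$tetrahedra), 6L)
  expect_equal(mesh_volume(mesh), 0.001, tolerance = 1e-12)
  expect_equal(mesh_area(mesh, surface = "voxel"), 6.0, tolerance = 1e-10)
  expect_equal(mesh_area(mesh, include_closures = FALSE,
                         surface = "voxel"), 5.0, tolerance = 1e-10)
})

test_that("an uncapped aperture refuses to mesh", {
  cav <- single_voxel_cavity()
  expect_error(tetrahedralize(cav, list()), "uncapped aperture")
})

hemi <- make_phantom(phantom_spec("hemisphere", aperture_radius_mm = 15,
                                  wall_gap_fraction = 0.05, rng_seed = 31))
hemi_parts <- local({
  v <- hemi$volume
  bone <- v$values >= select_bone_threshold(v)
  bridged <- bridge_gaps(bone, 1.5, v$spacing)
  cav <- grow_cavity(v, bridged, hemi$truth$seed_voxel,
                     bone_unbridged = bone)
  cl <- build_closures(cav)
  list(cav = cav, cl = cl, mesh = tetrahedralize(cav, cl))
})

test_that("the boundary is watertight with spherical topology", {
  # exact manifold sphere topology on the minimal cavity: a cube surface
  cav <- single_voxel_cavity()
  mesh1 <- tetrahedralize(cav, build_closures(cav))
  bt1 <- mesh1$boundary_triangles
  e1 <- rbind(bt1[, c(1, 2)], bt1[, c(2, 3)], bt1[, c(3, 1)])
  k1 <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  expect_true(all(table(k1) == 2))
  expect_equal(length(unique(as.vector(bt1))) - length(unique(k1)) +
                 nrow(bt1), 2L)

  # a digitized hemisphere: closed (every edge an even number of times,
  # nearly all manifold; staircase corners can touch along an edge) and
  # still of spherical Euler characteristic
  mesh <- hemi_parts$mesh
  bt <- mesh$boundary_triangles
  edges <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  expect_true(all(cnt %% 2 == 0))           # no naked edges: closed surface
  expect_gt(mean(cnt == 2), 0.999)          # manifold almost everywhere
  nv <- length(unique(as.vector(bt)))
  ne <- length(unique(key))
  nf <- nrow(bt)
  expect_equal(nv - ne + nf, 2L)
})

test_that("mesh volume is exact and matches the divergence oracle", {
  mesh <- hemi_parts$mesh
  vox <- mesh$voxel_count * prod(mesh$spacing) / 1000
  expect_equal(mesh_volume(mesh), vox, tolerance = 1e-12)
  expect_equal(mesh_volume(mesh), divergence_volume(mesh),
               tolerance = 1e-9)
})

test_that("smoothed area approximates the closed forms", {
  mesh <- hemi_parts$mesh
  expect_rel(mesh_area(mesh), 3 * pi * 15^2, 0.05)
  expect_rel(mesh_area(mesh, include_closures = FALSE), 2 * pi * 15^2, 0.05)
})

test_that("depth axis lands on the constructed posterior point", {
  labs <- vapply(hemi_parts$cl, function(x) x$label, "")
  ant <- hemi_parts$cl[[which(labs == "anterior")]]
  ax <- depth_axis(hemi_parts$mesh, ant)
  diag_tol <- sqrt(3) * 0.5
  expect_lt(abs(ax$length_mm - 15), diag_tol)
  expect_equal(sqrt(sum(ax$unit_direction^2)), 1, tolerance = 1e-12)
  # deterministic under reruns (ties broken lexicographically)
  ax2 <- depth_axis(hemi_parts$mesh, ant)
  expect_identical(ax$posterior_point, ax2$posterior_point)

  cone <- make_phantom(phantom_spec("cone", depth_mm = 40,
                                    aperture_radius_mm = 20,
                                    wall_gap_fraction = 0.05, rng_seed = 3))
  m <- measure_phantom(cone)
  expect_lt(abs(m$depth_mm - 40), diag_tol)
})

test_that("profile conserves volume for any bin count", {
  labs <- vapply(hemi_parts$cl, function(x) x$label, "")
  ant <- hemi_parts$cl[[which(labs == "anterior")]]
  ax <- depth_axis(hemi_parts$mesh, ant)
  for (nb in c(1L, 7L, 10L)) {
    pr <- volume_profile(hemi_parts$mesh, ax, nb)
    expect_length(pr$profile, nb)
    expect_equal(sum(pr$profile) + pr$excluded_anterior_ml,
                 mesh_volume(hemi_parts$mesh), tolerance = 1e-9)
  }
})

test_that("an axis-aligned cylinder gives 10 equal bins", {
  cyl <- cylinder_cavity(radius_mm = 10, length_mm = 30, vx = 0.5)
  cl <- build_closures(cyl$cavity)
  mesh <- tetrahedralize(cyl$cavity, cl)
  pr <- volume_profile(mesh, cyl$axis, 10L)
  expect_lt(diff(range(pr$profile)) / mean(pr$profile), 0.01)
  expect_equal(pr$excluded_anterior_ml, 0)
})

test_that("a cone profile increases anteriorly with cubic cumulative mass", {
  cone <- make_phantom(phantom_spec("cone", depth_mm = 40,
                                    aperture_radius_mm = 20,
                                    wall_gap_fraction = 0, rng_seed = 3))
  m <- measure_phantom(cone)
  expect_true(all(diff(m$profile) < 0))  # bin 1 (rim) largest, apex smallest
  cum_from_apex <- cumsum(rev(m$profile)) / sum(m$profile)
  expect_lt(max(abs(cum_from_apex - ((1:10) / 10)^3)), 0.02)
})

test_that("volume anterior to the axis origin is excluded", {
  cone <- make_phantom(phantom_spec("cone", depth_mm = 40,
                                    aperture_radius_mm = 20,
                                    wall_gap_fraction = 0, rng_seed = 3))
  v <- cone$volume
  bone <- v$values >= select_bone_threshold(v)
  bridged <- bridge_gaps(bone, 1.5, v$spacing)
  cav <- grow_cavity(v, bridged, cone$truth$seed_voxel,
                     bone_unbridged = bone)
  cl <- build_closures(cav)
  mesh <- tetrahedralize(cav, cl)
  labs <- vapply(cl, function(x) x$label, "")
  ant <- cl[[which(labs == "anterior")]]
  ax <- depth_axis(mesh, ant)
  # move the axis origin 5 mm into the cavity: the basal frustum is excluded
  shift <- 5
  ax$anterior_point <- ax$anterior_point + shift * ax$unit_direction
  ax$length_mm <- ax$length_mm - shift
  pr <- volume_profile(mesh, ax, 10L)
  a <- 20; h <- 40
  frustum <- pi * a^2 * h / 3 * (1 - (1 - shift / h)^3) / 1000
  expect_rel(pr$excluded_anterior_ml, frustum, 0.05)
  expect_equal(sum(pr$profile) + pr$excluded_anterior_ml,
               mesh_volume(mesh), tolerance = 1e-9)
})

test_that("metrics are invariant to origin translation and mirroring", {
  sp <- phantom_spec("paraboloid", depth_mm = 30, aperture_radius_mm = 16,
                     wall_gap_fraction = 0.05, rng_seed = 13)
  ph <- make_phantom(sp)
  m0 <- measure_phantom(ph)
  shifted <- image_volume(ph$volume$values, ph$volume$spacing,
                          ph$volume$origin + c(10, -5, 3.2))
  m1 <- measure_orbit(shifted, ph$truth$seed_voxel)
  expect_equal(m1$volume_ml, m0$volume_ml, tolerance = 1e-9)
  expect_equal(m1$area_mm2, m0$area_mm2, tolerance = 1e-8)
  expect_equal(m1$depth_mm, m0$depth_mm, tolerance = 1e-8)
  # bin assignment is discontinuous at bin edges, so a handful of
  # tetrahedra may flip bins under floating-point translation
  expect_equal(m1$profile, m0$profile, tolerance = 1e-3)

  mir_vals <- ph$volume$values[rev(seq_len(dim(ph$volume$values)[1])), , ]
  mir <- image_volume(mir_vals, ph$volume$spacing, ph$volume$origin)
  seed <- ph$truth$seed_voxel
  seed[1] <- dim(mir_vals)[1] - 1L - seed[1]
  m2 <- measure_orbit(mir, seed, side = "right")
  expect_equal(m2$volume_ml, m0$volume_ml, tolerance = 1e-6)
  expect_equal(m2$area_mm2, m0$area_mm2, tolerance = 1e-5)
  expect_equal(m2$depth_mm, m0$depth_mm, tolerance = 1e-6)
})

test_that("the lacrimal-channel defect inflates volume by the pocket", {
  spl <- phantom_spec("paraboloid", depth_mm = 38, aperture_radius_mm = 21,
                      wall_gap_fraction = 0.05,
                      defect = "lacrimal_channel", rng_seed = 4)
  phl <- make_phantom(spl)
  ml <- suppressWarnings(measure_phantom(phl))
  over <- ml$volume_ml - phl$truth$volume_ml
  expect_rel(over, phl$truth$defect_extra_volume_ml, 0.10)
  # the intact contralateral side differs by more than the screening rule
  spr <- phantom_spec("paraboloid", depth_mm = 38, aperture_radius_mm = 21,
                      wall_gap_fraction = 0.05, side = "right",
                      rng_seed = 4)
  mr <- measure_phantom(make_phantom(spr), side = "right")
  expect_gt(abs(ml$volume_ml - mr$volume_ml), 0.2)
})
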