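#' Phantom specification
#'
#' Describes a CT-like orbital phantom: a cavity of one of three closed-form
#' shape families filled with soft tissue, enclosed by a thin bone shell that
#' opens anteriorly through a planar circular aperture. A configurable
#' fraction of wall voxels can be knocked out to mimic the thin, partly
#' discontinuous bone lining of real orbital walls.
#'
#' The cavity axis runs along +z with the aperture plane anterior (low z) and
#' the apex posterior. For the `hemisphere` family the depth equals the
#' aperture radius and `depth_mm` is ignored.
#'
#' @param shape_family `"hemisphere"`, `"cone"` or `"paraboloid"`.
#' @param depth_mm cavity depth from aperture plane to apex (mm).
#' @param aperture_radius_mm radius of the anterior opening (mm).
#' @param wall_thickness_mm bone shell thickness (mm); at least one voxel.
#' @param wall_gap_fraction fraction in `[0, 1)` of wall voxels replaced by
#'   soft-tissue density (seeded, reproducible).
#' @param material_hu named numeric: HU for `air`, `soft_tissue`, `bone`.
#' @param voxel_spacing_mm voxel spacing (mm), length 3.
#' @param side `"left"` or `"right"`; the right side mirrors defect placement.
#' @param defect `"none"`, `"lacrimal_channel"` or `"wall_fracture"`
#'   (applied by [inject_defect()]).
#' @param rng_seed integer seed controlling wall-gap placement.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_family = c("hemisphere", "cone", "paraboloid"),
                         depth_mm = 40, aperture_radius_mm = 20,
                         wall_thickness_mm = 1.5, wall_gap_fraction = 0.05,
                         material_hu = c(air = -1000, soft_tissue = 40,
                                         bone = 700),
                         voxel_spacing_mm = c(0.5, 0.5, 0.5),
                         side = c("left", "right"),
                         defect = c("none", "lacrimal_channel",
                                    "wall_fracture"),
                         rng_seed = 1L) {
  shape_family <- match.arg(shape_family)
  side <- match.arg(side)
  defect <- match.arg(defect)
  voxel_spacing_mm <- rep_len(as.numeric(voxel_spacing_mm), 3L)
  if (shape_family == "hemisphere") depth_mm <- aperture_radius_mm
  if (depth_mm <= 0) stop("depth_mm must be positive")
  if (aperture_radius_mm <= 0) stop("aperture_radius_mm must be positive")
  if (wall_thickness_mm < max(voxel_spacing_mm))
    stop("wall thinner than one voxel")
  if (wall_gap_fraction < 0 || wall_gap_fraction >= 1)
    stop("wall_gap_fraction must be in [0, 1)")
  stopifnot(all(c("air", "soft_tissue", "bone") %in% names(material_hu)))
  if (!(material_hu["bone"] > material_hu["soft_tissue"] &&
        material_hu["soft_tissue"] > material_hu["air"]))
    stop("material HUs must satisfy bone > soft_tissue > air")
  structure(list(shape_family = shape_family, depth_mm = depth_mm,
                 aperture_radius_mm = aperture_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 wall_gap_fraction = wall_gap_fraction,
                 material_hu = material_hu,
                 voxel_spacing_mm = voxel_spacing_mm,
                 side = side, defect = defect,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$shape_family, ", depth ", signif(x$depth_mm, 4),
      " mm, aperture r ", signif(x$aperture_radius_mm, 4), " mm, ", x$side,
      if (x$defect != "none") paste0(", defect: ", x$defect), "\n", sep = "")
  invisible(x)
}

# closed-form cavity measures; area split into lateral wall and aperture cap
phantom_closed_forms <- function(spec) {
  a <- spec$aperture_radius_mm
  h <- spec$depth_mm
  switch(spec$shape_family,
    hemisphere = list(volume_mm3 = 2 / 3 * pi * a^3,
                      lateral_mm2 = 2 * pi * a^2,
                      cap_mm2 = pi * a^2,
                      depth_mm = a),
    cone = list(volume_mm3 = pi * a^2 * h / 3,
                lateral_mm2 = pi * a * sqrt(a^2 + h^2),
                cap_mm2 = pi * a^2,
                depth_mm = max(h, a)),
    paraboloid = list(volume_mm3 = pi * a^2 * h / 2,
                      lateral_mm2 = pi * a^4 / (6 * h^2) *
                        ((1 + 4 * h^2 / a^2)^1.5 - 1),
                      cap_mm2 = pi * a^2,
                      depth_mm = max(h, a)))
}

# squared radial profile of the cavity at axial offset u = z - z_aperture
cavity_rho2 <- function(spec, u) {
  a <- spec$aperture_radius_mm
  h <- spec$depth_mm
  out <- switch(spec$shape_family,
    hemisphere = a^2 - u^2,
    cone = (a * (1 - u / h))^2,
    paraboloid = a^2 * (1 - u / h))
  out[u < 0 | u > h] <- -1
  pmax(out, -1)
}

#' Generate a CT-like orbital phantom
#'
#' Builds an attenuation volume in which the cavity interior is soft tissue,
#' enclosed by a bone shell of the requested thickness with
#' `wall_gap_fraction` of its voxels replaced by soft-tissue density, opening
#' anteriorly through a planar circular aperture into air. The returned truth
#' carries the closed-form volume, surface area and depth, the aperture
#' centroid and apex in mm, plus the generator's voxel label masks and an
#' interior seed voxel for segmentation.
#'
#' @param spec a [phantom_spec()].
#' @param margin_mm air margin around the shell (mm).
#' @param grid_dim optional fixed grid dimensions; an error is raised if the
#'   cavity plus shell does not fit.
#' @return A list with elements `volume` ([image_volume]) and `truth`
#'   (`phantom_truth`).
#' @export
make_phantom <- function(spec, margin_mm = 3, grid_dim = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing_mm
  # defects need room beyond the shell (external pocket / soft-tissue slab)
  if (spec$defect == "lacrimal_channel")
    margin_mm <- max(margin_mm, 2 * (3 * 600 / (4 * pi))^(1 / 3) +
                       spec$wall_thickness_mm + 4)
  if (spec$defect == "wall_fracture")
    margin_mm <- max(margin_mm, 18 + spec$wall_thickness_mm)
  a <- spec$aperture_radius_mm
  h <- spec$depth_mm
  wall <- spec$wall_thickness_mm
  rmax <- switch(spec$shape_family, hemisphere = a, cone = a, paraboloid = a)
  ext_xy <- 2 * (rmax + wall + margin_mm)
  ext_z <- h + wall + 2 * margin_mm + wall
  need <- as.integer(ceiling(c(ext_xy, ext_xy, ext_z) / sp))
  if (is.null(grid_dim)) {
    dims <- need
  } else {
    dims <- as.integer(grid_dim)
    if (any(dims < need))
      stop("cavity (with wall and margin) exceeds grid bounds")
  }
  origin <- c(0, 0, 0)
  cx <- origin[1] + dims[1] * sp[1] / 2
  cy <- origin[2] + dims[2] * sp[2] / 2
  za <- origin[3] + margin_mm + wall   # aperture plane z (mm)

  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * sp[1] - cx
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * sp[2] - cy
  zs <- origin[3] + (seq_len(dims[3]) - 0.5) * sp[3] - za
  rho2 <- outer(xs^2, ys^2, `+`)
  cavity <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    r2 <- cavity_rho2(spec, zs[k])
    if (r2 >= 0) cavity[, , k] <- rho2 <= r2
  }

  shell <- cpp_sqdist(as.logical(cavity), dims, sp) <= wall^2 + 1e-9
  shell <- array(shell, dims) & !cavity
  # open the anterior aperture: nothing anterior of the plane within the rim
  open_disk <- outer(seq_len(dims[1]), seq_len(dims[2]),
                     function(i, j) rho2[cbind(i, j)] <= a^2)
  for (k in seq_len(dims[3])) {
    if (zs[k] < 0) shell[, , k][open_disk] <- FALSE
  }

  hu <- array(spec$material_hu[["air"]], dims)
  hu[shell] <- spec$material_hu[["bone"]]
  # knock out a random fraction of wall voxels (thin-bone dropout)
  gap_idx <- integer(0)
  if (spec$wall_gap_fraction > 0) {
    widx <- which(shell)
    ngap <- floor(spec$wall_gap_fraction * length(widx))
    if (ngap > 0)
      gap_idx <- with_seed(spec$rng_seed, sample(widx, ngap))
    hu[gap_idx] <- spec$material_hu[["soft_tissue"]]
  }
  hu[cavity] <- spec$material_hu[["soft_tissue"]]

  bone_labels <- shell
  bone_labels[gap_idx] <- FALSE

  cf <- phantom_closed_forms(spec)
  seed_k <- which.min(abs(zs - h / 2))
  seed_ijk <- c(which.min(abs(xs)), which.min(abs(ys)), seed_k) - 1L
  truth <- structure(list(
    volume_ml = cf$volume_mm3 / 1000,
    area_mm2 = cf$lateral_mm2 + cf$cap_mm2,
    area_lateral_mm2 = cf$lateral_mm2,
    area_cap_mm2 = cf$cap_mm2,
    depth_mm = cf$depth_mm,
    aperture_centroid = c(cx, cy, za),
    apex_point = c(cx, cy, za + h),
    defect = spec$defect,
    defect_extra_volume_ml = 0,
    side = spec$side,
    seed_voxel = seed_ijk,
    cavity_mask = cavity,
    bone_mask = bone_labels), class = "phantom_truth")
  vol <- image_volume(hu, spacing = sp, origin = origin)
  out <- list(volume = vol, truth = truth)
  if (spec$defect != "none")
    out <- inject_defect(vol, truth, spec$defect, side = spec$side)
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> V = ", signif(x$volume_ml, 5), " mL, A = ",
      signif(x$area_mm2, 5), " mm^2, depth = ", signif(x$depth_mm, 4),
      " mm, defect: ", x$defect, "\n", sep = "")
  invisible(x)
}

#' Inject a segmentation-defeating defect into a phantom
#'
#' `lacrimal_channel` carves a soft-tissue tunnel through the bone shell
#' connecting the cavity to an external soft-tissue pocket of known volume,
#' emulating a mucosally thickened lacrimal duct that gets swallowed by the
#' automated segmentation: downstream volume is overestimated by the
#' connected extra soft tissue (recorded exactly in
#' `truth$defect_extra_volume_ml`). `wall_fracture` removes a contiguous
#' wall patch and surrounds it with a large soft-tissue slab so that an
#' unguarded segmentation leaks; the slab volume is recorded as the at-risk
#' volume.
#'
#' @param volume phantom [image_volume].
#' @param truth matching `phantom_truth` (carries the label masks).
#' @param kind `"none"`, `"lacrimal_channel"` or `"wall_fracture"`.
#' @param channel_radius_mm tunnel radius (mm).
#' @param pocket_volume_ml external pocket volume (mL).
#' @param patch_area_mm2 fracture patch area (mm^2).
#' @param side phantom side; the defect sits on the lateral (+x for left,
#'   -x for right) wall at mid depth.
#' @return list with updated `volume` and `truth`.
#' @export
inject_defect <- function(volume, truth, kind = c("none", "lacrimal_channel",
                                                  "wall_fracture"),
                          channel_radius_mm = 1.5, pocket_volume_ml = 0.6,
                          patch_area_mm2 = 100,
                          side = truth$side %||% "left") {
  kind <- match.arg(kind)
  if (kind == "none") return(list(volume = volume, truth = truth))
  sp <- volume$spacing
  dims <- dim(volume$values)
  hu <- volume$values
  soft <- max(hu[truth$cavity_mask])
  sgn <- if (side == "left") 1 else -1

  ctr <- truth$aperture_centroid
  zmid <- ctr[3] + 0.5 * (truth$apex_point[3] - ctr[3])
  # outermost cavity x at mid depth, on the defect side
  kmid <- max(1L, min(dims[3], round((zmid - volume$origin[3]) / sp[3] + 0.5)))
  slab <- truth$cavity_mask[, , kmid]
  if (!any(slab)) stop("defect plane does not intersect the cavity")
  jmid <- max(1L, min(dims[2], round((ctr[2] - volume$origin[2]) / sp[2] + 0.5)))
  row <- which(slab[, jmid])
  if (!length(row)) stop("defect plane does not intersect the cavity")
  iedge <- if (sgn > 0) max(row) else min(row)
  x0 <- volume$origin[1] + (iedge - 0.5) * sp[1]
  p0 <- c(x0, ctr[2], zmid)
  wall_mm <- 3 * max(sp)

  xs <- volume$origin[1] + (seq_len(dims[1]) - 0.5) * sp[1]
  ys <- volume$origin[2] + (seq_len(dims[2]) - 0.5) * sp[2]
  zs <- volume$origin[3] + (seq_len(dims[3]) - 0.5) * sp[3]

  if (kind == "lacrimal_channel") {
    rp <- (3 * pocket_volume_ml * 1000 / (4 * pi))^(1 / 3)
    pc <- p0 + sgn * c(truth_wall_estimate(truth, sp) + rp + 1, 0, 0)
    if ((pc[1] + rp) > max(xs) || (pc[1] - rp) < min(xs))
      stop("defect pocket does not fit inside the grid")
    carve <- array(FALSE, dims)
    # tunnel: cylinder along x from cavity edge to the pocket center
    xlo <- min(p0[1], pc[1]); xhi <- max(p0[1], pc[1])
    ii <- which(xs >= xlo - sp[1] & xs <= xhi + sp[1])
    d2yz <- outer((ys - p0[2])^2, (zs - p0[3])^2, `+`)
    tube <- d2yz <= channel_radius_mm^2
    for (i in ii) carve[i, , ] <- carve[i, , ] | tube
    # pocket sphere
    for (k in which(abs(zs - pc[3]) <= rp)) {
      r2 <- rp^2 - (zs[k] - pc[3])^2
      carve[, , k] <- carve[, , k] |
        (outer((xs - pc[1])^2, (ys - pc[2])^2, `+`) <= r2)
    }
    if (!any(carve & truth$bone_mask))
      stop("defect does not intersect the bone wall")
    hu[carve] <- soft
    truth$bone_mask[carve] <- FALSE
    extra <- carve & !truth$cavity_mask
    truth$defect_extra_volume_ml <- sum(extra) * prod(sp) / 1000
    truth$defect <- "lacrimal_channel"
  } else { # wall_fracture
    rf <- sqrt(patch_area_mm2 / pi)
    d2 <- outer((xs - p0[1])^2, (ys - p0[2])^2, `+`)
    patch <- array(FALSE, dims)
    for (k in which(abs(zs - p0[3]) <= rf + wall_mm)) {
      patch[, , k] <- d2 + (zs[k] - p0[3])^2 <= (rf + wall_mm)^2
    }
    hit <- patch & truth$bone_mask
    if (!any(hit)) stop("defect does not intersect the bone wall")
    hu[hit] <- soft
    truth$bone_mask[hit] <- FALSE
    # embed everything behind the aperture plane in soft tissue: through the
    # fracture the cavity now leaks into an effectively unbounded surround
    za <- truth$aperture_centroid[3]
    ext <- array(FALSE, dims)
    ext[, , zs >= za] <- TRUE
    ext <- ext & !truth$cavity_mask & !truth$bone_mask
    hu[ext] <- soft
    truth$at_risk_volume_ml <- sum(ext) * prod(sp) / 1000
    truth$defect <- "wall_fracture"
  }
  list(volume = image_volume(hu, spacing = sp, origin = volume$origin,
                             orientation = volume$orientation),
       truth = truth)
}

# crude shell thickness estimate (mm) used to place defects beyond the wall
truth_wall_estimate <- function(truth, sp) {
  3 * max(sp)
}
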