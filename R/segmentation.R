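#' Segmentation configuration
#'
#' Tunable parameters of the automated cavity segmentation.
#'
#' @param hu_threshold bone threshold in HU, or `"auto"` to derive it from
#'   the image histogram with [select_bone_threshold()].
#' @param gap_bridge_radius_mm radius (mm) of the ball structuring element
#'   used to close gaps in the thin bone walls; 0 disables bridging.
#' @param max_iterations upper bound on front-propagation iterations.
#' @param leak_guard_factor growth in one iteration exceeding this multiple
#'   of the median of all previous per-iteration increments aborts the
#'   segmentation with a leak error (must be > 1).
#' @param leak_warmup_iterations iterations before the leak guard arms.
#' @param posterior_cap_area_max_mm2 apertures with cap area at or below this
#'   bound are labeled posterior; the largest aperture is always anterior.
#' @param air_hu_cutoff voxels at or below this HU are treated as air: they
#'   are excluded from the histogram used for automatic thresholding and the
#'   growing front never enters them (open air outside the anterior rim
#'   stops the front).
#' @param seed_ball_radius_mm radius of the initial seed ball (mm).
#' @param reclaim_min_voxels minimum 6-connected component size (voxels) for
#'   the post-growth reclaim of tissue swallowed by gap bridging; isolated
#'   wall-dropout voxels stay excluded.
#' @param max_volume_ml plausibility ceiling on the grown cavity volume
#'   (mL); exceeding it raises a leak error. Adult orbital volumes stay
#'   below about 40 mL, so the default 60 mL only trips when the front has
#'   escaped the orbit. This complements the median-based spike rule, which
#'   cannot see a leak whose front grows gradually.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(hu_threshold = "auto",
                                gap_bridge_radius_mm = 1.5,
                                max_iterations = 1000L,
                                leak_guard_factor = 5,
                                leak_warmup_iterations = 10L,
                                posterior_cap_area_max_mm2 = 300,
                                air_hu_cutoff = -200,
                                seed_ball_radius_mm = 2,
                                reclaim_min_voxels = 8L,
                                max_volume_ml = 60) {
  if (!identical(hu_threshold, "auto") && !is.numeric(hu_threshold))
    stop("hu_threshold must be a number or \"auto\"")
  if (gap_bridge_radius_mm < 0) stop("gap_bridge_radius_mm must be >= 0")
  if (leak_guard_factor <= 1) stop("leak_guard_factor must be > 1")
  structure(list(hu_threshold = hu_threshold,
                 gap_bridge_radius_mm = gap_bridge_radius_mm,
                 max_iterations = as.integer(max_iterations),
                 leak_guard_factor = leak_guard_factor,
                 leak_warmup_iterations = as.integer(leak_warmup_iterations),
                 posterior_cap_area_max_mm2 = posterior_cap_area_max_mm2,
                 air_hu_cutoff = air_hu_cutoff,
                 seed_ball_radius_mm = seed_ball_radius_mm,
                 reclaim_min_voxels = as.integer(reclaim_min_voxels),
                 max_volume_ml = max_volume_ml),
            class = "segmentation_config")
}

#' Automatic bone threshold
#'
#' Derives the HU cut separating soft tissue from bone by Otsu's criterion
#' (maximum between-class variance) over the integer-rounded histogram of
#' voxels above the air cutoff. Deterministic for a fixed input; ties are
#' broken toward the lowest maximizing cut.
#'
#' @param volume an [image_volume].
#' @param air_hu_cutoff voxels at or below this HU are ignored.
#' @return Threshold in HU; voxels with values `>=` the threshold are bone.
#' @export
select_bone_threshold <- function(volume, air_hu_cutoff = -200) {
  v <- round(volume$values[volume$values > air_hu_cutoff])
  if (!length(v)) stop("no voxels above the air cutoff")
  tab <- table(v)
  u <- as.numeric(names(tab))
  n <- as.numeric(tab)
  if (length(u) < 2)
    stop("image histogram is constant above the air cutoff; no threshold")
  w <- cumsum(n)
  m <- cumsum(n * u)
  ntot <- w[length(w)]
  mtot <- m[length(m)]
  # cut after value u[i]: class 0 = values <= u[i]
  i <- seq_len(length(u) - 1L)
  w0 <- w[i] / ntot
  mu0 <- m[i] / w[i]
  mu1 <- (mtot - m[i]) / (ntot - w[i])
  sb <- w0 * (1 - w0) * (mu0 - mu1)^2
  best <- which.max(sb)
  (u[best] + u[best + 1L]) / 2
}

#' Bridge gaps in a thin bone mask
#'
#' Morphological closing (dilation followed by erosion) of the bone mask
#' with a ball structuring element of the given physical radius, sealing
#' dropouts where thin orbital walls fall below CT resolution. The result
#' always contains the input mask; radius 0 is the identity.
#'
#' @param bone_mask logical 3-D array.
#' @param radius_mm physical closing radius (mm).
#' @param spacing voxel spacing (mm), length 3.
#' @return Logical array of the same dimensions.
#' @export
bridge_gaps <- function(bone_mask, radius_mm, spacing) {
  stopifnot(length(dim(bone_mask)) == 3L)
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  if (radius_mm == 0 || !any(bone_mask)) return(bone_mask)
  dims <- dim(bone_mask)
  r2 <- radius_mm^2 + 1e-9
  # exact Euclidean closing: dilate = within radius of bone, erode = farther
  # than radius from the dilation's complement
  dil <- cpp_sqdist(as.logical(bone_mask), dims, spacing) <= r2
  out <- array(cpp_sqdist(!dil, dims, spacing) > r2, dims)
  out | bone_mask
}

#' Grow the orbital cavity from an interior seed
#'
#' Iterative front propagation (one 6-connected voxel layer per iteration)
#' from a small seed ball, restricted to non-air voxels and blocked by the
#' (bridged) bone mask. A leak guard aborts when the front, after an initial
#' warm-up, suddenly adds far more voxels than its running median increment
#' (a sign that the cavity is escaping through a wall opening into
#' surrounding tissue).
#'
#' Closing a thin wall around an acute cavity apex inevitably swallows a few
#' voxels of cavity tissue where the cavity is narrower than the structuring
#' ball. When the unbridged bone mask is supplied via `bone_unbridged`, a
#' reclaim pass therefore returns coherent pockets of
#' bridged-but-not-bone tissue voxels (6-connected components of at least
#' `reclaim_min_voxels` voxels touching the cavity) to the cavity after the
#' primary growth. Isolated wall-dropout voxels are not reclaimed, and
#' escape routes through genuine wall gaps stay sealed: everything beyond
#' the bridged shell is out of reach of the reclaim.
#'
#' @param volume an [image_volume].
#' @param bone logical bone mask aligned to `volume` (typically the bridged
#'   mask from [bridge_gaps()]).
#' @param seed 0-based voxel index triplet inside the cavity.
#' @param config a [segmentation_config()].
#' @param bone_unbridged optional unbridged (thresholded) bone mask enabling
#'   the reclaim pass.
#' @return An object of class `cavity_segment`: the cavity `mask`, the seed,
#'   per-iteration growth counts, and the labeled boundary faces (bone
#'   versus aperture, apertures grouped into connected components).
#' @export
grow_cavity <- function(volume, bone, seed, config = segmentation_config(),
                        bone_unbridged = NULL) {
  dims <- dim(volume$values)
  stopifnot(identical(dim(bone), dims), length(seed) == 3L)
  seed <- as.integer(seed)
  if (any(seed < 0L) || any(seed >= dims))
    stop("seed voxel outside the grid")
  if (bone[seed[1] + 1L, seed[2] + 1L, seed[3] + 1L])
    stop("seed voxel lies in bone")
  allowed <- !bone & volume$values > config$air_hu_cutoff
  if (!allowed[seed[1] + 1L, seed[2] + 1L, seed[3] + 1L])
    stop("seed voxel lies in air")
  off <- ball_offsets(config$seed_ball_radius_mm, volume$spacing)
  si <- sweep(off, 2, seed, `+`)
  keep <- si[, 1] >= 0 & si[, 1] < dims[1] & si[, 2] >= 0 &
    si[, 2] < dims[2] & si[, 3] >= 0 & si[, 3] < dims[3]
  si <- si[keep, , drop = FALSE]
  seeds <- linear_index(si[, 1], si[, 2], si[, 3], dims)
  max_vox <- config$max_volume_ml * 1000 / prod(volume$spacing)
  res <- cpp_region_grow(as.logical(allowed), dims, as.integer(seeds),
                         config$max_iterations, config$leak_guard_factor,
                         config$leak_warmup_iterations, max_vox)
  if (res$leak)
    stop("leak detected at iteration ", res$iterations,
         ": cavity growth escaped its bounds (spike above ",
         config$leak_guard_factor, "x median increment or volume beyond ",
         config$max_volume_ml, " mL)")
  if (res$exhausted)
    stop("segmentation did not terminate within ", config$max_iterations,
         " iterations")
  mask <- array(res$mask, dims)
  bone_eff <- bone
  if (!is.null(bone_unbridged)) {
    reclaimable <- bone & !bone_unbridged & !mask &
      volume$values > config$air_hu_cutoff
    if (any(reclaimable)) {
      ridx <- which(reclaimable)
      comp <- cpp_components(as.integer(ridx - 1L), dims, 6L)
      # a component is reclaimed only if it is a coherent pocket (not an
      # isolated wall-dropout voxel) and touches the grown cavity
      nb6 <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0,
                      0, 0, 1, 0, 0, -1, 0, 0, 0), ncol = 3, byrow = TRUE)
      storage.mode(nb6) <- "integer"
      touch <- array(cpp_morph(as.logical(mask), dims, nb6, TRUE),
                     dims)[ridx]
      size_ok <- table(comp)
      keep_comp <- as.integer(names(size_ok))[
        size_ok >= config$reclaim_min_voxels]
      keep_comp <- intersect(keep_comp, unique(comp[touch]))
      if (length(keep_comp)) mask[ridx[comp %in% keep_comp]] <- TRUE
    }
    # boundary labels against the bone actually bounding the final cavity
    bone_eff <- bone & !mask
  }
  faces <- boundary_faces(mask, bone_eff, dims)
  structure(list(mask = mask, seed_point = seed, faces = faces,
                 growth = res$added, iterations = res$iterations,
                 spacing = volume$spacing, origin = volume$origin),
            class = "cavity_segment")
}

#' @export
print.cavity_segment <- function(x, ...) {
  vol <- sum(x$mask) * prod(x$spacing) / 1000
  nap <- length(unique(x$faces$component[x$faces$label == "aperture"]))
  cat("<cavity_segment> ", sum(x$mask), " voxels (", signif(vol, 5),
      " mL), ", x$iterations, " iterations, ", nap,
      " aperture component(s)\n", sep = "")
  invisible(x)
}

# Boundary faces of the cavity mask: one row per voxel face between a cavity
# voxel and a non-cavity voxel (or the grid edge). `label` is "bone" when the
# outside voxel is bone, else "aperture"; aperture faces are grouped into
# 26-connected components over their owner voxels.
boundary_faces <- function(mask, bone, dims) {
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  owner <- integer(0); dir <- integer(0); is_bone <- logical(0)
  idx_arr <- array(seq_len(prod(dims)), dims)
  for (d in seq_along(shifts)) {
    s <- shifts[[d]]
    # neighbor of voxel v in direction s
    nb_mask <- array(FALSE, dims)   # neighbor is cavity?
    nb_bone <- array(FALSE, dims)
    src <- lapply(1:3, function(ax) {
      r <- seq_len(dims[ax]) + s[ax]
      r[r < 1 | r > dims[ax]] <- NA
      r
    })
    ok <- !is.na(src[[1]]) & TRUE
    # build index grids lazily via array subsetting with clamped ranges
    rx <- src[[1]]; ry <- src[[2]]; rz <- src[[3]]
    vx <- which(!is.na(rx)); vy <- which(!is.na(ry)); vz <- which(!is.na(rz))
    nb_mask[vx, vy, vz] <- mask[rx[vx], ry[vy], rz[vz]]
    nb_bone[vx, vy, vz] <- bone[rx[vx], ry[vy], rz[vz]]
    sel <- mask & !nb_mask
    w <- which(sel)
    owner <- c(owner, w)
    dir <- c(dir, rep.int(d, length(w)))
    is_bone <- c(is_bone, nb_bone[w])
  }
  faces <- data.frame(owner = owner - 1L, dir = dir,
                      label = ifelse(is_bone, "bone", "aperture"),
                      component = NA_integer_,
                      stringsAsFactors = FALSE)
  ap <- faces$label == "aperture"
  if (any(ap)) {
    ow <- faces$owner[ap]
    uo <- sort(unique(ow))
    lab <- cpp_components(as.integer(uo), as.integer(dims))
    faces$component[ap] <- lab[match(ow, uo)]
  }
  faces
}

#' Construct planar closure caps over cavity apertures
#'
#' Every aperture component (a connected patch of cavity boundary not backed
#' by bone) receives a planar cap: a least-squares plane is fitted to the
#' face centers, the aperture faces are projected onto that plane and kept as
#' the cap triangulation. The largest-area cap is labeled `anterior`; all
#' remaining caps are `posterior` (a warning is issued if one exceeds
#' `posterior_cap_area_max_mm2`). The cap centroid is the area-weighted
#' centroid of its triangles (the "mid-point" anchoring the depth axis).
#'
#' @param cavity a [grow_cavity()] result.
#' @param bone bridged bone mask (unused placement context, kept for
#'   interface symmetry).
#' @param config a [segmentation_config()].
#' @return List of `closure_surface` objects (empty for a sealed cavity).
#' @export
build_closures <- function(cavity, bone = NULL,
                           config = segmentation_config()) {
  stopifnot(inherits(cavity, "cavity_segment"))
  faces <- cavity$faces
  ap <- faces[faces$label == "aperture", , drop = FALSE]
  if (!nrow(ap)) return(list())
  comps <- sort(unique(ap$component))
  sp <- cavity$spacing
  caps <- lapply(comps, function(cid) {
    f <- ap[ap$component == cid, , drop = FALSE]
    tri <- face_triangles(f, sp, cavity$origin, dim(cavity$mask))
    ctrs <- face_centers(f, sp, cavity$origin, dim(cavity$mask))
    # least-squares plane through face centers
    mu <- colMeans(ctrs)
    cc <- sweep(ctrs, 2, mu)
    normal <- if (nrow(ctrs) >= 3) {
      svd(cc, nu = 0, nv = 3)$v[, 3]
    } else {
      dirv <- face_normal_dir(f$dir[1])
      dirv / sqrt(sum(dirv^2))
    }
    planarity <- if (nrow(ctrs) >= 3) max(abs(cc %*% normal)) else 0
    if (planarity > 3 * max(sp))
      warning("aperture loop deviates from planarity by ",
              signif(planarity, 3), " mm; cap built on best-fit plane")
    ptri <- project_triangles(tri, mu, normal)
    areas <- triangle_areas(ptri)
    area <- sum(areas)
    cen <- c(sum(areas * (ptri[, 1] + ptri[, 4] + ptri[, 7]) / 3),
             sum(areas * (ptri[, 2] + ptri[, 5] + ptri[, 8]) / 3),
             sum(areas * (ptri[, 3] + ptri[, 6] + ptri[, 9]) / 3)) / area
    structure(list(label = NA_character_, triangles = ptri,
                   centroid = cen, area_mm2 = area, normal = normal,
                   plane_point = mu, component = cid),
              class = "closure_surface")
  })
  areas <- vapply(caps, function(cp) cp$area_mm2, 0)
  anterior <- which.max(areas)
  for (i in seq_along(caps)) {
    if (i == anterior) {
      caps[[i]]$label <- "anterior"
    } else {
      caps[[i]]$label <- "posterior"
      if (areas[i] > config$posterior_cap_area_max_mm2)
        warning("posterior cap of ", signif(areas[i], 4),
                " mm^2 exceeds posterior_cap_area_max_mm2")
    }
  }
  caps
}

#' @export
print.closure_surface <- function(x, ...) {
  cat("<closure_surface> ", x$label, ", area ", signif(x$area_mm2, 5),
      " mm^2, centroid (", paste(signif(x$centroid, 5), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

face_normal_dir <- function(d) {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))[d, ]
}

# physical centers of voxel faces (owner 0-based linear index, dir 1..6)
face_centers <- function(faces, spacing, origin, dims) {
  ijk <- index_triplet(faces$owner, dims)
  ctr <- voxel_center_mm(ijk, spacing, origin)
  nrm <- t(vapply(faces$dir, face_normal_dir, numeric(3)))
  ctr + 0.5 * nrm * matrix(spacing, nrow(ctr), 3, byrow = TRUE)
}

# two triangles (outward-oriented) per voxel face, n x 9 mm coordinates
face_triangles <- function(faces, spacing, origin, dims) {
  ijk <- index_triplet(faces$owner, dims)
  n <- nrow(ijk)
  tri <- matrix(0, 2 * n, 9)
  # quad corners in cyclic order per direction, as corner offsets (0/1)
  quad_tab <- list(
    `1` = rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1)),
    `2` = rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0)),
    `3` = rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0)),
    `4` = rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)),
    `5` = rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)),
    `6` = rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0)))
  for (d in 1:6) {
    sel <- which(faces$dir == d)
    if (!length(sel)) next
    q <- quad_tab[[d]]
    corner <- lapply(1:4, function(c4) {
      sweep(sweep(ijk[sel, , drop = FALSE] + matrix(q[c4, ], length(sel), 3,
                                                    byrow = TRUE),
                  2, spacing, `*`), 2, origin, `+`)
    })
    tri[2 * sel - 1, ] <- cbind(corner[[1]], corner[[2]], corner[[3]])
    tri[2 * sel, ] <- cbind(corner[[1]], corner[[3]], corner[[4]])
  }
  tri
}

# orthogonal projection of n x 9 triangles onto the plane (point, normal)
project_triangles <- function(tri, point, normal) {
  out <- tri
  for (v in 0:2) {
    cols <- v * 3 + 1:3
    p <- tri[, cols, drop = FALSE]
    d <- (sweep(p, 2, point) %*% normal)[, 1]
    out[, cols] <- p - outer(d, normal)
  }
  out
}
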