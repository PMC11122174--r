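# 6-tetrahedron decomposition of the unit cube about the main diagonal
# (corner c has offsets (c&1, c>>1&1, c>>2&1); indices are 0-based corners).
TET_DECOMP <- rbind(c(0, 1, 3, 7), c(0, 3, 2, 7), c(0, 2, 6, 7),
                    c(0, 6, 4, 7), c(0, 4, 5, 7), c(0, 5, 1, 7))

#' Tetrahedralize a segmented cavity
#'
#' Decomposes every cavity voxel into six tetrahedra about the voxel's main
#' diagonal, giving a mesh whose total tetrahedron volume equals the voxel
#' volume exactly. Boundary faces are kept as outward-oriented triangles
#' labeled `bone`, `anterior_closure` or `posterior_closure` according to
#' what lies behind them; the mesh is watertight by construction and an
#' error is raised if an aperture has no matching closure cap.
#'
#' For surface-area measurement a smoothed boundary is extracted alongside:
#' the binary mask is Gaussian-smoothed and the 0.5 iso-surface is
#' triangulated by marching tetrahedra, removing the staircase bias of raw
#' voxel faces; its triangles are labeled by proximity to the closure planes.
#'
#' @param cavity a [grow_cavity()] result.
#' @param closures caps from [build_closures()].
#' @param smoothing_sigma_mm Gaussian sigma (mm) for the smoothed surface;
#'   `NULL` (default) uses one voxel (the largest spacing component).
#' @return An object of class `orbit_mesh` with `vertices` (mm), `tetrahedra`
#'   (vertex indices), `boundary_triangles` + `boundary_labels`, and a
#'   smoothed `surface` (`triangles` n x 9 mm, `labels`).
#' @export
tetrahedralize <- function(cavity, closures = list(),
                           smoothing_sigma_mm = NULL) {
  stopifnot(inherits(cavity, "cavity_segment"))
  if (is.null(smoothing_sigma_mm)) smoothing_sigma_mm <- max(cavity$spacing)
  mask <- cavity$mask
  dims <- dim(mask)
  if (!any(mask)) stop("empty cavity")
  sp <- cavity$spacing
  org <- cavity$origin

  faces <- cavity$faces
  ap <- faces$label == "aperture"
  if (any(ap)) {
    covered <- vapply(closures, function(cp) cp$component, 0L)
    missing_comp <- setdiff(unique(faces$component[ap]), covered)
    if (length(missing_comp))
      stop("uncapped aperture: mesh would not be watertight")
    cap_label <- setNames(
      vapply(closures, function(cp) paste0(cp$label, "_closure"), ""),
      as.character(covered))
  }

  vox <- which(mask) - 1L
  ijk <- index_triplet(vox, dims)
  nxc <- dims[1] + 1L; nyc <- dims[2] + 1L
  corner_id <- function(di, dj, dk)
    (ijk[, 1] + di) + nxc * ((ijk[, 2] + dj) + nyc * (ijk[, 3] + dk))
  corners <- sapply(0:7, function(c8)
    corner_id(bitwAnd(c8, 1L), bitwAnd(bitwShiftR(c8, 1L), 1L),
              bitwAnd(bitwShiftR(c8, 2L), 1L)))
  if (is.null(dim(corners))) corners <- matrix(corners, nrow = 1)

  nv <- nrow(ijk)
  tets <- matrix(0, nv * 6, 4)
  for (t in 1:6) tets[seq_len(nv) + (t - 1) * nv, ] <-
    corners[, TET_DECOMP[t, ] + 1L, drop = FALSE]

  # boundary triangles as corner ids, outward orientation per face direction
  quad_tab <- list(
    rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1)),
    rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0)),
    rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0)),
    rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)),
    rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)),
    rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0)))
  fijk <- index_triplet(faces$owner, dims)
  btri <- matrix(0, 2 * nrow(faces), 3)
  for (d in 1:6) {
    sel <- which(faces$dir == d)
    if (!length(sel)) next
    q <- quad_tab[[d]]
    cid <- sapply(1:4, function(c4)
      (fijk[sel, 1] + q[c4, 1]) + nxc * ((fijk[sel, 2] + q[c4, 2]) +
                                           nyc * (fijk[sel, 3] + q[c4, 3])))
    if (is.null(dim(cid))) cid <- matrix(cid, nrow = 1)
    btri[2 * sel - 1, ] <- cid[, c(1, 2, 3)]
    btri[2 * sel, ] <- cid[, c(1, 3, 4)]
  }
  blab <- rep(faces$label, each = 2)
  if (any(ap)) {
    bcomp <- rep(faces$component, each = 2)
    apt <- blab == "aperture"
    blab[apt] <- cap_label[as.character(bcomp[apt])]
  }

  # dense lookup over the corner lattice is much faster than match()
  ncorn <- nxc * nyc * (dims[3] + 1L)
  lut <- integer(ncorn)
  lut[c(as.vector(tets), as.vector(btri)) + 1L] <- 1L
  uid <- which(lut == 1L) - 1L
  lut[uid + 1L] <- seq_along(uid)
  cijk <- cbind(uid %% nxc, (uid %/% nxc) %% nyc, uid %/% (nxc * nyc))
  vertices <- sweep(sweep(cijk, 2, sp, `*`), 2, org, `+`)
  tets <- matrix(lut[tets + 1L], ncol = 4)
  btri <- matrix(lut[btri + 1L], ncol = 3)

  surface <- smoothed_surface(mask, sp, org, closures, smoothing_sigma_mm)

  structure(list(vertices = vertices, tetrahedra = tets,
                 boundary_triangles = btri, boundary_labels = blab,
                 surface = surface, spacing = sp, origin = org,
                 voxel_count = nv), class = "orbit_mesh")
}

#' @export
print.orbit_mesh <- function(x, ...) {
  cat("<orbit_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$tetrahedra),
      " tetrahedra, ", nrow(x$boundary_triangles),
      " boundary triangles\n", sep = "")
  cat("  volume ", signif(mesh_volume(x), 6), " mL, smoothed area ",
      signif(mesh_area(x), 6), " mm^2\n", sep = "")
  invisible(x)
}

# Gaussian-smoothed 0.5 iso-surface of the cavity mask with triangle labels
smoothed_surface <- function(mask, sp, org, closures, sigma_mm) {
  dims <- dim(mask)
  field <- as.numeric(mask)
  if (sigma_mm > 0)
    field <- cpp_gauss3d(field, dims, sigma_mm / sp)
  tri <- cpp_marching_tets(field, dims, sp, org, 0.5)
  labels <- rep("bone", nrow(tri))
  if (nrow(tri) && length(closures)) {
    cen <- cbind((tri[, 1] + tri[, 4] + tri[, 7]) / 3,
                 (tri[, 2] + tri[, 5] + tri[, 8]) / 3,
                 (tri[, 3] + tri[, 6] + tri[, 9]) / 3)
    # unit normals, to keep wall triangles skimming the cap plane out of the cap
    e1 <- tri[, 4:6] - tri[, 1:3]
    e2 <- tri[, 7:9] - tri[, 1:3]
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nl <- sqrt(rowSums(nrm^2))
    nl[nl == 0] <- 1
    tol <- 1.2 * max(sp) + sigma_mm
    for (cp in closures) {
      d <- abs((sweep(cen, 2, cp$plane_point) %*% cp$normal)[, 1])
      radial <- sqrt(pmax(rowSums(sweep(cen, 2, cp$centroid)^2) - d^2, 0))
      rmax <- 0
      for (vv in 0:2) {
        p <- cp$triangles[, vv * 3 + 1:3, drop = FALSE]
        rmax <- max(rmax, sqrt(max(rowSums(sweep(p, 2, cp$centroid)^2))))
      }
      align <- abs((nrm %*% cp$normal)[, 1]) / nl
      sel <- d <= tol & radial <= rmax + 2 * max(sp) & align >= 0.5
      labels[sel] <- paste0(cp$label, "_closure")
    }
  }
  list(triangles = tri, labels = labels)
}

#' Mesh volume
#'
#' Sum of tetrahedron volumes, `sum(|det|)/6`, converted to mL
#' (1 mL = 1000 mm^3). For voxel-decomposed meshes this equals the voxel
#' count times the voxel volume exactly.
#'
#' @param mesh an [orbit_mesh].
#' @return Volume in mL.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "orbit_mesh"))
  if (!nrow(mesh$tetrahedra)) stop("empty mesh")
  v <- mesh$vertices
  t <- mesh$tetrahedra
  a <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  b <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  cc <- v[t[, 4], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(abs(det)) / 6 / 1000
}

#' Mesh surface area
#'
#' Sum of boundary triangle areas in mm^2. The default measures the
#' smoothed (marching-tetrahedra) surface, which removes the staircase bias
#' of raw voxel faces; `surface = "voxel"` measures the raw voxel boundary.
#' Closure caps are included by default.
#'
#' @param mesh an [orbit_mesh].
#' @param include_closures include the anterior/posterior closure caps?
#' @param surface `"smoothed"` or `"voxel"`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh, include_closures = TRUE,
                      surface = c("smoothed", "voxel")) {
  stopifnot(inherits(mesh, "orbit_mesh"))
  surface <- match.arg(surface)
  if (surface == "smoothed") {
    tri <- mesh$surface$triangles
    lab <- mesh$surface$labels
  } else {
    bt <- mesh$boundary_triangles
    if (!nrow(bt)) stop("empty boundary")
    v <- mesh$vertices
    tri <- cbind(v[bt[, 1], , drop = FALSE], v[bt[, 2], , drop = FALSE],
                 v[bt[, 3], , drop = FALSE])
    lab <- mesh$boundary_labels
  }
  if (!include_closures) {
    keep <- !grepl("_closure$", lab)
    tri <- tri[keep, , drop = FALSE]
  }
  if (!nrow(tri)) stop("empty boundary")
  sum(triangle_areas(tri))
}

#' Axial depth axis
#'
#' The depth axis runs from the mid-point (area-weighted centroid) of the
#' anterior closure cap to the posterior point of the orbital volume: the
#' mesh vertex farthest from that centroid. Distance ties are broken by
#' lexicographic vertex order, so the axis is deterministic.
#'
#' @param mesh an [orbit_mesh].
#' @param anterior the anterior `closure_surface`.
#' @return An object of class `depth_axis` with `anterior_point`,
#'   `posterior_point`, `unit_direction` and `length_mm`.
#' @export
depth_axis <- function(mesh, anterior) {
  stopifnot(inherits(mesh, "orbit_mesh"),
            inherits(anterior, "closure_surface"))
  a <- anterior$centroid
  v <- mesh$vertices
  d2 <- (v[, 1] - a[1])^2 + (v[, 2] - a[2])^2 + (v[, 3] - a[3])^2
  dmax <- max(d2)
  if (dmax <= 0) stop("degenerate mesh: all vertices coincide with anterior")
  cand <- which(d2 >= dmax - 1e-9)
  if (length(cand) > 1) {
    vv <- v[cand, , drop = FALSE]
    cand <- cand[order(vv[, 1], vv[, 2], vv[, 3])[1]]
  }
  p <- as.numeric(v[cand, ])
  len <- sqrt(sum((p - a)^2))
  structure(list(anterior_point = a, posterior_point = p,
                 unit_direction = (p - a) / len, length_mm = len),
            class = "depth_axis")
}

#' @export
print.depth_axis <- function(x, ...) {
  cat("<depth_axis> length ", signif(x$length_mm, 5), " mm\n", sep = "")
  invisible(x)
}

#' Depth-binned volume profile
#'
#' Projects every tetrahedron centroid onto the depth axis and accumulates
#' tetrahedron volumes into `n_bins` equal axial bins. The axial coordinate
#' `t` runs from 0 at the anterior closure mid-point to the axis length `L`
#' at the posterior point; bins are half-open `[k L/n, (k+1) L/n)` with the
#' last bin closed, so bin 1 abuts the anterior rim and the last bin holds
#' the apex. Volume projecting at `t < 0` (anterior to the closure
#' mid-point) is excluded from the profile and reported separately; the
#' profile plus the exclusion always sums to the mesh volume.
#'
#' @param mesh an [orbit_mesh].
#' @param axis a [depth_axis].
#' @param n_bins number of bins (default 10).
#' @return List with `profile` (mL per bin) and `excluded_anterior_ml`.
#' @export
volume_profile <- function(mesh, axis, n_bins = 10L) {
  stopifnot(inherits(mesh, "orbit_mesh"), inherits(axis, "depth_axis"),
            n_bins >= 1)
  v <- mesh$vertices
  t4 <- mesh$tetrahedra
  cen <- (v[t4[, 1], , drop = FALSE] + v[t4[, 2], , drop = FALSE] +
            v[t4[, 3], , drop = FALSE] + v[t4[, 4], , drop = FALSE]) / 4
  a <- v[t4[, 2], , drop = FALSE] - v[t4[, 1], , drop = FALSE]
  b <- v[t4[, 3], , drop = FALSE] - v[t4[, 1], , drop = FALSE]
  cc <- v[t4[, 4], , drop = FALSE] - v[t4[, 1], , drop = FALSE]
  volt <- abs(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
                a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
                a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6 / 1000
  tt <- (sweep(cen, 2, axis$anterior_point) %*% axis$unit_direction)[, 1]
  L <- axis$length_mm
  excl <- tt < 0
  bin <- pmin(floor(tt / (L / n_bins)) + 1L, n_bins)
  profile <- vapply(seq_len(n_bins), function(k)
    sum(volt[!excl & bin == k]), 0)
  list(profile = profile, excluded_anterior_ml = sum(volt[excl]))
}

#' Measure an orbital cavity end to end
#'
#' Runs the full automated pipeline on an attenuation volume: bone
#' thresholding (automatic unless fixed in the configuration), gap bridging,
#' bounded cavity growth from the seed, closure construction,
#' tetrahedralization and metric extraction.
#'
#' @param volume an [image_volume].
#' @param seed 0-based interior voxel triplet (phantoms carry one in their
#'   truth metadata; clinical volumes require a user-supplied seed).
#' @param config a [segmentation_config()].
#' @param side `"left"` or `"right"` carried through to the metrics.
#' @param n_bins profile bins.
#' @param include_closures include closure caps in the surface area?
#' @param smoothing_sigma_mm Gaussian sigma for the smoothed surface (mm);
#'   `NULL` uses one voxel.
#' @return An object of class `orbit_metrics`: `volume_ml`, `area_mm2`,
#'   `depth_mm`, `profile`, `excluded_anterior_ml`, `side`, plus the bone
#'   threshold and iteration count actually used.
#' @export
measure_orbit <- function(volume, seed, config = segmentation_config(),
                          side = "left", n_bins = 10L,
                          include_closures = TRUE,
                          smoothing_sigma_mm = NULL) {
  thr <- if (identical(config$hu_threshold, "auto"))
    select_bone_threshold(volume, config$air_hu_cutoff)
  else config$hu_threshold
  bone <- volume$values >= thr
  bridged <- bridge_gaps(bone, config$gap_bridge_radius_mm, volume$spacing)
  cavity <- grow_cavity(volume, bridged, seed, config, bone_unbridged = bone)
  closures <- build_closures(cavity, bridged, config)
  if (!length(closures))
    stop("sealed cavity: no aperture to anchor the depth axis")
  mesh <- tetrahedralize(cavity, closures, smoothing_sigma_mm)
  anterior <- closures[[which(vapply(closures, function(cp) cp$label, "")
                              == "anterior")]]
  axis <- depth_axis(mesh, anterior)
  prof <- volume_profile(mesh, axis, n_bins)
  structure(list(volume_ml = mesh_volume(mesh),
                 area_mm2 = mesh_area(mesh, include_closures),
                 depth_mm = axis$length_mm,
                 profile = prof$profile,
                 excluded_anterior_ml = prof$excluded_anterior_ml,
                 side = side, threshold_hu = thr,
                 iterations = cavity$iterations),
            class = "orbit_metrics")
}

#' @export
print.orbit_metrics <- function(x, ...) {
  cat("<orbit_metrics> (", x$side, ")\n", sep = "")
  cat("  volume: ", signif(x$volume_ml, 6), " mL\n", sep = "")
  cat("  surface area: ", signif(x$area_mm2, 6), " mm^2\n", sep = "")
  cat("  axial depth: ", signif(x$depth_mm, 5), " mm\n", sep = "")
  cat("  profile (anterior -> apex, mL): ",
      paste(signif(x$profile, 3), collapse = " "), "\n", sep = "")
  if (x$excluded_anterior_ml > 0)
    cat("  excluded anterior: ", signif(x$excluded_anterior_ml, 4),
        " mL\n", sep = "")
  invisible(x)
}
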