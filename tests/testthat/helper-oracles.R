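# Independent oracles and small builders shared across the test files.

# Exhaustive Otsu: brute-force search over every integer cut, maximizing
# between-class variance computed directly from the two groups.
otsu_exhaustive <- function(values, air_cutoff = -200) {
  v <- round(values[values > air_cutoff])
  u <- sort(unique(v))
  best <- -Inf
  best_i <- NA
  for (i in seq_len(length(u) - 1)) {
    lo <- v[v <= u[i]]
    hi <- v[v > u[i]]
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) {
      best <- sb
      best_i <- i
    }
  }
  (u[best_i] + u[best_i + 1]) / 2
}

# Divergence-theorem volume from the labeled boundary triangles (mL):
# V = (1/3) * sum over outward-oriented triangles of centroid . n * A
divergence_volume <- function(mesh) {
  v <- mesh$vertices
  bt <- mesh$boundary_triangles
  p1 <- v[bt[, 1], , drop = FALSE]
  p2 <- v[bt[, 2], , drop = FALSE]
  p3 <- v[bt[, 3], , drop = FALSE]
  a <- p2 - p1
  b <- p3 - p1
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2 * area * outward normal
  cen <- (p1 + p2 + p3) / 3
  sum(rowSums(cen * cr)) / 6 / 1000
}

# ICC(A,1) via R's own ANOVA decomposition (two-way, no replication)
icc_aov <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(y = as.vector(m), s = factor(rep(seq_len(n), k)),
                   r = factor(rep(seq_len(k), each = n)))
  a <- anova(lm(y ~ s + r, data = df))
  msr <- a["s", "Mean Sq"]
  msc <- a["r", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# cavity_segment built directly from masks (bypasses segmentation) so the
# morphometry operations can be tested on constructed geometry
cavity_from_mask <- function(mask, bone, spacing = c(1, 1, 1),
                             origin = c(0, 0, 0)) {
  structure(list(mask = mask, seed_point = c(0L, 0L, 0L),
                 faces = orbitometry:::boundary_faces(mask, bone, dim(mask)),
                 growth = numeric(0), iterations = 0L,
                 spacing = spacing, origin = origin),
            class = "cavity_segment")
}

# axis-aligned cylinder cavity along z, open at low z, with a bone shell
cylinder_cavity <- function(radius_mm = 10, length_mm = 30, vx = 0.5) {
  marg <- 3
  nxy <- ceiling(2 * (radius_mm + marg) / vx)
  nz <- ceiling((length_mm + 2 * marg) / vx)
  dims <- c(nxy, nxy, nz)
  sp <- rep(vx, 3)
  cx <- nxy * vx / 2
  z0 <- marg
  xs <- (seq_len(nxy) - 0.5) * vx - cx
  zs <- (seq_len(nz) - 0.5) * vx - z0
  rho2 <- outer(xs^2, xs^2, `+`)
  mask <- array(FALSE, dims)
  for (k in which(zs >= 0 & zs < length_mm))
    mask[, , k] <- rho2 <= radius_mm^2
  shell <- array(orbitometry:::cpp_sqdist(as.logical(mask), dims, sp) <=
                   1.5^2 + 1e-9, dims) & !mask
  for (k in which(zs < 0)) shell[, , k][rho2 <= radius_mm^2] <- FALSE
  list(cavity = cavity_from_mask(mask, shell, sp),
       axis = structure(list(anterior_point = c(cx, cx, z0),
                             posterior_point = c(cx, cx, z0 + length_mm),
                             unit_direction = c(0, 0, 1),
                             length_mm = length_mm),
                        class = "depth_axis"),
       z0 = z0, length_mm = length_mm)
}

# full pipeline shortcut on a phantom
measure_phantom <- function(ph, ...) {
  measure_orbit(ph$volume, ph$truth$seed_voxel, ...)
}

expect_rel <- function(value, target, tol) {
  expect_lt(abs(value - target) / abs(target), tol)
}
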