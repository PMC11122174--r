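# Voxel offsets of a ball with the given physical radius (mm) under
# anisotropic spacing; always includes the center voxel.
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(0L, as.integer(ceiling(radius_mm / spacing)))
  g <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  keep <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 +
    (g$dk * spacing[3])^2 <= radius_mm^2 + 1e-9
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

# 0-based linear index from 0-based (i,j,k) voxel indices
linear_index <- function(i, j, k, dims) i + dims[1] * (j + dims[2] * k)

# inverse of linear_index, returns 0-based matrix [i j k]
index_triplet <- function(lin, dims) {
  i <- lin %% dims[1]
  j <- (lin %/% dims[1]) %% dims[2]
  k <- lin %/% (dims[1] * dims[2])
  cbind(i = i, j = j, k = k)
}

# physical mm coordinates of voxel centers given 0-based index triplets
voxel_center_mm <- function(ijk, spacing, origin) {
  sweep(sweep(ijk + 0.5, 2, spacing, `*`), 2, origin, `+`)
}

# areas of triangles given n x 9 coordinate matrix (v1,v2,v3 by columns)
triangle_areas <- function(tri) {
  ax <- tri[, 4] - tri[, 1]; ay <- tri[, 5] - tri[, 2]; az <- tri[, 6] - tri[, 3]
  bx <- tri[, 7] - tri[, 1]; by <- tri[, 8] - tri[, 2]; bz <- tri[, 9] - tri[, 3]
  cx <- ay * bz - az * by
  cy <- az * bx - ax * bz
  cz <- ax * by - ay * bx
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
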