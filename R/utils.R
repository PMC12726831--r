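# Internal numerics shared across modules: array shifts, finite differences,
# trilinear interpolation, seeded evaluation, classed errors.

tb_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "tbmorph_error")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shift a 3D array along `axis` by `by` voxels with replicated (clamped) edges.
shift_clamp <- function(a, axis, by) {
  d <- dim(a)
  n <- d[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

# Central difference along `axis` (one-sided halves at the boundary).
central_diff <- function(a, axis) {
  (shift_clamp(a, axis, 1L) - shift_clamp(a, axis, -1L)) / 2
}

# Trilinear interpolation of 3D array `a` at continuous 1-based voxel
# coordinates (x, y, z); coordinates are clamped to the grid.
interp3 <- function(a, x, y, z) {
  d <- dim(a)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  z <- pmin(pmax(z, 1), nz)
  i0 <- pmin(floor(x), nx - 1L); fx <- x - i0
  j0 <- pmin(floor(y), ny - 1L); fy <- y - j0
  k0 <- pmin(floor(z), nz - 1L); fz <- z - k0
  nxy <- nx * ny
  base <- i0 + (j0 - 1) * nx + (k0 - 1) * nxy
  v000 <- a[base]
  v100 <- a[base + 1]
  v010 <- a[base + nx]
  v110 <- a[base + nx + 1]
  v001 <- a[base + nxy]
  v101 <- a[base + nxy + 1]
  v011 <- a[base + nxy + nx]
  v111 <- a[base + nxy + nx + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Exact partial derivatives of the trilinear interpolant of `a` at clamped
# continuous coordinates; returns list(gx, gy, gz) (piecewise per cell).
interp3_partials <- function(a, x, y, z) {
  d <- dim(a)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  z <- pmin(pmax(z, 1), nz)
  i0 <- pmin(floor(x), nx - 1L); fx <- x - i0
  j0 <- pmin(floor(y), ny - 1L); fy <- y - j0
  k0 <- pmin(floor(z), nz - 1L); fz <- z - k0
  nxy <- nx * ny
  base <- i0 + (j0 - 1) * nx + (k0 - 1) * nxy
  v000 <- a[base];            v100 <- a[base + 1]
  v010 <- a[base + nx];       v110 <- a[base + nx + 1]
  v001 <- a[base + nxy];      v101 <- a[base + nxy + 1]
  v011 <- a[base + nxy + nx]; v111 <- a[base + nxy + nx + 1]
  gx <- (v100 - v000) * (1 - fy) * (1 - fz) + (v110 - v010) * fy * (1 - fz) +
    (v101 - v001) * (1 - fy) * fz + (v111 - v011) * fy * fz
  gy <- (v010 - v000) * (1 - fx) * (1 - fz) + (v110 - v100) * fx * (1 - fz) +
    (v011 - v001) * (1 - fx) * fz + (v111 - v101) * fx * fz
  gz <- (v001 - v000) * (1 - fx) * (1 - fy) + (v101 - v100) * fx * (1 - fy) +
    (v011 - v010) * (1 - fx) * fy + (v111 - v110) * fx * fy
  list(gx = gx, gy = gy, gz = gz)
}

# Conservative trilinear scatter ("cloud in cell"): deposits mass[i] at
# clamped continuous coordinates (x,y,z)[i]; returns an array of dim `dim(mass)`.
splat3 <- function(mass, x, y, z) {
  d <- dim(mass)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  x <- pmin(pmax(as.vector(x), 1), nx)
  y <- pmin(pmax(as.vector(y), 1), ny)
  z <- pmin(pmax(as.vector(z), 1), nz)
  m <- as.vector(mass)
  keep <- m != 0
  x <- x[keep]; y <- y[keep]; z <- z[keep]; m <- m[keep]
  i0 <- pmin(floor(x), nx - 1L); fx <- x - i0
  j0 <- pmin(floor(y), ny - 1L); fy <- y - j0
  k0 <- pmin(floor(z), nz - 1L); fz <- z - k0
  nxy <- nx * ny
  base <- i0 + (j0 - 1) * nx + (k0 - 1) * nxy
  out <- numeric(prod(d))
  dep <- function(idx, w) {
    if (!length(idx)) return()
    agg <- rowsum(w, idx)
    out[as.integer(rownames(agg))] <<- out[as.integer(rownames(agg))] + agg[, 1]
  }
  dep(base,            m * (1 - fx) * (1 - fy) * (1 - fz))
  dep(base + 1,        m * fx * (1 - fy) * (1 - fz))
  dep(base + nx,       m * (1 - fx) * fy * (1 - fz))
  dep(base + nx + 1,   m * fx * fy * (1 - fz))
  dep(base + nxy,      m * (1 - fx) * (1 - fy) * fz)
  dep(base + nxy + 1,  m * fx * (1 - fy) * fz)
  dep(base + nxy + nx, m * (1 - fx) * fy * fz)
  dep(base + nxy + nx + 1, m * fx * fy * fz)
  array(out, dim = d)
}

# Voxel-center coordinate arrays (1-based), each shaped like the grid.
coord_arrays <- function(shape) {
  list(
    x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape),
    z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  )
}

# Mask/image center of mass in 1-based voxel coordinates.
com_voxel <- function(a) {
  tot <- sum(a)
  if (tot <= 0) tb_stop("tb_empty_lesion", "cannot compute center of mass of an all-zero array")
  d <- dim(a)
  cc <- coord_arrays(d)
  c(sum(cc$x * a), sum(cc$y * a), sum(cc$z * a)) / tot
}

# Separable block-mean downsampling by a factor of 2 (odd trailing voxels are
# folded into the last block); used by the multiresolution solver.
downsample2 <- function(a) {
  d <- dim(a)
  nd <- ceiling(d / 2)
  grp <- lapply(d, function(n) pmin((seq_len(n) + 1L) %/% 2L, ceiling(n / 2)))
  out <- array(0, dim = nd)
  cnt <- array(0, dim = nd)
  cc <- coord_arrays(d)
  idx <- grp[[1]][cc$x] + (grp[[2]][cc$y] - 1L) * nd[1] +
    (grp[[3]][cc$z] - 1L) * nd[1] * nd[2]
  s <- tapply(as.vector(a), idx, sum)
  n <- tabulate(idx, nbins = prod(nd))
  out[as.integer(names(s))] <- s
  out / pmax(n, 1)
}

# Trilinear resampling of a 3D array onto a new shape (aligned extents).
resample3 <- function(a, new_shape) {
  d <- dim(a)
  sc <- (d - 1) / pmax(new_shape - 1, 1)
  cc <- coord_arrays(new_shape)
  x <- 1 + (cc$x - 1) * sc[1]
  y <- 1 + (cc$y - 1) * sc[2]
  z <- 1 + (cc$z - 1) * sc[3]
  array(interp3(a, as.vector(x), as.vector(y), as.vector(z)), dim = new_shape)
}
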