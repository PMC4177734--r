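# Internal numeric helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded renders never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# clamp values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear interpolation of a gridded field
#'
#' Interpolates matrix `Z` (rows ~ `xg`, cols ~ `yg`, both strictly
#' increasing and regular) at arbitrary query points. Queries outside the
#' grid are clamped to the border (constant extrapolation).
#'
#' @param xg,yg grid coordinate vectors.
#' @param Z matrix of values, `dim = c(length(xg), length(yg))`.
#' @param xq,yq query coordinates (equal length vectors).
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
interp_bilinear <- function(xg, yg, Z, xq, yq) {
  nx <- length(xg); ny <- length(yg)
  dx <- if (nx > 1L) xg[2L] - xg[1L] else 1
  dy <- if (ny > 1L) yg[2L] - yg[1L] else 1
  fx <- clamp((xq - xg[1L]) / dx, 0, nx - 1)
  fy <- clamp((yq - yg[1L]) / dy, 0, ny - 1)
  i0 <- pmin(floor(fx), nx - 2L); i0[nx == 1L] <- 0L
  j0 <- pmin(floor(fy), ny - 2L); j0[ny == 1L] <- 0L
  if (nx == 1L) i0 <- rep(0L, length(fx))
  if (ny == 1L) j0 <- rep(0L, length(fy))
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  i1 <- pmin(i0 + 1L, nx - 1L); j1 <- pmin(j0 + 1L, ny - 1L)
  # 1-based linear indices into Z
  z00 <- Z[i0 + 1L + nx * j0]
  z10 <- Z[i1 + 1L + nx * j0]
  z01 <- Z[i0 + 1L + nx * j1]
  z11 <- Z[i1 + 1L + nx * j1]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

# Discrete Gaussian kernel with standard deviation `sigma` in sample units,
# truncated at 4 sigma, normalized to unit sum.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Convolve each column of matrix M with kernel k, reflecting at the borders.
conv_cols <- function(M, k) {
  nk <- length(k)
  if (nk == 1L) return(M * k)
  r <- (nk - 1L) %/% 2L
  n <- nrow(M)
  idx_top <- pmin(pmax(2L, seq.int(r + 1L, 2L)), n)       # reflect
  idx_bot <- pmax(pmin(n - 1L, seq.int(n - 1L, n - r)), 1L)
  Mp <- rbind(M[idx_top, , drop = FALSE], M, M[idx_bot, , drop = FALSE])
  out <- matrix(0, n, ncol(M))
  for (j in seq_len(nk)) out <- out + k[j] * Mp[seq.int(j, j + n - 1L), , drop = FALSE]
  out
}

# Separable Gaussian blur of a 3D array along chosen axes.
# sigmas are in voxel units; a sigma of 0 skips that axis.
gauss_blur3 <- function(A, sigma_x = 0, sigma_y = 0, sigma_z = 0) {
  d <- dim(A)
  if (sigma_x > 0) {
    M <- matrix(A, d[1L], d[2L] * d[3L])
    A <- array(conv_cols(M, gauss_kernel(sigma_x)), d)
  }
  if (sigma_y > 0) {
    A <- aperm(A, c(2L, 1L, 3L))
    M <- matrix(A, d[2L], d[1L] * d[3L])
    A <- aperm(array(conv_cols(M, gauss_kernel(sigma_y)), c(d[2L], d[1L], d[3L])),
               c(2L, 1L, 3L))
  }
  if (sigma_z > 0) {
    A <- aperm(A, c(3L, 1L, 2L))
    M <- matrix(A, d[3L], d[1L] * d[2L])
    A <- aperm(array(conv_cols(M, gauss_kernel(sigma_z)), c(d[3L], d[1L], d[2L])),
               c(2L, 3L, 1L))
  }
  A
}

# Greyscale erosion (min) / dilation (max) of a matrix over a disc of
# `radius` grid steps; NA-aware (NAs ignored in the window).
disc_offsets <- function(radius) {
  r <- as.integer(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_mat <- function(M, dx, dy, fill = NA_real_) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(fill, n, m)
  xs <- seq_len(n) - dx; ys <- seq_len(m) - dy
  okx <- xs >= 1L & xs <= n; oky <- ys >= 1L & ys <= m
  out[okx, oky] <- M[xs[okx], ys[oky]]
  out
}

morph_minmax <- function(M, radius, op = c("min", "max")) {
  op <- match.arg(op)
  off <- disc_offsets(radius)
  acc <- NULL
  for (i in seq_len(nrow(off))) {
    S <- shift_mat(M, off$dx[i], off$dy[i])
    if (is.null(acc)) acc <- S
    else acc <- if (op == "min") pmin(acc, S, na.rm = TRUE) else pmax(acc, S, na.rm = TRUE)
  }
  acc[is.infinite(acc)] <- NA_real_
  acc
}

# Greyscale morphological closing then opening (disc structuring element).
morph_smooth <- function(M, radius) {
  cl <- morph_minmax(morph_minmax(M, radius, "max"), radius, "min")
  morph_minmax(morph_minmax(cl, radius, "min"), radius, "max")
}

# 3x3 median filter, NA-aware.
median3 <- function(M) {
  off <- expand.grid(dx = -1:1, dy = -1:1)
  stk <- vapply(seq_len(nrow(off)),
                function(i) as.vector(shift_mat(M, off$dx[i], off$dy[i])),
                numeric(length(M)))
  out <- apply(stk, 1L, function(v) stats::median(v, na.rm = TRUE))
  matrix(out, nrow(M), ncol(M))
}

# Rotation matrix from small XYZ Euler angles (radians), R = Rz Ry Rx.
rot_xyz <- function(ang) {
  ax <- ang[1L]; ay <- ang[2L]; az <- ang[3L]
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler angles (XYZ convention) back out of a near-identity rotation matrix.
ang_from_rot <- function(R) {
  ay <- asin(clamp(-R[3L, 1L], -1, 1))
  ax <- atan2(R[3L, 2L], R[3L, 3L])
  az <- atan2(R[2L, 1L], R[1L, 1L])
  c(ax, ay, az)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
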