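#' Calibration and evaluation point patterns
#'
#' Builds the cross-scanner calibration layout: a lateral square-grid
#' pattern of points (defined in the ablation-laser frame) replicated at
#' `n_planes` equidistant axial positions, and an evaluation pattern made of
#' the centres of all small squares (the grid rotated by 45 degrees) placed
#' at the axial midpoints between adjacent calibration planes - the points
#' farthermost from the calibration points.
#'
#' @param working_space list with elements `x`, `y`, `z`, each a c(min, max)
#'   range in µm.
#' @param n_planes number of calibration planes (>= 2).
#' @param n_cells number of lateral grid cells per axis.
#' @return list with data.frames `calibration` and `evaluation`, each with
#'   columns `x`, `y`, `z` (µm), `role`, `plane`.
#' @export
make_patterns <- function(working_space = list(x = c(0, 4000), y = c(0, 4000),
                                               z = c(0, 2000)),
                          n_planes = 5L, n_cells = 8L) {
  ws <- working_space
  if (diff(ws$x) <= 0 || diff(ws$y) <= 0 || diff(ws$z) <= 0)
    stop("degenerate working space", call. = FALSE)
  if (n_planes < 2L) stop("need at least 2 calibration planes", call. = FALSE)
  gx <- seq(ws$x[1], ws$x[2], length.out = n_cells + 1L)
  gy <- seq(ws$y[1], ws$y[2], length.out = n_cells + 1L)
  zp <- seq(ws$z[1], ws$z[2], length.out = n_planes)
  cal <- do.call(rbind, lapply(seq_along(zp), function(p)
    data.frame(x = rep(gx, times = length(gy)),
               y = rep(gy, each = length(gx)),
               z = zp[p], role = "calibration", plane = p)))
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  zm <- (zp[-1] + zp[-length(zp)]) / 2
  ev <- do.call(rbind, lapply(seq_along(zm), function(p)
    data.frame(x = rep(cx, times = length(cy)),
               y = rep(cy, each = length(cx)),
               z = zm[p], role = "evaluation", plane = p)))
  list(calibration = cal, evaluation = ev)
}

#' Smooth synthetic inter-scanner distortion field
#'
#' One low-order harmonic per output axis: each displacement component is
#' `A_i sin(2 pi <p, k_i> / lambda + phi_i)` with a random direction `k_i`,
#' wavelength 1.5 times the largest extent and amplitude drawn within
#' [0.6, 1] of `amplitude`. Deterministic given the seed.
#'
#' @param amplitude maximal displacement amplitude, µm.
#' @param extent spatial scale of the working space, µm.
#' @param seed integer seed.
#' @return a function mapping an n x 3 point matrix to an n x 3
#'   displacement matrix.
#' @export
make_distortion <- function(amplitude = 50, extent = 4000, seed = 1L) {
  par <- with_seed(seed, {
    k <- matrix(stats::rnorm(9), 3, 3)
    k <- k / sqrt(rowSums(k^2))
    list(k = k, phi = stats::runif(3, 0, 2 * pi),
         A = amplitude * stats::runif(3, 0.6, 1))
  })
  lambda <- 1.5 * extent
  function(pts) {
    pts <- as.matrix(pts)
    sapply(1:3, function(i)
      par$A[i] * sin(2 * pi * (pts %*% par$k[i, ]) / lambda + par$phi[i]))
  }
}

#' Simulate ablate-and-detect point pairs
#'
#' Emulates the calibration procedure: each pattern point, defined in the
#' laser frame, is "ablated" and then "detected" in the imaging frame. The
#' imaging-frame coordinates are the laser coordinates plus the smooth
#' inter-scanner distortion plus isotropic Gaussian detection noise
#' (default sigma 10 µm, between the 2-3 µm optics accuracy and the
#' 18/35 µm imaging resolution).
#'
#' @param patterns output of [make_patterns()].
#' @param distortion a displacement function as from [make_distortion()],
#'   or `NULL` for a perfectly aligned pair of frames.
#' @param noise_sd detection noise standard deviation per axis, µm.
#' @param seed integer seed.
#' @return a data.frame of class `PointPairs` with laser-frame columns
#'   `x`, `y`, `z`, imaging-frame columns `u`, `v`, `w`, plus `role` and
#'   `plane`.
#' @export
simulate_point_pairs <- function(patterns, distortion = NULL, noise_sd = 10,
                                 seed = 1L) {
  pts <- rbind(patterns$calibration, patterns$evaluation)
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  uvw <- xyz
  if (!is.null(distortion)) uvw <- uvw + distortion(xyz)
  if (noise_sd > 0)
    uvw <- uvw + with_seed(seed, matrix(stats::rnorm(length(uvw), 0, noise_sd),
                                        nrow(uvw), 3))
  out <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    u = uvw[, 1], v = uvw[, 2], w = uvw[, 3],
                    role = pts$role, plane = pts$plane)
  class(out) <- c("PointPairs", "data.frame")
  out
}

#' Fit the tricubic imaging-to-laser mapping
#'
#' Least-squares tricubic B-spline fit of the mapping
#' `(x, y, z) = f(u, v, w)` to the calibration point pairs. One clamped
#' cubic tensor basis over the calibrated bounding box is shared by the
#' three output coordinates.
#'
#' @param pairs a `PointPairs` data.frame; only rows with
#'   `role == "calibration"` enter the fit.
#' @param n_intervals knot intervals per axis (u, v, w). The default, one
#'   interval per two pattern cells laterally and per two plane spacings
#'   axially, keeps ordinary least squares overdetermined for the default
#'   pattern while following the calibration plane/cell structure.
#' @param ridge optional ridge penalty (0 = ordinary least squares).
#' @return an object of class `Mapping3D` with the knot vectors, the
#'   coefficient matrix, the fitted domain and calibration residual
#'   statistics.
#' @export
fit_mapping <- function(pairs, n_intervals = c(4, 4, 2), ridge = 0) {
  cal <- pairs[pairs$role == "calibration", , drop = FALSE]
  if (nrow(cal) < 256L)
    stop("need at least 4^4 = 256 well-distributed calibration pairs",
         call. = FALSE)
  uvw <- as.matrix(cal[, c("u", "v", "w")])
  xyz <- as.matrix(cal[, c("x", "y", "z")])
  domain <- apply(uvw, 2L, range)
  knots <- lapply(1:3, function(i)
    bs_knot_vector(domain[1, i], domain[2, i], n_intervals[i]))
  mats <- lapply(1:3, function(i) bs_design(knots[[i]], uvw[, i]))
  B <- tensor_rows(mats)
  coef <- ls_solve(B, xyz, ridge = ridge)
  res <- xyz - B %*% coef
  err <- sqrt(rowSums(res^2))
  structure(list(knots = knots, coef = coef, domain = domain,
                 n_intervals = n_intervals,
                 calibration_error = list(mean_abs = mean(err),
                                          max = max(err), n = length(err))),
            class = "Mapping3D")
}

#' @export
print.Mapping3D <- function(x, ...) {
  cat(sprintf("Mapping3D: tricubic B-spline, %d coefficients per axis\n",
              nrow(x$coef)))
  cat(sprintf("  calibration residuals: mean %.2f um, max %.2f um (n = %d)\n",
              x$calibration_error$mean_abs, x$calibration_error$max,
              x$calibration_error$n))
  invisible(x)
}

#' Map imaging-frame points to the laser frame
#'
#' @param mapping a [fit_mapping()] result.
#' @param uvw n x 3 matrix of imaging-frame coordinates, µm.
#' @return n x 3 matrix of laser-frame coordinates.
#' @export
predict_mapping <- function(mapping, uvw) {
  stopifnot(inherits(mapping, "Mapping3D"))
  uvw <- as.matrix(uvw)
  mats <- lapply(1:3, function(i) bs_design(mapping$knots[[i]], uvw[, i]))
  tensor_rows(mats) %*% mapping$coef
}

#' Mapping error statistics
#'
#' The mapping error of a point pair is the Euclidean norm
#' `|(x, y, z) - f(u, v, w)|`.
#'
#' @param mapping a [fit_mapping()] result.
#' @param pairs a `PointPairs` data.frame; all pairs must lie inside the
#'   mapping's fitted domain (a 1 µm tolerance is allowed).
#' @return list with `per_pair` (data.frame of errors), `mean_abs`, `max`,
#'   and `by_role` (mean absolute error per role).
#' @export
mapping_error <- function(mapping, pairs) {
  stopifnot(inherits(mapping, "Mapping3D"))
  uvw <- as.matrix(pairs[, c("u", "v", "w")])
  tol <- 1
  out_of <- which(uvw[, 1] < mapping$domain[1, 1] - tol |
                  uvw[, 1] > mapping$domain[2, 1] + tol |
                  uvw[, 2] < mapping$domain[1, 2] - tol |
                  uvw[, 2] > mapping$domain[2, 2] + tol |
                  uvw[, 3] < mapping$domain[1, 3] - tol |
                  uvw[, 3] > mapping$domain[2, 3] + tol)
  if (length(out_of) > 0)
    stop(sprintf("point pair(s) outside the calibrated domain: index %s",
                 paste(utils::head(out_of, 8L), collapse = ", ")),
         call. = FALSE)
  pred <- predict_mapping(mapping, uvw)
  err <- sqrt(rowSums((as.matrix(pairs[, c("x", "y", "z")]) - pred)^2))
  per <- data.frame(role = pairs$role, plane = pairs$plane, error = err)
  list(per_pair = per, mean_abs = mean(err), max = max(err),
       by_role = tapply(err, pairs$role, mean))
}
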