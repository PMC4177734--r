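# Tensor-product cubic B-spline least-squares fitting.
#
# The cubic basis itself comes from splines::splineDesign (clamped uniform
# knots); the tensor-product design, the (optionally iteratively reweighted)
# least-squares solve and the rank/support diagnostics live here. Shared by
# the bicubic boundary-surface fit and the tricubic scanner calibration.

# clamped uniform knot vector over [a, b] with n_intervals spans (degree 3)
bs_knot_vector <- function(a, b, n_intervals) {
  stopifnot(b > a, n_intervals >= 1)
  c(rep(a, 3), seq(a, b, length.out = n_intervals + 1), rep(b, 3))
}

# number of basis functions for a clamped cubic knot vector
bs_ncoef <- function(knots) length(knots) - 4L

# cubic B-spline design matrix; queries clamped into the domain
bs_design <- function(knots, x) {
  a <- knots[4L]; b <- knots[length(knots) - 3L]
  splines::splineDesign(knots, clamp(x, a, b), ord = 4L)
}

# row-wise tensor (Khatri-Rao) product of design matrices
tensor_rows <- function(mats) {
  B <- mats[[1L]]
  for (i in seq_along(mats)[-1L]) {
    Bi <- mats[[i]]
    mB <- ncol(B); mI <- ncol(Bi)
    B <- B[, rep(seq_len(mB), times = mI), drop = FALSE] *
      Bi[, rep(seq_len(mI), each = mB), drop = FALSE]
  }
  B
}

# weighted least squares with rank/support diagnostics.
# Returns coefficients (ncol(B) x ncol(Y)); errors on rank deficiency
# identifying unsupported basis columns unless ridge > 0.
ls_solve <- function(B, Y, w = NULL, ridge = 0) {
  Y <- as.matrix(Y)
  if (!is.null(w)) {
    sw <- sqrt(w)
    B <- B * sw
    Y <- Y * sw
  }
  p <- ncol(B)
  if (ridge > 0) {
    B <- rbind(B, diag(sqrt(ridge), p))
    Y <- rbind(Y, matrix(0, p, ncol(Y)))
  }
  qrB <- qr(B)
  if (qrB$rank < p) {
    support <- colSums(abs(B) > 1e-12) > 0
    bad <- which(!support)
    msg <- if (length(bad) > 0)
      sprintf("rank-deficient fit: %d basis function(s) without data support (columns %s)",
              length(bad), paste(utils::head(bad, 8L), collapse = ", "))
    else
      sprintf("rank-deficient fit: rank %d < %d coefficients", qrB$rank, p)
    stop(msg, call. = FALSE)
  }
  qr.coef(qrB, Y)
}

# second-difference penalty rows (P-spline) over a 2D coefficient lattice
# of size mx x my; returns a matrix with one row per penalized difference.
penalty_rows_2d <- function(mx, my) {
  rows <- list()
  idx <- function(i, j) (j - 1L) * mx + i
  for (j in seq_len(my)) for (i in seq_len(mx - 2L)) {
    r <- numeric(mx * my)
    r[idx(i, j)] <- 1; r[idx(i + 1L, j)] <- -2; r[idx(i + 2L, j)] <- 1
    rows[[length(rows) + 1L]] <- r
  }
  for (j in seq_len(my - 2L)) for (i in seq_len(mx)) {
    r <- numeric(mx * my)
    r[idx(i, j)] <- 1; r[idx(i, j + 1L)] <- -2; r[idx(i, j + 2L)] <- 1
    rows[[length(rows) + 1L]] <- r
  }
  do.call(rbind, rows)
}

# robust (IRLS, Tukey bisquare) tensor-spline scalar fit.
# pts: n x d matrix of coordinates; z: n values; knots: list of knot vectors.
# `smooth` adds a second-difference coefficient penalty (P-spline style,
# relative to the design scale): it leaves densely supported regions
# essentially untouched but keeps the surface tame where the lattice has
# little or no data (e.g. the corners of a disc-shaped candidate cloud).
fit_tensor_spline <- function(pts, z, knots, iterations = 5L, ridge = 0,
                              smooth = 0, tukey_factor = 3) {
  pts <- as.matrix(pts)
  mats <- lapply(seq_along(knots), function(i) bs_design(knots[[i]], pts[, i]))
  B <- tensor_rows(mats)
  z0 <- mean(z)
  zc <- z - z0
  P <- NULL
  if (smooth > 0 && length(knots) == 2L) {
    mx <- bs_ncoef(knots[[1L]]); my <- bs_ncoef(knots[[2L]])
    lam <- smooth * mean(colSums(B^2))
    P <- sqrt(lam) * penalty_rows_2d(mx, my)
  }
  solve_w <- function(w) {
    Bw <- if (is.null(w)) B else B * sqrt(w)
    zw <- if (is.null(w)) zc else zc * sqrt(w)
    if (!is.null(P)) { Bw <- rbind(Bw, P); zw <- c(zw, numeric(nrow(P))) }
    ls_solve(Bw, zw, ridge = ridge)
  }
  coef <- solve_w(NULL)
  if (iterations > 0L) {
    for (it in seq_len(iterations)) {
      r <- zc - drop(B %*% coef)
      s <- stats::median(abs(r))
      cc <- max(tukey_factor * s, 1e-3)   # guard exact fits
      u <- r / cc
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (sum(w > 0) < ncol(B) && is.null(P)) break
      coef_new <- tryCatch(solve_w(w), error = function(e) NULL)
      if (is.null(coef_new)) break
      coef <- coef_new
    }
  }
  r <- zc - drop(B %*% coef)
  list(coef = drop(coef) + z0, knots = knots, rms = sqrt(mean(r^2)),
       residuals = r)
}

# evaluate a tensor-spline fit at query coordinates (n x d)
eval_tensor_spline <- function(fit, pts) {
  pts <- as.matrix(pts)
  mats <- lapply(seq_along(fit$knots),
                 function(i) bs_design(fit$knots[[i]], pts[, i]))
  drop(tensor_rows(mats) %*% fit$coef)
}
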