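#' Plan a ring of tracking landmarks
#'
#' Small laser-ablated craters surrounding the cochleostomy serve as
#' fiducials for OCT-based tracking. Landmarks are equally spaced on a ring
#' whose centroid coincides with the channel centre, so rotational tracking
#' errors are not amplified at the ablation site.
#'
#' @param channel_center lateral channel centre c(x, y), µm.
#' @param ring_radius landmark ring radius, µm; must exceed the channel
#'   radius plus the laser spot radius.
#' @param count number of landmarks (>= 3, non-collinear by construction).
#' @param channel_diameter channel diameter, µm.
#' @param spot_radius laser spot radius, µm.
#' @param phase angular offset of the first landmark, radians.
#' @return a data.frame of class `LandmarkSet` with columns `x`, `y`, `z`
#'   (z = 0 reference plane), and attributes `centroid` and `ring_radius`.
#' @export
plan_landmarks <- function(channel_center = c(0, 0), ring_radius = 800,
                           count = 4L, channel_diameter = 1000,
                           spot_radius = 100, phase = 0) {
  if (count < 3L)
    stop("at least 3 landmarks are required (non-collinear layout)",
         call. = FALSE)
  if (ring_radius <= channel_diameter / 2 + spot_radius)
    stop("landmark ring overlaps the channel: ring radius must exceed channel radius + spot radius",
         call. = FALSE)
  a <- phase + 2 * pi * (seq_len(count) - 1L) / count
  out <- data.frame(x = channel_center[1] + ring_radius * cos(a),
                    y = channel_center[2] + ring_radius * sin(a),
                    z = 0)
  structure(out, class = c("LandmarkSet", "data.frame"),
            centroid = c(mean(out$x), mean(out$y)),
            ring_radius = ring_radius)
}

#' Ablate landmark craters on a phantom
#'
#' @param phantom a `Phantom`.
#' @param landmarks a [plan_landmarks()] set.
#' @param duration crater pulse duration, µs (default 100: deepest, most
#'   visible craters).
#' @return the updated `Phantom`.
#' @export
ablate_landmarks <- function(phantom, landmarks, duration = 100) {
  for (i in seq_len(nrow(landmarks)))
    phantom <- apply_pulse(phantom, c(landmarks$x[i], landmarks$y[i]), duration)
  phantom
}

#' Localize landmark craters in a volume
#'
#' Sub-voxel crater centres from the detected surface height map: within a
#' search window around each expected position, the local surface baseline
#' is estimated from the window border, and the centre is the
#' depth-weighted centroid of the crater (depths above half the maximal
#' crater depth). Landmarks outside the field of view or without a
#' sufficiently deep crater are flagged invalid.
#'
#' @param vol an `OctVolume` covering the landmark ring.
#' @param expected expected landmark positions (data.frame with `x`, `y`).
#' @param window_halfwidth half-width of the square search window, µm.
#' @param min_crater_depth minimum crater depth accepted, µm.
#' @param threshold surface-detection intensity threshold.
#' @param exclude optional list(center =, diameter =): lateral disc (e.g.
#'   the cochleostomy itself) excluded from windows and baselines.
#' @param surface optional precomputed bone `SurfaceModel` for `vol`.
#' @return data.frame with columns `x`, `y`, `z` (detected, µm) and
#'   `valid`.
#' @export
localize_landmarks <- function(vol, expected, window_halfwidth = 450,
                               min_crater_depth = 30, threshold = 0.3,
                               exclude = NULL, surface = NULL) {
  stopifnot(inherits(vol, "OctVolume"))
  if (is.null(surface)) surface <- detect_bone_surface(vol, threshold)
  H <- surface$z
  H[!surface$valid] <- NA_real_
  if (!is.null(exclude)) {
    m <- make_channel_mask(vol$x, vol$y, exclude$center %||% c(0, 0),
                           exclude$diameter %||% 1000)
    H[m] <- NA_real_
  }
  n <- nrow(expected)
  out <- data.frame(x = rep(NA_real_, n), y = NA_real_, z = NA_real_,
                    valid = FALSE)
  for (i in seq_len(n)) {
    ex <- expected$x[i]; ey <- expected$y[i]
    ix <- which(abs(vol$x - ex) <= window_halfwidth)
    iy <- which(abs(vol$y - ey) <= window_halfwidth)
    if (length(ix) < 5L || length(iy) < 5L) next   # outside the field
    Wd <- H[ix, iy, drop = FALSE]
    if (all(is.na(Wd))) next
    border <- c(Wd[1, ], Wd[nrow(Wd), ], Wd[, 1], Wd[, ncol(Wd)])
    baseline <- stats::median(border, na.rm = TRUE)
    depth <- Wd - baseline
    dmax <- max(depth, na.rm = TRUE)
    if (!is.finite(dmax) || dmax < min_crater_depth) next
    wgt <- pmax(depth - dmax / 2, 0)
    wgt[is.na(wgt)] <- 0
    sw <- sum(wgt)
    if (sw <= 0) next
    gx <- matrix(vol$x[ix], length(ix), length(iy))
    gy <- matrix(vol$y[iy], length(ix), length(iy), byrow = TRUE)
    out$x[i] <- sum(wgt * gx) / sw
    out$y[i] <- sum(wgt * gy) / sw
    out$z[i] <- baseline
    out$valid[i] <- TRUE
  }
  out
}

#' Estimate the rigid displacement from landmark correspondences
#'
#' Closed-form least-squares rigid alignment (SVD-based point-set
#' registration) mapping the reference landmark positions onto the detected
#' ones. Exact to numerical precision for three or more non-collinear
#' noise-free correspondences.
#'
#' @param reference data.frame with `x`, `y`, `z` reference positions.
#' @param detected data.frame with `x`, `y`, `z` and optionally `valid`.
#' @return a [rigid_transform()] with a `residuals` attribute (per-landmark
#'   alignment residual, µm).
#' @export
estimate_displacement <- function(reference, detected) {
  stopifnot(nrow(reference) == nrow(detected))
  valid <- if ("valid" %in% names(detected)) detected$valid else
    rep(TRUE, nrow(detected))
  valid <- valid & is.finite(detected$x) & is.finite(detected$y)
  if (sum(valid) < 3L)
    stop("tracking lost; halt ablation (fewer than 3 valid landmarks)",
         call. = FALSE)
  zr <- if ("z" %in% names(reference)) reference$z else 0
  zd <- if ("z" %in% names(detected)) detected$z else 0
  Rf <- cbind(reference$x, reference$y, zr)[valid, , drop = FALSE]
  Df <- cbind(detected$x, detected$y, zd)[valid, , drop = FALSE]
  rc <- colMeans(Rf); dc <- colMeans(Df)
  Rc <- sweep(Rf, 2, rc); Dc <- sweep(Df, 2, dc)
  sv_ref <- svd(Rc)$d
  if (sv_ref[2] < 1e-6 * max(sv_ref[1], 1))
    stop("tracking lost; halt ablation (landmarks collinear)", call. = FALSE)
  H <- t(Rc) %*% Dc
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  Rot <- sv$v %*% s %*% t(sv$u)
  tr <- as.numeric(dc - Rot %*% rc)
  ang <- ang_from_rot(Rot)
  if (any(abs(ang) > 5 * pi / 180))
    stop("tracking lost; halt ablation (implausibly large rotation)",
         call. = FALSE)
  out <- structure(list(t = tr, ang = ang, R = Rot), class = "RigidTransform")
  fit <- sweep(Rf %*% t(Rot), 2, tr, `+`)
  attr(out, "residuals") <- sqrt(rowSums((Df - fit)^2))
  out
}

#' Motion-correct a pulse plan
#'
#' Maps every planned pulse position through the estimated displacement so
#' the pulses land on the intended tissue positions. Durations are
#' unchanged. Corrected pulses leaving the working space are dropped (with
#' a message); the minimum-spacing invariant is re-verified.
#'
#' @param plan a `PulsePlan`.
#' @param transform a [rigid_transform()].
#' @param working_space optional list with `x` and `y` ranges (µm) of the
#'   laser working space.
#' @return the corrected `PulsePlan`.
#' @export
apply_correction <- function(plan, transform, working_space = NULL) {
  stopifnot(inherits(plan, "PulsePlan"), inherits(transform, "RigidTransform"))
  if (nrow(plan) == 0L) return(plan)
  at <- attributes(plan)
  pts <- transform_points(transform, cbind(plan$x, plan$y, 0))
  plan$x <- pts[, 1]; plan$y <- pts[, 2]
  if (!is.null(working_space)) {
    keep <- plan$x >= working_space$x[1] & plan$x <= working_space$x[2] &
            plan$y >= working_space$y[1] & plan$y <= working_space$y[2]
    if (any(!keep)) {
      message(sprintf("dropping %d corrected pulse(s) outside the working space",
                      sum(!keep)))
      plan <- plan[keep, , drop = FALSE]
      plan$order <- seq_len(nrow(plan))
    }
  }
  spacing <- at$spacing %||% 0
  if (nrow(plan) >= 2L && spacing > 0) {
    dmin <- min(stats::dist(cbind(plan$x, plan$y)))
    if (dmin < spacing - 1e-6)
      warning("minimum pulse spacing violated after correction")
  }
  structure(plan, class = c("PulsePlan", "data.frame"),
            round_index = at$round_index, spacing = at$spacing)
}
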