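#' Surface models
#'
#' A `SurfaceModel` represents a depth surface `z = s(x, y)` either as a
#' lateral-grid height map or as a bicubic B-spline. Grid models carry a
#' validity mask; spline models are valid on their fitted lateral domain.
#'
#' @param x,y lateral grid vectors, µm.
#' @param z height-map matrix (`length(x)` x `length(y)`), µm.
#' @param valid logical matrix marking positions where the surface is
#'   defined (defaults to finite `z`).
#' @return an object of class `SurfaceModel` (kind `"grid"`).
#' @export
surface_grid <- function(x, y, z, valid = NULL) {
  stopifnot(nrow(z) == length(x), ncol(z) == length(y))
  if (is.null(valid)) valid <- is.finite(z)
  structure(list(kind = "grid", x = x, y = y, z = z, valid = valid),
            class = "SurfaceModel")
}

surface_spline <- function(fit, domain) {
  structure(list(kind = "spline", fit = fit, domain = domain),
            class = "SurfaceModel")
}

#' @export
print.SurfaceModel <- function(x, ...) {
  if (x$kind == "grid")
    cat(sprintf("SurfaceModel (grid): %d x %d samples, depth range [%.1f, %.1f] um, %.0f%% valid\n",
                length(x$x), length(x$y), min(x$z[x$valid]), max(x$z[x$valid]),
                100 * mean(x$valid)))
  else
    cat(sprintf("SurfaceModel (bicubic spline): domain x [%.0f, %.0f], y [%.0f, %.0f] um\n",
                x$domain$x[1], x$domain$x[2], x$domain$y[1], x$domain$y[2]))
  invisible(x)
}

#' Evaluate a surface model
#'
#' @param surface a `SurfaceModel`.
#' @param x,y query coordinates, µm (equal-length vectors).
#' @return depth values, µm; `NA` where the surface is invalid.
#' @export
eval_surface <- function(surface, x, y) {
  stopifnot(inherits(surface, "SurfaceModel"))
  if (surface$kind == "grid") {
    z <- surface$z
    z[!surface$valid] <- NA_real_
    interp_bilinear(surface$x, surface$y, z, x, y)
  } else {
    eval_tensor_spline(surface$fit, cbind(x, y))
  }
}

#' Circular channel mask on a lateral grid
#'
#' @param x,y lateral grid vectors, µm.
#' @param center channel centre c(x, y), µm.
#' @param diameter channel diameter, µm (default 1000, the roughly 1 mm
#'   cochleostomy).
#' @return logical matrix, `TRUE` inside the channel disc.
#' @export
make_channel_mask <- function(x, y, center = c(0, 0), diameter = 1000) {
  outer(x - center[1], y - center[2], function(xx, yy)
    xx^2 + yy^2 <= (diameter / 2)^2)
}

#' Detect the air-bone surface
#'
#' The superficial air-bone interface carries a strong specular reflex, so
#' it is found per A-scan as the first intensity sample above a threshold,
#' refined to the sub-voxel centre of the local reflex peak, and then
#' regularized by grayscale morphological closing/opening plus a median
#' filter on the height map (removing speckle dropouts and outliers).
#'
#' @param vol an `OctVolume`.
#' @param threshold intensity threshold within the dynamic range.
#' @param smooth_radius structuring-element radius of the morphological
#'   smoothing, in lateral voxels.
#' @param refine logical: refine each crossing to the sub-voxel reflex peak
#'   by parabolic interpolation.
#' @param min_depth optional lateral matrix (or scalar) of per-A-scan lower
#'   search bounds, µm: crossings above this depth are ignored. Inside a
#'   closed loop the channel can only deepen, so bounding the search by the
#'   previous round's surface suppresses spurious shallow crossings where
#'   the steep channel wall smears the reflex across the lateral PSF.
#' @return a grid `SurfaceModel` on the volume's lateral grid; the validity
#'   mask is `FALSE` where no crossing exists.
#' @export
detect_bone_surface <- function(vol, threshold = 0.3, smooth_radius = 1,
                                refine = TRUE, min_depth = NULL) {
  stopifnot(inherits(vol, "OctVolume"))
  dr <- if (!is.null(vol$geom)) vol$geom$dynamic_range else max(vol$I)
  if (threshold <= 0 || threshold > dr)
    stop("threshold must lie within the dynamic range", call. = FALSE)
  d <- dim(vol$I); nlat <- d[1] * d[2]; nz <- d[3]
  M <- matrix(vol$I, nlat, nz)
  above <- M >= threshold
  if (!is.null(min_depth)) {
    kmin <- pmax(1L, ceiling((as.vector(min_depth) - vol$w[1]) / vol$spacing[3]) + 1L)
    kmin[!is.finite(kmin)] <- 1L
    above <- above & outer(kmin, seq_len(nz), `<=`)
  }
  firstw <- rep(NA_integer_, nlat)
  for (k in seq(nz, 1L)) firstw[above[, k]] <- k
  if (all(is.na(firstw)))
    stop("empty volume: no suprathreshold crossing found", call. = FALSE)
  dz <- vol$spacing[3]
  height <- rep(NA_real_, nlat)
  ok <- which(!is.na(firstw))
  if (refine) {
    for (i in ok) {
      k0 <- firstw[i]
      ks <- k0:min(k0 + 4L, nz)
      p <- ks[which.max(M[i, ks])]
      if (p > 1L && p < nz) {
        y0 <- M[i, p - 1L]; y1 <- M[i, p]; y2 <- M[i, p + 1L]
        den <- y0 - 2 * y1 + y2
        delta <- if (abs(den) > 1e-12) clamp(0.5 * (y0 - y2) / den, -0.5, 0.5) else 0
      } else delta <- 0
      height[i] <- vol$w[p] + delta * dz
    }
  } else {
    height[ok] <- vol$w[firstw[ok]]
  }
  H <- matrix(height, d[1], d[2])
  valid <- !is.na(H)
  H <- morph_smooth(H, smooth_radius)
  H <- median3(H)
  valid2 <- valid & is.finite(H)
  surface_grid(vol$x, vol$y, H, valid2)
}

#' Segmentation options for the critical boundary
#'
#' @param min_offset,max_offset axial search window below the detected bone
#'   surface, µm.
#' @param grad_sigma axial Gaussian-derivative scale, µm.
#' @param lat_sigma lateral pre-smoothing scale, µm: speckle decorrelates
#'   voxel to voxel while the boundary is laterally smooth, so lateral
#'   averaging raises the edge contrast-to-noise before gradient detection.
#' @param snr candidate acceptance threshold, in robust (MAD-based) noise
#'   units of the axial gradient inside the search window.
#' @param log_floor relative intensity floor added before the logarithm;
#'   the gradient operates on the log of the smoothed volume, which turns
#'   multiplicative speckle into additive noise of constant variance and
#'   backscatter steps into depth-independent log steps.
#' @param band_depth axial extent below an edge within which the
#'   confirming dark-side gradient is sought, µm. The boundary appears as a
#'   thin bright band (the endosteum) over dark fluid, so the detection
#'   statistic is the rising-edge gradient plus the magnitude of the
#'   steepest falling gradient within this band below it.
#' @param max_jump maximum axial index jump between linked candidates in
#'   adjacent A-scans, voxels.
#' @param min_chain minimum linked chain length, A-scans.
#' @param channel_center,channel_diameter definition of the channel region
#'   used for the confidence score (`NULL` diameter = whole field).
#' @return a list of options.
#' @export
boundary_opts <- function(min_offset = 50, max_offset = 600, grad_sigma = 12,
                          lat_sigma = 25, snr = 3, log_floor = 1e-3,
                          band_depth = 80, max_jump = 2, min_chain = 10,
                          channel_center = c(0, 0),
                          channel_diameter = NULL) {
  list(min_offset = min_offset, max_offset = max_offset,
       grad_sigma = grad_sigma, lat_sigma = lat_sigma,
       snr = snr, log_floor = log_floor, band_depth = band_depth,
       max_jump = max_jump,
       min_chain = min_chain, channel_center = channel_center,
       channel_diameter = channel_diameter)
}

#' Segment the bone-endosteum-perilymph boundary
#'
#' Gradient-based edge detection with model-based edge linking, frame by
#' frame: in each B-scan the axial Gaussian-derivative gradient is evaluated
#' below the bone surface; the strongest positive gradient per A-scan is a
#' candidate edge if it exceeds a robust noise threshold, and candidates are
#' linked into chains with a bounded axial jump between adjacent A-scans and
#' a minimum chain length. Confidence is the fraction of channel A-scans
#' carrying a linked candidate.
#'
#' @param vol an enhanced `OctVolume` (history-compounded and
#'   attenuation-compensated).
#' @param bone_surface the detected air-bone `SurfaceModel`.
#' @param opts a [boundary_opts()] list.
#' @return a data.frame of candidate points (`x`, `y`, `z` in µm, `grad`,
#'   `frame`) of class `BoundaryCandidates`, with attributes `confidence`
#'   (in [0, 1]) and `n_ascans`.
#' @export
segment_critical_boundary <- function(vol, bone_surface, opts = boundary_opts()) {
  stopifnot(inherits(vol, "OctVolume"), inherits(bone_surface, "SurfaceModel"))
  d <- dim(vol$I); nx <- d[1]; ny <- d[2]; nz <- d[3]
  dz <- vol$spacing[3]
  surf <- eval_surface(bone_surface,
                       rep(vol$x, times = ny), rep(vol$y, each = nx))
  surf <- matrix(surf, nx, ny)

  # axial gradient of the log of the laterally smoothed volume
  sm <- gauss_blur3(vol$I,
                    sigma_x = opts$lat_sigma / vol$spacing[1],
                    sigma_y = opts$lat_sigma / vol$spacing[2],
                    sigma_z = opts$grad_sigma / dz)
  sm <- log(sm + opts$log_floor * max(sm))
  G <- array(0, d)
  G[, , 2:(nz - 1)] <- (sm[, , 3:nz] - sm[, , 1:(nz - 2)]) / (2 * dz)
  # band statistic: rising edge plus steepest fall within band_depth below
  wb <- max(1L, ceiling(opts$band_depth / dz))
  Mn <- G
  for (s in seq_len(wb)) {
    ks <- seq_len(nz - s)
    Mn[, , ks] <- pmin(Mn[, , ks, drop = FALSE], G[, , ks + s, drop = FALSE])
  }
  G <- G - Mn

  mask <- if (is.null(opts$channel_diameter)) matrix(TRUE, nx, ny)
          else make_channel_mask(vol$x, vol$y, opts$channel_center,
                                 opts$channel_diameter)

  # per A-scan: up to 3 local gradient maxima above the robust noise gate
  K <- 3L
  cand_w <- matrix(NA_real_, nx, ny)   # sub-voxel axial index of winner
  cand_g <- matrix(NA_real_, nx, ny)
  linked <- matrix(FALSE, nx, ny)
  for (j in seq_len(ny)) {
    Gj <- matrix(G[, j, ], nx, nz)
    ck <- matrix(NA_real_, nx, K)      # candidate axial indices (sub-voxel)
    cg <- matrix(NA_real_, nx, K)
    for (i in seq_len(nx)) {
      s <- surf[i, j]
      if (!is.finite(s)) next
      k0 <- max(2L, ceiling((s + opts$min_offset - vol$w[1]) / dz) + 1L)
      # the confirming dark band must lie inside the measured range, so the
      # window ends a band depth above the bottom of the volume
      k1 <- min(nz - wb - 2L, floor((s + opts$max_offset - vol$w[1]) / dz) + 1L)
      if (k1 - k0 < 4L) next
      g <- Gj[i, k0:k1]
      med <- stats::median(g)
      noise <- stats::mad(g)
      thr <- med + opts$snr * max(noise, 1e-12)
      # interior local maxima above the gate
      loc <- which(g > c(-Inf, g[-length(g)]) & g >= c(g[-1], -Inf) & g > thr)
      if (length(loc) == 0L) next
      loc <- loc[order(-g[loc])][seq_len(min(K, length(loc)))]
      for (q in seq_along(loc)) {
        k <- k0 + loc[q] - 1L
        y0 <- Gj[i, k - 1L]; y1 <- Gj[i, k]; y2 <- Gj[i, k + 1L]
        den <- y0 - 2 * y1 + y2
        delta <- if (abs(den) > 1e-12) clamp(0.5 * (y0 - y2) / den, -0.5, 0.5) else 0
        ck[i, q] <- k + delta
        cg[i, q] <- g[loc[q]]
      }
    }
    # chain DP over A-scans: a candidate links to any candidate of the
    # previous A-scan within max_jump, or bridges one missing A-scan
    fwd <- matrix(0L, nx, K); bwd <- matrix(0L, nx, K)
    for (i in seq_len(nx)) for (q in seq_len(K)) {
      if (is.na(ck[i, q])) next
      best <- 0L
      if (i > 1L) for (p in seq_len(K))
        if (!is.na(ck[i - 1L, p]) && abs(ck[i, q] - ck[i - 1L, p]) <= opts$max_jump)
          best <- max(best, fwd[i - 1L, p])
      if (best == 0L && i > 2L) for (p in seq_len(K))
        if (!is.na(ck[i - 2L, p]) && abs(ck[i, q] - ck[i - 2L, p]) <= 1.5 * opts$max_jump)
          best <- max(best, fwd[i - 2L, p])
      fwd[i, q] <- best + 1L
    }
    for (i in seq.int(nx, 1L)) for (q in seq_len(K)) {
      if (is.na(ck[i, q])) next
      best <- 0L
      if (i < nx) for (p in seq_len(K))
        if (!is.na(ck[i + 1L, p]) && abs(ck[i, q] - ck[i + 1L, p]) <= opts$max_jump)
          best <- max(best, bwd[i + 1L, p])
      if (best == 0L && i < nx - 1L) for (p in seq_len(K))
        if (!is.na(ck[i + 2L, p]) && abs(ck[i, q] - ck[i + 2L, p]) <= 1.5 * opts$max_jump)
          best <- max(best, bwd[i + 2L, p])
      bwd[i, q] <- best + 1L
    }
    thru <- fwd + bwd - 1L
    thru[is.na(ck)] <- 0L
    for (i in seq_len(nx)) {
      q <- which.max(thru[i, ])
      if (length(q) == 1L && thru[i, q] >= opts$min_chain) {
        linked[i, j] <- TRUE
        cand_w[i, j] <- ck[i, q]
        cand_g[i, j] <- cg[i, q]
      }
    }
  }

  sel <- which(linked, arr.ind = TRUE)
  z <- vol$w[1] + (cand_w[linked] - 1) * dz
  out <- data.frame(x = vol$x[sel[, 1]], y = vol$y[sel[, 2]], z = z,
                    grad = cand_g[linked], frame = sel[, 2])
  # candidates lie strictly below the detected surface by construction;
  # enforce the invariant against interpolation edge effects
  keep <- out$z > surf[sel] + 1e-9
  out <- out[keep, , drop = FALSE]
  linked[sel[!keep, , drop = FALSE]] <- FALSE
  n_mask <- sum(mask & is.finite(surf))
  conf <- if (n_mask > 0) sum(linked & mask) / n_mask else 0
  structure(out, class = c("BoundaryCandidates", "data.frame"),
            confidence = conf, n_ascans = n_mask)
}

#' Confidence of a candidate set
#' @param candidates a `BoundaryCandidates` data.frame.
#' @return scalar confidence in [0, 1].
#' @export
boundary_confidence <- function(candidates) {
  attr(candidates, "confidence") %||% 0
}

#' Fit a bicubic B-spline surface to boundary candidates
#'
#' Robust tensor-product cubic fit across all frames, pooling candidate
#' points from the whole volume so single-frame gaps are bridged by
#' neighbouring frames. Outliers are down-weighted by iteratively
#' reweighted least squares (Tukey bisquare at `tukey_factor` times the
#' median absolute residual).
#'
#' @param candidates a `BoundaryCandidates` data.frame.
#' @param knot_spacing control-point spacing, µm.
#' @param iterations IRLS iterations.
#' @param tukey_factor bisquare cutoff in median-absolute-residual units.
#' @param ridge optional ridge penalty on the coefficients (0 = ordinary
#'   least squares).
#' @param smooth relative strength of a second-difference penalty on the
#'   control lattice. Candidate clouds cover a disc (the channel), so the
#'   corners of the rectangular tensor lattice are unsupported; the penalty
#'   keeps them tame without noticeably biasing supported regions. Set to 0
#'   for a pure (unpenalized) least-squares fit on fully supported data.
#' @param min_confidence required segmentation confidence; below it the
#'   caller should use the fallback virtual structure.
#' @return a spline `SurfaceModel`.
#' @export
fit_boundary_surface <- function(candidates, knot_spacing = 150,
                                 iterations = 5L, tukey_factor = 3,
                                 ridge = 0, smooth = 1e-3,
                                 min_confidence = 0.5) {
  conf <- boundary_confidence(candidates)
  if (conf < min_confidence)
    stop(sprintf("segmentation confidence %.2f below %.2f: use fallback",
                 conf, min_confidence), call. = FALSE)
  if (nrow(candidates) < 16L)
    stop("too few candidate points for a bicubic fit: use fallback",
         call. = FALSE)
  rx <- range(candidates$x); ry <- range(candidates$y)
  nix <- max(1L, round(diff(rx) / knot_spacing))
  niy <- max(1L, round(diff(ry) / knot_spacing))
  knots <- list(bs_knot_vector(rx[1], rx[2], nix),
                bs_knot_vector(ry[1], ry[2], niy))
  fit <- tryCatch(
    fit_tensor_spline(cbind(candidates$x, candidates$y), candidates$z,
                      knots, iterations = iterations, ridge = ridge,
                      smooth = smooth, tukey_factor = tukey_factor),
    error = function(e)
      stop(sprintf("insufficient lateral support for the control lattice (%s): use fallback",
                   conditionMessage(e)), call. = FALSE))
  surface_spline(fit, domain = list(x = rx, y = ry))
}

#' Derive the stop surface
#'
#' The stop surface is parallel to the segmented boundary, shallower by the
#' chosen standoff `offset` (the target residual-layer thickness).
#'
#' @param boundary a `SurfaceModel`.
#' @param offset standoff distance, µm, >= 0.
#' @return a `SurfaceModel` of the same kind.
#' @export
make_stop_surface <- function(boundary, offset) {
  stopifnot(inherits(boundary, "SurfaceModel"))
  if (!is.numeric(offset) || offset < 0)
    stop("offset must be non-negative", call. = FALSE)
  shift_surface(boundary, -offset)
}

# shift a surface by dz (positive = deeper); exact for both kinds because
# the clamped cubic basis sums to one
shift_surface <- function(surface, dz) {
  out <- surface
  if (surface$kind == "grid") out$z <- surface$z + dz
  else out$fit$coef <- surface$fit$coef + dz
  out
}

#' Residual-thickness map
#'
#' Residual bone thickness above the stop surface and penetration beyond
#' it, measured along the optical (z) axis on the channel mask:
#' `thickness = max(stop - bottom, 0)`, `penetration = max(bottom - stop, 0)`.
#' The two decompose the signed distance exactly:
#' `thickness - penetration = stop - bottom` pointwise.
#'
#' @param bottom the detected channel-bottom `SurfaceModel` (grid kind).
#' @param stop the stop `SurfaceModel`.
#' @param channel_mask logical matrix on `bottom`'s grid, or a list
#'   `list(center =, diameter =)`.
#' @return an object of class `ThicknessMap` with elements `x`, `y`,
#'   `thickness`, `penetration`, `mask`.
#' @export
thickness_map <- function(bottom, stop, channel_mask) {
  stopifnot(inherits(bottom, "SurfaceModel"), bottom$kind == "grid",
            inherits(stop, "SurfaceModel"))
  x <- bottom$x; y <- bottom$y
  mask <- if (is.list(channel_mask))
    make_channel_mask(x, y, channel_mask$center %||% c(0, 0),
                      channel_mask$diameter %||% 1000)
  else channel_mask
  stopifnot(is.logical(mask), all(dim(mask) == dim(bottom$z)))
  nx <- length(x); ny <- length(y)
  sz <- matrix(eval_surface(stop, rep(x, times = ny), rep(y, each = nx)), nx, ny)
  bz <- bottom$z
  bz[!bottom$valid] <- NA_real_
  if (any(mask & (!is.finite(bz) | !is.finite(sz))))
    stop("surface invalid inside the channel mask", call. = FALSE)
  diffz <- sz - bz
  structure(list(x = x, y = y,
                 thickness = pmax(diffz, 0),
                 penetration = pmax(-diffz, 0),
                 mask = mask), class = "ThicknessMap")
}

#' @export
print.ThicknessMap <- function(x, ...) {
  th <- x$thickness[x$mask]
  cat(sprintf("ThicknessMap: %d channel positions, thickness [%.1f, %.1f] um (mean %.1f), max penetration %.1f um\n",
              sum(x$mask), min(th), max(th), mean(th),
              max(x$penetration[x$mask])))
  invisible(x)
}

#' Fallback virtual critical structure
#'
#' While the boundary is still invisible beneath thick bone, ablation is
#' planned against a virtual critical structure parallel to the original
#' bone surface at a nominal depth (a finite stand-in for "at infinity";
#' the loop additionally caps the per-round depth). The resulting channel
#' bottom stays approximately parallel to the original surface.
#'
#' @param original_surface the round-0 bone `SurfaceModel`.
#' @param nominal_depth depth of the virtual structure below the original
#'   surface, µm.
#' @return a `SurfaceModel` parallel to the original surface.
#' @export
fallback_virtual_structure <- function(original_surface, nominal_depth) {
  stopifnot(inherits(original_surface, "SurfaceModel"), nominal_depth >= 0)
  shift_surface(original_surface, nominal_depth)
}
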