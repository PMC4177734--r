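#' Scan geometry for the OCT renderer
#'
#' Describes the sampled volume and the imaging model parameters. The axial
#' and lateral point-spread functions default to the measured 18 µm and
#' 35 µm FWHM of the swept-source system being emulated. Axial sampling must
#' satisfy Nyquist for the axial PSF (spacing at most half the FWHM).
#'
#' @param fov lateral field of view c(width_x, width_y), µm.
#' @param center lateral centre of the field, µm.
#' @param spacing voxel spacing c(dx, dy, dz), µm.
#' @param zlim axial (depth) range covered, µm.
#' @param axial_fwhm,lateral_fwhm PSF full widths at half maximum, µm.
#' @param noise_floor mean additive noise level (fraction of dynamic range).
#' @param speckle logical, render multiplicative speckle.
#' @param speckle_contrast coefficient of variation of the unit-mean speckle
#'   field (1 = fully developed speckle).
#' @param dynamic_range intensity ceiling; output is clipped to
#'   [0, dynamic_range].
#' @param reflex_amplitude pre-blur impulse amplitude of the specular reflex
#'   at the air-tissue interface.
#' @param refractive_index per-tissue index (geometric depth = optical depth
#'   at the default of 1; kept configurable).
#' @return an object of class `ScanGeometry`.
#' @export
scan_geometry <- function(fov = c(1400, 1400), center = c(0, 0),
                          spacing = c(20, 20, 6), zlim = c(-100, 1500),
                          axial_fwhm = 18, lateral_fwhm = 35,
                          noise_floor = 1e-4, speckle = TRUE,
                          speckle_contrast = 1, dynamic_range = 1,
                          reflex_amplitude = 2, refractive_index = 1) {
  stopifnot(all(fov > 0), all(spacing > 0), axial_fwhm > 0, lateral_fwhm > 0,
            zlim[2] > zlim[1], dynamic_range > 0, speckle_contrast >= 0,
            noise_floor >= 0)
  if (spacing[3] > axial_fwhm / 2)
    stop("axial spacing must be at most half the axial PSF FWHM (Nyquist)",
         call. = FALSE)
  structure(list(fov = fov, center = center, spacing = spacing, zlim = zlim,
                 axial_fwhm = axial_fwhm, lateral_fwhm = lateral_fwhm,
                 noise_floor = noise_floor, speckle = speckle,
                 speckle_contrast = speckle_contrast,
                 dynamic_range = dynamic_range,
                 reflex_amplitude = reflex_amplitude,
                 refractive_index = refractive_index),
            class = "ScanGeometry")
}

# construct an OctVolume container from an intensity array and grids
oct_volume <- function(I, x, y, w, spacing, acq_index = 0L, geom = NULL) {
  stopifnot(length(dim(I)) == 3L, dim(I)[1] == length(x),
            dim(I)[2] == length(y), dim(I)[3] == length(w),
            all(spacing > 0))
  structure(list(I = I, x = x, y = y, w = w, spacing = spacing,
                 acq_index = as.integer(acq_index), geom = geom),
            class = "OctVolume")
}

#' @export
print.OctVolume <- function(x, ...) {
  d <- dim(x$I)
  cat(sprintf("OctVolume: %d x %d A-scans x %d samples, spacing (%.1f, %.1f, %.1f) um, round %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$acq_index))
  invisible(x)
}

#' Render an OCT-like volume from a phantom
#'
#' Forward model per A-scan: tissue-class backscatter profile multiplied by
#' cumulative round-trip Beer-Lambert attenuation, an impulse-like specular
#' reflex at the air-tissue interface, convolution with the axial/lateral
#' Gaussian PSF, multiplication by unit-mean per-voxel speckle in scattering
#' tissue, an additive exponentially distributed noise floor, and clipping
#' to the dynamic range. The phantom's rigid pose is honoured: voxels sample
#' the displaced tissue.
#'
#' @param phantom a [make_phantom()] object.
#' @param geom a [scan_geometry()].
#' @param seed integer; the render is bit-reproducible given
#'   (phantom, geom, seed).
#' @param acq_index acquisition (loop round) index stored in the volume.
#' @return an `OctVolume`.
#' @examples
#' ph <- make_phantom(list(extent = c(400, 400), apex_depth = 300,
#'                         curvature_radius = Inf, t_e = 40), seed = 1)
#' g <- scan_geometry(fov = c(400, 400), zlim = c(-50, 450),
#'                    speckle = FALSE, noise_floor = 0)
#' v <- render_oct(ph, g, seed = 1)
#' @export
render_oct <- function(phantom, geom, seed = 1L, acq_index = 0L) {
  stopifnot(inherits(phantom, "Phantom"), inherits(geom, "ScanGeometry"))
  sp <- geom$spacing
  x <- seq(geom$center[1] - geom$fov[1] / 2, geom$center[1] + geom$fov[1] / 2,
           by = sp[1])
  y <- seq(geom$center[2] - geom$fov[2] / 2, geom$center[2] + geom$fov[2] / 2,
           by = sp[2])
  w <- seq(geom$zlim[1], geom$zlim[2], by = sp[3])
  nx <- length(x); ny <- length(y); nz <- length(w); nlat <- nx * ny
  if (diff(range(phantom$x)) < geom$fov[1] - 1e-9 ||
      diff(range(phantom$y)) < geom$fov[2] - 1e-9)
    stop("scan field of view exceeds the phantom extent", call. = FALSE)

  # sample positions in the phantom frame (inverse pose)
  inv <- invert_transform(phantom$pose)
  X <- rep(x, times = ny); Y <- rep(y, each = nx)
  identity_pose <- all(abs(phantom$pose$ang) < 1e-12)
  mu_tab <- c(phantom$optics$air$mu, phantom$optics$bone$mu,
              phantom$optics$endosteum$mu, phantom$optics$perilymph$mu)
  bs_tab <- c(phantom$optics$air$backscatter, phantom$optics$bone$backscatter,
              phantom$optics$endosteum$backscatter,
              phantom$optics$perilymph$backscatter)
  sp_tab <- c(phantom$optics$air$speckle, phantom$optics$bone$speckle,
              phantom$optics$endosteum$speckle, phantom$optics$perilymph$speckle)

  S <- matrix(0, nlat, nz)        # backscatter x attenuation
  SPK <- matrix(FALSE, nlat, nz)  # speckle-carrying voxels
  path <- numeric(nlat)           # accumulated one-way optical depth
  first_tissue <- rep(NA_integer_, nlat)
  if (identity_pose) {
    px <- X - phantom$pose$t[1]; py <- Y - phantom$pose$t[2]
    zb_col <- interp_bilinear(phantom$x, phantom$y, phantom$zb, px, py)
    ze_col <- interp_bilinear(phantom$x, phantom$y, phantom$ze, px, py)
  }
  n_idx <- geom$refractive_index
  for (k in seq_len(nz)) {
    if (identity_pose) {
      pz <- w[k] - phantom$pose$t[3]
      zb_k <- zb_col; ze_k <- ze_col
    } else {
      px <- inv$R[1, 1] * X + inv$R[1, 2] * Y + inv$R[1, 3] * w[k] + inv$t[1]
      py <- inv$R[2, 1] * X + inv$R[2, 2] * Y + inv$R[2, 3] * w[k] + inv$t[2]
      pz <- inv$R[3, 1] * X + inv$R[3, 2] * Y + inv$R[3, 3] * w[k] + inv$t[3]
      zb_k <- interp_bilinear(phantom$x, phantom$y, phantom$zb, px, py)
      ze_k <- interp_bilinear(phantom$x, phantom$y, phantom$ze, px, py)
    }
    cls <- 1L + (pz >= zb_k) + (pz >= ze_k) + (pz >= ze_k + phantom$t_e)
    mu_k <- mu_tab[cls] * n_idx
    S[, k] <- bs_tab[cls] * exp(-2 * (path + 0.5 * mu_k * sp[3]))
    SPK[, k] <- sp_tab[cls]
    path <- path + mu_k * sp[3]
    hit <- is.na(first_tissue) & cls > 1L
    if (any(hit)) {
      first_tissue[hit] <- k
      # specular reflex at the air-tissue interface (no attenuation above);
      # split between the two voxels straddling the interface so the blurred
      # peak centre is unbiased by the axial sampling grid
      hi <- which(hit)
      pz_hit <- if (length(pz) == 1L) rep(pz, length(hi)) else pz[hi]
      f <- clamp((pz_hit - zb_k[hi]) / sp[3], 0, 1)
      S[hi + nlat * (k - 1L)] <- S[hi + nlat * (k - 1L)] +
        geom$reflex_amplitude * (1 - f)
      if (k > 1L)
        S[hi + nlat * (k - 2L)] <- S[hi + nlat * (k - 2L)] +
          geom$reflex_amplitude * f
    }
  }

  A <- array(S, c(nx, ny, nz))
  if (!is.null(phantom$reflectors) && nrow(phantom$reflectors) > 0) {
    pts <- transform_points(phantom$pose,
                            as.matrix(phantom$reflectors[, c("x", "y", "z")]))
    for (i in seq_len(nrow(pts))) {
      ii <- round((pts[i, 1] - x[1]) / sp[1]) + 1L
      jj <- round((pts[i, 2] - y[1]) / sp[2]) + 1L
      kk <- round((pts[i, 3] - w[1]) / sp[3]) + 1L
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny && kk >= 1 && kk <= nz)
        A[ii, jj, kk] <- A[ii, jj, kk] + phantom$reflectors$amplitude[i]
    }
  }

  s2v <- 1 / (2 * sqrt(2 * log(2)))  # FWHM -> sigma
  A <- gauss_blur3(A,
                   sigma_x = geom$lateral_fwhm * s2v / sp[1],
                   sigma_y = geom$lateral_fwhm * s2v / sp[2],
                   sigma_z = geom$axial_fwhm * s2v / sp[3])

  A <- with_seed(seed, {
    if (geom$speckle && geom$speckle_contrast > 0) {
      shp <- 1 / geom$speckle_contrast^2
      g <- array(stats::rgamma(nx * ny * nz, shape = shp, rate = shp),
                 c(nx, ny, nz))
      spk3 <- array(SPK, c(nx, ny, nz))
      A <- A * ifelse(spk3, g, 1)
    }
    if (geom$noise_floor > 0)
      A <- A + geom$noise_floor * array(stats::rexp(nx * ny * nz), c(nx, ny, nz))
    A
  })
  A <- clamp(A, 0, geom$dynamic_range)
  oct_volume(A, x, y, w, sp, acq_index = acq_index, geom = geom)
}
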