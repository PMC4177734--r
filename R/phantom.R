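#' Tissue optical parameters
#'
#' Attenuation coefficients (1/µm), relative backscatter levels and speckle
#' flags per tissue class. Defaults are tuned so that the bone signal meets
#' the rendering noise floor at a depth of about half a millimetre, matching
#' the penetration of swept-source OCT into compact bone: with
#' `mu = 0.008/µm`, `backscatter = 0.3` and a noise floor of `1e-4`,
#' `0.3 * exp(-2 * 0.008 * z) = 1e-4` at `z = 500 µm`. The endosteum is
#' modelled as scattering twice as strongly as bone (in both backscatter and
#' attenuation), the perilymph as nearly transparent fluid, and air as empty.
#'
#' @param bone,endosteum,perilymph,air lists with elements `mu` (attenuation,
#'   1/µm), `backscatter` (arbitrary units on the renderer's dynamic range)
#'   and `speckle` (logical: does this class carry fully developed speckle).
#' @return a named list of per-class parameter lists, class `tissue_optics`.
#' @export
tissue_optics <- function(
    bone      = list(mu = 0.008,  backscatter = 0.3,  speckle = TRUE),
    endosteum = list(mu = 0.016,  backscatter = 0.6,  speckle = TRUE),
    perilymph = list(mu = 2e-4,   backscatter = 0.01, speckle = TRUE),
    air       = list(mu = 0,      backscatter = 0,    speckle = FALSE)) {
  cls <- list(air = air, bone = bone, endosteum = endosteum, perilymph = perilymph)
  for (nm in names(cls)) {
    p <- cls[[nm]]
    stopifnot(is.numeric(p$mu), p$mu >= 0, is.numeric(p$backscatter),
              p$backscatter >= 0, is.logical(p$speckle))
  }
  structure(cls, class = "tissue_optics")
}

#' Construct a digital cochlea phantom
#'
#' Builds the ground-truth tissue geometry the closed loop runs against: a
#' (by default flat) air-bone top surface `z_b(x, y)`, and beneath it the
#' outer boundary of the endosteum `z_e(x, y)` shaped as a spherical cap that
#' is convex towards the surface (shallowest at the apex over the channel
#' centre, deeper towards the rim - the curvature of the cochlear wall seen
#' from outside). The endosteum is a thin layer of constant thickness `t_e`
#' below `z_e`; everything deeper is perilymph. Depth `z` increases into the
#' tissue, with 0 at the undisturbed bone surface plane.
#'
#' @param params a list with elements
#'   \describe{
#'     \item{extent}{lateral field c(width_x, width_y) in µm (centred at 0).}
#'     \item{spacing}{ground-truth lateral grid step, µm (default 10).}
#'     \item{surface_depth}{depth of the flat initial bone surface, µm
#'       (default 0).}
#'     \item{surface_tilt}{optional c(sx, sy) slope in µm per µm applied to
#'       the initial surface (default c(0, 0)).}
#'     \item{apex_depth}{depth of the boundary apex below z = 0, µm.}
#'     \item{curvature_radius}{radius of the spherical-cap boundary, µm;
#'       `Inf` gives a plane parallel to the surface.}
#'     \item{t_e}{endosteum thickness, µm, must be < 50.}
#'     \item{channel_center}{lateral position of the cochleostomy centre
#'       (and the boundary apex), µm (default c(0, 0)).}
#'     \item{optics}{a [tissue_optics()] record.}
#'   }
#' @param seed integer; stored for provenance. The geometry is deterministic,
#'   the seed governs downstream speckle realizations only.
#' @return an object of class `Phantom`: lateral grids `x`, `y`, height maps
#'   `zb` (air-bone surface) and `ze` (bone-endosteum boundary), `t_e`,
#'   `optics`, rigid `pose`, and the `critical_hit` flag.
#' @examples
#' ph <- make_phantom(list(apex_depth = 1200, curvature_radius = 1500,
#'                         t_e = 40), seed = 1)
#' # ground-truth bone thickness at the apex equals the apex depth
#' phantom_thickness(ph, 0, 0)
#' @export
make_phantom <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    extent = c(1400, 1400), spacing = 10, surface_depth = 0,
    surface_tilt = c(0, 0), apex_depth = 1200, curvature_radius = 1500,
    t_e = 40, channel_center = c(0, 0), optics = tissue_optics()), params)
  stopifnot(all(p$extent > 0), p$spacing > 0, p$apex_depth > 0,
            p$curvature_radius > 0, p$t_e > 0)
  if (p$t_e >= 50)
    stop("endosteum thickness t_e must be below 50 um", call. = FALSE)
  x <- seq(-p$extent[1] / 2, p$extent[1] / 2, by = p$spacing)
  y <- seq(-p$extent[2] / 2, p$extent[2] / 2, by = p$spacing)
  zb <- outer(x, y, function(xx, yy)
    p$surface_depth + p$surface_tilt[1] * xx + p$surface_tilt[2] * yy)
  r2 <- outer(x - p$channel_center[1], y - p$channel_center[2],
              function(xx, yy) xx^2 + yy^2)
  if (is.finite(p$curvature_radius)) {
    R <- p$curvature_radius
    sag <- R - sqrt(pmax(R^2 - pmin(r2, R^2), 0))
    ze <- p$surface_depth + p$apex_depth + sag
  } else {
    ze <- matrix(p$surface_depth + p$apex_depth, length(x), length(y))
  }
  if (!all(ze > zb))
    stop("inconsistent geometry: boundary must lie strictly below the surface",
         call. = FALSE)
  structure(list(
    x = x, y = y, zb = zb, ze = ze, t_e = p$t_e, optics = p$optics,
    pose = rigid_transform(), critical_hit = FALSE, reflectors = NULL,
    spacing = p$spacing, channel_center = p$channel_center,
    params = p, seed = as.integer(seed)), class = "Phantom")
}

#' @export
print.Phantom <- function(x, ...) {
  cat(sprintf("Phantom: %.0f x %.0f um field (grid %.0f um), apex depth %.0f um, t_e %.0f um\n",
              diff(range(x$x)), diff(range(x$y)), min(x$ze) - min(x$zb), x$t_e))
  cat(sprintf("  bone surface depth range [%.1f, %.1f] um; critical hit: %s\n",
              min(x$zb), max(x$zb), x$critical_hit))
  invisible(x)
}

# interpolated height maps in the phantom frame
phantom_height <- function(phantom, xq, yq, what = c("bone", "boundary", "perilymph")) {
  what <- match.arg(what)
  Z <- switch(what, bone = phantom$zb, boundary = phantom$ze,
              perilymph = phantom$ze + phantom$t_e)
  interp_bilinear(phantom$x, phantom$y, Z, xq, yq)
}

#' Ground-truth residual bone thickness
#'
#' Distance along the optical axis from the current channel bottom to the
#' bone-endosteum boundary, in the phantom frame.
#'
#' @param phantom a [make_phantom()] object.
#' @param x,y lateral query coordinates, µm.
#' @return thickness in µm (vector).
#' @export
phantom_thickness <- function(phantom, x, y) {
  phantom_height(phantom, x, y, "boundary") - phantom_height(phantom, x, y, "bone")
}

#' Apply one laser pulse to the phantom
#'
#' Deepens the bone surface by an additive Gaussian crater
#' `d(r) = d0 * exp(-2 r^2 / w0^2)` with `w0 = 100` µm (the 1/e^2 radius of
#' the 200 µm TEM00 spot) and a centre depth of 1 µm per µs of pulse
#' duration, linearly mapping the tunable 20-100 µs durations onto the
#' 20-100 µm single-pulse ablation depths. Overlapping craters add. The
#' bottom is clipped at the perilymph boundary `z_e + t_e`; any crater
#' reaching past `z_e` (into the endosteum) raises the phantom's
#' `critical_hit` flag.
#'
#' @param phantom a `Phantom`.
#' @param position lateral pulse centre c(x, y), µm, in the phantom frame.
#' @param duration pulse duration in µs, within [20, 100].
#' @param spot_radius 1/e^2 crater radius w0, µm.
#' @param depth_per_us crater centre depth per µs of duration.
#' @return the updated `Phantom`.
#' @export
apply_pulse <- function(phantom, position, duration, spot_radius = 100,
                        depth_per_us = 1) {
  stopifnot(inherits(phantom, "Phantom"), length(position) == 2L)
  if (!is.finite(duration) || duration < 20 || duration > 100)
    stop("pulse duration must lie within [20, 100] us", call. = FALSE)
  if (position[1] < min(phantom$x) || position[1] > max(phantom$x) ||
      position[2] < min(phantom$y) || position[2] > max(phantom$y))
    stop("pulse position outside the phantom field", call. = FALSE)
  d0 <- duration * depth_per_us
  # restrict the update to a 4*w0 box around the centre (crater < 1e-13 d0 outside)
  ix <- which(abs(phantom$x - position[1]) <= 4 * spot_radius)
  iy <- which(abs(phantom$y - position[2]) <= 4 * spot_radius)
  r2 <- outer(phantom$x[ix] - position[1], phantom$y[iy] - position[2],
              function(xx, yy) xx^2 + yy^2)
  crater <- d0 * exp(-2 * r2 / spot_radius^2)
  zb_new <- phantom$zb[ix, iy, drop = FALSE] + crater
  ze_loc <- phantom$ze[ix, iy, drop = FALSE]
  if (any(zb_new > ze_loc)) phantom$critical_hit <- TRUE
  phantom$zb[ix, iy] <- pmin(zb_new, ze_loc + phantom$t_e)
  phantom
}

#' Displace the phantom rigidly
#'
#' Composes the given transform with the phantom pose; subsequent renders
#' see the moved tissue. Emulates relative patient/optics displacements.
#'
#' @param phantom a `Phantom`.
#' @param transform a [rigid_transform()] (angles < 5 degrees).
#' @return the updated `Phantom`.
#' @export
apply_displacement <- function(phantom, transform) {
  stopifnot(inherits(phantom, "Phantom"), inherits(transform, "RigidTransform"))
  phantom$pose <- compose_transform(transform, phantom$pose)
  phantom
}

#' Add isolated point reflectors to a phantom
#'
#' Point reflectors are rendered as impulses before PSF blurring and serve
#' to measure the imaging point-spread function.
#'
#' @param phantom a `Phantom`.
#' @param points data.frame with columns `x`, `y`, `z` (µm, phantom frame)
#'   and `amplitude`.
#' @return the updated `Phantom`.
#' @export
add_reflectors <- function(phantom, points) {
  stopifnot(inherits(phantom, "Phantom"),
            all(c("x", "y", "z", "amplitude") %in% names(points)))
  phantom$reflectors <- rbind(phantom$reflectors,
                              points[, c("x", "y", "z", "amplitude")])
  phantom
}
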