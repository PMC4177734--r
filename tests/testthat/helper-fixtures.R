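# Shared small fixtures. Geometries are kept tiny so the suite stays fast;
# the full-size study conditions live in test-acceptance.R.

# flat-surface phantom with a plane boundary at the given depth
flat_phantom <- function(depth, extent = c(700, 700), t_e = 40, ...) {
  make_phantom(list(extent = extent, apex_depth = depth,
                    curvature_radius = Inf, t_e = t_e, ...), seed = 1)
}

# small noise-free geometry
clean_geom <- function(fov = c(600, 600), zlim = c(-50, 1400), ...) {
  scan_geometry(fov = fov, spacing = c(20, 20, 6), zlim = zlim,
                speckle = FALSE, noise_floor = 0, ...)
}

# small speckled geometry with default noise
noisy_geom <- function(fov = c(600, 600), zlim = c(-50, 1400), ...) {
  scan_geometry(fov = fov, spacing = c(20, 20, 6), zlim = zlim, ...)
}

# n independent speckle renders of a static phantom
speckle_stack <- function(phantom, geom, n, seed0 = 100) {
  lapply(seq_len(n), function(s) render_oct(phantom, geom, seed = seed0 + s))
}

# empty (all-static) change masks for a volume list
static_masks <- function(vols) {
  d <- dim(vols[[1]]$I)
  rep(list(matrix(FALSE, d[1], d[2])), length(vols))
}

# synthetic piecewise Beer-Lambert A-scan volume (3 x 3 lateral copies)
layered_volume <- function(mu, b, breaks, zmax = 1200, dz = 6) {
  w <- seq(0, zmax, by = dz)
  lay <- findInterval(w, breaks) + 1L
  I <- b[lay] * exp(-2 * (cumsum(mu[lay] * dz) - mu[lay] * dz / 2))
  octguide:::oct_volume(array(rep(I, each = 9), c(3, 3, length(w))),
                        x = c(0, 20, 40), y = c(0, 20, 40), w = w,
                        spacing = c(20, 20, dz))
}
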