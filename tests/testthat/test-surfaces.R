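test_that("the air-bone surface is recovered within half a voxel noise-free", {
  ph <- make_phantom(list(extent = c(800, 800), surface_depth = 300,
                          apex_depth = 900, curvature_radius = Inf), seed = 1)
  v <- render_oct(ph, clean_geom(), seed = 1)
  s <- detect_bone_surface(v, 0.3)
  expect_true(all(s$valid))
  expect_lt(max(abs(s$z[s$valid] - 300)), 3)   # half an axial voxel
})

test_that("a 2-degree surface tilt is recovered within 0.2 degrees", {
  ph <- make_phantom(list(extent = c(900, 900), surface_depth = 300,
                          surface_tilt = c(tan(2 * pi / 180), 0),
                          apex_depth = 900, curvature_radius = Inf), seed = 1)
  v <- render_oct(ph, clean_geom(), seed = 1)
  s <- detect_bone_surface(v, 0.3)
  df <- data.frame(z = as.vector(s$z),
                   x = rep(s$x, length(s$y)), y = rep(s$y, each = length(s$x)))
  tilt <- atan(stats::coef(stats::lm(z ~ x + y, df))[["x"]]) * 180 / pi
  expect_equal(tilt, 2, tolerance = 0.1)
})

test_that("speckled surface detection stays within the axial resolution", {
  ph <- flat_phantom(400)
  v <- render_oct(ph, noisy_geom(), seed = 9)
  s <- detect_bone_surface(v, 0.3)
  expect_lt(sqrt(mean(s$z[s$valid]^2)), 18)
  expect_error(detect_bone_surface(v, 2), "dynamic range")
  empty <- v
  empty$I[] <- 0
  expect_error(detect_bone_surface(empty, 0.3), "empty volume")
})

test_that("boundary candidates localize the noise-free boundary within a voxel", {
  ph <- flat_phantom(400)
  v <- render_oct(ph, clean_geom(), seed = 1)
  s <- detect_bone_surface(v, 0.3)
  cand <- segment_critical_boundary(compensate_attenuation(v), s)
  expect_gte(boundary_confidence(cand), 0.95)
  within1 <- mean(abs(cand$z - 400) <= 6)
  expect_gte(within1, 0.95)
  # all candidates lie strictly below the detected surface
  surf_at <- eval_surface(s, cand$x, cand$y)
  expect_true(all(cand$z > surf_at))
})

test_that("a boundary beyond the imaging depth is flagged invisible", {
  ph <- flat_phantom(700)
  v <- render_oct(ph, noisy_geom(), seed = 7)
  s <- detect_bone_surface(v, 0.3)
  cand <- segment_critical_boundary(compensate_attenuation(v), s)
  expect_lt(boundary_confidence(cand), 0.2)
  expect_error(fit_boundary_surface(cand), "fallback")
})

test_that("an unpenalized bicubic fit reproduces representable surfaces", {
  set.seed(3)
  kx <- octguide:::bs_knot_vector(-300, 300, 4)
  ky <- octguide:::bs_knot_vector(-300, 300, 4)
  coefs <- matrix(runif(49, 900, 1100), 7, 7)
  gx <- seq(-300, 300, by = 20)
  pts <- expand.grid(x = gx, y = gx)
  truth <- octguide:::eval_tensor_spline(
    list(coef = as.vector(coefs), knots = list(kx, ky)),
    cbind(pts$x, pts$y))
  cand <- structure(data.frame(x = pts$x, y = pts$y, z = truth,
                               grad = 1, frame = 1),
                    class = c("BoundaryCandidates", "data.frame"),
                    confidence = 1, n_ascans = nrow(pts))
  fit <- fit_boundary_surface(cand, knot_spacing = 150, smooth = 0)
  resid <- eval_surface(fit, pts$x, pts$y) - truth
  expect_lt(sqrt(mean(resid^2)), 1e-6)
})

test_that("the robust fit resists jitter and one-sided outliers", {
  # ground truth: spherical-cap boundary sampled over a disc; 10% of the
  # candidates are displaced 200 um deeper, the rest carry 10 um jitter
  set.seed(5)
  gx <- seq(-480, 480, by = 20)
  pts <- expand.grid(x = gx, y = gx)
  pts <- pts[pts$x^2 + pts$y^2 <= 500^2, ]
  truth <- 1200 + 1500 - sqrt(1500^2 - (pts$x^2 + pts$y^2))
  z <- truth + rnorm(nrow(pts), 0, 10)
  out <- sample(nrow(pts), round(0.1 * nrow(pts)))
  z[out] <- z[out] + 200
  cand <- structure(data.frame(x = pts$x, y = pts$y, z = z, grad = 1, frame = 1),
                    class = c("BoundaryCandidates", "data.frame"),
                    confidence = 1, n_ascans = nrow(pts))
  fit <- fit_boundary_surface(cand)
  err <- eval_surface(fit, pts$x, pts$y) - truth
  expect_lt(sqrt(mean(err^2)), 10)
})

test_that("frames without candidates are bridged by neighbouring frames", {
  set.seed(6)
  gx <- seq(-300, 300, by = 20)
  pts <- expand.grid(x = gx, y = gx)
  truth <- 1000 + 0.1 * pts$x + 0.05 * pts$y
  keep <- pts$y != 0        # one frame entirely missing
  cand <- structure(data.frame(x = pts$x[keep], y = pts$y[keep],
                               z = truth[keep], grad = 1, frame = 1),
                    class = c("BoundaryCandidates", "data.frame"),
                    confidence = 1, n_ascans = sum(keep))
  fit <- fit_boundary_surface(cand)
  at0 <- eval_surface(fit, gx, rep(0, length(gx)))
  expect_lt(max(abs(at0 - (1000 + 0.1 * gx))), 1)
})

test_that("the stop surface is an exact offset of the boundary", {
  set.seed(8)
  gx <- seq(-300, 300, by = 30)
  pts <- expand.grid(x = gx, y = gx)
  z <- 1000 + 30 * sin(pts$x / 100) + rnorm(nrow(pts), 0, 5)
  cand <- structure(data.frame(x = pts$x, y = pts$y, z = z, grad = 1, frame = 1),
                    class = c("BoundaryCandidates", "data.frame"),
                    confidence = 1, n_ascans = nrow(pts))
  bnd <- fit_boundary_surface(cand)
  stop_s <- make_stop_surface(bnd, 100)
  qx <- runif(1e4, -300, 300); qy <- runif(1e4, -300, 300)
  dev <- eval_surface(bnd, qx, qy) - 100 - eval_surface(stop_s, qx, qy)
  expect_lt(max(abs(dev)), 1e-9)
  expect_error(make_stop_surface(bnd, -5), "non-negative")
  # offset zero is the identity
  same <- make_stop_surface(bnd, 0)
  expect_equal(eval_surface(same, qx[1:50], qy[1:50]),
               eval_surface(bnd, qx[1:50], qy[1:50]))
})

test_that("thickness and penetration decompose the stop-bottom distance", {
  x <- seq(-320, 320, by = 20); y <- x
  bottom <- surface_grid(x, y, matrix(200, length(x), length(y)))
  stop1 <- surface_grid(x, y, matrix(500, length(x), length(y)))
  tm <- thickness_map(bottom, stop1, list(center = c(0, 0), diameter = 600))
  expect_true(all(tm$thickness[tm$mask] == 300))
  expect_true(all(tm$penetration[tm$mask] == 0))

  bottom2 <- surface_grid(x, y, matrix(510, length(x), length(y)))
  tm2 <- thickness_map(bottom2, stop1, list(center = c(0, 0), diameter = 600))
  expect_true(all(tm2$thickness[tm2$mask] == 0))
  expect_true(all(tm2$penetration[tm2$mask] == 10))

  # exact decomposition on a random pair of surfaces
  set.seed(10)
  zb <- matrix(rnorm(length(x)^2, 400, 80), length(x))
  zs <- matrix(rnorm(length(x)^2, 420, 80), length(x))
  tm3 <- thickness_map(surface_grid(x, y, zb), surface_grid(x, y, zs),
                       list(center = c(0, 0), diameter = 600))
  expect_equal(tm3$thickness - tm3$penetration, zs - zb, tolerance = 1e-12)
  expect_true(all(tm3$thickness * tm3$penetration == 0))

  # invalid surface inside the mask is an error
  bad <- surface_grid(x, y, zb, valid = matrix(FALSE, length(x), length(y)))
  expect_error(thickness_map(bad, stop1,
                             list(center = c(0, 0), diameter = 600)),
               "invalid")
})

test_that("thickness against a curved phantom matches ground truth", {
  ph <- make_phantom(list(extent = c(900, 900), apex_depth = 350,
                          curvature_radius = 1500), seed = 1)
  v <- render_oct(ph, clean_geom(fov = c(800, 800)), seed = 1)
  s <- detect_bone_surface(v, 0.3)
  cand <- segment_critical_boundary(compensate_attenuation(v), s)
  bnd <- fit_boundary_surface(cand)
  stop_s <- make_stop_surface(bnd, 100)
  tm <- thickness_map(s, stop_s, list(center = c(0, 0), diameter = 500))
  nx <- length(tm$x)
  X <- rep(tm$x, length(tm$y)); Y <- rep(tm$y, each = nx)
  truth <- pmax(octguide:::interp_bilinear(ph$x, ph$y, ph$ze, X, Y) - 100 -
                octguide:::interp_bilinear(ph$x, ph$y, ph$zb, X, Y), 0)
  err <- (tm$thickness - matrix(truth, nx))[tm$mask]
  expect_lt(sqrt(mean(err^2)), 6)   # one axial voxel RMS
})

test_that("the fallback virtual structure parallels the original surface", {
  x <- seq(-300, 300, by = 20); y <- x
  z <- outer(x, y, function(a, b) 5 + 0.02 * a)
  orig <- surface_grid(x, y, z)
  virt <- fallback_virtual_structure(orig, 1e6)
  expect_equal(virt$z, z + 1e6)
  virt2 <- fallback_virtual_structure(orig, 500)
  expect_equal(eval_surface(virt2, 100, -40) - eval_surface(orig, 100, -40), 500)
})
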