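test_that("landmark rings are symmetric and validated", {
  lm <- plan_landmarks(channel_center = c(10, -20), ring_radius = 800,
                       count = 4)
  expect_equal(attr(lm, "centroid"), c(10, -20), tolerance = 1e-9)
  lm6 <- plan_landmarks(count = 6)
  ang <- sort(atan2(lm6$y, lm6$x))
  expect_equal(diff(ang), rep(pi / 3, 5), tolerance = 1e-9)
  expect_error(plan_landmarks(count = 2), "at least 3")
  expect_error(plan_landmarks(ring_radius = 550), "overlaps")
})

test_that("noise-free crater centres are localized within 5 um", {
  ph <- make_phantom(list(extent = c(2600, 2600), apex_depth = 1200), seed = 1)
  lm <- plan_landmarks(ring_radius = 800, count = 4)
  ph <- ablate_landmarks(ph, lm)
  g <- clean_geom(fov = c(2500, 2500), zlim = c(-80, 320))
  det <- localize_landmarks(render_oct(ph, g, seed = 1), lm)
  expect_true(all(det$valid))
  expect_lt(max(sqrt((det$x - lm$x)^2 + (det$y - lm$y)^2)), 5)

  # a landmark outside the field of view is flagged invalid
  far <- rbind(lm, data.frame(x = 5000, y = 0, z = 0))
  det2 <- localize_landmarks(render_oct(ph, g, seed = 1), far)
  expect_false(det2$valid[5])
  expect_true(all(det2$valid[1:4]))
})

test_that("speckled localization stays within half the lateral resolution", {
  ph <- make_phantom(list(extent = c(2600, 2600), apex_depth = 1200), seed = 1)
  lm <- plan_landmarks(ring_radius = 800, count = 4)
  ph <- ablate_landmarks(ph, lm)
  g <- noisy_geom(fov = c(2500, 2500), zlim = c(-80, 320))
  errs <- unlist(lapply(1:3, function(s) {
    det <- localize_landmarks(render_oct(ph, g, seed = 30 + s), lm)
    sqrt((det$x - lm$x)^2 + (det$y - lm$y)^2)
  }))
  expect_lt(sqrt(mean(errs^2)), 17.5)
})

test_that("rigid recovery is exact for noise-free correspondences", {
  ref <- data.frame(x = c(800, 0, -800, 0), y = c(0, 800, 0, -800), z = 0)
  det <- ref
  tr0 <- estimate_displacement(ref, det)
  expect_equal(tr0$t, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(tr0$R, diag(3), tolerance = 1e-12)
  expect_equal(max(attr(tr0, "residuals")), 0, tolerance = 1e-9)

  truth <- rigid_transform(c(50, -30, 20), c(0.004, -0.002, 0.01))
  det2 <- as.data.frame(transform_points(truth, as.matrix(ref)))
  names(det2) <- c("x", "y", "z")
  tr <- estimate_displacement(ref, det2)
  expect_equal(tr$t, truth$t, tolerance = 1e-6)
  expect_equal(tr$R, truth$R, tolerance = 1e-9)

  # fewer than 3 valid points or collinear layouts lose tracking
  bad <- det2; bad$valid <- c(TRUE, TRUE, FALSE, FALSE)
  expect_error(estimate_displacement(ref, bad), "tracking lost")
  lin <- data.frame(x = c(0, 100, 200, 300), y = 0, z = 0)
  expect_error(estimate_displacement(lin, lin), "tracking lost")
})

test_that("displacement estimation is rotation-equivariant", {
  set.seed(31)
  ref <- data.frame(x = rnorm(5, sd = 500), y = rnorm(5, sd = 500), z = 0)
  truth <- rigid_transform(c(40, -10, 5), c(0, 0, 0.02))
  det <- as.data.frame(transform_points(truth, as.matrix(ref)))
  names(det) <- c("x", "y", "z")
  pre <- rigid_transform(angles = c(0, 0, 0.03))
  ref2 <- as.data.frame(transform_points(pre, as.matrix(ref)))
  det2 <- as.data.frame(transform_points(pre, as.matrix(det)))
  names(ref2) <- names(det2) <- c("x", "y", "z")
  t1 <- estimate_displacement(ref, det)
  t2 <- estimate_displacement(ref2, det2)
  expect_equal(t2$R, pre$R %*% t1$R %*% t(pre$R), tolerance = 1e-9)
})

test_that("pure rotations are not amplified at the layout centroid", {
  ref <- as.data.frame(plan_landmarks(count = 4))
  truth <- rigid_transform(angles = c(0, 0, 0.02))
  det <- as.data.frame(transform_points(truth, as.matrix(ref)))
  names(det) <- c("x", "y", "z")
  set.seed(32)
  noise <- matrix(rnorm(12, 0, 8), 4, 3)
  detn <- det + noise
  tr <- estimate_displacement(ref, detn)
  # error at the channel centre (the centroid) vs mean landmark noise
  centre_err <- sqrt(sum((transform_points(tr, cbind(0, 0, 0)) -
                          transform_points(truth, cbind(0, 0, 0)))^2))
  expect_lte(centre_err, mean(sqrt(rowSums(noise^2))))
})

test_that("motion correction maps plans onto the displaced tissue", {
  plan <- structure(data.frame(x = c(0, 200), y = c(0, 100), duration = 60,
                               class = "middle", energy = pulse_energy(60),
                               order = 1:2),
                    class = c("PulsePlan", "data.frame"),
                    spacing = 150, round_index = 1L)
  idt <- apply_correction(plan, rigid_transform())
  expect_equal(idt$x, plan$x)
  tr <- rigid_transform(c(100, 0, 0))
  out <- apply_correction(plan, tr)
  expect_equal(out$x, plan$x + 100)
  expect_equal(out$y, plan$y)
  expect_equal(out$duration, plan$duration)
  # pulses leaving the working space are dropped
  ws <- list(x = c(-150, 150), y = c(-150, 150))
  expect_message(out2 <- apply_correction(plan, tr, working_space = ws),
                 "dropping")
  expect_equal(nrow(out2), 1L)
})

test_that("corrected pulses land on the intended tissue after displacement", {
  ph <- make_phantom(list(extent = c(2600, 2600), apex_depth = 1200), seed = 1)
  lm <- plan_landmarks(ring_radius = 800, count = 4)
  ph <- ablate_landmarks(ph, lm)
  g <- noisy_geom(fov = c(2500, 2500), zlim = c(-80, 320))
  ref <- localize_landmarks(render_oct(ph, g, seed = 41), lm)
  disp <- c(120, -60, 0)
  phd <- apply_displacement(ph, rigid_transform(disp))
  det <- localize_landmarks(render_oct(phd, g, seed = 42), ref)
  tr <- estimate_displacement(ref, det)
  # a pulse intended for tissue point p must now be fired at p + disp
  intended <- cbind(c(0, 150, -80), c(0, -60, 40))
  corrected <- transform_points(tr, cbind(intended, 0))[, 1:2]
  err_corr <- sqrt(rowSums((corrected -
                            sweep(intended, 2, disp[1:2], `+`))^2))
  expect_lt(max(err_corr), 30)
  err_unc <- sqrt(sum(disp^2))
  expect_gt(err_unc, 100)
})
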