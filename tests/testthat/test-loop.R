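# a small, fast noise-free configuration: flat boundary 160 um below a flat
# surface, 400 um channel, short pulses only
small_cfg <- function(seed = 5, ...) {
  loop_config(seed = seed, target = 100, channel_diameter = 400,
              geometry = list(fov = c(800, 800), spacing = c(20, 20, 6),
                              zlim = c(-60, 420), speckle = FALSE,
                              noise_floor = 0),
              planning = plan_constraints(spacing = 100, margin = 10,
                                          collateral = TRUE,
                                          overshoot_allowance = 30,
                                          class_durations = c(20, 20, 20)),
              ...)
}
small_phantom <- function() {
  make_phantom(list(extent = c(900, 900), apex_depth = 160,
                    curvature_radius = Inf), seed = 1)
}

test_that("a noise-free flat layer converges within the arithmetic bound", {
  res <- run_loop(small_cfg(), small_phantom())
  bound <- ceiling((160 - 100) / 20) + 2
  expect_identical(res$termination, "converged")
  expect_lte(res$n_rounds, bound)
  expect_false(res$eval_gt$critical_hit)
  expect_lt(res$eval_gt$mean_abs, 20)
})

test_that("identical configuration and seed reproduce the loop exactly", {
  r1 <- run_loop(small_cfg(), small_phantom())
  r2 <- run_loop(small_cfg(), small_phantom())
  expect_identical(r1$termination, r2$termination)
  expect_identical(r1$n_rounds, r2$n_rounds)
  expect_identical(r1$phantom_final$zb, r2$phantom_final$zb)
  expect_equal(r1$eval_gt$mean_abs, r2$eval_gt$mean_abs, tolerance = 1e-12)
  # a different seed gives a different (but valid) result under speckle
  cfgx <- small_cfg(); cfgx$geometry$speckle <- TRUE
  cfgy <- small_cfg(seed = 6); cfgy$geometry$speckle <- TRUE
  rx <- run_loop(cfgx, small_phantom())
  ry <- run_loop(cfgy, small_phantom())
  expect_false(identical(rx$phantom_final$zb, ry$phantom_final$zb))
})

test_that("ground-truth excess above the stop surface never increases", {
  res <- run_loop(small_cfg(), small_phantom())
  gx <- vapply(res$rounds, function(r) r$gt_excess_max, numeric(1))
  expect_true(all(diff(gx) <= 1e-9))
})

test_that("every applied pulse is accounted for in exactly one round's plan", {
  res <- run_loop(small_cfg(), small_phantom())
  plans <- lapply(res$rounds, function(r) r$plan)
  plans <- plans[!vapply(plans, is.null, logical(1))]
  all_pulses <- do.call(rbind, plans)
  expect_equal(nrow(all_pulses),
               sum(vapply(res$rounds, function(r) r$n_pulses, numeric(1))))
  # removed volume matches the nominal crater volume of the applied plan
  removed <- sum(res$phantom_final$zb - small_phantom()$zb) *
    res$phantom_final$spacing^2
  nominal <- sum(all_pulses$duration) * pi * 100^2 / 2
  expect_equal(removed, nominal, tolerance = 0.02)
})

test_that("a run without a critical hit leaves the endosteum intact", {
  res <- run_loop(small_cfg(), small_phantom())
  expect_false(res$phantom_final$critical_hit)
  expect_true(all(res$phantom_final$zb < res$phantom_final$ze))
})

test_that("an invisible boundary keeps the loop in guarded fallback mode", {
  ph <- make_phantom(list(extent = c(900, 900), apex_depth = 900,
                          curvature_radius = Inf), seed = 1)
  cfg <- small_cfg(max_rounds = 3)
  res <- run_loop(cfg, ph)
  expect_identical(res$termination, "max_rounds")
  expect_true(all(vapply(res$rounds, function(r) r$mode, character(1)) ==
                  "fallback"))
  # fallback digs a bottom parallel to the original surface
  mask <- make_channel_mask(res$phantom_final$x, res$phantom_final$y,
                            c(0, 0), 300)
  dug <- (res$phantom_final$zb - ph$zb)[mask]
  expect_gt(mean(dug), 20)
  expect_lt(stats::sd(dug), 15)
})

test_that("the loop tracks and corrects injected displacements", {
  cfg <- small_cfg(seed = 9,
                   tracking = list(enabled = TRUE, jitter_sd = 25,
                                   ring_radius = 700))
  cfg$geometry$fov <- c(1700, 1700)
  ph <- make_phantom(list(extent = c(1800, 1800), apex_depth = 160,
                          curvature_radius = Inf), seed = 1)
  res <- run_loop(cfg, ph)
  expect_identical(res$termination, "converged")
  expect_false(res$eval_gt$critical_hit)
  # the recorded corrections are genuine (non-identity) rigid transforms
  trs <- lapply(res$rounds, function(r) r$transform)
  trs <- trs[!vapply(trs, is.null, logical(1))]
  expect_gt(length(trs), 0)
  expect_true(any(vapply(trs, function(t) sqrt(sum(t$t^2)) > 5, logical(1))))
  # accuracy survives the motion (same order as the static run)
  expect_lt(res$eval_gt$mean_abs, 30)
})

test_that("evaluation reports match brute-force per-position arithmetic", {
  ph <- small_phantom()
  stop_gt <- surface_grid(ph$x, ph$y, ph$ze - 100)
  ev0 <- evaluate_result(ph, stop_gt, list(center = c(0, 0), diameter = 400))
  # untouched phantom: bottom is 60 above the stop everywhere
  expect_equal(ev0$mean_abs, 60, tolerance = 1e-9)
  expect_equal(ev0$max_penetration, 0)

  # overshoot case: bottom 10 below the stop everywhere
  ph2 <- ph
  ph2$zb <- ph$ze - 90
  ev2 <- evaluate_result(ph2, stop_gt, list(center = c(0, 0), diameter = 400))
  expect_equal(ev2$mean_abs, 10, tolerance = 1e-9)
  expect_equal(ev2$max_penetration, 10, tolerance = 1e-9)

  # random bottom: error map equals brute-force subtraction
  set.seed(12)
  ph3 <- ph
  ph3$zb <- ph$ze - 100 + matrix(rnorm(length(ph$zb), 0, 15), nrow(ph$zb))
  mask <- make_channel_mask(ph$x, ph$y, c(0, 0), 400)
  ev3 <- evaluate_result(ph3, stop_gt, mask)
  brute <- (ph3$zb - (ph$ze - 100))[mask]
  expect_equal(sort(ev3$errors$error), sort(brute), tolerance = 1e-12)
  expect_equal(ev3$mean_abs, mean(abs(brute)), tolerance = 1e-12)
  expect_equal(ev3$max_penetration, max(pmax(brute, 0)), tolerance = 1e-12)
})

test_that("the analytic foresight bound reflects the imaging physics", {
  expect_identical(foresight_bound(500, 100), 5)
  expect_identical(foresight_bound(450, 100), 4)
})
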