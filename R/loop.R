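#' Closed-loop configuration
#'
#' Assembles and validates all parameter blocks of the control loop. Every
#' block can be partially overridden; unset entries keep their defaults.
#'
#' @param target target residual-layer thickness above the boundary, µm.
#' @param tolerance termination tolerance: the loop stops once the measured
#'   residual thickness is at most this everywhere on the channel, µm.
#' @param max_rounds hard round limit.
#' @param channel_center,channel_diameter cochleostomy location and size, µm.
#' @param seed master seed; every render and every jitter draw derives its
#'   seed from it.
#' @param geometry argument list for [scan_geometry()].
#' @param enhance list: `exponent`, `floor` (attenuation compensation),
#'   `history_window` (rounds of history kept for compounding),
#'   `change_dilate` (radius around a pulse marked as changed, µm).
#' @param surfaces list: `threshold`, `smooth_radius` (surface detection),
#'   `boundary` (overrides for [boundary_opts()]), `knot_spacing`,
#'   `iterations` (boundary fit), `confidence` (visibility gate in [0, 1]).
#' @param planning a [plan_constraints()] list; defaults to collateral-aware
#'   planning with the margin equal to the termination tolerance.
#' @param overcut radial extension of the planned region beyond the channel
#'   mask, µm. The 200 µm spot cannot produce a vertical wall, so the wall
#'   cone is placed outside the evaluated channel bottom by planning pulses
#'   in an annulus around it.
#' @param fallback list: `nominal_depth` of the virtual structure and
#'   `max_total_depth` safety stop below the original surface, µm.
#' @param termination_quantile fraction of channel positions required below
#'   tolerance (1 = strict).
#' @param tracking list: `enabled`, `jitter_sd` (per-round lateral
#'   displacement scale, µm), `ring_radius`, `count`, `working_space`.
#' @param store_volumes keep every acquired volume in the result (memory!).
#' @return a list of class `LoopConfig`.
#' @export
loop_config <- function(target = 100, tolerance = 10, max_rounds = 50,
                        channel_center = c(0, 0), channel_diameter = 1000,
                        seed = 1L,
                        geometry = list(), enhance = list(),
                        surfaces = list(), planning = NULL, overcut = 150,
                        fallback = list(), termination_quantile = 0.99,
                        tracking = list(), store_volumes = FALSE) {
  stopifnot(target >= 0, tolerance >= 0, max_rounds >= 1,
            channel_diameter > 0)
  geometry <- utils::modifyList(list(fov = c(1400, 1400),
                                     spacing = c(20, 20, 6),
                                     zlim = c(-100, 1500)), geometry)
  enhance <- utils::modifyList(list(exponent = 2, floor = 1e-6,
                                    history_window = 8, change_dilate = 200),
                               enhance)
  surfaces <- utils::modifyList(list(threshold = 0.3, smooth_radius = 1,
                                     boundary = list(), knot_spacing = 150,
                                     iterations = 5, confidence = 0.5),
                                surfaces)
  planning <- planning %||% plan_constraints(margin = tolerance,
                                             collateral = TRUE,
                                             overshoot_allowance = 30)
  fallback <- utils::modifyList(list(nominal_depth = 1e6,
                                     max_total_depth = 2000), fallback)
  tracking <- utils::modifyList(list(enabled = FALSE, jitter_sd = 0,
                                     ring_radius = 800, count = 4,
                                     working_space = NULL), tracking)
  structure(list(target = target, tolerance = tolerance,
                 max_rounds = max_rounds, channel_center = channel_center,
                 channel_diameter = channel_diameter, seed = as.integer(seed),
                 geometry = geometry, enhance = enhance, surfaces = surfaces,
                 planning = planning, overcut = overcut, fallback = fallback,
                 termination_quantile = termination_quantile,
                 tracking = tracking, store_volumes = store_volumes),
            class = "LoopConfig")
}

# derived seed for round r, purpose offset p; kept inside 32-bit range
round_seed <- function(seed, r, p = 0L) {
  (as.numeric(seed) + 1009 * r + 104729 * p) %% 2147483647
}

#' Run the closed control loop
#'
#' Alternates laser ablation and OCT scanning against the phantom: each
#' round acquires a volume, compounds it with usable history, detects the
#' air-bone surface, compensates attenuation, segments the subsurface
#' boundary, derives the stop surface (fitted boundary minus the target
#' standoff if the segmentation is confident, otherwise the fallback
#' virtual structure parallel to the original surface), computes the
#' residual-thickness map, tests termination, plans the next pulse pattern,
#' corrects it for any tracked displacement, and ablates. The loop halts on
#' convergence, the round limit, lost tracking, or a critical-structure
#' hit - never silently.
#'
#' @param config a [loop_config()].
#' @param phantom a [make_phantom()] object covering the channel region.
#' @return an object of class `LoopResult`: per-round records, the
#'   termination reason (`converged`, `max_rounds`, `tracking_lost` or
#'   `critical_hit`), the final phantom, the final detected surfaces, and
#'   evaluation reports against ground truth and against the detected
#'   surfaces.
#' @export
run_loop <- function(config, phantom) {
  stopifnot(inherits(config, "LoopConfig"), inherits(phantom, "Phantom"))
  cfg <- config
  geom <- do.call(scan_geometry, cfg$geometry)
  bopts <- utils::modifyList(
    boundary_opts(channel_center = cfg$channel_center,
                  channel_diameter = cfg$channel_diameter),
    cfg$surfaces$boundary)

  hist_vols <- list(); hist_rounds <- integer(0)
  pulse_masks <- list()          # per round: lateral change discs
  original_surface <- NULL
  rounds <- list()
  termination <- "max_rounds"
  final <- NULL

  # landmark tracking setup
  landmarks <- NULL; reference <- NULL
  if (isTRUE(cfg$tracking$enabled)) {
    landmarks <- plan_landmarks(cfg$channel_center,
                                ring_radius = cfg$tracking$ring_radius,
                                count = cfg$tracking$count,
                                channel_diameter = cfg$channel_diameter)
    phantom <- ablate_landmarks(phantom, landmarks)
    ref_vol <- render_oct(phantom, geom, seed = round_seed(cfg$seed, 0L, 2L),
                          acq_index = 0L)
    reference <- localize_landmarks(
      ref_vol, landmarks, threshold = cfg$surfaces$threshold,
      exclude = list(center = cfg$channel_center,
                     diameter = cfg$channel_diameter + 2 * (cfg$overcut + 100)))
    if (sum(reference$valid) < 3L)
      stop("landmark reference acquisition failed", call. = FALSE)
  }

  mask_cache <- NULL
  for (r in seq_len(cfg$max_rounds)) {
    vol <- render_oct(phantom, geom, seed = round_seed(cfg$seed, r),
                      acq_index = r)
    if (is.null(mask_cache)) {
      mask_cache <- make_channel_mask(vol$x, vol$y, cfg$channel_center,
                                      cfg$channel_diameter)
      mask_plan <- make_channel_mask(vol$x, vol$y, cfg$channel_center,
                                     cfg$channel_diameter + 2 * cfg$overcut)
    }

    # usable history: volumes from recent rounds, masked where ablated since
    if (length(hist_vols) > 0) {
      masks <- lapply(hist_rounds, function(r0) {
        m <- matrix(FALSE, length(vol$x), length(vol$y))
        for (pm in pulse_masks[seq_along(pulse_masks) >= r0]) m <- m | pm
        m
      })
      volc <- history_compound(vol, volume_history(hist_vols, masks))
    } else volc <- vol

    # monotone-ablation bound: the bottom cannot lie above last round's
    # bottom (minus a noise slack), which rejects wall-smeared reflexes
    min_depth <- if (r > 1L) bottom_z - 30 else NULL
    surf <- detect_bone_surface(volc, threshold = cfg$surfaces$threshold,
                                smooth_radius = cfg$surfaces$smooth_radius,
                                min_depth = min_depth)
    surf$valid <- is.finite(surf$z)   # smoothing inpaints isolated dropouts
    if (r == 1L) {
      original_surface <- surf
      pred_z <- surf$z    # dead-reckoned bottom: surface + applied craters
    }
    # channel-bottom estimate: the deeper of the detected surface and the
    # controller's own ablation ledger. Near the channel wall the reflex is
    # smeared across the lateral PSF and detection biases shallow; the
    # accumulated nominal crater depths bound the bottom from above there.
    bottom_z <- pmax(surf$z, pred_z)
    bottom <- surface_grid(vol$x, vol$y, bottom_z,
                           valid = is.finite(bottom_z))

    volz <- compensate_attenuation(volc, exponent = cfg$enhance$exponent,
                                   floor = cfg$enhance$floor)
    cand <- segment_critical_boundary(volz, bottom, bopts)
    conf <- boundary_confidence(cand)

    boundary <- NULL
    if (conf >= cfg$surfaces$confidence)
      boundary <- tryCatch(
        fit_boundary_surface(cand, knot_spacing = cfg$surfaces$knot_spacing,
                             iterations = cfg$surfaces$iterations,
                             min_confidence = cfg$surfaces$confidence),
        error = function(e) NULL)
    if (!is.null(boundary)) {
      mode <- "fitted"
      stop_surface <- make_stop_surface(boundary, cfg$target)
    } else {
      mode <- "fallback"
      stop_surface <- fallback_virtual_structure(original_surface,
                                                 cfg$fallback$nominal_depth)
    }
    tmap <- thickness_map(bottom, stop_surface, mask_cache)
    tmap_plan <- thickness_map(bottom, stop_surface, mask_plan)

    th <- tmap$thickness[tmap$mask]
    rec <- list(round = r, mode = mode, confidence = conf,
                thickness_max = max(th), thickness_mean = mean(th),
                gt_excess_max = max((phantom$ze - cfg$target - phantom$zb)[
                  make_channel_mask(phantom$x, phantom$y, cfg$channel_center,
                                    cfg$channel_diameter)]),
                n_pulses = 0L, transform = NULL,
                bottom_z = bottom_z, stop = stop_surface)
    if (cfg$store_volumes) rec$volume <- vol

    # termination judges the physical surface: both bottom and stop are
    # band-limited by the PSF and the 200 um spot, so the measured map is
    # smoothed to spot scale before the reached-all-over test (pointwise
    # excursions at the 20 um grid scale are measurement noise)
    tmap_term <- tmap
    sigma_vox <- 40 / vol$spacing[1]
    num <- gauss_blur3(array((tmap$thickness - tmap$penetration) * tmap$mask,
                             c(dim(tmap$mask), 1L)),
                       sigma_x = sigma_vox, sigma_y = sigma_vox)[, , 1]
    den <- gauss_blur3(array(tmap$mask * 1, c(dim(tmap$mask), 1L)),
                       sigma_x = sigma_vox, sigma_y = sigma_vox)[, , 1]
    sm_th <- num / pmax(den, 1e-9)
    tmap_term$thickness <- pmax(sm_th, 0)
    tmap_term$penetration <- pmax(-sm_th, 0)
    if (mode == "fitted" &&
        is_terminated(tmap_term, cfg$tolerance, cfg$termination_quantile)) {
      termination <- "converged"
      rounds[[r]] <- rec
      final <- list(bottom = bottom, stop = stop_surface, boundary = boundary,
                    thickness = tmap, confidence = conf)
      break
    }

    eligible <- NULL
    if (mode == "fallback") {
      depth_now <- bottom_z - original_surface$z
      eligible <- depth_now < cfg$fallback$max_total_depth
    }
    if (mode == "fitted") {
      # the fitted stop surface is extrapolation where no candidates lie
      # nearby; cap the measured thickness there so only cautious pulses
      # are planned against an unsupported stop estimate
      supp <- matrix(FALSE, length(vol$x), length(vol$y))
      ix <- round((cand$x - vol$x[1]) / vol$spacing[1]) + 1L
      iy <- round((cand$y - vol$y[1]) / vol$spacing[2]) + 1L
      supp[cbind(ix, iy)] <- TRUE
      rad <- ceiling(cfg$surfaces$knot_spacing / vol$spacing[1])
      supp <- morph_minmax(ifelse(supp, 1, 0), rad, "max") > 0
      cap <- cfg$planning$margin + cfg$planning$class_bounds[1]  # <= middle class
      tmap_plan$thickness[!supp & tmap_plan$thickness > cap] <- cap
    }
    plan <- plan_ablation(tmap_plan, cfg$planning, round_index = r,
                          eligible = eligible)

    # displacement injection and motion correction
    corrected <- plan
    if (isTRUE(cfg$tracking$enabled)) {
      t_scan <- tryCatch(
        estimate_displacement(reference, localize_landmarks(
          vol, reference, threshold = cfg$surfaces$threshold,
          exclude = list(center = cfg$channel_center,
                         diameter = cfg$channel_diameter +
                           2 * (cfg$overcut + 100)))),
        error = function(e) e)
      if (cfg$tracking$jitter_sd > 0) {
        jit <- with_seed(round_seed(cfg$seed, r, 3L),
                         stats::rnorm(2, 0, cfg$tracking$jitter_sd))
        phantom <- apply_displacement(phantom, rigid_transform(c(jit, 0)))
      }
      tvol <- render_oct(phantom, geom, seed = round_seed(cfg$seed, r, 4L),
                         acq_index = r)
      t_now <- tryCatch(
        estimate_displacement(reference, localize_landmarks(
          tvol, reference, threshold = cfg$surfaces$threshold,
          exclude = list(center = cfg$channel_center,
                         diameter = cfg$channel_diameter +
                           2 * (cfg$overcut + 100)))),
        error = function(e) e)
      if (inherits(t_scan, "error") || inherits(t_now, "error")) {
        termination <- "tracking_lost"
        rounds[[r]] <- rec
        final <- list(bottom = bottom, stop = stop_surface,
                      boundary = boundary, thickness = tmap,
                      confidence = conf)
        break
      }
      correction <- compose_transform(t_now, invert_transform(t_scan))
      rec$transform <- correction
      corrected <- apply_correction(plan, correction,
                                    working_space = cfg$tracking$working_space)
    }

    # ablate: convert world pulse positions into the phantom frame
    if (nrow(corrected) > 0) {
      inv <- invert_transform(phantom$pose)
      pos_ph <- transform_points(inv, cbind(corrected$x, corrected$y, 0))
      w0 <- 100   # 1/e^2 crater radius of the 200 um spot
      for (i in seq_len(nrow(corrected))) {
        phantom <- apply_pulse(phantom, pos_ph[i, 1:2], corrected$duration[i])
        # ledger update of the dead-reckoned bottom (nominal crater model)
        pred_z <- pred_z + corrected$duration[i] *
          outer(vol$x - corrected$x[i], vol$y - corrected$y[i],
                function(xx, yy) exp(-2 * (xx^2 + yy^2) / w0^2))
      }
    }
    rec$n_pulses <- nrow(corrected)
    rec$plan <- corrected
    rounds[[r]] <- rec

    # change mask of this round's pulses, dilated by the configured radius
    pm <- matrix(FALSE, length(vol$x), length(vol$y))
    if (nrow(corrected) > 0) {
      for (i in seq_len(nrow(corrected)))
        pm <- pm | outer(vol$x - corrected$x[i], vol$y - corrected$y[i],
                         function(xx, yy)
                           xx^2 + yy^2 <= cfg$enhance$change_dilate^2)
    }
    pulse_masks[[r]] <- pm

    hist_vols <- c(hist_vols, list(vol))
    hist_rounds <- c(hist_rounds, r)
    if (length(hist_vols) > cfg$enhance$history_window) {
      keep <- seq.int(length(hist_vols) - cfg$enhance$history_window + 1L,
                      length(hist_vols))
      hist_vols <- hist_vols[keep]; hist_rounds <- hist_rounds[keep]
    }

    if (phantom$critical_hit) {
      termination <- "critical_hit"
      final <- list(bottom = bottom, stop = stop_surface, boundary = boundary,
                    thickness = tmap, confidence = conf)
      break
    }
  }
  if (is.null(final))
    final <- list(bottom = bottom, stop = stop_surface, boundary = boundary,
                  thickness = tmap, confidence = conf)

  # ground-truth evaluation: final channel bottom vs ground-truth stop surface
  stop_gt <- surface_grid(phantom$x, phantom$y, phantom$ze - cfg$target)
  eval_gt <- evaluate_result(phantom, stop_gt,
                             list(center = cfg$channel_center,
                                  diameter = cfg$channel_diameter))
  # postoperative-scan emulation: detected bottom vs detected stop surface
  tm <- final$thickness
  signed <- (tm$penetration - tm$thickness)[tm$mask]
  eval_detected <- list(mean_abs = mean(abs(signed)), sd = stats::sd(signed),
                        max_penetration = max(tm$penetration[tm$mask]))

  structure(list(rounds = rounds, n_rounds = length(rounds),
                 termination = termination, phantom_final = phantom,
                 detected = final, eval_gt = eval_gt,
                 eval_detected = eval_detected, config = cfg),
            class = "LoopResult")
}

#' @export
print.LoopResult <- function(x, ...) {
  cat(sprintf("LoopResult: %d rounds, termination '%s'\n",
              x$n_rounds, x$termination))
  cat(sprintf("  ground truth vs stop surface: mean abs %.2f um (sd %.2f), max penetration %.2f um\n",
              x$eval_gt$mean_abs, x$eval_gt$sd, x$eval_gt$max_penetration))
  cat(sprintf("  critical-structure hit: %s\n", x$eval_gt$critical_hit))
  invisible(x)
}

#' Evaluate the final channel against a stop surface
#'
#' Strict whole-channel evaluation: per-position signed error between the
#' ground-truth channel bottom of the (final) phantom and the stop surface,
#' over the channel mask. Reported are the mean absolute error, its
#' standard deviation, the maximal penetration beyond the stop surface, and
#' the per-position error map.
#'
#' @param phantom_final the `Phantom` after the loop.
#' @param stop a `SurfaceModel` stop surface (in the phantom frame).
#' @param mask logical matrix on the phantom grid, or
#'   `list(center =, diameter =)`.
#' @return an object of class `EvaluationReport`: `mean_abs`, `sd`,
#'   `max_penetration` (µm), `critical_hit`, and `errors` (data.frame
#'   `x`, `y`, `error` with positive = penetration).
#' @export
evaluate_result <- function(phantom_final, stop, mask) {
  stopifnot(inherits(phantom_final, "Phantom"), inherits(stop, "SurfaceModel"))
  x <- phantom_final$x; y <- phantom_final$y
  m <- if (is.list(mask))
    make_channel_mask(x, y, mask$center %||% c(0, 0),
                      mask$diameter %||% 1000)
  else mask
  stopifnot(is.logical(m), all(dim(m) == dim(phantom_final$zb)))
  nx <- length(x); ny <- length(y)
  sz <- matrix(eval_surface(stop, rep(x, times = ny), rep(y, each = nx)),
               nx, ny)
  if (any(m & !is.finite(sz)))
    stop("stop surface invalid inside the mask", call. = FALSE)
  err <- phantom_final$zb - sz            # positive = bottom beyond stop
  sel <- which(m, arr.ind = TRUE)
  ev <- err[m]
  structure(list(mean_abs = mean(abs(ev)), sd = stats::sd(abs(ev)),
                 max_penetration = max(pmax(ev, 0)),
                 critical_hit = phantom_final$critical_hit,
                 errors = data.frame(x = x[sel[, 1]], y = y[sel[, 2]],
                                     error = ev)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: mean abs error %.2f um (sd %.2f), max penetration %.2f um, critical hit: %s\n",
              x$mean_abs, x$sd, x$max_penetration, x$critical_hit))
  invisible(x)
}

#' Foresight: confidently guided rounds
#'
#' Number of ablation rounds executed under confident boundary guidance
#' (fitted mode), i.e. the foresight window between first boundary
#' visibility and reaching the stop surface. The analytic counterpart is
#' `floor(imaging_depth / max_pulse_depth)`: with roughly half a millimetre
#' of imaging depth in bone and at most 100 µm ablated per round and
#' position, the boundary is visible at least 4-5 rounds before exposure.
#'
#' @param result a `LoopResult`.
#' @return integer count of fitted-mode rounds.
#' @export
foresight_rounds <- function(result) {
  stopifnot(inherits(result, "LoopResult"))
  sum(vapply(result$rounds, function(r) r$mode == "fitted", logical(1)))
}

#' @rdname foresight_rounds
#' @param imaging_depth usable imaging depth in bone, µm.
#' @param max_pulse_depth deepest single-pulse crater, µm.
#' @export
foresight_bound <- function(imaging_depth = 500, max_pulse_depth = 100) {
  floor(imaging_depth / max_pulse_depth)
}
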