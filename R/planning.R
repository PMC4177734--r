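#' Planning constraints
#'
#' Tunables for pulse-pattern planning. Durations map linearly to crater
#' depths (1 µm per µs over the tunable 20-100 µs range) and to pulse
#' energies (4.2 mJ at 20 µs, 28.5 mJ at 100 µs). The duration is chosen
#' quasi-proportional to the local excess thickness: clamped into the
#' tunable range and quantized to three classes (short 20 µs below 100 µm
#' excess, middle 60 µs up to 300 µm, long 100 µs above), or kept continuous
#' when `proportional = TRUE`.
#'
#' @param spacing minimum pulse centre spacing, µm (0.75 of the 200 µm spot
#'   diameter; Gaussian crater tails make denser firing redundant).
#' @param margin eligibility margin above the target, µm: positions with
#'   thickness at most `target + margin` receive no pulse.
#' @param target residual thickness aimed for, µm. Thickness maps measured
#'   against the stop surface already include the standoff, so the default
#'   is 0.
#' @param class_bounds excess-thickness bounds (µm) separating
#'   short/middle/long duration classes.
#' @param class_durations durations (µs) of the three classes.
#' @param min_duration,max_duration tunable duration range, µs.
#' @param depth_per_us crater depth per µs of duration.
#' @param proportional logical: continuous clamp instead of class
#'   quantization.
#' @param collateral logical: enable collateral-aware duration capping. A
#'   crater is 200 µm wide, so a pulse also deepens its neighbours; with
#'   the cap enabled, each pulse duration is reduced (or the pulse skipped)
#'   so that the predicted crater never pushes any position of the map more
#'   than `overshoot_allowance` beyond its local stop, accounting for
#'   craters already planned in the same round.
#' @param spot_radius 1/e^2 crater radius used by the collateral
#'   prediction, µm.
#' @param overshoot_allowance tolerated predicted overshoot beyond the
#'   stop surface, µm.
#' @return a list of constraints.
#' @export
plan_constraints <- function(spacing = 150, margin = 10, target = 0,
                             class_bounds = c(100, 300),
                             class_durations = c(20, 60, 100),
                             min_duration = 20, max_duration = 100,
                             depth_per_us = 1, proportional = FALSE,
                             collateral = FALSE, spot_radius = 100,
                             overshoot_allowance = 10) {
  stopifnot(spacing > 0, margin >= 0, target >= 0,
            length(class_bounds) == 2L, length(class_durations) == 3L,
            min_duration >= 20, max_duration <= 100, spot_radius > 0,
            overshoot_allowance >= 0)
  list(spacing = spacing, margin = margin, target = target,
       class_bounds = class_bounds, class_durations = class_durations,
       min_duration = min_duration, max_duration = max_duration,
       depth_per_us = depth_per_us, proportional = proportional,
       collateral = collateral, spot_radius = spot_radius,
       overshoot_allowance = overshoot_allowance)
}

#' Pulse energy for a duration
#'
#' Linear map of the printed endpoints: 20 µs -> 4.2 mJ, 100 µs -> 28.5 mJ.
#'
#' @param duration pulse duration, µs.
#' @return energy in mJ.
#' @export
pulse_energy <- function(duration) {
  4.2 + (duration - 20) * (28.5 - 4.2) / 80
}

#' Choose a pulse duration for a local thickness
#'
#' @param thickness local residual thickness, µm; must exceed `target`.
#' @param target residual thickness aimed for, µm.
#' @param constraints a [plan_constraints()] list.
#' @return list with `duration` (µs), `class` ("short"/"middle"/"long"),
#'   `energy` (mJ) and `depth` (nominal crater depth, µm). The nominal
#'   depth never exceeds the excess thickness by more than the short-pulse
#'   depth.
#' @export
duration_for_thickness <- function(thickness, target = 0,
                                   constraints = plan_constraints()) {
  cn <- constraints
  if (!is.finite(thickness) || thickness <= target)
    stop("thickness must exceed the target", call. = FALSE)
  excess <- thickness - target
  if (cn$proportional) {
    dur <- clamp(excess / cn$depth_per_us, cn$min_duration, cn$max_duration)
  } else {
    dur <- if (excess < cn$class_bounds[1]) cn$class_durations[1]
           else if (excess < cn$class_bounds[2]) cn$class_durations[2]
           else cn$class_durations[3]
    # quantized duration may still not out-deepen the excess by more than
    # the short-pulse depth
    dur <- min(dur, clamp(excess / cn$depth_per_us, cn$min_duration,
                          cn$max_duration))
  }
  cls <- if (excess < cn$class_bounds[1]) "short"
         else if (excess < cn$class_bounds[2]) "middle" else "long"
  list(duration = dur, class = cls, energy = pulse_energy(dur),
       depth = dur * cn$depth_per_us)
}

#' Plan one round of ablation pulses
#'
#' Greedy coverage of the thickness map: repeatedly apply the next pulse to
#' the in-mask position of maximal residual thickness where no pulse has
#' been planned yet (a disc of the minimum-spacing radius around every
#' planned pulse is claimed), until no position with thickness above
#' `target + margin` remains. Ties are broken lexicographically by (y, x).
#'
#' @param t a [thickness_map()] object.
#' @param constraints a [plan_constraints()] list.
#' @param round_index loop round recorded with the plan.
#' @param eligible optional logical matrix further restricting candidate
#'   positions (e.g. a safety cap).
#' @return a data.frame of class `PulsePlan` with columns `x`, `y`
#'   (µm), `duration` (µs), `class`, `energy` (mJ), `order`; possibly empty.
#' @export
plan_ablation <- function(t, constraints = plan_constraints(),
                          round_index = 0L, eligible = NULL) {
  stopifnot(inherits(t, "ThicknessMap"))
  cn <- constraints
  th <- t$thickness
  ok <- t$mask & th > cn$target + cn$margin
  if (!is.null(eligible)) ok <- ok & eligible
  nx <- length(t$x); ny <- length(t$y)
  idx <- which(ok)
  out_x <- numeric(0); out_y <- numeric(0); out_dur <- numeric(0)
  out_cls <- character(0); out_en <- numeric(0)
  if (length(idx) > 0) {
    ix <- (idx - 1L) %% nx + 1L
    iy <- (idx - 1L) %/% nx + 1L
    px <- t$x[ix]; py <- t$y[iy]
    tv <- th[idx]
    # all map positions participate in the collateral bound (also those
    # already at or past their stop)
    if (cn$collateral) {
      all_idx <- which(t$mask)
      ax <- t$x[(all_idx - 1L) %% nx + 1L]
      ay <- t$y[(all_idx - 1L) %/% nx + 1L]
      at <- (t$thickness - t$penetration)[all_idx]   # signed distance to stop
    }
    ord <- order(-tv, py, px)
    claimed <- rep(FALSE, length(idx))
    for (q in ord) {
      if (claimed[q]) next
      sel <- duration_for_thickness(tv[q], cn$target, cn)
      dur <- sel$duration; cls <- sel$class
      if (cn$collateral) {
        d2 <- (ax - px[q])^2 + (ay - py[q])^2
        near <- which(d2 < (2.5 * cn$spot_radius)^2)
        g <- exp(-2 * d2[near] / cn$spot_radius^2)
        # total predicted penetration of any neighbour stays within the
        # allowance; neighbours already past it bound the added depth to
        # 1 um per pulse instead of vetoing the whole neighbourhood
        cap <- min(pmax(at[near] + cn$overshoot_allowance, 1) / g) /
          cn$depth_per_us
        if (cap < cn$min_duration) next          # no admissible pulse here
        if (dur > cap) {
          ok <- cn$class_durations[cn$class_durations <= cap]
          if (cn$proportional) dur <- max(cn$min_duration, min(dur, cap))
          else if (length(ok) > 0) dur <- max(ok) else next
          cls <- if (dur <= cn$class_durations[1]) "short"
                 else if (dur <= cn$class_durations[2]) "middle" else "long"
        }
        at[near] <- at[near] - dur * cn$depth_per_us * g
      }
      out_x <- c(out_x, px[q]); out_y <- c(out_y, py[q])
      out_dur <- c(out_dur, dur); out_cls <- c(out_cls, cls)
      out_en <- c(out_en, pulse_energy(dur))
      claimed <- claimed | ((px - px[q])^2 + (py - py[q])^2 < cn$spacing^2)
    }
  }
  plan <- data.frame(x = out_x, y = out_y, duration = out_dur,
                     class = out_cls, energy = out_en,
                     order = seq_along(out_x))
  structure(plan, class = c("PulsePlan", "data.frame"),
            round_index = as.integer(round_index),
            spacing = cn$spacing)
}

#' Termination test
#'
#' The loop stops when the stop surface has been reached all over the
#' channel bottom: residual thickness at most `tolerance` at every lateral
#' position of the channel mask.
#'
#' @param t a [thickness_map()] object.
#' @param tolerance allowed residual thickness, µm.
#' @param quantile fraction of channel positions required below tolerance
#'   (1 = strict "all over" reading; 0.99 available as a laxer criterion).
#' @return logical.
#' @export
is_terminated <- function(t, tolerance = 10, quantile = 1) {
  stopifnot(inherits(t, "ThicknessMap"), tolerance >= 0)
  th <- t$thickness[t$mask]
  if (length(th) == 0L) return(TRUE)
  mean(th <= tolerance) >= quantile
}
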