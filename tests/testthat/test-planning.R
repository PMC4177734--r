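# small helper: thickness map from a bare matrix on a regular grid
toy_map <- function(th, spacing = 100, mask = NULL) {
  nx <- nrow(th); ny <- ncol(th)
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing
  y <- (seq_len(ny) - (ny + 1) / 2) * spacing
  structure(list(x = x, y = y, thickness = pmax(th, 0),
                 penetration = pmax(-th, 0),
                 mask = mask %||% matrix(TRUE, nx, ny)),
            class = "ThicknessMap")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force greedy oracle: repeatedly take the strictly-eligible position
# of maximal thickness (ties by y then x), claim a spacing disc, repeat
oracle_order <- function(t, spacing, margin) {
  nx <- length(t$x)
  pos <- data.frame(x = rep(t$x, length(t$y)), y = rep(t$y, each = nx),
                    th = as.vector(t$thickness),
                    ok = as.vector(t$mask) & as.vector(t$thickness) > margin)
  out <- list()
  repeat {
    el <- which(pos$ok)
    if (length(el) == 0) break
    el <- el[order(-pos$th[el], pos$y[el], pos$x[el])]
    p <- el[1]
    out[[length(out) + 1]] <- c(pos$x[p], pos$y[p])
    pos$ok <- pos$ok & ((pos$x - pos$x[p])^2 + (pos$y - pos$y[p])^2 >= spacing^2)
  }
  do.call(rbind, out)
}

test_that("greedy planning matches the exhaustive priority oracle", {
  cn <- plan_constraints(spacing = 150, margin = 10)
  set.seed(21)
  for (trial in 1:5) {
    th <- matrix(sample(0:400, 25, replace = TRUE), 5, 5)
    t <- toy_map(th)
    plan <- plan_ablation(t, cn)
    orc <- oracle_order(t, cn$spacing, cn$margin)
    if (is.null(orc)) {
      expect_equal(nrow(plan), 0L)
    } else {
      expect_equal(cbind(plan$x, plan$y), unname(orc))
    }
  }
})

test_that("the first pulse lands on the single peak and flat maps plan nothing", {
  th <- matrix(50, 5, 5); th[2, 4] <- 300
  plan <- plan_ablation(toy_map(th))
  t <- toy_map(th)
  expect_equal(c(plan$x[1], plan$y[1]), c(t$x[2], t$y[4]))
  # all thickness at or below target + margin: empty plan
  empty <- plan_ablation(toy_map(matrix(10, 5, 5)))
  expect_equal(nrow(empty), 0L)
})

test_that("plans respect the minimum pulse spacing", {
  set.seed(22)
  th <- matrix(runif(400, 0, 500), 20, 20)
  plan <- plan_ablation(toy_map(th, spacing = 40))
  if (nrow(plan) >= 2)
    expect_gte(min(stats::dist(cbind(plan$x, plan$y))), 150)
})

test_that("progress is guaranteed whenever the map is not terminated", {
  set.seed(23)
  for (trial in 1:10) {
    th <- matrix(runif(64, 0, 40), 8, 8)
    t <- toy_map(th, spacing = 60)
    if (!is_terminated(t, 10)) {
      plan <- plan_ablation(t)
      expect_gte(nrow(plan), 1L)
      # the first pulse sits at the global maximum
      mx <- which(t$thickness == max(t$thickness), arr.ind = TRUE)[1, ]
      expect_equal(c(plan$x[1], plan$y[1]),
                   c(t$x[mx[1]], t$y[mx[2]]))
    }
  }
})

test_that("durations are quasi-proportional with printed endpoints and classes", {
  expect_equal(duration_for_thickness(500)[c("duration", "class")],
               list(duration = 100, class = "long"))
  sel <- duration_for_thickness(30)
  expect_equal(sel$duration, 20)
  expect_equal(sel$class, "short")
  expect_lte(sel$depth, 30 + 20)   # never out-deepens excess by > short depth
  expect_equal(duration_for_thickness(150)$duration, 60)
  expect_equal(duration_for_thickness(150)$class, "middle")
  expect_error(duration_for_thickness(5, target = 10), "exceed")
  # energy endpoints of the linear map
  expect_equal(pulse_energy(20), 4.2)
  expect_equal(pulse_energy(100), 28.5)
  expect_equal(duration_for_thickness(500)$energy, 28.5)
  # proportional mode clamps continuously
  cn <- plan_constraints(proportional = TRUE)
  expect_equal(duration_for_thickness(57, constraints = cn)$duration, 57)
  expect_equal(duration_for_thickness(700, constraints = cn)$duration, 100)
})

test_that("safety: planned depth never exceeds excess plus the short depth", {
  set.seed(24)
  th <- matrix(runif(100, 11, 600), 10, 10)
  t <- toy_map(th, spacing = 80)
  plan <- plan_ablation(t)
  nx <- length(t$x)
  for (i in seq_len(nrow(plan))) {
    ix <- which(t$x == plan$x[i]); iy <- which(t$y == plan$y[i])
    excess <- t$thickness[ix, iy]
    expect_lte(plan$duration[i], excess + 20)
  }
})

test_that("collateral capping bounds predicted neighbour penetration", {
  # a deep deficit right next to a converged position: the cap must shrink
  # or skip the pulse rather than punch the neighbour through
  th <- matrix(0, 9, 9)
  th[5, 5] <- 400          # wants a long pulse
  t <- toy_map(th, spacing = 30)   # neighbours 30 um away, already at stop
  cn <- plan_constraints(spacing = 150, collateral = TRUE,
                         overshoot_allowance = 30)
  plan <- plan_ablation(t, cn)
  if (nrow(plan) > 0) {
    # predicted penetration of the 30-um neighbour stays within allowance
    g <- exp(-2 * 30^2 / 100^2)
    expect_lte(plan$duration[1] * g, 0 + 30 + 1e-9)
  }
  # without the cap the long pulse goes through unchecked
  plan2 <- plan_ablation(t, plan_constraints(spacing = 150))
  expect_equal(plan2$duration[1], 100)
})

test_that("termination agrees with the brute-force all-position check", {
  expect_true(is_terminated(toy_map(matrix(0, 4, 4)), 10))
  one <- matrix(0, 4, 4); one[2, 3] <- 11
  expect_false(is_terminated(toy_map(one), 10))
  set.seed(25)
  for (trial in 1:20) {
    th <- matrix(runif(36, 0, 25), 6, 6)
    t <- toy_map(th)
    expect_identical(is_terminated(t, 10),
                     all(t$thickness[t$mask] <= 10))
  }
  # quantile criterion
  th <- matrix(0, 10, 10); th[1, 1] <- 50
  expect_true(is_terminated(toy_map(th), 10, quantile = 0.99))
})
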