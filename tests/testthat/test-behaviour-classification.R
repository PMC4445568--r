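test_that("bottom distance interpolates the dive position between fixes", {
  # 20 x 20 grid: 50 m everywhere except deeper (80 m) for x >= 1000
  depths <- matrix(50, 20, 20)
  depths[, 11:20] <- 80
  g <- bathy_grid(depths, cell_size = 100)
  trk <- data.frame(animal = 1, time = c(0, 1200), x = c(500, 1500),
                    y = c(500, 500))
  # dive exactly at the first fix over the 50 m cell
  d1 <- make_dive(rep(0, 11), 100, max_depth = 47, start = 0)
  expect_equal(bottom_distance(d1, trk, g), 3)
  # midway in time: position at x = 1000, in the 80 m half
  d2 <- make_dive(rep(0, 11), 100, max_depth = 47, start = 600)
  expect_equal(bottom_distance(d2, trk, g), 33)
  # deeper than the mapped bottom gives a negative distance
  d3 <- make_dive(rep(0, 11), 100, max_depth = 52, start = 0)
  expect_equal(bottom_distance(d3, trk, g), -2)
  # outside the bracketing fixes: missing
  d4 <- make_dive(rep(0, 11), 100, max_depth = 47, start = 5000)
  expect_true(is.na(bottom_distance(d4, trk, g)))
})

test_that("benthic mixture recovers two separated components", {
  set.seed(11)
  d <- c(rnorm(2500, -3, 2), rnorm(2500, 20, 10))
  fit <- fit_benthic_mixture(d)
  bm <- fit$means[fit$benthic_component]
  expect_equal(bm, -3, tolerance = 0.5 / 3)
  # threshold equals the closed-form upper 95 % quantile of the benthic
  # component
  expect_equal(fit$threshold,
               bm + qnorm(0.95) * fit$sds[fit$benthic_component])
  expect_equal(fit$threshold, -3 + qnorm(0.95) * 2, tolerance = 0.3)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
})

test_that("a single tight component near zero makes every dive benthic", {
  set.seed(12)
  d <- rnorm(600, 0, 0.5)
  fit <- fit_benthic_mixture(d)
  expect_equal(fit$K, 1L)
  # the threshold is that component's upper 95 % quantile, so 95 % of
  # the dives fall below it
  expect_equal(mean(fit$benthic), 0.95, tolerance = 0.03)
})

test_that("predatory tactic per segment follows the majority rule", {
  b <- c(TRUE, TRUE, TRUE, FALSE,  TRUE, TRUE, FALSE, FALSE, NA)
  s <- c(1, 1, 1, 1,  2, 2, 2, 2,  3)
  pt <- ptactic_per_segment(b, s)
  expect_equal(unname(pt[["1"]]), 1L)   # 3 of 4 benthic
  expect_equal(unname(pt[["2"]]), 0L)   # exact tie -> pelagic
  expect_false("3" %in% names(pt))      # no classified dives
})

test_that("trip direction labels out/inward legs and within-range trips", {
  dt <- 1200
  # 0.5 -> 8 km out (16 nodes), wobbling hover (30 nodes), return
  set.seed(2)
  leg <- seq(500, 8000, length.out = 16)
  x <- c(leg, 8000 + rnorm(30, 0, 60), rev(leg))
  n <- length(x)
  ho <- data.frame(animal = 1, start = c(-3600, n * dt + 3600),
                   end = c(0, (n + 4) * dt + 3600),
                   site_x = 0, site_y = 0)
  trk <- data.frame(animal = 1, bout = 1,
                    time = seq(0, by = dt, length.out = n),
                    x = x, y = 0, HS = NA)
  lab <- classify_trip_direction(trk, ho)
  expect_equal(lab[2], "outward")
  expect_equal(lab[n - 2], "inward")
  expect_true(any(lab == "other"))
  # all nodes carry exactly one label
  expect_true(all(lab %in% c("outward", "inward", "within_range",
                             "transiting", "other")))
  # outward sections start within 2 km; inward sections end within 2 km
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  d_site <- abs(x)
  for (i in seq_along(r$values)) {
    if (r$values[i] == "outward") expect_lte(d_site[starts[i]], 2000)
    if (r$values[i] == "inward") expect_lte(d_site[ends[i]], 2000)
  }
  # a trip that never leaves the 2 km range
  trk2 <- trk
  trk2$x <- 500 + 900 * sin(seq_len(n) / 4)
  expect_true(all(classify_trip_direction(trk2, ho) == "within_range"))
  # no bracketing events: everything is 'other', with a warning
  expect_warning(
    lab3 <- classify_trip_direction(trk, ho[0, ]), "no haul-out")
  expect_true(all(lab3 == "other"))
})

test_that("noisy distance series segment at smoothed sign changes", {
  dt <- 1200
  ho <- data.frame(animal = 1, start = c(-3600, 90 * dt + 3600),
                   end = c(0, 95 * dt + 3600), site_x = 0, site_y = 0)
  set.seed(4)
  out_leg <- seq(600, 9000, length.out = 40)
  back_leg <- seq(9000, 600, length.out = 40)
  x <- c(out_leg, back_leg) + rnorm(80, 0, 120)  # sub-window wiggles
  x[1] <- 600; x[80] <- 600
  trk <- data.frame(animal = 1, bout = 1,
                    time = seq(0, by = dt, length.out = 80),
                    x = x, y = 0, HS = NA)
  lab <- classify_trip_direction(trk, ho)
  # the smoothing removes the sub-window oscillations: one outward and
  # one inward section dominate
  expect_gte(sum(lab == "outward"), 30)
  expect_gte(sum(lab == "inward"), 30)
  expect_equal(length(rle(lab)$values[rle(lab)$values %in%
                                        c("outward", "inward")]), 2)
})

test_that("mean-shift changepoints match an exhaustive search", {
  set.seed(21)
  for (rep in 1:8) {
    x <- rnorm(24, 0, 0.3) +
      rep(c(0, sample(c(-1.5, 1.5), 1)), c(12, 12)) * (rep %% 2 == 0)
    got <- changepoints_mean(x, min_seg = 5)
    want <- cp_brute(x, min_seg = 5)$cps
    expect_equal(got, as.integer(want))
  }
})

test_that("a clear mean shift in log skewness is located precisely", {
  set.seed(31)
  y <- c(rnorm(100, 0, 0.2), rnorm(100, 1.5, 0.2))
  cps <- changepoints_mean(y)
  expect_equal(length(cps), 1L)
  expect_lte(abs(cps - 100), 2)
  # homogeneous series: no changepoints
  expect_length(changepoints_mean(rnorm(200, 0, 0.2)), 0)
})

test_that("resting detection recovers simulated resting bouts", {
  cfg <- sim_config(n_animals = 2, days = 10, resting_rate = 0.08,
                    shallow_rate = 0, missed_surfacing_rate = 0,
                    seed = 47)
  ds <- simulate_dataset(cfg)
  m <- dive_metrics(ds$dives)
  m <- m[order(m$animal, m$start), ]
  det <- detect_resting(m$SK, m$animal)
  tr <- merge(data.frame(animal = m$animal, dive_id = m$dive_id,
                         got = det$resting),
              ds$truth, by = c("animal", "dive_id"))
  expect_gt(sum(tr$resting), 100)
  recall <- mean(tr$got[tr$resting])
  precision <- mean(tr$resting[tr$got])
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # an animal with no resting stays all-active
  cfg0 <- sim_config(n_animals = 1, days = 6, resting_rate = 0,
                     shallow_rate = 0, missed_surfacing_rate = 0,
                     seed = 48)
  ds0 <- simulate_dataset(cfg0)
  m0 <- dive_metrics(ds0$dives)
  det0 <- detect_resting(m0$SK, m0$animal)
  expect_lte(mean(det0$resting), 0.02)
})

test_that("resting indicator per segment uses diving-time majority", {
  resting <- c(TRUE, TRUE, FALSE,  FALSE, FALSE, TRUE)
  dur <- c(300, 300, 100,  300, 300, 100)
  seg <- c(1, 1, 1,  2, 2, 2)
  rd <- resting_per_segment(resting, dur, seg)
  expect_equal(unname(rd[["1"]]), 1L)
  expect_equal(unname(rd[["2"]]), 0L)
})
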