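mk_points <- function(times, x = 0, y = 0, error = 10, animal = 1) {
  data.frame(animal = rep_len(animal, length(times)), time = times,
             x = rep_len(x, length(times)),
             y = rep_len(y, length(times)),
             error = rep_len(error, length(times)))
}

test_that("GPS filtering and bout cutting follow the gap rules", {
  # clean 6 h track: one bout
  p <- mk_points(seq(0, 6 * 3600, by = 1200))
  b <- filter_and_cut(p)
  expect_equal(unique(b$bout), 1L)
  # fixes with error > 50 m are dropped
  p2 <- p
  p2$error[5] <- 120
  b2 <- filter_and_cut(p2)
  expect_equal(nrow(b2), nrow(p) - 1)
  expect_equal(attr(b2, "n_dropped_error"), 1L)
  # a 30 h gap at sea cuts the track in two
  t3 <- c(seq(0, 4 * 3600, by = 1200),
          seq(4 * 3600 + 30 * 3600, 4 * 3600 + 34 * 3600, by = 1200))
  b3 <- filter_and_cut(mk_points(t3))
  expect_equal(length(unique(b3$bout)), 2L)
  # the same gap fully inside a haul-out event: the 48 h rule applies
  ho <- data.frame(animal = 1, start = 4 * 3600 + 600,
                   end = 4 * 3600 + 30 * 3600 - 600)
  b4 <- filter_and_cut(mk_points(t3), haulouts = ho)
  expect_equal(length(unique(b4$bout)), 1L)
  # bouts shorter than 3 h are discarded
  t5 <- c(seq(0, 2 * 3600, by = 1200),
          seq(40 * 3600, 50 * 3600, by = 1200))
  b5 <- filter_and_cut(mk_points(t5))
  expect_true(all(b5$time >= 40 * 3600))
  expect_warning(filter_and_cut(mk_points(numeric(0))), "empty")
})

test_that("regularization interpolates positions and computes speed", {
  # stationary bout
  p <- mk_points(seq(0, 6 * 3600, by = 1200), x = 100, y = 200)
  p$bout <- 1L
  r <- regularize_track(p)
  expect_true(all(r$HS[-nrow(r)] == 0))
  expect_true(all(diff(r$time) == 1200))
  # straight line at 1 m/s with fixes every 600 s
  tt <- seq(0, 4 * 3600, by = 600)
  p2 <- data.frame(animal = 1, time = tt, x = tt * 1.0, y = 0,
                   error = 5, bout = 1L)
  r2 <- regularize_track(p2)
  expect_equal(r2$HS[-nrow(r2)], rep(1.0, nrow(r2) - 1))
  # fixes every 1500 s on a bent path: hand-computed interpolation
  p3 <- data.frame(animal = 1, time = c(0, 1500, 3000),
                   x = c(0, 1500, 1500), y = c(0, 0, 1500),
                   error = 5, bout = 1L)
  # grid nodes at 0, 1200, 2400 (the 3000 s bout holds three nodes)
  r3 <- regularize_track(p3)
  expect_equal(r3$x, c(0, 1200, 1500))
  expect_equal(r3$y, c(0, 0, 900))
})

test_that("residence time matches closed forms", {
  # stationary animal: RT equals the whole bout duration at every node
  n <- 19
  trk <- data.frame(animal = 1, bout = 1,
                    time = seq(0, by = 1200, length.out = n),
                    x = 500, y = 500, HS = 0)
  rt <- residence_time(trk, r = 400, t = 1)
  expect_equal(rt, rep((n - 1) * 1200 / 3600, n))
  # straight line at 0.5 m/s: the chord through the centre gives
  # RT = 2r/v = 1600 s at interior nodes
  tt <- seq(0, by = 1200, length.out = 30)
  trk2 <- data.frame(animal = 1, bout = 1, time = tt,
                     x = 0.5 * tt, y = 0, HS = 0.5)
  rt2 <- residence_time(trk2, r = 400, t = 1)
  interior <- 5:25
  expect_equal(rt2[interior], rep(1600 / 3600, length(interior)),
               tolerance = 1e-9)
  expect_error(residence_time(trk2, r = -1), "r must")
  expect_error(residence_time(trk2, r = 400, t = -1), "t must")
  # haul-out proximity masking
  rt3 <- residence_time(trk, r = 400, t = 1,
                        sites = data.frame(x = 600, y = 500))
  expect_true(all(is.na(rt3)))
})

test_that("residence time equals the brute-force oracle on random tracks", {
  worst <- 0
  for (s in 1:100) {
    n <- sample(30:200, 1)
    trk <- random_track(n, seed = 5000 + s)
    rt <- residence_time(trk, r = 400, t = 1)
    oracle <- vapply(seq_len(n), function(k)
      rt_oracle_node(trk$time, trk$x, trk$y, k, 400, 3600), numeric(1))
    worst <- max(worst, max(abs(rt - oracle)))
  }
  expect_lt(worst, 1e-9)
})

test_that("two-state movement classification recovers simulated states", {
  cfg <- sim_config(n_animals = 2, days = 10, gps_dropout_prob = 0,
                    gps_error_sd = 0, sea_mean_h = 2000,
                    haul_mean_h = 0.6, speed_mean = c(1.2, 0.2),
                    seed = 3)
  trk <- simulate_track(cfg)
  reg <- regularize_track(filter_and_cut(trk$track, trk$haulouts))
  reg <- classify_movement_type(reg, trk$haulouts)
  m <- merge(reg, trk$states[, c("animal", "time", "state", "hauled")],
             by = c("animal", "time"))
  m <- m[!is.na(m$MT) & !is.na(m$state) & !m$hauled, ]
  expect_gt(nrow(m), 800)
  expect_gte(mean((m$MT == 1) == (m$state == 2)), 0.9)
  # label convention: extensive (MT = 0) nodes are faster on average
  expect_gt(mean(m$HS[m$MT == 0]), mean(m$HS[m$MT == 1]))
  # per-state mean speeds: step speeds are drawn as max(0, N(mu, sd)),
  # whose mean has the closed form mu*pnorm(mu/sd) + sd*dnorm(mu/sd).
  # Posterior overlap biases a single animal's state mean by up to a
  # few percent, so the across-animal average is held to 10 % and each
  # animal to 15 %.
  tmean <- function(mu, sd) mu * pnorm(mu / sd) + sd * dnorm(mu / sd)
  sp <- sapply(attr(reg, "hmm_fits"), function(f) sort(f$mean_speed))
  expect_equal(mean(sp[1, ]), tmean(0.2, 0.12), tolerance = 0.1)
  expect_equal(mean(sp[2, ]), tmean(1.2, 0.3), tolerance = 0.1)
  for (j in seq_len(ncol(sp))) {
    expect_equal(unname(sp[1, j]), tmean(0.2, 0.12), tolerance = 0.15)
    expect_equal(unname(sp[2, j]), tmean(1.2, 0.3), tolerance = 0.15)
  }
})

test_that("single-regime tracks fall back to the speed threshold", {
  cfg <- sim_config(n_animals = 1, days = 8, gps_dropout_prob = 0,
                    gps_error_sd = 0, sea_mean_h = 2000,
                    haul_mean_h = 0.6,
                    state_transition = matrix(c(0, 1, 0, 1), 2, 2,
                                              byrow = TRUE),
                    speed_mean = c(1.2, 0.2), seed = 5)
  trk <- simulate_track(cfg)
  reg <- classify_movement_type(
    regularize_track(filter_and_cut(trk$track, trk$haulouts)),
    trk$haulouts)
  expect_gte(mean(reg$MT == 1, na.rm = TRUE), 0.95)
})
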