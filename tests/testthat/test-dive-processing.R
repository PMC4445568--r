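test_that("shallow-dive flag uses the 5.6 m threshold, boundary inclusive", {
  d <- rbind(path_dive(5.0, 1, 1, 30, dive_id = "a"),
             path_dive(5.6, 1, 1, 30, dive_id = "b"),
             path_dive(50, 1, 1, 30, dive_id = "c"))
  expect_equal(flag_shallow(d), c("shallow", "shallow", "ok"))
})

test_that("compressed-record flag catches interior near-surface readings", {
  # clean square 50 m dive, interior >= 42 m
  expect_equal(flag_compressed(path_dive(50, 2, 2, 200)), "ok")
  # interior reading at 10 m (< 12.5 m = 25 % of 50 m)
  d <- make_dive(c(0, 30, 50, 10, 45, 50, 50, 50, 40, 20, 0), 300, 50)
  expect_equal(flag_compressed(d), "compressed")
  # > 50 % of the duration shallower than 25 % of max depth:
  # depths sit at 10 m (< 12.5) for the middle 60 % of the record
  d2 <- make_dive(c(0, 50, 10, 10, 10, 10, 10, 10, 10, 50, 0), 300, 50)
  expect_equal(flag_compressed(d2), "compressed")
  # malformed record: missing profile point
  bad <- path_dive(50, 1, 1, 100)
  bad$d10 <- NULL
  expect_error(flag_compressed(bad), "malformed")
})

test_that("bottom phase interpolates threshold crossings and sums excursions", {
  # square dive 0->50 m in 25 s, 200 s flat, 25 s ascent:
  # crossings of 42.5 m at t = 21.25 and 228.75, BT = 207.5 s
  sq <- path_dive(50, 2, 2, 200)
  expect_equal(bottom_phase(sq)$BT, 207.5)
  # symmetric v-dive to 50 m in 100 s: 15 % of each leg below 42.5 m
  tt <- seq(0, 100, length.out = 11)
  vd <- make_dive(pmin(tt, 100 - tt), 100, 50)
  expect_equal(bottom_phase(vd)$BT, 15)
  # two bottom excursions are summed (hand computation):
  # crossings at 36 and 139 give BT = 103 on a 300 s dive
  d <- make_dive(c(0, 40.625, 50, 50, 50, 50 - 225 / 19,
                   25, 15, 8, 3, 0), 300, 50)
  expect_equal(bottom_phase(d)$BT, 103)
})

test_that("standardized bottom time follows the maxBT identity", {
  # worked dive: duration 300 s, depth 50 m, v_max 2 m/s, BT 103 s
  # -> min travel 42.5 s, maxBT 257.5 s, stBT = 0.4
  d <- make_dive(c(0, 40.625, 50, 50, 50, 50 - 225 / 19,
                   25, 15, 8, 3, 0), 300, 50)
  sb <- standardized_bottom_time(d, v_max = 2)
  expect_equal(sb$BT, 103)
  expect_equal(sb$maxBT, 257.5)
  expect_equal(sb$stBT, 0.4)
  # square dive travelling exactly at v_max: BT = maxBT, stBT = 1
  sq <- path_dive(50, 2, 2, 200)
  expect_equal(standardized_bottom_time(sq, v_max = 2)$stBT, 1)
  # profile never reaching 85 % of the recorded max depth: BT = 0
  tt <- seq(0, 100, length.out = 11)
  shallow_profile <- make_dive(pmin(tt, 100 - tt), 100, max_depth = 100)
  expect_equal(standardized_bottom_time(shallow_profile, v_max = 2)$stBT, 0)
  expect_error(standardized_bottom_time(sq, v_max = 0), "v_max")
  # non-positive maxBT is NA with a warning
  quick <- path_dive(50, 2, 2, 0)
  quick$duration <- 40
  expect_warning(out <- standardized_bottom_time(quick, v_max = 2),
                 "maxBT")
  expect_true(is.na(out$stBT))
})

test_that("maximum vertical speed is the 0.95 pooled-leg-speed quantile", {
  # constant leg speeds; flat bottom of 8 leg-times aligns the profile
  # knots with the 11-point sampling grid so speeds are recovered
  # exactly
  d <- do.call(rbind, lapply(1:30, function(i)
    path_dive(50, 2, 2, 8 * 25, dive_id = paste0("d", i))))
  expect_equal(unname(max_vertical_speed(d, min_dives = 10)), 2,
               tolerance = 1e-6)
  # linear-interpolation quantile convention: speeds 1..100 -> 95.05
  d2 <- do.call(rbind, lapply(1:100, function(i)
    path_dive(50, i, i, 8 * 50 / i, dive_id = paste0("d", i))))
  expect_equal(unname(max_vertical_speed(d2, min_dives = 10)),
               quantile(1:100, 0.95, names = FALSE), tolerance = 1e-6)
  expect_equal(quantile(1:100, 0.95, names = FALSE), 95.05)
  # few dives fall back to the population quantile with a message
  d3 <- rbind(d, path_dive(50, 3, 3, 100, animal = 2, dive_id = "x"))
  expect_message(vm <- max_vertical_speed(d3, min_dives = 10),
                 "population")
  expect_equal(vm[["2"]], vm[["1"]])
})

test_that("time-at-depth index is maximal for a square dive at v_max", {
  sq <- path_dive(50, 2, 2, 200)
  expect_equal(time_at_depth_index(sq, v_max = 2), 1, tolerance = 1e-9)
  tt <- seq(0, 100, length.out = 11)
  vd <- make_dive(pmin(tt, 100 - tt), 100, 50)
  sq2 <- path_dive(50, 1, 1, 0)
  sq2$duration <- 100   # same depth and duration as the v-dive
  expect_lt(time_at_depth_index(vd, v_max = 2), 1)
})

test_that("dive skewness is the ascent/descent speed ratio", {
  expect_equal(dive_skewness(path_dive(30, 1, 1, 60)), 1,
               tolerance = 0.02)
  expect_equal(dive_skewness(path_dive(30, 1, 0.5, 60)), 0.5,
               tolerance = 0.05)
  # drifting resting dive: slow descent, fast ascent
  expect_equal(dive_skewness(path_dive(30, 0.2, 1.6, 40)), 8,
               tolerance = 0.12 * 8)
})

test_that("per-dive metric invariants hold on generated dives", {
  cfg <- sim_config(n_animals = 2, days = 5, shallow_rate = 0,
                    missed_surfacing_rate = 0, seed = 101)
  ds <- simulate_dataset(cfg)
  m <- dive_metrics(ds$dives)
  ok <- m$qc == "ok" & !is.na(m$stBT)
  expect_gt(sum(ok), 500)
  expect_true(all(m$BT[ok] >= 0))
  expect_true(all(m$BT[ok] <= m$maxBT[ok] + 1e-9 |
                    m$stBT[ok] == 1))
  expect_true(all(m$maxBT[ok] <= m$duration[ok] + 1e-9))
  expect_true(all(m$stBT[ok] >= 0 & m$stBT[ok] <= 1))
  expect_true(all(m$SK[ok] > 0, na.rm = TRUE))
  # stBT is invariant to uniform time rescaling with v_max rescaled
  d <- m[which(ok)[1:20], ]
  base <- standardized_bottom_time(d, v_max = 2)$stBT
  d2 <- d
  d2$duration <- d$duration * 3
  resc <- standardized_bottom_time(d2, v_max = 2 / 3)$stBT
  expect_equal(resc, base, tolerance = 1e-9)
})

test_that("adding flat bottom time increases BT and stBT", {
  flats <- c(20, 60, 120, 240)
  sb <- standardized_bottom_time(
    do.call(rbind, lapply(seq_along(flats), function(i)
      path_dive(40, 1.2, 1.2, flats[i], dive_id = paste0("f", i)))),
    v_max = 2)
  expect_true(all(diff(sb$BT) > 0))
  expect_true(all(diff(sb$stBT) > 0))
})

test_that("QC recovers injected concatenated dives", {
  cfg <- sim_config(n_animals = 2, days = 6, shallow_rate = 0.05,
                    missed_surfacing_rate = 0.08, seed = 7)
  ds <- simulate_dataset(cfg)
  m <- dive_qc(ds$dives)
  tr <- merge(m, ds$truth, by = c("animal", "dive_id"))
  conc <- tr$artefact == "missed_surf"
  expect_gt(sum(conc), 100)
  expect_gte(mean(tr$qc[conc] == "compressed"), 0.9)
  # clean dives pass
  clean <- tr$artefact == "none"
  expect_gte(mean(tr$qc[clean] == "ok"), 0.97)
})
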