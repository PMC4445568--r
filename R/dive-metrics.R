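profile_cols <- function() paste0("d", 0:10)

# Extract the 11-point profile matrix, failing on malformed records.
profile_matrix <- function(dives) {
  pc <- profile_cols()
  if (!all(pc %in% names(dives)))
    stop("malformed dive records: expected 11 profile columns d0..d10")
  m <- as.matrix(dives[, pc])
  if (anyNA(m)) stop("malformed dive records: missing profile depths")
  m
}

# Time spent at or below (deeper than) a depth threshold along a
# piecewise-linear profile, with entry/exit crossing times by linear
# interpolation. Multiple excursions below the threshold are summed.
phase_below <- function(tt, dd, thr) {
  tt <- as.numeric(tt)
  dd <- as.numeric(dd)
  below <- dd >= thr
  if (!any(below)) return(c(time = 0, entry = NA, exit = NA))
  total <- 0
  entry <- exit <- NA_real_
  for (i in seq_len(length(tt) - 1)) {
    d1 <- dd[i]; d2 <- dd[i + 1]
    t1 <- tt[i]; t2 <- tt[i + 1]
    if (d1 >= thr && d2 >= thr) {
      total <- total + (t2 - t1)
      if (is.na(entry)) entry <- t1
      exit <- t2
    } else if (d1 < thr && d2 >= thr) {
      tc <- t1 + (thr - d1) / (d2 - d1) * (t2 - t1)
      total <- total + (t2 - tc)
      if (is.na(entry)) entry <- tc
      exit <- t2
    } else if (d1 >= thr && d2 < thr) {
      tc <- t1 + (d1 - thr) / (d1 - d2) * (t2 - t1)
      total <- total + (tc - t1)
      if (is.na(entry)) entry <- t1
      exit <- tc
    }
  }
  c(time = total, entry = entry, exit = exit)
}


#' Flag compressed (concatenated) dive records
#'
#' A record is flagged as compressed when, excluding the initial descent
#' and final ascent, it contains depth readings in the upper quarter of
#' the dive's maximum depth without surfacing, or when the time spent in
#' that upper layer exceeds half the dive duration (time fractions by
#' linear interpolation between profile points). Such records arise when
#' a missed surfacing merges several dives into one profile.
#'
#' @param dives data frame of dive records with `duration`, `max_depth`
#'   and profile columns `d0..d10`.
#' @param upper_frac fraction of maximum depth defining the upper layer
#'   (default 0.25).
#' @param time_frac maximum tolerated fraction of the duration in the
#'   upper layer (default 0.5).
#' @return Character vector, `"compressed"` or `"ok"` per dive.
#' @export
flag_compressed <- function(dives, upper_frac = 0.25, time_frac = 0.5) {
  m <- profile_matrix(dives)
  vapply(seq_len(nrow(m)), function(i) {
    maxd <- dives$max_depth[i]
    dur <- dives$duration[i]
    thr <- upper_frac * maxd
    dd <- m[i, ]
    tt <- seq(0, dur, length.out = 11)
    deep <- which(dd >= thr)
    if (length(deep) >= 2) {
      interior <- dd[(deep[1] + 1):(deep[length(deep)] - 1)]
      if (length(interior) && any(interior < thr)) return("compressed")
    }
    shallow_time <- dur - phase_below(tt, dd, thr)[["time"]]
    if (shallow_time > time_frac * dur) return("compressed")
    "ok"
  }, character(1))
}

#' Flag shallow dives
#'
#' Dives not deeper than `threshold` metres are flagged; below this depth
#' missed surfacings are frequent and records unreliable. The boundary is
#' inclusive (`max_depth <= threshold` is shallow).
#'
#' @param dives data frame with a `max_depth` column.
#' @param threshold depth threshold in metres (default 5.6).
#' @return Character vector, `"shallow"` or `"ok"` per dive.
#' @export
flag_shallow <- function(dives, threshold = 5.6) {
  ifelse(dives$max_depth <= threshold, "shallow", "ok")
}

#' Quality-control dive records
#'
#' Applies [flag_compressed()] and [flag_shallow()]; a record failing
#' both rules is reported as compressed.
#'
#' @inheritParams flag_compressed
#' @inheritParams flag_shallow
#' @return `dives` with a `qc` column in `{ok, compressed, shallow}`.
#' @export
dive_qc <- function(dives, upper_frac = 0.25, time_frac = 0.5,
                    threshold = 5.6) {
  comp <- flag_compressed(dives, upper_frac, time_frac)
  shal <- flag_shallow(dives, threshold)
  dives$qc <- ifelse(comp == "compressed", "compressed",
                     ifelse(shal == "shallow", "shallow", "ok"))
  dives
}

#' Bottom phase of a dive
#'
#' The bottom phase is the time spent in the lower 15 % of the dive's
#' maximum depth; crossing times are found by linear interpolation
#' between profile points and multiple bottom excursions are summed.
#'
#' @param dives data frame of dive records.
#' @param bottom_frac fraction of maximum depth defining the bottom-phase
#'   boundary (default 0.85, i.e. the lower 15 %).
#' @return Data frame with `entry`, `exit` (s from dive start) and `BT`
#'   (bottom time, s) per dive.
#' @export
bottom_phase <- function(dives, bottom_frac = 0.85) {
  m <- profile_matrix(dives)
  out <- t(vapply(seq_len(nrow(m)), function(i) {
    tt <- seq(0, dives$duration[i], length.out = 11)
    phase_below(tt, m[i, ], bottom_frac * dives$max_depth[i])
  }, c(time = 0, entry = 0, exit = 0)))
  data.frame(entry = out[, "entry"], exit = out[, "exit"],
             BT = out[, "time"])
}

#' Standardized bottom time
#'
#' Bottom time as a fraction of the maximum potential bottom time:
#' `stBT = BT / maxBT` with `maxBT = duration - minimum travel time`,
#' where the minimum travel time is the time needed to reach the
#' bottom-phase boundary (15 % of maximum depth) from the surface and
#' back at the maximum vertical speed. Values are clipped to `[0, 1]`
#' (11-point quantization can push the ratio marginally above 1); dives
#' whose `maxBT` is non-positive return `NA` with a warning.
#'
#' @param dives data frame of dive records.
#' @param v_max maximum vertical speed (m/s): a single value or one per
#'   dive (e.g. the per-animal 0.95 speed quantile from
#'   [max_vertical_speed()]).
#' @param bottom_frac bottom-phase boundary fraction (default 0.85).
#' @return Data frame with `BT`, `maxBT` and `stBT` per dive.
#' @export
standardized_bottom_time <- function(dives, v_max, bottom_frac = 0.85) {
  if (any(v_max <= 0)) stop("v_max must be > 0")
  bp <- bottom_phase(dives, bottom_frac)
  travel <- 2 * bottom_frac * dives$max_depth / v_max
  maxbt <- dives$duration - travel
  stbt <- pmin(pmax(bp$BT / maxbt, 0), 1)
  bad <- maxbt <= 0
  if (any(bad)) {
    warning(sum(bad), " dive(s) with non-positive maxBT set to NA")
    stbt[bad] <- NA
  }
  data.frame(BT = bp$BT, maxBT = maxbt, stBT = stbt)
}

#' Per-dive vertical leg speeds
#'
#' Descent speed is the depth of the bottom-phase boundary divided by the
#' time from dive start to first bottom-phase entry; ascent speed is the
#' symmetric quantity for the exit. This definition is consistent with
#' the minimum-travel-time geometry used by
#' [standardized_bottom_time()].
#'
#' @inheritParams bottom_phase
#' @return Data frame with `descent_speed` and `ascent_speed` (m/s).
#' @export
leg_speeds <- function(dives, bottom_frac = 0.85) {
  bp <- bottom_phase(dives, bottom_frac)
  depth_b <- bottom_frac * dives$max_depth
  desc <- ifelse(!is.na(bp$entry) & bp$entry > 0, depth_b / bp$entry, NA)
  asc_t <- dives$duration - bp$exit
  asc <- ifelse(!is.na(bp$exit) & asc_t > 0, depth_b / asc_t, NA)
  data.frame(descent_speed = desc, ascent_speed = asc)
}

#' Maximum vertical speed per animal
#'
#' The 0.95 quantile of each individual's pooled distribution of per-dive
#' descent and ascent speeds (linear-interpolation quantile, R type 7).
#' Animals with fewer than `min_dives` valid dives fall back to the
#' population quantile, with a message.
#'
#' @param dives data frame of QC-passed dive records with an `animal`
#'   column.
#' @param prob quantile probability (default 0.95).
#' @param min_dives minimum valid dives per animal (default 50).
#' @param bottom_frac bottom-phase boundary fraction.
#' @return Named numeric vector of maximum vertical speeds (m/s), one per
#'   animal.
#' @export
max_vertical_speed <- function(dives, prob = 0.95, min_dives = 50,
                               bottom_frac = 0.85) {
  ls <- leg_speeds(dives, bottom_frac)
  sp <- c(ls$descent_speed, ls$ascent_speed)
  an <- rep(dives$animal, 2)
  ok <- !is.na(sp) & sp > 0
  sp <- sp[ok]; an <- an[ok]
  pool <- quantile(sp, prob, names = FALSE, type = 7)
  animals <- sort(unique(dives$animal))
  out <- vapply(animals, function(a) {
    # a dive contributes two leg speeds
    si <- sp[an == a]
    if (length(si) < 2 * min_dives) {
      message("animal ", a, ": too few dives, using population quantile")
      pool
    } else quantile(si, prob, names = FALSE, type = 7)
  }, numeric(1))
  names(out) <- animals
  out
}

#' Time-at-depth index
#'
#' An alternative vertical foraging index: the area under the time-depth
#' profile relative to the maximum area attainable for the same duration
#' and maximum depth when travelling at the maximum vertical speed (a
#' square dive at `v_max` scores 1; a v-shaped dive is minimal for its
#' depth and duration).
#'
#' @inheritParams standardized_bottom_time
#' @return Numeric vector of TAD values.
#' @export
time_at_depth_index <- function(dives, v_max) {
  if (any(v_max <= 0)) stop("v_max must be > 0")
  m <- profile_matrix(dives)
  area <- vapply(seq_len(nrow(m)), function(i) {
    tt <- seq(0, dives$duration[i], length.out = 11)
    sum(diff(tt) * (m[i, -1] + m[i, -11]) / 2)
  }, numeric(1))
  denom <- dives$max_depth * dives$duration -
    dives$max_depth^2 / v_max
  ifelse(denom > 0, area / denom, NA)
}

#' Dive skewness
#'
#' The ratio of ascent to descent vertical speed. Symmetric dives score
#' 1; drifting resting dives (slow descent, fast ascent) score well above
#' 1. Dives with an undefined leg speed return `NA`.
#'
#' @inheritParams bottom_phase
#' @return Numeric vector of skewness values (`SK`).
#' @export
dive_skewness <- function(dives, bottom_frac = 0.85) {
  ls <- leg_speeds(dives, bottom_frac)
  sk <- ls$ascent_speed / ls$descent_speed
  sk[!is.finite(sk) | sk <= 0] <- NA
  sk
}

#' Compute all per-dive metrics
#'
#' Runs quality control and computes bottom phase, standardized bottom
#' time, time-at-depth index, leg speeds and skewness for the dives that
#' pass QC (metrics are `NA` for flagged records).
#'
#' @param dives data frame of dive records (`animal`, `dive_id`, `start`,
#'   `duration`, `max_depth`, `d0..d10`).
#' @param v_max optional named per-animal maximum vertical speed vector;
#'   estimated with [max_vertical_speed()] from the QC-passed dives when
#'   `NULL`.
#' @param bottom_frac bottom-phase boundary fraction (default 0.85).
#' @param shallow_threshold shallow-dive QC threshold (m, default 5.6).
#' @return `dives` augmented with `qc`, `BT`, `maxBT`, `stBT`, `TAD`,
#'   `descent_speed`, `ascent_speed`, `SK` and the `v_max` used.
#' @export
dive_metrics <- function(dives, v_max = NULL, bottom_frac = 0.85,
                         shallow_threshold = 5.6) {
  dives <- dive_qc(dives, threshold = shallow_threshold)
  ok <- dives$qc == "ok"
  if (is.null(v_max))
    v_max <- max_vertical_speed(dives[ok, ], bottom_frac = bottom_frac)
  vm <- unname(v_max[as.character(dives$animal)])
  if (anyNA(vm)) vm[is.na(vm)] <- mean(v_max)
  for (col in c("BT", "maxBT", "stBT", "TAD", "descent_speed",
                "ascent_speed", "SK"))
    dives[[col]] <- NA_real_
  if (any(ok)) {
    sb <- standardized_bottom_time(dives[ok, ], vm[ok], bottom_frac)
    dives$BT[ok] <- sb$BT
    dives$maxBT[ok] <- sb$maxBT
    dives$stBT[ok] <- sb$stBT
    dives$TAD[ok] <- time_at_depth_index(dives[ok, ], vm[ok])
    ls <- leg_speeds(dives[ok, ], bottom_frac)
    dives$descent_speed[ok] <- ls$descent_speed
    dives$ascent_speed[ok] <- ls$ascent_speed
    dives$SK[ok] <- dive_skewness(dives[ok, ], bottom_frac)
  }
  dives$v_max <- vm
  dives
}
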