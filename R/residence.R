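# Inside-interval of a circle along one trajectory segment.
# Returns c(ta, tb) in time units, or NULL when the segment never enters
# the circle. The inside region of a segment is a single interval.
segment_inside <- function(x1, y1, x2, y2, t1, t2, cx, cy, r) {
  dx <- x2 - x1; dy <- y2 - y1
  fx <- x1 - cx; fy <- y1 - cy
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  if (a < 1e-12) {               # stationary segment
    if (cc <= 0) return(c(t1, t2)) else return(NULL)
  }
  disc <- b * b - 4 * a * cc
  if (disc < 0) return(NULL)
  sq <- sqrt(disc)
  s1 <- (-b - sq) / (2 * a)
  s2 <- (-b + sq) / (2 * a)
  lo <- max(s1, 0); hi <- min(s2, 1)
  if (lo >= hi) {
    # touching or outside within [0,1]; keep closed-interval endpoints
    if (lo > hi) return(NULL)
  }
  c(t1 + lo * (t2 - t1), t1 + hi * (t2 - t1))
}

# One-directional residence scan: from node i forward along the bout,
# return the last time inside the circle before an excursion outside
# longer than t_sec (or before the track ends). Bridged excursions
# (<= t_sec) are crossed.
rt_scan_forward <- function(times, xs, ys, i, r, t_sec) {
  n <- length(times)
  last_inside <- times[i]
  j <- i
  while (j < n) {
    seg <- segment_inside(xs[j], ys[j], xs[j + 1], ys[j + 1],
                          times[j], times[j + 1],
                          xs[i], ys[i], r)
    if (is.null(seg) || seg[2] <= last_inside) {
      if (times[j + 1] - last_inside > t_sec) return(last_inside)
    } else {
      ta <- max(seg[1], last_inside)
      if (ta - last_inside > t_sec) return(last_inside)
      last_inside <- seg[2]
    }
    j <- j + 1
  }
  last_inside
}

#' Residence time along a regular track
#'
#' For each node, the time elapsed from the moment the trajectory enters
#' a circle of radius `r` centred on the node to the moment it leaves the
#' circle for longer than the threshold `t` (shorter excursions are
#' bridged). The entry is found by scanning backward and the exit by
#' scanning forward along the bout; crossing times are obtained by linear
#' interpolation along trajectory segments. Residence is censored at bout
#' boundaries. Nodes within `r` of a haul-out site are returned as `NA`,
#' since their residence is dominated by time spent at the site.
#'
#' @param reg_track regular track from [regularize_track()] (`animal`,
#'   `bout`, `time`, `x`, `y`).
#' @param r circle radius in metres (default 400).
#' @param t excursion time threshold in hours (default 1).
#' @param sites optional data frame of haul-out sites (`x`, `y`) for
#'   proximity masking.
#' @return Numeric vector of residence times in hours, aligned with the
#'   rows of `reg_track`.
#' @export
residence_time <- function(reg_track, r = 400, t = 1, sites = NULL) {
  if (r <= 0) stop("r must be > 0")
  if (t < 0) stop("t must be >= 0")
  t_sec <- t * 3600
  rt <- rep(NA_real_, nrow(reg_track))
  idx <- split(seq_len(nrow(reg_track)),
               list(reg_track$animal, reg_track$bout), drop = TRUE)
  for (ii in idx) {
    times <- reg_track$time[ii]
    xs <- reg_track$x[ii]
    ys <- reg_track$y[ii]
    n <- length(ii)
    for (k in seq_len(n)) {
      fwd <- rt_scan_forward(times, xs, ys, k, r, t_sec)
      bwd <- -rt_scan_forward(-rev(times), rev(xs), rev(ys),
                              n - k + 1, r, t_sec)
      rt[ii[k]] <- (fwd - bwd) / 3600
    }
  }
  if (!is.null(sites) && nrow(sites)) {
    for (s in seq_len(nrow(sites))) {
      near <- sqrt((reg_track$x - sites$x[s])^2 +
                     (reg_track$y - sites$y[s])^2) <= r
      rt[near] <- NA
    }
  }
  rt
}
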