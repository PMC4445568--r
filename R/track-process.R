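#' Filter GPS fixes and cut tracks into bouts
#'
#' Drops positions with reported error above `max_error` (50 m retains
#' only good-quality GPS fixes), then cuts each animal's series into
#' bouts wherever no position is available for `sea_gap` hours at sea or
#' `haul_gap` hours while hauled out (a gap is classified as hauled out
#' when it overlaps a haul-out event). Bouts shorter than `min_bout`
#' hours are discarded.
#'
#' @param points data frame of fixes (`animal`, `time`, `x`, `y`,
#'   `error`), sorted by time within animal.
#' @param haulouts data frame of haul-out events (`animal`, `start`,
#'   `end`); used to classify gaps.
#' @param max_error maximum retained position error (m, default 50).
#' @param sea_gap,haul_gap bout-cutting gap thresholds (h; defaults 24
#'   and 48).
#' @param min_bout minimum bout duration (h, default 3).
#' @return `points` filtered, with a `bout` id column; counts of dropped
#'   fixes and bouts are reported via attributes `n_dropped_error` and
#'   `n_dropped_short`.
#' @export
filter_and_cut <- function(points, haulouts = NULL, max_error = 50,
                           sea_gap = 24, haul_gap = 48, min_bout = 3) {
  if (!nrow(points)) {
    warning("empty input track")
    points$bout <- integer(0)
    return(points)
  }
  keep <- points$error <= max_error
  n_err <- sum(!keep)
  pts <- points[keep, ]
  out <- lapply(split(pts, pts$animal), function(p) {
    p <- p[order(p$time), ]
    gap <- diff(p$time)
    gs <- p$time[-nrow(p)]
    ge <- p$time[-1]
    hauled_gap <- rep(FALSE, length(gap))
    if (!is.null(haulouts)) {
      ho <- haulouts[haulouts$animal == p$animal[1], ]
      if (nrow(ho))
        hauled_gap <- vapply(seq_along(gap), function(i)
          any(ho$start < ge[i] & ho$end > gs[i]), logical(1))
    }
    cut_here <- gap > ifelse(hauled_gap, haul_gap, sea_gap) * 3600
    p$bout <- cumsum(c(1L, as.integer(cut_here)))
    p
  })
  pts <- do.call(rbind, out)
  rownames(pts) <- NULL
  # drop short bouts
  key <- paste(pts$animal, pts$bout)
  dur <- tapply(pts$time, key, function(t) diff(range(t)))
  short <- names(dur)[dur <= min_bout * 3600]
  n_short <- length(unique(short))
  pts <- pts[!(key %in% short), ]
  rownames(pts) <- NULL
  attr(pts, "n_dropped_error") <- n_err
  attr(pts, "n_dropped_short") <- n_short
  pts
}

#' Regularize bouts onto a fixed time grid
#'
#' Linearly interpolates each bout's positions onto a regular grid of
#' `dt` seconds starting at the first fix of the bout, and computes
#' horizontal speed at node `j` as the displacement from node `j` to node
#' `j + 1` divided by `dt` (`NA` at the last node of a bout).
#'
#' @param points output of [filter_and_cut()] (requires a `bout`
#'   column).
#' @param dt node spacing in seconds (default 1200, i.e. 20 min).
#' @return Data frame of regular nodes: `animal`, `bout`, `time`, `x`,
#'   `y`, `HS` (m/s).
#' @export
regularize_track <- function(points, dt = 1200) {
  stopifnot("bout" %in% names(points))
  out <- lapply(split(points, list(points$animal, points$bout),
                      drop = TRUE), function(p) {
    p <- p[order(p$time), ]
    if (diff(range(p$time)) < dt) return(NULL)
    tg <- seq(min(p$time), max(p$time), by = dt)
    x <- approx(p$time, p$x, xout = tg)$y
    y <- approx(p$time, p$y, xout = tg)$y
    hs <- c(sqrt(diff(x)^2 + diff(y)^2) / dt, NA)
    data.frame(animal = p$animal[1], bout = p$bout[1], time = tg,
               x = x, y = y, HS = hs)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out <- out[order(out$animal, out$bout, out$time), ]
  rownames(out) <- NULL
  out
}
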