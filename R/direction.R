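#' Classify trip direction relative to haul-out sites
#'
#' For each regular node between two haul-out events, the distance to the
#' nearest of the bracketing haul-out sites is computed, first
#' differences are smoothed with a centred running average (`window_h`
#' hours wide), and each inter-haul-out interval is divided into sections
#' wherever the smoothed difference changes sign (the boundary node joins
#' the following section). Sections are labelled: `outward` (persistent
#' increase starting within `range_km` of the previous site), `inward`
#' (persistent decrease ending within `range_km` of the next site),
#' `within_range` (entirely within `range_km` of a site), `transiting`
#' (from within range of one site to within range of a different site),
#' and `other` (no persistent directionality away from sites). Nodes
#' during a haul-out event, or in intervals with no bracketing events,
#' are labelled `within_range` and `other` respectively.
#'
#' @param reg_track regular track from [regularize_track()].
#' @param haulouts haul-out events (`animal`, `start`, `end`, `site_x`,
#'   `site_y`).
#' @param window_h running-average window width in hours (default 6).
#' @param range_km haul-out range threshold in kilometres (default 2).
#' @return Character vector of labels aligned with `reg_track` rows.
#' @export
classify_trip_direction <- function(reg_track, haulouts, window_h = 6,
                                    range_km = 2) {
  rng <- range_km * 1000
  lab <- rep("other", nrow(reg_track))
  dt <- median(diff(sort(unique(reg_track$time))))
  k <- max(1L, floor(window_h * 3600 / (2 * dt)))
  for (a in unique(reg_track$animal)) {
    ia <- which(reg_track$animal == a)
    ho <- haulouts[haulouts$animal == a, ]
    ho <- ho[order(ho$start), ]
    tt <- reg_track$time[ia]
    if (!nrow(ho)) {
      warning("animal ", a, ": no haul-out events, all nodes 'other'")
      next
    }
    in_haul <- vapply(tt, function(t)
      any(ho$start <= t & t < ho$end), logical(1))
    lab[ia[in_haul]] <- "within_range"
    prev_ev <- findInterval(tt, ho$end)        # last event ended before t
    next_ev <- prev_ev + 1L
    grp <- prev_ev
    for (g in unique(grp[!in_haul])) {
      ig <- ia[grp == g & !in_haul]
      if (!length(ig)) next
      x <- reg_track$x[ig]; y <- reg_track$y[ig]
      has_prev <- g >= 1 && g <= nrow(ho)
      has_next <- g + 1 <= nrow(ho)
      if (!has_prev && !has_next) { lab[ig] <- "other"; next }
      dp <- if (has_prev)
        sqrt((x - ho$site_x[g])^2 + (y - ho$site_y[g])^2) else Inf
      dn <- if (has_next)
        sqrt((x - ho$site_x[g + 1])^2 + (y - ho$site_y[g + 1])^2)
      else Inf
      d <- pmin(dp, dn)
      n <- length(ig)
      if (n < 2) { lab[ig] <- if (d[1] <= rng) "within_range" else
        "other"; next }
      dd <- c(NA, diff(d))
      dd[1] <- dd[2]
      sm <- vapply(seq_len(n), function(i)
        mean(dd[max(1, i - k):min(n, i + k)], na.rm = TRUE),
        numeric(1))
      s <- sign(sm)
      # a zero inherits the following non-zero sign
      for (i in rev(seq_len(n - 1))) if (s[i] == 0) s[i] <- s[i + 1]
      if (s[n] == 0) s[n] <- if (n > 1) s[n - 1] else 1
      sec <- cumsum(c(1, as.integer(diff(s) != 0)))
      for (sc in unique(sec)) {
        is <- which(sec == sc)
        f <- is[1]; l <- is[length(is)]
        lab_s <-
          if (all(d[is] <= rng)) "within_range"
          else if (d[f] <= rng && d[l] <= rng && has_prev && has_next &&
                   (dp[f] <= rng) != (dp[l] <= rng)) "transiting"
          else if (s[f] > 0 && has_prev && dp[f] <= rng) "outward"
          else if (s[f] < 0 && has_next && dn[l] <= rng) "inward"
          else "other"
        lab[ig[is]] <- lab_s
      }
    }
  }
  lab
}
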