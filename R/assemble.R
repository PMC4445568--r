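#' Build trajectory segments from a regular track
#'
#' A trajectory segment is the interval between two consecutive regular
#' nodes of a bout; it carries the leading node's horizontal indices
#' (`HS`, `MT`, `RT`, `Direction`) and position, and the distance to the
#' nearest haul-out site.
#'
#' @param reg_track regular track with `HS`, and optionally `MT`, `RT`
#'   and `Direction` columns already attached.
#' @param sites haul-out site coordinates (`x`, `y`).
#' @return Data frame of segments (`animal`, `bout`, `seg`, `t0`, `t1`,
#'   `x`, `y`, `dist_site`, `HS`, `MT`, `RT`, `Direction`).
#' @export
build_segments <- function(reg_track, sites = NULL) {
  rt <- reg_track
  if (is.null(rt$MT)) rt$MT <- NA_integer_
  if (is.null(rt$RT)) rt$RT <- NA_real_
  if (is.null(rt$Direction)) rt$Direction <- NA_character_
  out <- lapply(split(rt, list(rt$animal, rt$bout), drop = TRUE),
                function(p) {
    p <- p[order(p$time), ]
    n <- nrow(p)
    if (n < 2) return(NULL)
    i <- seq_len(n - 1)
    data.frame(animal = p$animal[1], bout = p$bout[1], seg = i,
               t0 = p$time[i], t1 = p$time[i + 1],
               x = p$x[i], y = p$y[i],
               HS = p$HS[i], MT = p$MT[i], RT = p$RT[i],
               Direction = p$Direction[i])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out$dist_site <- if (!is.null(sites) && nrow(sites)) {
    d <- rep(Inf, nrow(out))
    for (s in seq_len(nrow(sites)))
      d <- pmin(d, sqrt((out$x - sites$x[s])^2 +
                          (out$y - sites$y[s])^2))
    d
  } else Inf
  out
}

#' Aggregate dive variables per trajectory segment
#'
#' Dives are assigned to the segment containing their start time.
#' `stBT` and `Depth` are means over QC-passed dives; the predatory
#' tactic and resting indicators use the majority rules
#' ([ptactic_per_segment()], [resting_per_segment()]). Haul-out,
#' surfacing and shallow-diving occupancy times are accumulated for the
#' downstream exclusion rule.
#'
#' @param segments output of [build_segments()].
#' @param metrics per-dive metrics from [dive_metrics()], augmented with
#'   logical columns `benthic` and `resting`.
#' @param haulouts haul-out events (`animal`, `start`, `end`).
#' @return `segments` with dive aggregates and occupancy times, plus the
#'   transformed indices `neg_HS` and `invRT` (`-1000/RT` with RT in
#'   seconds).
#' @export
aggregate_dives <- function(segments, metrics, haulouts = NULL) {
  seg <- segments
  n <- nrow(seg)
  seg$n_dives <- 0L
  seg$stBT <- seg$Depth <- NA_real_
  seg$frac_benthic <- seg$resting_frac <- NA_real_
  seg$Ptactic <- seg$RestingD <- NA_integer_
  seg$dive_time <- seg$shallow_time <- 0
  for (a in unique(seg$animal)) {
    is_a <- which(seg$animal == a)
    sa <- seg[is_a, ]
    ma <- metrics[metrics$animal == a, ]
    if (!nrow(ma)) next
    ord <- order(sa$t0)
    pos <- findInterval(ma$start, sa$t0[ord])
    sid <- rep(NA_integer_, nrow(ma))
    inside <- pos >= 1 & ma$start < sa$t1[ord][pmax(pos, 1)]
    sid[inside] <- is_a[ord][pos[inside]]
    for (s in unique(sid[!is.na(sid)])) {
      di <- which(sid == s)
      m <- ma[di, ]
      ok <- m$qc == "ok" & !is.na(m$stBT)
      seg$n_dives[s] <- sum(ok)
      if (any(ok)) {
        seg$stBT[s] <- mean(m$stBT[ok])
        seg$Depth[s] <- mean(m$max_depth[ok])
      }
      clsd <- !is.na(m$benthic)
      if (any(clsd)) {
        seg$frac_benthic[s] <- mean(m$benthic[clsd])
        seg$Ptactic[s] <- as.integer(seg$frac_benthic[s] > 0.5)
      }
      rokd <- !is.na(m$resting) & m$qc != "shallow"
      if (any(rokd)) {
        seg$resting_frac[s] <-
          sum(m$duration[rokd] * m$resting[rokd]) /
          sum(m$duration[rokd])
        seg$RestingD[s] <- as.integer(seg$resting_frac[s] > 0.5)
      }
      seg$dive_time[s] <- sum(m$duration[m$qc != "shallow"])
      seg$shallow_time[s] <- sum(m$duration[m$qc == "shallow"])
    }
  }
  seg$haul_time <- 0
  if (!is.null(haulouts))
    for (a in unique(seg$animal)) {
      is_a <- which(seg$animal == a)
      ho <- haulouts[haulouts$animal == a, ]
      if (!nrow(ho)) next
      for (h in seq_len(nrow(ho))) {
        ov <- pmax(0, pmin(seg$t1[is_a], ho$end[h]) -
                     pmax(seg$t0[is_a], ho$start[h]))
        seg$haul_time[is_a] <- seg$haul_time[is_a] + ov
      }
    }
  dt <- seg$t1 - seg$t0
  seg$surface_time <- pmax(0, dt - seg$haul_time - seg$dive_time -
                             seg$shallow_time)
  seg$neg_HS <- -seg$HS
  seg$invRT <- ifelse(!is.na(seg$RT) & seg$RT > 0,
                      -1000 / (seg$RT * 3600), NA)
  seg
}

#' Apply the segment exclusion filters
#'
#' Removes segments dominated (> 50 % of the time) by haul-out, surface
#' or shallow-diving behaviour, segments within the residence-time
#' radius of a haul-out site, segments in the `transiting` or
#' `within_range` direction categories, and segments with missing model
#' covariates. Each excluded row carries exactly one primary reason (in
#' that priority order) and per-rule counts are attached.
#'
#' @param segments output of [aggregate_dives()] (with `Direction`).
#' @param r residence radius for haul-out proximity (m, default 400).
#' @return List with `retained`, `excluded` (with a `reason` column) and
#'   `counts` (per-reason tally).
#' @export
apply_exclusions <- function(segments, r = 400) {
  dt <- segments$t1 - segments$t0
  occ <- (segments$haul_time + segments$surface_time +
            segments$shallow_time) > 0.5 * dt
  near <- segments$dist_site <= r
  dirx <- segments$Direction %in% c("transiting", "within_range")
  need <- c("stBT", "Depth", "RestingD", "Ptactic", "Direction",
            "HS", "MT", "RT")
  miss <- Reduce(`|`, lapply(need, function(v) is.na(segments[[v]])))
  reason <- rep(NA_character_, nrow(segments))
  reason[miss] <- "missing"
  reason[dirx] <- "direction"
  reason[near] <- "near_haulout"
  reason[occ] <- "occupancy"
  keep <- is.na(reason)
  excluded <- segments[!keep, ]
  excluded$reason <- reason[!keep]
  counts <- table(factor(reason[!keep],
                         levels = c("occupancy", "near_haulout",
                                    "direction", "missing")))
  list(retained = segments[keep, ], excluded = excluded,
       counts = counts)
}

#' Model-ready covariate table
#'
#' Formats retained segments as the modelling table: the response
#' `stBT`, the three horizontal indices (`neg_HS`, `MT`, `invRT`), the
#' behavioural covariates and `animal` as a factor. `Direction` uses
#' `outward` as the reference level.
#'
#' @param retained retained segments from [apply_exclusions()].
#' @return Data frame ready for the model-fitting functions.
#' @export
build_model_table <- function(retained) {
  data.frame(animal = factor(retained$animal),
             stBT = retained$stBT,
             neg_HS = retained$neg_HS,
             MT = retained$MT,
             invRT = retained$invRT,
             RestingD = retained$RestingD,
             Ptactic = retained$Ptactic,
             Depth = retained$Depth,
             Direction = factor(retained$Direction,
                                levels = c("outward", "inward",
                                           "other")))
}

#' Coarsen the temporal resolution of the segment table
#'
#' Emulates lower-resolution sampling by taking every `p`-th node of the
#' regular trajectory (`p` odd; 3, 9 and 15 give 1, 3 and 5 h segments
#' from a 20-min grid). Dive variables are averaged over the `p`
#' underlying fine segments (majority for the binary indicators,
#' dive-count/time weighted); `HS` is recomputed as displacement between
#' thinned nodes over the coarse interval; `RT` and `Direction` are
#' recomputed from the thinned trajectory; `MT` is the most frequent of
#' the `p` fine-scale states (odd `p`, so no ties). `p = 1` returns the
#' input unchanged.
#'
#' @param segments fine-scale output of [aggregate_dives()].
#' @param p thinning factor (odd positive integer).
#' @param haulouts haul-out events for the direction classifier.
#' @param sites haul-out site coordinates for proximity masking.
#' @param r,t residence-time parameters (m, h).
#' @return Coarsened segment table with the same columns.
#' @export
coarsen_resolution <- function(segments, p, haulouts = NULL,
                               sites = NULL, r = 400, t = 1) {
  if (p %% 2 == 0) stop("p must be odd (a majority state must exist)")
  if (p == 1) return(segments)
  groups <- lapply(split(seq_len(nrow(segments)),
                         list(segments$animal, segments$bout),
                         drop = TRUE), function(ii) {
    ii <- ii[order(segments$t0[ii])]
    ng <- floor(length(ii) / p)
    if (!ng) return(NULL)
    lapply(seq_len(ng), function(g) ii[((g - 1) * p + 1):(g * p)])
  })
  groups <- unlist(groups[!vapply(groups, is.null, logical(1))],
                   recursive = FALSE)
  coarse <- do.call(rbind, lapply(groups, function(ii) {
    s <- segments[ii, ]
    w <- ifelse(is.na(s$n_dives), 0, s$n_dives)
    wmean <- function(v, w) {
      ok <- !is.na(v) & w > 0
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * w[ok]) / sum(w[ok])
    }
    mt <- s$MT[!is.na(s$MT)]
    fb <- wmean(s$frac_benthic, w)
    rf <- wmean(s$resting_frac, s$dive_time)
    data.frame(animal = s$animal[1], bout = s$bout[1], seg = s$seg[1],
               t0 = s$t0[1], t1 = s$t1[nrow(s)],
               x = s$x[1], y = s$y[1],
               HS = NA_real_,
               MT = if (length(mt)) as.integer(mean(mt) > 0.5)
                    else NA_integer_,
               RT = NA_real_, Direction = NA_character_,
               dist_site = min(s$dist_site),
               n_dives = sum(s$n_dives),
               stBT = wmean(s$stBT, w), Depth = wmean(s$Depth, w),
               frac_benthic = fb,
               resting_frac = rf,
               Ptactic = if (is.na(fb)) NA_integer_ else
                 as.integer(fb > 0.5),
               RestingD = if (is.na(rf)) NA_integer_ else
                 as.integer(rf > 0.5),
               dive_time = sum(s$dive_time),
               shallow_time = sum(s$shallow_time),
               haul_time = sum(s$haul_time),
               surface_time = sum(s$surface_time))
  }))
  rownames(coarse) <- NULL
  # thinned trajectory: the leading node of each coarse segment
  thin <- data.frame(animal = coarse$animal, bout = coarse$bout,
                     time = coarse$t0, x = coarse$x, y = coarse$y,
                     HS = NA_real_)
  ord <- order(thin$animal, thin$bout, thin$time)
  thin <- thin[ord, ]
  key <- paste(thin$animal, thin$bout)
  hs <- c(sqrt(diff(thin$x)^2 + diff(thin$y)^2) / diff(thin$time), NA)
  hs[c(key[-1] != key[-length(key)], TRUE)] <- NA
  thin$HS <- hs
  thin$RT <- residence_time(thin, r = r, t = t, sites = sites)
  thin$Direction <- if (!is.null(haulouts))
    classify_trip_direction(thin, haulouts) else NA_character_
  m <- match(paste(coarse$animal, coarse$bout, coarse$t0),
             paste(thin$animal, thin$bout, thin$time))
  coarse$HS <- thin$HS[m]
  coarse$RT <- thin$RT[m]
  coarse$Direction <- thin$Direction[m]
  coarse$neg_HS <- -coarse$HS
  coarse$invRT <- ifelse(!is.na(coarse$RT) & coarse$RT > 0,
                         -1000 / (coarse$RT * 3600), NA)
  coarse
}
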