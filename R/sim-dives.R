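# Linear predictor of per-dive standardized bottom time from ground-truth
# covariates (the generative model is shared by the table simulator).
dive_linpred <- function(eff, resting, benthic, depth, neg_hs, dir) {
  eff$intercept +
    eff$restingd * resting +
    eff$ptactic * benthic +
    eff$depth * depth +
    eff$hfi * neg_hs +
    eff$hfi_ptactic * neg_hs * benthic +
    eff$hfi_depth * neg_hs * depth +
    eff$dir_inward * (dir == "inward") +
    eff$dir_other * (dir == "other")
}

# Solve the flat-bottom duration needed so a down-flat-up dive attains a
# target standardized bottom time, given leg speeds and the maximum
# vertical speed that defines the minimum travel time.
solve_bottom_flat <- function(stbt, maxd, s_d, s_a, v_max) {
  stbt <- pmin(pmax(stbt, 0.02), 0.95)
  A <- maxd * (1 / s_d + 1 / s_a - 1.7 / v_max)
  B <- 0.15 * maxd * (1 / s_d + 1 / s_a)
  flat <- (stbt * A - B) / (1 - stbt)
  pmin(pmax(flat, 0), 1250)
}

#' Simulate dive records over a track
#'
#' Generates per-animal dive series during the at-sea periods of a
#' simulated track. Benthic dives reach the local (mapped) bottom depth
#' plus a configurable signed offset; pelagic dives terminate strictly
#' above the bottom; resting dives drift down slowly and ascend fast
#' (strongly skewed) and occur in bouts during which horizontal movement
#' is minimal. Per-dive bottom time is set top-down so that standardized
#' bottom time follows the ground-truth linear model in `config`
#' (`effect_sizes`), with a shared per-20-min-segment residual so the
#' segment means obey the model at the configured residual scale. Each
#' dive is serialized as 11 depth readings equally spaced in time.
#' Artefacts (missed-surfacing concatenated dives, dives shallower than
#' 5.6 m) are injected at configured rates.
#'
#' @param track_sim output of [simulate_track()].
#' @param bathymetry a [bathy_grid()] covering the track.
#' @param config the [sim_config()] used for the track.
#' @return A list with `dives` (animal, dive_id, start, duration,
#'   max_depth, d0..d10), `truth` (per-dive class and generation
#'   internals), and `animal_pars` (per-animal maximum vertical speed and
#'   random intercept/slope).
#' @export
simulate_dives <- function(track_sim, bathymetry, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(bathymetry, "bathy_grid"))
  cfg <- config
  eff <- cfg$effect_sizes
  dt <- cfg$gps_interval
  all_dives <- all_truth <- vector("list", cfg$n_animals)
  apars <- vector("list", cfg$n_animals)

  for (a in seq_len(cfg$n_animals)) {
    st <- track_sim$states[track_sim$states$animal == a, ]
    ho <- track_sim$haulouts[track_sim$haulouts$animal == a, ]
    t_end <- max(st$time)
    with_seed(derive_seed(cfg$seed, a * 10 + 2), {
      v_max_a <- runif(1, cfg$max_vertical_speed_range[1],
                       cfg$max_vertical_speed_range[2])
      u1 <- rnorm(1, 0, eff$sd_intercept)
      u2 <- rnorm(1, 0, eff$sd_slope)

      # per-step ground-truth covariates on the regular grid
      n_st <- nrow(st)
      hs_true <- c(sqrt(diff(st$x)^2 + diff(st$y)^2) / diff(st$time), NA)
      seg_time <- st$time

      # at-sea intervals = complement of haul-out events
      bounds <- c(0, as.vector(t(ho[, c("start", "end")])), t_end)
      sea <- matrix(bounds, ncol = 2, byrow = TRUE)
      sea <- sea[sea[, 2] - sea[, 1] > 600, , drop = FALSE]

      # resting-bout windows along at-sea time
      rw_start <- rw_end <- numeric(0)
      if (cfg$resting_rate > 0)
        for (r in seq_len(nrow(sea))) {
          len_h <- (sea[r, 2] - sea[r, 1]) / 3600
          nb <- rpois(1, cfg$resting_rate * len_h)
          if (nb > 0) {
            s0 <- sort(runif(nb, sea[r, 1], sea[r, 2]))
            e0 <- pmin(s0 + rexp(nb, 1 / (cfg$resting_mean_h * 3600)),
                       sea[r, 2])
            rw_start <- c(rw_start, s0); rw_end <- c(rw_end, e0)
          }
        }
      in_resting <- function(t) {
        if (!length(rw_start)) return(rep(FALSE, length(t)))
        vapply(t, function(ti) any(ti >= rw_start & ti < rw_end),
               logical(1))
      }

      gap_mean <- max(10, 3600 / cfg$dive_rate - 200)
      dl <- list(); k <- 0
      for (r in seq_len(nrow(sea))) {
        len <- sea[r, 2] - sea[r, 1]
        # the provisional step deliberately underestimates the dive
        # cycle so the final repacking fills the whole interval
        n_cand <- ceiling(len / (gap_mean + 30)) + 5
        gaps <- 10 + rexp(n_cand, 1 / gap_mean)
        t_prov <- sea[r, 1] + cumsum(gaps + 50)
        t_prov <- t_prov[t_prov < sea[r, 2] - 60]
        nd <- length(t_prov)
        if (!nd) next
        tactic_benthic <- runif(1) < cfg$p_benthic_tactic
        resting <- in_resting(t_prov)
        follow <- runif(nd) < cfg$tactic_fidelity
        benthic_active <- ifelse(follow, tactic_benthic, !tactic_benthic)
        benthic <- ifelse(resting,
                          runif(nd) >= cfg$resting_frac_pelagic,
                          benthic_active)

        # all per-dive randomness is drawn once, so the repacking pass
        # below is deterministic given a start time
        z_off <- rnorm(nd, cfg$benthic_depth_bias, cfg$benthic_depth_sd)
        u_frac <- runif(nd, cfg$dive_depth_frac[1],
                        cfg$dive_depth_frac[2])
        s_d <- ifelse(resting, runif(nd, 0.15, 0.30),
                      pmin(v_max_a * exp(0.25 * (rnorm(nd) - 1.645)),
                           v_max_a * 1.12))
        s_a <- ifelse(resting, runif(nd, 1.2, 1.7),
                      pmin(v_max_a * exp(0.25 * (rnorm(nd) - 1.645)),
                           v_max_a * 1.12))
        s_d <- pmax(s_d, 0.15); s_a <- pmax(s_a, 0.35)
        # the model residual is attached per dive (drawn once), keeping
        # the repacking pass deterministic; segment means then follow
        # the linear model with a residual scale of roughly
        # resid_sd / sqrt(dives per segment)
        z_dive <- rnorm(nd, 0, eff$resid_sd)
        build <- function(t0) {
          px <- approx(st$time, st$x, xout = t0, rule = 2)$y
          py <- approx(st$time, st$y, xout = t0, rule = 2)$y
          bottom <- bathy_depth_at(bathymetry, px, py)
          bottom[is.na(bottom)] <- 30
          maxd <- ifelse(benthic,
                         pmax(bottom + z_off, 6.5),
                         pmax(pmin(bottom * u_frac, bottom - 1),
                              pmin(6.5, bottom - 1)))
          maxd <- pmax(maxd, 1.2)
          bin <- pmin(pmax(findInterval(t0, seg_time), 1), n_st)
          neg_hs <- -hs_true[bin]
          neg_hs[is.na(neg_hs)] <- -cfg$speed_mean[2]
          # resting bouts are horizontally static
          neg_hs[resting] <- pmax(neg_hs[resting], -0.08)
          dirv <- st$dir_truth[bin]
          dirv[is.na(dirv)] <- "other"
          mu <- dive_linpred(eff, as.numeric(resting),
                             as.numeric(benthic), maxd, neg_hs, dirv) +
            u1 + u2 * neg_hs + z_dive
          # a dive travelling at v_max has stBT = 1 whatever its bottom
          # time, so low targets require slow travel: when the target
          # sits below the geometric floor 0.15*H/(H - 1.7/v), both legs
          # are slowed until the floor drops just under the target
          st_t <- pmin(pmax(mu, 0.16), 0.95)
          H <- 1 / s_d + 1 / s_a
          floor0 <- 0.15 * H / (H - 1.7 / v_max_a)
          cf <- rep(1, nd)
          low <- st_t < floor0
          cf[low] <- v_max_a * H[low] *
            (1 - 0.15 / (0.98 * st_t[low])) / 1.7
          cf <- pmin(pmax(cf, maxd * H / 900), 1)
          sd2 <- s_d * cf
          sa2 <- s_a * cf
          flat <- solve_bottom_flat(st_t, maxd, sd2, sa2, v_max_a)
          dur <- maxd / sd2 + maxd / sa2 + flat
          list(maxd = maxd, s_d = sd2, s_a = sa2, flat = flat,
               dur = dur, mu = mu, neg_hs = neg_hs, dir = dirv,
               bottom = bottom, bin = bin)
        }
        # second pass: repack start times with the realized durations
        # (padded, since the rebuild at the new times perturbs each
        # duration through its segment's covariates)
        g1 <- build(t_prov)
        t_fin <- sea[r, 1] + cumsum(gaps[seq_len(nd)] +
                                      c(0, 1.1 * g1$dur[-nd] + 10))
        g <- build(t_fin)
        # durations can shift marginally between passes (the dive is
        # relocated); trim the flat bottom so dives never overlap
        allowed <- c(diff(t_fin) - 5, Inf)
        legs <- g$maxd / g$s_d + g$maxd / g$s_a
        g$flat <- pmin(g$flat, pmax(allowed - legs, 0))
        g$dur <- legs + g$flat
        keep <- t_fin + g$dur < sea[r, 2] & legs <= allowed
        if (!any(keep)) next
        k <- k + 1
        dl[[k]] <- data.frame(start = t_fin, resting = resting,
                              benthic = benthic, maxd = g$maxd,
                              s_d = g$s_d, s_a = g$s_a, flat = g$flat,
                              dur = g$dur, mu = g$mu, neg_hs = g$neg_hs,
                              dir = g$dir, bottom = g$bottom,
                              bin = g$bin)[keep, ]
      }
      if (!length(dl)) {
        all_dives[[a]] <- NULL
        next
      }
      dd <- do.call(rbind, dl)
      nd <- nrow(dd)

      # artefact injection
      art <- rep("none", nd)
      u <- runif(nd)
      art[u < cfg$shallow_rate] <- "shallow"
      art[u >= cfg$shallow_rate &
            u < cfg$shallow_rate + cfg$missed_surfacing_rate] <-
        "missed_surf"

      # serialize to 11 equally-time-spaced depth readings
      frac <- seq(0, 1, length.out = 11)
      prof <- matrix(0, nd, 11)
      max_depth <- dd$maxd
      duration <- dd$dur
      for (i in seq_len(nd)) {
        if (art[i] == "shallow") {
          avail <- if (i < nd) dd$start[i + 1] - dd$start[i] - 2 else
            1500
          md <- runif(1, 1.5, 5.3)
          du <- min(2 * md / 0.8 + runif(1, 10, 30), avail)
          max_depth[i] <- md; duration[i] <- du
          tt <- frac * du
          prof[i, ] <- pmin(0.8 * tt, 0.8 * (du - tt), md)
        } else if (art[i] == "missed_surf") {
          # two dives compressed into one record by a missed surfacing:
          # the profile dips to near-surface mid-record without a
          # registered surfacing
          avail <- if (i < nd) dd$start[i + 1] - dd$start[i] - 2 else
            1500
          du <- min(max(2 * dd$dur[i], 120), avail, 1500)
          if (du < 80) {
            art[i] <- "none"
            tt <- frac * duration[i]
            prof[i, ] <- pmin(dd$s_d[i] * tt,
                              dd$s_a[i] * (duration[i] - tt),
                              dd$maxd[i])
          } else {
            md <- dd$maxd[i]; md2 <- md * runif(1, 0.6, 1)
            dsurf <- 0.05 * max(md, md2)
            wt <- c(0, 0.15, 0.35, 0.45, 0.55, 0.7, 0.85, 1) * du
            wd <- c(0, md, md, dsurf, dsurf, md2, md2, 0)
            duration[i] <- du; max_depth[i] <- max(md, md2)
            prof[i, ] <- approx(wt, wd, xout = frac * du)$y
          }
        } else {
          tt <- frac * duration[i]
          prof[i, ] <- pmin(dd$s_d[i] * tt,
                            dd$s_a[i] * (duration[i] - tt),
                            dd$maxd[i])
        }
      }
      colnames(prof) <- paste0("d", 0:10)
      # realized standardized bottom time of the constructed geometry
      A <- dd$maxd * (1 / dd$s_d + 1 / dd$s_a - 1.7 / v_max_a)
      B <- 0.15 * dd$maxd * (1 / dd$s_d + 1 / dd$s_a)
      stbt_real <- (dd$flat + B) / (dd$flat + A)

      cls <- ifelse(dd$resting, "resting",
                    ifelse(dd$benthic, "benthic", "pelagic"))
      dives <- data.frame(animal = a,
                          dive_id = paste0(a, "_", seq_len(nd)),
                          start = dd$start, duration = duration,
                          max_depth = max_depth)
      dives <- cbind(dives, as.data.frame(prof))
      truth <- data.frame(animal = a, dive_id = dives$dive_id,
                          class = cls, resting = dd$resting,
                          benthic = dd$benthic, artefact = art,
                          stbt_target = pmin(pmax(dd$mu, 0.02), 0.95),
                          stbt_real = stbt_real,
                          neg_hs_true = dd$neg_hs, dir_truth = dd$dir,
                          bottom_true = dd$bottom, bin = dd$bin,
                          s_d = dd$s_d, s_a = dd$s_a)
      all_dives[[a]] <- dives
      all_truth[[a]] <- truth
      apars[[a]] <- data.frame(animal = a, v_max = v_max_a,
                               u_intercept = u1, u_slope = u2)
    })
  }
  list(dives = do.call(rbind, all_dives),
       truth = do.call(rbind, all_truth),
       animal_pars = do.call(rbind, apars))
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper: bathymetry, tracks, haul-outs, dives and ground
#' truth from one configuration.
#'
#' @param config a [sim_config()].
#' @param bathymetry optional [bathy_grid()]; generated from the config
#'   seed when omitted.
#' @return A list with `config`, `bathymetry`, `track`, `haulouts`,
#'   `sites`, `states`, `dives`, `truth`, `animal_pars`.
#' @export
simulate_dataset <- function(config = sim_config(), bathymetry = NULL) {
  if (is.null(bathymetry))
    bathymetry <- synth_bathymetry(seed = derive_seed(config$seed, 99))
  trk <- simulate_track(config)
  dv <- simulate_dives(trk, bathymetry, config)
  c(list(config = config, bathymetry = bathymetry), trk, dv)
}
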