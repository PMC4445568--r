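# Planar extent of the synthetic world (m); matches the default
# synth_bathymetry() domain. The study system is a single fjord, so a
# flat plane in metres is used throughout (no geodesy).
world_extent <- function() 20000

haulout_site_coords <- function(n_sites, extent = world_extent()) {
  data.frame(site = seq_len(n_sites),
             x = extent * seq_len(n_sites) / (n_sites + 1),
             y = rep(300, n_sites))
}

# Alternating haul-out / at-sea renewal schedule over [0, t_end].
# Starts hauled out (animals are tagged at a haul-out site).
sim_haulout_schedule <- function(t_end, haul_mean_h, sea_mean_h) {
  starts <- ends <- numeric(0)
  t <- 0
  hauled <- TRUE
  while (t < t_end) {
    if (hauled) {
      dur <- max(1800, rexp(1, 1 / (haul_mean_h * 3600)))
      starts <- c(starts, t)
      ends <- c(ends, min(t + dur, t_end))
    } else {
      dur <- max(3600, rexp(1, 1 / (sea_mean_h * 3600)))
    }
    t <- t + dur
    hauled <- !hauled
  }
  data.frame(start = starts, end = ends)
}

#' Simulate GPS tracks, haul-out events and movement states
#'
#' Generates one two-state correlated random walk per animal on a planar
#' world, with haul-out events during which the animal sits at a fixed
#' shore site. Steps are taken on the regular tag interval
#' (`gps_interval`); state 1 is extensive (fast, directional), state 2
#' intensive (slow, tortuous). Before a scheduled haul-out the animal
#' steers back towards its haul-out site, producing outward/inward trip
#' structure. GPS fixes are jittered by `gps_error_sd` and, governed by
#' `gps_dropout_prob`, either missed or delayed, emulating tag behaviour.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   `track` (animal, time, x, y, error), `haulouts` (animal, start, end,
#'   site, site_x, site_y), `sites` (site coordinates), and `states`
#'   (ground truth per regular step: animal, time, x, y, hauled, state
#'   with 1 = extensive / 2 = intensive / `NA` hauled, and `dir_truth`,
#'   the generated trip phase in `outward`/`inward`/`other`).
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  ext <- world_extent()
  sites <- haulout_site_coords(cfg$n_haulout_sites)
  dt <- cfg$gps_interval
  t_end <- cfg$days * 86400
  tracks <- states <- hauls <- vector("list", cfg$n_animals)

  for (a in seq_len(cfg$n_animals)) {
    with_seed(derive_seed(cfg$seed, a * 10 + 1), {
      sched <- sim_haulout_schedule(t_end, cfg$haul_mean_h, cfg$sea_mean_h)
      site_id <- integer(nrow(sched))
      tg <- seq(0, t_end, by = dt)
      n <- length(tg)
      x <- y <- numeric(n)
      st <- integer(n)
      hauled <- logical(n)
      phase <- character(n)
      # start hauled at a random site
      cur_site <- sample.int(nrow(sites), 1)
      if (nrow(sched)) site_id[1] <- cur_site
      x[1] <- sites$x[cur_site]; y[1] <- sites$y[cur_site]
      st[1] <- 1L
      heading <- runif(1, -pi, pi)
      haul_end_t <- -Inf
      new_target <- function(sx)
        c(min(max(sx + rnorm(1, 0, 4000), 500), ext - 500),
          runif(1, 2500, 14000))
      target <- new_target(sites$x[cur_site])
      for (k in seq_len(n - 1)) {
        t <- tg[k]
        hi <- which(sched$start <= t & t < sched$end)
        nxt <- which(sched$start > t)
        next_haul <- if (length(nxt)) sched$start[nxt[1]] else Inf
        if (length(hi)) {          # hauled out: pinned to the site
          if (site_id[hi[1]] == 0) {
            cur_site <- which.min((sites$x - x[k])^2 + (sites$y - y[k])^2)
            site_id[hi[1]] <- cur_site
          }
          cur_site <- site_id[hi[1]]
          hauled[k] <- TRUE
          st[k] <- NA
          phase[k] <- "haul"
          x[k] <- sites$x[cur_site]; y[k] <- sites$y[cur_site]
          x[k + 1] <- x[k]; y[k + 1] <- y[k]
          if (sched$end[hi[1]] > haul_end_t) {
            haul_end_t <- sched$end[hi[1]]
            # each trip heads for a fresh offshore foraging ground
            target <- new_target(sites$x[cur_site])
          }
          next
        }
        # at sea: evolve the state chain
        st[k] <- if (k > 1 && !hauled[k - 1] && !is.na(st[k - 1])) {
          s_prev <- st[k - 1]
          if (runif(1) < cfg$state_transition[s_prev, 1]) 1L else 2L
        } else 1L
        sp_target <- max(0, rnorm(1, cfg$speed_mean[st[k]],
                                  cfg$speed_sd[st[k]]))
        d_site <- sqrt((sites$x[cur_site] - x[k])^2 +
                         (sites$y[cur_site] - y[k])^2)
        v_ret <- max(cfg$speed_mean[1], 0.3)
        need <- d_site / v_ret
        if (is.finite(next_haul) && (next_haul - t) <= need * 1.3 + dt) {
          # return leg: head for the haul-out site
          phase[k] <- "inward"
          heading <- atan2(sites$y[cur_site] - y[k],
                           sites$x[cur_site] - x[k]) +
            rnorm(1, 0, 0.15)
          sp <- if (d_site < 150) 0 else
            min(max(sp_target, v_ret, d_site / max(next_haul - t, dt)), 2.5)
        } else {
          d_target <- sqrt((target[1] - x[k])^2 + (target[2] - y[k])^2)
          if (d_target > 1500 && t - haul_end_t <= 5 * 3600) {
            # outbound transit towards the trip's foraging ground
            phase[k] <- "outward"
            heading <- atan2(target[2] - y[k], target[1] - x[k]) +
              rnorm(1, 0, 0.2)
            sp <- max(sp_target, cfg$speed_mean[1])
          } else {
            phase[k] <- "other"
            near_wall <- x[k] < 1500 || x[k] > ext - 1500 ||
              y[k] < 1500 || y[k] > ext - 1500
            heading <- if (near_wall)
              atan2(ext / 2 - y[k], ext / 2 - x[k]) + rnorm(1, 0, 0.5)
            else heading + rnorm(1, 0, 1 / sqrt(cfg$turn_kappa[st[k]]))
            sp <- sp_target
          }
        }
        # directed transit legs are extensive movement by construction
        if (phase[k] %in% c("outward", "inward")) st[k] <- 1L
        x[k + 1] <- x[k] + sp * dt * cos(heading)
        y[k + 1] <- y[k] + sp * dt * sin(heading)
        # reflect at the world boundary
        if (x[k + 1] < 100) x[k + 1] <- 200 - x[k + 1]
        if (x[k + 1] > ext - 100) x[k + 1] <- 2 * (ext - 100) - x[k + 1]
        if (y[k + 1] < 100) y[k + 1] <- 200 - y[k + 1]
        if (y[k + 1] > ext - 100) y[k + 1] <- 2 * (ext - 100) - y[k + 1]
      }
      hi <- which(sched$start <= tg[n] & tg[n] < sched$end)
      if (length(hi)) { hauled[n] <- TRUE; st[n] <- NA; phase[n] <- "haul" }
      else { st[n] <- st[n - 1]; phase[n] <- "other" }
      # unassigned scheduled events (none started yet) default to nearest
      site_id[site_id == 0] <- cur_site

      # GPS fixes: thinned / delayed / jittered
      u <- runif(n)
      keep <- u >= cfg$gps_dropout_prob * 0.5
      delayed <- u >= cfg$gps_dropout_prob * 0.5 &
        u < cfg$gps_dropout_prob
      delay <- ifelse(delayed, pmin(rexp(n, 1 / 180), 900), 0)
      tf <- tg + delay
      fx <- approx(tg, x, xout = tf, rule = 2)$y +
        rnorm(n, 0, cfg$gps_error_sd)
      fy <- approx(tg, y, xout = tf, rule = 2)$y +
        rnorm(n, 0, cfg$gps_error_sd)
      err <- pmin(rlnorm(n, log(12), 0.6), 45)
      # a small fraction of poor-quality fixes (error > 50 m) exercises
      # the downstream filter; suppressed for noise-free configurations
      bad <- runif(n) < 0.05 & cfg$gps_error_sd > 0
      err[bad] <- runif(sum(bad), 51, 150)
      fx[bad] <- fx[bad] + rnorm(sum(bad), 0, err[bad] / 1.96)
      fy[bad] <- fy[bad] + rnorm(sum(bad), 0, err[bad] / 1.96)
      trk <- data.frame(animal = a, time = tf, x = fx, y = fy,
                        error = err)[keep, ]
      trk <- trk[order(trk$time), ]
      trk <- trk[!duplicated(trk$time), ]
      tracks[[a]] <- trk
      states[[a]] <- data.frame(animal = a, time = tg, x = x, y = y,
                                hauled = hauled, state = st,
                                dir_truth = ifelse(phase == "haul", NA,
                                                   phase))
      hauls[[a]] <- data.frame(animal = a, start = sched$start,
                               end = sched$end, site = site_id,
                               site_x = sites$x[site_id],
                               site_y = sites$y[site_id])
    })
  }
  list(track = do.call(rbind, tracks),
       haulouts = do.call(rbind, hauls),
       sites = sites,
       states = do.call(rbind, states))
}
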