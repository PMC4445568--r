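#' Simulation configuration
#'
#' Parameters for the synthetic biologging generator. Defaults emulate the
#' tag behaviour and study conditions of a fjord-resident harbour seal
#' population tracked with GPS phone tags: target 20-min GPS interval with
#' occasional delayed or missed registrations, dives stored as 11-point
#' time-depth profiles, haul-out events from a wet/dry sensor, and a
#' two-state (extensive/intensive) horizontal movement process with a
#' stationary intensive fraction near 0.77.
#'
#' The ground-truth linear model for standardized bottom time
#' (`effect_sizes`) defaults to the study-scale coefficients: intercept
#' 0.480, resting-while-diving -0.278, benthic predatory tactic 0.138,
#' mean dive depth 0.002 per metre, horizontal-index slope 0.001,
#' index-by-tactic interaction 0.063, index-by-depth interaction 0.001,
#' trip-direction contrasts 0.013 (inward) and 0.006 (other), residual
#' standard deviation `sqrt(0.0243)`, and between-individual standard
#' deviations `sqrt(4e-4)` (intercept) and `sqrt(6e-4)` (index slope).
#'
#' @param n_animals number of simulated individuals.
#' @param days tracking duration per individual (days).
#' @param gps_interval target GPS sampling interval (s).
#' @param gps_dropout_prob probability that a scheduled fix is missed.
#' @param gps_error_sd GPS position jitter standard deviation (m).
#' @param state_transition 2x2 row-stochastic matrix of per-step
#'   transition probabilities between extensive (state 1) and intensive
#'   (state 2) movement.
#' @param speed_mean,speed_sd per-state step-speed mean and sd (m/s),
#'   extensive first.
#' @param turn_kappa per-state angular concentration of turning angles
#'   (larger = more directional), extensive first.
#' @param haul_mean_h mean haul-out event duration (h).
#' @param sea_mean_h mean at-sea interval between haul-outs (h).
#' @param n_haulout_sites number of haul-out sites along the shore.
#' @param dive_rate dives per hour while at sea.
#' @param dive_depth_frac pelagic dives reach this fraction range of the
#'   local bottom depth (length-2 vector).
#' @param benthic_depth_bias,benthic_depth_sd mean and sd (m) of the
#'   signed offset of benthic maximum dive depth below the mapped bottom
#'   (positive = deeper than mapped, emulating bathymetry/tide error).
#' @param p_benthic_tactic probability that an at-sea period uses the
#'   benthic tactic; within a period dives follow the period tactic with
#'   probability `tactic_fidelity`.
#' @param tactic_fidelity see `p_benthic_tactic`.
#' @param max_vertical_speed population-mean maximum vertical speed (m/s);
#'   per-animal values are drawn uniformly within
#'   `max_vertical_speed_range`.
#' @param max_vertical_speed_range length-2 vector (m/s).
#' @param resting_rate resting-bout starts per at-sea hour.
#' @param resting_mean_h mean resting-bout duration (h).
#' @param resting_frac_pelagic fraction of resting dives that are pelagic.
#' @param shallow_rate fraction of dives generated shallower than 5.6 m.
#' @param missed_surfacing_rate fraction of dives generated as
#'   concatenated double-dives (missed surfacing artefact).
#' @param effect_sizes named list of ground-truth coefficients for the
#'   per-segment standardized bottom time model; see Details.
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 14,
                       days = 180,
                       gps_interval = 1200,
                       gps_dropout_prob = 0.15,
                       gps_error_sd = 15,
                       state_transition = matrix(c(0.90, 0.10,
                                                   0.03, 0.97),
                                                 2, 2, byrow = TRUE),
                       speed_mean = c(1.0, 0.25),
                       speed_sd = c(0.30, 0.12),
                       turn_kappa = c(8, 0.7),
                       haul_mean_h = 6,
                       sea_mean_h = 18,
                       n_haulout_sites = 3,
                       dive_rate = 24,
                       dive_depth_frac = c(0.15, 0.70),
                       benthic_depth_bias = 2.8,
                       benthic_depth_sd = 1.5,
                       p_benthic_tactic = 0.5,
                       tactic_fidelity = 0.9,
                       max_vertical_speed = 1.97,
                       max_vertical_speed_range = c(1.75, 2.16),
                       resting_rate = 0.04,
                       resting_mean_h = 1.5,
                       resting_frac_pelagic = 2 / 3,
                       shallow_rate = 0.10,
                       missed_surfacing_rate = 0.05,
                       effect_sizes = list(),
                       seed = 1L) {
  eff <- list(intercept = 0.480, restingd = -0.278, ptactic = 0.138,
              depth = 0.002, hfi = 0.001, hfi_ptactic = 0.063,
              hfi_depth = 0.001, dir_inward = 0.013, dir_other = 0.006,
              sd_intercept = sqrt(4e-4), sd_slope = sqrt(6e-4),
              resid_sd = sqrt(0.0243))
  eff[names(effect_sizes)] <- effect_sizes
  cfg <- list(n_animals = as.integer(n_animals), days = days,
              gps_interval = gps_interval,
              gps_dropout_prob = gps_dropout_prob,
              gps_error_sd = gps_error_sd,
              state_transition = state_transition,
              speed_mean = speed_mean, speed_sd = speed_sd,
              turn_kappa = turn_kappa,
              haul_mean_h = haul_mean_h, sea_mean_h = sea_mean_h,
              n_haulout_sites = as.integer(n_haulout_sites),
              dive_rate = dive_rate, dive_depth_frac = dive_depth_frac,
              benthic_depth_bias = benthic_depth_bias,
              benthic_depth_sd = benthic_depth_sd,
              p_benthic_tactic = p_benthic_tactic,
              tactic_fidelity = tactic_fidelity,
              max_vertical_speed = max_vertical_speed,
              max_vertical_speed_range = max_vertical_speed_range,
              resting_rate = resting_rate,
              resting_mean_h = resting_mean_h,
              resting_frac_pelagic = resting_frac_pelagic,
              shallow_rate = shallow_rate,
              missed_surfacing_rate = missed_surfacing_rate,
              effect_sizes = eff, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tm <- cfg$state_transition
  if (!is.matrix(tm) || any(dim(tm) != 2) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-8))
    stop("state_transition must be a 2x2 row-stochastic matrix")
  if (all(cfg$speed_mean == 0) && all(cfg$speed_sd == 0))
    stop("non-stochastic config: step speeds are zero in both states")
  if (cfg$gps_error_sd < 0) stop("gps_error_sd must be >= 0")
  if (cfg$gps_dropout_prob < 0 || cfg$gps_dropout_prob > 1)
    stop("gps_dropout_prob must be a probability")
  pos <- c(n_animals = cfg$n_animals, days = cfg$days,
           gps_interval = cfg$gps_interval, haul_mean_h = cfg$haul_mean_h,
           sea_mean_h = cfg$sea_mean_h, dive_rate = cfg$dive_rate,
           max_vertical_speed = cfg$max_vertical_speed,
           resting_mean_h = cfg$resting_mean_h)
  if (any(pos <= 0))
    stop("non-positive parameter: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  if (any(cfg$speed_sd < 0) || any(cfg$speed_mean < 0))
    stop("speed parameters must be >= 0")
  rates <- c(cfg$resting_rate, cfg$shallow_rate,
             cfg$missed_surfacing_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  invisible(cfg)
}
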