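#' Distance between maximum dive depth and the sea bottom
#'
#' Each dive is located by linear time-interpolation between the two GPS
#' fixes bracketing its start (constant swim speed on a straight line is
#' assumed), the bottom depth is looked up in the bathymetry cell
#' containing that position, and the signed distance
#' `bottom depth - max depth` is returned (positive above the bottom,
#' negative when the dive is deeper than the mapped bottom, which occurs
#' through location, bathymetry and tidal errors).
#'
#' @param dives data frame of dive records (`animal`, `start`,
#'   `max_depth`).
#' @param track data frame of filtered GPS fixes (`animal`, `time`, `x`,
#'   `y`).
#' @param bathymetry a [bathy_grid()].
#' @return Numeric vector of bottom distances (m); `NA` when the dive is
#'   not bracketed by fixes or falls outside the grid.
#' @export
bottom_distance <- function(dives, track, bathymetry) {
  out <- rep(NA_real_, nrow(dives))
  for (a in unique(dives$animal)) {
    id <- which(dives$animal == a)
    tr <- track[track$animal == a, ]
    if (nrow(tr) < 2) next
    tr <- tr[order(tr$time), ]
    tt <- dives$start[id]
    inside <- tt >= min(tr$time) & tt <= max(tr$time)
    px <- approx(tr$time, tr$x, xout = tt)$y
    py <- approx(tr$time, tr$y, xout = tt)$y
    bd <- bathy_depth_at(bathymetry, px, py)
    out[id] <- ifelse(inside, bd - dives$max_depth[id], NA)
  }
  out
}

#' Classify benthic versus pelagic dives from bottom distances
#'
#' Fits normal mixtures with `K` components (EM, model selection by BIC)
#' to the distribution of bottom distances. The component whose mean is
#' closest to zero is taken as the benthic component (dives reaching the
#' sea bottom, with scatter from location/bathymetry/tide errors); the
#' classification threshold is that component's upper 95 % quantile in
#' closed form, `mean + qnorm(0.95) * sd`. Dives at or below the
#' threshold are benthic.
#'
#' @param distances numeric vector of bottom distances (m); `NA` dropped.
#' @param K candidate component counts (default `1:5`).
#' @param seed integer seed for the EM initialization subset (large
#'   samples are initialized from a random subset).
#' @return A list of class `mixture_fit`: `K` (selected), `weights`,
#'   `means`, `sds`, `fit_score` (BIC per candidate K),
#'   `benthic_component`, `threshold` (m), and `benthic`, a logical
#'   vector aligned with `distances` (`NA` where the distance is
#'   missing).
#' @export
fit_benthic_mixture <- function(distances, K = 1:5, seed = 1L) {
  ok <- !is.na(distances)
  d <- distances[ok]
  if (length(d) < 50) stop("too few bottom distances for mixture fit")
  fit <- with_seed(seed, tryCatch(
    mclust::Mclust(d, G = K, modelNames = "V", verbose = FALSE),
    error = function(e) NULL))
  if (is.null(fit))
    fit <- with_seed(seed,
                     mclust::Mclust(d, G = K, modelNames = "E",
                                    verbose = FALSE))
  if (is.null(fit)) stop("mixture estimation failed for all K")
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, length(means))
  bcomp <- which.min(abs(means))
  thr <- means[bcomp] + qnorm(0.95) * sds[bcomp]
  benthic <- rep(NA, length(distances))
  benthic[ok] <- d <= thr
  structure(list(K = fit$G,
                 weights = as.numeric(fit$parameters$pro),
                 means = means, sds = sds,
                 fit_score = fit$BIC,
                 benthic_component = bcomp,
                 threshold = thr,
                 benthic = benthic),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> K = %d, benthic component mean %.2f m,",
              x$K, x$means[x$benthic_component]),
      sprintf("threshold %.2f m\n", x$threshold))
  invisible(x)
}

#' Predatory tactic per trajectory segment
#'
#' Majority rule: a segment is benthic (`Ptactic = 1`) when more than
#' half of its dives are benthic; exactly half counts as pelagic
#' (`Ptactic = 0`); segments without classified dives are `NA`.
#'
#' @param benthic logical per-dive benthic indicator.
#' @param segment segment id per dive (same length).
#' @return Named integer vector of 0/1 per segment.
#' @export
ptactic_per_segment <- function(benthic, segment) {
  ok <- !is.na(benthic)
  tapply(benthic[ok], segment[ok],
         function(b) as.integer(mean(b) > 0.5))
}
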