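#' Multiple changepoint detection for shifts in the mean
#'
#' Penalized exact segmentation (PELT) of a univariate series under a
#' squared-error cost normalized by a robust noise variance estimate
#' (median absolute deviation of first differences). A changepoint is
#' admitted when splitting reduces the penalized cost; the default
#' penalty is `penalty_mult * log(n)`, a BIC-like choice.
#'
#' @param x numeric series.
#' @param penalty_mult penalty multiplier (default 3).
#' @param min_seg minimum segment length (default 5).
#' @param sigma optional known noise standard deviation; estimated
#'   robustly when `NULL`.
#' @return Integer vector of changepoint positions (the last index of
#'   each segment except the final one); empty when the series is
#'   homogeneous.
#' @export
changepoints_mean <- function(x, penalty_mult = 3, min_seg = 5,
                              sigma = NULL) {
  n <- length(x)
  if (n < 2 * min_seg) return(integer(0))
  if (is.null(sigma)) sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma < 1e-8) sigma <- max(sd(x), 1e-8)
  pen <- penalty_mult * log(n)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {   # cost of x[a..b]
    s <- cs[b + 1] - cs[a]
    s2 <- cs2[b + 1] - cs2[a]
    (s2 - s^2 / (b - a + 1)) / sigma^2
  }
  f <- rep(Inf, n + 1)
  f[1] <- -pen
  last <- integer(n + 1)
  cand <- 0L
  for (t in seq_len(n)) {
    if (t < min_seg) next
    ok <- cand[t - cand >= min_seg]
    if (!length(ok)) next
    costs <- vapply(ok, function(s) f[s + 1] + segcost(s + 1, t) + pen,
                    numeric(1))
    j <- which.min(costs)
    f[t + 1] <- costs[j]
    last[t + 1] <- ok[j]
    # PELT pruning
    keep <- vapply(cand, function(s)
      s > t - min_seg || f[s + 1] + segcost(s + 1, t) <= f[t + 1],
      logical(1))
    cand <- c(cand[keep], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- last[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Detect resting-while-diving periods
#'
#' Resting dives drift down slowly and ascend fast, so series of
#' consecutive resting dives have elevated log dive skewness. The series
#' of `log(SK)` per animal is segmented at mean shifts
#' ([changepoints_mean()]), and the per-segment mean `log(SK)` values
#' are classified with a 1-2 component normal mixture (BIC): when two
#' components separated by at least `min_separation` are found, the
#' higher-mean component marks resting segments; otherwise all segments
#' are active. When too few segments exist for a mixture fit, segments
#' above `fallback_logsk` are called resting.
#'
#' @param sk per-dive skewness values (ordered in time within animal).
#' @param animal animal id per dive.
#' @param min_dives minimum dives with valid skewness per animal
#'   (shorter series are returned all-active, with a warning).
#' @param penalty_mult,min_seg passed to [changepoints_mean()].
#' @param min_separation minimum difference of component means in
#'   `log(SK)` to accept a resting component (default 0.5).
#' @param fallback_logsk threshold on segment mean `log(SK)` used when
#'   there are fewer than 5 segments (default 1).
#' @return A list with `resting`, a logical per-dive vector, and
#'   `segmentation`, a per-animal list of changepoints, segment means
#'   and segment classes.
#' @export
detect_resting <- function(sk, animal, min_dives = 50,
                           penalty_mult = 3, min_seg = 5,
                           min_separation = 0.5, fallback_logsk = 1) {
  resting <- rep(FALSE, length(sk))
  segm <- list()
  for (a in unique(animal)) {
    ia <- which(animal == a)
    ok <- ia[!is.na(sk[ia]) & sk[ia] > 0]
    if (length(ok) < min_dives) {
      warning("animal ", a, ": skewness series too short, all active")
      next
    }
    y <- log(sk[ok])
    cps <- changepoints_mean(y, penalty_mult, min_seg)
    bounds <- c(0, cps, length(y))
    segid <- rep(seq_len(length(bounds) - 1), diff(bounds))
    means <- tapply(y, segid, mean)
    cls <- classify_segment_means(as.numeric(means), min_separation,
                                  fallback_logsk)
    resting[ok] <- cls[segid]
    segm[[as.character(a)]] <- list(changepoints = cps,
                                    segment_means = as.numeric(means),
                                    segment_resting = cls)
  }
  list(resting = resting, segmentation = segm)
}

# Classify segment-level mean log(SK): TRUE = resting.
classify_segment_means <- function(m, min_separation, fallback_logsk) {
  if (length(m) < 5) return(m > fallback_logsk)
  fit <- with_seed(1L, tryCatch(
    mclust::Mclust(m, G = 1:2, modelNames = c("E", "V"),
                   verbose = FALSE),
    error = function(e) NULL))
  if (is.null(fit) || fit$G == 1) return(rep(FALSE, length(m)))
  mu <- as.numeric(fit$parameters$mean)
  if (diff(range(mu)) < min_separation) return(rep(FALSE, length(m)))
  hi <- which.max(mu)
  fit$classification == hi
}

#' Resting-while-diving indicator per trajectory segment
#'
#' `RestingD = 1` when more than half the diving time within the segment
#' belongs to resting dive series.
#'
#' @param resting logical per-dive resting indicator.
#' @param duration per-dive duration (s), used as the time weight.
#' @param segment segment id per dive.
#' @return Named integer vector of 0/1 per segment.
#' @export
resting_per_segment <- function(resting, duration, segment) {
  ok <- !is.na(resting)
  tapply(seq_along(resting)[ok], segment[ok], function(i)
    as.integer(sum(duration[i] * resting[i]) / sum(duration[i]) > 0.5))
}
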