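# Fixture builders and independent oracles used across the suite.

# One dive record as a one-row data frame (11 profile depths).
make_dive <- function(depths, duration, max_depth = max(depths),
                      animal = 1, start = 0, dive_id = "d1") {
  stopifnot(length(depths) == 11)
  d <- data.frame(animal = animal, dive_id = dive_id, start = start,
                  duration = duration, max_depth = max_depth)
  d[paste0("d", 0:10)] <- as.list(depths)
  d
}

# Down-flat-up dive sampled at 11 equally spaced times.
path_dive <- function(maxd, s_d, s_a, flat, ...) {
  dur <- maxd / s_d + maxd / s_a + flat
  tt <- seq(0, dur, length.out = 11)
  make_dive(pmin(s_d * tt, s_a * (dur - tt), maxd), dur, maxd, ...)
}

# Independent residence-time oracle: full scan of all circle crossings
# along the trajectory, interval merge, then bridging of gaps <= t_sec.
rt_oracle_node <- function(times, xs, ys, k, r, t_sec) {
  n <- length(times)
  cx <- xs[k]; cy <- ys[k]
  dx <- diff(xs); dy <- diff(ys)
  fx <- xs[-n] - cx; fy <- ys[-n] - cy
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - r^2
  ta <- tb <- rep(NA_real_, n - 1)
  stat <- a < 1e-12
  ta[stat & cc <= 0] <- times[-n][stat & cc <= 0]
  tb[stat & cc <= 0] <- times[-1][stat & cc <= 0]
  mov <- !stat
  disc <- b^2 - 4 * a * cc
  hit <- mov & disc >= 0
  s1 <- s2 <- rep(NA_real_, n - 1)
  s1[hit] <- (-b[hit] - sqrt(disc[hit])) / (2 * a[hit])
  s2[hit] <- (-b[hit] + sqrt(disc[hit])) / (2 * a[hit])
  lo <- pmax(s1, 0); hi <- pmin(s2, 1)
  use <- hit & lo <= hi
  ta[use] <- times[-n][use] + lo[use] * diff(times)[use]
  tb[use] <- times[-n][use] + hi[use] * diff(times)[use]
  ok <- !is.na(ta)
  iv <- cbind(ta[ok], tb[ok])
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  # merge touching/overlapping intervals, then bridge gaps <= t_sec
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1)
    for (i in 2:nrow(iv)) {
      gap <- iv[i, 1] - merged[nrow(merged), 2]
      if (gap <= t_sec)
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
      else merged <- rbind(merged, iv[i, ])
    }
  hitrow <- which(merged[, 1] <= times[k] & times[k] <= merged[, 2])
  (merged[hitrow[1], 2] - merged[hitrow[1], 1]) / 3600
}

# Random-walk regular track for the residence-time equivalence checks.
random_track <- function(n, seed, dt = 1200) {
  set.seed(seed)
  sp <- runif(n - 1, 0, 0.8)
  h <- cumsum(rnorm(n - 1, 0, 0.8))
  data.frame(animal = 1, bout = 1, time = seq(0, by = dt, length.out = n),
             x = c(0, cumsum(sp * dt * cos(h))),
             y = c(0, cumsum(sp * dt * sin(h))),
             HS = NA)
}

# Exhaustive penalized mean-changepoint search (up to max_k changes).
cp_brute <- function(x, penalty_mult = 3, min_seg = 5, sigma = NULL,
                     max_k = 3) {
  n <- length(x)
  if (is.null(sigma)) sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma < 1e-8) sigma <- max(sd(x), 1e-8)
  pen <- penalty_mult * log(n)
  cost <- function(a, b) {
    v <- x[a:b]
    sum((v - mean(v))^2) / sigma^2
  }
  total <- function(cps) {
    bounds <- c(0, cps, n)
    if (any(diff(bounds) < min_seg)) return(Inf)
    sum(vapply(seq_len(length(bounds) - 1), function(i)
      cost(bounds[i] + 1, bounds[i + 1]), numeric(1))) +
      pen * length(cps)
  }
  best <- list(cps = integer(0), cost = total(integer(0)))
  for (k in seq_len(max_k)) {
    for (cps in combn(seq_len(n - 1), k, simplify = FALSE)) {
      ct <- total(unlist(cps))
      if (ct < best$cost) best <- list(cps = unlist(cps), cost = ct)
    }
  }
  best
}
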