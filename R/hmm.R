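# von Mises density (mean 0), numerically stable via scaled Bessel.
dvm0 <- function(theta, kappa) {
  exp(kappa * (cos(theta) - 1)) / (2 * pi * besselI(kappa, 0,
                                                    expon.scaled = TRUE))
}

# Best & Fisher (1981) approximation of the inverse of the mean
# resultant length A(kappa).
vm_kappa <- function(rbar) {
  rbar <- min(max(rbar, 1e-6), 0.999)
  k <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
  else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  min(max(k, 1e-3), 50)
}

# Two-state hidden Markov model on (log step speed, turning angle) with
# normal and von Mises state-dependent distributions, fitted by
# Baum-Welch with a deterministic quantile-based initialization.
fit_hmm2 <- function(log_speed, angle, max_iter = 200, tol = 1e-6) {
  n <- length(log_speed)
  mu <- c(quantile(log_speed, 0.75, names = FALSE),
          quantile(log_speed, 0.25, names = FALSE))
  sdv <- rep(max(sd(log_speed), 1e-3), 2)
  kap <- c(2, 0.3)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  delta <- c(0.5, 0.5)
  emis <- function() {
    e <- cbind(dnorm(log_speed, mu[1], sdv[1]),
               dnorm(log_speed, mu[2], sdv[2]))
    okang <- !is.na(angle)
    e[okang, 1] <- e[okang, 1] * dvm0(angle[okang], kap[1])
    e[okang, 2] <- e[okang, 2] * dvm0(angle[okang], kap[2])
    pmax(e, 1e-300)
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    e <- emis()
    # scaled forward-backward
    alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2)
    sc <- numeric(n)
    a <- delta * e[1, ]; sc[1] <- sum(a); alpha[1, ] <- a / sc[1]
    for (tt in 2:n) {
      a <- (alpha[tt - 1, ] %*% A) * e[tt, ]
      sc[tt] <- sum(a); alpha[tt, ] <- a / sc[tt]
    }
    beta[n, ] <- 1
    for (tt in (n - 1):1)
      beta[tt, ] <- (A %*% (e[tt + 1, ] * beta[tt + 1, ])) / sc[tt + 1]
    ll <- sum(log(sc))
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    xi <- matrix(0, 2, 2)
    for (tt in seq_len(n - 1)) {
      x <- (alpha[tt, ] %o% (e[tt + 1, ] * beta[tt + 1, ])) * A
      xi <- xi + x / sum(x)
    }
    A <- xi / rowSums(xi)
    delta <- gam[1, ]
    for (k in 1:2) {
      w <- gam[, k]
      mu[k] <- weighted.mean(log_speed, w)
      sdv[k] <- max(sqrt(weighted.mean((log_speed - mu[k])^2, w)), 1e-3)
      okang <- !is.na(angle)
      if (any(okang)) {
        rbar <- weighted.mean(cos(angle[okang]), w[okang])
        kap[k] <- vm_kappa(rbar)
      }
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  # Viterbi decoding
  e <- log(emis()); lA <- log(A)
  v <- matrix(-Inf, n, 2); ptr <- matrix(0L, n, 2)
  v[1, ] <- log(pmax(delta, 1e-12)) + e[1, ]
  for (tt in 2:n) for (k in 1:2) {
    cand <- v[tt - 1, ] + lA[, k]
    ptr[tt, k] <- which.max(cand)
    v[tt, k] <- max(cand) + e[tt, k]
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (tt in (n - 1):1) path[tt] <- ptr[tt + 1, path[tt + 1]]
  list(mu = mu, sd = sdv, kappa = kap, trans = A, loglik = ll,
       states = path, gamma = gam)
}

#' Classify movement type along a regular track
#'
#' Fits, per animal, a discrete-time two-state hidden Markov model to
#' node step speeds (log scale, normal state distributions) and turning
#' angles (von Mises), and Viterbi-decodes the state sequence. The state
#' with the lower mean speed is labelled intensive (`MT = 1`, slow and
#' tortuous); the other extensive (`MT = 0`, fast and directional).
#' Initialization is deterministic (speed quantiles), so results are
#' reproducible. A degenerate track with (near-)constant speed collapses
#' to a single state: a warning is issued and `MT` is set by a speed
#' threshold instead.
#'
#' @param reg_track regular track from [regularize_track()].
#' @param haulouts optional haul-out events (`animal`, `start`, `end`);
#'   nodes inside an event are excluded from fitting and get `MT = NA`
#'   (a hauled-out animal is not searching in either mode).
#' @param speed_eps floor added to speeds before the log (m/s).
#' @param fallback_threshold speed threshold (m/s) used for the
#'   degenerate single-state fallback (slower than this = intensive).
#' @param min_separation minimum difference of fitted state mean speeds
#'   (m/s); closer states indicate a single speed regime and trigger the
#'   threshold fallback.
#' @return `reg_track` with an `MT` column (0/1); per-animal fits are
#'   attached as attribute `hmm_fits` (state mean speeds in m/s,
#'   concentrations, transition matrix, log-likelihood).
#' @export
classify_movement_type <- function(reg_track, haulouts = NULL,
                                   speed_eps = 1e-3,
                                   fallback_threshold = 0.5,
                                   min_separation = 0.15) {
  reg_track$MT <- NA_integer_
  fits <- list()
  for (a in unique(reg_track$animal)) {
    ia <- which(reg_track$animal == a)
    sub <- reg_track[ia, ]
    hs <- sub$HS
    if (!is.null(haulouts)) {
      ho <- haulouts[haulouts$animal == a, ]
      if (nrow(ho))
        hs[vapply(sub$time, function(t)
          any(ho$start <= t & t < ho$end), logical(1))] <- NA
    }
    # turning angle between consecutive steps within each bout
    ang <- rep(NA_real_, nrow(sub))
    for (b in unique(sub$bout)) {
      ib <- which(sub$bout == b)
      if (length(ib) < 3) next
      dx <- diff(sub$x[ib]); dy <- diff(sub$y[ib])
      h <- atan2(dy, dx)
      turn <- c(NA, diff(h))
      turn <- ((turn + pi) %% (2 * pi)) - pi
      ang[ib[-length(ib)]] <- turn
    }
    usable <- which(!is.na(hs))
    if (length(usable) < 20) {
      reg_track$MT[ia[usable]] <-
        as.integer(hs[usable] < fallback_threshold)
      next
    }
    ls <- log(hs[usable] + speed_eps)
    if (sd(ls) < 1e-6) {
      warning("animal ", a,
              ": degenerate single-speed track, threshold fallback")
      reg_track$MT[ia[usable]] <-
        as.integer(hs[usable] < fallback_threshold)
      next
    }
    fit <- fit_hmm2(ls, ang[usable])
    # posterior-weighted arithmetic mean speed per state
    fit$mean_speed <- colSums(fit$gamma * hs[usable]) /
      colSums(fit$gamma)
    if (abs(diff(fit$mean_speed)) < min_separation) {
      # states collapsed onto one speed regime: a two-state reading
      # would be arbitrary, so classify by the speed threshold
      reg_track$MT[ia[usable]] <-
        as.integer(hs[usable] < fallback_threshold)
      fit$intensive_state <- NA
      fits[[as.character(a)]] <- fit
      next
    }
    slow <- which.min(fit$mean_speed)
    mt <- as.integer(fit$states == slow)
    reg_track$MT[ia[usable]] <- mt
    fit$intensive_state <- slow
    fits[[as.character(a)]] <- fit
  }
  attr(reg_track, "hmm_fits") <- fits
  reg_track
}
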