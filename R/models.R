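all_fixed_terms <- function(hfi) {
  c("RestingD", "Depth", "Ptactic", "Direction",
    paste0(hfi, ":Depth"), paste0(hfi, ":Ptactic"),
    paste0(hfi, ":Direction"))
}

model_formula <- function(hfi, terms, random) {
  rhs <- paste(c(hfi, terms), collapse = " + ")
  rnd <- switch(random,
                none = "",
                intercept = " + (1 | animal)",
                slope = paste0(" + (1 + ", hfi, " | animal)"))
  as.formula(paste("stBT ~", rhs, rnd))
}

fit_one <- function(data, hfi, terms, random, reml = TRUE) {
  f <- model_formula(hfi, terms, random)
  if (random == "none") lm(f, data = data)
  else suppressMessages(suppressWarnings(
    lme4::lmer(f, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular =
                                             "ignore"))))
}

# Likelihood ratio test between nested fits; REML = TRUE compares REML
# criteria (valid here because the fixed part is identical).
lrt_p <- function(small, big, reml = FALSE) {
  ll_s <- if (inherits(small, "lm") && reml)
    logLik(small, REML = TRUE) else logLik(small)
  ll_b <- if (inherits(big, "lm") && reml)
    logLik(big, REML = TRUE) else logLik(big)
  stat <- max(0, 2 * (as.numeric(ll_b) - as.numeric(ll_s)))
  df <- attr(ll_b, "df") - attr(ll_s, "df")
  if (df <= 0) return(1)
  pchisq(stat, df, lower.tail = FALSE)
}

# Random subset without replacement; capped below the table size so
# repeated subsamples always differ (degenerate resampling would give
# zero bootstrap variance).
subsample_idx <- function(n_total, n, seed) {
  n <- min(n, floor(0.8 * n_total))
  with_seed(seed, sample.int(n_total, max(n, 2)))
}

#' Select the random-effects structure by resampled likelihood ratio
#' tests
#'
#' On each of `s` random subsets of `n` rows, the full fixed-effects
#' model is fitted (REML) with no random effect, a random intercept per
#' animal, and a random intercept plus horizontal-index slope; nested
#' likelihood ratio tests at `alpha` pick the repetition's winner, and
#' the structure selected most often wins overall. Singular fits are
#' counted and their repetition skipped; more than half singular is an
#' error.
#'
#' @param table model table from [build_model_table()] or
#'   [simulate_model_table()].
#' @param hfi name of the horizontal index column (`"neg_HS"`, `"MT"` or
#'   `"invRT"`).
#' @param s number of repetitions (default 100).
#' @param n subsample size (default 7000; shrunk with a warning when the
#'   table is smaller).
#' @param alpha LRT significance threshold (default 0.01).
#' @param seed integer seed; each repetition uses a derived stream.
#' @return List with `structure` (modal winner, one of `none`,
#'   `intercept`, `slope`), `tally`, and `n_singular`.
#' @export
select_random_structure <- function(table, hfi, s = 100, n = 7000,
                                    alpha = 0.01, seed = 1L) {
  if (length(unique(table$animal)) < 2)
    stop("random-structure selection requires >= 2 individuals")
  if (n > nrow(table)) {
    warning("n reduced to table size ", nrow(table))
    n <- nrow(table)
  }
  terms <- setdiff(all_fixed_terms(hfi), character(0))
  winners <- character(0)
  n_sing <- 0L
  for (rep in seq_len(s)) {
    idx <- subsample_idx(nrow(table), n, derive_seed(seed, rep))
    d <- droplevels(table[idx, ])
    m0 <- fit_one(d, hfi, terms, "none")
    m1 <- tryCatch(fit_one(d, hfi, terms, "intercept"),
                   error = function(e) NULL)
    m2 <- tryCatch(fit_one(d, hfi, terms, "slope"),
                   error = function(e) NULL)
    if (is.null(m1) && is.null(m2)) next
    # a singular fit estimates the extra variance at the boundary: it
    # cannot support the richer structure, so it loses its test rather
    # than voiding the repetition
    sing2 <- is.null(m2) || lme4::isSingular(m2, tol = 1e-5)
    sing1 <- is.null(m1) || lme4::isSingular(m1, tol = 1e-5)
    if (sing1 || sing2) n_sing <- n_sing + 1L
    p_slope <- if (sing2 || sing1) 1 else lrt_p(m1, m2, reml = TRUE)
    p_int <- if (sing1) 1 else lrt_p(m0, m1, reml = TRUE)
    winners <- c(winners,
                 if (p_slope < alpha) "slope"
                 else if (p_int < alpha) "intercept"
                 else "none")
  }
  if (!length(winners))
    stop("all repetitions failed to fit")
  tally <- table(factor(winners, levels = c("none", "intercept",
                                            "slope")))
  list(structure = names(tally)[which.max(tally)], tally = tally,
       n_singular = n_sing)
}

#' Forward selection of fixed effects on resampled subsets
#'
#' On each of `reps` subsamples of `n` rows, candidate covariates (main
#' effects and their interactions with the horizontal index, which is
#' always kept) are added greedily: at each step every admissible
#' candidate is refitted (maximum likelihood), the best by AIC is
#' proposed, and it is retained only if the likelihood ratio test
#' against the current model is significant at `alpha`; otherwise the
#' repetition stops. Interactions are admissible only once their main
#' effect is in the model, and the resting-by-index interaction is never
#' tested. The final specification keeps the terms selected in at least
#' `keep_frac` of the repetitions (plus any main effect required by a
#' kept interaction).
#'
#' @inheritParams select_random_structure
#' @param random random structure (`"none"`, `"intercept"`, `"slope"`).
#' @param reps number of repetitions (default 30).
#' @param alpha LRT threshold for keeping a candidate (default 0.05; an
#'   0.01 variant can be passed for comparison).
#' @param keep_frac selection-frequency threshold (default 1/3).
#' @return List with `terms` (selected), `frequency` (per candidate),
#'   and `trace` (per repetition: order added and LRT p-values).
#' @export
forward_select_fixed <- function(table, hfi, random = "slope",
                                 reps = 30, n = 7000, alpha = 0.05,
                                 keep_frac = 1 / 3, seed = 1L) {
  if (n > nrow(table)) {
    warning("n reduced to table size ", nrow(table))
    n <- nrow(table)
  }
  candidates <- all_fixed_terms(hfi)
  mains <- c("RestingD", "Depth", "Ptactic", "Direction")
  trace <- vector("list", reps)
  sel_count <- setNames(numeric(length(candidates)), candidates)
  for (rep in seq_len(reps)) {
    idx <- subsample_idx(nrow(table), n, derive_seed(seed, 1000 + rep))
    d <- droplevels(table[idx, ])
    current <- character(0)
    cur_fit <- fit_one(d, hfi, current, random, reml = FALSE)
    order_added <- character(0)
    pvals <- numeric(0)
    repeat {
      adm <- setdiff(candidates, current)
      adm <- adm[vapply(adm, function(tm) {
        if (!grepl(":", tm)) return(TRUE)
        main <- sub(paste0(hfi, ":"), "", tm)
        main %in% current
      }, logical(1))]
      if (!length(adm)) break
      fits <- lapply(adm, function(tm) tryCatch(
        fit_one(d, hfi, c(current, tm), random, reml = FALSE),
        error = function(e) NULL))
      okf <- !vapply(fits, is.null, logical(1))
      if (!any(okf)) break
      aics <- vapply(fits[okf], AIC, numeric(1))
      best <- which(okf)[which.min(aics)]
      p <- lrt_p(cur_fit, fits[[best]])
      if (p < alpha) {
        current <- c(current, adm[best])
        cur_fit <- fits[[best]]
        order_added <- c(order_added, adm[best])
        pvals <- c(pvals, p)
      } else break
    }
    sel_count[current] <- sel_count[current] + 1
    trace[[rep]] <- list(terms = order_added, p = pvals)
  }
  freq <- sel_count / reps
  terms <- candidates[freq >= keep_frac]
  for (tm in terms[grepl(":", terms)]) {
    main <- sub(paste0(hfi, ":"), "", tm)
    if (!main %in% terms) terms <- c(terms, main)
  }
  terms <- candidates[candidates %in% terms]   # canonical order
  list(terms = terms, frequency = freq, trace = trace)
}

# Marginal and conditional R2 for a (possibly mixed) linear model:
# fixed-effects variance over fixed + random + residual.
#' Marginal and conditional R-squared of a fitted model
#'
#' Variance explained by the fixed effects (marginal) and by fixed plus
#' random effects (conditional), using the standard variance
#' decomposition; the random-slope contribution uses the second moments
#' of the index in the fitting data.
#'
#' @param fit a fit from [fit_final()] internals (`lm` or `lmerMod`).
#' @param data the data used for fitting.
#' @param hfi horizontal index column name (for the random slope).
#' @return Named vector with `marginal` and `conditional`.
#' @export
r2_mixed <- function(fit, data, hfi) {
  if (inherits(fit, "lm")) {
    vf <- var(fitted(fit))
    vr <- sigma(fit)^2
    r2 <- vf / (vf + vr)
    return(c(marginal = r2, conditional = r2))
  }
  X <- lme4::getME(fit, "X")
  vf <- var(as.vector(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)$animal
  x <- data[[hfi]]
  vre <- if (nrow(vc) == 2)
    vc[1, 1] + 2 * vc[1, 2] * mean(x) + vc[2, 2] * mean(x^2)
  else vc[1, 1]
  vr <- sigma(fit)^2
  c(marginal = vf / (vf + vre + vr),
    conditional = (vf + vre) / (vf + vre + vr))
}

#' Fit the final mixed model with bootstrap errors
#'
#' Fits the selected specification by REML on the full table and
#' estimates parameter standard errors as the standard deviation of the
#' estimates over `boot_reps` refits on random subsamples of `n` rows
#' (the same resampling device used during selection, which also damps
#' serial autocorrelation). Random variances at the boundary are
#' reported as zero with a flag. Marginal and conditional R-squared are
#' attached.
#'
#' @inheritParams forward_select_fixed
#' @param terms fixed-effect terms beyond the index (from
#'   [forward_select_fixed()]).
#' @param boot_reps number of bootstrap refits (default 100).
#' @return An object of class `mixed_model_fit`: `coefficients` (data
#'   frame of estimates and bootstrap SEs), `random` (variances and
#'   SEs), `r2`, `logLik`, `AIC`, `n`, and the underlying `fit`.
#' @export
fit_final <- function(table, hfi, terms, random = "slope",
                      boot_reps = 100, n = 7000, seed = 1L) {
  if (n > nrow(table)) n <- nrow(table)
  fit <- fit_one(table, hfi, terms, random, reml = TRUE)
  get_pars <- function(f) {
    if (inherits(f, "lm")) {
      fe <- coef(f)
      rv <- c(intercept_var = 0, slope_var = 0,
              resid_var = sigma(f)^2)
    } else {
      fe <- lme4::fixef(f)
      vc <- lme4::VarCorr(f)$animal
      rv <- c(intercept_var = vc[1, 1],
              slope_var = if (nrow(vc) == 2) vc[2, 2] else 0,
              resid_var = sigma(f)^2)
    }
    c(fe, rv)
  }
  point <- get_pars(fit)
  boot <- matrix(NA_real_, boot_reps, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(boot_reps)) {
    idx <- subsample_idx(nrow(table), n, derive_seed(seed, 2000 + b))
    f <- tryCatch(fit_one(droplevels(table[idx, ]), hfi, terms, random,
                          reml = TRUE),
                  error = function(e) NULL)
    if (is.null(f)) next
    p <- get_pars(f)
    boot[b, names(p)[names(p) %in% colnames(boot)]] <-
      p[names(p) %in% colnames(boot)]
  }
  se <- apply(boot, 2, sd, na.rm = TRUE)
  nfe <- length(point) - 3
  coefs <- data.frame(term = names(point)[seq_len(nfe)],
                      estimate = unname(point[seq_len(nfe)]),
                      se = unname(se[seq_len(nfe)]))
  rnd <- data.frame(component = c("intercept", paste0(hfi, " slope"),
                                  "residual"),
                    variance = unname(point[nfe + 1:3]),
                    se = unname(se[nfe + 1:3]))
  rnd$boundary <- rnd$variance < 1e-10
  structure(list(coefficients = coefs, random = rnd,
                 r2 = r2_mixed(fit, table, hfi),
                 logLik = as.numeric(logLik(fit)), AIC = AIC(fit),
                 n = nrow(table), hfi = hfi, terms = terms,
                 random_structure = random, fit = fit,
                 boot = boot),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> stBT ~ %s, random = %s, n = %d\n",
              paste(c(x$hfi, x$terms), collapse = " + "),
              x$random_structure, x$n))
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4)), row.names = FALSE)
  cat("Random variances:\n")
  print(transform(x$random, variance = signif(variance, 3),
                  se = signif(se, 2)), row.names = FALSE)
  cat(sprintf("Marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  invisible(x)
}

# Effect size of the horizontal index at given tactic and depth values.
hfi_effect <- function(fit, ptactic = 0, depth = NULL) {
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  b <- co[fit$hfi]
  ip <- paste0(fit$hfi, ":Ptactic")
  idp <- paste0(fit$hfi, ":Depth")
  if (ip %in% names(co)) b <- b + co[ip] * ptactic
  if (!is.null(depth) && idp %in% names(co)) b <- b + co[idp] * depth
  unname(b)
}

#' Sensitivity of the index relationship to temporal resolution
#'
#' Reruns forward selection and the final fit on coarsened tables and
#' reports the horizontal-index effect size (at both predatory-tactic
#' levels) with bootstrap 95 % confidence intervals per resolution.
#'
#' @param tables named list of model tables (names are the thinning
#'   factors, e.g. `"1"`, `"3"`, `"9"`, `"15"`).
#' @inheritParams forward_select_fixed
#' @inheritParams fit_final
#' @return Data frame with one row per resolution and tactic level.
#' @export
resolution_sensitivity <- function(tables, hfi, random = "slope",
                                   reps = 30, n = 7000, alpha = 0.05,
                                   keep_frac = 1 / 3, boot_reps = 100,
                                   seed = 1L) {
  out <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    tab <- tab[complete.cases(tab), ]
    if (nrow(tab) < 50 * length(unique(tab$animal))) {
      warning("resolution ", nm, ": table too small, skipped")
      next
    }
    sel <- forward_select_fixed(tab, hfi, random, reps = reps,
                                n = min(n, nrow(tab)), alpha = alpha,
                                keep_frac = keep_frac, seed = seed)
    ff <- fit_final(tab, hfi, sel$terms, random,
                    boot_reps = boot_reps, n = min(n, nrow(tab)),
                    seed = seed)
    md <- mean(tab$Depth, na.rm = TRUE)
    for (pt in c(0, 1)) {
      eff <- hfi_effect(ff, ptactic = pt, depth = md)
      # delta CI from bootstrap replicates of the combined effect
      co <- ff$boot
      b <- co[, ff$hfi]
      ip <- paste0(ff$hfi, ":Ptactic")
      idp <- paste0(ff$hfi, ":Depth")
      if (ip %in% colnames(co)) b <- b + co[, ip] * pt
      if (idp %in% colnames(co)) b <- b + co[, idp] * md
      se <- sd(b, na.rm = TRUE)
      out[[length(out) + 1]] <-
        data.frame(p = nm, tactic = c("pelagic", "benthic")[pt + 1],
                   effect = eff, lo = eff - 1.96 * se,
                   hi = eff + 1.96 * se,
                   terms = paste(sel$terms, collapse = "+"))
    }
  }
  do.call(rbind, out)
}
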