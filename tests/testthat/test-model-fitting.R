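test_that("random-structure selection tracks the generating structure", {
  # table-level truth at the study's variance scales: random intercept
  # and index slope present
  tab <- simulate_model_table(14, 5000, seed = 42)
  sr <- select_random_structure(tab, "neg_HS", s = 10, n = 7000,
                                seed = 1)
  expect_equal(sr$structure, "slope")
  expect_gte(sr$tally[["slope"]] / sum(sr$tally), 0.7)
  # no between-individual variance: the slope structure is rarely won
  tab0 <- simulate_model_table(14, 1000,
                               effects = list(sd_intercept = 0,
                                              sd_slope = 0),
                               seed = 43)
  sr0 <- select_random_structure(tab0, "neg_HS", s = 10, n = 7000,
                                 seed = 1)
  expect_true(sr0$structure %in% c("none", "intercept"))
  expect_lte(sr0$tally[["slope"]] / sum(sr0$tally), 0.2)
  # single individual is a precondition violation
  tab1 <- tab[tab$animal == 1, ]
  expect_error(select_random_structure(tab1, "neg_HS"), "individuals")
})

test_that("forward selection keeps true effects and drops null ones", {
  tab <- simulate_model_table(8, 1500, seed = 7)
  sel <- forward_select_fixed(tab, "neg_HS", random = "intercept",
                              reps = 8, n = 3000, seed = 2)
  expect_true(all(c("RestingD", "Ptactic", "Depth") %in% sel$terms))
  expect_gte(sel$frequency[["RestingD"]], 1 / 3)
  # null covariates: only the index relates to the response
  tab0 <- simulate_model_table(
    8, 1000,
    effects = list(restingd = 0, ptactic = 0, depth = 0,
                   hfi_ptactic = 0, hfi_depth = 0, dir_inward = 0,
                   dir_other = 0, hfi = 0.1,
                   sd_intercept = 0, sd_slope = 0),
    seed = 9)
  sel0 <- forward_select_fixed(tab0, "neg_HS", random = "intercept",
                               reps = 9, n = 2000, alpha = 0.01,
                               seed = 3)
  expect_true(all(sel0$frequency < 1 / 3))
  # the index itself is always in the fitted model
  ff <- fit_final(tab0, "neg_HS", sel0$terms, "intercept",
                  boot_reps = 4, n = 2000, seed = 4)
  expect_true("neg_HS" %in% ff$coefficients$term)
})

test_that("a noise-free fixed-effects table is recovered exactly", {
  tab <- simulate_model_table(4, 400,
                              effects = list(resid_sd = 1e-9,
                                             sd_intercept = 0,
                                             sd_slope = 0),
                              seed = 11)
  eff <- attr(tab, "effects")
  ff <- fit_final(tab, "neg_HS",
                  c("RestingD", "Depth", "Ptactic", "Direction",
                    "neg_HS:Depth", "neg_HS:Ptactic"),
                  random = "none", boot_reps = 4, n = 1000, seed = 5)
  co <- setNames(ff$coefficients$estimate, ff$coefficients$term)
  expect_equal(co[["RestingD"]], eff$restingd, tolerance = 1e-6)
  expect_equal(co[["Ptactic"]], eff$ptactic, tolerance = 1e-6)
  expect_equal(co[["Depth"]], eff$depth, tolerance = 1e-6)
  expect_equal(unname(ff$r2["marginal"]), 1, tolerance = 1e-6)
  expect_equal(unname(ff$r2["conditional"]),
               unname(ff$r2["marginal"]))
})

test_that("conditional R2 is never below marginal R2", {
  tab <- simulate_model_table(6, 800, seed = 21)
  for (rs in c("intercept", "slope")) {
    ff <- fit_final(tab, "neg_HS", c("RestingD", "Ptactic"), rs,
                    boot_reps = 3, n = 1500, seed = 6)
    expect_gte(ff$r2["conditional"], ff$r2["marginal"] - 1e-12)
    expect_true(all(ff$random$variance >= 0))
  }
})

test_that("selection traces and bootstrap errors are seed-reproducible", {
  tab <- simulate_model_table(6, 600, seed = 31)
  s1 <- forward_select_fixed(tab, "neg_HS", "intercept", reps = 4,
                             n = 1200, seed = 8)
  s2 <- forward_select_fixed(tab, "neg_HS", "intercept", reps = 4,
                             n = 1200, seed = 8)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$frequency, s2$frequency)
  f1 <- fit_final(tab, "neg_HS", s1$terms, "intercept", boot_reps = 5,
                  n = 1200, seed = 9)
  f2 <- fit_final(tab, "neg_HS", s1$terms, "intercept", boot_reps = 5,
                  n = 1200, seed = 9)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$random, f2$random)
})

test_that("a common intensification response gives positive slopes for all indices", {
  # latent searching intensity drives the vertical index up and the
  # horizontal indices towards their intensive ends
  set.seed(15)
  n <- 4000
  animal <- factor(rep(1:4, each = n / 4))
  z <- rnorm(n)                               # latent intensity
  hs <- pmax(0.02, 1 - 0.4 * z + rnorm(n, 0, 0.2))
  rt_h <- pmax(0.2, 2 + 1.5 * z + rnorm(n, 0, 0.5))
  tab <- data.frame(animal = animal,
                    stBT = 0.5 + 0.08 * z + rnorm(n, 0, 0.1),
                    neg_HS = -hs,
                    MT = as.numeric(z + rnorm(n, 0, 0.5) > 0),
                    invRT = -1000 / (rt_h * 3600),
                    RestingD = 0, Ptactic = 0, Depth = 30,
                    Direction = factor("outward",
                                       levels = c("outward", "inward",
                                                  "other")))
  for (hfi in c("neg_HS", "MT", "invRT")) {
    ff <- fit_final(tab, hfi, character(0), "intercept",
                    boot_reps = 3, n = 2000, seed = 10)
    est <- ff$coefficients$estimate[ff$coefficients$term == hfi]
    expect_gt(est, 0)
  }
})

test_that("omitting the resting covariate attenuates the index effect", {
  tab <- simulate_model_table(6, 1500, seed = 55)
  full <- fit_final(tab, "neg_HS", c("RestingD", "Ptactic", "Depth"),
                    "intercept", boot_reps = 3, n = 3000, seed = 11)
  red <- fit_final(tab, "neg_HS", c("Ptactic", "Depth"),
                   "intercept", boot_reps = 3, n = 3000, seed = 11)
  b_full <- full$coefficients$estimate[full$coefficients$term ==
                                         "neg_HS"]
  b_red <- red$coefficients$estimate[red$coefficients$term == "neg_HS"]
  expect_lt(b_red, b_full)
})

test_that("resolution sensitivity reports stable effects for constant truth", {
  # no between-individual variance, so the generating truth is exactly
  # the same at every resolution (independent tables re-draw random
  # effects otherwise)
  e0 <- list(sd_intercept = 0, sd_slope = 0)
  tabs <- list("1" = simulate_model_table(6, 1200, e0, seed = 61),
               "3" = simulate_model_table(6, 400, e0, seed = 62),
               "9" = simulate_model_table(6, 150, e0, seed = 63))
  rs <- resolution_sensitivity(tabs, "neg_HS", random = "intercept",
                               reps = 4, n = 1500, boot_reps = 6,
                               seed = 12)
  expect_true(all(c("1", "3", "9") %in% rs$p))
  # constant generating truth: benthic-level effects at coarser
  # resolutions fall inside each other's 95 % intervals
  b <- rs[rs$tactic == "benthic", ]
  for (i in seq_len(nrow(b) - 1))
    expect_true(b$effect[i + 1] <= b$hi[i] + 1e-9 &&
                  b$effect[i + 1] >= b$lo[i] - 1e-9 ||
                  b$effect[i] <= b$hi[i + 1] + 1e-9 &&
                  b$effect[i] >= b$lo[i + 1] - 1e-9)
})
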