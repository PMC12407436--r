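# cell-means difference-in-differences computed by hand
hand_did <- function(events, trt, baseline) {
  m <- function(tr, ph) mean(events$righting_time[events$treatment == tr &
                                                    events$phase == ph])
  (m(trt, "T1_test") - m(trt, "T0_ambient")) -
    (m(baseline, "T1_test") - m(baseline, "T0_ambient"))
}

test_that("identical righting times give all-zero effects", {
  f <- gen_flips(seed = 1, star_sd = 0, sdlog = 0,
                 t1_multipliers = c("12to12" = 1, "12to14.5" = 1,
                                    "12to17" = 1))
  expect_true(all(abs(f$records$righting_time - 34.5) < 1e-9))
  did <- fit_did(f$records)
  expect_equal(did$interaction$estimate, c(0, 0), tolerance = 1e-8)
  expect_equal(did$percent_change$percent_change, c(0, 0, 0),
               tolerance = 1e-8)
})

test_that("the DiD interaction on balanced data equals the hand-computed contrast", {
  f <- gen_flips(seed = 2)$records
  did <- fit_did(f)
  for (trt in c("12to14.5", "12to17")) {
    term <- paste0(".trt", trt, ":.phaseT1_test")
    # balanced within star-phase: mixed-model interaction equals cell means
    expect_equal(did$interaction$estimate[did$interaction$term == term],
                 hand_did(f, trt, "12to12"), tolerance = 1e-6)
  }
})

test_that("an injected -15% warm-phase multiplier is recovered", {
  f <- gen_flips(seed = 3,
                 stars_per_treatment = c("12to12" = 8, "12to17" = 8),
                 flips_per_star_phase = 28, star_sd = 5, sdlog = 0.25,
                 t1_multipliers = c("12to12" = 1, "12to17" = 0.85),
                 growth_frac = c("12to12" = 0.05, "12to17" = 0.11))
  did <- fit_did(f$records)
  pc <- did$percent_change
  expect_lt(abs(pc$percent_change[pc$treatment == "12to17"] - (-15)), 8)
  expect_lt(abs(pc$percent_change[pc$treatment == "12to12"] - 0), 8)
})

test_that("percent change uses model-adjusted phase means", {
  f <- gen_flips(seed = 4)$records
  did <- fit_did(f)
  # with balanced flips per star-phase, adjusted means equal raw cell means
  for (trt in unique(f$treatment)) {
    m0 <- mean(f$righting_time[f$treatment == trt & f$phase == "T0_ambient"])
    m1 <- mean(f$righting_time[f$treatment == trt & f$phase == "T1_test"])
    row <- did$percent_change[did$percent_change$treatment == trt, ]
    expect_equal(row$percent_change, 100 * (m1 - m0) / m0, tolerance = 0.2)
  }
})

test_that("ambient summary matches the closed-form t interval", {
  f <- data.frame(star_id = c("s1", "s2"), treatment = "12to12",
                  phase = "T0_ambient", clock_time = c(0, 50),
                  righting_time = c(20, 40), diameter = NA_real_)
  s <- ambient_summary(f)
  expect_equal(s$mean, 30)
  hw <- stats::qt(0.975, 1) * stats::sd(c(20, 40)) / sqrt(2)
  expect_equal(s$ci, c(30 - hw, 30 + hw), tolerance = 1e-12)

  cst <- f; cst$righting_time <- 30
  s2 <- ambient_summary(cst)
  expect_equal(s2$ci, c(30, 30))
})

test_that("generator defaults reproduce the ambient baseline mean", {
  f <- gen_flips(seed = 5)$records
  s <- ambient_summary(f)
  expect_lt(abs(s$mean - 34.5), 3 * s$half_width)
})

test_that("fatigue slope is near zero under clock-independent times", {
  f <- gen_flips(seed = 6)$records
  ft <- fatigue_trend(f)
  expect_lt(abs(ft$overall$t), 3)
  expect_false(any(ft$first_minute$flagged, na.rm = TRUE))
})

test_that("an injected linear fatigue slope is recovered within its CI", {
  f <- gen_flips(seed = 7, sdlog = 0.2)$records
  f$righting_time <- f$righting_time + f$clock_time / 60  # +1 s per minute
  ft <- fatigue_trend(f)
  expect_lt(abs(ft$overall$slope - 1 / 60), 3 * ft$overall$se)
  expect_lt(ft$overall$p, 0.05)
})

test_that("a 3x minute-1 inflation in one run is flagged", {
  f <- gen_flips(seed = 8, minute1_inflation = 1)$records
  inflate <- f$treatment == "12to17" & f$phase == "T1_test" &
    f$clock_time < 60
  f$righting_time[inflate] <- f$righting_time[inflate] * 3
  ft <- fatigue_trend(f)
  fm <- ft$first_minute
  expect_true(fm$flagged[fm$run == "12to17/T1_test"])
})

test_that("within-treatment growth tests and Welch contrasts are sound", {
  f <- gen_flips(seed = 9)$records
  gc <- growth_compare(f)
  expect_identical(nrow(gc$per_star), 21L)
  expect_true(all(gc$within$p <= 1))
  # Welch df equals the Welch-Satterthwaite formula
  a <- gc$per_star$growth[gc$per_star$treatment == "12to12"]
  b <- gc$per_star$growth[gc$per_star$treatment == "12to17"]
  va <- var(a) / length(a); vb <- var(b) / length(b)
  df_ws <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  row <- gc$between[gc$between$contrast == "12to12 vs 12to17", ]
  expect_equal(row$df, df_ws, tolerance = 1e-9)
  expect_equal(row$t, (mean(a) - mean(b)) / sqrt(va + vb), tolerance = 1e-9)
})

test_that("Holm adjustment follows the hand-applied step-down ordering", {
  expect_equal(stats::p.adjust(c(0.01, 0.04, 0.20), method = "holm"),
               c(0.03, 0.08, 0.20))
  f <- gen_flips(seed = 10)$records
  gc <- growth_compare(f)
  ord <- order(gc$between$p_raw)
  hand <- pmin(1, cummax((3:1) * gc$between$p_raw[ord]))
  expect_equal(gc$between$p_adj[ord], hand, tolerance = 1e-12)
  expect_true(all(gc$between$p_adj >= gc$between$p_raw))
})

test_that("degenerate flip inputs fail or downgrade as documented", {
  f <- gen_flips(seed = 11, stars_per_treatment = c("12to12" = 3))$records
  expect_error(fit_did(f), ">= 2 treatments")
  expect_error(fit_did(gen_flips(seed = 12)$records, baseline = "nope"),
               "baseline")
})
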