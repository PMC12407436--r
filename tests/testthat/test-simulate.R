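test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_morphometrics(seed = 1), gen_morphometrics(seed = 1))
  expect_identical(gen_cloning(seed = 2), gen_cloning(seed = 2))
  expect_identical(gen_settlement(seed = 3), gen_settlement(seed = 3))
  expect_identical(gen_growth(seed = 4), gen_growth(seed = 4))
  expect_identical(gen_flips(seed = 5), gen_flips(seed = 5))
  expect_false(identical(gen_flips(seed = 5), gen_flips(seed = 6)))
})

test_that("every generator passes its schema validation silently", {
  expect_silent(validate_records(gen_morphometrics(seed = 1)$records,
                                 "morphometrics", check_design = TRUE))
  expect_silent(validate_records(gen_cloning(seed = 1)$records, "cloning"))
  expect_silent(validate_records(gen_settlement(seed = 1)$records,
                                 "settlement"))
  expect_silent(validate_records(
    gen_growth(seed = 1, fate_probs = c(MIA = .1, high_and_dry = .1,
                                        mortality = .1))$records, "growth"))
  expect_silent(validate_records(gen_flips(seed = 1)$records, "flips"))
})

test_that("noiseless morphometrics lie exactly on the quadratic", {
  chars <- list(score = list(peak = 15, curvature = -1, intercept = 2,
                             loading = 1))
  d <- gen_morphometrics(seed = 2, characters = chars, jar_sd = 0,
                         residual_sd = 0, latent_sd = 0)
  fit <- fit_quadratic(d$records$temperature, d$records$value)
  expect_equal(fit$t_opt, 15, tolerance = 1e-9)
  expect_equal(fit$a, -1, tolerance = 1e-9)
  expect_equal(max(abs(d$records$value -
                         (2 - (d$records$temperature - 15)^2))), 0,
               tolerance = 1e-12)
})

test_that("intraclass correlation matches jar_sd^2 / (jar_sd^2 + residual_sd^2)", {
  chars <- list(score = list(peak = 15, curvature = 0, intercept = 0,
                             loading = 1))
  d <- gen_morphometrics(seed = 3, characters = chars,
                         temperatures = 12, jars_per_temp = 400,
                         larvae_per_jar = 10, jar_sd = 1, residual_sd = 0.5)
  v <- d$records$value
  jm <- tapply(v, d$records$jar_id, mean)
  # ANOVA ICC estimator
  msb <- 10 * var(jm)
  msw <- mean(tapply(v, d$records$jar_id, var))
  icc <- (msb - msw) / (msb + 9 * msw)
  expect_equal(icc, 1 / (1 + 0.25), tolerance = 0.05)
})

test_that("missingness lands uniformly at the requested rate", {
  d <- gen_morphometrics(seed = 4, missing_rate = 0.2,
                         jars_per_temp = 10, larvae_per_jar = 20)
  rate <- mean(is.na(d$records$value))
  expect_lt(abs(rate - 0.2), 0.02)
})

test_that("clone counts sum to the jar total and track the probability table", {
  cl <- gen_cloning(seed = 5, n_per_jar = 80)
  cnt <- cl$records[c("class1", "class2", "class3", "class4", "settled")]
  expect_true(all(rowSums(cnt) == 80))
  # LLN: empirical class frequencies approach the truth at large n
  big <- gen_cloning(seed = 6, n_per_jar = 20000, jars_per_temp = 1)
  for (i in seq_len(nrow(big$records))) {
    emp <- as.numeric(big$records[i, 3:7]) / 20000
    tru <- big$truth$class_probs[as.character(big$records$temperature[i]), ]
    expect_lt(max(abs(emp - tru)), 0.015)
  }
})

test_that("the clone probability table elevates clone odds only at the top", {
  pr <- make_clone_probs(c(12, 14, 16, 18, 20), top_odds_ratio = 1.5)
  clone <- rowSums(pr[, c("class2", "class3", "class4")])
  odds <- clone / (1 - clone)
  expect_equal(unname(odds["20"] / odds["12"]), 1.5, tolerance = 1e-9)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  expect_equal(length(unique(round(clone[1:4], 12))), 1L)
})

test_that("detection rate of the 1.5x clone-odds contrast matches analytic power", {
  # pooled larva-level one-sided z test of top temperature vs the rest;
  # its power is available in closed form from the truth table
  pr_tab <- make_clone_probs(c(12, 14, 16, 18, 20))
  clone <- rowSums(pr_tab[, c("class2", "class3", "class4")])
  p1 <- clone["20"]; p0 <- clone["12"]
  n1 <- 3 * 80; n0 <- 12 * 80
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  power <- stats::pnorm((p1 - p0) / se - stats::qnorm(0.95))

  set.seed(60)
  B <- 60
  hits <- replicate(B, {
    cl <- gen_cloning(n_per_jar = 80)
    pr <- clone_proportions(cl$records)
    top <- pr$temperature == 20
    k1 <- sum(pr$n_clone[top]);  m1 <- sum(pr$n_total[top])
    k0 <- sum(pr$n_clone[!top]); m0 <- sum(pr$n_total[!top])
    ph1 <- k1 / m1; ph0 <- k0 / m0
    z <- (ph1 - ph0) / sqrt(ph1 * (1 - ph1) / m1 + ph0 * (1 - ph0) / m0)
    z > stats::qnorm(0.95)
  })
  mc <- sqrt(power * (1 - power) / B)
  expect_lt(abs(mean(hits) - power), 3.5 * mc + 0.02)
  expect_gt(mean(hits), 0.6)
})

test_that("settlement truth records the cell probabilities actually simulated", {
  s <- gen_settlement(seed = 7, rearing_logit = 1, reps_per_cell = 200,
                      n_per_well = 20, replicate_sd = 0)
  for (i in seq_len(nrow(s$truth$cells))) {
    cell <- s$truth$cells[i, ]
    sub <- s$records[s$records$rearing_temperature == cell$rearing_temperature &
                       s$records$test_temperature == cell$test_temperature, ]
    expect_lt(abs(mean(sub$n_settled / sub$n_exposed) - cell$p_settle), 0.03)
  }
  expect_true(all(s$records$n_attached >= s$records$n_settled))
})

test_that("growth generator hits its cell means and fate frequencies", {
  g <- gen_growth(seed = 8, n_per_cell = 300, juvenile_effect = 3.5)
  surv <- g$records[g$records$fate == "survived", ]
  rates <- growth_rate_abs(surv$D0, surv$DT, surv$T_days)
  cell <- paste(surv$larval_temp, surv$juvenile_temp)
  mu <- tapply(rates, cell, mean)
  tru <- g$truth$cells
  expect_equal(as.vector(mu[paste(tru$larval_temp, tru$juvenile_temp)]),
               tru$mean_rate, tolerance = 0.12)

  gf <- gen_growth(seed = 9, n_per_cell = 500,
                   fate_probs = c(MIA = 0.2, high_and_dry = 0.1,
                                  mortality = 0.05))
  expect_lt(abs(mean(gf$records$fate == "MIA") - 0.2), 0.03)
  expect_true(all(gf$records$T_days[gf$records$fate != "survived"] < 41))
})

test_that("flip streams accumulate clock time and honour multipliers", {
  f <- gen_flips(seed = 10, sdlog = 0.3)
  r <- f$records
  one <- r[r$star_id == "star01" & r$phase == "T0_ambient", ]
  expect_equal(one$clock_time[1], 0)
  expect_true(all(diff(one$clock_time) > 0))
  # T1/T0 mean ratio per treatment tracks the multiplier
  big <- gen_flips(seed = 11, stars_per_treatment = c("12to12" = 40,
                                                      "12to17" = 40),
                   flips_per_star_phase = 30, star_sd = 2, sdlog = 0.3,
                   t1_multipliers = c("12to12" = 1, "12to17" = 0.85),
                   growth_frac = c("12to12" = 0.05, "12to17" = 0.11))$records
  for (trt in c("12to12", "12to17")) {
    m0 <- mean(big$righting_time[big$treatment == trt &
                                   big$phase == "T0_ambient"])
    m1 <- mean(big$righting_time[big$treatment == trt &
                                   big$phase == "T1_test"])
    target <- if (trt == "12to12") 1 else 0.85
    expect_lt(abs(m1 / m0 - target), 0.05)
  }
})

test_that("minute-1 inflation applies only to early flips", {
  base <- gen_flips(seed = 12, minute1_inflation = 1)$records
  infl <- gen_flips(seed = 12, minute1_inflation = 3)$records
  # first flip of every run starts at clock 0 and is inflated 3x
  first <- base$clock_time == 0
  expect_equal(infl$righting_time[first], 3 * base$righting_time[first],
               tolerance = 1e-9)
})

test_that("flip totals give the design's mean flips per star", {
  f <- gen_flips(seed = 13)$records
  s <- flip_summary(f)
  expect_identical(s$n_stars, 21L)
  expect_identical(s$n_flips, 21L * 28L)
  expect_equal(s$mean_flips_per_star, 28)
})
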