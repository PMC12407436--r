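# independent grouped-binomial logit MLE by Newton-Raphson
newton_logit <- function(X, k, n, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- stats::plogis(drop(X %*% beta))
    W <- n * p * (1 - p)
    score <- crossprod(X, k - n * p)
    beta <- beta + solve(crossprod(X, X * W), score)
  }
  drop(beta)
}

test_that("a no-effect design gives a near-zero contrast with p near 1", {
  d <- data.frame(replicate_id = paste0("J", 1:8),
                  temp = rep(c(12, 16), each = 4),
                  n_settled = 25L, n_exposed = 50L)
  # a perfectly null dataset puts the variance estimate on the boundary;
  # the fixed-effects fallback is the documented behaviour there
  r <- suppressWarnings(fit_binomial_mixed(d, "temp", "n_settled",
                                           "n_exposed"))
  expect_equal(r$contrasts$estimate, 0, tolerance = 1e-6)
  expect_gt(r$contrasts$p_adj, 0.99)
})

test_that("with the random SD pinned at zero the fit is the plain logit MLE", {
  set.seed(44)
  d <- data.frame(replicate_id = paste0("J", 1:3),
                  temp = c(11, 14, 17),
                  n_settled = c(12L, 30L, 21L), n_exposed = 50L)
  r <- fit_binomial_mixed(d, "temp", "n_settled", "n_exposed",
                          force_glm = TRUE)
  X <- stats::model.matrix(~ factor(d$temp))
  beta_hat <- newton_logit(X, d$n_settled, d$n_exposed)
  expect_equal(r$fixed_effects$estimate, unname(beta_hat), tolerance = 1e-6)
  expect_equal(r$random_intercept_sd, 0)
  expect_true(r$converged)
})

test_that("an injected +1.5 logit contrast is recovered within Wald error", {
  s <- gen_settlement(seed = 71, rearing_temps = c(12, 16), test_temps = 14,
                      rearing_logit = 1.5, replicate_sd = 0.3,
                      reps_per_cell = 6, n_per_well = 50)
  r <- fit_binomial_mixed(s$records, "rearing_temperature",
                          "n_settled", "n_exposed")
  est <- -r$contrasts$estimate[1]  # contrast is low - high
  se <- r$contrasts$se[1]
  expect_lt(abs(est - 1.5), 1.96 * se)
  expect_lt(r$omnibus$p, 0.01)
})

test_that("pairwise p values are Bonferroni-adjusted exactly", {
  s <- gen_settlement(seed = 72, rearing_temps = c(11, 14, 17),
                      test_temps = 14, rearing_logit = c(0, 0.6, 1.1),
                      reps_per_cell = 4, n_per_well = 40)
  r <- fit_binomial_mixed(s$records, "rearing_temperature",
                          "n_settled", "n_exposed")
  m <- nrow(r$contrasts)
  expect_identical(m, 3L)
  raw <- 2 * stats::pnorm(-abs(r$contrasts$z))
  expect_equal(r$contrasts$p_adj, pmin(1, m * raw), tolerance = 1e-8)
})

test_that("cloning trend matches lm and a permutation oracle", {
  cl <- gen_cloning(seed = 73)
  pr <- clone_proportions(cl$records)
  tr <- cloning_trend(pr)
  ref <- stats::anova(stats::lm(proportion ~ temperature, data = pr))
  expect_equal(tr$F, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(tr$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  # permutation distribution of F agrees with the F-test p value
  set.seed(1)
  perm <- replicate(4000, {
    cloning_trend(data.frame(temperature = sample(pr$temperature),
                             proportion = pr$proportion))$F
  })
  p_perm <- mean(perm >= tr$F)
  expect_lt(abs(p_perm - tr$p), 3 * sqrt(tr$p * (1 - tr$p) / 4000) + 0.01)
})

test_that("the F - R-squared identity reproduces the printed-style statistic", {
  # 15 jars and R^2 = 0.1459 imply F(1,13) = 2.22 at printed precision
  r2 <- 0.1459
  expect_equal(round((r2 / (1 - r2)) * 13, 2), 2.22)
  # and cloning_trend reports exactly that identity on real output
  cl <- gen_cloning(seed = 74)
  tr <- cloning_trend(clone_proportions(cl$records))
  expect_equal(tr$F, tr$r_squared / (1 - tr$r_squared) * (tr$n - 2),
               tolerance = 1e-12)
})

test_that("identical proportions give a flat trend: R2 = 0, F = 0, p = 1", {
  pr <- data.frame(temperature = rep(c(12, 16, 20), each = 3),
                   proportion = 0.4)
  tr <- cloning_trend(pr)
  expect_equal(tr$r_squared, 0)
  expect_equal(tr$F, 0)
  expect_equal(tr$p, 1)
})

test_that("factorial settlement ANOVA matches a from-scratch SS decomposition", {
  s <- gen_settlement(seed = 75, test_logit = 1.5, n_per_well = 25,
                      reps_per_cell = 8)
  res <- factorial_proportion_anova(s$records)
  d <- data.frame(p = s$records$n_settled / s$records$n_exposed,
                  A = factor(s$records$rearing_temperature),
                  B = factor(s$records$test_temperature))
  # balanced two-way SS by hand
  gm <- mean(d$p)
  mA <- tapply(d$p, d$A, mean); mB <- tapply(d$p, d$B, mean)
  mAB <- tapply(d$p, interaction(d$A, d$B), mean)
  nA <- table(d$A); nB <- table(d$B); nAB <- table(interaction(d$A, d$B))
  ssA <- sum(nA * (mA - gm)^2)
  ssB <- sum(nB * (mB - gm)^2)
  cells <- expand.grid(A = levels(d$A), B = levels(d$B))
  key <- interaction(cells$A, cells$B)
  ssAB <- sum(nAB[key] * (mAB[key] - mA[cells$A] - mB[cells$B] + gm)^2)
  tab <- res$table
  expect_equal(tab$sum_sq[tab$term == "rearing"], ssA, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "test"], ssB, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "rearing:test"], unname(ssAB),
               tolerance = 1e-10)
  # only the injected main effect should be strong
  expect_lt(tab$p[tab$term == "test"], 0.01)
  expect_gt(tab$p[tab$term == "rearing"], 0.05)
})

test_that("degenerate factorial designs are rejected or zeroed", {
  s <- gen_settlement(seed = 76)$records
  s$n_settled <- 2L; s$n_attached <- 3L
  res <- factorial_proportion_anova(s)
  expect_true(all(res$table$F[!is.na(res$table$F)] == 0))
  expect_true(all(res$table$p[!is.na(res$table$p)] == 1))

  one_rep <- gen_settlement(seed = 77, reps_per_cell = 1)$records
  expect_error(factorial_proportion_anova(one_rep), "single replicate")

  s2 <- gen_settlement(seed = 78)$records
  s2 <- s2[!(s2$rearing_temperature == 12 & s2$test_temperature == 12), ]
  expect_error(factorial_proportion_anova(s2), "empty cell")
})
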