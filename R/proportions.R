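## Proportion outcomes: settlement and cloning.
##
## Settlement (and cloning incidence) are binomial outcomes on groups of
## larvae sharing a replicate exposure (jar or well), so the default model
## is a logistic mixed model with a random intercept per replicate.
## The temperature-shift settlement design is additionally analysed as a
## two-way ANOVA on replicate-level proportions, the route matching its
## reported F statistics.

#' Logistic mixed model for grouped binomial outcomes
#'
#' Fits `cbind(successes, failures) ~ level + (1 | replicate)` by maximum
#' likelihood with the Laplace approximation, and reports fixed effects on
#' the logit scale, an omnibus likelihood-ratio test for the factor, and
#' all pairwise level contrasts as Wald z tests with Bonferroni-adjusted
#' p values. If the mixed fit fails to converge the model is refitted as an
#' ordinary logistic regression (random-intercept SD pinned at 0) and the
#' result flagged.
#'
#' @param outcomes Data frame with one row per replicate group.
#' @param level Name of the factor column (e.g. temperature as a factor).
#' @param n_success,n_total Names of the success-count and group-size
#'   columns.
#' @param replicate Name of the replicate identifier column.
#' @param force_glm Pin the random-intercept SD at 0 and fit a plain
#'   logistic regression (useful with one replicate per level).
#' @return Object of class `"binomial_mixed"`: `fixed_effects` (estimate,
#'   se, z, p per coefficient), `omnibus` (LRT chisq, df, p), `contrasts`
#'   (pairwise level differences on the logit scale, Bonferroni-adjusted,
#'   with a between-replicate `df` for small-sample t intervals),
#'   `random_intercept_sd`, `converged`, `separation` flag, and the fitted
#'   model object.
#' @export
fit_binomial_mixed <- function(outcomes, level, n_success, n_total,
                               replicate = "replicate_id",
                               force_glm = FALSE) {
  k <- outcomes[[n_success]]
  n <- outcomes[[n_total]]
  stopifnot(all(k >= 0), all(k <= n))
  d <- data.frame(.lvl = factor(outcomes[[level]]),
                  .rep = factor(outcomes[[replicate]]),
                  .k = k, .fail = n - k)
  if (nlevels(d$.lvl) < 2L) stop("need >= 2 factor levels", call. = FALSE)
  if (nrow(d) < 2L) stop("need >= 2 replicate groups", call. = FALSE)

  fit <- NULL
  if (!force_glm) {
    fit <- tryCatch(
      lme4::glmer(cbind(.k, .fail) ~ .lvl + (1 | .rep), data = d,
                  family = stats::binomial()),
      error = function(e) NULL, warning = function(w) NULL)
  }
  # converged = FALSE only when the mixed fit failed and we fell back
  converged <- force_glm || !is.null(fit)
  if (is.null(fit)) {
    if (!force_glm)
      warning("mixed fit did not converge; reporting fixed-effects fallback",
              call. = FALSE)
    fit <- stats::glm(cbind(.k, .fail) ~ .lvl, data = d,
                      family = stats::binomial())
    re_sd <- 0
    co <- summary(fit)$coefficients
    null_fit <- stats::glm(cbind(.k, .fail) ~ 1, data = d,
                           family = stats::binomial())
    lrt <- stats::anova(null_fit, fit, test = "Chisq")
    omnibus <- list(chisq = lrt$Deviance[2L], df = lrt$Df[2L],
                    p = lrt$`Pr(>Chi)`[2L])
  } else {
    re_sd <- sqrt(unname(lme4::VarCorr(fit)$.rep[1L, 1L]))
    co <- summary(fit)$coefficients
    null_fit <- lme4::glmer(cbind(.k, .fail) ~ 1 + (1 | .rep), data = d,
                            family = stats::binomial())
    lrt <- stats::anova(null_fit, fit)
    omnibus <- list(chisq = lrt$Chisq[2L], df = lrt$Df[2L],
                    p = lrt$`Pr(>Chisq)`[2L])
  }

  fixed <- data.frame(term = rownames(co), estimate = co[, 1L],
                      se = co[, 2L], z = co[, 3L],
                      p = 2 * stats::pnorm(-abs(co[, 3L])))
  rownames(fixed) <- NULL
  separation <- any(abs(fixed$estimate) > 15) || any(fixed$se > 100)

  em <- emmeans::emmeans(fit, ".lvl")
  ct <- as.data.frame(emmeans::contrast(em, "pairwise",
                                        adjust = "bonferroni"))
  # between-replicate df for small-sample t intervals on contrasts; the
  # Wald z is anti-conservative when replicates are few
  df_btw <- max(nrow(d) - nlevels(d$.lvl), 1L)
  contrasts <- data.frame(contrast = as.character(ct$contrast),
                          estimate = ct$estimate, se = ct$SE,
                          z = ct$estimate / ct$SE, df = df_btw,
                          p_adj = ct$p.value)

  structure(list(fixed_effects = fixed, omnibus = omnibus,
                 contrasts = contrasts, random_intercept_sd = re_sd,
                 converged = converged, separation = separation,
                 model = fit),
            class = "binomial_mixed")
}

#' Linear trend of clone proportion on temperature
#'
#' Ordinary least-squares regression of the per-jar clone proportion on
#' temperature, reporting the slope, R-squared, the F statistic
#' `F = (R2 / (1 - R2)) * (n - 2)` on (1, n-2) df, and its p value.
#'
#' @param jar_props Data frame with `temperature` and `proportion` columns,
#'   one row per jar (see [clone_proportions()]).
#' @return List with `slope`, `intercept`, `r_squared`, `F`, `df`, `p`,
#'   and `n`.
#' @export
cloning_trend <- function(jar_props) {
  stopifnot(all(c("temperature", "proportion") %in% names(jar_props)))
  n <- nrow(jar_props)
  if (n < 3L) stop("need >= 3 jars", call. = FALSE)
  if (stats::var(jar_props$proportion) == 0)
    return(list(slope = 0, intercept = jar_props$proportion[1L],
                r_squared = 0, F = 0, df = c(1L, n - 2L), p = 1, n = n))
  fit <- stats::lm(proportion ~ temperature, data = jar_props)
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0  # all proportions identical
  Fstat <- if (r2 >= 1) Inf else (r2 / (1 - r2)) * (n - 2)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  if (Fstat == 0) p <- 1
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, F = Fstat, df = c(1L, n - 2L), p = p, n = n)
}

#' Per-jar clone proportions from clone-class counts
#'
#' Combines the three cloning classes (mostly-complete regenerating clones,
#' half-size clones, and tiny clones) into a single "clone" count per jar
#' and divides by the jar's total classified larvae (all four classes plus
#' spontaneously settled individuals).
#'
#' @param counts Clone-class count records (see [validate_records()],
#'   schema `"cloning"`).
#' @return Data frame with `jar_id`, `temperature`, `n_clone`, `n_total`,
#'   `proportion`.
#' @export
clone_proportions <- function(counts) {
  counts <- validate_records(counts, "cloning")
  n_clone <- counts$class2 + counts$class3 + counts$class4
  n_total <- n_clone + counts$class1 + counts$settled
  data.frame(jar_id = counts$jar_id, temperature = counts$temperature,
             n_clone = n_clone, n_total = n_total,
             proportion = n_clone / n_total)
}

#' Two-way ANOVA of settlement proportions in a factorial design
#'
#' Analyses replicate-level settled proportions from a rearing-temperature
#' by test-temperature factorial with interaction, returning the full F
#' table. Both temperatures enter as factors.
#'
#' @param outcomes Settlement outcome records (schema `"settlement"`),
#'   one row per replicate well/jar.
#' @param response Which count to analyse as the numerator: `"settled"`
#'   (default) or `"attached"`.
#' @return List with `table` (term, df, sum_sq, F, p) and the underlying
#'   `aov` fit.
#' @export
factorial_proportion_anova <- function(outcomes,
                                       response = c("settled", "attached")) {
  response <- match.arg(response)
  outcomes <- validate_records(outcomes, "settlement")
  num <- if (response == "settled") outcomes$n_settled else outcomes$n_attached
  d <- data.frame(prop = num / outcomes$n_exposed,
                  rearing = factor(outcomes$rearing_temperature),
                  test = factor(outcomes$test_temperature))
  cells <- table(d$rearing, d$test)
  if (any(cells == 0L)) stop("empty cell in factorial design", call. = FALSE)
  if (all(cells == 1L))
    stop("single replicate per cell: interaction untestable", call. = FALSE)
  fit <- stats::aov(prop ~ rearing * test, data = d)
  list(table = .anova_table(fit), fit = fit)
}
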