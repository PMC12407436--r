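## Righting-response performance under a simulated marine heatwave.
##
## Each star is flipped continuously for 10 minutes at ambient temperature
## (phase T0) and again, a week later, at its treatment's test temperature
## (phase T1). The headline analysis is a difference-in-differences mixed
## model: the change in righting time from T0 to T1 in each warmed
## treatment, relative to the same change in the unwarmed control, with a
## random intercept per star to absorb persistent individual differences.

.prep_flips <- function(events, baseline) {
  events <- validate_records(events, "flips")
  treatments <- unique(events$treatment)
  if (!baseline %in% treatments)
    stop("baseline treatment '", baseline, "' not present", call. = FALSE)
  events$.trt <- stats::relevel(factor(events$treatment), ref = baseline)
  events$.phase <- factor(events$phase, levels = .valid_phases)
  events
}

#' Difference-in-differences mixed model for righting times
#'
#' Fits `righting_time ~ treatment * phase + (1 | star)` by REML on the
#' raw seconds scale (a log-scale option is available since righting times
#' are right-skewed). The treatment-by-phase interaction coefficients are
#' the DiD estimates: each warmed treatment's T0-to-T1 change minus the
#' control's. Coefficients are reported with Wald z tests. Per-treatment
#' percent change of T1 versus T0 is computed from model-adjusted phase
#' means.
#'
#' @param events Flip-event records (schema `"flips"`).
#' @param baseline Control treatment label (default `"12to12"`).
#' @param log_scale Model `log(righting_time)` instead of raw seconds.
#' @param exclude_first_minute Sensitivity option: drop flips with
#'   `clock_time < 60` s, where acclimation outliers concentrate.
#' @return Object of class `"did_result"`: `fixed_effects` (estimate, se,
#'   z, p), `interaction` (the DiD rows only), `percent_change` (per
#'   treatment, from adjusted means), `random_intercept_sd`, `converged`,
#'   and the fitted model.
#' @export
fit_did <- function(events, baseline = "12to12", log_scale = FALSE,
                    exclude_first_minute = FALSE) {
  events <- .prep_flips(events, baseline)
  if (exclude_first_minute) events <- events[events$clock_time >= 60, ]
  both <- tapply(events$.phase, events$treatment,
                 function(p) length(unique(p)))
  if (sum(both >= 2L) < 2L)
    stop("need >= 2 treatments observed in both phases", call. = FALSE)
  events$.y <- if (log_scale) log(events$righting_time) else
    events$righting_time

  fit <- tryCatch(
    lme4::lmer(.y ~ .trt * .phase + (1 | star_id), data = events,
               REML = TRUE),
    error = function(e) NULL)
  converged <- !is.null(fit)
  if (is.null(fit)) {
    warning("mixed fit failed; reporting fixed-effects fallback",
            call. = FALSE)
    fit <- stats::lm(.y ~ .trt * .phase, data = events)
    re_sd <- 0
    co <- summary(fit)$coefficients[, 1:2, drop = FALSE]
  } else {
    re_sd <- sqrt(unname(lme4::VarCorr(fit)$star_id[1L, 1L]))
    co <- summary(fit)$coefficients[, 1:2, drop = FALSE]
  }
  z <- co[, 1L] / co[, 2L]
  fixed <- data.frame(term = rownames(co), estimate = co[, 1L],
                      se = co[, 2L], z = z,
                      p = 2 * stats::pnorm(-abs(z)))
  rownames(fixed) <- NULL
  interaction <- fixed[grepl(":", fixed$term), , drop = FALSE]

  # model-adjusted phase means per treatment -> percent change T1 vs T0
  em <- as.data.frame(emmeans::emmeans(fit, c(".trt", ".phase")))
  names(em)[1:2] <- c("treatment", "phase")
  wide <- stats::reshape(em[c("treatment", "phase", "emmean")],
                         idvar = "treatment", timevar = "phase",
                         direction = "wide")
  m0 <- wide$emmean.T0_ambient
  m1 <- wide$emmean.T1_test
  if (log_scale) {
    pct <- 100 * (exp(m1 - m0) - 1)
  } else {
    pct <- 100 * (m1 - m0) / m0
  }
  percent_change <- data.frame(treatment = as.character(wide$treatment),
                               mean_T0 = m0, mean_T1 = m1,
                               percent_change = pct)

  structure(list(fixed_effects = fixed, interaction = interaction,
                 percent_change = percent_change,
                 random_intercept_sd = re_sd, converged = converged,
                 baseline = baseline, log_scale = log_scale,
                 n_flips = nrow(events),
                 n_stars = length(unique(events$star_id)),
                 model = fit),
            class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("Difference-in-differences mixed model (%d flips, %d stars; baseline %s)\n",
              x$n_flips, x$n_stars, x$baseline))
  print(x$interaction, digits = 3)
  cat("Percent change T1 vs T0 (model-adjusted means):\n")
  print(x$percent_change, digits = 3)
  invisible(x)
}

#' Summary of ambient (baseline-phase) righting times
#'
#' Mean righting time with a normal-theory t confidence interval computed
#' per flip, plus a clustered alternative computed over per-star means
#' (flips within a star are dependent, so the per-flip interval is
#' anti-conservative; both are reported).
#'
#' @param events Flip-event records; typically pre-filtered to
#'   `phase == "T0_ambient"`. Rows from other phases are dropped.
#' @param level Confidence level (default 0.95).
#' @return List with `mean`, `ci` (per-flip), `ci_clustered` (per-star
#'   means), `half_width`, `n_flips`, `n_stars`.
#' @export
ambient_summary <- function(events, level = 0.95) {
  events <- validate_records(events, "flips")
  events <- events[events$phase == "T0_ambient", , drop = FALSE]
  y <- events$righting_time
  if (length(y) < 2L) stop("need >= 2 flips", call. = FALSE)
  m <- mean(y)
  hw <- stats::qt(1 - (1 - level) / 2, df = length(y) - 1L) *
    stats::sd(y) / sqrt(length(y))
  sm <- tapply(y, events$star_id, mean)
  ci_cl <- if (length(sm) >= 2L) {
    hww <- stats::qt(1 - (1 - level) / 2, df = length(sm) - 1L) *
      stats::sd(sm) / sqrt(length(sm))
    c(mean(sm) - hww, mean(sm) + hww)
  } else c(NA_real_, NA_real_)
  list(mean = m, ci = c(m - hw, m + hw), ci_clustered = ci_cl,
       half_width = hw, n_flips = length(y),
       n_stars = length(unique(events$star_id)))
}

#' Fatigue diagnostics over the 10-minute flipping clock
#'
#' Tests whether righting time drifts with experimental clock time:
#' an overall mixed-model slope (random intercept per star, Satterthwaite
#' t test), per-run OLS slopes (a run = one treatment-phase combination),
#' and a first-minute diagnostic comparing minute-1 righting times against
#' minutes 2-10 within each run (one-sided Wilcoxon rank-sum: are early
#' flips slower?).
#'
#' @param events Flip-event records (schema `"flips"`).
#' @param alpha Flagging level for the first-minute diagnostic.
#' @return List with `overall` (slope s per s, se, t, df, p), `per_run`
#'   (slope test per run) and `first_minute` (per-run medians and Wilcoxon
#'   p, with a `flagged` column).
#' @export
fatigue_trend <- function(events, alpha = 0.05) {
  events <- validate_records(events, "flips")
  events$run <- interaction(events$treatment, events$phase, drop = TRUE,
                            sep = "/")
  # stars with a single flip carry no within-star slope information
  nfl <- table(events$star_id)
  single <- names(nfl)[nfl == 1L]
  if (length(single)) {
    message(length(single), " star(s) with a single flip dropped from slope model")
    events <- events[!events$star_id %in% single, , drop = FALSE]
  }
  fit <- lmerTest::lmer(righting_time ~ clock_time + (1 | star_id),
                        data = events, REML = TRUE)
  co <- summary(fit)$coefficients
  overall <- list(slope = co["clock_time", "Estimate"],
                  se = co["clock_time", "Std. Error"],
                  t = co["clock_time", "t value"],
                  df = co["clock_time", "df"],
                  p = co["clock_time", "Pr(>|t|)"])

  per_run <- do.call(rbind, lapply(split(events, events$run), function(d) {
    if (nrow(d) < 3L || stats::sd(d$clock_time) == 0)
      return(data.frame(run = d$run[1L], n = nrow(d), slope = NA, t = NA,
                        p = NA))
    s <- summary(stats::lm(righting_time ~ clock_time, data = d))$coefficients
    data.frame(run = d$run[1L], n = nrow(d),
               slope = s["clock_time", "Estimate"],
               t = s["clock_time", "t value"],
               p = s["clock_time", "Pr(>|t|)"])
  }))
  rownames(per_run) <- NULL

  first_minute <- do.call(rbind, lapply(split(events, events$run), function(d) {
    early <- d$righting_time[d$clock_time < 60]
    late <- d$righting_time[d$clock_time >= 60]
    if (length(early) < 2L || length(late) < 2L)
      return(data.frame(run = d$run[1L], n_early = length(early),
                        median_early = stats::median(early),
                        median_late = stats::median(late),
                        p = NA, flagged = FALSE))
    p <- suppressWarnings(
      stats::wilcox.test(early, late, alternative = "greater")$p.value)
    data.frame(run = d$run[1L], n_early = length(early),
               median_early = stats::median(early),
               median_late = stats::median(late),
               p = p, flagged = p < alpha)
  }))
  rownames(first_minute) <- NULL

  list(overall = overall, per_run = per_run, first_minute = first_minute)
}

#' Growth over the heatwave week, within and between treatments
#'
#' Each star is measured at both flipping trials; growth is
#' `(diam_T1 - diam_T0) / diam_T0` per star. Within each treatment a
#' paired t test asks whether diameters changed; between treatments,
#' pairwise Welch t tests on the per-star growth fractions are adjusted by
#' the Holm step-down procedure.
#'
#' @param events Flip-event records carrying a `diameter` for each trial
#'   (per-star phase means are used when diameters vary within a trial).
#' @return List with `per_star` (star, treatment, d0, d1, growth),
#'   `within` (per-treatment paired t on diameters, mean growth mm and
#'   percent), and `between` (pairwise Welch t with `p_raw` and Holm
#'   `p_adj`; skipped pairs have `NA`).
#' @export
growth_compare <- function(events) {
  events <- validate_records(events, "flips")
  events <- events[!is.na(events$diameter), , drop = FALSE]
  agg <- stats::aggregate(diameter ~ star_id + treatment + phase,
                          data = events, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("star_id", "treatment"),
                         timevar = "phase", direction = "wide")
  names(wide) <- sub("^diameter\\.", "", names(wide))
  ok <- !is.na(wide$T0_ambient) & !is.na(wide$T1_test)
  wide <- wide[ok, , drop = FALSE]
  per_star <- data.frame(star_id = wide$star_id, treatment = wide$treatment,
                         d0 = wide$T0_ambient, d1 = wide$T1_test,
                         growth = (wide$T1_test - wide$T0_ambient) /
                           wide$T0_ambient)

  within <- do.call(rbind, lapply(split(per_star, per_star$treatment),
                                  function(d) {
    tt <- if (nrow(d) >= 2L && stats::sd(d$d1 - d$d0) > 0)
      stats::t.test(d$d1, d$d0, paired = TRUE) else NULL
    data.frame(treatment = d$treatment[1L], n = nrow(d),
               mean_growth_abs = mean(d$d1 - d$d0),
               sd_growth_abs = stats::sd(d$d1 - d$d0),
               mean_growth_pct = 100 * mean(d$growth),
               t = if (is.null(tt)) NA else unname(tt$statistic),
               p = if (is.null(tt)) NA else tt$p.value)
  }))
  rownames(within) <- NULL

  trts <- unique(per_star$treatment)
  pairs <- if (length(trts) >= 2L) utils::combn(trts, 2L, simplify = FALSE)
           else list()
  between <- do.call(rbind, lapply(pairs, function(pr) {
    a <- per_star$growth[per_star$treatment == pr[1L]]
    b <- per_star$growth[per_star$treatment == pr[2L]]
    if (length(a) < 2L || length(b) < 2L ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      return(data.frame(contrast = paste(pr, collapse = " vs "),
                        t = NA, df = NA, p_raw = NA))
    wt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(contrast = paste(pr, collapse = " vs "),
               t = unname(wt$statistic), df = unname(wt$parameter),
               p_raw = wt$p.value)
  }))
  if (!is.null(between) && nrow(between)) {
    between$p_adj <- NA_real_
    tested <- !is.na(between$p_raw)
    between$p_adj[tested] <- stats::p.adjust(between$p_raw[tested],
                                             method = "holm")
    rownames(between) <- NULL
  }
  list(per_star = per_star, within = within, between = between)
}
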