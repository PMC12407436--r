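## Juvenile growth and fate analyses for the 2x2 factorial rearing
## experiments (larval temperature x juvenile temperature).

#' Absolute growth rate (micrometres per day)
#'
#' `(DT - D0) / T`: diameter change over the days until the final
#' measurement. Negative rates are legitimate (juveniles shrink before
#' dying) and pass through unchanged.
#'
#' @param D0 Initial diameter (um), positive.
#' @param DT Final diameter (um).
#' @param T_days Day of the final measurement (>= 1).
#' @return Growth rate in um/day.
#' @export
growth_rate_abs <- function(D0, DT, T_days) {
  stopifnot(all(D0 > 0), all(T_days >= 1))
  (DT - D0) / T_days
}

#' Relative growth (fraction of initial diameter)
#'
#' `(DT - D0) / D0`: fractional diameter change over a fixed interval.
#'
#' @inheritParams growth_rate_abs
#' @return Fractional growth (e.g. 0.5 for 50% growth); bounded below
#'   by -1.
#' @export
growth_rate_rel <- function(D0, DT) {
  stopifnot(all(D0 > 0))
  (DT - D0) / D0
}

#' Factorial ANOVA of juvenile growth with Tukey HSD
#'
#' Computes the chosen growth metric per juvenile, excludes bona fide
#' mortality records (their pre-death shrinkage is not growth), and fits a
#' two-way ANOVA of growth on larval rearing temperature, juvenile test
#' temperature and their interaction. Tukey HSD contrasts on the cell
#' means accompany the omnibus table. Juveniles lost mid-experiment (MIA,
#' stranded) contribute growth up to their last measurement day.
#'
#' @param records Juvenile growth records (schema `"growth"`).
#' @param metric `"abs"` for um/day ([growth_rate_abs()]) or `"rel"` for
#'   fractional growth ([growth_rate_rel()]).
#' @return Object of class `"growth_anova"`: `growth` (per-star values and
#'   factors), `cell_means` (mean, sd, sem, n per treatment cell),
#'   `table` (ANOVA terms with F and p), `tukey` (adjusted pairwise cell
#'   contrasts), `n_excluded`, and the `aov` fit.
#' @export
factorial_growth_anova <- function(records, metric = c("abs", "rel")) {
  metric <- match.arg(metric)
  records <- validate_records(records, "growth")
  excl <- records$fate == "mortality"
  d <- records[!excl, , drop = FALSE]
  g <- if (metric == "abs") growth_rate_abs(d$D0, d$DT, d$T_days)
       else growth_rate_rel(d$D0, d$DT)
  d <- data.frame(star_id = d$star_id, growth = g,
                  larval = factor(d$larval_temp),
                  juvenile = factor(d$juvenile_temp))
  cells <- table(d$larval, d$juvenile)
  if (any(cells == 0L)) stop("empty cell in factorial design", call. = FALSE)
  if (any(cells < 2L)) stop("need >= 2 juveniles per cell", call. = FALSE)

  fit <- stats::aov(growth ~ larval * juvenile, data = d)
  tab <- .anova_table(fit)

  agg <- stats::aggregate(growth ~ larval + juvenile, data = d,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  cm <- data.frame(larval = agg$larval, juvenile = agg$juvenile,
                   mean = agg$growth[, "mean"], sd = agg$growth[, "sd"],
                   n = agg$growth[, "n"])
  cm$sem <- cm$sd / sqrt(cm$n)

  tuk <- stats::TukeyHSD(stats::aov(growth ~ interaction(larval, juvenile),
                                    data = d))[[1L]]
  tukey <- data.frame(contrast = rownames(tuk), diff = tuk[, "diff"],
                      lwr = tuk[, "lwr"], upr = tuk[, "upr"],
                      p_adj = tuk[, "p adj"])
  rownames(tukey) <- NULL

  structure(list(growth = d, cell_means = cm, table = tab, tukey = tukey,
                 n_excluded = sum(excl), metric = metric, fit = fit),
            class = "growth_anova")
}

# tidy an aov fit's ANOVA table; a term explaining exactly zero variance
# reports F = 0, p = 1 (anova() returns 0/0 = NaN when the residual SS is
# also zero)
.anova_table <- function(fit) {
  if (stats::var(fit$model[[1L]]) == 0) {
    an0 <- suppressWarnings(stats::anova(fit))
    tab <- data.frame(term = trimws(rownames(an0)), df = an0$Df,
                      sum_sq = 0, F = c(rep(0, nrow(an0) - 1L), NA),
                      p = c(rep(1, nrow(an0) - 1L), NA))
    rownames(tab) <- NULL
    return(tab)
  }
  an <- stats::anova(fit)
  tab <- data.frame(term = trimws(rownames(an)), df = an$Df,
                    sum_sq = an$`Sum Sq`, F = an$`F value`, p = an$`Pr(>F)`)
  rownames(tab) <- NULL
  zero <- !is.na(tab$F) & !is.finite(tab$F) & tab$sum_sq == 0
  zero <- zero | (is.nan(tab$F) & tab$sum_sq == 0)
  tab$F[zero] <- 0
  tab$p[zero] <- 1
  tab
}

# one-way ANOVA F from explicit group sums; exact zero when group means
# are identical (QR-based anova() leaves ~1e-30 roundoff there, and the
# uniform-fate layout must report F = 0, p = 1 exactly)
.oneway_f <- function(y, g) {
  g <- factor(g)
  n <- length(y)
  k <- nlevels(g)
  gm <- tapply(y, g, mean)
  gn <- tapply(y, g, length)
  grand <- mean(y)
  ss_b <- sum(gn * (gm - grand)^2)
  ss_w <- sum((y - gm[g])^2)
  df1 <- k - 1L; df2 <- n - k
  if (ss_w == 0) {
    Fv <- if (ss_b == 0) 0 else Inf
  } else Fv <- (ss_b / df1) / (ss_w / df2)
  p <- if (Fv == 0) 1 else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, df1 = df1, df2 = df2, p = p)
}

#' Per-factor tests of a juvenile fate category
#'
#' Converts a fate category into a binary indicator and tests it against
#' each design factor separately with a linear-model (one-way ANOVA) F
#' test — the analysis style the factorial experiments report — plus a
#' Fisher exact test alongside, since normal-theory F on rare binary
#' events is fragile. Factors with a single observed level are skipped
#' with a note.
#'
#' @param records Juvenile growth records (schema `"growth"`).
#' @param fate Fate category to test (e.g. `"mortality"`, `"MIA"`,
#'   `"high_and_dry"`).
#' @param factors Design factor columns to test against; defaults to all
#'   available.
#' @return Data frame with one row per factor: `factor`, `df1`, `df2`,
#'   `F`, `p`, `fisher_p`, `n_events`, `skipped`.
#' @export
fate_tests <- function(records, fate,
                       factors = c("juvenile_temp", "larval_temp", "box_id",
                                   "box_side", "chamber_position")) {
  records <- validate_records(records, "growth")
  stopifnot(fate %in% .valid_fates)
  ind <- as.numeric(records$fate == fate)
  out <- lapply(factors, function(fc) {
    f <- factor(records[[fc]])
    if (nlevels(f) < 2L)
      return(data.frame(factor = fc, df1 = NA, df2 = NA, F = NA, p = NA,
                        fisher_p = NA, n_events = sum(ind), skipped = TRUE))
    ow <- .oneway_f(ind, f)
    fp <- if (length(unique(ind)) < 2L) 1
          else stats::fisher.test(table(f, ind))$p.value
    data.frame(factor = fc, df1 = ow$df1, df2 = ow$df2, F = ow$F, p = ow$p,
               fisher_p = fp, n_events = sum(ind), skipped = FALSE)
  })
  do.call(rbind, out)
}
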