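## Synthetic-data generators.
##
## Every experimental design in the pipeline has a generator that produces
## records in the canonical schema plus a machine-readable truth record, so
## each analysis stage can be exercised against known ground truth. The
## generators emulate the *statistical* structure the analyses assume —
## jar-clustered concave quadratic temperature responses, multinomial
## clone classes, logit-normal replicate effects on settlement, factorial
## growth with fate categories, and star-clustered righting-time streams —
## not the underlying biology.

.default_characters <- list(
  body_length    = list(peak = 17.5, curvature = -1.2, intercept = 420, loading = 1.0),
  body_width     = list(peak = 18.0, curvature = -0.8, intercept = 300, loading = 0.8),
  stomach_length = list(peak = 17.0, curvature = -1.0, intercept = 180, loading = 0.9),
  arm_length     = list(peak = 16.5, curvature = -0.9, intercept = 150, loading = 0.7)
)

#' Generate jar-clustered morphometric records from known quadratic TPCs
#'
#' Each character c follows
#' `value = intercept_c + curvature_c (t - peak_c)^2 +
#'  loading_c (jar + dev) + noise`,
#' with one latent effect per jar (`N(0, jar_sd^2)`), a shared latent
#' "development" factor per larva (`N(0, latent_sd^2)`) that induces the
#' between-character correlation the PC1 composite assumes, and
#' independent residual noise per measurement. Missing values are applied
#' uniformly at `missing_rate`.
#'
#' @param stage Developmental stage label.
#' @param temperatures Tested temperatures (degrees C); default the
#'   five-point embryo exposure series.
#' @param jars_per_temp,larvae_per_jar Replicate jars per temperature
#'   (default 3) and larvae measured per jar (default 10).
#' @param characters Named list; each entry a list with `peak` (degrees C),
#'   `curvature` (< 0 for a concave response), `intercept` and `loading`.
#' @param jar_sd,latent_sd,residual_sd SDs of the jar effect, the shared
#'   per-larva development factor, and the residual (score units).
#' @param missing_rate Fraction of measurements left blank, in [0, 1).
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return List with `records` (long morphometric data frame) and `truth`
#'   (per-character peaks and the generator parameters).
#' @export
gen_morphometrics <- function(stage = "embryo",
                              temperatures = c(10, 12, 14, 16, 18),
                              jars_per_temp = 3L, larvae_per_jar = 10L,
                              characters = .default_characters,
                              jar_sd = 0.2, latent_sd = 0,
                              residual_sd = 0.5, missing_rate = 0,
                              seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 1, jars_per_temp >= 1,
            larvae_per_jar >= 1)
  if (!is.null(seed)) set.seed(seed)
  cn <- names(characters)
  stopifnot(length(cn) >= 1L, !is.null(cn))

  rows <- vector("list", length(temperatures) * jars_per_temp)
  r <- 0L
  for (t in temperatures) {
    for (j in seq_len(jars_per_temp)) {
      jar_id <- sprintf("T%g_J%d", t, j)
      jar_eff <- stats::rnorm(1L, 0, jar_sd)
      dev <- stats::rnorm(larvae_per_jar, 0, latent_sd)
      per_char <- lapply(cn, function(ch) {
        p <- characters[[ch]]
        p$intercept + p$curvature * (t - p$peak)^2 +
          p$loading * (jar_eff + dev) +
          stats::rnorm(larvae_per_jar, 0, residual_sd)
      })
      r <- r + 1L
      rows[[r]] <- data.frame(
        stage = stage, temperature = t, jar_id = jar_id,
        larva_id = rep(sprintf("%s_L%02d", jar_id, seq_len(larvae_per_jar)),
                       times = length(cn)),
        character = rep(cn, each = larvae_per_jar),
        value = unlist(per_char, use.names = FALSE))
    }
  }
  records <- do.call(rbind, rows)
  if (missing_rate > 0) {
    drop <- stats::runif(nrow(records)) < missing_rate
    records$value[drop] <- NA_real_
  }
  truth <- list(
    character_peaks = vapply(characters, `[[`, numeric(1), "peak"),
    jar_sd = jar_sd, latent_sd = latent_sd, residual_sd = residual_sd,
    temperatures = temperatures, jars_per_temp = jars_per_temp,
    larvae_per_jar = larvae_per_jar, missing_rate = missing_rate)
  list(records = records, truth = truth)
}

#' Clone-class probability table with elevated cloning at the top temperature
#'
#' Baseline class probabilities at every temperature except the warmest,
#' where the combined odds of the three clone classes are multiplied by
#' `top_odds_ratio` (clone mass rescaled, class composition preserved).
#'
#' @param temperatures Tested temperatures.
#' @param base Named probabilities over
#'   `class1, class2, class3, class4, settled` (must sum to 1).
#' @param top_odds_ratio Clone-odds multiplier at `max(temperatures)`.
#' @return Matrix, one row per temperature, columns the five classes.
#' @export
make_clone_probs <- function(temperatures,
                             base = c(class1 = 0.55, class2 = 0.20,
                                      class3 = 0.12, class4 = 0.08,
                                      settled = 0.05),
                             top_odds_ratio = 1.5) {
  stopifnot(abs(sum(base) - 1) < 1e-8)
  pr <- matrix(rep(base, length(temperatures)), nrow = length(temperatures),
               byrow = TRUE, dimnames = list(as.character(temperatures),
                                             names(base)))
  clone_cols <- c("class2", "class3", "class4")
  i <- which.max(temperatures)
  p_clone <- sum(base[clone_cols])
  odds <- p_clone / (1 - p_clone) * top_odds_ratio
  p_new <- odds / (1 + odds)
  pr[i, clone_cols] <- base[clone_cols] * (p_new / p_clone)
  pr[i, c("class1", "settled")] <- base[c("class1", "settled")] *
    ((1 - p_new) / (1 - p_clone))
  pr
}

#' Generate per-jar clone-class counts
#'
#' Multinomial draws per jar from a temperature-specific probability table.
#'
#' @param temperatures Tested temperatures.
#' @param jars_per_temp Jars per temperature (default 3).
#' @param n_per_jar Larvae classified per jar (default 80).
#' @param class_probs Probability matrix as from [make_clone_probs()].
#' @param seed Optional integer seed.
#' @return List with `records` (schema `"cloning"`) and `truth` (the
#'   probability table).
#' @export
gen_cloning <- function(temperatures = c(12, 14, 16, 18, 20),
                        jars_per_temp = 3L, n_per_jar = 80L,
                        class_probs = make_clone_probs(temperatures),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_along(temperatures)) {
    t <- temperatures[i]
    draws <- stats::rmultinom(jars_per_temp, n_per_jar, class_probs[i, ])
    for (j in seq_len(jars_per_temp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        jar_id = sprintf("T%g_J%d", t, j), temperature = t,
        class1 = draws["class1", j], class2 = draws["class2", j],
        class3 = draws["class3", j], class4 = draws["class4", j],
        settled = draws["settled", j])
    }
  }
  list(records = do.call(rbind, rows),
       truth = list(class_probs = class_probs, n_per_jar = n_per_jar))
}

.level_offsets <- function(levels, spec) {
  # scalar -> offset on every level above the first; vector -> per level
  if (length(spec) == 1L) c(0, rep(spec, length(levels) - 1L))
  else { stopifnot(length(spec) == length(levels)); spec }
}

#' Generate factorial settlement outcomes with replicate random effects
#'
#' Each replicate well holds `n_per_well` larvae; its settlement
#' probability is `plogis(intercept + rearing offset + test offset +
#' interaction + well effect)` with well effects `N(0, replicate_sd^2)`
#' on the logit scale. Attachment without full settlement is added on top
#' so `n_settled <= n_attached <= n_exposed`.
#'
#' @param rearing_temps,test_temps Factor levels (degrees C).
#' @param reps_per_cell Replicate wells per cell (default 6).
#' @param n_per_well Larvae per well (default 5).
#' @param intercept_logit Baseline log-odds of settlement.
#' @param rearing_logit,test_logit Level offsets: a scalar applies to every
#'   level above the first, or give one offset per level.
#' @param interaction_logit Extra log-odds in the (top rearing, top test)
#'   cell.
#' @param replicate_sd SD of the well random effect (logit scale).
#' @param p_attach_extra Probability that an unsettled larva is at least
#'   attached.
#' @param seed Optional integer seed.
#' @return List with `records` (schema `"settlement"`) and `truth`
#'   (cell-wise settlement probabilities and the logit parameters).
#' @export
gen_settlement <- function(rearing_temps = c(12, 16), test_temps = c(12, 16),
                           reps_per_cell = 6L, n_per_well = 5L,
                           intercept_logit = 0, rearing_logit = 0,
                           test_logit = 0, interaction_logit = 0,
                           replicate_sd = 0.3, p_attach_extra = 0.2,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ro <- .level_offsets(rearing_temps, rearing_logit)
  to <- .level_offsets(test_temps, test_logit)
  rows <- list()
  truth_cells <- list()
  for (i in seq_along(rearing_temps)) for (k in seq_along(test_temps)) {
    eta0 <- intercept_logit + ro[i] + to[k] +
      if (i == length(rearing_temps) && k == length(test_temps))
        interaction_logit else 0
    truth_cells[[length(truth_cells) + 1L]] <- data.frame(
      rearing_temperature = rearing_temps[i],
      test_temperature = test_temps[k],
      logit = eta0, p_settle = stats::plogis(eta0))
    for (rpl in seq_len(reps_per_cell)) {
      eta <- eta0 + stats::rnorm(1L, 0, replicate_sd)
      n_settled <- stats::rbinom(1L, n_per_well, stats::plogis(eta))
      n_attached <- n_settled +
        stats::rbinom(1L, n_per_well - n_settled, p_attach_extra)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = sprintf("R%g_T%g_W%d", rearing_temps[i],
                               test_temps[k], rpl),
        rearing_temperature = rearing_temps[i],
        test_temperature = test_temps[k],
        n_exposed = n_per_well, n_attached = n_attached,
        n_settled = n_settled)
    }
  }
  list(records = do.call(rbind, rows),
       truth = list(cells = do.call(rbind, truth_cells),
                    intercept_logit = intercept_logit,
                    rearing_offsets = ro, test_offsets = to,
                    interaction_logit = interaction_logit,
                    replicate_sd = replicate_sd))
}

#' Generate 2x2 factorial juvenile growth records with fate categories
#'
#' Per-juvenile growth rates are normal around treatment-cell means; fates
#' (`MIA`, `high_and_dry`, `mortality`) are drawn per juvenile from
#' cell-independent probabilities unless a per-cell table is given.
#' Mortality records get negative growth (shrinkage before death) and
#' truncated records an earlier last-measurement day. Chamber layout
#' follows a 12-chamber box per cell: 4 corner / 8 interior chambers,
#' half on the hinge side.
#'
#' @param larval_temps,juvenile_temps Factor levels (degrees C).
#' @param n_per_cell Juveniles per cell (default 12).
#' @param base_rate Growth rate (um/day) in the baseline cell.
#' @param juvenile_effect,larval_effect,interaction_effect Additive rate
#'   offsets (um/day) for the higher juvenile temperature, higher larval
#'   temperature, and their combination.
#' @param rate_sd Between-juvenile SD of growth rate (um/day).
#' @param D0_mean,D0_sd Initial diameter distribution (um).
#' @param T_total Experiment length in days (default 41).
#' @param fate_probs Named probabilities for `MIA`, `high_and_dry`,
#'   `mortality` (remainder survive).
#' @param seed Optional integer seed.
#' @return List with `records` (schema `"growth"`) and `truth` (cell mean
#'   rates and all parameters).
#' @export
gen_growth <- function(larval_temps = c(11, 16), juvenile_temps = c(11, 16),
                       n_per_cell = 12L, base_rate = 5,
                       juvenile_effect = 3.5, larval_effect = 0,
                       interaction_effect = 0, rate_sd = 2.5,
                       D0_mean = 550, D0_sd = 60, T_total = 41L,
                       fate_probs = c(MIA = 0, high_and_dry = 0,
                                      mortality = 0),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sum(fate_probs) <= 1)
  chamber_pos <- rep(c(rep("corner", 2L), rep("interior", 4L)), 2L)
  box_side <- rep(c("hinge", "non_hinge"), each = 6L)
  rows <- list()
  cells <- list()
  for (i in seq_along(larval_temps)) for (k in seq_along(juvenile_temps)) {
    mu <- base_rate +
      (k - 1L) * juvenile_effect + (i - 1L) * larval_effect +
      (i - 1L) * (k - 1L) * interaction_effect
    cells[[length(cells) + 1L]] <- data.frame(
      larval_temp = larval_temps[i], juvenile_temp = juvenile_temps[k],
      mean_rate = mu)
    box <- sprintf("B%d%d", i, k)
    fates <- sample(c(names(fate_probs), "survived"), n_per_cell,
                    replace = TRUE,
                    prob = c(fate_probs, 1 - sum(fate_probs)))
    for (s in seq_len(n_per_cell)) {
      pos <- ((s - 1L) %% 12L) + 1L
      d0 <- max(stats::rnorm(1L, D0_mean, D0_sd), 100)
      fate <- fates[s]
      if (fate == "mortality") {
        t_days <- sample(seq(5L, max(T_total - 5L, 5L)), 1L)
        rate <- -abs(stats::rnorm(1L, 2, 1))  # shrinks before dying
      } else if (fate %in% c("MIA", "high_and_dry")) {
        t_days <- sample(seq(5L, max(T_total - 5L, 5L)), 1L)
        rate <- stats::rnorm(1L, mu, rate_sd)
      } else {
        t_days <- T_total
        rate <- stats::rnorm(1L, mu, rate_sd)
      }
      dt <- max(d0 + rate * t_days, 50)
      rows[[length(rows) + 1L]] <- data.frame(
        star_id = sprintf("%s_S%02d", box, s),
        larval_temp = larval_temps[i], juvenile_temp = juvenile_temps[k],
        box_id = box, chamber_position = chamber_pos[pos],
        box_side = box_side[pos], D0 = d0, DT = dt,
        T_days = as.integer(t_days), fate = fate)
    }
  }
  list(records = do.call(rbind, rows),
       truth = list(cells = do.call(rbind, cells), rate_sd = rate_sd,
                    fate_probs = fate_probs, T_total = T_total))
}

#' Generate star-clustered righting-time streams for the heatwave design
#'
#' Each star flips continuously through a 10-minute run in each phase;
#' flip k starts when flip k-1 (plus a handling pause) ends, so clock
#' times accumulate realistically. Expected righting time is
#' `(baseline_mean + star effect) * multiplier[treatment, phase]` with
#' multiplicative lognormal residuals (mean 1), matching the positive,
#' right-skewed character of righting times. Flips beginning inside the
#' first minute can be inflated by `minute1_inflation` to emulate
#' acclimation outliers. Diameters grow between phases by per-treatment
#' fractions.
#'
#' @param stars_per_treatment Named integer vector: stars per treatment.
#' @param flips_per_star_phase Flips per star per phase (default 14, i.e.
#'   about 28 per star across both phases).
#' @param baseline_mean Mean ambient righting time in seconds.
#' @param star_sd SD of the per-star intercept (seconds).
#' @param sdlog Lognormal residual log-SD.
#' @param t1_multipliers Named vector: multiplicative change of T1 times
#'   relative to T0 per treatment (1 = no change).
#' @param minute1_inflation Multiplier on righting times of flips starting
#'   before 60 s (default 1 = none).
#' @param handling_s Pause between righting and the next flip (seconds).
#' @param growth_frac Named vector of fractional diameter growth between
#'   phases per treatment.
#' @param growth_sd_cm Between-star SD of absolute diameter growth (cm).
#' @param diameter_range Initial diameter range (cm).
#' @param seed Optional integer seed.
#' @return List with `records` (schema `"flips"`) and `truth` (all
#'   parameters, incl. the implied percent change per treatment).
#' @export
gen_flips <- function(stars_per_treatment = c("12to12" = 7L, "12to14.5" = 6L,
                                              "12to17" = 8L),
                      flips_per_star_phase = 14L, baseline_mean = 34.5,
                      star_sd = 5, sdlog = 0.4,
                      t1_multipliers = c("12to12" = 1, "12to14.5" = 0.812,
                                         "12to17" = 0.897),
                      minute1_inflation = 1, handling_s = 3,
                      growth_frac = c("12to12" = 0.05, "12to14.5" = 0.10,
                                      "12to17" = 0.11),
                      growth_sd_cm = 0.05,
                      diameter_range = c(0.9, 1.8), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trts <- names(stars_per_treatment)
  stopifnot(!is.null(trts), all(trts %in% names(t1_multipliers)),
            all(t1_multipliers > 0))
  rows <- list()
  sidx <- 0L
  for (trt in trts) {
    for (s in seq_len(stars_per_treatment[[trt]])) {
      sidx <- sidx + 1L
      star <- sprintf("star%02d", sidx)
      eff <- stats::rnorm(1L, 0, star_sd)
      d0 <- stats::runif(1L, diameter_range[1L], diameter_range[2L])
      for (phase in .valid_phases) {
        mult <- if (phase == "T1_test") t1_multipliers[[trt]] else 1
        mu <- max(baseline_mean + eff, 1) * mult
        raw <- mu * stats::rlnorm(flips_per_star_phase,
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog)
        clock <- c(0, cumsum(raw[-length(raw)] + handling_s))
        inflate <- ifelse(clock < 60, minute1_inflation, 1)
        times <- raw * inflate
        # re-accumulate so inflated early flips push later start times
        clock <- c(0, cumsum(times[-length(times)] + handling_s))
        diam <- if (phase == "T1_test")
          max(d0 * (1 + growth_frac[[trt]]) +
                stats::rnorm(1L, 0, growth_sd_cm), 0.1) else d0
        rows[[length(rows) + 1L]] <- data.frame(
          star_id = star, treatment = trt, phase = phase,
          clock_time = clock, righting_time = times, diameter = diam)
      }
    }
  }
  list(records = do.call(rbind, rows),
       truth = list(baseline_mean = baseline_mean, star_sd = star_sd,
                    sdlog = sdlog, t1_multipliers = t1_multipliers,
                    percent_change = 100 * (t1_multipliers - 1),
                    minute1_inflation = minute1_inflation,
                    growth_frac = growth_frac,
                    flips_per_star_phase = flips_per_star_phase))
}

#' Summary counts for a flip-event collection
#'
#' @param events Flip-event records (schema `"flips"`).
#' @return List with `n_flips`, `n_stars`, `mean_flips_per_star`.
#' @export
flip_summary <- function(events) {
  events <- validate_records(events, "flips")
  n <- nrow(events)
  s <- length(unique(events$star_id))
  list(n_flips = n, n_stars = s, mean_flips_per_star = n / s)
}
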