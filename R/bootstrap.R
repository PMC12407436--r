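## Two-stage cluster bootstrap for the thermal optimum.
##
## Larvae are reared in replicate jars, so observations within a jar are
## dependent ("replicate effects"). The bootstrap honours that structure by
## resampling in two stages: jars with replacement first, then larvae with
## replacement within each drawn jar (each drawn copy of a jar gets an
## independent redraw of larvae). The quadratic peak is recomputed on each
## resample and the percentile interval taken from the resulting
## distribution.
##
## By default stage 1 resamples jars *within temperature*, preserving the
## design's temperature coverage so every resample supports a quadratic
## fit; unstratified jar resampling (a single pooled jar urn) is available
## via `stratify = FALSE`.

# Partition scored data by jar; basis for both resampling routes.
.jar_index <- function(data) {
  stopifnot(all(c("temperature", "jar_id", "score") %in% names(data)))
  if (anyNA(data$score) || anyNA(data$temperature))
    stop("scored data must not contain missing values", call. = FALSE)
  key <- interaction(data$temperature, data$jar_id, drop = TRUE, sep = "\r")
  rows <- split(seq_len(nrow(data)), key)
  if (any(lengths(rows) == 0L)) stop("empty jar", call. = FALSE)
  jt <- vapply(rows, function(r) data$temperature[r[1L]], numeric(1))
  list(rows = rows, temp = jt,
       strata = split(seq_along(rows), jt))
}

# One two-stage resample, as row indices into the original data.
.resample_indices <- function(idx, stratify = TRUE) {
  drawn <- if (stratify) {
    unlist(lapply(idx$strata, function(js) {
      js[sample.int(length(js), length(js), replace = TRUE)]
    }), use.names = FALSE)
  } else {
    J <- length(idx$rows)
    sample.int(J, J, replace = TRUE)
  }
  unlist(lapply(drawn, function(j) {
    r <- idx$rows[[j]]
    r[sample.int(length(r), length(r), replace = TRUE)]
  }), use.names = FALSE)
}

#' Two-stage cluster resample of jar-structured observations
#'
#' Stage 1 draws jars with replacement (within temperature stratum by
#' default); stage 2 draws, within each drawn jar, as many larvae with
#' replacement as that jar originally held. Every drawn copy of a jar is an
#' independent larva redraw.
#'
#' @param data Data frame with `temperature`, `jar_id` and `score` columns
#'   (e.g. the output of [score_composite()]).
#' @param stratify Resample jars within temperature (default) or from a
#'   single pooled urn.
#' @return A resampled data frame with the same columns and, under equal
#'   jar sizes, the same number of rows.
#' @export
resample_clustered <- function(data, stratify = TRUE) {
  idx <- .jar_index(data)
  out <- data[.resample_indices(idx, stratify), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentile cluster-bootstrap confidence interval for the thermal optimum
#'
#' Repeats [resample_clustered()] `n_boot` times, refits the quadratic TPC
#' to each resample, records the clamped peak, and returns the empirical
#' `(1-level)/2` and `1-(1-level)/2` quantiles of the peak distribution
#' (linear-interpolation quantiles). A resample with fewer than 3 distinct
#' temperatures (possible only unstratified) is redrawn, up to 100 attempts
#' per replicate, so `n_boot` is exact.
#'
#' @inheritParams resample_clustered
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @return Object of class `"peak_ci"`: `level`, `lower`, `upper`,
#'   `n_boot`, `boot_peaks`, `t_opt` (the full-data estimate), the tested
#'   range, and the redraw count.
#' @examples
#' d <- gen_morphometrics(seed = 1)
#' s <- data.frame(temperature = d$records$temperature,
#'                 jar_id = d$records$jar_id, score = d$records$value)
#' set.seed(2)
#' bootstrap_peak_ci(s, n_boot = 200)
#' @export
bootstrap_peak_ci <- function(data, n_boot = 1000L, level = 0.95,
                              stratify = TRUE) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  idx <- .jar_index(data)
  t_all <- data$temperature
  y_all <- data$score
  if (length(unique(t_all)) < 3L)
    stop("quadratic unidentifiable: need >= 3 distinct temperatures",
         call. = FALSE)
  fit0 <- fit_quadratic(t_all, y_all)
  t_min <- fit0$t_min; t_max <- fit0$t_max

  peaks <- numeric(n_boot)
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(100L)) {
      rows <- .resample_indices(idx, stratify)
      tb <- t_all[rows]
      if (length(unique(tb)) >= 3L) break
      n_redraws <- n_redraws + 1L
      if (attempt == 100L)
        stop("resample degenerate after 100 redraws", call. = FALSE)
    }
    beta <- .quad_ols(tb, y_all[rows])
    peaks[b] <- peak(beta[3L], beta[2L], t_min, t_max)
  }

  qs <- stats::quantile(peaks, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(level = level, lower = qs[1L], upper = qs[2L],
                 n_boot = as.integer(n_boot), boot_peaks = peaks,
                 t_opt = fit0$t_opt, t_min = t_min, t_max = t_max,
                 stratified = stratify, n_redraws = n_redraws),
            class = "peak_ci")
}

#' @export
print.peak_ci <- function(x, ...) {
  cat(sprintf("Thermal optimum %.1f degC, %d%% cluster-bootstrap CI [%.1f, %.1f]\n",
              x$t_opt, round(100 * x$level), x$lower, x$upper))
  cat(sprintf("  %d resamples (%s), tested range [%.1f, %.1f] degC\n",
              x$n_boot, if (x$stratified) "stratified by temperature"
              else "pooled jars", x$t_min, x$t_max))
  invisible(x)
}

#' Screen jars for undue influence on the thermal optimum
#'
#' For each jar, reports (i) its standardized jar-mean residual among the
#' jar means at its temperature and (ii) the shift in the estimated optimum
#' when the jar is left out and the quadratic refitted. Jars whose
#' standardized residual exceeds `threshold` (in SD of within-temperature
#' jar means) are flagged for analyst review; nothing is ever dropped
#' automatically — exclusions are an explicit, logged analyst decision.
#'
#' @inheritParams resample_clustered
#' @param threshold Flagging threshold in SD units (default 3).
#' @return Data frame with one row per jar: `jar_id`, `temperature`, `n`,
#'   `jar_mean`, `z` (standardized residual, `NA` when the jar is the only
#'   one at its temperature), `t_opt_shift` from the leave-one-jar-out
#'   refit, `flagged`, and `screenable`.
#' @export
jar_effect_screen <- function(data, threshold = 3) {
  idx <- .jar_index(data)
  fit0 <- fit_quadratic(data$temperature, data$score)
  jar_ids <- vapply(idx$rows, function(r) data$jar_id[r[1L]], character(1))
  jm <- vapply(idx$rows, function(r) mean(data$score[r]), numeric(1))

  # leave-one-out deviation of each jar mean from the other jars at its
  # temperature, standardized by the pooled SD of the *other* jars'
  # deviations (pooling across temperatures). Including the candidate jar
  # in its own scale would cap |z| near 1 at three jars per temperature
  # and mask exactly the gross outliers the screen exists to catch.
  dev <- rep(NA_real_, length(jm))
  for (s in idx$strata) {
    if (length(s) >= 2L) {
      for (j in s) dev[j] <- jm[j] - mean(jm[setdiff(s, j)])
    }
  }
  z <- rep(NA_real_, length(jm))
  for (j in which(!is.na(dev))) {
    others <- dev[setdiff(which(!is.na(dev)), j)]
    if (length(others) >= 2L && stats::sd(others) > 0)
      z[j] <- dev[j] / stats::sd(others)
  }
  shift <- vapply(seq_along(idx$rows), function(j) {
    keep <- setdiff(seq_len(nrow(data)), idx$rows[[j]])
    if (length(unique(data$temperature[keep])) < 3L) return(NA_real_)
    fit_quadratic(data$temperature[keep], data$score[keep])$t_opt - fit0$t_opt
  }, numeric(1))

  out <- data.frame(jar_id = jar_ids, temperature = idx$temp,
                    n = lengths(idx$rows), jar_mean = jm, z = z,
                    t_opt_shift = shift,
                    flagged = !is.na(z) & abs(z) > threshold,
                    screenable = !is.na(z))
  rownames(out) <- NULL
  out[order(out$temperature, out$jar_id), ]
}
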