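# shared fixture builders; everything is generated in code

# scored, jar-structured data on an exact (optionally noisy) parabola
make_scored <- function(temps = c(10, 12, 14, 16, 18), jars = 3, n = 10,
                        peak = 15, curvature = -1, jar_sd = 0, sd = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- expand.grid(rep = seq_len(n), jar = seq_len(jars),
                      temperature = temps)
  jar_key <- paste0("T", rows$temperature, "_J", rows$jar)
  jar_eff <- stats::rnorm(length(unique(jar_key)), 0, jar_sd)
  names(jar_eff) <- unique(jar_key)
  data.frame(
    temperature = rows$temperature,
    jar_id = jar_key,
    score = curvature * (rows$temperature - peak)^2 +
      jar_eff[jar_key] + stats::rnorm(nrow(rows), 0, sd))
}

# minimal valid morphometric record table
make_morpho <- function(n = 10) {
  data.frame(stage = "embryo", temperature = rep(c(10, 14, 18), length.out = n),
             jar_id = "J1", larva_id = sprintf("L%02d", seq_len(n)),
             character = "length", value = seq_len(n) * 10)
}

# independent dense-grid argmax of a fitted quadratic over [lo, hi]
grid_peak <- function(a, b, lo, hi, by = 0.001) {
  g <- seq(lo, hi, by = by)
  g[which.max(a * g^2 + b * g)]
}
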