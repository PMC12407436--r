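#' @keywords internal
"_PACKAGE"

## Canonical record schemas for the five experiment shapes.
##
## All records are plain long-format data frames: one row per atomic
## observation, missing values as NA (written as empty fields, never 0).

# schema registry: required columns and their types
.thermopt_schemas <- list(
  morphometrics = list(
    cols = c(stage = "character", temperature = "numeric",
             jar_id = "character", larva_id = "character",
             character = "character", value = "numeric"),
    na_ok = "value"
  ),
  cloning = list(
    cols = c(jar_id = "character", temperature = "numeric",
             class1 = "integer", class2 = "integer", class3 = "integer",
             class4 = "integer", settled = "integer"),
    na_ok = character(0)
  ),
  settlement = list(
    cols = c(replicate_id = "character", rearing_temperature = "numeric",
             test_temperature = "numeric", n_exposed = "integer",
             n_attached = "integer", n_settled = "integer"),
    na_ok = character(0)
  ),
  growth = list(
    cols = c(star_id = "character", larval_temp = "numeric",
             juvenile_temp = "numeric", box_id = "character",
             chamber_position = "character", box_side = "character",
             D0 = "numeric", DT = "numeric", T_days = "integer",
             fate = "character"),
    na_ok = character(0)
  ),
  flips = list(
    cols = c(star_id = "character", treatment = "character",
             phase = "character", clock_time = "numeric",
             righting_time = "numeric", diameter = "numeric"),
    na_ok = "diameter"
  )
)

# designed temperature sets per developmental stage (union over experiments)
.stage_temperatures <- list(
  embryo       = list(c(10, 12, 14, 16, 18)),
  bipinnaria   = list(c(12, 14, 16, 18, 20), c(11, 14, 17)),
  brachiolaria = list(c(12, 14, 16, 18, 20), c(11, 14, 17))
)

.valid_stages <- c("embryo", "bipinnaria", "brachiolaria")
.valid_fates <- c("survived", "MIA", "high_and_dry", "mortality")
.valid_phases <- c("T0_ambient", "T1_test")

#' Known record schemas
#'
#' @return Character vector of schema names understood by [read_table()],
#'   [write_table()] and [validate_records()].
#' @export
schema_names <- function() names(.thermopt_schemas)

.fail_rows <- function(what, rows) {
  stop(sprintf("%s (rows: %s)", what,
               paste(utils::head(rows, 10L), collapse = ", ")),
       call. = FALSE)
}

#' Validate a record collection against its schema
#'
#' Checks column presence/type and every schema invariant: non-negative
#' measurements and counts, count bounds (settled/attached within exposed),
#' key uniqueness for morphometrics, positive righting times, valid factor
#' levels, and (optionally) that each stage's temperatures belong to one of
#' the designed exposure sets.
#'
#' @param df Data frame of records.
#' @param schema One of [schema_names()].
#' @param check_design For `"morphometrics"`: also require the temperature
#'   set of each stage to match a designed exposure series. Disable when
#'   validating free-form simulated designs.
#' @return `df`, invisibly, with columns coerced to schema types.
#' @export
validate_records <- function(df, schema = schema_names(),
                             check_design = FALSE) {
  schema <- match.arg(schema)
  sc <- .thermopt_schemas[[schema]]
  missing_cols <- setdiff(names(sc$cols), names(df))
  extra_cols <- setdiff(names(df), names(sc$cols))
  if (length(missing_cols))
    stop(sprintf("schema '%s': missing columns [%s]%s", schema,
                 paste(missing_cols, collapse = ", "),
                 if (length(extra_cols))
                   sprintf("; unexpected columns [%s]",
                           paste(extra_cols, collapse = ", ")) else ""),
         call. = FALSE)
  df <- df[names(sc$cols)]
  for (cn in names(sc$cols)) {
    df[[cn]] <- switch(sc$cols[[cn]],
                       character = as.character(df[[cn]]),
                       numeric = as.numeric(df[[cn]]),
                       integer = {
                         v <- as.numeric(df[[cn]])
                         if (any(!is.na(v) & v != round(v)))
                           .fail_rows(sprintf("column '%s' must be integer", cn),
                                      which(!is.na(v) & v != round(v)))
                         as.integer(round(v))
                       })
    if (!cn %in% sc$na_ok && anyNA(df[[cn]]))
      .fail_rows(sprintf("column '%s' has missing values", cn),
                 which(is.na(df[[cn]])))
  }

  switch(schema,
    morphometrics = {
      bad <- which(!df$stage %in% .valid_stages)
      if (length(bad)) .fail_rows("unknown developmental stage", bad)
      bad <- which(!is.na(df$value) & df$value < 0)
      if (length(bad)) .fail_rows("negative measurement value", bad)
      key <- paste(df$stage, df$jar_id, df$larva_id, df$character, sep = "\r")
      if (anyDuplicated(key))
        .fail_rows("duplicate (stage, jar, larva, character) key",
                   which(duplicated(key)))
      if (check_design) {
        for (st in unique(df$stage)) {
          temps <- sort(unique(df$temperature[df$stage == st]))
          ok <- any(vapply(.stage_temperatures[[st]],
                           function(s) all(temps %in% s), logical(1)))
          if (!ok)
            stop(sprintf("stage '%s' temperatures {%s} match no designed exposure set",
                         st, paste(temps, collapse = ", ")), call. = FALSE)
        }
      }
    },
    cloning = {
      cnt <- as.matrix(df[c("class1", "class2", "class3", "class4", "settled")])
      bad <- which(apply(cnt < 0, 1L, any))
      if (length(bad)) .fail_rows("negative class count", bad)
    },
    settlement = {
      bad <- which(df$n_exposed < 0 | df$n_attached < 0 | df$n_settled < 0)
      if (length(bad)) .fail_rows("negative count", bad)
      bad <- which(df$n_settled > df$n_exposed)
      if (length(bad)) .fail_rows("n_settled exceeds n_exposed", bad)
      bad <- which(df$n_attached > df$n_exposed)
      if (length(bad)) .fail_rows("n_attached exceeds n_exposed", bad)
    },
    growth = {
      bad <- which(!df$fate %in% .valid_fates)
      if (length(bad)) .fail_rows("unknown fate category", bad)
      bad <- which(df$D0 <= 0)
      if (length(bad)) .fail_rows("D0 must be positive", bad)
      bad <- which(df$T_days < 1)
      if (length(bad)) .fail_rows("T_days must be >= 1", bad)
      bad <- which(!df$chamber_position %in% c("corner", "interior"))
      if (length(bad)) .fail_rows("chamber_position must be corner/interior", bad)
      bad <- which(!df$box_side %in% c("hinge", "non_hinge"))
      if (length(bad)) .fail_rows("box_side must be hinge/non_hinge", bad)
    },
    flips = {
      bad <- which(!df$phase %in% .valid_phases)
      if (length(bad)) .fail_rows("phase must be T0_ambient/T1_test", bad)
      bad <- which(df$righting_time <= 0)
      if (length(bad)) .fail_rows("righting_time must be positive", bad)
      # a run lasts 10 min; the final flip may start before and end after 600 s
      bad <- which(df$clock_time < 0)
      if (length(bad)) .fail_rows("clock_time must be non-negative", bad)
    })
  invisible(df)
}

#' Read a validated record table from CSV
#'
#' Empty fields are read as missing (`NA`); validation then enforces which
#' columns may carry missing values. Fails with a column diff if the header
#' does not match the schema, and with offending row numbers on any
#' invariant violation.
#'
#' @inheritParams validate_records
#' @param path CSV file path.
#' @return Validated data frame of records.
#' @export
read_table <- function(path, schema = schema_names(), check_design = FALSE) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = "", check.names = FALSE)
  validate_records(df, schema, check_design = check_design)
}

#' Write a record table to CSV
#'
#' Missing values are written as empty fields (never 0), so that
#' `read_table(write_table(x))` reproduces `x` exactly.
#'
#' @param df Validated record data frame.
#' @inheritParams read_table
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema = schema_names()) {
  schema <- match.arg(schema)
  df <- validate_records(df, schema)
  out <- df
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- .format_exact(out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# shortest decimal string that parses back to the identical double
.format_exact <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- as.character(v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

#' Run configuration
#'
#' Bundles the reproducibility and inference settings shared across the
#' pipeline stages.
#'
#' @param seed Integer RNG seed.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param ci_level Confidence level as a fraction (default 0.95).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_boot = 1000L, ci_level = 0.95,
                       alpha = 0.05) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1, alpha > 0, alpha < 1)
  structure(list(seed = as.integer(seed), n_boot = as.integer(n_boot),
                 ci_level = ci_level, alpha = alpha),
            class = "run_config")
}
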