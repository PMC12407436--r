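## PC1 composite development scores.
##
## Morphometric characters within a stage are highly correlated (they all
## track the same underlying developmental progression), so the analysis
## summarises each character set by the first principal component of the
## standardized character matrix. The resulting composite is the response
## fed to the thermal-performance-curve fit.

#' Fit a PC1 composite specification
#'
#' Performs correlation-matrix PCA on the chosen character set and keeps the
#' leading eigenvector as the composite's loadings. Characters are
#' standardized (centered, unit variance) before the eigendecomposition so
#' that micrometre lengths and ordinal stage scores contribute on a common
#' scale; loadings are therefore invariant to any rescaling of measurement
#' units. The sign of the component is fixed so that the loadings of
#' `size_characters` sum to a non-negative value, i.e. a higher score always
#' means a larger / more developed larva.
#'
#' @param records Long-format morphometric records (see
#'   [validate_records()]), or any data frame with `larva_id`, `jar_id`,
#'   `character` and `value` columns.
#' @param characters Character set to include (>= 2 names).
#' @param complete_case If `TRUE` (default) only larvae measured on every
#'   character in the set enter the fit; if `FALSE`, missing entries are
#'   mean-imputed before the eigendecomposition.
#' @param size_characters Characters counted as "size-type" for the sign
#'   orientation rule; defaults to all of `characters`.
#' @return An object of class `"composite_spec"`: characters, per-character
#'   centers and scales, unit-norm loadings, the applied orientation sign,
#'   the leading eigenvalue (`var_explained_abs`) and its share of total
#'   variance, and the number of larvae used.
#' @seealso [score_composite()]
#' @export
fit_pc1 <- function(records, characters, complete_case = TRUE,
                    size_characters = characters) {
  if (length(characters) < 2L)
    stop("need at least 2 characters for a composite", call. = FALSE)
  X <- pivot_characters(records, characters)
  ids <- X$ids
  M <- X$matrix

  if (complete_case) {
    keep <- stats::complete.cases(M)
    M <- M[keep, , drop = FALSE]
    ids <- ids[keep, , drop = FALSE]
  }
  if (nrow(M) < 3L)
    stop("fewer than 3 sufficiently complete observations", call. = FALSE)
  if (nrow(M) < ncol(M))
    stop("fewer observations than characters after missingness handling",
         call. = FALSE)

  centers <- colMeans(M, na.rm = TRUE)
  scales <- apply(M, 2L, stats::sd, na.rm = TRUE)
  zero_var <- names(which(scales == 0 | is.na(scales)))
  if (length(zero_var))
    stop("zero-variance character(s): ", paste(zero_var, collapse = ", "),
         call. = FALSE)

  Z <- sweep(sweep(M, 2L, centers), 2L, scales, "/")
  if (!complete_case && anyNA(Z)) Z[is.na(Z)] <- 0  # mean imputation
  R <- stats::cor(Z)
  eg <- eigen(R, symmetric = TRUE)
  loadings <- eg$vectors[, 1L]
  names(loadings) <- characters
  orientation <- if (sum(loadings[size_characters]) < 0) -1 else 1
  loadings <- loadings * orientation

  structure(list(
    characters = characters,
    centers = centers,
    scales = scales,
    loadings = loadings,
    orientation = orientation,
    var_explained_abs = eg$values[1L],
    var_explained = eg$values[1L] / sum(eg$values),
    n_obs = nrow(M),
    complete_case = complete_case
  ), class = "composite_spec")
}

#' Score records against a composite specification
#'
#' Computes `sum_j loading_j * (value_j - center_j) / scale_j` for each
#' larva. Scores of the fitting sample have mean zero and variance equal to
#' the leading eigenvalue of the character correlation matrix.
#'
#' @param records Long-format morphometric records.
#' @param spec A `"composite_spec"` from [fit_pc1()].
#' @param complete_case If `TRUE` (default) larvae missing any spec
#'   character are skipped (a message reports how many); if `FALSE` their
#'   missing standardized values are imputed as 0 (the character mean).
#' @return Data frame with `stage` (if present), `temperature`, `jar_id`,
#'   `larva_id` and the composite `score`, one row per scored larva.
#' @export
score_composite <- function(records, spec, complete_case = spec$complete_case) {
  stopifnot(inherits(spec, "composite_spec"))
  X <- pivot_characters(records, spec$characters)
  M <- X$matrix
  Z <- sweep(sweep(M, 2L, spec$centers), 2L, spec$scales, "/")
  incomplete <- !stats::complete.cases(Z)
  if (complete_case) {
    if (any(incomplete))
      message(sum(incomplete), " record(s) skipped: missing required characters")
    Z <- Z[!incomplete, , drop = FALSE]
    ids <- X$ids[!incomplete, , drop = FALSE]
  } else {
    Z[is.na(Z)] <- 0
    ids <- X$ids
  }
  ids$score <- drop(Z %*% spec$loadings)
  rownames(ids) <- NULL
  ids
}

#' Pivot long morphometric records to a larva-by-character matrix
#'
#' A view used by the composite fit; the long table remains the storage
#' format so per-character missingness stays first-class.
#'
#' @param records Long-format morphometric records.
#' @param characters Columns of the output matrix, in order.
#' @return List with `ids` (one row of identifying columns per larva) and
#'   `matrix` (values, `NA` where unmeasured).
#' @export
pivot_characters <- function(records, characters) {
  needed <- c("jar_id", "larva_id", "character", "value")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("records lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  records <- records[records$character %in% characters, , drop = FALSE]
  id_cols <- intersect(c("stage", "temperature", "jar_id", "larva_id"),
                       names(records))
  key <- interaction(records$jar_id, records$larva_id, drop = TRUE, sep = "\r")
  ids <- records[!duplicated(key), id_cols, drop = FALSE]
  rownames(ids) <- NULL
  ukey <- key[!duplicated(key)]
  M <- matrix(NA_real_, nrow = length(ukey), ncol = length(characters),
              dimnames = list(NULL, characters))
  ri <- match(key, ukey)
  ci <- match(records$character, characters)
  M[cbind(ri, ci)] <- records$value
  list(ids = ids, matrix = M)
}
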