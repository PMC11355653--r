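#' Code the fitting outcome as a numeric response
#'
#' Fitting is coded +1 and non-fitting -1, the response used by the PLS
#' regression.
#'
#' @param outcomes character vector in `c("fitting", "non_fitting")`.
#' @return Numeric vector of +1 / -1 in the same order.
#' @export
code_response <- function(outcomes) {
  if (length(outcomes) == 0) stop("empty outcome list", call. = FALSE)
  bad <- !outcomes %in% c("fitting", "non_fitting")
  if (any(bad))
    stop("unknown outcome label(s): ",
         paste(unique(outcomes[bad]), collapse = ", "), call. = FALSE)
  ifelse(outcomes == "fitting", 1, -1)
}

#' Decode a coded response back to outcome labels
#'
#' @param y numeric vector of +1 / -1.
#' @return Character vector of `"fitting"` / `"non_fitting"`.
#' @export
decode_response <- function(y) {
  stopifnot(all(y %in% c(-1, 1)))
  ifelse(y > 0, "fitting", "non_fitting")
}

#' Z-score a measurement matrix
#'
#' Each column is centred to mean 0 and scaled to sample SD 1 (denominator
#' n - 1), with the statistics computed over observed entries only; missing
#' entries stay `NA`. A constant column cannot be scaled and becomes all
#' zeros, with a warning — small resampling folds can produce such columns
#' and must not abort the analysis.
#'
#' @param raw numeric matrix (participants x variables), `NA` = missing.
#' @return A list with `Z` (the z-scored matrix, `NA`s preserved),
#'   `column_means`, `column_sds` (original units) and `missing_mask`.
#' @export
zscore_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) stop("need at least 2 rows to normalize", call. = FALSE)
  n_obs <- colSums(!is.na(raw))
  if (any(n_obs < 2))
    stop("column(s) with fewer than 2 observed values: ",
         paste(colnames(raw)[n_obs < 2], collapse = ", "), call. = FALSE)
  mu <- colMeans(raw, na.rm = TRUE)
  sdv <- apply(raw, 2, sd, na.rm = TRUE)
  const <- sdv == 0
  if (any(const)) {
    warning("constant column(s) z-scored to zero: ",
            paste(colnames(raw)[const], collapse = ", "), call. = FALSE)
    sdv[const] <- 1  # divide by 1; centred values are already zero
  }
  Z <- sweep(sweep(raw, 2, mu), 2, sdv, "/")
  list(Z = Z, column_means = mu, column_sds = ifelse(const, 0, sdv),
       missing_mask = is.na(raw))
}

#' Impute missing cells of a normalized matrix
#'
#' Missing values are replaced, after normalization, with a value close to
#' zero (1e-6 by default) so they sit at the column mean and barely
#' influence the fit.
#'
#' @param Z normalized matrix with `NA`s at missing cells.
#' @param value imputation constant (default `1e-6`).
#' @return The matrix with every `NA` replaced by `value`.
#' @export
impute_missing <- function(Z, value = 1e-6) {
  Z[is.na(Z)] <- value
  Z
}

#' Build a PLS design matrix from a cohort
#'
#' Runs the full preprocessing chain: restrict to the requested variables,
#' z-score per column over observed entries, impute missing cells with the
#' near-zero constant, and code the outcome as +1/-1.
#'
#' @param cohort a [cohort_table].
#' @param keys variable keys to include (default: all columns present).
#' @param imputation_value constant for [impute_missing()].
#' @return An object of class `design_matrix`: list with `X` (z-scored,
#'   imputed), `y` (+1/-1), `column_keys`, `column_means`, `column_sds`,
#'   `missing_mask`, `participant_id`.
#' @export
build_design_matrix <- function(cohort, keys = colnames(cohort$measurements),
                                imputation_value = 1e-6) {
  stopifnot(inherits(cohort, "cohort_table"))
  missing_keys <- setdiff(keys, colnames(cohort$measurements))
  if (length(missing_keys))
    stop("variables absent from cohort: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  raw <- cohort$measurements[, keys, drop = FALSE]
  nz <- zscore_normalize(raw)
  structure(list(X = impute_missing(nz$Z, imputation_value),
                 y = code_response(cohort$outcome),
                 column_keys = keys,
                 column_means = nz$column_means,
                 column_sds = nz$column_sds,
                 missing_mask = nz$missing_mask,
                 participant_id = cohort$participant_id),
            class = "design_matrix")
}
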