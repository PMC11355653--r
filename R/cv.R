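#' Trichotomous classification of a continuous PLS prediction
#'
#' Predictions above the half-width (default 0.1) are called fitting, below
#' its negative non-fitting; the closed middle zone, including the
#' boundaries, is called unknown — ambiguous cases are deliberately left
#' undecided rather than forced.
#'
#' @param yhat numeric vector of finite continuous predictions.
#' @param halfwidth half-width of the unknown zone (default 0.1).
#' @return Character vector in `c("fitting", "non_fitting", "unknown")`.
#' @export
#' @examples
#' classify_response(c(0.5, -0.3, 0.1, 0))
classify_response <- function(yhat, halfwidth = 0.1) {
  if (any(!is.finite(yhat))) stop("non-finite prediction", call. = FALSE)
  stopifnot(halfwidth >= 0)
  ifelse(yhat > halfwidth, "fitting",
         ifelse(yhat < -halfwidth, "non_fitting", "unknown"))
}

#' Select the top-k variables of a VIP ranking
#'
#' @param vip a `vip_result`.
#' @param k number of variables, `1 <= k <= p`.
#' @return Character vector: the first `k` keys of the ranking.
#' @export
select_top_k <- function(vip, k) {
  stopifnot(inherits(vip, "vip_result"))
  if (k < 1 || k > length(vip$ranking))
    stop(sprintf("k must lie in [1, %d]", length(vip$ranking)),
         call. = FALSE)
  vip$ranking[seq_len(k)]
}

# default knobs shared by the CV drivers; pipeline_config() builds a full
# superset of these
.cv_defaults <- function(config = list()) {
  defaults <- list(normalization_mode = "global",
                   selection_mode = "pooled",
                   imputation_value = 1e-6,
                   classification_halfwidth = 0.1,
                   degenerate_fold = "unknown")
  defaults[names(config)] <- config
  stopifnot(defaults$normalization_mode %in% c("global", "fold"),
            defaults$selection_mode %in% c("pooled", "nested"),
            defaults$degenerate_fold %in% c("unknown", "error"))
  defaults
}

# z-score by training-fold statistics, impute, fit, predict held-out rows;
# under "global" normalization Xn is the pre-normalized full matrix and the
# fold step is a plain subset.  Returns the continuous predictions for
# test_idx.  `keys` may be NULL under nested selection, meaning: rank by
# VIP within the training fold and take the top k_nested.
.fold_predict <- function(cohort, train_idx, test_idx, keys, A, config,
                          Xn_global = NULL, k_nested = NULL) {
  y <- code_response(cohort$outcome)
  if (length(unique(y[train_idx])) < 2) {
    # a single-class training fold cannot discriminate; under the default
    # policy its held-out predictions are undecidable ("unknown")
    if (config$degenerate_fold == "error")
      stop("training fold contains a single class", call. = FALSE)
    return(rep(NA_real_, length(test_idx)))
  }

  if (config$normalization_mode == "global") {
    X_all <- Xn_global
  } else {
    raw_train <- cohort$measurements[train_idx, , drop = FALSE]
    nz <- zscore_normalize(raw_train)
    sds <- ifelse(nz$column_sds == 0, 1, nz$column_sds)
    Z_all <- sweep(sweep(cohort$measurements, 2, nz$column_means), 2,
                   sds, "/")
    Z_all[, nz$column_sds == 0] <- 0
    Z_all[is.na(cohort$measurements)] <- NA
    X_all <- impute_missing(Z_all, config$imputation_value)
  }

  if (is.null(keys)) {  # nested selection inside the training fold
    design_tr <- list(X = X_all[train_idx, , drop = FALSE],
                      y = y[train_idx], column_keys = colnames(X_all))
    A_sel <- min(choose_components(design_tr),
                 length(train_idx) - 1, ncol(X_all))
    keys <- select_top_k(vip_scores(fit_pls(design_tr, A_sel)), k_nested)
  }

  X_sel <- X_all[, keys, drop = FALSE]
  A_use <- min(A, length(train_idx) - 1, length(keys))
  fit <- tryCatch(
    fit_pls(list(X = X_sel[train_idx, , drop = FALSE],
                 y = y[train_idx], column_keys = keys),
            A_use),
    error = function(e) {
      if (config$degenerate_fold == "error") stop(e)
      NULL  # e.g. constant X with no usable component
    })
  if (is.null(fit)) return(rep(NA_real_, length(test_idx)))
  predict(fit, X_sel[test_idx, , drop = FALSE])
}

.make_cv_report <- function(cohort, scheme, selected, pred_df, config) {
  n <- length(cohort$participant_id)
  call_code <- c(fitting = 1, non_fitting = -1, unknown = 0)
  pred_df$correct <- ifelse(pred_df$call == "unknown", NA,
                            pred_df$call == pred_df$truth)
  tallies <- list(n_correct = sum(pred_df$correct %in% TRUE),
                  n_incorrect = sum(pred_df$correct %in% FALSE),
                  n_unknown = sum(is.na(pred_df$correct)),
                  n_total = nrow(pred_df))
  if (scheme == "leave_two_out") {
    hm <- matrix(NA_real_, n, n, dimnames = list(cohort$participant_id,
                                                 cohort$participant_id))
    hm[cbind(match(pred_df$predicted_participant, cohort$participant_id),
             match(pred_df$co_held_out_participant,
                   cohort$participant_id))] <- call_code[pred_df$call]
  } else {
    hm <- matrix(call_code[pred_df$call], n, 1,
                 dimnames = list(cohort$participant_id, "call"))
  }
  structure(list(scheme = scheme,
                 k_variables = length(selected),
                 selected_keys = selected,
                 predictions = pred_df,
                 tallies = tallies,
                 accuracy_fraction = tallies$n_correct / tallies$n_total,
                 heatmap = hm,
                 config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("cv_report [%s, k = %d]: %d/%d correct (%.1f%%), %d incorrect (%.1f%%), %d unknown (%.1f%%)\n",
              x$scheme, x$k_variables, t$n_correct, t$n_total,
              100 * t$n_correct / t$n_total,
              t$n_incorrect, 100 * t$n_incorrect / t$n_total,
              t$n_unknown, 100 * t$n_unknown / t$n_total))
  invisible(x)
}

.cv_driver <- function(cohort, selected, A, config, pairs) {
  config <- .cv_defaults(config)
  y <- code_response(cohort$outcome)
  ids <- cohort$participant_id
  nested <- config$selection_mode == "nested"
  k_nested <- length(selected)
  keys <- if (nested) NULL else selected

  Xn_global <- NULL
  if (config$normalization_mode == "global") {
    cols <- if (nested) colnames(cohort$measurements) else selected
    missing_keys <- setdiff(cols, colnames(cohort$measurements))
    if (length(missing_keys))
      stop("selected variables absent from cohort: ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    nz <- suppressWarnings(
      zscore_normalize(cohort$measurements[, cols, drop = FALSE]))
    Xn_global <- impute_missing(nz$Z, config$imputation_value)
  }

  if (is.null(A)) {
    design_all <- list(
      X = if (!is.null(Xn_global)) Xn_global else
        impute_missing(suppressWarnings(
          zscore_normalize(cohort$measurements))$Z,
          config$imputation_value),
      y = y, column_keys = if (nested) colnames(cohort$measurements)
      else selected)
    A <- choose_components(design_all)
  }

  rows <- lapply(pairs, function(pr) {
    test_idx <- pr$test
    yhat <- .fold_predict(cohort, setdiff(seq_along(ids), test_idx),
                          test_idx, keys, A, config, Xn_global, k_nested)
    data.frame(predicted_participant = ids[test_idx],
               co_held_out_participant =
                 if (length(test_idx) == 2) rev(ids[test_idx])
                 else NA_character_,
               continuous_response = unname(yhat),
               call = ifelse(is.finite(yhat),
                             classify_response(ifelse(is.finite(yhat),
                                                      yhat, 0),
                                               config$classification_halfwidth),
                             "unknown"),
               truth = cohort$outcome[test_idx],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exhaustive leave-one-out cross-validation
#'
#' For each participant, the validation PLS is refit on the other `n - 1`
#' participants and the held-out participant's continuous response is
#' predicted and classified by the trichotomous rule, yielding exactly `n`
#' predictions.
#'
#' @param cohort a [cohort_table] with at least 4 participants.
#' @param selected variable keys used by the validation PLS (under nested
#'   selection, only their number is used: the top-k set is re-ranked
#'   within each training fold).
#' @param A component count; `NULL` (default) picks the smallest count
#'   reaching 90% cumulative explained response variance, then caps it at
#'   `min(k, n_train - 1)` per fold.
#' @param config list of options: `normalization_mode` (`"global"`:
#'   z-score/impute the full matrix once before folding, the default;
#'   `"fold"`: recompute statistics within each training fold),
#'   `selection_mode` (`"pooled"` or `"nested"`), `imputation_value`,
#'   `classification_halfwidth`, and `degenerate_fold` (`"unknown"`, the
#'   default: a training fold that cannot support a fit — single class, or
#'   constant predictors — yields undecidable, i.e. unknown, calls for its
#'   held-out participants; `"error"`: such folds abort the run).
#' @return A `cv_report`: per-prediction records, tallies
#'   (`n_correct + n_incorrect + n_unknown = n_total`), accuracy fraction
#'   and the call vector.
#' @export
leave_one_out_cv <- function(cohort, selected, A = NULL, config = list()) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- length(cohort$participant_id)
  if (n < 4) stop("need at least 4 participants", call. = FALSE)
  pairs <- lapply(seq_len(n), function(i) list(test = i))
  pred <- .cv_driver(cohort, selected, A, config, pairs)
  .make_cv_report(cohort, "leave_one_out", selected, pred,
                  .cv_defaults(config))
}

#' Exhaustive leave-two-out cross-validation
#'
#' For every unordered pair of participants the model is refit on the
#' remaining `n - 2` and both held-out participants are predicted, so each
#' participant is predicted once per possible co-held-out partner:
#' `n * (n - 1)` predictions in total, `n - 1` per participant (210 and 14
#' for `n = 15`). The prediction of participant i with partner j fills
#' heatmap cell (row i, column j).
#'
#' @inheritParams leave_one_out_cv
#' @return A `cv_report` with an `n x n` heatmap of calls coded +1 /
#'   -1 / 0 and an empty diagonal.
#' @export
leave_two_out_cv <- function(cohort, selected, A = NULL, config = list()) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- length(cohort$participant_id)
  if (n < 5) stop("need at least 5 participants", call. = FALSE)
  prs <- combn(n, 2, simplify = FALSE)
  pairs <- lapply(prs, function(ij) list(test = ij))
  pred <- .cv_driver(cohort, selected, A, config, pairs)
  .make_cv_report(cohort, "leave_two_out", selected, pred,
                  .cv_defaults(config))
}

#' Accuracy sweep over top-k variable counts
#'
#' Runs the requested cross-validation schemes for each k in `k_range`,
#' selecting the top-k variables of the supplied VIP ranking, and reports
#' the best k per scheme (ties broken by the smaller k).
#'
#' @param cohort a [cohort_table].
#' @param vip a `vip_result` from the initial full-variable PLS.
#' @param k_range integer vector of variable counts (default `1:10`).
#' @param schemes subset of `c("leave_one_out", "leave_two_out")`.
#' @param A component count, `NULL` for automatic.
#' @param config see [leave_one_out_cv()].
#' @return List with `reports` (named `k<k>_<scheme>`), `accuracy` (a
#'   data.frame of k, scheme, accuracy fraction and tallies) and `best_k`
#'   (named by scheme).
#' @export
accuracy_sweep <- function(cohort, vip, k_range = 1:10,
                           schemes = c("leave_one_out", "leave_two_out"),
                           A = NULL, config = list()) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  reports <- list()
  acc <- NULL
  for (k in k_range) {
    selected <- select_top_k(vip, k)
    for (scheme in schemes) {
      rep_k <- if (scheme == "leave_one_out")
        leave_one_out_cv(cohort, selected, A, config)
      else leave_two_out_cv(cohort, selected, A, config)
      reports[[sprintf("k%d_%s", k, scheme)]] <- rep_k
      acc <- rbind(acc, data.frame(k = k, scheme = scheme,
                                   accuracy = rep_k$accuracy_fraction,
                                   n_correct = rep_k$tallies$n_correct,
                                   n_incorrect = rep_k$tallies$n_incorrect,
                                   n_unknown = rep_k$tallies$n_unknown,
                                   n_total = rep_k$tallies$n_total))
    }
  }
  best_k <- vapply(schemes, function(s) {
    a <- acc[acc$scheme == s, ]
    a$k[which.max(a$accuracy)]
  }, numeric(1))
  list(reports = reports, accuracy = acc, best_k = best_k)
}
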