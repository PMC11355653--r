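#' Cohort tables
#'
#' A cohort table holds one row per participant: a binary fitting outcome,
#' the dMRI measurement matrix over (a subset of) the 78-variable grid with
#' `NA` marking missing cells, and optional baseline characteristics.
#'
#' @param participant_id character vector of unique participant identifiers.
#' @param outcome character vector in `c("fitting", "non_fitting")`.
#' @param measurements numeric matrix, rows = participants, columns named by
#'   canonical variable keys; `NA` = missing.
#' @param baseline optional data.frame of baseline characteristics
#'   (age_years, bmi_kg_m2, parity, family_history_pop, hysterectomy,
#'   popq_stage, tvl_exam_cm, postmenopausal, avulsion), one row per
#'   participant.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(participant_id, outcome, measurements,
                         baseline = NULL) {
  participant_id <- as.character(participant_id)
  if (anyDuplicated(participant_id))
    stop("participant_id values must be unique", call. = FALSE)
  if (!all(outcome %in% c("fitting", "non_fitting")))
    stop("outcome must be 'fitting' or 'non_fitting'", call. = FALSE)
  measurements <- as.matrix(measurements)
  if (nrow(measurements) != length(participant_id))
    stop("measurements must have one row per participant", call. = FALSE)
  keys <- colnames(measurements)
  if (is.null(keys) || !all(is_variable_key(keys)))
    stop("measurement columns must be named by valid variable keys",
         call. = FALSE)
  info <- parse_variable_key(keys)
  ang <- is_angle_parameter(info$parameter)
  vals_ang <- measurements[, ang, drop = FALSE]
  vals_len <- measurements[, !ang, drop = FALSE]
  if (any(vals_len < 0, na.rm = TRUE))
    stop("lengths/areas must be non-negative", call. = FALSE)
  if (any(vals_ang <= 0 | vals_ang >= 360, na.rm = TRUE))
    stop("angles must lie in (0, 360) degrees", call. = FALSE)
  rownames(measurements) <- participant_id
  if (!is.null(baseline)) {
    baseline <- as.data.frame(baseline)
    if (nrow(baseline) != length(participant_id))
      stop("baseline must have one row per participant", call. = FALSE)
    rownames(baseline) <- participant_id
  }
  structure(list(participant_id = participant_id,
                 outcome = as.character(outcome),
                 measurements = measurements,
                 baseline = baseline),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d participants (%d fitting / %d non-fitting), %d variables\n",
              length(x$participant_id), sum(x$outcome == "fitting"),
              sum(x$outcome == "non_fitting"), ncol(x$measurements)))
  cat(sprintf("missing cells: %d of %d\n", sum(is.na(x$measurements)),
              length(x$measurements)))
  invisible(x)
}

.baseline_columns <- c("age_years", "bmi_kg_m2", "parity",
                       "family_history_pop", "hysterectomy", "popq_stage",
                       "tvl_exam_cm", "postmenopausal", "avulsion")

#' Read a cohort CSV
#'
#' Expects one row per participant with columns `participant_id`, `outcome`,
#' any of the known baseline columns, and measurement columns named
#' `parameter__manoeuvre__pessary`. Empty cells denote missing measurements
#' (never sentinel numbers).
#'
#' @param path path to the CSV file.
#' @param strict if `TRUE` (default), unknown columns or invalid variable
#'   keys are an error; if `FALSE` they are dropped with a message.
#' @return A [cohort_table].
#' @export
read_cohort <- function(path, strict = TRUE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "outcome") %in% names(df)))
    stop("cohort CSV needs 'participant_id' and 'outcome' columns",
         call. = FALSE)
  other <- setdiff(names(df), c("participant_id", "outcome",
                                .baseline_columns))
  valid <- is_variable_key(other)
  if (any(!valid)) {
    bad <- other[!valid]
    if (strict)
      stop("unknown or invalid columns: ", paste(bad, collapse = ", "),
           call. = FALSE)
    message("dropping ", length(bad), " unrecognised column(s): ",
            paste(bad, collapse = ", "))
    other <- other[valid]
  }
  meas <- as.matrix(df[, other, drop = FALSE])
  storage.mode(meas) <- "double"
  base_cols <- intersect(.baseline_columns, names(df))
  baseline <- if (length(base_cols)) df[, base_cols, drop = FALSE] else NULL
  cohort_table(df$participant_id, df$outcome, meas, baseline)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing measurements are written as empty
#' cells.
#'
#' @param cohort a [cohort_table].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(participant_id = cohort$participant_id,
                   outcome = cohort$outcome,
                   stringsAsFactors = FALSE)
  if (!is.null(cohort$baseline))
    df <- cbind(df, cohort$baseline)
  df <- cbind(df, as.data.frame(cohort$measurements))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an analysis report to disk
#'
#' VIP results and cross-validation reports are written as JSON with every
#' field preserved; a leave-two-out report's heatmap is additionally written
#' as a CSV matrix (rows = predicted participant, columns = co-held-out
#' participant, empty diagonal) next to the JSON file, with extension
#' `.heatmap.csv`.
#'
#' @param report a `vip_result` or `cv_report` object.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, c("vip_result", "cv_report")))
  obj <- unclass(report)
  obj$.class <- class(report)[1]
  if (inherits(report, "vip_result"))
    obj$scores <- as.list(obj$scores)  # keep key names in the JSON object
  if (inherits(report, "cv_report")) {
    hm <- report$heatmap
    obj$heatmap <- list(participants = rownames(hm),
                        values = apply(hm, 1, function(r) unname(r),
                                       simplify = FALSE))
    csv_path <- sub("\\.json$", "", path)
    csv_path <- paste0(csv_path, ".heatmap.csv")
    write.csv(as.data.frame(hm), csv_path, row.names = TRUE, na = "")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path JSON path.
#' @return The reconstructed `vip_result` or `cv_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "cv_report")) {
    ids <- obj$heatmap$participants
    hm <- do.call(rbind, obj$heatmap$values)
    rownames(hm) <- ids
    colnames(hm) <- ids
    obj$heatmap <- hm
    obj$predictions <- as.data.frame(obj$predictions)
    obj$selected_keys <- as.character(obj$selected_keys)
  } else {
    obj$scores <- unlist(obj$scores)
    obj$ranking <- as.character(obj$ranking)
  }
  structure(obj, class = cls)
}
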