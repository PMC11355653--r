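#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one object so a run can be
#' reproduced from its echoed config alone.
#'
#' @param components integer component count for the PLS fits, or `"auto"`
#'   (default) to use the smallest count reaching 90% cumulative explained
#'   response variance.
#' @param k_range variable counts swept in the validation stage (default
#'   `1:10`).
#' @param schemes cross-validation schemes to run.
#' @param selection_mode `"pooled"` (default): VIP selection once on the
#'   full cohort, then cross-validate the selected variables; `"nested"`:
#'   re-rank within every training fold, avoiding selection bias at the
#'   price of a different variable set per fold.
#' @param normalization_mode `"global"` (default): z-score and impute the
#'   full matrix once before folding; `"fold"`: recompute normalization
#'   statistics within each training fold.
#' @param imputation_value constant replacing missing cells after
#'   normalization (default `1e-6`).
#' @param classification_halfwidth half-width of the unknown zone of the
#'   trichotomous rule (default 0.1).
#' @param seed integer seed for any synthetic-data generation; the
#'   analysis itself is deterministic.
#' @param rounding_decimals decimals used when percentages are formatted
#'   in printed reports (default 1).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(components = "auto",
                            k_range = 1:10,
                            schemes = c("leave_one_out", "leave_two_out"),
                            selection_mode = c("pooled", "nested"),
                            normalization_mode = c("global", "fold"),
                            imputation_value = 1e-6,
                            classification_halfwidth = 0.1,
                            seed = 1,
                            rounding_decimals = 1) {
  selection_mode <- match.arg(selection_mode)
  normalization_mode <- match.arg(normalization_mode)
  schemes <- match.arg(schemes, several.ok = TRUE)
  stopifnot(classification_halfwidth >= 0, all(k_range >= 1))
  structure(list(components = components, k_range = k_range,
                 schemes = schemes, selection_mode = selection_mode,
                 normalization_mode = normalization_mode,
                 imputation_value = imputation_value,
                 classification_halfwidth = classification_halfwidth,
                 seed = seed, rounding_decimals = rounding_decimals),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end: preprocessing (z-score, imputation, +1/-1
#' coding), an initial PLS over all available variables with its
#' explained-variance profile and VIP scores, a top-k accuracy sweep over
#' both cross-validation schemes, the best-k reports, and the baseline
#' characteristics table (when baseline data are present). Identical input
#' and config give identical output.
#'
#' @param cohort a [cohort_table], or a path to a cohort CSV.
#' @param config a [pipeline_config()].
#' @return List with `vip` (`vip_result`), `explained_variance`
#'   (cumulative X/Y fractions of the initial fit), `sweep` (see
#'   [accuracy_sweep()]), `best_reports` (best-k `cv_report` per scheme),
#'   `baseline` (data.frame or `NULL`) and the echoed `config`.
#' @export
run_full_pipeline <- function(cohort, config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(config, "pipeline_config"))
  design <- build_design_matrix(cohort,
                                imputation_value = config$imputation_value)
  A <- if (identical(config$components, "auto")) choose_components(design)
  else config$components
  initial <- fit_pls(design, A)
  vip <- vip_scores(initial)
  cv_cfg <- list(normalization_mode = config$normalization_mode,
                 selection_mode = config$selection_mode,
                 imputation_value = config$imputation_value,
                 classification_halfwidth =
                   config$classification_halfwidth)
  A_cv <- if (identical(config$components, "auto")) NULL
  else config$components
  sweep_res <- accuracy_sweep(cohort, vip, config$k_range, config$schemes,
                              A_cv, cv_cfg)
  best_reports <- lapply(config$schemes, function(s) {
    sweep_res$reports[[sprintf("k%d_%s", sweep_res$best_k[[s]], s)]]
  })
  names(best_reports) <- config$schemes
  baseline <- if (!is.null(cohort$baseline)) baseline_table(cohort)
  else NULL
  list(vip = vip,
       explained_variance = cumulative_explained_variance(initial),
       initial_components = A,
       sweep = sweep_res,
       best_reports = best_reports,
       baseline = baseline,
       config = config)
}

#' Render a leave-two-out heatmap as text
#'
#' Produces the character-grid analogue of the prediction heatmap: rows are
#' the predicted participant, columns the co-held-out participant; `+`
#' marks a correct call, `x` an incorrect one, `?` unknown, and `.` the
#' empty diagonal. The underlying call codes (+1 fitting, -1 non-fitting,
#' 0 unknown) are returned alongside.
#'
#' @param report a leave-two-out `cv_report`.
#' @return Invisibly, a list with `text` (character vector, one row per
#'   participant) and `codes` (the n x n call matrix); the grid is also
#'   printed.
#' @export
render_heatmap_text <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  if (report$scheme != "leave_two_out")
    stop("heatmap rendering needs a leave-two-out report", call. = FALSE)
  hm <- report$heatmap
  ids <- rownames(hm)
  first <- !duplicated(report$predictions$predicted_participant)
  truth <- setNames(report$predictions$truth[first],
                    report$predictions$predicted_participant[first])[ids]
  truth_code <- ifelse(truth == "fitting", 1, -1)
  ch <- matrix(".", nrow(hm), ncol(hm))
  off <- !is.na(hm)
  ch[off & hm == 0] <- "?"
  ch[off & hm != 0 & hm == truth_code[row(hm)]] <- "+"
  ch[off & hm != 0 & hm != truth_code[row(hm)]] <- "x"
  lines <- vapply(seq_len(nrow(ch)), function(i)
    sprintf("%-5s %s", ids[i], paste(ch[i, ], collapse = " ")),
    character(1))
  cat(lines, sep = "\n")
  invisible(list(text = lines, codes = hm))
}
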