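#' Effect profiles for synthetic cohorts
#'
#' An effect profile describes the statistical structure a synthetic cohort
#' should carry: which variables separate the fitting from the non-fitting
#' group and by how much (in SD units), the per-parameter base means and
#' SDs on the measurement scale, how strongly a parameter's repeated
#' measurements (across manoeuvres and pessary conditions) correlate within
#' a participant, and the rate of missing cells.
#'
#' @param informative_keys character vector of variable keys that carry a
#'   group difference.
#' @param standardized_effect difference of group means in SD units on each
#'   informative key; the sign is the direction of the fitting group
#'   relative to the non-fitting group.
#' @param base_means,base_sds named numeric vectors over the eight
#'   anatomical parameters, on the measurement scale (cm, cm^2, degrees).
#' @param within_participant_correlation exchangeable correlation in
#'   `[0, 1)` between conditions of the same parameter within a
#'   participant.
#' @param missing_rate probability in `[0, 0.5)` that any measurement cell
#'   is missing (missing completely at random).
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(informative_keys = character(0),
                           standardized_effect = 0,
                           base_means = default_base_means(),
                           base_sds = default_base_sds(),
                           within_participant_correlation = 0.5,
                           missing_rate = 0) {
  stopifnot(all(is_variable_key(informative_keys)),
            is.finite(standardized_effect),
            within_participant_correlation >= 0,
            within_participant_correlation < 1,
            missing_rate >= 0, missing_rate < 0.5)
  if (!all(.parameters %in% names(base_means)) ||
      !all(.parameters %in% names(base_sds)))
    stop("base_means and base_sds must cover all eight parameters",
         call. = FALSE)
  if (any(base_sds <= 0)) stop("base_sds must be positive", call. = FALSE)
  structure(list(informative_keys = informative_keys,
                 standardized_effect = standardized_effect,
                 base_means = base_means, base_sds = base_sds,
                 within_participant_correlation =
                   within_participant_correlation,
                 missing_rate = missing_rate),
            class = "effect_profile")
}

#' Default anatomical base means
#'
#' Typical mid-sagittal / coronal pelvic-floor values for a POP cohort:
#' TVL 7.3 cm at rest on dMRI, cervix around 2.8 cm, the pubococcygeal
#' reference line around 10 cm, sacrococcygeal angle near 110 degrees, and
#' a levator hiatal area near 17 cm^2. Values are documented guesses on the
#' measurement scale; the analysis z-scores everything, so only the ratios
#' effect/SD matter downstream.
#'
#' @return Named numeric vector over the eight parameters.
#' @export
default_base_means <- function() {
  c(PCL_length = 10.0, TVL = 7.3, CL = 2.8,
    pubococcygeal_angle = 25, sacrococcygeal_angle = 110,
    sacrococcygeal_straight_length = 11.0,
    pubococcygeal_sacral_angle = 100, LHA = 17)
}

#' Default anatomical base SDs
#'
#' @return Named numeric vector over the eight parameters (cm, cm^2,
#'   degrees).
#' @export
default_base_sds <- function() {
  c(PCL_length = 1.0, TVL = 1.2, CL = 0.8,
    pubococcygeal_angle = 8, sacrococcygeal_angle = 12,
    sacrococcygeal_straight_length = 1.2,
    pubococcygeal_sacral_angle = 12, LHA = 4)
}

#' Default informative-variable profile
#'
#' The six variables that the clinical analysis ranked highest by VIP form
#' the default informative set: total vaginal length during Valsalva and at
#' rest without a pessary, cervical length at rest with ring-with-support,
#' sacrococcygeal angle during Valsalva with ring-with-support, total
#' vaginal length at rest with a ring, and the pubococcygeal angle at rest
#' with a ring. Default standardized effect is 1.5 SD, a strong but
#' clinically plausible separation for an exploratory imaging biomarker.
#'
#' @param standardized_effect effect size in SD units (default 1.5).
#' @param missing_rate default 0.02, a low MCAR rate mimicking occasional
#'   unreadable images.
#' @param ... further arguments passed to [effect_profile()].
#' @return An `effect_profile` with the six-variable informative set.
#' @export
default_effect_profile <- function(standardized_effect = 1.5,
                                   missing_rate = 0.02, ...) {
  keys <- c(variable_key("TVL", "valsalva", "none"),
            variable_key("TVL", "rest", "none"),
            variable_key("CL", "rest", "ring_support"),
            variable_key("sacrococcygeal_angle", "valsalva", "ring_support"),
            variable_key("TVL", "rest", "ring"),
            variable_key("pubococcygeal_angle", "rest", "ring"))
  effect_profile(informative_keys = keys,
                 standardized_effect = standardized_effect,
                 missing_rate = missing_rate, ...)
}

#' Generate a synthetic cohort
#'
#' Draws a two-group cohort over the full 78-variable grid. Within each
#' participant, the conditions of one anatomical parameter share an
#' exchangeable correlation `rho` (constructed as
#' `sqrt(rho) * shared + sqrt(1 - rho) * independent`, which is positive
#' definite for any `rho` in `[0, 1)`); distinct parameters are
#' independent. Informative keys get a mean shift of
#' `standardized_effect * SD` in the fitting group. Cells are then masked
#' missing independently at `missing_rate`. Baseline characteristics are
#' drawn to resemble an elderly POP cohort (age ~ N(69.7, 8.5), group BMI
#' means 27.8 / 23.9, POP-Q stage-3 probability higher in the non-fitting
#' group) and are consumed only by the baseline statistics, never by the
#' PLS pipeline.
#'
#' @param n_fitting,n_nonfitting group sizes, each at least 2 (defaults
#'   9 and 6, the clinical group sizes).
#' @param profile an [effect_profile()]; default [default_effect_profile()].
#' @param seed integer seed; the cohort is a deterministic function of
#'   (sizes, profile, seed).
#' @return A [cohort_table] with `n_fitting + n_nonfitting` participants.
#' @export
#' @examples
#' coh <- generate_cohort(9, 6, seed = 1)
#' table(coh$outcome)
generate_cohort <- function(n_fitting = 9, n_nonfitting = 6,
                            profile = default_effect_profile(),
                            seed = 1) {
  stopifnot(inherits(profile, "effect_profile"),
            n_fitting >= 2, n_nonfitting >= 2)
  n <- n_fitting + n_nonfitting
  keys <- enumerate_variable_grid()
  info <- parse_variable_key(keys)
  rho <- profile$within_participant_correlation

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  outcome <- c(rep("fitting", n_fitting), rep("non_fitting", n_nonfitting))
  z <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  for (p in unique(info$parameter)) {
    cols <- which(info$parameter == p)
    shared <- rnorm(n)
    eps <- matrix(rnorm(n * length(cols)), n, length(cols))
    z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * eps
  }
  # mean shift on informative keys, fitting group only
  shift <- ifelse(keys %in% profile$informative_keys,
                  profile$standardized_effect, 0)
  z[outcome == "fitting", ] <- sweep(
    z[outcome == "fitting", , drop = FALSE], 2, shift, "+")

  mu <- profile$base_means[info$parameter]
  sdv <- profile$base_sds[info$parameter]
  meas <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")
  # keep values physically admissible after noise
  ang <- is_angle_parameter(info$parameter)
  meas[, !ang][meas[, !ang] < 0] <- 0
  meas[, ang][meas[, ang] <= 0] <- 1e-3
  meas[, ang][meas[, ang] >= 360] <- 359.999

  if (profile$missing_rate > 0) {
    mask <- matrix(runif(n * length(keys)) < profile$missing_rate,
                   n, length(keys))
    meas[mask] <- NA_real_
  }

  baseline <- data.frame(
    age_years = rnorm(n, 69.7, 8.5),
    bmi_kg_m2 = rnorm(n, ifelse(outcome == "fitting", 27.8, 23.9),
                      ifelse(outcome == "fitting", 3.8, 3.2)),
    parity = sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25)),
    family_history_pop = runif(n) <
      ifelse(outcome == "fitting", 0.22, 0.67),
    hysterectomy = runif(n) < ifelse(outcome == "fitting", 0.11, 0.17),
    popq_stage = ifelse(runif(n) <
                          ifelse(outcome == "fitting", 0.33, 0.83), 3L, 2L),
    tvl_exam_cm = rnorm(n, ifelse(outcome == "fitting", 8.6, 8.2),
                        ifelse(outcome == "fitting", 1.5, 0.8)),
    postmenopausal = runif(n) < 0.93,
    avulsion = sample(c("none", "minor", "major"), n, replace = TRUE,
                      prob = c(0.47, 0.13, 0.40)),
    stringsAsFactors = FALSE)

  cohort_table(sprintf("P%02d", seq_len(n)), outcome, meas, baseline)
}

# save/restore the global RNG state so cohort generation does not disturb
# a caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
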