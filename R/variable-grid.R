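#' The dMRI measurement grid
#'
#' Each measurement is identified by an anatomical parameter, the manoeuvre
#' during which it was measured (rest, pelvic-floor contraction, Valsalva)
#' and the pessary condition (no pessary, ring, ring with support, Falk).
#' Six parameters are measured under all 3 x 4 = 12 conditions;
#' sacrococcygeal straight length and the pubococcygeal-sacral angle are
#' measured at the three manoeuvres only without a pessary, giving
#' 6 x 12 + 2 x 3 = 78 variables in total.
#'
#' @name variable_grid
NULL

# enum orders are canonical: they define ranking tie-breaks and column order
.parameters <- c("PCL_length", "TVL", "CL", "pubococcygeal_angle",
                 "sacrococcygeal_angle", "sacrococcygeal_straight_length",
                 "pubococcygeal_sacral_angle", "LHA")
.manoeuvres <- c("rest", "contraction", "valsalva")
.pessaries  <- c("none", "ring", "ring_support", "falk")
# measured only without a pessary
.no_pessary_parameters <- c("sacrococcygeal_straight_length",
                            "pubococcygeal_sacral_angle")
# angles live in degrees, everything else in cm (LHA in cm^2)
.angle_parameters <- c("pubococcygeal_angle", "sacrococcygeal_angle",
                       "pubococcygeal_sacral_angle")

#' Create a variable key
#'
#' @param parameter anatomical parameter, one of
#'   `r paste0('"', .parameters, '"', collapse = ", ")`.
#' @param manoeuvre one of `"rest"`, `"contraction"`, `"valsalva"`.
#' @param pessary one of `"none"`, `"ring"`, `"ring_support"`, `"falk"`.
#' @return A character scalar `parameter__manoeuvre__pessary`, the canonical
#'   column name for that measurement.
#' @export
#' @examples
#' variable_key("TVL", "valsalva", "none")
variable_key <- function(parameter, manoeuvre, pessary) {
  parameter <- match.arg(parameter, .parameters)
  manoeuvre <- match.arg(manoeuvre, .manoeuvres)
  pessary <- match.arg(pessary, .pessaries)
  if (parameter %in% .no_pessary_parameters && pessary != "none")
    stop(sprintf("parameter '%s' is measured only without a pessary",
                 parameter), call. = FALSE)
  paste(parameter, manoeuvre, pessary, sep = "__")
}

#' Split a variable key into its components
#'
#' @param key character vector of `parameter__manoeuvre__pessary` keys.
#' @return A data.frame with columns `key`, `parameter`, `manoeuvre`,
#'   `pessary`.
#' @export
parse_variable_key <- function(key) {
  parts <- strsplit(key, "__", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed variable key(s): ",
         paste(key[bad], collapse = ", "), call. = FALSE)
  m <- do.call(rbind, parts)
  out <- data.frame(key = key, parameter = m[, 1], manoeuvre = m[, 2],
                    pessary = m[, 3], stringsAsFactors = FALSE)
  ok <- out$parameter %in% .parameters &
    out$manoeuvre %in% .manoeuvres &
    out$pessary %in% .pessaries &
    !(out$parameter %in% .no_pessary_parameters & out$pessary != "none")
  if (any(!ok))
    stop("invalid variable key(s): ",
         paste(key[!ok], collapse = ", "), call. = FALSE)
  out
}

#' Test whether strings are valid grid keys
#'
#' @param key character vector.
#' @return Logical vector, `TRUE` where the key belongs to the 78-variable
#'   grid.
#' @export
is_variable_key <- function(key) key %in% enumerate_variable_grid()

#' Enumerate the full 78-variable measurement grid
#'
#' Returns every valid (parameter, manoeuvre, pessary) combination exactly
#' once, in canonical order: parameter first, then manoeuvre, then pessary,
#' each in enum order. This order is used for CSV columns and for breaking
#' ties in VIP rankings.
#'
#' @return Character vector of length 78 of canonical keys.
#' @export
#' @examples
#' length(enumerate_variable_grid())  # 78
enumerate_variable_grid <- function() {
  keys <- character(0)
  for (p in .parameters) {
    pess <- if (p %in% .no_pessary_parameters) "none" else .pessaries
    for (m in .manoeuvres)
      for (d in pess)
        keys <- c(keys, paste(p, m, d, sep = "__"))
  }
  keys
}

#' Is a parameter an angle?
#'
#' Angles are recorded in degrees and must lie in (0, 360); lengths and the
#' levator hiatal area are in cm / cm^2 and must be non-negative.
#'
#' @param parameter character vector of parameter names.
#' @return Logical vector.
#' @export
is_angle_parameter <- function(parameter) parameter %in% .angle_parameters
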