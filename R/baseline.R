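#' Group summary
#'
#' @param n group size.
#' @param mean,sd group mean and SD in the variable's units.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 1, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Summarise raw values as a group summary
#'
#' @param x numeric vector.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x) {
  x <- x[!is.na(x)]
  group_summary(length(x), mean(x), if (length(x) > 1) sd(x) else 0)
}

#' Pooled mean and SD of several groups
#'
#' Size-weighted mean; the pooled SD is reconstructed from the total sum of
#' squares (within-group plus between-group), i.e. the SD one would obtain
#' from the concatenated raw data.
#'
#' @param groups list of [group_summary()] objects (at least 2).
#' @return A [group_summary()] for the combined population.
#' @export
#' @examples
#' pooled_mean_sd(list(group_summary(9, 8.6, 1.5),
#'                     group_summary(6, 8.2, 0.8)))
pooled_mean_sd <- function(groups) {
  stopifnot(length(groups) >= 2,
            all(vapply(groups, inherits, logical(1), "group_summary")))
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  N <- sum(n)
  if (N == 0) stop("zero total n", call. = FALSE)
  gm <- sum(n * m) / N
  # total SS = within (n_i - 1) s_i^2 + between n_i (m_i - gm)^2
  ss <- sum((n - 1) * s^2) + sum(n * (m - gm)^2)
  group_summary(N, gm, if (N > 1) sqrt(ss / (N - 1)) else 0)
}

#' Independent-samples t-test
#'
#' Two-sided test of equal group means, from raw values or from
#' (n, mean, sd) summaries. Default is the pooled-variance test; Welch's
#' unequal-variance form is available via `var_equal = FALSE`. Because
#' published summaries are rounded, a p-value recomputed from them bounds
#' rather than pins the raw-data p-value.
#'
#' @param g1,g2 numeric vectors of raw values, or [group_summary()]
#'   objects.
#' @param var_equal pooled-variance test if `TRUE` (default).
#' @return List with `t`, `df`, `p`.
#' @export
t_test_independent <- function(g1, g2, var_equal = TRUE) {
  if (is.numeric(g1)) g1 <- summarize_group(g1)
  if (is.numeric(g2)) g2 <- summarize_group(g2)
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"),
            g1$n >= 2, g2$n >= 2)
  if (g1$sd == 0 && g2$sd == 0)
    stop("both groups are degenerate (zero SD)", call. = FALSE)
  if (var_equal) {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  t <- (g1$mean - g2$mean) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. For combined n of at most
#' `exact_limit` the two-sided p-value is exact: every assignment of the
#' pooled midranks to the two groups is enumerated and
#' `P(|U - n1*n2/2| >= |U_obs - n1*n2/2|)` computed under the permutation
#' null, which handles ties correctly. Above the limit a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param g1,g2 numeric vectors (ordinal data allowed).
#' @param exact_limit largest combined n for full enumeration (default 20).
#' @return List with `U` (the statistic of group 1), `p` and `method`.
#' @export
mann_whitney_u <- function(g1, g2, exact_limit = 20) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (!length(g1) || !length(g2)) stop("empty group", call. = FALSE)
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  r <- rank(c(g1, g2))  # midranks for ties
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    splits <- combn(n, n1)
    R1 <- colSums(matrix(r[splits], nrow = n1))
    U_all <- R1 - n1 * (n1 + 1) / 2
    eps <- sqrt(.Machine$double.eps)
    p <- mean(abs(U_all - mu) >= abs(U_obs - mu) - eps)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(U_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation with tie correction"
  }
  list(U = U_obs, p = p, method = method)
}

#' Exact contingency-table test
#'
#' Exact conditional test of independence for an r x c table of counts
#' with fixed margins. The two-sided p-value is the sum of probabilities of
#' all margin-compatible tables whose point probability does not exceed
#' that of the observed table (the point-probability rule). 2 x 2 tables
#' use the hypergeometric distribution directly; larger tables are fully
#' enumerated with multivariate-hypergeometric probabilities, which is why
#' the total count is capped.
#'
#' @param table matrix of non-negative integer counts.
#' @param max_total enumeration bound on the total count (default 30).
#' @return List with `p`.
#' @export
#' @examples
#' exact_contingency_test(matrix(c(3, 5, 6, 1), 2, 2))  # p = 0.119
exact_contingency_test <- function(table, max_total = 30) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  N <- sum(tab)
  if (N > max_total)
    stop("table total exceeds the enumeration bound", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0) || nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p = 1))  # degenerate margins: nothing to test
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    x <- tab[1, 1]
    support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    d <- dhyper(support, rs[1], rs[2], cs[1])
    p_obs <- dhyper(x, rs[1], rs[2], cs[1])
    p <- sum(d[d <= p_obs * (1 + 1e-7)])
    return(list(p = min(1, p)))
  }
  list(p = .exact_rc_p(tab, rs, cs, N))
}

# generic r x c path: enumerate every margin-fixed table and sum the
# probabilities of those no more probable than the observed one
.exact_rc_p <- function(tab, rs = rowSums(tab), cs = colSums(tab),
                        N = sum(tab)) {
  log_p_obs <- .log_table_prob(tab, rs, cs, N)
  acc <- new.env()
  acc$p <- 0
  .enumerate_tables(matrix(0L, nrow(tab), ncol(tab)), 1L, 1L, rs, cs, N,
                    log_p_obs + log1p(1e-7), acc)
  min(1, acc$p)
}

# log probability of a margin-fixed table under the multivariate
# hypergeometric null: prod(r_i!) prod(c_j!) / (N! prod(n_ij!))
.log_table_prob <- function(tab, rs, cs, N) {
  sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
    sum(lfactorial(tab))
}

# recursive enumeration of all tables with the observed margins; cells are
# filled row-major, the last cell of each row/column forced by the margin
.enumerate_tables <- function(tab, i, j, rs, cs, N, log_cut, acc) {
  nr <- length(rs); nc <- length(cs)
  row_left <- rs[i] - sum(tab[i, seq_len(j - 1)])
  col_left <- cs[j] - sum(tab[seq_len(i - 1), j])
  if (i == nr) {  # last row forced by column margins
    tab[i, j:nc] <- cs[j:nc] - colSums(tab[seq_len(i - 1), j:nc,
                                           drop = FALSE])
    if (any(tab[i, ] < 0)) return(invisible())
    lp <- .log_table_prob(tab, rs, cs, N)
    if (lp <= log_cut) acc$p <- acc$p + exp(lp)
    return(invisible())
  }
  if (j == nc) {  # last column of a row forced by the row margin
    if (row_left < 0 || row_left > col_left) return(invisible())
    tab[i, j] <- row_left
    .enumerate_tables(tab, i + 1L, 1L, rs, cs, N, log_cut, acc)
    return(invisible())
  }
  for (v in 0:min(row_left, col_left)) {
    tab[i, j] <- v
    .enumerate_tables(tab, i, j + 1L, rs, cs, N, log_cut, acc)
  }
  invisible()
}

#' Baseline characteristics table
#'
#' Compares the fitting and non-fitting groups on the cohort's baseline
#' characteristics, choosing the test by variable type: pooled-variance
#' t-test for continuous variables (age, BMI, examination TVL), exact
#' Mann-Whitney for ordinal (parity), and the exact contingency test for
#' nominal ones (family history, hysterectomy, POP-Q stage 3,
#' postmenopausal state, avulsion as a 2 x 3 table).
#'
#' @param cohort a [cohort_table] with baseline characteristics.
#' @return A data.frame with one row per characteristic: pooled, fitting
#'   and non-fitting summaries (formatted), the test used, and the
#'   p-value.
#' @export
baseline_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  b <- cohort$baseline
  if (is.null(b)) stop("cohort has no baseline characteristics",
                       call. = FALSE)
  fit <- cohort$outcome == "fitting"
  rows <- list()

  cont <- c(age_years = "Age (years)", bmi_kg_m2 = "BMI (kg/m2)",
            tvl_exam_cm = "TVL at examination (cm)")
  for (v in names(cont)) {
    if (!v %in% names(b)) next
    g1 <- summarize_group(b[[v]][fit]); g2 <- summarize_group(b[[v]][!fit])
    pool <- pooled_mean_sd(list(g1, g2))
    tt <- t_test_independent(g1, g2)
    rows[[v]] <- data.frame(
      characteristic = cont[[v]],
      total = sprintf("%.1f ± %.1f", pool$mean, pool$sd),
      fitting = sprintf("%.1f ± %.1f", g1$mean, g1$sd),
      non_fitting = sprintf("%.1f ± %.1f", g2$mean, g2$sd),
      test = "t-test", p = tt$p, stringsAsFactors = FALSE)
  }

  if ("parity" %in% names(b)) {
    mw <- mann_whitney_u(b$parity[fit], b$parity[!fit])
    med_rng <- function(x) sprintf("%g (%g-%g)", stats::median(x),
                                   min(x), max(x))
    rows$parity <- data.frame(
      characteristic = "Parity", total = med_rng(b$parity),
      fitting = med_rng(b$parity[fit]),
      non_fitting = med_rng(b$parity[!fit]),
      test = "Mann-Whitney U", p = mw$p, stringsAsFactors = FALSE)
  }

  nom <- c(family_history_pop = "Family history of POP",
           hysterectomy = "Hysterectomy",
           postmenopausal = "Postmenopausal")
  for (v in names(nom)) {
    if (!v %in% names(b)) next
    tab <- rbind(c(sum(b[[v]][fit]), sum(!b[[v]][fit])),
                 c(sum(b[[v]][!fit]), sum(!b[[v]][!fit])))
    pct <- function(x) sprintf("%.1f%%", 100 * mean(x))
    rows[[v]] <- data.frame(
      characteristic = nom[[v]], total = pct(b[[v]]),
      fitting = pct(b[[v]][fit]), non_fitting = pct(b[[v]][!fit]),
      test = "exact test", p = exact_contingency_test(tab)$p,
      stringsAsFactors = FALSE)
  }

  if ("popq_stage" %in% names(b)) {
    s3 <- b$popq_stage >= 3
    tab <- rbind(c(sum(s3[fit]), sum(!s3[fit])),
                 c(sum(s3[!fit]), sum(!s3[!fit])))
    rows$popq <- data.frame(
      characteristic = "POP-Q stage 3+",
      total = sprintf("%.1f%%", 100 * mean(s3)),
      fitting = sprintf("%.1f%%", 100 * mean(s3[fit])),
      non_fitting = sprintf("%.1f%%", 100 * mean(s3[!fit])),
      test = "exact test", p = exact_contingency_test(tab)$p,
      stringsAsFactors = FALSE)
  }

  if ("avulsion" %in% names(b)) {
    lv <- c("none", "minor", "major")
    tab <- rbind(table(factor(b$avulsion[fit], levels = lv)),
                 table(factor(b$avulsion[!fit], levels = lv)))
    keep <- colSums(tab) > 0
    rows$avulsion <- data.frame(
      characteristic = "Levator ani avulsion (none/minor/major)",
      total = paste(sprintf("%.1f%%", 100 * colMeans(
        rbind(table(factor(b$avulsion, levels = lv))) /
          length(b$avulsion))), collapse = " / "),
      fitting = paste(sprintf("%.1f%%",
                              100 * tab[1, ] / sum(fit)), collapse = " / "),
      non_fitting = paste(sprintf("%.1f%%",
                                  100 * tab[2, ] / sum(!fit)),
                          collapse = " / "),
      test = "exact test",
      p = exact_contingency_test(tab[, keep, drop = FALSE])$p,
      stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
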