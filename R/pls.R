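#' Fit a PLS1 regression
#'
#' NIPALS partial least squares for a single response. Predictors and
#' response are centred internally; for a univariate response the weight of
#' each component is the (normalized) covariance direction
#' `w_a = X_a' y_a / ||X_a' y_a||`, so the fit is deterministic — no random
#' initialisation is involved. Components deflate both `X` and `y`;
#' per-component explained-variance fractions are computed from the
#' deflation residuals. With `A = min(n - 1, p)` on complete full-rank data
#' the regression vector coincides with ordinary least squares.
#'
#' @param design a `design_matrix` from [build_design_matrix()], or any
#'   list with numeric matrix `X`, response `y` and `column_keys`.
#' @param A number of components, `1 <= A <= min(n - 1, p)`.
#' @return An object of class `pls_fit`: weights `W` (p x A, unit-norm
#'   columns), X-loadings `P`, scores `T` (mutually orthogonal columns),
#'   y-loadings `q`, regression vector `b_coef` and `intercept` on the
#'   normalized scale, per-component explained-variance fractions
#'   `explvar_X` and `explvar_Y`, and `column_keys`.
#' @export
fit_pls <- function(design, A) {
  X <- as.matrix(design$X)
  y <- as.numeric(design$y)
  n <- nrow(X); p <- ncol(X)
  if (length(unique(y)) < 2)
    stop("response is degenerate (single class)", call. = FALSE)
  if (A < 1 || A > min(n - 1, p))
    stop(sprintf("A must lie in [1, %d]", min(n - 1, p)), call. = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  Xa <- sweep(X, 2, xm); ya <- y - ym
  ssx <- sum(Xa^2); ssy <- sum(ya^2)

  W <- P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- explvar_X <- explvar_Y <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * p) {
      # residual X carries no covariance with y; truncate
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      explvar_X <- explvar_X[seq_len(a - 1)]
      explvar_Y <- explvar_Y[seq_len(a - 1)]
      A <- a - 1
      break
    }
    w <- w / nw
    t <- drop(Xa %*% w); tt <- sum(t^2)
    pl <- drop(crossprod(Xa, t)) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pl)
    ya <- ya - t * qa
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
    explvar_X[a] <- tt * sum(pl^2) / ssx
    explvar_Y[a] <- qa^2 * tt / ssy
  }
  if (A == 0) stop("no usable component: X is uncorrelated with y",
                   call. = FALSE)
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(A = A, W = W, P = P, T = Tm, q = q,
                 b_coef = b, intercept = ym - sum(xm * b),
                 explvar_X = explvar_X, explvar_Y = explvar_Y,
                 column_keys = design$column_keys),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("pls_fit: %d component(s), %d variables\n",
              x$A, length(x$column_keys)))
  ev <- cumulative_explained_variance(x)
  cat("cumulative explained variance (X):",
      paste(sprintf("%.3f", ev$X), collapse = " "), "\n")
  cat("cumulative explained variance (y):",
      paste(sprintf("%.3f", ev$Y), collapse = " "), "\n")
  invisible(x)
}

#' Cumulative explained variance of a PLS fit
#'
#' @param model a `pls_fit`.
#' @return List with numeric vectors `X` and `Y`: cumulative fractions of
#'   predictor and response sum of squares explained by components
#'   `1..A`; both non-decreasing in `[0, 1]`.
#' @export
cumulative_explained_variance <- function(model) {
  stopifnot(inherits(model, "pls_fit"))
  list(X = cumsum(model$explvar_X), Y = cumsum(model$explvar_Y))
}

#' Predict from a PLS fit
#'
#' @param object a `pls_fit`.
#' @param Xnew matrix on the model's normalized scale, columns ordered (or
#'   named) as the model's `column_keys`.
#' @param ... unused.
#' @return Numeric vector of continuous (unbounded) predicted responses
#'   `Xnew %*% b_coef + intercept`.
#' @export
predict.pls_fit <- function(object, Xnew, ...) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(object$column_keys))
    stop("Xnew has wrong number of columns", call. = FALSE)
  if (!is.null(colnames(Xnew))) {
    if (!setequal(colnames(Xnew), object$column_keys))
      stop("Xnew columns do not match the model's variables", call. = FALSE)
    Xnew <- Xnew[, object$column_keys, drop = FALSE]
  }
  drop(Xnew %*% object$b_coef) + object$intercept
}

#' VIP scores of a PLS fit
#'
#' Variable importance in projection (Wold's formula): with unit-norm
#' weights,
#' `VIP_j = sqrt( p * sum_a SSY_a * w_ja^2 / sum_a SSY_a )`, where
#' `SSY_a = q_a^2 * t_a't_a` is the response sum of squares captured by
#' component `a`. The mean squared VIP is 1 by construction, so scores
#' above 1 flag variables that contribute more than average; thresholds at
#' 1, 1.5 and 2 are tallied. Ties in the ranking are broken by canonical
#' grid order.
#'
#' @param model a `pls_fit`.
#' @return An object of class `vip_result`: named `scores`, the component
#'   count `model_A`, `ranking` (keys in descending score), and counts
#'   `n_above_1`, `n_above_1_5`, `n_above_2`.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_fit"))
  ssy <- model$q^2 * colSums(model$T^2)
  p <- nrow(model$W)
  vip <- sqrt(p * drop(model$W^2 %*% ssy) / sum(ssy))
  names(vip) <- model$column_keys
  ord <- order(-vip, match(model$column_keys, enumerate_variable_grid()),
               seq_along(vip))
  structure(list(scores = vip, model_A = model$A,
                 ranking = model$column_keys[ord],
                 n_above_1 = sum(vip > 1),
                 n_above_1_5 = sum(vip > 1.5),
                 n_above_2 = sum(vip > 2)),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, n = 10, ...) {
  cat(sprintf("vip_result (%d components): %d variables with VIP > 1, %d > 1.5, %d > 2\n",
              x$model_A, x$n_above_1, x$n_above_1_5, x$n_above_2))
  top <- head(x$ranking, n)
  info <- parse_variable_key(top)
  cat(sprintf("%6s  %-32s %-12s %s\n", "VIP", "parameter", "manoeuvre",
              "pessary"))
  for (i in seq_along(top))
    cat(sprintf("%6.2f  %-32s %-12s %s\n", x$scores[top[i]],
                info$parameter[i], info$manoeuvre[i], info$pessary[i]))
  invisible(x)
}

#' Choose a component count from explained variance
#'
#' The smallest number of components whose cumulative explained response
#' variance reaches `threshold`, capped at `min(n - 1, p)`. Used as the
#' default component count for the initial VIP analysis.
#'
#' @param design a `design_matrix`.
#' @param threshold cumulative Y-variance target (default 0.9).
#' @return Integer component count.
#' @export
choose_components <- function(design, threshold = 0.9) {
  A_max <- min(nrow(design$X) - 1, ncol(design$X))
  fit <- fit_pls(design, A_max)
  cy <- cumulative_explained_variance(fit)$Y
  hit <- which(cy >= threshold)
  if (length(hit)) hit[1] else fit$A
}
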