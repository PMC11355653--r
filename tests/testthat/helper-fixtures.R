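# shared test fixtures, all built in code

# random complete design with named columns and a two-class response,
# suitable for fit_pls()
random_design <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  y <- rep(c(1, -1), length.out = n)[sample(n)]
  list(X = X, y = y, column_keys = colnames(X))
}

# continuous-response variant (PLS1 is agnostic to the response scale)
random_design_cont <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, y = rnorm(n), column_keys = colnames(X))
}

# tiny hand-built cohort over a few grid keys
tiny_cohort <- function(n_fit = 3, n_non = 3, seed = 1,
                        keys = c("TVL__rest__none", "TVL__valsalva__none",
                                 "CL__rest__ring_support",
                                 "LHA__rest__falk")) {
  set.seed(seed)
  n <- n_fit + n_non
  meas <- matrix(abs(rnorm(n * length(keys), 7, 1)), n,
                 dimnames = list(NULL, keys))
  cohort_table(sprintf("P%02d", seq_len(n)),
               c(rep("fitting", n_fit), rep("non_fitting", n_non)),
               meas)
}

# independently coded Wold VIP, straight from the formula
brute_force_vip <- function(model) {
  ssy <- model$q^2 * colSums(model$T^2)
  p <- nrow(model$W)
  sapply(seq_len(p), function(j) {
    num <- sum(ssy * (model$W[j, ] / sqrt(colSums(model$W^2)))^2)
    sqrt(p * num / sum(ssy))
  })
}
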