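# Brute-force oracles, deliberately written as plain loops so they stay
# independent of the vectorized linear algebra they are used to check.

# cross-basis row for one history: W[(j,k)] = sum_l f_j(q[l]) * c_k(l)
brute_crossbasis_row <- function(q, lags, fx_spec, wl_spec) {
  vx <- basis_dim(fx_spec); vl <- basis_dim(wl_spec)
  out <- numeric(vx * vl)
  for (j in seq_len(vx)) for (k in seq_len(vl)) {
    s <- 0
    for (li in seq_along(lags)) {
      fj <- eval_basis(q[li], fx_spec)$values[1, j]
      ck <- eval_basis(lags[li], wl_spec)$values[1, k]
      s <- s + fj * ck
    }
    out[(j - 1) * vl + k] <- s
  }
  unname(out)
}

# predicted log-HR contribution at one (x, l) point, centered at x0
brute_pred_point <- function(x, l, fx_spec, wl_spec, eta, x0) {
  vx <- basis_dim(fx_spec); vl <- basis_dim(wl_spec)
  s <- 0
  for (j in seq_len(vx)) for (k in seq_len(vl)) {
    fj <- eval_basis(x, fx_spec)$values[1, j] -
      eval_basis(x0, fx_spec)$values[1, j]
    ck <- eval_basis(l, wl_spec)$values[1, k]
    s <- s + eta[(j - 1) * vl + k] * fj * ck
  }
  unname(s)
}

brute_cumulative <- function(q, lags, fx_spec, wl_spec, eta, x0) {
  s <- 0
  for (li in seq_along(lags))
    s <- s + brute_pred_point(q[li], lags[li], fx_spec, wl_spec, eta, x0)
  s
}

# a hand-set fitted model around a given cross-basis (no data involved)
toy_fit <- function(cb, eta, vcov = NULL) {
  p <- length(eta)
  if (is.null(vcov)) {
    set.seed(99)
    A <- matrix(rnorm(p * p), p)
    vcov <- crossprod(A) / p + diag(p) * 0.01
  }
  structure(list(eta = eta, vcov = vcov, loglik = -100, df_total = p,
                 n_events = 50L, term_index = list(cb = seq_len(p)),
                 crossbases = list(cb = cb), ties = "efron"),
            class = "dlnm_fit")
}

# random small basis specs for property tests; intercept_ok = FALSE keeps
# the spec admissible as an exposure basis inside a cross-basis
random_small_spec <- function(kind_pool, boundary, intercept_ok = TRUE) {
  kind <- sample(kind_pool, 1)
  ic <- intercept_ok && sample(c(TRUE, FALSE), 1)
  switch(kind,
    linear = basis_spec("linear", boundary = boundary),
    constant = basis_spec("constant", boundary = boundary),
    logshift = basis_spec("logshift", boundary = boundary, shift = 1),
    threshold = basis_spec("threshold",
                           knots = sort(runif(sample(1:2, 1),
                                              boundary[1] + 0.1,
                                              boundary[2] - 0.1)),
                           boundary = boundary),
    bspline = basis_spec("bspline", degree = 2,
                         knots = mean(boundary), boundary = boundary,
                         intercept = ic),
    step = basis_spec("step", knots = mean(boundary), boundary = boundary,
                      intercept = ic))
}
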