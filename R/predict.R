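# --- internal helpers -------------------------------------------------------

# coefficient block and covariance block of one cross-basis term
cb_block <- function(fit, term) {
  stopifnot(inherits(fit, "dlnm_fit"))
  if (is.null(term)) {
    if (length(fit$crossbases) == 0L)
      stop("fit contains no cross-basis term")
    term <- names(fit$crossbases)[1]
  }
  cb <- fit$crossbases[[term]]
  if (is.null(cb)) stop("no cross-basis term named '", term, "'")
  idx <- fit$term_index[[term]]
  list(cb = cb, eta = fit$eta[idx],
       V = fit$vcov[idx, idx, drop = FALSE])
}

# centered transformation row z(x, l) with exposure index varying slowest:
# z[(j-1)*vl + k] = (f_j(x) - f_j(x0)) * c_k(l)
pred_rows <- function(cb, x, lags, x0) {
  r0 <- center_basis_row(cb$fx_spec, x0)
  R <- eval_basis(x, cb$fx_spec)$values
  Rc <- sweep(R, 2L, r0)
  C <- eval_basis(lags, cb$wl_spec)$values
  # one row per (x[i], lags[i]) pair
  stopifnot(nrow(Rc) == nrow(C))
  vl <- ncol(C)
  out <- matrix(0, nrow(Rc), ncol(Rc) * vl)
  for (j in seq_len(ncol(Rc)))
    out[, (j - 1L) * vl + seq_len(vl)] <- Rc[, j] * C
  out
}

delta_se <- function(Z, V) {
  sqrt(pmax(0, rowSums((Z %*% V) * Z)))
}

pred_frame <- function(x, lag, beta, se, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(x = x, lag = lag, loghr = beta, se = se,
             hr = exp(beta),
             hr_lo = exp(beta - z * se),
             hr_hi = exp(beta + z * se))
}

# --- exported prediction surface -------------------------------------------

#' Lag-response curve at a given exposure intensity
#'
#' Predicted risk contributions along the lag dimension for a constant
#' exposure intensity `x_p`, relative to the reference exposure `x0`
#' (HR(x0) = 1). The same basis functions used for estimation are applied at
#' prediction, and standard errors come from the delta method (quadratic
#' form with the coefficient covariance matrix). For a distributed lag model
#' (linear `f(x)`) the curve is the unit-exposure lag-response scaled by
#' `x_p - x0`.
#'
#' @param fit a `"dlnm_fit"`.
#' @param x_p exposure intensity, inside the exposure-basis boundary (no
#'   extrapolation).
#' @param lag_grid lags at which to evaluate (default: the estimation lag
#'   grid).
#' @param x0 reference exposure (default 0, the natural reference for
#'   occupational exposures).
#' @param term name of the cross-basis term (default: the first one).
#' @param level confidence level for the reported interval.
#' @return data frame with columns `x`, `lag`, `loghr`, `se`, `hr`,
#'   `hr_lo`, `hr_hi`.
#' @export
predict_lag_curve <- function(fit, x_p, lag_grid = NULL, x0 = 0,
                              term = NULL, level = 0.95) {
  blk <- cb_block(fit, term)
  if (is.null(lag_grid)) lag_grid <- blk$cb$lag_grid
  Z <- pred_rows(blk$cb, rep(x_p, length(lag_grid)), lag_grid, x0)
  beta <- drop(Z %*% blk$eta)
  pred_frame(x_p, lag_grid, beta, delta_se(Z, blk$V), level)
}

#' Exposure-response curve at a given lag
#'
#' Predicted risk contributions along the exposure dimension for a fixed lag
#' `lag_p`; the lag-specific slice of the bidimensional risk surface.
#'
#' @inheritParams predict_lag_curve
#' @param lag_p lag at which to evaluate.
#' @param x_grid exposure values, inside the exposure-basis boundary.
#' @return data frame with columns `x`, `lag`, `loghr`, `se`, `hr`,
#'   `hr_lo`, `hr_hi`.
#' @export
predict_exposure_curve <- function(fit, lag_p, x_grid, x0 = 0,
                                   term = NULL, level = 0.95) {
  blk <- cb_block(fit, term)
  Z <- pred_rows(blk$cb, x_grid, rep(lag_p, length(x_grid)), x0)
  beta <- drop(Z %*% blk$eta)
  pred_frame(x_grid, lag_p, beta, delta_se(Z, blk$V), level)
}

#' Bidimensional risk surface over an exposure x lag grid
#'
#' @inheritParams predict_lag_curve
#' @param x_grid exposure values.
#' @param lag_grid lags (default: the estimation lag grid).
#' @return An object of class `"prediction_grid"`: list with `x_values`,
#'   `lag_values`, `betahat` and `se` (matrices, exposures in rows and lags
#'   in columns), `x0` and `level`. `as.data.frame()` flattens it to the
#'   long CSV layout.
#' @export
predict_grid <- function(fit, x_grid, lag_grid = NULL, x0 = 0,
                         term = NULL, level = 0.95) {
  blk <- cb_block(fit, term)
  if (is.null(lag_grid)) lag_grid <- blk$cb$lag_grid
  nx <- length(x_grid); nl <- length(lag_grid)
  Z <- pred_rows(blk$cb, rep(x_grid, each = nl), rep(lag_grid, times = nx), x0)
  beta <- matrix(drop(Z %*% blk$eta), nrow = nx, byrow = TRUE)
  se <- matrix(delta_se(Z, blk$V), nrow = nx, byrow = TRUE)
  dimnames(beta) <- dimnames(se) <- list(paste0("x", x_grid),
                                         paste0("lag", lag_grid))
  structure(list(x_values = x_grid, lag_values = lag_grid,
                 betahat = beta, se = se, x0 = x0, level = level),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf("<prediction_grid> %d exposures x %d lags (reference x0 = %g)\n",
              length(x$x_values), length(x$lag_values), x$x0))
  invisible(x)
}

#' @export
as.data.frame.prediction_grid <- function(x, ...) {
  z <- stats::qnorm(1 - (1 - x$level) / 2)
  data.frame(x = rep(x$x_values, times = length(x$lag_values)),
             lag = rep(x$lag_values, each = length(x$x_values)),
             loghr = as.vector(x$betahat), se = as.vector(x$se),
             hr = exp(as.vector(x$betahat)),
             hr_lo = exp(as.vector(x$betahat) - z * as.vector(x$se)),
             hr_hi = exp(as.vector(x$betahat) + z * as.vector(x$se)))
}

#' Overall cumulative effect of an exposure history
#'
#' Total log-hazard-ratio accumulated over the lag window by a complete
#' exposure history `q_h`, relative to a constant-`x0` history, with its
#' delta-method standard error. Equals the sum over lags of the lag-specific
#' contributions evaluated at the actual (varying) exposures.
#'
#' @inheritParams predict_lag_curve
#' @param q_h numeric exposure history, one entry per lag of the estimation
#'   lag grid (entry `j` is the exposure at lag `lag_grid[j]`).
#' @return data frame (one row) with `loghr`, `se`, `hr`, `hr_lo`, `hr_hi`.
#' @examples
#' # after fitting, the history "20 WLM/year over the last 10 years":
#' # q <- ifelse(2:40 <= 9, 20, 0); cumulative_effect(fit, q)
#' @export
cumulative_effect <- function(fit, q_h, x0 = 0, term = NULL, level = 0.95) {
  blk <- cb_block(fit, term)
  lg <- blk$cb$lag_grid
  if (length(q_h) != length(lg))
    stop("q_h must have one entry per lag (", length(lg), ")")
  Z <- pred_rows(blk$cb, q_h, lg, x0)
  zc <- matrix(colSums(Z), nrow = 1L)
  beta <- drop(zc %*% blk$eta)
  pred_frame(NA_real_, NA_real_, beta, delta_se(zc, blk$V), level)[
    , c("loghr", "se", "hr", "hr_lo", "hr_hi")]
}

#' Cumulative risk trajectory along an exposure profile
#'
#' Applies [cumulative_effect()] to the exposure history seen at each
#' evaluation time, showing how the risk evolves dynamically as past
#' exposures move through the lag window (a forward-perspective summary).
#'
#' @inheritParams cumulative_effect
#' @param profile an [exposure_profile()].
#' @param eval_times integer times at which to compute the cumulative risk.
#' @return data frame with columns `time`, `loghr`, `se`, `hr`, `hr_lo`,
#'   `hr_hi`.
#' @export
risk_trajectory <- function(fit, profile, eval_times, x0 = 0,
                            term = NULL, level = 0.95) {
  blk <- cb_block(fit, term)
  lg <- blk$cb$lag_grid
  out <- lapply(eval_times, function(t) {
    q <- exposure_history(profile, t, min(lg), max(lg))
    cumulative_effect(fit, q, x0 = x0, term = term, level = level)
  })
  cbind(data.frame(time = eval_times), do.call(rbind, out))
}
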