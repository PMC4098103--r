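#' Cross-basis degrees of freedom
#'
#' The number of coefficients `v_x * v_l` spent by a cross-basis, which is
#' the degrees of freedom used to model the exposure-lag-response
#' association.
#'
#' @param fx_spec,wl_spec [basis_spec()] objects for the exposure and lag
#'   dimensions.
#' @return integer `v_x * v_l`.
#' @examples
#' crossbasis_df(basis_spec("linear"), basis_spec("constant")) # 1
#' @export
crossbasis_df <- function(fx_spec, wl_spec) {
  basis_dim(fx_spec) * basis_dim(wl_spec)
}

#' Build a cross-basis design matrix from exposure histories
#'
#' Combines an exposure-response basis `f(x)` and a lag-response basis
#' `w(l)` into the tensor-product cross-basis of a distributed lag
#' non-linear model. Row `i` of the result is
#' `W[i, (j,k)] = sum_l f_j(q_i[l]) * c_k(l)`
#' where `q_i` is the exposure history of observation `i` over the lag grid
#' and `c_k` are the lag-basis functions; the sum over the lag window
#' cumulates the contributions of all past exposure events. Columns are
#' ordered with the exposure-basis index `j` varying slowest and the
#' lag-basis index `k` fastest (names `cb_j_k`); coefficient vectors,
#' covariance matrices and all prediction code follow this order.
#'
#' With a linear `f(x)` the cross-basis reduces exactly to the distributed
#' lag model matrix `Q %*% C`; with linear `f(x)` and constant `w(l)` its
#' single column is the row sums of `Q`, the traditional unweighted
#' cumulative exposure.
#'
#' The exposure basis must not carry an intercept: inside the tensor product
#' an intercept in `f(x)` makes `W` rank-deficient and the coefficients
#' unidentifiable.
#'
#' @param Q a `"history_matrix"` from [build_history_matrix()], or a plain
#'   numeric matrix with one exposure history per row (then `lag_grid` must
#'   be supplied).
#' @param fx_spec [basis_spec()] for the exposure dimension, without
#'   intercept. A `NULL` boundary is resolved to the range of the observed
#'   history entries.
#' @param wl_spec [basis_spec()] for the lag dimension. A `NULL` boundary is
#'   resolved to the lag window.
#' @param lag_grid integer lags, only when `Q` is a plain matrix.
#' @param check_rank logical; verify that `W` has full column rank after
#'   removing all-zero columns and warn otherwise.
#' @return An object of class `"crossbasis"`: list with `W` (the
#'   `N x (v_x * v_l)` matrix), `fx_spec`, `wl_spec` (boundaries resolved),
#'   `lag_grid`, `column_order` (data frame of `(j, k)` per column) and `C`
#'   (the evaluated lag-basis matrix).
#' @examples
#' p <- exposure_profile("a", 1:50, rep(c(0, 20), c(40, 10)))
#' Q <- build_history_matrix(list(p), data.frame(subject_id = "a", time = 50),
#'                           l0 = 2, L = 40)
#' cb <- build_crossbasis(Q, basis_spec("linear"), basis_spec("constant"))
#' cb$W  # unweighted cumulative exposure over the window
#' @export
build_crossbasis <- function(Q, fx_spec, wl_spec, lag_grid = NULL,
                             check_rank = TRUE) {
  if (inherits(Q, "history_matrix")) {
    lag_grid <- Q$lag_grid
    Q <- Q$Q
  }
  stopifnot(is.matrix(Q), !is.null(lag_grid),
            length(lag_grid) == ncol(Q),
            inherits(fx_spec, "basis_spec"), inherits(wl_spec, "basis_spec"))
  if (!all(is.finite(Q))) stop("exposure histories must be finite")
  if (fx_spec$intercept)
    stop("the exposure basis f(x) must be defined without an intercept: ",
         "an intercept in f(x) makes the cross-basis rank-deficient ",
         "(unidentifiable coefficients)")
  fx_spec <- resolve_boundary(fx_spec, as.numeric(Q))
  wl_spec <- resolve_boundary(wl_spec, as.numeric(lag_grid))
  # R entries for all histories at once: f_j applied elementwise to Q
  Rall <- eval_basis(as.numeric(Q), fx_spec)$values  # (N*nl) x v_x
  C <- eval_basis(lag_grid, wl_spec)$values          # (L-l0+1) x v_l
  crossbasis_from_parts(Rall, C, nrow(Q), fx_spec, wl_spec, lag_grid,
                        check_rank = check_rank)
}

# assemble W from precomputed exposure-basis values (stacked column-major
# over histories) and lag-basis matrix C; lets grid drivers share Rall and C
# across candidate models. Rall may be a list of pre-reshaped N x nl
# matrices (one per exposure-basis column).
crossbasis_from_parts <- function(Rall, C, N, fx_spec, wl_spec, lag_grid,
                                  check_rank = TRUE) {
  if (!is.list(Rall))
    Rall <- lapply(seq_len(ncol(Rall)),
                   function(j) matrix(Rall[, j], nrow = N))
  vx <- length(Rall); vl <- ncol(C)
  W <- matrix(0, N, vx * vl)
  for (j in seq_len(vx))
    W[, (j - 1L) * vl + seq_len(vl)] <- Rall[[j]] %*% C
  column_order <- data.frame(j = rep(seq_len(vx), each = vl),
                             k = rep(seq_len(vl), times = vx))
  colnames(W) <- paste0("cb_", column_order$j, "_", column_order$k)
  if (check_rank) {
    nz <- colSums(abs(W)) > 0
    if (qr(W[, nz, drop = FALSE])$rank < sum(nz))
      warning("cross-basis matrix is rank-deficient after removing all-zero ",
              "columns; check basis specifications")
  }
  structure(list(W = W, fx_spec = fx_spec, wl_spec = wl_spec,
                 lag_grid = as.integer(lag_grid), column_order = column_order,
                 C = C),
            class = "crossbasis")
}

#' @export
print.crossbasis <- function(x, ...) {
  cat(sprintf("<crossbasis> %d x %d (v_x = %d [%s], v_l = %d [%s]), lags %d-%d\n",
              nrow(x$W), ncol(x$W),
              basis_dim(x$fx_spec), x$fx_spec$kind,
              basis_dim(x$wl_spec), x$wl_spec$kind,
              min(x$lag_grid), max(x$lag_grid)))
  invisible(x)
}

#' Export a cross-basis matrix to CSV
#'
#' The cross-basis is regression-agnostic: the exported matrix can be placed
#' in the design matrix of any model with a linear predictor. Columns keep
#' their `cb_j_k` names.
#'
#' @param cb a `"crossbasis"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_crossbasis <- function(cb, path) {
  stopifnot(inherits(cb, "crossbasis"))
  utils::write.csv(as.data.frame(cb$W), path, row.names = FALSE)
  invisible(path)
}
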