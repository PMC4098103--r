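#' Specify a one-dimensional basis transformation
#'
#' A basis spec defines the transformation applied to one dimension of an
#' exposure-lag-response association: the exposure-response function `f(x)`
#' or the lag-response function `w(l)`. The spec is a pure description;
#' [eval_basis()] turns it into a numeric basis matrix.
#'
#' Available kinds:
#' \describe{
#'   \item{`linear`}{the identity, one column.}
#'   \item{`constant`}{a column of ones. As a lag basis this recovers the
#'     traditional unweighted cumulative-exposure index.}
#'   \item{`step`}{piecewise-constant indicators with cut-offs `knots`.
#'     With an intercept, `c` cut-offs give `c + 1` disjoint 0/1 columns
#'     (one per stratum); without, the first stratum is the reference and
#'     is dropped.}
#'   \item{`threshold`}{hinge functions `max(0, x - tau)`, one column per
#'     cut-off in `knots` (the linear-threshold model).}
#'   \item{`bspline`}{B-splines of the given `degree` with interior `knots`
#'     on `boundary`. Excluding the intercept removes the left-terminal
#'     basis function, so the fitted curve is constrained to zero at the
#'     left boundary (a "left constraint"); `right_constrained = TRUE`
#'     additionally removes the right-terminal function so the curve is
#'     zero at the right boundary.}
#'   \item{`nspline`}{natural cubic splines (linear beyond the boundary
#'     knots), dimension `length(knots) + 1 + intercept`.}
#'   \item{`logshift`}{the one-column transformation `log(x + shift)`.}
#' }
#'
#' The basis dimension `v` is a pure function of the spec; see
#' [basis_dim()].
#'
#' @param kind character; one of `"linear"`, `"constant"`, `"step"`,
#'   `"threshold"`, `"bspline"`, `"nspline"`, `"logshift"`.
#' @param degree integer B-spline degree (quadratic, `2`, by default).
#' @param knots numeric vector of interior knots (spline kinds) or cut-offs
#'   (`step`, `threshold`), strictly increasing and strictly inside
#'   `boundary`.
#' @param boundary length-2 numeric support of the basis. May be left `NULL`
#'   and resolved later from the data range (exposure dimension) or the lag
#'   window (lag dimension); spline kinds refuse evaluation outside it.
#' @param intercept logical; keep the constant/terminal component of the
#'   basis. Exposure bases inside a cross-basis must not carry an intercept.
#' @param right_constrained logical; B-splines only, drop the right-terminal
#'   basis function so predictions vanish at the right boundary.
#' @param shift positive offset for `logshift`, `f(x) = log(x + shift)`.
#' @return An object of class `"basis_spec"`.
#' @seealso [eval_basis()], [basis_dim()], [build_crossbasis()]
#' @examples
#' basis_spec("bspline", degree = 2, knots = 13.3, boundary = c(2, 40))
#' basis_spec("step", knots = 20, boundary = c(2, 40), intercept = TRUE)
#' @export
basis_spec <- function(kind = c("linear", "constant", "step", "threshold",
                                "bspline", "nspline", "logshift"),
                       degree = 2L, knots = numeric(0), boundary = NULL,
                       intercept = FALSE, right_constrained = FALSE,
                       shift = 1) {
  kind <- match.arg(kind)
  knots <- as.numeric(knots)
  if (length(knots) && is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing")
  if (!is.null(boundary)) {
    boundary <- as.numeric(boundary)
    if (length(boundary) != 2L || !all(is.finite(boundary)) ||
        boundary[1] >= boundary[2])
      stop("boundary must be two increasing finite values")
    if (length(knots) &&
        (min(knots) <= boundary[1] || max(knots) >= boundary[2]))
      stop("knots must lie strictly inside the boundary")
  }
  if (kind %in% c("step", "threshold") && length(knots) == 0L)
    stop(sprintf("'%s' basis needs at least one cut-off in 'knots'", kind))
  if (right_constrained && kind != "bspline")
    stop("right constraint is defined for B-spline bases only")
  degree <- as.integer(degree)
  if (kind == "bspline" && degree < 1L)
    stop("B-spline degree must be >= 1")
  if (kind == "logshift" && shift <= 0)
    stop("logshift 'shift' must be positive")
  spec <- structure(
    list(kind = kind, degree = degree, knots = knots, boundary = boundary,
         intercept = isTRUE(intercept),
         right_constrained = isTRUE(right_constrained),
         shift = shift),
    class = "basis_spec")
  v <- basis_dim(spec)
  if (v < 1L)
    stop("basis dimension would be ", v, "; check intercept/constraints")
  spec
}

#' Basis dimension
#'
#' Number of columns `v` the spec evaluates to. This is the bookkeeping that
#' drives the degrees of freedom of a cross-basis (`v_x * v_l`).
#'
#' @param spec a [basis_spec()].
#' @return integer dimension, at least 1 for a valid spec.
#' @export
basis_dim <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  v <- switch(spec$kind,
    linear = 1L,
    constant = 1L,
    logshift = 1L,
    threshold = length(spec$knots),
    step = length(spec$knots) + as.integer(spec$intercept),
    bspline = length(spec$knots) + spec$degree +
      as.integer(spec$intercept) - as.integer(spec$right_constrained),
    nspline = length(spec$knots) + 1L + as.integer(spec$intercept))
  as.integer(v)
}

resolve_boundary <- function(spec, points) {
  if (is.null(spec$boundary)) {
    spec$boundary <- range(points)
    if (length(spec$knots) &&
        (min(spec$knots) <= spec$boundary[1] ||
         max(spec$knots) >= spec$boundary[2]))
      stop("knots must lie strictly inside the boundary implied by the data")
  }
  spec
}

# Full-rank B-spline design on the augmented knot sequence; optionally with
# first-order linear continuation beyond the boundary.
bspline_design <- function(x, spec, extrapolate = FALSE) {
  b <- spec$boundary
  aug <- c(rep(b[1], spec$degree + 1L), spec$knots, rep(b[2], spec$degree + 1L))
  ord <- spec$degree + 1L
  inside <- x >= b[1] & x <= b[2]
  if (!extrapolate && !all(inside))
    stop("points outside the basis boundary [", b[1], ", ", b[2],
         "]; extrapolation is not performed silently")
  xc <- pmin(pmax(x, b[1]), b[2])
  m <- splines::splineDesign(aug, xc, ord = ord)
  if (extrapolate && any(!inside)) {
    out <- which(!inside)
    d1 <- splines::splineDesign(aug, xc[out], ord = ord, derivs = 1L)
    m[out, ] <- m[out, , drop = FALSE] + (x[out] - xc[out]) * d1
  }
  if (!spec$intercept) m <- m[, -1L, drop = FALSE]
  if (spec$right_constrained) m <- m[, -ncol(m), drop = FALSE]
  m
}

#' Evaluate a basis spec at a set of points
#'
#' @param points numeric vector of evaluation points (exposure values or
#'   lags), all finite.
#' @param spec a [basis_spec()].
#' @param extrapolate logical; allow first-order (linear) continuation of
#'   spline bases beyond their boundary. Off by default: out-of-range points
#'   are an error, never silently extrapolated.
#' @return An object of class `"basis_matrix"`: a list with `values`
#'   (`length(points) x v` matrix), `spec` (with boundary resolved) and
#'   `points`.
#' @examples
#' eval_basis(2:40, basis_spec("constant"))
#' b <- eval_basis(0:40, basis_spec("bspline", knots = 20, boundary = c(0, 40),
#'                                  intercept = TRUE))
#' rowSums(b$values) # partition of unity
#' @export
eval_basis <- function(points, spec, extrapolate = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  points <- as.numeric(points)
  if (!all(is.finite(points))) stop("evaluation points must be finite")
  spec <- resolve_boundary(spec, points)
  # exposure histories repeat the same intensities across lags and risk
  # sets; evaluating at the distinct values only is much cheaper
  if (length(points) > 1000L) {
    u <- unique(points)
    if (length(u) < length(points) / 4) {
      mu <- eval_basis(u, spec, extrapolate = extrapolate)
      m <- mu$values[match(points, u), , drop = FALSE]
      return(structure(list(values = m, spec = mu$spec, points = points),
                       class = "basis_matrix"))
    }
  }
  m <- switch(spec$kind,
    linear = matrix(points, ncol = 1L),
    constant = matrix(1, nrow = length(points), ncol = 1L),
    logshift = matrix(log(points + spec$shift), ncol = 1L),
    threshold = vapply(spec$knots, function(tau) pmax(0, points - tau),
                       numeric(length(points))),
    step = {
      cuts <- c(-Inf, spec$knots, Inf)
      idx <- findInterval(points, spec$knots) + 1L  # stratum 1..c+1
      full <- matrix(0, length(points), length(spec$knots) + 1L)
      full[cbind(seq_along(points), idx)] <- 1
      if (spec$intercept) full else full[, -1L, drop = FALSE]
    },
    bspline = bspline_design(points, spec, extrapolate),
    nspline = {
      b <- spec$boundary
      if (!extrapolate && any(points < b[1] | points > b[2]))
        stop("points outside the basis boundary [", b[1], ", ", b[2],
             "]; extrapolation is not performed silently")
      # natural splines are linear beyond the boundary knots, so ns() is
      # already the first-order continuation
      unclass(splines::ns(points, knots = spec$knots,
                          Boundary.knots = b, intercept = spec$intercept))
    })
  if (!is.matrix(m)) m <- matrix(m, nrow = length(points))
  if (!is.double(m)) storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (ncol(m) != basis_dim(spec))
    stop("internal error: basis dimension mismatch")
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  structure(list(values = m, spec = spec, points = points),
            class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("<basis_matrix> %s basis, %d points x %d columns\n",
              x$spec$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Remove the intercept from an evaluated basis (left constraint)
#'
#' For B-spline lag bases this removes the left-terminal basis function, so
#' the lag-response curve is forced through zero at the start of the lag
#' window (null risk at lag `l0`).
#'
#' @param basis a `"basis_matrix"` from [eval_basis()].
#' @return A `"basis_matrix"` re-evaluated without the intercept, one column
#'   fewer.
#' @export
drop_intercept <- function(basis) {
  stopifnot(inherits(basis, "basis_matrix"))
  spec <- basis$spec
  if (!spec$intercept)
    stop("basis has no intercept to drop")
  if (basis_dim(spec) <= 1L)
    stop("dropping the intercept would leave an empty basis")
  spec$intercept <- FALSE
  eval_basis(basis$points, spec)
}

#' Apply a right constraint to an evaluated B-spline basis
#'
#' Removes the right-terminal basis function so that every fitted
#' lag-response curve is exactly zero at the right boundary `L` of the lag
#' window (null risk at the end of the lag period), whatever the
#' coefficients.
#'
#' @param basis a `"basis_matrix"` with a B-spline spec.
#' @return A `"basis_matrix"` with `right_constrained = TRUE`, one column
#'   fewer.
#' @export
apply_right_constraint <- function(basis) {
  stopifnot(inherits(basis, "basis_matrix"))
  spec <- basis$spec
  if (spec$kind != "bspline")
    stop("right constraint is defined for B-spline bases only")
  if (spec$right_constrained)
    stop("basis is already right-constrained")
  if (basis_dim(spec) <= 1L)
    stop("right constraint would leave an empty basis")
  spec$right_constrained <- TRUE
  eval_basis(basis$points, spec)
}

#' Basis row at the reference exposure
#'
#' Evaluates the basis at the centering value `x0`. Prediction code
#' subtracts this row from every exposure-basis row so that all risk
#' summaries are expressed relative to `x0` (HR(x0) = 1). Fitting is
#' unaffected: in a Cox model the baseline hazard absorbs any constant.
#'
#' @param spec a [basis_spec()] with a resolved boundary.
#' @param x0 reference exposure value, inside the boundary.
#' @return numeric vector of length `basis_dim(spec)`.
#' @export
center_basis_row <- function(spec, x0) {
  stopifnot(inherits(spec, "basis_spec"), length(x0) == 1L, is.finite(x0))
  if (is.null(spec$boundary))
    stop("spec boundary must be resolved before centering")
  if (x0 < spec$boundary[1] || x0 > spec$boundary[2])
    stop("reference value x0 = ", x0, " lies outside the basis boundary")
  unname(eval_basis(x0, spec)$values[1, ])
}

#' Serialize / deserialize a basis spec
#'
#' Flat list representation used by configuration files and fitted-model
#' serialization.
#'
#' @param spec a [basis_spec()].
#' @return `basis_spec_to_list()`: a plain named list;
#'   `basis_spec_from_list()`: a `"basis_spec"`.
#' @export
basis_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  unclass(spec)
}

#' @rdname basis_spec_to_list
#' @param x a named list as produced by `basis_spec_to_list()`.
#' @export
basis_spec_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(x$kind))
  basis_spec(kind = x$kind,
             degree = if (is.null(x$degree)) 2L else x$degree,
             knots = if (is.null(x$knots)) numeric(0) else x$knots,
             boundary = x$boundary,
             intercept = isTRUE(x$intercept),
             right_constrained = isTRUE(x$right_constrained),
             shift = if (is.null(x$shift)) 1 else x$shift)
}
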