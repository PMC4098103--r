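#' Subject-level exposure profile
#'
#' A profile records the exposure intensity sustained by one subject in each
#' time unit (year). Time is an integer grid; lag `l` at evaluation time `t`
#' refers to the exposure received in year `t - l`. Times before the start
#' of the recorded profile contribute zero exposure.
#'
#' @param subject_id scalar identifier.
#' @param time_axis integer vector of consecutive times (years of age or
#'   follow-up years) at which `intensity` is recorded.
#' @param intensity numeric vector of exposure intensity per time unit
#'   (e.g. WLM/year or cigarette packs x 100/year), same length as
#'   `time_axis`.
#' @return An object of class `"exposure_profile"`.
#' @export
exposure_profile <- function(subject_id, time_axis, intensity) {
  time_axis <- as.integer(time_axis)
  intensity <- as.numeric(intensity)
  if (length(time_axis) != length(intensity))
    stop("time_axis and intensity must have the same length")
  if (length(time_axis) == 0L)
    stop("profile must contain at least one time point")
  if (any(diff(time_axis) != 1L))
    stop("time_axis must be consecutive integers")
  if (any(!is.finite(intensity)))
    stop("intensity must be finite at every recorded time")
  structure(list(subject_id = subject_id, time_axis = time_axis,
                 intensity = intensity),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("<exposure_profile> subject %s, years %d-%d, total %.2f\n",
              format(x$subject_id), min(x$time_axis), max(x$time_axis),
              sum(x$intensity)))
  invisible(x)
}

# intensity at arbitrary integer times: 0 before the profile start, held at
# the recorded values inside, 0 after the recorded end (cohort readers that
# need a carry-forward rule extend the profile explicitly).
profile_intensity_at <- function(profile, times) {
  out <- numeric(length(times))
  idx <- match(times, profile$time_axis)
  ok <- !is.na(idx)
  out[ok] <- profile$intensity[idx[ok]]
  out
}

#' Exposure history vector
#'
#' The vector of past exposure intensities `(x_{t-l0}, ..., x_{t-L})` seen
#' from evaluation time `t` over the lag window `l0..L`. Entry `j`
#' corresponds to lag `l0 + j - 1`, i.e. the exposure received in year
#' `t - (l0 + j - 1)`.
#'
#' @param profile an [exposure_profile()].
#' @param t integer evaluation time.
#' @param l0,L integer lag window, `0 <= l0 <= L`.
#' @return numeric vector of length `L - l0 + 1`, named by lag.
#' @examples
#' p <- exposure_profile("a", 1:50, rep(c(0, 20), c(40, 10)))
#' exposure_history(p, t = 50, l0 = 2, L = 40)
#' @export
exposure_history <- function(profile, t, l0, L) {
  stopifnot(inherits(profile, "exposure_profile"))
  l0 <- as.integer(l0); L <- as.integer(L); t <- as.integer(t)
  if (l0 < 0L || l0 > L) stop("need 0 <= l0 <= L")
  lags <- l0:L
  q <- profile_intensity_at(profile, t - lags)
  names(q) <- paste0("lag", lags)
  q
}

#' Matrix of exposure histories
#'
#' Stacks [exposure_history()] vectors for a set of (subject, time)
#' evaluation points into the `N x (L - l0 + 1)` matrix `Q` used to build
#' lag-basis and cross-basis design matrices. Row order follows
#' `eval_points`.
#'
#' @param profiles list of [exposure_profile()] objects.
#' @param eval_points data frame with columns `subject_id` and `time`.
#' @param l0,L integer lag window.
#' @return An object of class `"history_matrix"`: list with `Q` (numeric
#'   matrix), `lag_grid` (integers `l0:L`) and `row_index` (the
#'   `eval_points` used).
#' @export
build_history_matrix <- function(profiles, eval_points, l0, L) {
  stopifnot(is.data.frame(eval_points),
            all(c("subject_id", "time") %in% names(eval_points)))
  ids <- vapply(profiles, function(p) as.character(p$subject_id), "")
  if (anyDuplicated(ids)) stop("duplicate subject ids in profiles")
  pos <- match(as.character(eval_points$subject_id), ids)
  if (anyNA(pos))
    stop("unknown subject id(s): ",
         paste(unique(eval_points$subject_id[is.na(pos)]), collapse = ", "))
  lags <- as.integer(l0):as.integer(L)
  Q <- matrix(0, nrow = nrow(eval_points), ncol = length(lags),
              dimnames = list(NULL, paste0("lag", lags)))
  axes <- lapply(profiles, `[[`, "time_axis")
  common <- all(vapply(axes[-1], identical, TRUE, y = axes[[1]]))
  if (common) {
    # all profiles share one time grid: gather by index instead of per row
    X <- do.call(rbind, lapply(profiles, `[[`, "intensity"))
    t0 <- axes[[1]][1]
    tmax <- axes[[1]][length(axes[[1]])]
    tt <- as.integer(eval_points$time)
    for (li in seq_along(lags)) {
      src <- tt - lags[li]
      ok <- src >= t0 & src <= tmax
      Q[ok, li] <- X[cbind(pos[ok], src[ok] - t0 + 1L)]
    }
  } else {
    for (i in seq_len(nrow(eval_points)))
      Q[i, ] <- exposure_history(profiles[[pos[i]]], eval_points$time[i],
                                 l0, L)
  }
  structure(list(Q = Q, lag_grid = lags, row_index = eval_points),
            class = "history_matrix")
}

#' Export a history matrix to CSV for audit
#'
#' Writes one row per (subject, evaluation time) with the lag-indexed
#' exposure history columns, so the expansion feeding a cross-basis can be
#' inspected outside R.
#'
#' @param h a `"history_matrix"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history_matrix <- function(h, path) {
  stopifnot(inherits(h, "history_matrix"))
  utils::write.csv(cbind(h$row_index, as.data.frame(h$Q)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.history_matrix <- function(x, ...) {
  cat(sprintf("<history_matrix> %d histories x lags %d-%d\n",
              nrow(x$Q), min(x$lag_grid), max(x$lag_grid)))
  invisible(x)
}
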