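#' True exposure-lag-response scenarios
#'
#' Defines the nine scenarios used to validate the estimators, each the
#' product `f_s(x) * w_s(l)` of an exposure-response shape and a lag-response
#' shape over lags 0-40 and exposures 0-10:
#' \describe{
#'   \item{exposure-response `f_s`}{`linear` (`theta * x`), `plateau`
#'     (`theta * log(1 + x)`, rising then flattening), `exponential`
#'     (`theta * (exp(x / kappa) - 1)`, accelerating). All satisfy
#'     `f_s(0) = 0` and are scaled so `f_s(10)` equals the common amplitude.}
#'   \item{lag-response `w_s`}{`constant` (equal weight at every lag),
#'     `decay` (`exp(-l / tau)`), `peak` (Gaussian bump centered mid-lag,
#'     anchored to exactly zero at lag 40). Each is normalized to sum to one
#'     over lags 0-40, so the amplitude is carried by `f_s` alone.}
#' }
#' The amplitude is the log-hazard-ratio of a subject continuously exposed
#' at intensity 10 relative to an unexposed one; the default gives strong
#' but non-degenerate signals (hazard ratios in the single digits for
#' realistic histories).
#'
#' @param name scenario name, `"<f>-<w>"` with `f` in
#'   `linear`/`plateau`/`exponential` and `w` in `constant`/`decay`/`peak`.
#' @param amplitude common scale `f_s(10)` of the exposure-response (log-HR
#'   units).
#' @param tau decay constant (years) of the `decay` lag-response.
#' @param peak_center,peak_sd center and width (years) of the `peak`
#'   lag-response.
#' @param kappa rate constant of the `exponential` exposure-response.
#' @param L maximum lag (the lag window is `0..L`).
#' @return An object of class `"scenario"`: list with `name`, functions
#'   `f_s` and `w_s`, `l0 = 0`, `L`, and the parameters.
#' @export
scenario_def <- function(name, amplitude = 4, tau = 10,
                         peak_center = 15, peak_sd = 8, kappa = 5, L = 40) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L ||
      !parts[1] %in% c("linear", "plateau", "exponential") ||
      !parts[2] %in% c("constant", "decay", "peak"))
    stop("scenario name must be '<linear|plateau|exponential>-",
         "<constant|decay|peak>'")
  f_s <- switch(parts[1],
    linear = local({ th <- amplitude / 10
      function(x) th * x }),
    plateau = local({ th <- amplitude / log(11)
      function(x) th * log(1 + x) }),
    exponential = local({ th <- amplitude / (exp(10 / kappa) - 1)
      function(x) th * (exp(x / kappa) - 1) }))
  lags <- 0:L
  w_raw <- switch(parts[2],
    constant = rep(1, length(lags)),
    decay = exp(-lags / tau),
    peak = exp(-(lags - peak_center)^2 / (2 * peak_sd^2)) -
           exp(-(L - peak_center)^2 / (2 * peak_sd^2)))
  if (any(w_raw < 0)) stop("lag-response weights must be non-negative")
  w_norm <- w_raw / sum(w_raw)
  w_s <- function(l) {
    if (any(l < 0 | l > L)) stop("lag outside 0..", L)
    w_norm[match(l, lags)]
  }
  structure(list(name = name, f_s = f_s, w_s = w_s, l0 = 0L, L = as.integer(L),
                 amplitude = amplitude, tau = tau, peak_center = peak_center,
                 peak_sd = peak_sd, kappa = kappa,
                 fx_shape = parts[1], wl_shape = parts[2]),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s, lags 0-%d, amplitude %.2f\n",
              x$name, x$L, x$amplitude))
  invisible(x)
}

#' Generate random time-varying exposure profiles
#'
#' Exposure is laid down in random occupational-like spells: each subject
#' receives a Poisson number of spells, each with a uniform start on the
#' follow-up window, a geometric duration and a uniform intensity in 0-10.
#' Overlapping spells keep the maximum intensity, so every yearly intensity
#' stays within 0-10. Consecutive exposed years therefore share intensities
#' (serially correlated exposure), as in occupational histories.
#'
#' @param ns number of subjects (at least 2).
#' @param seed optional integer seed (a `NULL` seed uses the current RNG
#'   state).
#' @param t_max last follow-up year (profiles cover `1..t_max`).
#' @param spell_rate expected number of exposure spells per subject.
#' @param spell_mean_dur mean spell duration in years.
#' @param intensity_max upper bound of the uniform spell intensity.
#' @return list of `ns` [exposure_profile()] objects on years `1..t_max`.
#' @export
gen_profiles <- function(ns, seed = NULL, t_max = 100, spell_rate = 6,
                         spell_mean_dur = 10, intensity_max = 10) {
  if (ns < 2) stop("ns must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  p_geo <- 1 / spell_mean_dur
  lapply(seq_len(ns), function(i) {
    x <- numeric(t_max)
    for (s in seq_len(stats::rpois(1, spell_rate))) {
      start <- sample.int(t_max, 1)
      dur <- stats::rgeom(1, p_geo) + 1L
      idx <- start:min(t_max, start + dur - 1L)
      x[idx] <- pmax(x[idx], stats::runif(1, 0, intensity_max))
    }
    exposure_profile(paste0("s", i), seq_len(t_max), x)
  })
}

#' True cumulative effect of an exposure history
#'
#' The known log-hazard-ratio `sum_l f_s(q[l]) * w_s(l)` of a history under
#' a simulation scenario, over the scenario lag window `0..L`.
#'
#' @param q numeric history of length `L + 1`; entry `j` is the exposure at
#'   lag `j - 1`.
#' @param scenario a [scenario_def()].
#' @return numeric scalar.
#' @export
true_cumulative <- function(q, scenario) {
  stopifnot(inherits(scenario, "scenario"))
  lags <- scenario$l0:scenario$L
  if (length(q) != length(lags))
    stop("history must have length ", length(lags))
  sum(scenario$f_s(q) * scenario$w_s(lags))
}

# ns x t_max matrix of true cumulative effects at every time, by sliding the
# lag window over the intensity matrix (times before year 1 contribute 0)
effect_series <- function(profiles, scenario) {
  X <- do.call(rbind, lapply(profiles, function(p) p$intensity))
  t_max <- ncol(X)
  FX <- matrix(scenario$f_s(X), nrow = nrow(X))
  w <- scenario$w_s(scenario$l0:scenario$L)
  eff <- matrix(0, nrow(X), t_max)
  for (li in seq_along(w)) {
    l <- scenario$l0 + li - 1L
    cols <- seq_len(t_max - l)
    if (l < t_max)
      eff[, cols + l] <- eff[, cols + l] + w[li] * FX[, cols, drop = FALSE]
  }
  eff
}

#' Permutational assignment of survival times to subjects
#'
#' Marries a pre-drawn set of candidate event/censoring times to subjects
#' conditional on their true time-varying (log-)hazard contributions. Times
#' are processed in ascending order (ties in random order): an event time is
#' given to one not-yet-assigned subject drawn with probability proportional
#' to `exp(effect)` of that subject at that time; a censoring time is given
#' uniformly among the remaining subjects. Every subject is assigned exactly
#' one time. With all effects zero, the assignment is a uniform random
#' permutation.
#'
#' @param times numeric candidate times, one per subject.
#' @param is_event logical, same length: `TRUE` for event times, `FALSE`
#'   for censoring times.
#' @param effect matrix of true cumulative (log-hazard) effects, subjects in
#'   rows, columns indexed by integer time `1..ncol(effect)`.
#' @param seed optional integer seed.
#' @return data frame with columns `subject` (row of `effect`), `time`,
#'   `status` (1 event / 0 censored), ordered by subject.
#' @export
permutational_assign <- function(times, is_event, effect, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(effect)
  if (length(times) != n || length(is_event) != n)
    stop("need exactly one candidate time per subject")
  if (any(times < 1 | times > ncol(effect)))
    stop("candidate times must index columns of the effect matrix")
  ord <- order(times, stats::runif(n))
  unassigned <- rep(TRUE, n)
  subj <- integer(n)
  for (k in ord) {
    t <- times[k]
    pool <- which(unassigned)
    if (is_event[k]) {
      e <- effect[pool, t]
      pr <- exp(e - max(e))
      pick <- pool[sample.int(length(pool), 1, prob = pr)]
    } else {
      pick <- pool[sample.int(length(pool), 1)]
    }
    subj[k] <- pick
    unassigned[pick] <- FALSE
  }
  out <- data.frame(subject = subj, time = times,
                    status = as.integer(is_event))
  out[order(out$subject), , drop = FALSE]
}

#' Simulate a cohort under a known exposure-lag-response scenario
#'
#' Generates `ns` exposure profiles over years 1-100, computes each
#' subject's true cumulative effect series under the scenario, draws
#' candidate times uniformly on the integers 2-100 (a random ~25% of
#' subjects receiving censoring times, the rest event times), and assigns
#' them with [permutational_assign()]. With 400 subjects this yields
#' approximately 300 uncensored events.
#'
#' @param scenario a [scenario_def()] or scenario name.
#' @param ns number of subjects.
#' @param seed integer seed driving the whole replicate.
#' @param censor_frac probability that a subject receives a censoring time.
#' @param t_max last follow-up year.
#' @param ... further arguments to [gen_profiles()].
#' @return An object of class `"simulated_cohort"`: list with `profiles`,
#'   `events` (data frame `subject`, `time`, `status`), `effect` (the
#'   `ns x t_max` true cumulative effect matrix), `scenario` and `seed`.
#' @export
simulate_dataset <- function(scenario, ns, seed = NULL, censor_frac = 0.25,
                             t_max = 100, ...) {
  if (is.character(scenario)) scenario <- scenario_def(scenario)
  stopifnot(inherits(scenario, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  profiles <- gen_profiles(ns, seed = NULL, t_max = t_max, ...)
  eff <- effect_series(profiles, scenario)
  times <- sample(2:t_max, ns, replace = TRUE)
  is_event <- stats::runif(ns) >= censor_frac
  ev <- permutational_assign(times, is_event, eff)
  structure(list(profiles = profiles, events = ev, effect = eff,
                 scenario = scenario, seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %s: %d subjects, %d events (%.0f%% censored)\n",
              x$scenario$name, nrow(x$events), sum(x$events$status),
              100 * mean(1 - x$events$status)))
  invisible(x)
}

#' Counting-process expansion of a simulated cohort
#'
#' Risk-set expansion of a [simulate_dataset()] cohort for fitting, with
#' exposure histories over the scenario lag window `0..L` evaluated at every
#' event time at which a subject is at risk.
#'
#' @param sim a `"simulated_cohort"`.
#' @return A `"cp_data"` object (see [expand_cohort()]) with one history
#'   matrix named `x`.
#' @export
expand_sim_cohort <- function(sim) {
  stopifnot(inherits(sim, "simulated_cohort"))
  subjects <- data.frame(subject_id = vapply(sim$profiles,
                                             function(p) p$subject_id, ""),
                         entry_age = 1L,
                         exit_age = sim$events$time,
                         event = sim$events$status)
  expand_cohort(subjects, list(x = sim$profiles),
                l0 = sim$scenario$l0, L = sim$scenario$L, calendar = FALSE)
}
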