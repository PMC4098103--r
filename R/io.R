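#' Read a cohort in the 5-year-interval miners layout
#'
#' Reads a subject table and a tidy long-format exposure table in which
#' cumulative radon and smoking totals are recorded at the end of 5-year age
#' intervals, and reconstructs yearly exposure profiles: each interval's
#' cumulative increment is allocated uniformly within the interval
#' (increment / 5 per year). Radon exposure is zero after the last recorded
#' interval; smoking is held constant at the last yearly rate through the
#' end of follow-up. Exposure before the first recorded interval (and before
#' birth) is zero.
#'
#' @param subjects_path CSV with columns `subject_id`, `entry_age`,
#'   `exit_age`, `event`, `year_entry`.
#' @param exposure_path CSV with columns `subject_id`,
#'   `age_interval_start`, `cumulative_radon_wlm`,
#'   `cumulative_smoking_packs100`; one row per subject per 5-year interval,
#'   cumulative totals measured at the end of the interval.
#' @param col_map optional named character vector renaming file columns to
#'   the canonical names above (`c(canonical = "file_column")`).
#' @return list with `subjects` (data frame) and `profiles` (list with
#'   elements `radon` and `smoking`, each a list of [exposure_profile()]).
#' @export
read_cohort <- function(subjects_path, exposure_path, col_map = NULL) {
  rd <- function(path, need) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty file: ", path)
    if (!is.null(col_map))
      for (nm in names(col_map))
        names(df)[names(df) == col_map[[nm]]] <- nm
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
    df
  }
  subjects <- rd(subjects_path,
                 c("subject_id", "entry_age", "exit_age", "event"))
  expo <- rd(exposure_path,
             c("subject_id", "age_interval_start",
               "cumulative_radon_wlm", "cumulative_smoking_packs100"))
  profiles <- list(radon = list(), smoking = list())
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    e <- expo[expo$subject_id == sid, , drop = FALSE]
    if (nrow(e) == 0L)
      stop("no exposure records for subject ", sid)
    o <- order(e$age_interval_start)
    e <- e[o, , drop = FALSE]
    if (any(diff(e$age_interval_start) != 5))
      stop("subject ", sid, ": age intervals must advance by 5 years ",
           "(rows ", paste(rownames(e), collapse = ","), ")")
    inc_r <- diff(c(0, e$cumulative_radon_wlm))
    inc_s <- diff(c(0, e$cumulative_smoking_packs100))
    if (any(inc_r < 0) || any(inc_s < 0))
      stop("subject ", sid, ": cumulative exposure decreases (rows ",
           paste(rownames(e)[c(which(inc_r < 0), which(inc_s < 0))],
                 collapse = ","), ")")
    first_age <- e$age_interval_start[1]
    last_age <- e$age_interval_start[nrow(e)] + 4L
    ages <- first_age:max(last_age, subjects$exit_age[i])
    rate_r <- rep(c(inc_r / 5, 0), c(rep(5L, nrow(e)),
                                     length(ages) - 5L * nrow(e)))
    last_smoke <- inc_s[nrow(e)] / 5
    rate_s <- rep(c(inc_s / 5, last_smoke),
                  c(rep(5L, nrow(e)), length(ages) - 5L * nrow(e)))
    profiles$radon[[i]] <- exposure_profile(sid, ages, rate_r[seq_along(ages)])
    profiles$smoking[[i]] <- exposure_profile(sid, ages,
                                              rate_s[seq_along(ages)])
  }
  message(nrow(subjects), " subjects, ", sum(subjects$event),
          " events, ", nrow(expo), " exposure intervals read")
  list(subjects = subjects, profiles = profiles)
}

#' Write a synthetic miniature cohort in the miners CSV layout
#'
#' Generates a fully synthetic cohort (exposure spells from
#' [gen_profiles()], events assigned by the permutational algorithm under a
#' linear-constant radon effect) and writes it in the 5-year-interval layout
#' read by [read_cohort()], so the whole pipeline can be exercised without
#' any external data. Deterministic for a given seed.
#'
#' @param ns number of subjects.
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param radon_effect true log-HR per WLM-year of weighted cumulative radon
#'   exposure used when assigning events.
#' @return named character vector with the paths of the `subjects` and
#'   `exposure` CSV files, invisibly.
#' @export
make_fixture <- function(ns, seed, dir, radon_effect = 4e-4) {
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  radon <- gen_profiles(ns, t_max = 100, intensity_max = 200)
  smoking <- gen_profiles(ns, t_max = 100, spell_rate = 1,
                          spell_mean_dur = 30, intensity_max = 5)
  # true effect: linear in radon intensity, constant over lags 2-40
  X <- do.call(rbind, lapply(radon, function(p) p$intensity))
  eff <- matrix(0, ns, 100)
  for (l in 2:40) {
    cols <- seq_len(100 - l)
    eff[, cols + l] <- eff[, cols + l] + radon_effect * X[, cols]
  }
  entry <- 20L
  times <- sample(25:90, ns, replace = TRUE)
  is_event <- stats::runif(ns) >= 0.3
  ev <- permutational_assign(times, is_event, eff)
  subjects <- data.frame(subject_id = vapply(radon, function(p)
                           p$subject_id, ""),
                         entry_age = entry,
                         exit_age = ev$time,
                         event = ev$status,
                         year_entry = sample(1950:1960, ns, replace = TRUE))
  # aggregate yearly intensities to cumulative 5-year intervals (ages 0-99)
  rows <- list()
  for (i in seq_len(ns)) {
    starts <- seq(0L, 95L, by = 5L)
    cum_r <- cumsum(vapply(starts, function(s)
      sum(profile_intensity_at(radon[[i]], s:(s + 4L))), 0))
    cum_s <- cumsum(vapply(starts, function(s)
      sum(profile_intensity_at(smoking[[i]], s:(s + 4L))), 0))
    keep <- starts < subjects$exit_age[i]
    rows[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                            age_interval_start = starts[keep],
                            cumulative_radon_wlm = round(cum_r[keep], 3),
                            cumulative_smoking_packs100 = round(cum_s[keep], 3))
  }
  expo <- do.call(rbind, rows)
  sp <- file.path(dir, "subjects.csv")
  ep <- file.path(dir, "exposure.csv")
  utils::write.csv(subjects, sp, row.names = FALSE)
  utils::write.csv(expo, ep, row.names = FALSE)
  invisible(c(subjects = sp, exposure = ep))
}

# fixed a-priori smoking cross-basis: natural cubic spline with one knot for
# the exposure-response, step function with a single cut-off at lag 20 for
# the lag structure
smoking_crossbasis <- function(Qz, knot = 2.5, lag_cut = 20) {
  build_crossbasis(Qz,
                   basis_spec("nspline", knots = knot,
                              boundary = c(0, max(max(Qz$Q), knot + 1)),
                              intercept = FALSE),
                   basis_spec("step", knots = lag_cut,
                              boundary = range(Qz$lag_grid) + c(-0.5, 0.5),
                              intercept = TRUE))
}

#' Default DLM/DLNM candidate set for cohort analysis
#'
#' A compact candidate table in the spirit of the cohort analysis: linear,
#' piecewise-constant and quadratic B-spline options for `f(x)` crossed with
#' constant, piecewise-constant and left-constrained quadratic B-spline
#' options for `w(l)`.
#'
#' @param exposure_knots cut-offs / knots for the exposure dimension
#'   (WLM/year).
#' @param lag_knot interior knot for the lag B-splines.
#' @param lag_window integer lag window.
#' @param exposure_boundary optional support of the exposure bases (defaults
#'   to the data range at fit time).
#' @return list of `list(fx = , wl = )` pairs.
#' @export
cohort_candidates <- function(exposure_knots = c(26.7, 60.2, 122.2),
                              lag_knot = 13.3, lag_window = c(2, 40),
                              exposure_boundary = NULL) {
  lin <- basis_spec("linear", boundary = exposure_boundary)
  fx_bs <- basis_spec("bspline", knots = exposure_knots[2],
                      boundary = exposure_boundary, intercept = FALSE)
  fx_step <- basis_spec("step", knots = exposure_knots,
                        boundary = exposure_boundary, intercept = FALSE)
  wl_const <- basis_spec("constant", boundary = lag_window)
  wl_step <- basis_spec("step", knots = c(10, 20, 30),
                        boundary = lag_window + c(-0.5, 0.5),
                        intercept = TRUE)
  wl_bs_ic <- basis_spec("bspline", knots = lag_knot, boundary = lag_window,
                         intercept = TRUE)
  wl_bs <- basis_spec("bspline", knots = lag_knot, boundary = lag_window,
                      intercept = FALSE)
  fx_list <- list(lin, lin, lin, lin, fx_bs, fx_step, fx_bs, fx_bs)
  wl_list <- list(wl_const, wl_step, wl_bs_ic, wl_bs,
                  wl_const, wl_step, wl_bs_ic, wl_bs)
  mapply(function(f, w) list(fx = f, wl = w), fx_list, wl_list,
         SIMPLIFY = FALSE)
}

#' Run the cohort analysis pipeline end to end
#'
#' Reads a cohort in the miners layout, expands it to counting-process form
#' with the radon exposure of interest, the fixed smoking cross-basis and a
#' linear calendar-time term, fits and selects among candidate radon
#' cross-bases by AIC/BIC, and writes the criterion table, prediction curves,
#' the bidimensional risk grid and cumulative-effect scenario summaries as
#' CSV files.
#'
#' @param subjects_path,exposure_path cohort CSV paths (see
#'   [read_cohort()]).
#' @param outdir output directory for the CSV artifacts.
#' @param candidates candidate list (default [cohort_candidates()]).
#' @param l0,L integer lag window for radon and smoking.
#' @param x0 reference exposure for all risk summaries.
#' @param x_pred exposure intensity for the reported lag-response curve.
#' @param lag_pred lag for the reported exposure-response curve.
#' @param seed integer seed (recorded for provenance; the pipeline itself is
#'   deterministic).
#' @return list with `selection` (criterion table and best fits), `cp`
#'   (the counting-process data), and the paths of the written artifacts.
#' @export
run_pipeline <- function(subjects_path, exposure_path, outdir,
                         candidates = cohort_candidates(),
                         l0 = 2, L = 40, x0 = 0, x_pred = 100, lag_pred = 15,
                         seed = 1L) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  coh <- read_cohort(subjects_path, exposure_path)
  cp <- expand_cohort(coh$subjects, coh$profiles, l0 = l0, L = L)
  extra <- list(smk = smoking_crossbasis(cp$histories$smoking))
  if (!is.null(cp$calendar)) extra$cal <- matrix(cp$calendar, ncol = 1)
  sel <- select_model(cp$histories$radon, candidates, cp$core, extra = extra)
  paths <- c(criteria = file.path(outdir, "criteria.csv"),
             lag_curve = file.path(outdir, "lag_curve.csv"),
             exposure_curve = file.path(outdir, "exposure_curve.csv"),
             grid = file.path(outdir, "risk_grid.csv"),
             scenarios = file.path(outdir, "scenario_hr.csv"),
             config = file.path(outdir, "config.csv"))
  utils::write.csv(sel$table, paths["criteria"], row.names = FALSE)
  best <- sel$best_aic
  lg <- l0:L
  utils::write.csv(predict_lag_curve(best, x_pred, x0 = x0, term = "cb"),
                   paths["lag_curve"], row.names = FALSE)
  xr <- best$crossbases$cb$fx_spec$boundary
  xg <- seq(xr[1], xr[2], length.out = 50)
  utils::write.csv(predict_exposure_curve(best, lag_pred, xg, x0 = x0,
                                          term = "cb"),
                   paths["exposure_curve"], row.names = FALSE)
  utils::write.csv(as.data.frame(predict_grid(best, xg, lg, x0 = x0,
                                              term = "cb")),
                   paths["grid"], row.names = FALSE)
  scen <- list(
    "20 WLM/year in the last 10 years" = ifelse(lg <= 9, 20, 0),
    "100 WLM/year in the last 10 years" = ifelse(lg <= 9, 100, 0),
    "20 WLM/year in the last 20 years" = ifelse(lg <= 19, 20, 0),
    "20 WLM/year 10-19 years ago" = ifelse(lg >= 10 & lg <= 19, 20, 0),
    "20 WLM/year 30-39 years ago" = ifelse(lg >= 30 & lg <= 39, 20, 0),
    "reference (no exposure)" = rep(x0, length(lg)))
  sc <- do.call(rbind, lapply(names(scen), function(nm)
    cbind(data.frame(scenario = nm),
          cumulative_effect(best, scen[[nm]], x0 = x0, term = "cb"))))
  utils::write.csv(sc, paths["scenarios"], row.names = FALSE)
  utils::write.csv(data.frame(key = c("seed", "l0", "L", "x0",
                                      "n_candidates", "ties"),
                              value = c(seed, l0, L, x0,
                                        length(candidates), "efron")),
                   paths["config"], row.names = FALSE)
  list(selection = sel, cp = cp, paths = paths)
}

#' Serialize a fitted model to a portable text file
#'
#' Writes coefficients, covariance and the basis metadata of every
#' cross-basis term as R source text (readable with [read_fit()]), so a fit
#' can be transported and used for prediction without refitting.
#'
#' @param fit a `"dlnm_fit"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "dlnm_fit"))
  obj <- list(eta = fit$eta, vcov = fit$vcov, loglik = fit$loglik,
              df_total = fit$df_total, n_events = fit$n_events,
              ties = fit$ties, term_index = fit$term_index,
              crossbases = lapply(fit$crossbases, function(cb)
                list(fx = basis_spec_to_list(cb$fx_spec),
                     wl = basis_spec_to_list(cb$wl_spec),
                     lag_grid = cb$lag_grid)))
  dput(obj, file = path)
  invisible(path)
}

#' @rdname write_fit
#' @return `read_fit()`: a `"dlnm_fit"` usable by the prediction functions.
#' @export
read_fit <- function(path) {
  obj <- dget(path)
  cbs <- lapply(obj$crossbases, function(x) {
    fx <- basis_spec_from_list(x$fx)
    wl <- basis_spec_from_list(x$wl)
    structure(list(W = NULL, fx_spec = fx, wl_spec = wl,
                   lag_grid = as.integer(x$lag_grid),
                   column_order = NULL,
                   C = eval_basis(x$lag_grid, wl)$values),
              class = "crossbasis")
  })
  structure(list(eta = obj$eta, vcov = obj$vcov, loglik = obj$loglik,
                 df_total = obj$df_total, n_events = obj$n_events,
                 term_index = obj$term_index, crossbases = cbs,
                 ties = obj$ties),
            class = "dlnm_fit")
}
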