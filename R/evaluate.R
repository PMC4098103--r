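#' Candidate model grid for the simulation study
#'
#' The 36-model grid crossed in the simulation study: 6 exposure-response
#' options (a simple linear term, or quadratic B-splines without intercept
#' and 0 knots, 1 knot at each of three positions, or 2 knots) by 6
#' lag-response options (a constant term, or quadratic B-splines with
#' intercept and 0 knots, 1 knot at each of three positions, or 2 knots).
#' Cross-basis degrees of freedom range from 1 x 1 = 1 to 4 x 5 = 20.
#'
#' @param exposure_knots knot positions offered for the exposure dimension.
#' @param lag_knots knot positions offered for the lag dimension.
#' @param exposure_boundary support of the exposure bases.
#' @param lag_window integer lag window `c(l0, L)`.
#' @param degree B-spline degree (quadratic by default).
#' @return list of `list(fx = , wl = )` candidate pairs (length 36 with the
#'   defaults).
#' @export
candidate_grid <- function(exposure_knots = c(3.3, 5, 6.7),
                           lag_knots = c(13.3, 20, 26.7),
                           exposure_boundary = c(0, 10),
                           lag_window = c(0, 40),
                           degree = 2) {
  stopifnot(length(exposure_knots) == 3L, length(lag_knots) == 3L)
  bs_x <- function(k) basis_spec("bspline", degree = degree, knots = k,
                                 boundary = exposure_boundary,
                                 intercept = FALSE)
  bs_l <- function(k) basis_spec("bspline", degree = degree, knots = k,
                                 boundary = lag_window, intercept = TRUE)
  fx_list <- c(list(basis_spec("linear", boundary = exposure_boundary),
                    bs_x(numeric(0))),
               lapply(exposure_knots, bs_x),
               list(bs_x(exposure_knots[c(1, 3)])))
  wl_list <- c(list(basis_spec("constant", boundary = lag_window),
                    bs_l(numeric(0))),
               lapply(lag_knots, bs_l),
               list(bs_l(lag_knots[c(1, 3)])))
  out <- list()
  for (fx in fx_list) for (wl in wl_list)
    out[[length(out) + 1L]] <- list(fx = fx, wl = wl)
  out
}

#' Fit the candidate grid to one simulated replicate and summarize it
#'
#' Simulates one cohort under the scenario, expands it to counting-process
#' form, fits every candidate cross-basis model, selects the best fit under
#' AIC and under BIC, and evaluates the true and estimated overall
#' cumulative effect for the exposure history of one randomly drawn subject
#' at one randomly drawn time between 41 and 100 (so that performance is
#' measured over the whole range of simulated exposure histories).
#'
#' @param scenario a [scenario_def()] or scenario name.
#' @param ns number of subjects.
#' @param seed integer seed for the replicate.
#' @param grid candidate list from [candidate_grid()].
#' @param ... further arguments to [simulate_dataset()].
#' @return one-row data frame with the true effect `beta_true`, the AIC- and
#'   BIC-selected estimates and standard errors, the selected dimensions
#'   `df_fx_*`, `df_wl_*`, non-linearity/non-constant indicators, the number
#'   of events, and the drawn (subject, time).
#' @export
evaluate_replicate <- function(scenario, ns, seed, grid = candidate_grid(),
                               ...) {
  if (is.character(scenario)) scenario <- scenario_def(scenario)
  sim <- simulate_dataset(scenario, ns, seed = seed, ...)
  cp <- expand_sim_cohort(sim)
  sel <- select_model(cp$histories$x, grid, cp$core,
                      exposure_boundary = grid[[1]]$fx$boundary)
  subj <- sample.int(ns, 1)
  t_eval <- sample(41:100, 1)
  q_h <- exposure_history(sim$profiles[[subj]], t_eval,
                          scenario$l0, scenario$L)
  beta_true <- true_cumulative(q_h, scenario)
  est <- lapply(list(aic = sel$best_aic, bic = sel$best_bic), function(f) {
    cumulative_effect(f, q_h, x0 = 0, term = "cb")
  })
  spec_of <- function(fit) fit$crossbases$cb
  row <- data.frame(
    seed = seed, subject = subj, time = t_eval,
    n_events = sum(cp$core$event),
    beta_true = beta_true,
    beta_aic = est$aic$loghr, se_aic = est$aic$se,
    beta_bic = est$bic$loghr, se_bic = est$bic$se,
    df_fx_aic = basis_dim(spec_of(sel$best_aic)$fx_spec),
    df_wl_aic = basis_dim(spec_of(sel$best_aic)$wl_spec),
    df_fx_bic = basis_dim(spec_of(sel$best_bic)$fx_spec),
    df_wl_bic = basis_dim(spec_of(sel$best_bic)$wl_spec),
    nonlin_aic = spec_of(sel$best_aic)$fx_spec$kind != "linear",
    nonlin_bic = spec_of(sel$best_bic)$fx_spec$kind != "linear",
    noncons_aic = spec_of(sel$best_aic)$wl_spec$kind != "constant",
    noncons_bic = spec_of(sel$best_bic)$wl_spec$kind != "constant")
  row
}

#' Aggregate per-replicate records into performance metrics
#'
#' Computes, separately for AIC- and BIC-selected estimators: relative bias
#' `mean((beta_hat - beta_true) / beta_true)`, coverage
#' `mean(|beta_hat - beta_true| <= z * SE)`, relative RMSE
#' `sqrt(mean(((beta_hat - beta_true) / beta_true)^2))`, the empirical
#' rejection rates for the hypotheses of linearity (`f(x) = x`) and constant
#' risk (`w(l) = c`) — the share of replicates whose selected model is
#' non-linear / non-constant — and the average selected degrees of freedom
#' per dimension.
#'
#' Replicates with `|beta_true|` below `eps` are excluded from the relative
#' metrics (a near-null history makes the ratio meaningless) but retained
#' for coverage and rejection rates; their count is reported.
#'
#' @param records data frame of rows from [evaluate_replicate()].
#' @param level nominal confidence level of the coverage indicator.
#' @param two_sided logical; use the two-sided quantile
#'   `qnorm(1 - (1 - level) / 2)` (default) rather than the one-sided
#'   `qnorm(level)`.
#' @param eps threshold on `|beta_true|` for the relative metrics.
#' @return An object of class `"study_result"`: list with `metrics` (data
#'   frame, one row per criterion), `n_replicates`, `n_degenerate`.
#' @export
aggregate_study <- function(records, level = 0.95, two_sided = TRUE,
                            eps = 1e-8) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  z <- if (two_sided) stats::qnorm(1 - (1 - level) / 2)
       else stats::qnorm(level)
  ok <- abs(records$beta_true) > eps
  one <- function(crit) {
    bh <- records[[paste0("beta_", crit)]]
    se <- records[[paste0("se_", crit)]]
    rel <- (bh[ok] - records$beta_true[ok]) / records$beta_true[ok]
    data.frame(
      criterion = toupper(crit),
      bias = mean(rel),
      coverage = mean(abs(bh - records$beta_true) <= z * se),
      rmse = sqrt(mean(rel^2)),
      reject_linearity = mean(records[[paste0("nonlin_", crit)]]),
      reject_constant = mean(records[[paste0("noncons_", crit)]]),
      avg_df_fx = mean(records[[paste0("df_fx_", crit)]]),
      avg_df_wl = mean(records[[paste0("df_wl_", crit)]]))
  }
  metrics <- rbind(one("aic"), one("bic"))
  structure(list(metrics = metrics, n_replicates = nrow(records),
                 n_degenerate = sum(!ok)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d replicates (%d with near-null true effect)\n",
              x$n_replicates, x$n_degenerate))
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the simulation study for one scenario
#'
#' Repeats [evaluate_replicate()] `m` times with one independent seed per
#' replicate (drawn reproducibly from the master seed) and aggregates the
#' records. Replicates in which every candidate model fails are dropped with
#' a message.
#'
#' @param scenario scenario name or [scenario_def()].
#' @param ns number of subjects per replicate.
#' @param m number of replicates.
#' @param seed master seed.
#' @param grid candidate list from [candidate_grid()].
#' @param ... further arguments to [simulate_dataset()].
#' @return a `"study_result"` with the per-replicate `records` attached.
#' @export
run_study <- function(scenario, ns, m, seed, grid = candidate_grid(), ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    rows[[i]] <- tryCatch(
      evaluate_replicate(scenario, ns, seeds[i], grid = grid, ...),
      error = function(e) {
        message("replicate ", i, " failed: ", conditionMessage(e))
        NULL
      })
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  res <- aggregate_study(records)
  res$records <- records
  res
}
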