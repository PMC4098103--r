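#' Expand a cohort to counting-process form
#'
#' Builds the risk-set expansion of a cohort for Cox regression with
#' time-varying exposure histories, using age as the time axis with delayed
#' entry at the cohort entry age (left truncation). Each subject contributes
#' one (start, stop] interval per event age at which they are at risk, and
#' exposure histories are evaluated at each such age, so covariates vary
#' within subject across risk sets.
#'
#' @param subjects data frame with columns `subject_id`, `entry_age`,
#'   `exit_age`, `event` (0/1) and optionally `year_entry` (calendar year at
#'   entry, used for the linear calendar-time confounder).
#' @param profiles named list of lists of [exposure_profile()] objects, one
#'   list per exposure (e.g. `list(radon = ..., smoking = ...)`), each
#'   indexed like `subjects` rows or matchable by subject id.
#' @param l0,L integer lag window applied to every exposure (default 2-40
#'   years: no effect in the last 2 years nor after 40 years).
#' @param calendar logical; add the calendar year at the risk-set age as a
#'   covariate column (requires `year_entry`).
#' @return An object of class `"cp_data"`: list with `core` (data frame
#'   `subject_id`, `start`, `stop`, `event`), one `"history_matrix"` per
#'   exposure in `histories`, and `calendar` (numeric vector or `NULL`).
#' @export
expand_cohort <- function(subjects, profiles, l0 = 2, L = 40,
                          calendar = !is.null(subjects$year_entry)) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "entry_age", "exit_age", "event")
                %in% names(subjects)))
  if (any(subjects$exit_age <= subjects$entry_age))
    stop("exit_age must exceed entry_age for every subject")
  event_ages <- sort(unique(subjects$exit_age[subjects$event == 1]))
  if (length(event_ages) == 0L) stop("cohort contains no events")
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    a <- event_ages[event_ages > subjects$entry_age[i] &
                    event_ages <= subjects$exit_age[i]]
    if (length(a) == 0L) next  # censored before the first event age
    start <- c(subjects$entry_age[i], a[-length(a)])
    rows[[i]] <- data.frame(
      subject_id = subjects$subject_id[i], start = start, stop = a,
      event = as.integer(a == subjects$exit_age[i] & subjects$event[i] == 1))
  }
  core <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(core) <- NULL
  eval_points <- data.frame(subject_id = core$subject_id, time = core$stop)
  histories <- lapply(profiles, function(pl) {
    ids <- vapply(pl, function(p) as.character(p$subject_id), "")
    miss <- setdiff(as.character(core$subject_id), ids)
    if (length(miss))
      stop("no exposure profile for subject(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    build_history_matrix(pl, eval_points, l0, L)
  })
  cal <- NULL
  if (calendar) {
    if (is.null(subjects$year_entry))
      stop("calendar = TRUE requires a 'year_entry' column")
    pos <- match(core$subject_id, subjects$subject_id)
    cal <- subjects$year_entry[pos] + (core$stop - subjects$entry_age[pos])
  }
  structure(list(core = core, histories = histories, calendar = cal,
                 lag_window = c(l0, L)),
            class = "cp_data")
}

#' @export
print.cp_data <- function(x, ...) {
  cat(sprintf("<cp_data> %d counting-process rows, %d events, exposures: %s\n",
              nrow(x$core), sum(x$core$event),
              paste(names(x$histories), collapse = ", ")))
  invisible(x)
}

# assemble the design matrix from a named list of terms (crossbasis objects,
# matrices, or vectors); returns X plus the column index of each term
assemble_design <- function(terms, n) {
  X <- NULL
  index <- list()
  for (nm in names(terms)) {
    tm <- terms[[nm]]
    m <- if (inherits(tm, "crossbasis")) tm$W else as.matrix(tm)
    if (nrow(m) != n) stop("term '", nm, "' has ", nrow(m),
                           " rows; expected ", n)
    colnames(m) <- paste0(nm, "_", seq_len(ncol(m)))
    index[[nm]] <- (if (is.null(X)) 0L else ncol(X)) + seq_len(ncol(m))
    X <- cbind(X, m)
  }
  list(X = X, index = index)
}

#' Fit a Cox model with cross-basis terms
#'
#' Maximizes the Cox partial likelihood (through [survival::coxph()]) for a
#' counting-process data set whose design matrix is assembled from
#' cross-basis and ordinary covariate terms. The Efron method is the default
#' for tie handling; Breslow is available for cross-checks.
#'
#' @param core data frame with columns `start`, `stop`, `event` (one row per
#'   subject-interval), as produced by [expand_cohort()] or the simulation
#'   expansion.
#' @param terms named list of covariate terms: `"crossbasis"` objects enter
#'   with all their columns and keep their basis metadata for prediction;
#'   numeric matrices/vectors enter as-is. May be empty or `NULL` for the
#'   null model.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `"dlnm_fit"`: list with `eta` (coefficients),
#'   `vcov` (inverse observed information), `loglik` (maximized partial
#'   log-likelihood), `df_total`, `n_events`, `term_index` (columns of each
#'   term), `crossbases` (metadata of each cross-basis term) and `ties`.
#' @export
fit_dlnm_cox <- function(core, terms = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(core),
            all(c("start", "stop", "event") %in% names(core)))
  if (any(core$start >= core$stop))
    stop("every interval must satisfy start < stop")
  d <- sum(core$event)
  if (d < 1L) stop("at least one event is required")
  y <- survival::Surv(core$start, core$stop, core$event)
  cbs <- list()
  if (is.null(terms) || length(terms) == 0L) {
    f <- survival::coxph(y ~ 1, ties = ties)
    return(structure(list(eta = numeric(0),
                          vcov = matrix(0, 0, 0),
                          loglik = as.numeric(f$loglik[1]),
                          df_total = 0L, n_events = d,
                          term_index = list(), crossbases = list(),
                          ties = ties),
                     class = "dlnm_fit"))
  }
  if (is.null(names(terms)) || any(names(terms) == ""))
    stop("all terms must be named")
  des <- assemble_design(terms, nrow(core))
  for (nm in names(terms))
    if (inherits(terms[[nm]], "crossbasis")) cbs[[nm]] <- terms[[nm]]
  X <- des$X
  # agreg.fit is the counting-process partial-likelihood maximizer behind
  # survival::coxph for (start, stop] data; calling it directly skips the
  # formula/model-frame machinery (identical estimates)
  fit <- withCallingHandlers(
    survival::agreg.fit(x = X, y = y, strata = NULL, offset = NULL,
                        init = NULL, control = survival::coxph.control(),
                        weights = rep(1, nrow(X)), method = ties,
                        rownames = NULL),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w)))
        stop("Cox model did not converge after ",
             survival::coxph.control()$iter.max, " iterations (",
             ncol(X), " coefficients, ", d, " events)")
      invokeRestart("muffleWarning")
    })
  if (anyNA(fit$coefficients)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  eta <- unname(fit$coefficients)
  V <- unname(fit$var)
  structure(list(eta = eta, vcov = V,
                 loglik = as.numeric(fit$loglik[2]),
                 df_total = length(eta), n_events = d,
                 term_index = des$index, crossbases = cbs,
                 ties = ties),
            class = "dlnm_fit")
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat(sprintf("<dlnm_fit> %d coefficients, %d events, loglik %.2f (%s ties)\n",
              x$df_total, x$n_events, x$loglik, x$ties))
  ab <- aic_bic(x)
  cat(sprintf("  AIC %.1f  BIC %.1f\n", ab[1], ab[2]))
  invisible(x)
}

#' Survival-adapted AIC and BIC
#'
#' `AIC = -2 * loglik + 2 * k` and `BIC = -2 * loglik + log(d) * k`, where
#' `loglik` is the maximized partial log-likelihood, `k` the number of all
#' estimated regression coefficients (cross-basis terms plus confounders)
#' and `d` the number of uncensored events. The BIC penalty `log(d)` adapts
#' the usual sample-size penalty to censored survival data.
#'
#' @param fit a `"dlnm_fit"`.
#' @return named numeric vector `c(AIC = , BIC = )`.
#' @export
aic_bic <- function(fit) {
  stopifnot(inherits(fit, "dlnm_fit"))
  if (fit$n_events == 0L) stop("no uncensored events: BIC undefined")
  k <- fit$df_total
  c(AIC = -2 * fit$loglik + 2 * k,
    BIC = -2 * fit$loglik + log(fit$n_events) * k)
}

#' Fit a grid of cross-basis candidates and select by AIC and BIC
#'
#' Rebuilds the exposure-of-interest cross-basis for every `(f(x), w(l))`
#' candidate pair, refits the Cox model with any fixed confounder terms, and
#' returns the best fit under each criterion together with the full
#' criterion table. Ties are broken in favour of fewer coefficients, then
#' candidate order.
#'
#' @param Q a `"history_matrix"` of the exposure of interest, aligned with
#'   `core` rows.
#' @param candidates list of `list(fx = basis_spec, wl = basis_spec)` pairs.
#' @param core counting-process data frame (see [fit_dlnm_cox()]).
#' @param extra named list of additional fixed terms (confounder cross-bases,
#'   calendar column, ...), or `NULL`.
#' @param ties tie-handling method.
#' @param exposure_boundary optional length-2 numeric; fixes the exposure
#'   basis boundary for all candidates (defaults to the observed range of
#'   `Q` per candidate).
#' @return list with `best_aic`, `best_bic` (both `"dlnm_fit"`), and `table`
#'   (data frame: candidate, fx, wl, df — the cross-basis df, k — all model
#'   coefficients including confounders, loglik, AIC, BIC, error).
#' @export
select_model <- function(Q, candidates, core, extra = NULL,
                         ties = "efron", exposure_boundary = NULL) {
  stopifnot(length(candidates) >= 1L)
  if (inherits(Q, "history_matrix")) {
    lag_grid <- Q$lag_grid
    Qm <- Q$Q
  } else stop("Q must be a history_matrix")
  tab <- data.frame(candidate = seq_along(candidates),
                    fx = NA_character_, wl = NA_character_,
                    df = NA_integer_, k = NA_integer_, loglik = NA_real_,
                    AIC = NA_real_, BIC = NA_real_,
                    error = NA_character_, stringsAsFactors = FALSE)
  fits <- vector("list", length(candidates))
  # evaluate each distinct exposure / lag basis once and share across the grid
  fx_specs <- lapply(candidates, function(cand) {
    fx <- cand$fx
    if (!is.null(exposure_boundary) && is.null(fx$boundary))
      fx$boundary <- exposure_boundary
    resolve_boundary(fx, as.numeric(Qm))
  })
  wl_specs <- lapply(candidates, function(cand)
    resolve_boundary(cand$wl, as.numeric(lag_grid)))
  fx_key <- vapply(fx_specs, function(s) paste(deparse(unclass(s)),
                                               collapse = ""), "")
  wl_key <- vapply(wl_specs, function(s) paste(deparse(unclass(s)),
                                               collapse = ""), "")
  Rall_cache <- lapply(fx_specs[!duplicated(fx_key)], function(s) {
    vals <- eval_basis(as.numeric(Qm), s)$values
    lapply(seq_len(ncol(vals)), function(j) matrix(vals[, j], nrow = nrow(Qm)))
  })
  names(Rall_cache) <- fx_key[!duplicated(fx_key)]
  C_cache <- lapply(wl_specs[!duplicated(wl_key)], function(s)
    eval_basis(lag_grid, s)$values)
  names(C_cache) <- wl_key[!duplicated(wl_key)]
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fx <- fx_specs[[i]]; wl <- wl_specs[[i]]
    tab$fx[i] <- describe_spec(fx)
    tab$wl[i] <- describe_spec(wl)
    res <- tryCatch({
      if (fx$intercept)
        stop("the exposure basis f(x) must be defined without an intercept")
      cb <- crossbasis_from_parts(Rall_cache[[fx_key[i]]],
                                  C_cache[[wl_key[i]]],
                                  nrow(Qm), fx, wl, lag_grid,
                                  check_rank = FALSE)
      fit <- fit_dlnm_cox(core, c(list(cb = cb), extra), ties = ties)
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      tab$error[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      ab <- aic_bic(res)
      tab$df[i] <- crossbasis_df(cand$fx, cand$wl)
      tab$k[i] <- res$df_total
      tab$loglik[i] <- res$loglik
      tab$AIC[i] <- ab[1]; tab$BIC[i] <- ab[2]
    }
  }
  ok <- which(!is.na(tab$AIC))
  if (length(ok) == 0L)
    stop("all candidate models failed to fit")
  pick <- function(crit) {
    o <- ok[order(tab[[crit]][ok], tab$df[ok], ok)]
    o[1]
  }
  ia <- pick("AIC"); ib <- pick("BIC")
  list(best_aic = fits[[ia]], best_bic = fits[[ib]],
       which_aic = ia, which_bic = ib, table = tab)
}

describe_spec <- function(spec) {
  paste0(spec$kind,
         if (spec$kind %in% c("bspline", "nspline", "step", "threshold") &&
             length(spec$knots))
           paste0("(", paste(signif(spec$knots, 4), collapse = ","), ")")
         else "",
         if (spec$intercept) "+ic" else "")
}
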