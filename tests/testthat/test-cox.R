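toy_cohort <- function() {
  profs <- list(exposure_profile("a", 1:50, rep(1, 50)),
                exposure_profile("b", 1:50, rep(2, 50)),
                exposure_profile("c", 1:50, rep(0, 50)))
  subjects <- data.frame(subject_id = c("a", "b", "c"),
                         entry_age = c(10, 10, 10),
                         exit_age = c(40, 35, 20),
                         event = c(1, 1, 0),
                         year_entry = c(1950, 1952, 1955))
  list(subjects = subjects, profiles = list(x = profs))
}

test_that("cohort expansion builds one row per risk set with delayed entry", {
  tc <- toy_cohort()
  cp <- expand_cohort(tc$subjects, tc$profiles, l0 = 2, L = 40)
  # event ages 35 and 40; subject c (censored at 20) is at risk at neither
  expect_false("c" %in% cp$core$subject_id)
  expect_equal(sum(cp$core$event), 2)
  # a is at risk at both event ages, b only at 35
  expect_equal(nrow(cp$core[cp$core$subject_id == "a", ]), 2)
  expect_equal(nrow(cp$core[cp$core$subject_id == "b", ]), 1)
  expect_true(all(cp$core$start < cp$core$stop))
  # calendar year advances with age from the entry year
  yr <- c(a = 1950, b = 1952)
  expect_equal(cp$calendar,
               unname(yr[cp$core$subject_id]) + cp$core$stop - 10)
  # censored subject entirely before the first event age contributes nothing
  tc$subjects$exit_age[3] <- 12
  cp2 <- expand_cohort(tc$subjects, tc$profiles)
  expect_false("c" %in% cp2$core$subject_id)
})

test_that("expanded histories obey the one-year shift identity across risk sets", {
  set.seed(10)
  profs <- lapply(1:5, function(i)
    exposure_profile(paste0("s", i), 1:80, runif(80, 0, 10)))
  subjects <- data.frame(subject_id = paste0("s", 1:5),
                         entry_age = 5,
                         exit_age = c(60, 61, 70, 75, 80),
                         event = c(1, 1, 1, 0, 1))
  cp <- expand_cohort(subjects, list(x = profs), l0 = 2, L = 40)
  Q <- cp$histories$x$Q
  idx <- which(cp$core$subject_id == "s3" & cp$core$stop %in% c(60, 61))
  expect_equal(unname(Q[idx[2], -1]), unname(Q[idx[1], -ncol(Q)]))
})

test_that("the partial-likelihood fit matches a hand-coded oracle on a tiny data set", {
  # three subjects, two events, one binary covariate, no ties
  core <- data.frame(start = c(0, 0, 0), stop = c(1, 2, 3),
                     event = c(1, 1, 0))
  x <- c(1, 0, 1)
  # brute-force partial likelihood (untied; Efron = Breslow here)
  pl <- function(b) {
    l1 <- b * x[1] - log(sum(exp(b * x)))
    l2 <- b * x[2] - log(sum(exp(b * x[2:3])))
    l1 + l2
  }
  opt <- optimize(pl, c(-10, 10), maximum = TRUE, tol = 1e-10)
  fit <- fit_dlnm_cox(core, list(z = matrix(x)))
  expect_equal(fit$eta, opt$maximum, tolerance = 1e-5)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-8)
  # model-based variance equals inverse observed information at the optimum
  h <- 1e-4
  info <- -(pl(fit$eta + h) - 2 * pl(fit$eta) + pl(fit$eta - h)) / h^2
  expect_equal(drop(fit$vcov), 1 / info, tolerance = 1e-4)
})

test_that("the null model log-likelihood has the closed risk-set-product form", {
  core <- data.frame(start = rep(0, 5), stop = c(2, 4, 5, 7, 9),
                     event = c(1, 0, 1, 1, 0))
  fit <- fit_dlnm_cox(core, NULL)
  expect_identical(fit$df_total, 0L)
  # events at 2, 5, 7 with risk sets of sizes 5, 3, 2
  expect_equal(fit$loglik, -(log(5) + log(3) + log(2)), tolerance = 1e-10)
  ab <- aic_bic(fit)
  expect_equal(unname(ab["AIC"]), unname(ab["BIC"]))
  expect_equal(unname(ab["AIC"]), -2 * fit$loglik)
})

test_that("Efron and Breslow agree exactly on tie-free data", {
  set.seed(11)
  n <- 40
  core <- data.frame(start = rep(0, n), stop = sort(runif(n, 1, 100)),
                     event = rbinom(n, 1, 0.7))
  X <- matrix(rnorm(2 * n), n)
  fe <- fit_dlnm_cox(core, list(x = X), ties = "efron")
  fb <- fit_dlnm_cox(core, list(x = X), ties = "breslow")
  expect_equal(fe$eta, fb$eta, tolerance = 1e-12)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-12)
})

test_that("estimates are invariant to row order of the counting-process data", {
  set.seed(12)
  sim <- simulate_dataset("linear-constant", 60, seed = 31)
  cp <- expand_sim_cohort(sim)
  cb <- build_crossbasis(cp$histories$x, basis_spec("linear", boundary = c(0, 10)),
                         basis_spec("constant"))
  f1 <- fit_dlnm_cox(cp$core, list(cb = cb))
  perm <- sample(nrow(cp$core))
  cb2 <- cb; cb2$W <- cb$W[perm, , drop = FALSE]
  f2 <- fit_dlnm_cox(cp$core[perm, ], list(cb = cb2))
  expect_equal(f1$eta, f2$eta, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("survival-adapted AIC/BIC use all coefficients and the event count", {
  fake <- function(ll, k, d)
    structure(list(loglik = ll, df_total = k, n_events = d),
              class = "dlnm_fit")
  ab1 <- aic_bic(fake(-1112.0, 6, 258))
  expect_equal(unname(ab1["AIC"]), 2236.0)
  expect_equal(unname(ab1["BIC"]), 2257.3, tolerance = 1e-4)
  ab2 <- aic_bic(fake(-1111.45, 8, 258))
  expect_equal(unname(ab2["AIC"]), 2238.9)
  expect_equal(unname(ab2["BIC"]), 2267.3, tolerance = 1e-4)
  # the identity BIC - AIC = (log d - 2) k
  for (k in c(1, 6, 8, 20)) {
    ab <- aic_bic(fake(-500, k, 258))
    expect_equal(unname(ab["BIC"] - ab["AIC"]), (log(258) - 2) * k,
                 tolerance = 1e-12)
  }
})

test_that("rank deficiency is reported with the offending columns", {
  set.seed(13)
  core <- data.frame(start = rep(0, 30), stop = sort(runif(30, 1, 50)),
                     event = rbinom(30, 1, 0.8))
  x <- rnorm(30)
  X <- cbind(x, 2 * x)
  expect_error(fit_dlnm_cox(core, list(x = X)), "rank deficient")
})

test_that("model selection returns the criterion minimizers with sane tie-breaking", {
  set.seed(14)
  sim <- simulate_dataset("linear-constant", 150, seed = 41)
  cp <- expand_sim_cohort(sim)
  cands <- list(
    list(fx = basis_spec("linear", boundary = c(0, 10)),
         wl = basis_spec("constant", boundary = c(0, 40))),
    list(fx = basis_spec("bspline", 2, 5, c(0, 10)),
         wl = basis_spec("bspline", 2, 20, c(0, 40), intercept = TRUE)))
  sel <- select_model(cp$histories$x, cands, cp$core)
  expect_s3_class(sel$best_aic, "dlnm_fit")
  expect_equal(nrow(sel$table), 2)
  expect_true(all(is.na(sel$table$error)))
  # identity holds column-wise in the criterion table
  expect_equal(sel$table$BIC - sel$table$AIC,
               (log(sum(cp$core$event)) - 2) * sel$table$k,
               tolerance = 1e-10)
  # a single candidate wins under both criteria
  sel1 <- select_model(cp$histories$x, cands[1], cp$core)
  expect_identical(sel1$which_aic, 1L)
  expect_identical(sel1$which_bic, 1L)
})

test_that("Wald tests hold their size on null data", {
  set.seed(15)
  null_sc <- scenario_def("linear-constant", amplitude = 0)
  rej <- vapply(1:120, function(i) {
    sim <- simulate_dataset(null_sc, 100, seed = 1000 + i)
    cp <- expand_sim_cohort(sim)
    cb <- build_crossbasis(cp$histories$x,
                           basis_spec("linear", boundary = c(0, 10)),
                           basis_spec("constant", boundary = c(0, 40)))
    f <- fit_dlnm_cox(cp$core, list(cb = cb))
    abs(f$eta / sqrt(drop(f$vcov))) > qnorm(0.975)
  }, logical(1))
  # binomial 99% band around 0.05 with 120 replicates
  expect_gt(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 120))
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 120))
})
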