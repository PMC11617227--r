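mk_recalls <- function(x_by_person, weights = NULL) {
  # build a person-day tibble from a named list of day vectors
  ids <- names(x_by_person)
  k <- lengths(x_by_person)
  if (is.null(weights)) weights <- rep(1, length(ids))
  tibble::tibble(
    person_id = rep(ids, k),
    day = unlist(lapply(k, seq_len)),
    survey_weight = rep(weights, k),
    intake = unlist(x_by_person)
  )
}

test_that("with no within-person noise the usual intake is the person mean", {
  rc <- mk_recalls(list(a = c(5, 5), b = c(9, 9), c = c(2, 2)))
  m <- fit_usual(rc, "intake")
  expect_equal(m$within_sd, 0)
  expect_equal(m$persons$usual, c(5, 9, 2))
})

test_that("fitting is invariant to person order and needs replicates", {
  rc <- mk_recalls(list(a = c(5, 7), b = c(9, 14), c = c(2, 3), d = 4))
  m1 <- fit_usual(rc, "intake")
  m2 <- fit_usual(rc[sample(nrow(rc)), ], "intake")
  expect_equal(m1$persons, m2$persons)
  expect_equal(m1$between_sd, m2$between_sd)

  no_rep <- mk_recalls(list(a = 5, b = 9, c = 2))
  expect_error(fit_usual(no_rep, "intake"), "replicate")
})

test_that("shrinkage reduces the spread of estimated usual intakes", {
  r <- small_recalls(n_wra = 400, n_children = 0, seed = 8,
                     replicate_fraction = 1)
  m <- fit_usual(r$recalls, "vitamin_a")
  person_means <- exp(m$persons$person_mean_t)
  expect_lt(var(log(m$persons$usual)), var(log(person_means)))
})

test_that("variance components and inadequacy are recovered from truth", {
  cfg <- synthetic_config(n_wra = 2000, n_children = 0, seed = 23,
                          recall_days = 2, replicate_fraction = 1,
                          within_person_cv = 0.4, between_person_cv = 0.4)
  r <- generate_recalls(cfg, REFS)
  tr <- survey_truth(r)$vitamin_a
  m <- fit_usual(r$recalls, "vitamin_a")
  expect_equal(m$within_sd, tr$sdlog_within, tolerance = 0.10)
  expect_equal(m$between_sd, tr$sdlog_between, tolerance = 0.10)

  # estimated prevalence below the stratum EARs within 3 pp of analytic truth
  p <- m$persons
  ear <- REFS$nutrients$ear[REFS$nutrients$nutrient == "vitamin_a"]
  names(ear) <- REFS$nutrients$group_id[REFS$nutrients$nutrient == "vitamin_a"]
  est <- prevalence_ear_cutpoint(m, ear[p$group_id], n_boot = 0)
  shares <- table(p$group_id) / nrow(p)
  truth_pct <- 100 * sum(shares * pnorm(
    (log(ear[names(shares)]) - tr$meanlog[["wra"]]) / tr$sdlog_between))
  expect_lt(abs(est$point - truth_pct), 3)
})

test_that("cut-point prevalence matches the closed-form oracle", {
  r <- small_recalls(n_wra = 1500, n_children = 0, seed = 31,
                     replicate_fraction = 1)
  m <- fit_usual(r$recalls, "zinc")
  tr <- survey_truth(r)$zinc
  thr <- exp(tr$meanlog[["wra"]])   # symmetric: true prevalence 50%
  est <- prevalence_ear_cutpoint(m, thr, n_boot = 0)
  expect_lt(abs(est$point - 50), 3)
  expect_equal(prevalence_ear_cutpoint(m, 1e-9, n_boot = 0)$point, 0)
  expect_equal(prevalence_ear_cutpoint(m, 1e9, n_boot = 0)$point, 100)
})

test_that("full-probability prevalence equals the quadrature oracle", {
  set.seed(41)
  absorbed <- c(0, runif(60, 0.1, 3))
  w <- runif(61, 0.5, 2)
  meanlog <- log(1.05); sdlog <- 0.2
  est <- prevalence_full_probability(absorbed, meanlog, sdlog, w, n_boot = 0)
  oracle_one <- vapply(absorbed, function(x) {
    if (x <= 0) return(1)
    stats::integrate(function(t) dlnorm(t, meanlog, sdlog), x, Inf,
                     rel.tol = 1e-10)$value
  }, 0)
  expect_equal(est$point, 100 * sum(w * oracle_one) / sum(w),
               tolerance = 1e-4)
  expect_equal(prevalence_full_probability(rep(100, 5), meanlog, sdlog,
                                           n_boot = 0)$point, 0,
               tolerance = 1e-6)
  expect_error(prevalence_full_probability(1, NA, sdlog), "missing")
})

test_that("fortificant is added per person-day before fitting", {
  rc <- mk_recalls(list(a = c(5, 5), b = c(9, 9)))
  rc$bouillon_g <- c(1, 1, 0.5, 0.5)
  rc$vitamin_a <- rc$intake
  same <- add_then_shrink_fortificant(rc, "vitamin_a", 0)
  expect_equal(same$vitamin_a, rc$vitamin_a)
  up <- add_then_shrink_fortificant(rc, "vitamin_a", 120)
  expect_equal(up$vitamin_a - rc$vitamin_a, rc$bouillon_g * 120,
               ignore_attr = TRUE)
  # 2 ug B12/g on 0.5 g bouillon adds exactly 1 ug that day
  rc$vitamin_b12 <- 1
  b <- add_then_shrink_fortificant(rc, "vitamin_b12", 2)
  expect_equal(b$vitamin_b12[3] - 1, 1.0)
  expect_error(add_then_shrink_fortificant(rc, "vitamin_a", -1),
               "nonnegative")
})

test_that("breast-milk nutrients shift usual intakes after fitting", {
  rc <- mk_recalls(list(a = c(5, 5), b = c(5, 5)))
  m <- fit_usual(rc, "intake")
  m$persons$breastfed <- c(TRUE, FALSE)
  m$persons$age_months <- c(10, 30)
  vols <- tibble::tibble(age_low_months = c(6, 9), age_high_months = c(9, 12),
                         milk_g_day = c(674, 616))
  comp <- tibble::tibble(nutrient = "intake", amount_per_g = 0.5)
  m2 <- shrink_then_add_breastmilk(m, vols, comp)
  expect_equal(m2$persons$usual, c(5 + 616 * 0.5, 5))  # only the breastfed
  # zero milk volume leaves intakes unchanged
  vols0 <- vols; vols0$milk_g_day <- 0
  expect_equal(shrink_then_add_breastmilk(m, vols0, comp)$persons$usual,
               c(5, 5))
  # a breastfed child outside the configured bands is an error
  m$persons$age_months <- c(40, 30)
  expect_error(shrink_then_add_breastmilk(m, vols, comp), "age bands")
})

test_that("post-stratification combines stratum prevalences by shares", {
  mk_est <- function(point, boot = numeric(0)) {
    structure(tibble::tibble(point = point, ci_low = point, ci_high = point,
                             n_effective = 10), boot = boot)
  }
  expect_equal(poststratify_6_59(list(mk_est(33)), 1)$point, 33)
  expect_equal(poststratify_6_59(list(mk_est(10), mk_est(50)),
                                 c(0.2, 0.8))$point, 42)
  expect_error(poststratify_6_59(list(mk_est(1), mk_est(2)), c(0.3, 0.6)),
               "sum to 1")
  # bootstrap replicates combine replicate-wise
  e1 <- mk_est(10, boot = c(8, 10, 12))
  e2 <- mk_est(50, boot = c(45, 50, 55))
  out <- poststratify_6_59(list(e1, e2), c(0.5, 0.5))
  expect_equal(attr(out, "boot"), c(26.5, 30, 33.5))
})

test_that("proportionally sampled strata reproduce the pooled estimate", {
  set.seed(61)
  n <- 1000; share_a <- 0.3
  stratum <- c(rep("a", n * share_a), rep("b", n * (1 - share_a)))
  x <- ifelse(stratum == "a", runif(n, 0, 2), runif(n, 1, 4))
  ind <- as.numeric(x < 1.5)
  pooled <- weighted_prevalence(ind, rep(1, n))
  es <- lapply(c("a", "b"), function(s) {
    structure(tibble::tibble(point = weighted_prevalence(ind[stratum == s]),
                             ci_low = 0, ci_high = 100,
                             n_effective = sum(stratum == s)),
              boot = numeric(0))
  })
  expect_equal(poststratify_6_59(es, c(share_a, 1 - share_a))$point, pooled,
               tolerance = 1e-9)
})
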