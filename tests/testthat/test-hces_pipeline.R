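test_that("AME weights anchor to the reference male and add up", {
  m <- tibble::tibble(household_id = 1, member_id = c("a", "b"),
                      sex = c("male", "female"), age_months = c(300, 300),
                      physiological_status = "none")
  w <- ame_weights(m, REFS)
  expect_equal(w$ame_weight[1], 1.0)           # male 25 y
  expect_equal(w$ame_weight[2], 2400 / 2900)   # WRA, nonpregnant energy req
  expect_equal(sum(w$ame_weight), 1 + 2400 / 2900)
  # a female with energy requirement 2200 would weigh 0.7586; check the rule
  expect_equal(round(2200 / 2900, 4), 0.7586)
  # unmatched stratum errors and names the member
  bad <- m; bad$age_months[2] <- 20000
  expect_error(ame_weights(bad, REFS), "b")
})

test_that("outlier truncation caps at the 95th percentile", {
  expect_equal(truncate_outliers(rep(3, 100)), rep(3, 100),
               ignore_attr = TRUE)

  x <- as.numeric(1:100)
  p95 <- unname(quantile(x, 0.95, type = 7))  # brute-force percentile oracle
  tr <- truncate_outliers(x)
  expect_equal(max(tr), p95)
  expect_equal(sum(tr > p95), 0)
  expect_equal(tr[x <= p95], x[x <= p95], ignore_attr = TRUE)

  y <- c(rep(0, 99), 500)
  p95y <- unname(quantile(y, 0.95, type = 7))
  expect_equal(max(truncate_outliers(y)), p95y)

  # below min_n: passes through, logged in the attribute
  z <- c(1, 2, 3, 1000)
  out <- truncate_outliers(z)
  expect_equal(as.numeric(out), z)
  expect_false(attr(out, "truncation")$applied)
  # empty column passes through
  expect_length(truncate_outliers(numeric(0)), 0)
})

test_that("household density is total nutrient over total energy per 1000", {
  cons <- tibble::tibble(household_id = c(1, 1), food = c("staple", "greens"),
                         g_day = c(475, 200))
  h <- tiny_hces(cons)
  pr <- household_density(h, REFS, truncate = FALSE)
  energy <- 475 * 4 + 200 * 0.5                 # 2000 kcal
  expect_equal(pr$energy_kcal_ame, energy)      # single member, AME 1
  expect_equal(pr$dens_vitamin_a, 200 * 2 / energy * 1000)  # 400/2000 -> 200
  expect_equal(pr$dens_iron, (475 * 0.02 + 200 * 0.02) / energy * 1000)

  # doubling all quantities leaves densities unchanged
  cons2 <- cons; cons2$g_day <- cons$g_day * 2
  pr2 <- household_density(tiny_hces(cons2), REFS, truncate = FALSE)
  expect_equal(pr2[, grep("^dens_", names(pr2))],
               pr[, grep("^dens_", names(pr))])

  # single-food diet: density is that food's nutrient-to-energy ratio x 1000
  pr3 <- household_density(
    tiny_hces(tibble::tibble(household_id = 1, food = "greens", g_day = 123)),
    REFS, truncate = FALSE)
  expect_equal(pr3$dens_vitamin_a, 2 / 0.5 * 1000)

  # missing composition entry is an error, not silently zero
  h4 <- tiny_hces(tibble::tibble(household_id = 1, food = "mystery",
                                 g_day = 10))
  expect_error(household_density(h4, REFS, truncate = FALSE), "mystery")
})

test_that("zero-energy households are excluded and logged", {
  cons <- tibble::tibble(household_id = c(1, 2), food = "staple",
                         g_day = c(100, 0))
  pr <- household_density(tiny_hces(cons), REFS, truncate = FALSE)
  expect_equal(pr$household_id, 1)
  expect_equal(attr(pr, "excluded"), 2)
})

test_that("adding foods moves densities the right way", {
  base <- tibble::tibble(household_id = 1, food = c("staple", "greens"),
                         g_day = c(400, 100))
  fc <- tiny_hces(base)$food_composition
  # a nutrient-free, energy-free food changes nothing
  fc_null <- rbind(fc, tibble::tibble(
    food = "water", energy_kcal_g = 0, vitamin_a_ug_g = 0, retinol_ug_g = 0,
    folate_ug_g = 0, folic_acid_ug_g = 0, vitamin_b12_ug_g = 0, iron_mg_g = 0,
    zinc_mg_g = 0, phytate_mg_g = 0, vehicle = "none",
    median_g_ame_day = NA, log_sd = NA))
  with_water <- rbind(base, tibble::tibble(household_id = 1, food = "water",
                                           g_day = 500))
  pr0 <- household_density(tiny_hces(base, food_composition = fc_null),
                           REFS, truncate = FALSE)
  pr1 <- household_density(tiny_hces(with_water, food_composition = fc_null),
                           REFS, truncate = FALSE)
  expect_equal(pr1[, grep("^dens_", names(pr1))],
               pr0[, grep("^dens_", names(pr0))])
  # energy without the nutrient strictly lowers every nutrient density
  with_oil <- rbind(base, tibble::tibble(household_id = 1, food = "oilfood",
                                         g_day = 50))
  pr2 <- household_density(tiny_hces(with_oil, food_composition = fc_null),
                           REFS, truncate = FALSE)
  expect_lt(pr2$dens_vitamin_a, pr0$dens_vitamin_a)
  expect_lt(pr2$dens_iron, pr0$dens_iron)
})

test_that("member selection is uniform, deterministic, and excludes
           households without eligible members", {
  m <- tibble::tibble(
    household_id = c(1, 1, 2, 3),
    member_id = c("w1", "w2", "m1", "c1"),
    sex = c("female", "female", "male", "female"),
    age_months = c(300, 400, 300, 24)
  )
  s1 <- select_member(m, "wra", REFS, seed = 7)
  expect_identical(s1, select_member(m, "wra", REFS, seed = 7))
  expect_equal(s1$household_id, 1)              # only household 1 has a WRA
  s_men <- select_member(m, "men", REFS, seed = 7)
  expect_equal(s_men$member_id, "m1")           # single eligible member
  expect_equal(nrow(select_member(m[m$household_id == 3, ], "men", REFS)), 0)

  # two eligible members: each picked about half the time over many seeds
  picks <- vapply(1:2000, function(s) {
    select_member(m, "wra", REFS, seed = s)$member_id
  }, "")
  expect_equal(mean(picks == "w1"), 0.5, tolerance = 0.05)
})

test_that("density prevalence counts weighted households correctly", {
  expect_equal(density_prevalence(c(1, 3), 2, direction = "below",
                                  n_boot = 0)$point, 50)
  expect_equal(density_prevalence(c(5, 6, 7), 2, direction = "below",
                                  n_boot = 0)$point, 0)
  # weighted oracle comparison
  set.seed(31)
  d <- runif(500, 0, 10); w <- runif(500, 0.2, 3); thr <- 4
  oracle <- 100 * sum(w * (d < thr)) / sum(w)
  expect_equal(density_prevalence(d, thr, w, "below", n_boot = 0)$point,
               oracle)
  # invariance to uniform weight rescaling
  expect_equal(density_prevalence(d, thr, w * 17, "below", n_boot = 0)$point,
               oracle)
  expect_error(density_prevalence(d, thr, w * 0, "below", n_boot = 0),
               "positive")
  # bootstrap CI brackets the point estimate
  est <- density_prevalence(d, thr, w, "below", n_boot = 200, seed = 1)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
})

test_that("iron full-probability risk matches closed form and Monte Carlo", {
  meanlog <- log(1.46); sdlog <- 0.5; er <- 2400
  dens <- 0.55  # absorbed mg / 1000 kcal
  est <- iron_density_probability(dens / 0.10, meanlog, sdlog, er,
                                  absorption_fraction = 0.10, n_boot = 0)
  closed <- plnorm(dens * er / 1000, meanlog, sdlog, lower.tail = FALSE)
  expect_equal(est$point, 100 * closed, tolerance = 1e-10)
  set.seed(77)
  mc <- mean(rlnorm(1e6, meanlog, sdlog) > dens * er / 1000)
  expect_equal(est$point / 100, mc, tolerance = 0.002)

  # boundaries: absorbed density far above support -> 0; zero intake -> 1
  expect_equal(iron_density_probability(1e6, meanlog, sdlog, er,
                                        n_boot = 0)$point, 0)
  expect_equal(iron_density_probability(0, meanlog, sdlog, er,
                                        n_boot = 0)$point, 100)
  expect_error(iron_density_probability(1, meanlog, sdlog, er,
                                        absorption_fraction = 0), "\\(0, 1\\]")
  expect_error(iron_density_probability(1, NA, sdlog, er), "missing")
})

test_that("full-probability converges to the cut-point rule as absorption
           tends to 1 with a point-mass requirement", {
  set.seed(5)
  dens <- runif(300, 0, 2)
  req <- 1.2; er <- 2000
  # near-degenerate requirement distribution around req
  est <- iron_density_probability(dens, log(req), 1e-9, er,
                                  absorption_fraction = 1, n_boot = 0)
  cut <- density_prevalence(dens * er / 1000, req, direction = "below",
                            n_boot = 0)
  expect_equal(est$point, cut$point, tolerance = 1e-6)
})

test_that("prevalences are invariant to uniform survey-weight rescaling", {
  h <- small_hces(n = 250, seed = 13)
  a1 <- assess_hces(h, REFS, n_boot = 0, seed = 2)
  h2 <- h; h2$households$survey_weight <- h$households$survey_weight * 40
  a2 <- assess_hces(h2, REFS, n_boot = 0, seed = 2)
  expect_equal(a1$point, a2$point, tolerance = 1e-12)
})
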