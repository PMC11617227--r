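test_that("level grids span the modeled ranges with 7 increasing levels", {
  expect_equal(range(default_level_grid("vitamin_a")), c(20, 250))
  expect_equal(range(default_level_grid("folic_acid")), c(20, 120))
  expect_equal(range(default_level_grid("vitamin_b12")), c(0.2, 2.0))
  expect_equal(range(default_level_grid("iron")), c(0.6, 5))
  expect_equal(range(default_level_grid("zinc")), c(0.6, 5))
  named_interior <- list(vitamin_a = c(40, 80, 120, 160, 200),
                         folic_acid = c(40, 80), vitamin_b12 = 1.2,
                         iron = c(1.8, 3), zinc = c(1.2, 3))
  for (nu in names(named_interior)) {
    g <- default_level_grid(nu)
    expect_length(g, 7)
    expect_true(all(diff(g) > 0))
    expect_true(all(named_interior[[nu]] %in% g))
  }
  expect_error(default_level_grid("selenium"), "no default level grid")
})

test_that("bouillon density addition follows the published arithmetic", {
  pr <- tibble::tibble(bouillon_g_ame = c(4, 0), energy_kcal_ame = 8000,
                       dens_vitamin_a = c(10, 10))
  # 4 g/d x 120 ug/g / 8000 kcal x 1000 = +60 ug/1000 kcal
  up <- apply_bouillon_hces(pr, "vitamin_a", 120)
  expect_equal(up$dens_vitamin_a, c(70, 10))   # non-consumer unchanged
  # linear in level
  up2 <- apply_bouillon_hces(pr, "vitamin_a", 240)
  expect_equal(up2$dens_vitamin_a - pr$dens_vitamin_a,
               2 * (up$dens_vitamin_a - pr$dens_vitamin_a))
  expect_error(apply_bouillon_hces(pr, "vitamin_a", -5), "nonnegative")
})

test_that("staple content modes: status quo, target, none", {
  sq <- staple_content(REFS$standards, "Cameroon", "status_quo")
  expect_equal(sq$content[sq$vehicle == "oil"], 9)
  tg <- staple_content(REFS$standards, "Cameroon", "target")
  expect_equal(tg$content[tg$vehicle == "oil"], 12)
  expect_equal(nrow(staple_content(REFS$standards, "Cameroon", "none")), 0)
  expect_error(staple_content(REFS$standards, "Atlantis"), "no fortification")
})

test_that("an all-zero scenario reproduces the baseline exactly", {
  h <- small_hces(n = 200, seed = 19)
  sc <- fortification_scenario("null", staple_mode = "none",
                               bouillon_levels = c(vitamin_a = 0, iron = 0))
  res <- run_scenario(h, sc, REFS, n_boot = 0)
  expect_equal(res$point, res$baseline, tolerance = 1e-12)
  expect_equal(res$pp_change, rep(0, nrow(res)), tolerance = 1e-12)
})

test_that("a constructed population drops by exactly the crossing fraction", {
  # households built so that a known fraction sits between the baseline
  # density and baseline + added density for one level
  n <- 100
  ame25 <- 1  # single adult male per household
  cons <- dplyr::bind_rows(
    tibble::tibble(household_id = 1:n, food = "staple", g_day = 500),
    tibble::tibble(household_id = 1:n, food = "greens",
                   g_day = seq(1, 200, length.out = n)),
    tibble::tibble(household_id = 1:n, food = "bouillon", g_day = 2)
  )
  h <- tiny_hces(cons, members = tibble::tibble(
    household_id = 1:n, member_id = paste0("m", 1:n), sex = "male",
    age_months = 300, physiological_status = "none"))
  pr <- household_density(h, REFS, truncate = FALSE)
  thr <- REFS$nutrients$ear[REFS$nutrients$nutrient == "vitamin_a" &
                              REFS$nutrients$group_id == "men_18_29"] /
    2900 * 1000
  level <- 150
  added <- 2 * level / pr$energy_kcal_ame * 1000
  expected_drop <- mean(pr$dens_vitamin_a < thr &
                          pr$dens_vitamin_a + added >= thr) * 100
  base <- assess_hces(h, REFS, n_boot = 0, seed = 3, groups = "men")
  fort <- assess_hces(h, REFS, n_boot = 0, seed = 3, groups = "men",
                      bouillon_levels = c(vitamin_a = level))
  pick <- function(a) a$point[a$nutrient == "vitamin_a" &
                                a$metric == "inadequate"]
  expect_equal(pick(base) - pick(fort), expected_drop, tolerance = 1e-9)
})

test_that("higher levels never increase inadequacy nor decrease excess", {
  h <- small_hces(n = 300, seed = 29)
  for (nu in c("vitamin_a", "zinc")) {
    res <- run_level_grid(h, nu, references = REFS, n_boot = 0, seed = 4)
    for (gp in unique(res$group)) {
      inad <- res$point[res$group == gp & res$metric == "inadequate"]
      excess <- res$point[res$group == gp & res$metric == "above_ul"]
      expect_true(all(diff(inad) <= 1e-9))
      expect_true(all(diff(excess) >= -1e-9))
    }
  }
})

test_that("partial coverage lies between the unfortified and full scenarios
           in expectation over the Bernoulli assignment", {
  h <- small_hces(n = 400, seed = 37)
  lv <- c(vitamin_b12 = 2)
  pick <- function(a) a$point[a$nutrient == "vitamin_b12" &
                                a$metric == "inadequate" & a$group == "wra"]
  p0 <- pick(assess_hces(h, REFS, n_boot = 0, seed = 1))
  p1 <- pick(assess_hces(h, REFS, bouillon_levels = lv, n_boot = 0, seed = 1))
  half <- vapply(1:40, function(s) {
    pick(assess_hces(h, REFS, bouillon_levels = lv, bouillon_coverage = 0.5,
                     n_boot = 0, seed = s))
  }, 0)
  expect_lt(abs(mean(half) - (p0 + p1) / 2), 1.5)
  expect_true(all(half <= p0 + 1e-9 & half >= p1 - 1e-9))
})

test_that("scenario validation rejects bad inputs", {
  expect_error(fortification_scenario(bouillon_levels = c(10)), "named")
  expect_error(fortification_scenario(bouillon_levels = c(iron = -1)),
               ">= 0")
  expect_error(fortification_scenario(bouillon_coverage = 2), "\\[0, 1\\]")
  expect_error(fortification_scenario(bouillon_iron_absorption = 0),
               "\\(0, 1\\]")
})

test_that("recall branch: fortification moves usual intakes as expected", {
  r <- small_recalls(n_wra = 250, n_children = 250, seed = 43)
  base <- assess_recalls(r, REFS, n_boot = 0, seed = 6)
  fort <- assess_recalls(r, REFS,
                         bouillon_levels = c(vitamin_b12 = 2,
                                             vitamin_a = 250),
                         n_boot = 0, seed = 6)
  for (gp in c("wra", "child_6_59")) {
    for (nu in c("vitamin_b12", "vitamin_a")) {
      b <- base$point[base$group == gp & base$nutrient == nu &
                        base$metric == "inadequate"]
      f <- fort$point[fort$group == gp & fort$nutrient == nu &
                        fort$metric == "inadequate"]
      expect_lte(f, b)
    }
  }
  # iron absorption sensitivity: 10% bouillon absorption helps at least as
  # much as 2%
  fe2 <- assess_recalls(r, REFS, bouillon_levels = c(iron = 5),
                        bouillon_iron_absorption = 0.02, n_boot = 0, seed = 6)
  fe10 <- assess_recalls(r, REFS, bouillon_levels = c(iron = 5),
                         bouillon_iron_absorption = 0.10, n_boot = 0,
                         seed = 6)
  pick <- function(a, gp) a$point[a$group == gp & a$nutrient == "iron" &
                                    a$metric == "inadequate"]
  expect_lte(pick(fe10, "wra"), pick(fe2, "wra"))
  expect_lte(pick(fe10, "child_6_59"), pick(fe2, "child_6_59"))
})
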