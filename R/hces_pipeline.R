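# Household branch: adult-male-equivalent weights, outlier truncation,
# household nutrient densities, random selection of one target-group member
# per household, and prevalence of inadequate / excessive apparent densities.

#' Adult-male-equivalent weights for household members
#'
#' Each member's AME weight is their age/sex-specific energy requirement
#' divided by the reference male's (18-30 y, moderate physical activity,
#' 2900 kcal/d). Women of reproductive age use nonpregnant, nonlactating
#' energy requirements.
#'
#' @param members Tibble with `member_id`, `sex`, `age_months` (and usually
#'   `household_id`).
#' @param references Reference tables from [default_references()].
#' @return `members` with `group_id`, `kcal_per_day` and `ame_weight` columns.
#' @export
#' @examples
#' refs <- default_references()
#' m <- tibble::tibble(household_id = 1, member_id = c("a", "b"),
#'                     sex = c("male", "female"), age_months = c(300, 300))
#' ame_weights(m, refs)$ame_weight
ame_weights <- function(members, references) {
  g <- match_group(members$age_months, members$sex, references$groups)
  if (anyNA(g)) {
    bad <- members$member_id[is.na(g)][1]
    stop("no energy-requirement stratum matches member ", bad,
         " (age ", members$age_months[is.na(g)][1], " mo)")
  }
  kcal <- references$energy$kcal_per_day[
    match(g, references$energy$group_id)]
  if (anyNA(kcal)) stop("energy requirement missing for stratum ",
                        g[is.na(kcal)][1])
  ref_kcal <- references$energy$kcal_per_day[
    references$energy$group_id == "men_18_29"]
  out <- members
  out$group_id <- g
  out$kcal_per_day <- kcal
  out$ame_weight <- kcal / ref_kcal
  out
}

#' Truncate episodic-acquisition outliers at the 95th percentile
#'
#' Apparent consumption per AME per day strictly above the (survey-weighted)
#' 95th percentile is replaced by that percentile value; values at or below
#' it are unchanged. With fewer than `min_n` nonmissing values the vector
#' passes through untouched (a 95th percentile would be meaningless) and the
#' skip is recorded in the `"truncation"` attribute.
#'
#' @param x Numeric vector of per-AME quantities for one food across
#'   households.
#' @param weights Optional survey weights.
#' @param p Truncation percentile (default 0.95).
#' @param min_n Minimum nonmissing values required to truncate.
#' @return `x` with outliers capped; attribute `"truncation"` records the
#'   cap and the number of values replaced (or the skip).
#' @export
truncate_outliers <- function(x, weights = NULL, p = 0.95, min_n = 20) {
  nn <- sum(!is.na(x))
  if (nn == 0) return(structure(x, truncation = list(applied = FALSE,
                                                     reason = "empty")))
  if (nn < min_n) {
    return(structure(x, truncation = list(applied = FALSE,
                                          reason = "fewer than min_n values")))
  }
  q <- weighted_quantile(x, p, weights)
  above <- !is.na(x) & x > q
  x[above] <- q
  structure(x, truncation = list(applied = TRUE, cap = q,
                                 n_replaced = sum(above)))
}

#' Apparent nutrient densities of household diets
#'
#' For each household: per-AME apparent consumption of every food (household
#' quantity over the recall period divided by total AME), truncated across
#' households at the 95th percentile per food, then converted through the
#' food-composition table to the density of each nutrient per 1000 kcal of
#' the household diet. Optionally adds fortificant content to staple-food
#' vehicles first (`staple_content`, mg/kg of vehicle; fortificant vitamin A
#' counts as preformed retinol and fortificant folic acid contributes
#' 1.7 ug DFE per ug to total folate). Households with zero total energy are
#' excluded and recorded in the `"excluded"` attribute.
#'
#' @param hces An `hces_data` object.
#' @param references Reference tables from [default_references()].
#' @param staple_content Optional tibble with `vehicle`, `nutrient`,
#'   `content` (mg per kg of vehicle), e.g. from [staple_content()].
#' @param truncate Apply [truncate_outliers()] per food (default TRUE).
#' @param p_truncate Truncation percentile.
#' @return Tibble with one row per household: `household_id`,
#'   `survey_weight`, `ame_total`, `energy_kcal_ame` (apparent energy per AME
#'   per day), `bouillon_g_ame`, and `dens_*` columns (amount per 1000 kcal)
#'   for vitamin_a, retinol, folate, folic_acid, vitamin_b12, iron, zinc and
#'   phytate.
#' @export
household_density <- function(hces, references, staple_content = NULL,
                              truncate = TRUE, p_truncate = 0.95) {
  stopifnot(inherits(hces, "hces_data"))
  fc <- fortify_composition(hces$food_composition, staple_content)

  missing_foods <- setdiff(unique(hces$consumption$food), fc$food)
  if (length(missing_foods) > 0) {
    stop("food composition missing for: ",
         paste(missing_foods, collapse = ", "))
  }

  ame <- ame_weights(hces$members, references)
  ame_total <- tapply(ame$ame_weight, ame$household_id, sum)
  hh <- hces$households
  hh$ame_total <- as.numeric(ame_total[as.character(hh$household_id)])

  cons <- hces$consumption
  cons$g_ame <- cons$g_day /
    hh$ame_total[match(cons$household_id, hh$household_id)]
  if (truncate) {
    w_hh <- hh$survey_weight[match(cons$household_id, hh$household_id)]
    cons$g_ame <- stats::ave(
      seq_len(nrow(cons)), cons$food,
      FUN = function(i) truncate_outliers(cons$g_ame[i], w_hh[i],
                                          p = p_truncate)
    ) |> as.numeric()
  }

  # households x foods matrix of per-AME grams
  food_levels <- fc$food
  m <- matrix(0, nrow = nrow(hh), ncol = length(food_levels),
              dimnames = list(NULL, food_levels))
  ri <- match(cons$household_id, hh$household_id)
  ci <- match(cons$food, food_levels)
  m[cbind(ri, ci)] <- cons$g_ame

  energy <- as.numeric(m %*% fc$energy_kcal_g)
  nutrients <- c("vitamin_a", "retinol", "folate", "folic_acid",
                 "vitamin_b12", "iron", "zinc", "phytate")
  dens <- vapply(nutrients, function(nu) {
    as.numeric(m %*% fc[[paste0(nu, if (nu %in% c("iron", "zinc", "phytate"))
      "_mg_g" else "_ug_g")]])
  }, numeric(nrow(hh)))
  dens <- matrix(dens, nrow = nrow(hh), ncol = length(nutrients))

  out <- tibble::tibble(
    household_id = hh$household_id,
    survey_weight = hh$survey_weight,
    ame_total = hh$ame_total,
    energy_kcal_ame = energy,
    bouillon_g_ame = if ("bouillon" %in% food_levels) m[, "bouillon"] else 0
  )
  for (j in seq_along(nutrients)) {
    out[[paste0("dens_", nutrients[j])]] <-
      ifelse(energy > 0, dens[, j] / energy * 1000, NA_real_)
  }
  excluded <- out$household_id[out$energy_kcal_ame <= 0]
  if (length(excluded) > 0) {
    out <- out[out$energy_kcal_ame > 0, ]
  }
  attr(out, "excluded") <- excluded
  out
}

# add fortificant mg/kg of vehicle to the composition table (per-gram units:
# mg/kg of vehicle = ug/g for vitamins, /1000 for minerals in mg/g)
fortify_composition <- function(fc, staple_content) {
  if (is.null(staple_content) || nrow(staple_content) == 0) return(fc)
  for (i in seq_len(nrow(staple_content))) {
    v <- staple_content$vehicle[i]
    nu <- staple_content$nutrient[i]
    content <- staple_content$content[i]
    if (content < 0) stop("staple content must be nonnegative")
    hit <- fc$vehicle == v
    if (!any(hit)) next
    switch(nu,
      vitamin_a = {
        fc$vitamin_a_ug_g[hit] <- fc$vitamin_a_ug_g[hit] + content
        fc$retinol_ug_g[hit] <- fc$retinol_ug_g[hit] + content
      },
      folic_acid = {
        fc$folate_ug_g[hit] <- fc$folate_ug_g[hit] + 1.7 * content
        fc$folic_acid_ug_g[hit] <- fc$folic_acid_ug_g[hit] + content
      },
      vitamin_b12 = fc$vitamin_b12_ug_g[hit] <-
        fc$vitamin_b12_ug_g[hit] + content,
      iron = fc$iron_mg_g[hit] <- fc$iron_mg_g[hit] + content / 1000,
      zinc = fc$zinc_mg_g[hit] <- fc$zinc_mg_g[hit] + content / 1000,
      stop("unknown fortificant nutrient: ", nu)
    )
  }
  fc
}

#' Randomly select one target-group member per household
#'
#' Households with more than one member of a target group contribute a single
#' uniformly selected member; households with none are excluded from that
#' group's analysis. Deterministic under `seed`.
#'
#' @param members Member tibble (with `household_id`, `member_id`, `sex`,
#'   `age_months`).
#' @param target_group One of `"child_6_59"`, `"wra"`, `"men"`.
#' @param references Reference tables.
#' @param seed Integer seed.
#' @return Tibble with one row per household that has an eligible member:
#'   `household_id`, `member_id`, `group_id` (the member's stratum).
#' @export
select_member <- function(members, target_group, references, seed = 1L) {
  g <- match_group(members$age_months, members$sex, references$groups,
                   target_only = TRUE)
  tg <- references$groups$target_group[match(g, references$groups$group_id)]
  elig <- members[!is.na(g) & tg == target_group & !is.na(tg), ]
  elig$group_id <- g[!is.na(g) & tg == target_group & !is.na(tg)]
  if (nrow(elig) == 0) {
    return(tibble::tibble(household_id = elig$household_id[0],
                          member_id = character(0), group_id = character(0)))
  }
  with_seed(seed, {
    u <- stats::runif(nrow(elig))
    keep <- tapply(seq_len(nrow(elig)), elig$household_id,
                   function(i) i[which.max(u[i])])
    elig[as.integer(keep), c("household_id", "member_id", "group_id")]
  })
}

#' Survey-weighted prevalence of densities beyond a threshold
#'
#' Weighted share of households whose apparent nutrient density lies below
#' (`direction = "below"`, inadequacy against the critical density) or above
#' (`direction = "above"`, excess against the tolerable upper density) the
#' per-household threshold, with a percentile household-bootstrap confidence
#' interval.
#'
#' @param density Numeric vector, one apparent density per household.
#' @param threshold Threshold density, scalar or per household (the selected
#'   member's stratum threshold).
#' @param weights Survey weights.
#' @param direction `"below"` or `"above"`.
#' @param n_boot Bootstrap replicates (default 500; 0 skips the CI).
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return One-row tibble: `point`, `ci_low`, `ci_high`, `n_effective`
#'   (percent scale), with the bootstrap replicates in attribute `"boot"`.
#' @export
#' @examples
#' density_prevalence(c(1, 3), 2, direction = "below")$point # 50
density_prevalence <- function(density, threshold, weights = NULL,
                               direction = c("below", "above"),
                               n_boot = 500, conf = 0.95, seed = NULL) {
  direction <- match.arg(direction)
  ind <- if (direction == "below") density < threshold else density > threshold
  boot_prevalence(as.numeric(ind), weights, n_boot = n_boot, conf = conf,
                  seed = seed)
}

#' Full-probability prevalence of inadequate iron density
#'
#' The probability-based analogue of the density method for iron: each
#' household's risk of inadequacy is the probability that the selected
#' member's absorbed-iron requirement (log-normal, per day) exceeds the
#' household's absorbed iron density scaled to that member's energy
#' requirement. Absorbed density is `iron_density * absorption_fraction`
#' (default 10% of the non-bouillon diet) plus any already-absorbed density
#' from fortified bouillon (`absorbed_extra_density`). The prevalence is the
#' weighted mean risk.
#'
#' @param iron_density Total (non-bouillon) iron density, mg/1000 kcal.
#' @param requirement_meanlog,requirement_sdlog Log-normal parameters of the
#'   absorbed-iron requirement (mg/day), scalar or per household.
#' @param energy_req_kcal Selected member's energy requirement (kcal/day),
#'   scalar or per household.
#' @param weights Survey weights.
#' @param absorption_fraction Fraction of dietary iron absorbed, in (0, 1].
#' @param absorbed_extra_density Absorbed iron density from bouillon,
#'   mg/1000 kcal.
#' @inheritParams density_prevalence
#' @return One-row tibble as [density_prevalence()].
#' @export
iron_density_probability <- function(iron_density, requirement_meanlog,
                                     requirement_sdlog, energy_req_kcal,
                                     weights = NULL,
                                     absorption_fraction = 0.10,
                                     absorbed_extra_density = 0,
                                     n_boot = 500, conf = 0.95, seed = NULL) {
  if (absorption_fraction <= 0 || absorption_fraction > 1) {
    stop("absorption_fraction must lie in (0, 1]")
  }
  if (anyNA(requirement_meanlog) || anyNA(requirement_sdlog)) {
    stop("absorbed-iron requirement model missing for some households")
  }
  absorbed_density <- iron_density * absorption_fraction +
    absorbed_extra_density
  absorbed_daily <- absorbed_density * energy_req_kcal / 1000
  risk <- ifelse(absorbed_daily <= 0, 1,
                 stats::plnorm(absorbed_daily, requirement_meanlog,
                               requirement_sdlog, lower.tail = FALSE))
  boot_prevalence(risk, weights, n_boot = n_boot, conf = conf, seed = seed)
}

# ---- full household branch -------------------------------------------------

# Precompute everything level-independent: density profiles (with staples)
# and per-group member selections joined to stratum thresholds.
prepare_hces <- function(hces, references, staple_content = NULL,
                         groups = c("child_6_59", "wra", "men"), seed = 1L,
                         truncate = TRUE) {
  profiles <- household_density(hces, references,
                                staple_content = staple_content,
                                truncate = truncate)
  thr <- density_thresholds(references)
  ironreq <- references$iron_requirements
  sel <- lapply(groups, function(gp) {
    s <- select_member(hces$members, gp, references,
                       seed = derive_seed(seed, paste0("sel_", gp)))
    s <- dplyr::inner_join(s, profiles, by = "household_id")
    s$energy_req <- references$energy$kcal_per_day[
      match(s$group_id, references$energy$group_id)]
    s$iron_req_meanlog <- log(ironreq$median_absorbed_mg[
      match(s$group_id, ironreq$group_id)])
    s$iron_req_sdlog <- ironreq$log_sd[match(s$group_id, ironreq$group_id)]
    s
  })
  names(sel) <- groups
  list(profiles = profiles, selections = sel, thresholds = thr,
       references = references)
}

threshold_for <- function(thr, nutrient, group_ids, what) {
  t0 <- thr[thr$nutrient == nutrient, ]
  t0[[what]][match(group_ids, t0$group_id)]
}

#' Assess (apparent) micronutrient adequacy of household diets
#'
#' Runs the whole household branch for one fortification setting: densities
#' with optional staple fortificant, a bouillon fortificant added as
#' `bouillon_g_ame * level / energy * 1000`, and per target group the
#' prevalence of inadequate apparent density (critical-density comparison;
#' full-probability approach for iron; absorbed zinc against the
#' physiological requirement) and of density above the tolerable upper
#' density (preformed retinol for vitamin A, folic acid for folate; none for
#' vitamin B12).
#'
#' @param hces An `hces_data` object.
#' @param references Reference tables.
#' @param staple_content Optional staple fortificant table (see
#'   [staple_content()]).
#' @param bouillon_levels Named vector of bouillon fortification levels
#'   (amount per gram: ug/g for vitamin A, folic acid, B12; mg/g for iron and
#'   zinc); missing nutrients default to 0.
#' @param bouillon_iron_absorption Fractional absorption of bouillon iron
#'   (default 2%).
#' @param iron_absorption Flat absorption of non-bouillon dietary iron
#'   (default 10%).
#' @param groups Target groups to assess.
#' @param bouillon_coverage Fraction of bouillon assumed fortified;
#'   households are assigned fortified/unfortified by a Bernoulli draw
#'   under the seed.
#' @param n_boot Bootstrap replicates per estimate.
#' @param seed Integer seed controlling member selection and bootstraps.
#' @return Tibble with columns `group`, `nutrient`, `metric`
#'   (`"inadequate"` or `"above_ul"`), `point`, `ci_low`, `ci_high`,
#'   `n_effective` (percent scale).
#' @export
assess_hces <- function(hces, references = default_references(),
                        staple_content = NULL,
                        bouillon_levels = numeric(0),
                        bouillon_iron_absorption = 0.02,
                        iron_absorption = 0.10,
                        groups = c("child_6_59", "wra", "men"),
                        bouillon_coverage = 1,
                        n_boot = 500, seed = 1L) {
  prep <- prepare_hces(hces, references, staple_content = staple_content,
                       groups = groups, seed = seed)
  assess_hces_prepared(prep, bouillon_levels, bouillon_iron_absorption,
                       iron_absorption, bouillon_coverage = bouillon_coverage,
                       n_boot = n_boot, seed = seed)
}

assess_hces_prepared <- function(prep, bouillon_levels = numeric(0),
                                 bouillon_iron_absorption = 0.02,
                                 iron_absorption = 0.10,
                                 bouillon_coverage = 1,
                                 n_boot = 500, seed = 1L,
                                 params = absorption_params(
                                   prep$references$absorption)) {
  if (bouillon_coverage < 0 || bouillon_coverage > 1) {
    stop("bouillon coverage must lie in [0, 1]")
  }
  cov_mult <- if (bouillon_coverage < 1) {
    ids <- prep$profiles$household_id
    fortified <- with_seed(derive_seed(seed, "coverage"),
                           stats::runif(length(ids)) < bouillon_coverage)
    stats::setNames(as.numeric(fortified), ids)
  } else NULL
  lv <- function(nu) {
    l <- unname(bouillon_levels[nu])
    if (is.na(l) || is.null(l)) 0 else l
  }
  if (any(unlist(bouillon_levels) < 0)) stop("fortification levels must be >= 0")
  thr <- prep$thresholds
  out <- list()
  for (gp in names(prep$selections)) {
    s <- prep$selections[[gp]]
    if (nrow(s) == 0) next
    fort_g <- if (is.null(cov_mult)) s$bouillon_g_ame else
      s$bouillon_g_ame * cov_mult[as.character(s$household_id)]
    add_dens <- function(level) fort_g * level / s$energy_kcal_ame * 1000
    est <- function(values_or_ind, kind, nutrient, metric, seed_label) {
      r <- values_or_ind
      b <- boot_prevalence(r, s$survey_weight, n_boot = n_boot,
                           seed = derive_seed(seed, seed_label))
      b$group <- gp; b$nutrient <- nutrient; b$metric <- metric
      attr_boot <- attr(b, "boot")
      b <- b[, c("group", "nutrient", "metric", "point", "ci_low",
                 "ci_high", "n_effective")]
      attr(b, "boot") <- attr_boot
      b
    }

    # vitamin A: total RAE vs critical density; preformed retinol vs UL
    va <- s$dens_vitamin_a + add_dens(lv("vitamin_a"))
    crit <- threshold_for(thr, "vitamin_a", s$group_id, "critical")
    out[[length(out) + 1]] <- est(as.numeric(va < crit), "ind",
                                  "vitamin_a", "inadequate",
                                  paste0(gp, "_va_in"))
    ret <- s$dens_retinol + add_dens(lv("vitamin_a"))
    up <- threshold_for(thr, "vitamin_a", s$group_id, "upper")
    out[[length(out) + 1]] <- est(as.numeric(ret > up), "ind",
                                  "vitamin_a", "above_ul",
                                  paste0(gp, "_va_ul"))

    # folate: DFE (fortificant x 1.7) vs critical; folic acid vs UL
    fo <- s$dens_folate + 1.7 * add_dens(lv("folic_acid"))
    crit <- threshold_for(thr, "folate", s$group_id, "critical")
    out[[length(out) + 1]] <- est(as.numeric(fo < crit), "ind",
                                  "folate", "inadequate",
                                  paste0(gp, "_fo_in"))
    fa <- s$dens_folic_acid + add_dens(lv("folic_acid"))
    up <- threshold_for(thr, "folate", s$group_id, "upper")
    out[[length(out) + 1]] <- est(as.numeric(fa > up), "ind",
                                  "folate", "above_ul",
                                  paste0(gp, "_fo_ul"))

    # vitamin B12: density method only; no UL defined
    b12 <- s$dens_vitamin_b12 + add_dens(lv("vitamin_b12"))
    crit <- threshold_for(thr, "vitamin_b12", s$group_id, "critical")
    out[[length(out) + 1]] <- est(as.numeric(b12 < crit), "ind",
                                  "vitamin_b12", "inadequate",
                                  paste0(gp, "_b12_in"))

    # iron: full-probability on the absorbed scale; UL on total density
    absorbed_extra <- add_dens(lv("iron")) * bouillon_iron_absorption
    absorbed_daily <- (s$dens_iron * iron_absorption + absorbed_extra) *
      s$energy_req / 1000
    risk <- ifelse(absorbed_daily <= 0, 1,
                   stats::plnorm(absorbed_daily, s$iron_req_meanlog,
                                 s$iron_req_sdlog, lower.tail = FALSE))
    out[[length(out) + 1]] <- est(risk, "risk", "iron", "inadequate",
                                  paste0(gp, "_fe_in"))
    fe_tot <- s$dens_iron + add_dens(lv("iron"))
    up <- threshold_for(thr, "iron", s$group_id, "upper")
    out[[length(out) + 1]] <- est(as.numeric(fe_tot > up), "ind",
                                  "iron", "above_ul", paste0(gp, "_fe_ul"))

    # zinc: absorbed (saturable model) vs physiological requirement;
    # UL on total density
    zn_dens <- s$dens_zinc + add_dens(lv("zinc"))
    zn_daily <- zn_dens * s$energy_req / 1000
    ph_daily <- s$dens_phytate * s$energy_req / 1000
    variant <- if (gp == "child_6_59") "child" else "adult"
    abs_zn <- absorbed_zinc(zn_daily, ph_daily, variant, params)
    ear_abs <- threshold_for(thr, "zinc", s$group_id, "ear")
    out[[length(out) + 1]] <- est(as.numeric(abs_zn < ear_abs), "ind",
                                  "zinc", "inadequate",
                                  paste0(gp, "_zn_in"))
    up <- threshold_for(thr, "zinc", s$group_id, "upper")
    out[[length(out) + 1]] <- est(as.numeric(zn_dens > up), "ind",
                                  "zinc", "above_ul", paste0(gp, "_zn_ul"))
  }
  boots <- lapply(out, attr, "boot")
  res <- dplyr::bind_rows(out)
  attr(res, "boot") <- boots
  res
}

#' Apparent individual bouillon intake by target group
#'
#' The household-survey analogue of individual bouillon consumption: the
#' household's apparent daily bouillon divided among members in proportion to
#' their AME weights (member intake = household grams x member AME / total
#' AME), summarised per target group over the selected members.
#'
#' @inheritParams assess_hces
#' @return Tibble with `group`, weighted `mean_g_day` and `median_g_day`, and
#'   the share of households with any bouillon (`percent_consuming`).
#' @export
bouillon_intake_summary <- function(hces, references = default_references(),
                                    groups = c("wra", "child_6_59", "men"),
                                    seed = 1L) {
  ame <- ame_weights(hces$members, references)
  ame_total <- tapply(ame$ame_weight, ame$household_id, sum)
  bou <- hces$consumption[hces$consumption$food == "bouillon", ]
  out <- lapply(groups, function(gp) {
    s <- select_member(hces$members, gp, references,
                       seed = derive_seed(seed, paste0("sel_", gp)))
    g_day <- bou$g_day[match(s$household_id, bou$household_id)]
    g_day[is.na(g_day)] <- 0
    at <- as.numeric(ame_total[as.character(s$household_id)])
    aw <- ame$ame_weight[match(s$member_id, ame$member_id)]
    ind <- g_day * aw / at
    w <- hces$households$survey_weight[
      match(s$household_id, hces$households$household_id)]
    tibble::tibble(
      group = gp,
      percent_consuming = weighted_prevalence(ind > 0, w),
      mean_g_day = stats::weighted.mean(ind, w),
      median_g_day = weighted_quantile(ind, 0.5, w)
    )
  })
  dplyr::bind_rows(out)
}
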