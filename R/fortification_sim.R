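# Fortification scenarios: status-quo vs. target staple fortification,
# bouillon level grids and iron-absorption sensitivity, with percentage-point
# impacts against the matched unfortified-bouillon baseline.

#' Default bouillon fortification level grids
#'
#' Seven strictly increasing candidate levels per nutrient spanning the
#' modeled ranges: 20-250 ug/g vitamin A, 20-120 ug/g folic acid,
#' 0.2-2.0 ug/g vitamin B12, 0.6-5 mg/g iron, 0.6-5 mg/g zinc. All grids can
#' be overridden wherever they are consumed.
#'
#' @param nutrient One of `"vitamin_a"`, `"folic_acid"`, `"vitamin_b12"`,
#'   `"iron"`, `"zinc"`.
#' @return Numeric vector of 7 levels (ug/g for vitamins, mg/g for
#'   minerals).
#' @export
#' @examples
#' default_level_grid("vitamin_a")
default_level_grid <- function(nutrient) {
  grids <- list(
    vitamin_a = c(20, 40, 80, 120, 160, 200, 250),
    folic_acid = c(20, 30, 40, 60, 80, 100, 120),
    vitamin_b12 = c(0.2, 0.4, 0.6, 0.8, 1.2, 1.6, 2.0),
    iron = c(0.6, 1.2, 1.8, 2.4, 3, 4, 5),
    zinc = c(0.6, 1.2, 1.8, 2.4, 3, 4, 5)
  )
  g <- grids[[nutrient]]
  if (is.null(g)) stop("no default level grid for nutrient: ", nutrient)
  g
}

#' Staple fortificant contents for a country and scenario mode
#'
#' `"status_quo"` uses [effective_content()] (target times observed
#' compliance); `"target"` assumes every mandatorily fortified food is
#' fortified at the target level; `"none"` removes staple fortification
#' (unfortified counterfactual).
#'
#' @param standards The `standards` table from [default_references()].
#' @param country Country name as in the table.
#' @param mode `"status_quo"`, `"target"`, or `"none"`.
#' @return Tibble with `vehicle`, `nutrient`, `content` (mg per kg vehicle).
#' @export
staple_content <- function(standards, country,
                           mode = c("status_quo", "target", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(tibble::tibble(vehicle = character(0), nutrient = character(0),
                          content = numeric(0)))
  }
  st <- standards[standards$country == country, ]
  if (nrow(st) == 0) stop("no fortification standards for country: ", country)
  tibble::tibble(
    vehicle = st$vehicle,
    nutrient = st$nutrient,
    content = if (mode == "status_quo") {
      effective_content(st$target_level, st$compliance_fraction)
    } else st$target_level
  )
}

#' Define a bouillon fortification scenario
#'
#' @param scenario_id Label for the scenario.
#' @param staple_mode `"status_quo"`, `"target"`, or `"none"` (existing
#'   mandatory staple programs; voluntary bouillon fortification is always
#'   excluded from baselines).
#' @param bouillon_levels Named vector of bouillon fortificant levels at the
#'   time of consumption (retention is taken as 1): ug/g for `vitamin_a`,
#'   `folic_acid`, `vitamin_b12`; mg/g for `iron`, `zinc`.
#' @param bouillon_coverage Fraction of bouillon fortified (default 1,
#'   the best-case assumption; lower values assign fortified bouillon to a
#'   Bernoulli subset of households/persons under the scenario seed).
#' @param bouillon_iron_absorption Fractional absorption of bouillon iron
#'   (0.02 primary; 0.04 and 0.10 sensitivity).
#' @param country Country whose staple standards apply.
#' @param seed Integer seed for scenario-level randomness.
#' @return Object of class `fortification_scenario`.
#' @export
fortification_scenario <- function(scenario_id = "scenario",
                                   staple_mode = c("status_quo", "target",
                                                   "none"),
                                   bouillon_levels = numeric(0),
                                   bouillon_coverage = 1,
                                   bouillon_iron_absorption = 0.02,
                                   country = "Cameroon",
                                   seed = 1L) {
  staple_mode <- match.arg(staple_mode)
  lv <- unlist(bouillon_levels)
  if (length(lv) && (is.null(names(lv)) || any(!nzchar(names(lv))))) {
    stop("bouillon_levels must be a named vector")
  }
  if (any(lv < 0)) stop("fortification levels must be >= 0")
  if (bouillon_coverage < 0 || bouillon_coverage > 1) {
    stop("bouillon coverage must lie in [0, 1]")
  }
  if (bouillon_iron_absorption <= 0 || bouillon_iron_absorption > 1) {
    stop("bouillon iron absorption must lie in (0, 1]")
  }
  structure(list(scenario_id = scenario_id, staple_mode = staple_mode,
                 bouillon_levels = lv, bouillon_coverage = bouillon_coverage,
                 bouillon_iron_absorption = bouillon_iron_absorption,
                 country = country, seed = as.integer(seed)),
            class = "fortification_scenario")
}

#' @export
print.fortification_scenario <- function(x, ...) {
  lv <- if (length(x$bouillon_levels)) {
    paste(names(x$bouillon_levels), x$bouillon_levels, sep = "=",
          collapse = ", ")
  } else "none"
  cat("<fortification_scenario> ", x$scenario_id, ": staples ",
      x$staple_mode, " (", x$country, "); bouillon ", lv,
      "; Fe absorption ", x$bouillon_iron_absorption * 100, "%\n", sep = "")
  invisible(x)
}

#' Add a bouillon fortificant to household density profiles
#'
#' The fortificant density added to a household is its apparent bouillon
#' consumption times the level, divided by apparent energy, times 1000; the
#' result is added to the baseline density. Non-consuming households are
#' unchanged; the addition is linear in the level.
#'
#' @param profiles Output of [household_density()].
#' @param nutrient Density column to augment (without the `dens_` prefix).
#' @param level Fortification level, amount per gram of bouillon.
#' @param factor Unit conversion applied to the addition (1.7 for folic acid
#'   expressed as dietary folate equivalents).
#' @return `profiles` with the augmented density column.
#' @export
#' @examples
#' pr <- tibble::tibble(bouillon_g_ame = 4, energy_kcal_ame = 8000,
#'                      dens_vitamin_a = 10)
#' apply_bouillon_hces(pr, "vitamin_a", 120)$dens_vitamin_a # 10 + 60
apply_bouillon_hces <- function(profiles, nutrient, level, factor = 1) {
  if (level < 0) stop("fortification level must be nonnegative")
  if (any(profiles$energy_kcal_ame <= 0)) {
    stop("household energy must be positive")
  }
  col <- paste0("dens_", nutrient)
  stopifnot(col %in% names(profiles))
  profiles[[col]] <- profiles[[col]] +
    profiles$bouillon_g_ame * level * factor / profiles$energy_kcal_ame * 1000
  profiles
}

#' Run a fortification scenario against a survey
#'
#' Computes prevalences of inadequate and above-UL (apparent) intake for
#' every target group and nutrient under the scenario, together with the
#' matched baseline (same staple mode, all bouillon levels 0) and the
#' percentage-point change `baseline - scenario` (positive = reduction).
#'
#' @param data An `hces_data` or `recall_data` object.
#' @param scenario A [fortification_scenario()].
#' @param references Reference tables.
#' @param n_boot Bootstrap replicates per estimate.
#' @return Tibble with `scenario_id`, `group`, `nutrient`, `metric`,
#'   `baseline`, `point`, `ci_low`, `ci_high`, `n_effective`, `pp_change`.
#' @export
run_scenario <- function(data, scenario, references = default_references(),
                         n_boot = 500) {
  stopifnot(inherits(scenario, "fortification_scenario"))
  sc <- staple_content(references$standards, scenario$country,
                       scenario$staple_mode)
  run1 <- function(levels, coverage) {
    if (inherits(data, "hces_data")) {
      assess_hces(data, references, staple_content = sc,
                  bouillon_levels = levels,
                  bouillon_iron_absorption = scenario$bouillon_iron_absorption,
                  bouillon_coverage = coverage,
                  n_boot = n_boot, seed = scenario$seed)
    } else if (inherits(data, "recall_data")) {
      assess_recalls(data, references, staple_content = sc,
                     bouillon_levels = levels,
                     bouillon_iron_absorption =
                       scenario$bouillon_iron_absorption,
                     bouillon_coverage = coverage,
                     n_boot = n_boot, seed = scenario$seed)
    } else stop("data must be hces_data or recall_data")
  }
  base <- run1(numeric(0), 1)
  res <- run1(scenario$bouillon_levels, scenario$bouillon_coverage)
  res$baseline <- base$point[match(
    paste(res$group, res$nutrient, res$metric),
    paste(base$group, base$nutrient, base$metric))]
  res$pp_change <- res$baseline - res$point
  res$scenario_id <- scenario$scenario_id
  boots <- attr(res, "boot")
  res <- res[, c("scenario_id", "group", "nutrient", "metric", "baseline",
                 "point", "ci_low", "ci_high", "n_effective", "pp_change")]
  attr(res, "boot") <- boots
  res
}

#' Run a full bouillon level grid for one nutrient
#'
#' Evaluates the survey at every level of the grid (plus level 0 as
#' baseline) for a single fortificant nutrient, holding the staple mode and
#' absorption assumptions fixed. This is the input expected by
#' [select_levels()].
#'
#' @param data An `hces_data` or `recall_data` object.
#' @param nutrient Fortificant nutrient (`"vitamin_a"`, `"folic_acid"`,
#'   `"vitamin_b12"`, `"iron"`, `"zinc"`).
#' @param levels Level grid; defaults to [default_level_grid()].
#' @param staple_mode,country,bouillon_iron_absorption,seed As in
#'   [fortification_scenario()].
#' @param references Reference tables.
#' @param n_boot Bootstrap replicates.
#' @return Tibble of scenario rows with a `level` column (0 = baseline),
#'   restricted to the metrics of the density/intake nutrient the
#'   fortificant feeds (e.g. fortificant `folic_acid` reports nutrient
#'   `folate`).
#' @export
run_level_grid <- function(data, nutrient, levels = default_level_grid(nutrient),
                           staple_mode = "status_quo", country = "Cameroon",
                           bouillon_iron_absorption = 0.02,
                           references = default_references(),
                           n_boot = 500, seed = 1L) {
  stopifnot(all(levels >= 0), !is.unsorted(levels, strictly = TRUE))
  target_nutrient <- switch(nutrient, folic_acid = "folate", nutrient)
  sc <- staple_content(references$standards, country, staple_mode)
  out <- list()
  if (inherits(data, "hces_data")) {
    prep <- prepare_hces(data, references, staple_content = sc, seed = seed)
    for (l in c(0, levels)) {
      r <- assess_hces_prepared(
        prep, stats::setNames(l, nutrient),
        bouillon_iron_absorption = bouillon_iron_absorption,
        n_boot = n_boot, seed = seed)
      r$level <- l
      out[[length(out) + 1]] <- r[r$nutrient == target_nutrient, ]
    }
  } else {
    for (l in c(0, levels)) {
      r <- assess_recalls(
        data, references, staple_content = sc,
        bouillon_levels = stats::setNames(l, nutrient),
        bouillon_iron_absorption = bouillon_iron_absorption,
        n_boot = n_boot, seed = seed)
      r$level <- l
      out[[length(out) + 1]] <- r[r$nutrient == target_nutrient, ]
    }
  }
  res <- dplyr::bind_rows(out)
  base <- res[res$level == 0, ]
  res$baseline <- base$point[match(paste(res$group, res$metric),
                                   paste(base$group, base$metric))]
  res$pp_change <- res$baseline - res$point
  res$fortificant <- nutrient
  res[res$level > 0, ]
}
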