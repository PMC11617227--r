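#' @importFrom rlang .data %||%
#' @importFrom dplyr filter mutate select left_join inner_join group_by
#'   summarise arrange bind_rows ungroup n
NULL

ref_file <- function(name) {
  path <- system.file("extdata", name, package = "bouillonfort")
  if (path == "") stop("packaged reference file not found: ", name)
  path
}

read_ref_csv <- function(name) {
  tibble::as_tibble(utils::read.csv(ref_file(name), stringsAsFactors = FALSE))
}

#' Load the packaged reference tables
#'
#' Returns the versioned reference data shipped with the package: demographic
#' strata, energy requirements (FAO moderate physical activity), EAR/UL values
#' (IOM, with EFSA physiological zinc requirements for children and corrected
#' IZiNCG values for adults), absorbed-iron requirement distributions for the
#' full-probability approach, national fortification standards with observed
#' compliance, absorption-model parameters, and breast-milk volume/composition
#' defaults. Every row carries a `source` column; the tables are inputs, not
#' hard-coded constants, and any element may be replaced by the user.
#'
#' @param dir Optional directory containing replacement CSVs with the same
#'   file names and schemas; files not present fall back to the packaged ones.
#' @return A named list of tibbles: `groups`, `energy`, `nutrients`,
#'   `iron_requirements`, `standards`, `absorption`, `breastmilk_volumes`,
#'   `breastmilk_composition`.
#' @export
#' @examples
#' refs <- default_references()
#' subset(refs$energy, group_id == "men_18_29")
default_references <- function(dir = NULL) {
  load1 <- function(name) {
    if (!is.null(dir) && file.exists(file.path(dir, name))) {
      tibble::as_tibble(utils::read.csv(file.path(dir, name),
                                        stringsAsFactors = FALSE))
    } else read_ref_csv(name)
  }
  refs <- list(
    groups = load1("demographic_groups.csv"),
    energy = load1("energy_requirements.csv"),
    nutrients = load1("nutrient_references.csv"),
    iron_requirements = load1("iron_requirements.csv"),
    standards = load1("fortification_standards.csv"),
    absorption = load1("absorption_params.csv"),
    breastmilk_volumes = load1("breastmilk_volumes.csv"),
    breastmilk_composition = load1("breastmilk_composition.csv")
  )
  validate_references(refs)
  refs
}

validate_references <- function(refs) {
  g <- refs$groups
  stopifnot(all(g$age_low_months < g$age_high_months))
  # target strata must partition each target population without overlap
  for (tg in c("child_6_59", "wra", "men")) {
    gg <- g[g$target_group == tg, ]
    gg <- gg[order(gg$age_low_months), ]
    if (nrow(gg) > 1) {
      stopifnot(all(gg$age_high_months[-nrow(gg)] == gg$age_low_months[-1]))
    }
  }
  stopifnot(all(refs$energy$kcal_per_day > 0))
  nr <- refs$nutrients
  stopifnot(all(nr$ear > 0))
  stopifnot(all(is.na(nr$ul[nr$nutrient == "vitamin_b12"])))
  same_scale <- !is.na(nr$ul) & nr$ul_basis == "total_intake" &
    nr$ear_basis == "total"
  stopifnot(all(nr$ul[same_scale] > nr$ear[same_scale]))
  stopifnot(all(refs$standards$target_level >= 0),
            all(refs$standards$compliance_fraction >= 0))
  invisible(refs)
}

#' Look up the demographic stratum for each person
#'
#' Ages are in months; strata are half-open intervals `[low, high)`. Strata
#' whose `sex` is `"any"` match either sex.
#'
#' @param age_months Numeric vector of ages in months.
#' @param sex Character vector, `"male"` or `"female"`, recycled.
#' @param groups The `groups` table from [default_references()].
#' @param target_only If `TRUE`, only strata belonging to a target population
#'   (children 6-59 mo, WRA, men) are matched.
#' @return Character vector of `group_id`, `NA` where no stratum matches.
#' @export
match_group <- function(age_months, sex, groups, target_only = FALSE) {
  sex <- rep_len(sex, length(age_months))
  if (target_only) groups <- groups[groups$target_group != "none", ]
  out <- rep(NA_character_, length(age_months))
  for (i in seq_len(nrow(groups))) {
    hit <- age_months >= groups$age_low_months[i] &
      age_months < groups$age_high_months[i] &
      (groups$sex[i] == "any" | sex == groups$sex[i]) & is.na(out)
    out[hit] <- groups$group_id[i]
  }
  out
}

#' Critical nutrient density for a demographic stratum
#'
#' The critical density is the amount of nutrient per 1000 kcal at which a
#' diet exactly meets the stratum's estimated average requirement when energy
#' needs are met: EAR divided by the energy requirement, times 1000.
#'
#' @param nutrient_ref One row of the `nutrients` reference table (carrying
#'   `ear` and `group_id`).
#' @param energy_req One row of the `energy` reference table (carrying
#'   `kcal_per_day` and `group_id`).
#' @return Density in the EAR's unit per 1000 kcal.
#' @export
#' @examples
#' refs <- default_references()
#' critical_density(
#'   subset(refs$nutrients, nutrient == "iron" & group_id == "wra_18_29"),
#'   subset(refs$energy, group_id == "wra_18_29")
#' )
critical_density <- function(nutrient_ref, energy_req) {
  stopifnot(nrow(nutrient_ref) == 1, nrow(energy_req) == 1)
  if (!identical(nutrient_ref$group_id, energy_req$group_id)) {
    stop("nutrient reference and energy requirement refer to different ",
         "strata: ", nutrient_ref$group_id, " vs ", energy_req$group_id)
  }
  if (energy_req$kcal_per_day <= 0) stop("energy requirement must be positive")
  nutrient_ref$ear / energy_req$kcal_per_day * 1000
}

#' Tolerable upper nutrient density for a demographic stratum
#'
#' UL divided by the energy requirement, times 1000. For nutrients with no
#' defined UL (vitamin B12) this signals an error of class
#' `bouillonfort_no_ul` rather than returning a numeric sentinel.
#'
#' @inheritParams critical_density
#' @return Density in the UL's unit per 1000 kcal.
#' @export
tolerable_upper_density <- function(nutrient_ref, energy_req) {
  stopifnot(nrow(nutrient_ref) == 1, nrow(energy_req) == 1)
  if (!identical(nutrient_ref$group_id, energy_req$group_id)) {
    stop("nutrient reference and energy requirement refer to different strata")
  }
  if (is.na(nutrient_ref$ul)) {
    stop(structure(
      class = c("bouillonfort_no_ul", "error", "condition"),
      list(message = paste0("no UL defined for ", nutrient_ref$nutrient),
           call = sys.call(-1))
    ))
  }
  if (energy_req$kcal_per_day <= 0) stop("energy requirement must be positive")
  nutrient_ref$ul / energy_req$kcal_per_day * 1000
}

#' Effective micronutrient content of a fortified staple
#'
#' Target fortification level times the observed compliance fraction. The
#' result is kept at full precision; rounding (half away from zero) happens
#' only when reproducing printed program tables via `printed_decimals`.
#' Compliance may exceed 1 (over-fortification). The effective content is
#' applied to 100% of the vehicle: the model does not distinguish partial
#' fortification from non-fortification.
#'
#' @param target_level Target content (mg/kg for staples, amount/g for
#'   bouillon).
#' @param compliance_fraction Observed compliance in `[0, Inf)`.
#' @return Effective content, same unit as `target_level`.
#' @export
#' @examples
#' effective_content(12, 0.75)   # Cameroon oil vitamin A -> 9 mg/kg
#' effective_content(28.3, 0.39) # Ghana wheat-flour zinc -> 11.037 mg/kg
effective_content <- function(target_level, compliance_fraction) {
  if (any(target_level < 0) || any(compliance_fraction < 0)) {
    stop("target level and compliance fraction must be nonnegative")
  }
  target_level * compliance_fraction
}

#' Status-quo fortification table with effective contents
#'
#' Applies [effective_content()] to every (country, vehicle, nutrient) row of
#' a fortification-standards table and adds the value rounded at the printed
#' precision, for comparison with published program tables.
#'
#' @param standards The `standards` table from [default_references()].
#' @return The table with `effective` and `effective_printed` columns.
#' @export
effective_content_table <- function(standards) {
  standards |>
    mutate(
      effective = effective_content(.data$target_level,
                                    .data$compliance_fraction),
      effective_printed = round_half_up(.data$effective,
                                        .data$printed_decimals)
    )
}

# critical / tolerable-upper densities for every stratum of the target groups
density_thresholds <- function(refs) {
  nr <- refs$nutrients |>
    inner_join(refs$energy[, c("group_id", "kcal_per_day")], by = "group_id")
  nr |>
    mutate(
      critical = .data$ear / .data$kcal_per_day * 1000,
      upper = ifelse(is.na(.data$ul), NA_real_,
                     .data$ul / .data$kcal_per_day * 1000)
    ) |>
    select("nutrient", "group_id", "ear", "ear_basis", "ul", "ul_basis",
           "kcal_per_day", "critical", "upper")
}
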