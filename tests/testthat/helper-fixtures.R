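# Shared fixtures, built in code. Reference tables are loaded once per run.

REFS <- default_references()
PARAMS <- absorption_params(REFS$absorption)

# Independent absorption oracles, written before the implementations were
# wired in; they never call the package's model functions.
armah_oracle <- function(nonheme, ferritin, phytate, p) {
  ln_pct <- p$intercept - 0.709 * log(ferritin) + 0.119 * log(p$ref_vitc_mg) +
    0.006 * log(p$ref_mfp_g + 0.1) - 0.055 * log(p$ref_tea_cups + 0.1) -
    0.247 * log(phytate + 1) - 0.137 * log(p$ref_calcium_mg) -
    0.083 * log(max(nonheme, 0.1))
  min(max(exp(ln_pct) / 100, 0), 1) * nonheme
}

zinc_oracle <- function(tdz_mg, tdp_mg, p) {
  tdz <- tdz_mg / 65.38; tdp <- tdp_mg / 660.04
  if (tdz == 0) return(0)
  krp <- p$kr_mmol * (1 + tdp / p$kp_mmol)
  f <- function(t) t - p$amax_mmol * (tdz - t) / (krp + (tdz - t))
  stats::uniroot(f, c(0, min(p$amax_mmol, tdz) * (1 - 1e-12)),
                 tol = 1e-14)$root * 65.38
}

# a tiny deterministic hces_data object with hand-computable densities
tiny_hces <- function(consumption, members = NULL, weights = NULL,
                      food_composition = NULL) {
  hh_ids <- unique(consumption$household_id)
  if (is.null(members)) {
    members <- tibble::tibble(
      household_id = hh_ids,
      member_id = paste0("m", hh_ids),
      sex = "male", age_months = 300, physiological_status = "none"
    )
  }
  if (is.null(weights)) weights <- rep(1, length(hh_ids))
  if (is.null(food_composition)) {
    food_composition <- tibble::tibble(
      food = c("staple", "greens", "oilfood", "flourfood", "bouillon"),
      energy_kcal_g = c(4, 0.5, 9, 3.5, 2.5),
      vitamin_a_ug_g = c(0, 2, 0, 0, 0),
      retinol_ug_g = c(0, 0, 0, 0, 0),
      folate_ug_g = c(0.3, 1, 0, 0.3, 0),
      folic_acid_ug_g = c(0, 0, 0, 0, 0),
      vitamin_b12_ug_g = c(0, 0, 0, 0, 0),
      iron_mg_g = c(0.02, 0.02, 0, 0.012, 0),
      zinc_mg_g = c(0.015, 0.003, 0, 0.008, 0),
      phytate_mg_g = c(5, 0.2, 0, 2, 0),
      vehicle = c("none", "none", "oil", "wheat_flour", "bouillon"),
      median_g_ame_day = NA_real_, log_sd = NA_real_
    )
  }
  structure(list(
    households = tibble::tibble(household_id = hh_ids,
                                survey_weight = weights),
    members = members,
    consumption = consumption,
    food_composition = food_composition,
    config = NULL
  ), class = "hces_data")
}

small_hces <- function(n = 400, seed = 42, ...) {
  generate_hces(synthetic_config(n_households = n, seed = seed, ...), REFS)
}

small_recalls <- function(n_wra = 200, n_children = 200, seed = 42, ...) {
  generate_recalls(synthetic_config(n_wra = n_wra, n_children = n_children,
                                    seed = seed, ...), REFS)
}
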