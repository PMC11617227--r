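# Absorption sub-models converting total intake to absorbed intake for iron,
# zinc and vitamin B12. Functional forms are implemented here; every
# coefficient is injectable via the packaged absorption_params.csv (see
# default_references()$absorption) so parameter sets can be swapped.

#' Absorption parameter sets as a nested list
#'
#' @param absorption The `absorption` tibble from [default_references()].
#' @return Named list of named numeric vectors, one per model.
#' @export
absorption_params <- function(absorption = default_references()$absorption) {
  split(stats::setNames(absorption$value, absorption$parameter),
        absorption$model) |>
    lapply(function(x) as.list(x))
}

#' Absorbed nonheme iron (log-linear prediction equation)
#'
#' Fractional absorption of total daily nonheme iron from a log-linear
#' regression on iron status (plasma ferritin) and dietary factors. Only
#' ferritin and phytate vary here; the remaining covariates (vitamin C,
#' meat/fish/poultry, tea, calcium) are fixed at the reference values shipped
#' in the parameter file. The fraction is strictly decreasing in ferritin and
#' in phytate, and is clamped to \[0, 1\].
#'
#' @param nonheme_iron Nonheme iron intake, mg/day (total diet excluding
#'   bouillon fortificant).
#' @param ferritin Plasma ferritin, ug/L; must be positive.
#' @param phytate Phytate intake, mg/day.
#' @param params Parameter list element `armah` from [absorption_params()].
#' @return Absorbed nonheme iron, mg/day.
#' @export
#' @examples
#' p <- absorption_params()
#' absorbed_nonheme_iron(10, ferritin = 15, phytate = 1500, params = p$armah)
absorbed_nonheme_iron <- function(nonheme_iron, ferritin, phytate,
                                  params = absorption_params()$armah) {
  if (any(nonheme_iron < 0) || any(phytate < 0)) {
    stop("iron and phytate intakes must be nonnegative")
  }
  if (any(ferritin <= 0)) stop("ferritin must be positive")
  p <- params
  ln_pct <- p$intercept +
    p$b_ln_ferritin * log(ferritin) +
    p$b_ln_vitc * log(p$ref_vitc_mg) +
    p$b_ln_mfp * log(p$ref_mfp_g + 0.1) +
    p$b_ln_tea * log(p$ref_tea_cups + 0.1) +
    p$b_ln_phytate * log(phytate + 1) +
    p$b_ln_calcium * log(p$ref_calcium_mg) +
    p$b_ln_nonheme * log(pmax(nonheme_iron, 0.1))
  frac <- pmin(pmax(exp(ln_pct) / 100, 0), 1)
  frac * nonheme_iron
}

#' Absorbed iron from the total diet plus fortified bouillon
#'
#' Three additive components: heme iron (a fixed share of non-bouillon iron,
#' absorbed at a fixed fraction), nonheme iron (through the prediction
#' equation in `"recall"` mode, where ferritin is available; or through a
#' flat fraction applied to total non-bouillon iron in `"hces"` mode, where
#' it is not), and iron from fortified bouillon absorbed at
#' `bouillon_absorption` (default 2%; 4% and 10% are the sensitivity
#' assumptions for more bioavailable formulations).
#'
#' In `"hces"` mode the heme split is not applied: the flat fraction covers
#' the total non-bouillon diet (configurable via `heme_fraction = 0`
#' semantics of the mode itself).
#'
#' @param total_iron Non-bouillon iron intake, mg/day.
#' @param bouillon_iron Iron from fortified bouillon, mg/day.
#' @param mode `"recall"` (ferritin-dependent equation) or `"hces"` (flat
#'   fraction).
#' @param ferritin,phytate Required in `"recall"` mode.
#' @param bouillon_absorption Fractional absorption of bouillon iron.
#' @param flat_absorption Flat fraction for `"hces"` mode.
#' @param params Full parameter list from [absorption_params()].
#' @return Absorbed iron, mg/day.
#' @export
absorbed_total_iron <- function(total_iron, bouillon_iron = 0,
                                mode = c("recall", "hces"),
                                ferritin = NULL, phytate = NULL,
                                bouillon_absorption = NULL,
                                flat_absorption = NULL,
                                params = absorption_params()) {
  mode <- match.arg(mode)
  if (any(total_iron < 0) || any(bouillon_iron < 0)) {
    stop("iron intakes must be nonnegative")
  }
  b_abs <- bouillon_absorption %||% params$bouillon_iron$default_absorption
  if (b_abs < 0 || b_abs > 1) stop("bouillon absorption must lie in [0, 1]")
  if (mode == "hces") {
    f <- flat_absorption %||% params$hces_iron$flat_absorption
    diet <- total_iron * f
  } else {
    if (is.null(ferritin) || is.null(phytate)) {
      stop("recall mode requires ferritin and phytate")
    }
    hf <- params$heme$heme_fraction
    ha <- params$heme$heme_absorption
    diet <- total_iron * hf * ha +
      absorbed_nonheme_iron(total_iron * (1 - hf), ferritin, phytate,
                            params$armah)
  }
  diet + bouillon_iron * b_abs
}

#' Absorbed zinc (saturable trivariate dose-response model)
#'
#' Absorbed zinc is the positive root of the saturable absorption relation
#' with maximal absorption `amax`, zinc-transporter constant `kr` and
#' phytate-binding constant `kp` (all in mmol/day): with
#' `A = amax + Z + kr (1 + P / kp)`,
#' `TAZ = (A - sqrt(A^2 - 4 amax Z)) / 2`. The result is monotone increasing
#' in zinc, decreasing in phytate, and bounded above by `amax`. Fortificant
#' zinc must be added to dietary zinc *before* calling this function.
#'
#' @param total_zinc Total zinc intake, mg/day (dietary + fortificant).
#' @param phytate Phytate intake, mg/day.
#' @param variant `"adult"` or `"child"` parameter set.
#' @param params Full parameter list from [absorption_params()].
#' @return Absorbed zinc, mg/day.
#' @export
#' @examples
#' absorbed_zinc(10, 2000, "adult")
absorbed_zinc <- function(total_zinc, phytate, variant = c("adult", "child"),
                          params = absorption_params()) {
  variant <- match.arg(variant)
  if (any(total_zinc < 0) || any(phytate < 0)) {
    stop("zinc and phytate must be nonnegative")
  }
  p <- params[[paste0("miller_", variant)]]
  if (any(unlist(p) <= 0)) stop("zinc model parameters must be positive")
  zn_mmol <- total_zinc / 65.38
  ph_mmol <- phytate / 660.04
  a <- p$amax_mmol + zn_mmol + p$kr_mmol * (1 + ph_mmol / p$kp_mmol)
  disc <- pmax(a^2 - 4 * p$amax_mmol * zn_mmol, 0)
  taz <- (a - sqrt(disc)) / 2
  taz * 65.38
}

#' Absorbed vitamin B12 (saturable active transport plus passive diffusion)
#'
#' Dose-dependent absorption with a saturable active component
#' `amax d / (d + k)` and a small passive fraction `p d`. The fractional
#' absorption `amax / (d + k) + p` is strictly decreasing in dose and the
#' absorbed amount is strictly concave, so doubling the dose less than
#' doubles absorption. Defaults are calibrated so that ~50% of a 1 ug/d
#' dose is absorbed. Fortificant B12 must be added to dietary B12 before
#' calling this function.
#'
#' @param total_b12 Total vitamin B12 intake, ug/day.
#' @param params Full parameter list from [absorption_params()].
#' @return Absorbed vitamin B12, ug/day.
#' @export
absorbed_b12 <- function(total_b12, params = absorption_params()) {
  if (any(total_b12 < 0)) stop("vitamin B12 intake must be nonnegative")
  p <- params$doets_modified
  p$amax_ug * total_b12 / (total_b12 + p$k_ug) +
    p$passive_fraction * total_b12
}
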