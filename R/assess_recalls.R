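# Scenario assessment for the 24-hr recall branch: staple and bouillon
# fortificants are added to person-days (add-then-shrink), usual intakes are
# fitted per target group, breast-milk nutrients are added for breastfed
# children (shrink-then-add), absorption models convert iron/zinc/B12 to the
# absorbed scale, and child results are post-stratified to 6-59 months.

staple_level <- function(staple_content, vehicle, nutrient) {
  if (is.null(staple_content) || nrow(staple_content) == 0) return(0)
  v <- staple_content$content[staple_content$vehicle == vehicle &
                                staple_content$nutrient == nutrient]
  if (length(v) == 0) 0 else sum(v)
}

#' Assess micronutrient adequacy from replicate 24-hr recalls
#'
#' Runs the whole individual-intake branch for one fortification setting.
#' Staple fortificants (mg/kg of vehicle, from [staple_content()]) and the
#' bouillon fortificant are added to each person-day before usual-intake
#' estimation; iron from bouillon is tracked separately and absorbed at
#' `bouillon_iron_absorption`. Inadequacy uses the EAR cut-point method
#' except iron (full-probability on the absorbed scale); zinc and B12
#' adequacy are evaluated on the absorbed scale (saturable zinc model;
#' dose-dependent B12 absorption against the EAR times the assumed 50%
#' reference absorption). Intakes above the UL use preformed retinol for
#' vitamin A and folic acid for folate; no UL exists for B12. Child
#' estimates are computed per breastfeeding stratum, shifted by breast-milk
#' nutrients, and post-stratified to 6-59 months.
#'
#' @param recall A `recall_data` object.
#' @param references Reference tables from [default_references()].
#' @param staple_content Optional staple fortificant table.
#' @param bouillon_levels Named vector of bouillon levels (ug/g for
#'   vitamin_a, folic_acid, vitamin_b12; mg/g for iron, zinc).
#' @param bouillon_iron_absorption Fractional absorption of bouillon iron.
#' @param bouillon_coverage Fraction of bouillon assumed fortified; persons
#'   are assigned fortified/unfortified by a Bernoulli draw under the seed.
#' @param poststrat_shares Named shares (`breastfed`, `non_breastfed`) for
#'   post-stratification; defaults to the generator config when available.
#' @param n_boot Person-bootstrap replicates.
#' @param seed Integer seed (bootstraps, coverage assignment).
#' @return Tibble with `group`, `nutrient`, `metric`, `point`, `ci_low`,
#'   `ci_high`, `n_effective` (percent scale).
#' @export
assess_recalls <- function(recall, references = default_references(),
                           staple_content = NULL,
                           bouillon_levels = numeric(0),
                           bouillon_iron_absorption = 0.02,
                           bouillon_coverage = 1,
                           poststrat_shares = NULL,
                           n_boot = 500, seed = 1L) {
  stopifnot(inherits(recall, "recall_data"))
  if (any(unlist(bouillon_levels) < 0)) stop("fortification levels must be >= 0")
  if (bouillon_coverage < 0 || bouillon_coverage > 1) {
    stop("bouillon coverage must lie in [0, 1]")
  }
  rc <- recall$recalls
  shares <- poststrat_shares %||%
    (if (!is.null(recall$config)) recall$config$poststrat_shares else NULL) %||%
    c(breastfed = 0.25, non_breastfed = 0.75)
  params <- absorption_params(references$absorption)
  lv <- function(nu) {
    l <- unname(bouillon_levels[nu]); if (is.null(l) || is.na(l)) 0 else l
  }

  # coverage: person-level Bernoulli fortified/unfortified assignment
  if (bouillon_coverage < 1) {
    ids <- unique(rc$person_id)
    fortified <- with_seed(derive_seed(seed, "coverage"),
                           stats::runif(length(ids)) < bouillon_coverage)
    mult <- as.numeric(fortified)[match(rc$person_id, ids)]
  } else mult <- 1
  rc$fort_bouillon_g <- rc$bouillon_g * mult

  # staple fortificants (day level, before usual-intake estimation)
  sc <- staple_content
  oil_va <- staple_level(sc, "oil", "vitamin_a")
  fl <- lapply(c(vitamin_a = "vitamin_a", folic_acid = "folic_acid",
                 vitamin_b12 = "vitamin_b12", iron = "iron", zinc = "zinc"),
               function(nu) staple_level(sc, "wheat_flour", nu))
  rc$vitamin_a <- rc$vitamin_a + rc$oil_g * oil_va + rc$flour_g * fl$vitamin_a
  rc$retinol <- rc$retinol + rc$oil_g * oil_va + rc$flour_g * fl$vitamin_a
  rc$folate <- rc$folate + 1.7 * rc$flour_g * fl$folic_acid
  rc$folic_acid <- rc$folic_acid + rc$flour_g * fl$folic_acid
  rc$vitamin_b12 <- rc$vitamin_b12 + rc$flour_g * fl$vitamin_b12
  rc$iron <- rc$iron + rc$flour_g * fl$iron / 1000
  rc$zinc <- rc$zinc + rc$flour_g * fl$zinc / 1000

  # bouillon fortificant, add-then-shrink (iron handled on the absorbed side)
  rc <- add_then_shrink_fortificant(rc, "vitamin_a", lv("vitamin_a"),
                                    "fort_bouillon_g")
  rc <- add_then_shrink_fortificant(rc, "retinol", lv("vitamin_a"),
                                    "fort_bouillon_g")
  rc <- add_then_shrink_fortificant(rc, "folate", lv("folic_acid"),
                                    "fort_bouillon_g", factor = 1.7)
  rc <- add_then_shrink_fortificant(rc, "folic_acid", lv("folic_acid"),
                                    "fort_bouillon_g")
  rc <- add_then_shrink_fortificant(rc, "vitamin_b12", lv("vitamin_b12"),
                                    "fort_bouillon_g")
  rc <- add_then_shrink_fortificant(rc, "zinc", lv("zinc"), "fort_bouillon_g")

  tg <- references$groups$target_group[
    match(rc$group_id, references$groups$group_id)]
  nr <- references$nutrients
  ironreq <- references$iron_requirements
  bm_vol <- references$breastmilk_volumes
  bm_cmp <- references$breastmilk_composition
  ref_of <- function(nutrient, group_ids, what) {
    r <- nr[nr$nutrient == nutrient, ]
    r[[what]][match(group_ids, r$group_id)]
  }
  milk_add <- function(p, nutrient) {
    # per-person breast-milk nutrient amount (0 for non-breastfed)
    conc <- bm_cmp$amount_per_g[bm_cmp$nutrient == nutrient]
    out <- rep(0, nrow(p))
    bf <- which(p$breastfed %in% TRUE)
    if (length(bf)) {
      vol <- rep(NA_real_, length(bf))
      for (i in seq_len(nrow(bm_vol))) {
        hit <- p$age_months[bf] >= bm_vol$age_low_months[i] &
          p$age_months[bf] < bm_vol$age_high_months[i]
        vol[hit] <- bm_vol$milk_g_day[i]
      }
      if (anyNA(vol)) stop("breastfed child outside milk-volume age bands")
      out[bf] <- vol * conc
    }
    out
  }

  out <- list()
  for (cls in c("wra", "child_6_59")) {
    sub <- rc[!is.na(tg) & tg == cls, ]
    if (nrow(sub) == 0) next
    cols <- c("vitamin_a", "retinol", "folate", "folic_acid", "vitamin_b12",
              "iron", "zinc", "phytate", "fort_bouillon_g")
    models <- lapply(cols, function(cc) fit_usual(sub, cc))
    names(models) <- cols
    p <- models[[1]]$persons
    u <- lapply(models, function(m) m$persons$usual)
    is_child <- cls == "child_6_59"
    milk <- if (is_child) {
      lapply(c(vitamin_a = "vitamin_a", retinol = "retinol",
               folate = "folate", vitamin_b12 = "vitamin_b12",
               iron = "iron", zinc = "zinc"),
             function(nu) milk_add(p, nu))
    } else NULL
    m_of <- function(nu) if (is_child) milk[[nu]] else 0

    est <- function(values, nutrient, metric, label) {
      res <- if (is_child) {
        bf <- p$breastfed %in% TRUE
        strata <- list(breastfed = bf, non_breastfed = !bf)
        present <- vapply(strata, any, TRUE)
        if (all(present)) {
          es <- Map(function(idx, nm) {
            boot_prevalence(values[idx], p$survey_weight[idx],
                            n_boot = n_boot,
                            seed = derive_seed(seed, paste0(label, nm)))
          }, strata, names(strata))
          poststratify_6_59(es, shares[names(strata)])
        } else {
          boot_prevalence(values, p$survey_weight, n_boot = n_boot,
                          seed = derive_seed(seed, label))
        }
      } else {
        boot_prevalence(values, p$survey_weight, n_boot = n_boot,
                        seed = derive_seed(seed, label))
      }
      res$group <- cls; res$nutrient <- nutrient; res$metric <- metric
      b <- attr(res, "boot")
      res <- res[, c("group", "nutrient", "metric", "point", "ci_low",
                     "ci_high", "n_effective")]
      attr(res, "boot") <- b
      res
    }

    # vitamin A (total RAE vs EAR; preformed retinol vs UL)
    va <- u$vitamin_a + m_of("vitamin_a")
    out[[length(out) + 1]] <- est(
      as.numeric(va < ref_of("vitamin_a", p$group_id, "ear")),
      "vitamin_a", "inadequate", paste0(cls, "_va_in"))
    ret <- u$retinol + m_of("retinol")
    out[[length(out) + 1]] <- est(
      as.numeric(ret > ref_of("vitamin_a", p$group_id, "ul")),
      "vitamin_a", "above_ul", paste0(cls, "_va_ul"))

    # folate (DFE vs EAR; folic acid vs UL)
    fo <- u$folate + m_of("folate")
    out[[length(out) + 1]] <- est(
      as.numeric(fo < ref_of("folate", p$group_id, "ear")),
      "folate", "inadequate", paste0(cls, "_fo_in"))
    out[[length(out) + 1]] <- est(
      as.numeric(u$folic_acid > ref_of("folate", p$group_id, "ul")),
      "folate", "above_ul", paste0(cls, "_fo_ul"))

    # vitamin B12: absorbed vs EAR x reference absorption; no UL
    b12_abs <- absorbed_b12(u$vitamin_b12 + m_of("vitamin_b12"), params)
    b12_req <- ref_of("vitamin_b12", p$group_id, "ear") *
      params$b12_requirement$absorbed_fraction_of_ear
    out[[length(out) + 1]] <- est(
      as.numeric(b12_abs < b12_req),
      "vitamin_b12", "inadequate", paste0(cls, "_b12_in"))

    # iron: absorbed usual intake, full-probability approach
    fe_diet <- u$iron + m_of("iron")
    fe_bou <- u$fort_bouillon_g * lv("iron")
    fe_abs <- absorbed_total_iron(
      fe_diet, bouillon_iron = fe_bou, mode = "recall",
      ferritin = p$ferritin_ug_l, phytate = u$phytate,
      bouillon_absorption = bouillon_iron_absorption, params = params)
    meanlog <- log(ironreq$median_absorbed_mg[
      match(p$group_id, ironreq$group_id)])
    sdlog <- ironreq$log_sd[match(p$group_id, ironreq$group_id)]
    risk <- ifelse(fe_abs <= 0, 1,
                   stats::plnorm(fe_abs, meanlog, sdlog, lower.tail = FALSE))
    out[[length(out) + 1]] <- est(risk, "iron", "inadequate",
                                  paste0(cls, "_fe_in"))
    out[[length(out) + 1]] <- est(
      as.numeric((u$iron + fe_bou) > ref_of("iron", p$group_id, "ul")),
      "iron", "above_ul", paste0(cls, "_fe_ul"))

    # zinc: absorbed (saturable model) vs physiological requirement; UL total
    zn_tot <- u$zinc + m_of("zinc")
    zn_abs <- absorbed_zinc(zn_tot, u$phytate,
                            if (is_child) "child" else "adult", params)
    out[[length(out) + 1]] <- est(
      as.numeric(zn_abs < ref_of("zinc", p$group_id, "ear")),
      "zinc", "inadequate", paste0(cls, "_zn_in"))
    out[[length(out) + 1]] <- est(
      as.numeric(u$zinc > ref_of("zinc", p$group_id, "ul")),
      "zinc", "above_ul", paste0(cls, "_zn_ul"))
  }
  boots <- lapply(out, attr, "boot")
  res <- dplyr::bind_rows(out)
  attr(res, "boot") <- boots
  res
}
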