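# Synthetic survey generator. The defaults are the study conditions the
# pipeline is tested under: right-skewed per-AME food quantities with
# episodic-acquisition outliers, bouillon consumed by most households with a
# median apparent intake of ~2.2 g/d per adult-male equivalent (so ~1.6-2.0 g/d apparent intake for adults), and replicate
# 24-hr recalls with separable between- and within-person variation.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Default synthetic food list
#'
#' Twelve generic food items (staples, oil, legumes, fish/meat, vegetables,
#' fruit, sugar, bouillon and a wheat-flour product) with plausible energy and
#' nutrient densities per gram, phytate content, fortification-vehicle flags
#' and right-skewed per-AME consumption parameters. These are synthetic
#' values, not any country's food-composition data.
#'
#' @return A tibble, one row per food.
#' @export
default_food_list <- function() read_ref_csv("food_list.csv")

#' Default household composition distribution
#'
#' A categorical distribution over household member rosters (sex and age-band
#' per member) emulating the mix of nuclear, extended and single-parent
#' households in the surveyed populations.
#'
#' @return A list with elements `prob` (numeric) and `members` (list of
#'   tibbles with `sex`, `age_low_months`, `age_high_months`).
#' @export
default_household_compositions <- function() {
  mk <- function(...) {
    rows <- list(...)
    tibble::tibble(
      sex = vapply(rows, `[[`, "", 1),
      age_low_months = vapply(rows, function(r) as.numeric(r[2]), 0),
      age_high_months = vapply(rows, function(r) as.numeric(r[3]), 0)
    )
  }
  man <- c("male", 216, 720); wra <- c("female", 216, 600)
  child <- c("any", 6, 60); adol <- c("any", 120, 180)
  list(
    prob = c(0.30, 0.20, 0.15, 0.10, 0.10, 0.05, 0.05, 0.05),
    members = list(
      mk(man, wra, child, child),
      mk(man, wra, child, adol),
      mk(man, wra, child),
      mk(wra, child, child),
      mk(man, wra),
      mk(wra, c("female", 600, 1440), child),
      mk(c("male", 720, 1440), c("female", 600, 1440)),
      mk(man, wra, c("female", 180, 216), child, c("any", 60, 120))
    )
  )
}

default_recall_medians <- function() {
  tibble::tribble(
    ~variable,      ~wra,  ~child,
    "vitamin_a",     400,    180,
    "retinol",       120,     55,
    "folate",        280,    120,
    "folic_acid",     20,     10,
    "vitamin_b12",   1.2,   0.55,
    "iron",           11,      5,
    "zinc",            9,    4.2,
    "phytate",      2200,    900,
    "bouillon_g",    1.9,    1.0,
    "oil_g",          20,      9,
    "flour_g",        50,     22
  )
}

#' Configuration for the synthetic survey generator
#'
#' Bundles every tunable of [generate_hces()] and [generate_recalls()] with
#' validation. All randomness is reproducible from `seed`.
#'
#' @param n_households Number of households for the HCES branch.
#' @param seed Integer seed; fixes every draw of the generator.
#' @param bouillon_consumer_fraction Probability a household (or recall
#'   respondent) consumes bouillon at all.
#' @param bouillon_median_g_per_ame_day Median bouillon grams per
#'   adult-male-equivalent per day among consumers.
#' @param bouillon_log_sd Log-scale SD of bouillon consumption.
#' @param food_list Food table as in [default_food_list()].
#' @param household_compositions As [default_household_compositions()].
#' @param outlier_fraction Share of household-by-food quantities inflated to
#'   emulate episodic acquisition.
#' @param outlier_multiplier Inflation factor for those outliers.
#' @param n_wra,n_children Persons per target group in the recall branch.
#' @param recall_days Days of recall for the replicate subset.
#' @param replicate_fraction Share of persons with replicate recall days.
#' @param within_person_cv,between_person_cv Coefficients of variation of
#'   day-to-day and person-to-person intake on the original scale.
#' @param breastfed_fraction_12_23mo Probability a 12-23-mo-old child is
#'   breastfed.
#' @param poststrat_shares Named shares (`breastfed`, `non_breastfed`) used to
#'   post-stratify child results to 6-59 mo; must sum to 1.
#' @param recall_medians Median usual intakes per day by target group, as in
#'   `default_recall_medians()`.
#' @param ferritin_median Named medians (`wra`, `child`) of plasma ferritin in
#'   ug/L.
#' @param ferritin_log_sd Log-scale SD of ferritin.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_households = 5000,
                             seed = 1L,
                             bouillon_consumer_fraction = 0.9,
                             bouillon_median_g_per_ame_day = 2.2,
                             bouillon_log_sd = 0.7,
                             food_list = default_food_list(),
                             household_compositions =
                               default_household_compositions(),
                             outlier_fraction = 0.03,
                             outlier_multiplier = 8,
                             n_wra = 900,
                             n_children = 900,
                             recall_days = 2,
                             replicate_fraction = 0.5,
                             within_person_cv = 0.4,
                             between_person_cv = 0.4,
                             breastfed_fraction_12_23mo = 0.8,
                             poststrat_shares = c(breastfed = 0.25,
                                                  non_breastfed = 0.75),
                             recall_medians = default_recall_medians(),
                             ferritin_median = c(wra = 30, child = 20),
                             ferritin_log_sd = 0.6) {
  probs <- c(bouillon_consumer_fraction, outlier_fraction,
             replicate_fraction, breastfed_fraction_12_23mo)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_households < 1) stop("n_households must be at least 1")
  if (within_person_cv < 0 || between_person_cv <= 0) {
    stop("coefficients of variation must be positive ",
         "(within-person CV may be 0 for the no-noise limit)")
  }
  if (bouillon_median_g_per_ame_day <= 0 || bouillon_log_sd <= 0) {
    stop("bouillon consumption parameters must be positive")
  }
  if (abs(sum(poststrat_shares) - 1) > 1e-9) {
    stop("poststrat_shares must sum to 1")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_households, " households, ",
      x$n_wra + x$n_children, " recall persons, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic household consumption survey
#'
#' Draws household rosters from the configured composition distribution,
#' computes each household's total adult-male-equivalent (AME), and assigns
#' per-food apparent daily consumption as (log-normal per-AME quantity) x
#' (household AME), with a configurable fraction of quantities inflated to
#' emulate episodic-acquisition outliers. Bouillon is present in a
#' Bernoulli subset of households. Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @param references Reference tables from [default_references()] (used for
#'   the energy requirements behind the AME weights).
#' @return An object of class `hces_data`: a list with tibbles `households`,
#'   `members`, `consumption`, the `food_composition` table, and the config.
#' @export
generate_hces <- function(config, references = default_references()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_households
    comp <- config$household_compositions
    comp_idx <- sample.int(length(comp$prob), n, replace = TRUE,
                           prob = comp$prob)
    type_sizes <- vapply(comp$members, nrow, 0L)
    sizes <- type_sizes[comp_idx]
    specs_all <- dplyr::bind_rows(comp$members)
    starts <- cumsum(c(0L, type_sizes[-length(type_sizes)]))
    spec <- specs_all[sequence(sizes) + rep(starts[comp_idx], sizes), ]
    members <- tibble::tibble(
      household_id = rep(seq_len(n), sizes),
      member_id = paste0(rep(seq_len(n), sizes), "_", sequence(sizes)),
      sex = ifelse(spec$sex == "any",
                   sample(c("male", "female"), nrow(spec), replace = TRUE),
                   spec$sex),
      age_months = floor(stats::runif(nrow(spec), spec$age_low_months,
                                      spec$age_high_months)),
      physiological_status = "none"
    )
    households <- tibble::tibble(
      household_id = seq_len(n),
      survey_weight = stats::runif(n, 0.5, 1.5)
    )

    ame <- ame_weights(members, references)
    ame_tot <- stats::aggregate(ame$ame_weight,
                                by = list(household_id = ame$household_id),
                                FUN = sum)
    ame_total <- ame_tot$x[match(seq_len(n), ame_tot$household_id)]

    fl <- config$food_list
    cons <- lapply(seq_len(nrow(fl)), function(i) {
      f <- fl$food[i]
      if (identical(fl$vehicle[i], "bouillon")) {
        consumer <- stats::runif(n) < config$bouillon_consumer_fraction
        g_ame <- stats::rlnorm(n, log(config$bouillon_median_g_per_ame_day),
                               config$bouillon_log_sd) * consumer
      } else {
        g_ame <- stats::rlnorm(n, log(fl$median_g_ame_day[i]), fl$log_sd[i])
        infl <- stats::runif(n) < config$outlier_fraction
        g_ame[infl] <- g_ame[infl] * config$outlier_multiplier
      }
      tibble::tibble(household_id = seq_len(n), food = f,
                     g_day = g_ame * ame_total)
    })
    consumption <- dplyr::bind_rows(cons)

    structure(list(households = households, members = members,
                   consumption = consumption,
                   food_composition = fl, config = config),
              class = "hces_data")
  })
}

#' @export
print.hces_data <- function(x, ...) {
  cat("<hces_data> ", nrow(x$households), " households, ",
      nrow(x$members), " members, ",
      length(unique(x$consumption$food)), " foods\n", sep = "")
  invisible(x)
}

#' Generate synthetic replicate 24-hr recalls
#'
#' Person-level usual intakes are log-normal with the configured
#' between-person CV; day-level intakes multiply the usual intake by
#' mean-one log-normal within-person noise, so with `within_person_cv = 0`
#' every replicate day equals the usual intake. A configurable subset of
#' persons contributes `recall_days` replicate days. The generating
#' parameters are recorded in the returned object's `truth` element so
#' parameter-recovery tests can compare estimates against analytic values
#' (usual intake below a cutoff `c` has true prevalence
#' `pnorm((log(c) - meanlog) / sdlog_between)`).
#'
#' @inheritParams generate_hces
#' @return An object of class `recall_data`: list with tibble `recalls`
#'   (one row per person-day), `truth`, and the config.
#' @export
generate_recalls <- function(config, references = default_references()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 1L, {
    n_w <- config$n_wra; n_c <- config$n_children
    persons <- tibble::tibble(
      person_id = c(sprintf("w%04d", seq_len(n_w)),
                    sprintf("c%04d", seq_len(n_c))),
      class = rep(c("wra", "child"), c(n_w, n_c)),
      sex = c(rep("female", n_w),
              sample(c("male", "female"), n_c, replace = TRUE)),
      age_months = c(floor(stats::runif(n_w, 180, 600)),
                     floor(stats::runif(n_c, 12, 60))),
      survey_weight = stats::runif(n_w + n_c, 0.5, 1.5)
    )
    persons$breastfed <- persons$class == "child" & persons$age_months < 24 &
      stats::runif(nrow(persons)) < config$breastfed_fraction_12_23mo
    persons$group_id <- match_group(persons$age_months, persons$sex,
                                    references$groups, target_only = TRUE)
    persons$ferritin_ug_l <- stats::rlnorm(
      nrow(persons),
      log(config$ferritin_median[persons$class]),
      config$ferritin_log_sd
    )

    sd_b <- cv_to_sdlog(config$between_person_cv)
    sd_w <- cv_to_sdlog(config$within_person_cv)
    n_rep <- round(config$replicate_fraction * nrow(persons))
    rep_ids <- sample(persons$person_id, n_rep)
    k <- ifelse(persons$person_id %in% rep_ids, config$recall_days, 1L)

    days <- tibble::tibble(
      person_id = rep(persons$person_id, k),
      day = unlist(lapply(k, seq_len))
    )
    recalls <- dplyr::left_join(days, persons, by = "person_id")

    med <- config$recall_medians
    truth <- list()
    for (i in seq_len(nrow(med))) {
      v <- med$variable[i]
      usual <- stats::rlnorm(nrow(persons),
                             log(ifelse(persons$class == "wra",
                                        med$wra[i], med$child[i])),
                             sd_b)
      if (v == "bouillon_g") {
        consumer <- stats::runif(nrow(persons)) <
          config$bouillon_consumer_fraction
        usual <- usual * consumer
      }
      u_day <- usual[match(recalls$person_id, persons$person_id)]
      noise <- if (sd_w > 0) {
        exp(stats::rnorm(nrow(recalls), 0, sd_w) - sd_w^2 / 2)
      } else 1
      recalls[[v]] <- u_day * noise
      truth[[v]] <- list(
        meanlog = c(wra = log(med$wra[i]), child = log(med$child[i])),
        sdlog_between = sd_b, sdlog_within = sd_w
      )
    }
    structure(list(recalls = recalls, truth = truth, config = config),
              class = "recall_data")
  })
}

#' @export
print.recall_data <- function(x, ...) {
  cat("<recall_data> ", length(unique(x$recalls$person_id)), " persons, ",
      nrow(x$recalls), " person-days\n", sep = "")
  invisible(x)
}

#' Generating parameters of a synthetic survey
#'
#' @param x A `recall_data` object.
#' @return The list of generating parameters per variable.
#' @export
survey_truth <- function(x) {
  stopifnot(inherits(x, "recall_data"))
  x$truth
}

#' Write a synthetic survey to plain CSV files
#'
#' Writes the same schemas the pipeline reads: `households.csv`,
#' `members.csv`, `consumption.csv`, `food_composition.csv` for household
#' data; `recalls.csv` for recall data; plus `truth.json` with the
#' generating parameters.
#'
#' @param x An `hces_data` or `recall_data` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  if (inherits(x, "hces_data")) {
    wr(x$households, "households.csv")
    wr(x$members, "members.csv")
    wr(x$consumption, "consumption.csv")
    wr(x$food_composition, "food_composition.csv")
    truth <- list(kind = "hces", seed = x$config$seed,
                  n_households = x$config$n_households)
  } else if (inherits(x, "recall_data")) {
    wr(x$recalls, "recalls.csv")
    truth <- c(list(kind = "recall", seed = x$config$seed), x$truth)
  } else stop("x must be hces_data or recall_data")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a survey written by [write_survey()]
#'
#' @param dir Directory containing the CSV files.
#' @return An `hces_data` or `recall_data` object (without config).
#' @export
read_survey <- function(dir) {
  rd <- function(name) {
    tibble::as_tibble(utils::read.csv(file.path(dir, name),
                                      stringsAsFactors = FALSE))
  }
  if (file.exists(file.path(dir, "households.csv"))) {
    structure(list(households = rd("households.csv"),
                   members = rd("members.csv"),
                   consumption = rd("consumption.csv"),
                   food_composition = rd("food_composition.csv"),
                   config = NULL),
              class = "hces_data")
  } else {
    rc <- rd("recalls.csv")
    truth <- NULL
    tj <- file.path(dir, "truth.json")
    if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    structure(list(recalls = rc, truth = truth, config = NULL),
              class = "recall_data")
  }
}
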