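# 24-hr recall branch: a simplified transform-decompose-shrink usual-intake
# estimator (in place of the NCI MIXTRAN/DISTRIB machinery; see the methods
# vignette for what this does and does not capture), EAR cut-point and
# full-probability prevalence, add-then-shrink fortification, shrink-then-add
# breast-milk nutrients, and post-stratification to 6-59 months.

#' Fit a simplified usual-intake model to replicate recalls
#'
#' Day intakes are log-transformed (with a small offset, half the smallest
#' positive value, when zeros are present), the within-person variance is
#' pooled over persons with replicate days, the between-person variance is
#' estimated by method of moments, and each person's mean is shrunk toward
#' the grand mean with the classical adjustment factor
#' `sqrt(between / (between + within / k))`, which removes the day-to-day
#' noise so the spread of the back-transformed values matches the usual
#' (long-term) intake distribution. Back-transformation applies the
#' log-normal mean correction `exp(. + within/2)`.
#'
#' @param recalls Person-day tibble with `person_id`, `survey_weight`, a
#'   `day` column and the intake column `nutrient`; person-level columns
#'   (`group_id`, `breastfed`, `age_months`) are carried through when
#'   present.
#' @param nutrient Name of the intake column to model.
#' @return An object of class `usual_intake_model`: list with the variance
#'   components (`between_sd`, `within_sd`, transformed scale), `grand_mean`,
#'   `offset`, and a `persons` tibble (sorted by `person_id`) with the
#'   shrunken `usual` intake per person.
#' @export
fit_usual <- function(recalls, nutrient) {
  stopifnot(nutrient %in% names(recalls))
  x <- recalls[[nutrient]]
  if (any(x < 0, na.rm = TRUE)) stop("intakes must be nonnegative")
  offset <- 0
  if (any(x == 0, na.rm = TRUE)) {
    pos <- x[x > 0 & !is.na(x)]
    offset <- if (length(pos)) min(pos) / 2 else 0.5
  }
  y <- log(x + offset)
  pid <- as.character(recalls$person_id)
  ord_levels <- sort(unique(pid))
  f <- factor(pid, levels = ord_levels)
  k <- as.integer(table(f))
  ybar <- as.numeric(tapply(y, f, mean))
  ss_within <- as.numeric(tapply(y, f, function(v) sum((v - mean(v))^2)))
  df_within <- sum(k - 1L)
  if (df_within == 0) {
    stop("cannot separate variance components: no person has replicate days")
  }
  within_var <- sum(ss_within) / df_within

  first <- !duplicated(f)
  w <- recalls$survey_weight[first][order(f[first])]
  if (is.null(w)) w <- rep(1, length(k))
  mu <- stats::weighted.mean(ybar, w)
  v_means <- sum(w * (ybar - mu)^2) / sum(w)
  between_var <- max(v_means - within_var * mean(1 / k), 0)

  shrink <- if (between_var > 0) {
    sqrt(between_var / (between_var + within_var / k))
  } else rep(0, length(k))
  usual <- pmax(exp(mu + shrink * (ybar - mu) + within_var / 2) - offset, 0)

  persons <- tibble::tibble(person_id = ord_levels, k = k,
                            person_mean_t = ybar, usual = usual,
                            survey_weight = w)
  for (col in c("group_id", "breastfed", "age_months", "class",
                "ferritin_ug_l")) {
    if (col %in% names(recalls)) {
      persons[[col]] <- recalls[[col]][first][order(f[first])]
    }
  }
  structure(list(nutrient = nutrient, transform = "log", offset = offset,
                 grand_mean = mu, between_sd = sqrt(between_var),
                 within_sd = sqrt(within_var), persons = persons),
            class = "usual_intake_model")
}

#' @export
print.usual_intake_model <- function(x, ...) {
  cat("<usual_intake_model> ", x$nutrient, ": ", nrow(x$persons),
      " persons; log-scale between SD ", signif(x$between_sd, 3),
      ", within SD ", signif(x$within_sd, 3), "\n", sep = "")
  invisible(x)
}

#' Prevalence of usual intake below the EAR (cut-point method)
#'
#' @param model A fitted [fit_usual()] model (possibly after
#'   [shrink_then_add_breastmilk()]).
#' @param ear EAR per day; scalar or one value per person (the person's
#'   stratum EAR).
#' @param n_boot Person-bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional bootstrap seed.
#' @return One-row tibble: `point`, `ci_low`, `ci_high`, `n_effective`
#'   (percent), bootstrap replicates in attribute `"boot"`.
#' @export
prevalence_ear_cutpoint <- function(model, ear, n_boot = 500, conf = 0.95,
                                    seed = NULL) {
  stopifnot(inherits(model, "usual_intake_model"))
  p <- model$persons
  boot_prevalence(as.numeric(p$usual < ear), p$survey_weight,
                  n_boot = n_boot, conf = conf, seed = seed)
}

#' Full-probability prevalence of inadequacy (absorbed scale)
#'
#' Weighted mean, over persons, of the probability that a log-normal
#' absorbed-nutrient requirement exceeds the person's absorbed usual intake.
#' Zero absorbed intake carries risk 1.
#'
#' @param absorbed_usual Absorbed usual intake per person, amount/day.
#' @param requirement_meanlog,requirement_sdlog Log-normal requirement
#'   parameters, scalar or per person.
#' @param weights Person survey weights.
#' @inheritParams prevalence_ear_cutpoint
#' @return One-row tibble as [prevalence_ear_cutpoint()].
#' @export
prevalence_full_probability <- function(absorbed_usual, requirement_meanlog,
                                        requirement_sdlog, weights = NULL,
                                        n_boot = 500, conf = 0.95,
                                        seed = NULL) {
  if (anyNA(requirement_meanlog) || anyNA(requirement_sdlog)) {
    stop("requirement distribution missing for some persons")
  }
  risk <- ifelse(absorbed_usual <= 0, 1,
                 stats::plnorm(absorbed_usual, requirement_meanlog,
                               requirement_sdlog, lower.tail = FALSE))
  boot_prevalence(risk, weights, n_boot = n_boot, conf = conf, seed = seed)
}

#' Add a bouillon fortificant to recall days (add-then-shrink)
#'
#' Each person-day's intake is incremented by that day's bouillon grams times
#' the fortification level *before* usual-intake estimation, so the
#' fortificant is carried through the measurement-error model like any other
#' food source.
#'
#' @param recalls Person-day tibble.
#' @param nutrient Intake column to augment.
#' @param level Fortification level, amount per gram of bouillon.
#' @param bouillon_col Column holding bouillon grams per day.
#' @param factor Unit conversion applied to the added amount (e.g. 1.7 to
#'   express added folic acid as dietary folate equivalents).
#' @return The augmented tibble.
#' @export
add_then_shrink_fortificant <- function(recalls, nutrient, level,
                                        bouillon_col = "bouillon_g",
                                        factor = 1) {
  if (level < 0) stop("fortification level must be nonnegative")
  recalls[[nutrient]] <- recalls[[nutrient]] +
    recalls[[bouillon_col]] * level * factor
  recalls
}

#' Add breast-milk nutrients to usual intakes (shrink-then-add)
#'
#' For breastfed children the daily nutrient contribution of breast milk
#' (age-band milk volume times milk nutrient concentration) is added *after*
#' usual-intake estimation, since milk intake is not captured by the recall's
#' food list. A breastfed child outside the configured age bands is an error.
#'
#' @param model A fitted [fit_usual()] model whose `persons` carry
#'   `breastfed` and `age_months`.
#' @param volumes Breast-milk volume table (`age_low_months`,
#'   `age_high_months`, `milk_g_day`).
#' @param composition Milk composition table (`nutrient`, `amount_per_g`).
#' @param nutrient Nutrient whose concentration to use (defaults to the
#'   model's nutrient).
#' @return The model with breastfed children's `usual` shifted by
#'   `volume x concentration`.
#' @export
shrink_then_add_breastmilk <- function(model, volumes, composition,
                                       nutrient = model$nutrient) {
  stopifnot(inherits(model, "usual_intake_model"))
  p <- model$persons
  if (is.null(p$breastfed) || is.null(p$age_months)) {
    stop("model persons lack breastfed/age_months columns")
  }
  conc <- composition$amount_per_g[composition$nutrient == nutrient]
  if (length(conc) != 1) stop("no milk composition entry for ", nutrient)
  bf <- which(p$breastfed %in% TRUE)
  if (length(bf)) {
    vol <- rep(NA_real_, length(bf))
    for (i in seq_len(nrow(volumes))) {
      hit <- p$age_months[bf] >= volumes$age_low_months[i] &
        p$age_months[bf] < volumes$age_high_months[i]
      vol[hit] <- volumes$milk_g_day[i]
    }
    if (anyNA(vol)) {
      stop("breastfed child at ", p$age_months[bf][is.na(vol)][1],
           " months falls outside the configured milk-volume age bands")
    }
    p$usual[bf] <- p$usual[bf] + vol * conc
  }
  model$persons <- p
  model
}

#' Post-stratify stratum prevalences to children 6-59 months
#'
#' Share-weighted average of stratum prevalence estimates (e.g. breastfed and
#' non-breastfed children), combining bootstrap replicates replicate-wise so
#' the confidence interval reflects both strata.
#'
#' @param estimates List of one-row prevalence tibbles (with `"boot"`
#'   attributes), one per stratum, in the order of `shares`.
#' @param shares Numeric stratum shares; must sum to 1 (tolerance 1e-9).
#' @param conf Confidence level for the combined interval.
#' @return One-row tibble as [prevalence_ear_cutpoint()].
#' @export
#' @examples
#' a <- structure(tibble::tibble(point = 10, ci_low = 8, ci_high = 12,
#'                               n_effective = 50), boot = numeric(0))
#' b <- structure(tibble::tibble(point = 50, ci_low = 45, ci_high = 55,
#'                               n_effective = 200), boot = numeric(0))
#' poststratify_6_59(list(a, b), c(0.2, 0.8))$point # 42
poststratify_6_59 <- function(estimates, shares, conf = 0.95) {
  if (abs(sum(shares) - 1) > 1e-9) stop("stratum shares must sum to 1")
  stopifnot(length(estimates) == length(shares))
  pts <- vapply(estimates, function(e) e$point, 0)
  point <- sum(shares * pts)
  boots <- lapply(estimates, attr, "boot")
  lens <- vapply(boots, length, 0L)
  if (all(lens > 0) && length(unique(lens)) == 1) {
    reps <- Reduce(`+`, Map(`*`, shares, boots))
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
    ci_low <- min(qs[1], point); ci_high <- max(qs[2], point)
  } else {
    reps <- numeric(0)
    ci_low <- sum(shares * vapply(estimates, function(e) e$ci_low, 0))
    ci_high <- sum(shares * vapply(estimates, function(e) e$ci_high, 0))
  }
  out <- tibble::tibble(point = point, ci_low = ci_low, ci_high = ci_high,
                        n_effective = sum(vapply(estimates,
                                                 function(e) e$n_effective,
                                                 0)))
  attr(out, "boot") <- reps
  out
}
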