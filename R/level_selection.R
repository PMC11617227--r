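# WHO-style selection of bouillon fortification levels: maximise the
# reduction in inadequate (apparent) intake subject to keeping intakes above
# the UL below a chosen threshold in every group considered.

#' Criteria for selecting fortification levels
#'
#' A level is "too high" when, for any group considered, the prevalence of
#' intake above the UL — the point estimate or the lower bound of its 95%
#' confidence interval, per `basis` — reaches `ul_threshold`. Among levels
#' that are not too high, the preferred level maximises the reduction in
#' inadequacy; the WHO goal flags groups whose residual inadequacy falls
#' below `inadequacy_goal` (2.5% by default). For zinc the child UL can be
#' excluded from consideration (`exclude_child_ul`), reflecting the
#' uncertainty around the UL for preschool children.
#'
#' @param ul_threshold Percent, conventionally 0.5, 5 or 10.
#' @param basis `"point_estimate"` or `"lower_ci"`.
#' @param inadequacy_goal Percent (WHO: 2.5).
#' @param exclude_child_ul Drop children's above-UL constraint (zinc option).
#' @return Object of class `selection_criteria`.
#' @export
selection_criteria <- function(ul_threshold = 5,
                               basis = c("point_estimate", "lower_ci"),
                               inadequacy_goal = 2.5,
                               exclude_child_ul = FALSE) {
  basis <- match.arg(basis)
  if (ul_threshold <= 0 || ul_threshold >= 100) {
    stop("ul_threshold must lie in (0, 100)")
  }
  if (inadequacy_goal <= 0 || inadequacy_goal >= 100) {
    stop("inadequacy_goal must lie in (0, 100)")
  }
  structure(list(ul_threshold = ul_threshold, basis = basis,
                 inadequacy_goal = inadequacy_goal,
                 exclude_child_ul = isTRUE(exclude_child_ul)),
            class = "selection_criteria")
}

#' Select acceptable bouillon fortification levels
#'
#' Applies [selection_criteria()] to grid results from [run_level_grid()]
#' (or any tibble with columns `level`, `group`, `nutrient`, `metric`,
#' `point`, `ci_low`, and optionally `baseline`). A level is acceptable iff
#' every group's above-UL metric (on the chosen basis) is strictly below the
#' threshold; nutrients without a UL (vitamin B12) have no constraint, so
#' every level is acceptable. The best level is the acceptable level with
#' the greatest total inadequacy reduction, ties broken toward the lower
#' level (conservative on excess risk).
#'
#' @param results Grid results for one fortificant nutrient.
#' @param criteria A [selection_criteria()].
#' @return Object of class `selection_result`: list with `nutrient`,
#'   `levels`, `acceptable_levels`, `best_level` (NA when no level is
#'   acceptable), and a `groups` tibble with inadequacy at the best level
#'   and the WHO `<2.5%` goal flag per group.
#' @export
select_levels <- function(results, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  nutrient <- unique(results$nutrient)
  if (length(nutrient) != 1) {
    stop("results must cover exactly one nutrient; got: ",
         paste(nutrient, collapse = ", "))
  }
  levels <- sort(unique(results$level))
  groups <- unique(results$group)

  inad <- results[results$metric == "inadequate", ]
  complete <- all(vapply(levels, function(l) {
    all(groups %in% inad$group[inad$level == l])
  }, TRUE))
  if (!complete) stop("incomplete grid: every level needs an inadequacy ",
                      "estimate for every group")

  ul <- results[results$metric == "above_ul", ]
  if (criteria$exclude_child_ul) ul <- ul[ul$group != "child_6_59", ]
  val <- if (criteria$basis == "point_estimate") ul$point else ul$ci_low

  acceptable <- vapply(levels, function(l) {
    v <- val[ul$level == l]
    length(v) == 0 || all(v < criteria$ul_threshold)
  }, TRUE)

  acc_levels <- levels[acceptable]
  if (length(acc_levels) > 0 &&
      !all(levels[levels <= max(acc_levels)] %in% acc_levels)) {
    warning("acceptable set is not downward-closed in level; ",
            "above-UL prevalence is not monotone in these results")
  }

  if (length(acc_levels) > 0) {
    score <- vapply(acc_levels, function(l) {
      sum(inad$point[inad$level == l])
    }, 0)
    best <- acc_levels[which.min(score)]  # which.min takes the first = lowest
    gi <- inad[inad$level == best, ]
    groups_tbl <- tibble::tibble(
      group = gi$group,
      inadequacy_at_best = gi$point,
      who_goal_met = gi$point < criteria$inadequacy_goal
    )
  } else {
    best <- NA_real_
    groups_tbl <- tibble::tibble(group = character(0),
                                 inadequacy_at_best = numeric(0),
                                 who_goal_met = logical(0))
  }
  structure(list(nutrient = nutrient, levels = levels,
                 acceptable_levels = acc_levels, best_level = best,
                 groups = groups_tbl, criteria = criteria),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$nutrient, " (UL threshold ",
      x$criteria$ul_threshold, "%, ", x$criteria$basis, ")\n", sep = "")
  cat("  acceptable levels: ",
      if (length(x$acceptable_levels)) {
        paste(x$acceptable_levels, collapse = ", ")
      } else "none", "\n", sep = "")
  cat("  best level: ", if (is.na(x$best_level)) "none" else x$best_level,
      "\n", sep = "")
  if (nrow(x$groups)) {
    for (i in seq_len(nrow(x$groups))) {
      cat("    ", x$groups$group[i], ": inadequacy ",
          signif(x$groups$inadequacy_at_best[i], 3), "%",
          if (x$groups$who_goal_met[i]) " (WHO <2.5% goal met)" else "",
          "\n", sep = "")
    }
  }
  invisible(x)
}
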