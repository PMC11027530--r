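#' Per-gestational-week summary of age at death
#'
#' The tabular form behind the classic mean +/- SD display: for each observed
#' gestational week, the number of deaths and the mean and sample SD
#' (n - 1 denominator; absent for single observations) of age at death in
#' weeks.
#'
#' @param records Records for one cause (or with a `joined_id` column, for
#'   several: the summary is then computed per cause).
#' @return Tibble: (`joined_id`,) `gestational_age_weeks`, `n_deaths`,
#'   `mean_age_weeks`, `sd_age_weeks`.
#' @export
per_gestweek_summary <- function(records) {
  if (nrow(records) == 0) abort("per_gestweek_summary: no records")
  rec <- mutate(records, .age_wk = if ("age_at_death_weeks" %in% names(records)) {
    .data$age_at_death_weeks
  } else {
    days_to_weeks(.data$age_at_death_days)
  })
  keys <- intersect(c("joined_id", "gestational_age_weeks"), names(rec))
  rec |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(n_deaths = n(),
              mean_age_weeks = mean(.data$.age_wk),
              sd_age_weeks = ifelse(n() >= 2, stats::sd(.data$.age_wk), NA_real_),
              .groups = "drop") |>
    arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Regress age at death on gestational age for one cause
#'
#' Record-level ordinary least squares of age at death (weeks) on gestational
#' age (weeks); the two-sided slope p-value uses the t-distribution with
#' n - 2 degrees of freedom. The screening verdict `passes` is the
#' conjunction slope < 0 and p < `alpha` — the signature of a cause whose
#' preterm victims die at an older postnatal age. With
#' `weighted_means = TRUE` the fit instead uses the per-gestational-week mean
#' ages weighted by week counts (a sensitivity variant of the same screen).
#'
#' @param records Records for a single cause, at least `min_n` rows spanning
#'   at least two distinct gestational weeks.
#' @param alpha Significance cutoff for the verdict (default 0.05).
#' @param min_n Minimum records for a fit (default 3).
#' @param weighted_means Fit on per-week means weighted by counts instead of
#'   record-level points.
#' @return One-row tibble: `slope`, `intercept`, `p_value`, `n`, `passes`.
#' @export
fit_gestage_regression <- function(records, alpha = 0.05, min_n = 3L,
                                   weighted_means = FALSE) {
  if (nrow(records) < min_n) {
    abort(sprintf("need at least %d records to fit (got %d)", min_n, nrow(records)))
  }
  g <- records$gestational_age_weeks
  if (length(unique(g)) < 2) {
    abort("all records at one gestational week: slope unidentifiable")
  }
  age <- if ("age_at_death_weeks" %in% names(records)) {
    records$age_at_death_weeks
  } else {
    days_to_weeks(records$age_at_death_days)
  }
  if (weighted_means) {
    sm <- per_gestweek_summary(tibble(gestational_age_weeks = g,
                                      age_at_death_weeks = age))
    fit <- lm(mean_age_weeks ~ gestational_age_weeks, data = sm,
              weights = sm$n_deaths)
  } else {
    fit <- lm(age ~ g)
  }
  cf <- summary(fit)$coefficients
  slope <- unname(cf[2, "Estimate"])
  p <- unname(cf[2, "Pr(>|t|)"])
  tibble(
    slope = slope,
    intercept = unname(cf[1, "Estimate"]),
    p_value = p,
    n = length(age),
    passes = slope < 0 && p < alpha
  )
}

gestage_subset_labels <- c("all", "before", "during", "after", "icd9", "icd10")

subset_records <- function(records, label) {
  switch(label,
    all = records,
    before = filter(records, .data$era == "before"),
    during = filter(records, .data$era == "during"),
    after = filter(records, .data$era == "after"),
    icd9 = filter(records, .data$icd_version == 9L),
    icd10 = filter(records, .data$icd_version == 10L),
    abort(sprintf("unknown subset label '%s'", label))
  )
}

#' Run the gestational-age screen across causes and robustness subsets
#'
#' Fits the gestational-age regression for every cause within each requested
#' subset of the data: `all`, the "Back to Sleep" eras (`before`, `during`,
#' `after`) and the coding eras (`icd9`, `icd10`). Causes that do not meet
#' the fit precondition in a subset (fewer than `min_n` records or a single
#' gestational week) are reported with `fit_ok = FALSE` rather than silently
#' dropped.
#'
#' @param records Harmonized record tibble with `joined_id`, `era`,
#'   `icd_version` (see [harmonize_records()]).
#' @param subsets Subset labels to evaluate.
#' @inheritParams fit_gestage_regression
#' @return Tibble: `joined_id`, `subset`, `n`, `slope`, `intercept`,
#'   `p_value`, `passes`, `fit_ok`.
#' @export
run_gestage_screen <- function(records, subsets = gestage_subset_labels,
                               alpha = 0.05, min_n = 3L) {
  bad <- setdiff(subsets, gestage_subset_labels)
  if (length(bad) > 0) abort(sprintf("unknown subset label '%s'", bad[1]))
  ids <- sort(unique(records$joined_id), method = "radix")
  out <- list()
  for (label in subsets) {
    sub <- subset_records(records, label)
    groups <- split(sub, sub$joined_id)
    for (id in ids) {
      rec <- groups[[id]]
      fit_ok <- !is.null(rec) && nrow(rec) >= min_n &&
        length(unique(rec$gestational_age_weeks)) >= 2
      if (fit_ok) {
        row <- fit_gestage_regression(rec, alpha = alpha, min_n = min_n)
        row <- mutate(row, joined_id = id, subset = label, fit_ok = TRUE)
      } else {
        row <- tibble(slope = NA_real_, intercept = NA_real_,
                      p_value = NA_real_,
                      n = if (is.null(rec)) 0L else nrow(rec),
                      passes = FALSE,
                      joined_id = id, subset = label, fit_ok = FALSE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  list_rbind(out) |>
    select("joined_id", "subset", "n", "slope", "intercept", "p_value",
           "passes", "fit_ok")
}
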