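#' Weekly age-at-death profile for one cause
#'
#' Tallies deaths per age-at-death week 0..52 and normalizes to frequencies
#' (each week's count divided by the cause's total), the representation used
#' for profile correlation against the SIDS reference.
#'
#' @param records Records for a single cause; `age_at_death_weeks` is used if
#'   present, otherwise derived from `age_at_death_days`.
#' @return Tibble with 53 rows: `week` (0..52), `count`, `frequency`
#'   (summing to 1).
#' @export
weekly_profile <- function(records) {
  if (nrow(records) == 0) abort("weekly_profile: no records for cause")
  wk <- if ("age_at_death_weeks" %in% names(records)) {
    records$age_at_death_weeks
  } else {
    days_to_weeks(records$age_at_death_days)
  }
  counts <- tabulate(wk + 1L, nbins = 53L)
  tibble(week = 0:52, count = counts, frequency = counts / sum(counts))
}

#' Weekly profiles for every cause
#'
#' @param records Record tibble with `joined_id`.
#' @return Long tibble: `joined_id`, `week`, `count`, `frequency`.
#' @export
weekly_profiles <- function(records) {
  records |>
    dplyr::group_split(.data$joined_id) |>
    map(function(g) mutate(weekly_profile(g), joined_id = g$joined_id[1])) |>
    list_rbind() |>
    select("joined_id", "week", "count", "frequency")
}

profile_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles, id_cols = "week",
                             names_from = "joined_id",
                             values_from = "frequency", values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  m[order(wide$week), , drop = FALSE]
}

#' Screen causes by weekly-profile correlation with a reference
#'
#' Computes the Pearson correlation between each cause's weekly frequency
#' vector (full 0..52 axis) and the reference cause's; causes with
#' `r >= threshold` (inclusive: "at least" a 0.5 correlation) are flagged.
#' Constant-frequency profiles have undefined correlation; they are excluded
#' from the screen and reported via `message()`.
#'
#' @param profiles Long profile tibble from [weekly_profiles()].
#' @param reference_id Joined id of the reference cause (e.g. the SIDS
#'   group); must be present.
#' @param threshold Inclusive Pearson-r cutoff (default 0.5).
#' @return Tibble: `joined_id`, `r_profile`, `n_profile` (number of paired
#'   weeks, 53), `in_profile_set`. The reference row has `r_profile = 1`.
#' @export
profile_screen <- function(profiles, reference_id, threshold = 0.5) {
  m <- profile_matrix(profiles)
  if (!reference_id %in% colnames(m)) {
    abort(sprintf("reference cause '%s' has no profile", reference_id))
  }
  ref <- m[, reference_id]
  sds <- apply(m, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sprintf("profile_screen: excluded %d constant profile(s): %s",
                    sum(constant), paste(colnames(m)[constant], collapse = ", ")))
  }
  r <- rep(NA_real_, ncol(m))
  r[!constant] <- apply(m[, !constant, drop = FALSE], 2, cor, y = ref)
  tibble(
    joined_id = colnames(m),
    r_profile = r,
    n_profile = nrow(m),
    in_profile_set = !is.na(r) & r >= threshold
  ) |> arrange(.data$joined_id)
}

#' Normalized annual mortality series per cause
#'
#' Counts deaths per cause per in-scope year and expresses each year's count
#' as a percent of the cause's mean annual count over those years (mean of
#' the normalized series is 100). Gap years (e.g. 1992-1994) are simply not
#' part of `years` and carry no value.
#'
#' @param records Record tibble with `joined_id`.
#' @param years Integer vector of in-scope years (gap-aware; at least one).
#' @return Long tibble: `joined_id`, `year`, `count`, `normalized`.
#' @export
annual_series <- function(records, years) {
  if (length(years) == 0) abort("`years` must be non-empty")
  years <- as.integer(sort(years))
  counts <- records |>
    filter(.data$year %in% years) |>
    count(.data$joined_id, .data$year)
  all_ids <- sort(unique(records$joined_id), method = "radix")
  full <- tidyr::expand_grid(joined_id = all_ids, year = years) |>
    left_join(counts, by = c("joined_id", "year")) |>
    mutate(count = ifelse(is.na(.data$n), 0L, .data$n)) |>
    select("joined_id", "year", "count")
  zero <- full |>
    group_by(.data$joined_id) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    filter(.data$total == 0)
  if (nrow(zero) > 0) {
    abort(sprintf("cause(s) with all-zero in-scope counts: %s",
                  paste(head(zero$joined_id, 5L), collapse = ", ")))
  }
  full |>
    group_by(.data$joined_id) |>
    mutate(normalized = 100 * .data$count / mean(.data$count)) |>
    ungroup()
}

#' Screen causes by annual-trend correlation with a reference
#'
#' Pearson correlation between each cause's normalized annual series and the
#' reference's over the shared in-scope years; a cause is flagged when
#' `r > 0` and the two-sided p-value (t-transform of r with n - 2 degrees of
#' freedom, via [stats::cor.test()]) is below `alpha`. Constant series have
#' undefined correlation and are excluded with a `message()`.
#'
#' @param series Long series tibble from [annual_series()].
#' @param reference_id Joined id of the reference cause.
#' @param alpha Strict two-sided significance cutoff (default 0.005).
#' @return Tibble: `joined_id`, `r_trend`, `p_trend`, `n_years`,
#'   `in_trend_set`.
#' @export
trend_screen <- function(series, reference_id, alpha = 0.005) {
  wide <- tidyr::pivot_wider(series, id_cols = "year",
                             names_from = "joined_id",
                             values_from = "normalized")
  wide <- wide[order(wide$year), , drop = FALSE]
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(m) < 3) abort("trend screen needs at least 3 shared years")
  if (!reference_id %in% colnames(m)) {
    abort(sprintf("reference cause '%s' has no annual series", reference_id))
  }
  ref <- m[, reference_id]
  res <- map(colnames(m), function(id) {
    x <- m[, id]
    if (stats::sd(x) == 0 || stats::sd(ref) == 0) {
      return(tibble(joined_id = id, r_trend = NA_real_, p_trend = NA_real_,
                    n_years = nrow(m), in_trend_set = FALSE))
    }
    ct <- stats::cor.test(x, ref, method = "pearson", alternative = "two.sided")
    tibble(joined_id = id, r_trend = unname(ct$estimate),
           p_trend = ct$p.value, n_years = nrow(m),
           in_trend_set = unname(ct$estimate) > 0 && ct$p.value < alpha)
  }) |> list_rbind()
  dropped <- res$joined_id[is.na(res$r_trend)]
  if (length(dropped) > 0) {
    message(sprintf("trend_screen: excluded %d constant series: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  arrange(res, .data$joined_id)
}

#' Intersect the profile and trend screen sets
#'
#' @param profile_ids,trend_ids Character vectors of joined ids flagged by
#'   each screen.
#' @return Sorted character vector of ids in both sets.
#' @export
intersect_screens <- function(profile_ids, trend_ids) {
  sort(intersect(profile_ids, trend_ids), method = "radix")
}

#' Assemble the screen verdict sets
#'
#' @param profile_result Tibble from [profile_screen()].
#' @param trend_result Tibble from [trend_screen()].
#' @return Object of class `screen_sets`: list with `profile_correlated`,
#'   `trend_correlated` and their `intersection` (which includes the
#'   reference cause whenever it satisfies both screens; self-correlation
#'   places it in the profile set by construction).
#' @export
screen_sets <- function(profile_result, trend_result) {
  p <- sort(profile_result$joined_id[profile_result$in_profile_set], method = "radix")
  t <- sort(trend_result$joined_id[trend_result$in_trend_set], method = "radix")
  structure(list(profile_correlated = p, trend_correlated = t,
                 intersection = intersect_screens(p, t)),
            class = "screen_sets")
}

#' Per-cause screen verdict table
#'
#' Joins the profile- and trend-screen statistics into the flat verdict table
#' the pipeline writes.
#'
#' @inheritParams screen_sets
#' @return Tibble: `joined_id`, `r_profile`, `n_profile`, `r_trend`,
#'   `p_trend`, `in_profile_set`, `in_trend_set`, `in_intersection`.
#' @export
screen_verdicts <- function(profile_result, trend_result) {
  out <- dplyr::full_join(profile_result, trend_result, by = "joined_id")
  mutate(out,
         in_profile_set = !is.na(.data$in_profile_set) & .data$in_profile_set,
         in_trend_set = !is.na(.data$in_trend_set) & .data$in_trend_set,
         in_intersection = .data$in_profile_set & .data$in_trend_set) |>
    arrange(.data$joined_id)
}
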