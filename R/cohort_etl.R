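#' Declare a fixed-width record layout
#'
#' Linked birth-infant death files are distributed as fixed-width text whose
#' column positions change across years; a layout spec pins the positions of
#' the fields this analysis needs and the sentinel codes that mean "unknown".
#'
#' @param year,gestational_age_weeks,age_at_death_days,cause_code Integer
#'   vectors `c(start, end)` of 1-based inclusive column positions.
#' @param width Total line width in characters; every line must have exactly
#'   this width.
#' @param unknown_gestation,unknown_age Character vectors of sentinel field
#'   values marking unknown gestation or age; rows carrying them are dropped
#'   (and counted), never imputed.
#' @return An object of class `layout_spec`.
#' @export
layout_spec <- function(year, gestational_age_weeks, age_at_death_days,
                        cause_code, width,
                        unknown_gestation = "99", unknown_age = "999") {
  fields <- list(year = year, gestational_age_weeks = gestational_age_weeks,
                 age_at_death_days = age_at_death_days, cause_code = cause_code)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (length(f) != 2L || f[1] > f[2] || f[1] < 1L || f[2] > width) {
      abort(sprintf("field '%s' positions must be c(start, end) within 1..width", nm))
    }
  }
  spans <- do.call(rbind, fields)
  o <- order(spans[, 1])
  if (any(spans[o, 1][-1] <= spans[o, 2][-length(fields)])) {
    abort("layout fields must not overlap")
  }
  structure(c(fields, list(width = as.integer(width),
                           unknown_gestation = unknown_gestation,
                           unknown_age = unknown_age)),
            class = "layout_spec")
}

#' Read a layout spec from a YAML file
#'
#' @param path YAML file with keys `width`, `year`, `gestational_age_weeks`,
#'   `age_at_death_days`, `cause_code` (each `[start, end]`) and optional
#'   `unknown_gestation` / `unknown_age` sentinel lists.
#' @return A [layout_spec()].
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  layout_spec(
    year = unlist(y$year),
    gestational_age_weeks = unlist(y$gestational_age_weeks),
    age_at_death_days = unlist(y$age_at_death_days),
    cause_code = unlist(y$cause_code),
    width = y$width,
    unknown_gestation = as.character(unlist(y$unknown_gestation %||% "99")),
    unknown_age = as.character(unlist(y$unknown_age %||% "999"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read death records from a fixed-width file
#'
#' Every line must match the layout width exactly; a mismatch is an error
#' naming the offending line. Rows whose gestation or age field carries a
#' declared unknown-value sentinel are dropped and counted (attribute
#' `n_dropped` on the result), mirroring a no-imputation policy. The ICD
#' version is derived from the year ([assign_icd_version()]).
#'
#' @param path Input file path.
#' @param layout A [layout_spec()].
#' @return Death-record tibble (`year`, `gestational_age_weeks`,
#'   `age_at_death_days`, `cause_code`, `icd_version`) with attribute
#'   `n_dropped`.
#' @export
read_records_fwf <- function(path, layout) {
  stopifnot(inherits(layout, "layout_spec"))
  lines <- readLines(path, warn = FALSE)
  widths <- nchar(lines)
  bad <- which(widths != layout$width)
  if (length(bad) > 0) {
    abort(sprintf("line %d has width %d, layout expects %d",
                  bad[1], widths[bad[1]], layout$width))
  }
  cut <- function(span) trimws(substr(lines, span[1], span[2]))
  year_f <- cut(layout$year)
  gest_f <- cut(layout$gestational_age_weeks)
  age_f <- cut(layout$age_at_death_days)
  code_f <- cut(layout$cause_code)
  drop <- gest_f %in% layout$unknown_gestation |
    age_f %in% layout$unknown_age |
    !nzchar(gest_f) | !nzchar(age_f)
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    message(sprintf("read_records_fwf: dropped %d row(s) with unknown gestation or age",
                    n_dropped))
  }
  year <- as.integer(year_f[!drop])
  out <- tibble(
    year = year,
    gestational_age_weeks = as.integer(gest_f[!drop]),
    age_at_death_days = as.integer(age_f[!drop]),
    cause_code = normalize_icd_code(code_f[!drop]),
    icd_version = assign_icd_version(year)
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write death records in the fixed-width dialect
#'
#' Numeric fields are zero-padded to the field width and the cause code is
#' left-justified space-padded, so that [read_records_fwf()] re-reads the
#' file bit-identically.
#'
#' @param records Death-record tibble.
#' @param path Output file path.
#' @param layout A [layout_spec()] whose fields tile the line (gaps are
#'   space-filled).
#' @return `path`, invisibly.
#' @export
write_records_fwf <- function(records, path, layout) {
  stopifnot(inherits(layout, "layout_spec"))
  line <- strrep(" ", layout$width)
  lines <- rep(line, nrow(records))
  put <- function(lines, span, text) {
    w <- span[2] - span[1] + 1L
    paste0(substr(lines, 1, span[1] - 1L), formatC(text, width = w),
           substr(lines, span[2] + 1L, nchar(lines)))
  }
  pad0 <- function(x, span) sprintf(paste0("%0", span[2] - span[1] + 1L, "d"), x)
  padl <- function(x, span) formatC(x, width = -(span[2] - span[1] + 1L))
  lines <- put(lines, layout$year, pad0(records$year, layout$year))
  lines <- put(lines, layout$gestational_age_weeks,
               pad0(records$gestational_age_weeks, layout$gestational_age_weeks))
  lines <- put(lines, layout$age_at_death_days,
               pad0(records$age_at_death_days, layout$age_at_death_days))
  lines <- put(lines, layout$cause_code, padl(records$cause_code, layout$cause_code))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write death records in the delimited dialect
#'
#' Tab-separated with columns `year`, `gestational_age_weeks`,
#' `age_at_death_days`, `cause_code`, `icd_version`.
#'
#' @param path File path.
#' @return [read_records_delim()] returns the record tibble.
#' @export
read_records_delim <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    year = readr::col_integer(),
    gestational_age_weeks = readr::col_integer(),
    age_at_death_days = readr::col_integer(),
    cause_code = readr::col_character(),
    icd_version = readr::col_integer()
  ), progress = FALSE)
}

#' @rdname read_records_delim
#' @param records Death-record tibble.
#' @export
write_records_delim <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Convert age at death from days to completed weeks
#'
#' Week indexing is 0-based half-open: week `w` covers days `[7w, 7w + 7)`,
#' so `floor(days / 7)`; an infant age in days lies in `[0, 364]` and the
#' result in `[0, 52]`.
#'
#' @param age_days Integer vector of ages at death in days.
#' @return Integer vector of age-at-death weeks.
#' @export
days_to_weeks <- function(age_days) {
  if (any(is.na(age_days)) || any(age_days < 0) || any(age_days > 364)) {
    abort("`age_days` must lie in [0, 364] (infant deaths only)")
  }
  as.integer(age_days %/% 7L)
}

#' Assign the "Back to Sleep" analysis era for a calendar year
#'
#' Years are grouped around the 1994 US safe-sleep campaign: 1986-1991
#' `before`, 1995-1999 `during`, 2000-2005 `after`; all other years
#' (including the 1992-1994 data gap) are `excluded`.
#'
#' @param year Integer vector of calendar years.
#' @return Factor with levels `before`, `during`, `after`, `excluded`.
#' @export
assign_era <- function(year) {
  out <- rep("excluded", length(year))
  out[year >= 1986 & year <= 1991] <- "before"
  out[year >= 1995 & year <= 1999] <- "during"
  out[year >= 2000 & year <= 2005] <- "after"
  factor(out, levels = c("before", "during", "after", "excluded"))
}

#' ICD revision in force for a death year
#'
#' US mortality coding used ICD-9 before 1999 and ICD-10 from 1999 on.
#'
#' @param year Integer vector of calendar years.
#' @return Integer vector of 9s and 10s.
#' @export
assign_icd_version <- function(year) {
  ifelse(year < 1999, 9L, 10L)
}

#' Drop ultra-rare causes
#'
#' A harmonized cause is retained iff its mean annual count over the in-scope
#' years strictly exceeds `min_mean_annual` (default "more than 20 cases per
#' year"); years with no cases count as zero. With `per_year = TRUE` the
#' stricter variant requires every in-scope year's count to exceed the
#' threshold.
#'
#' @param records Record tibble with a `joined_id` column.
#' @param years Integer vector of in-scope years (must be non-empty).
#' @param min_mean_annual Threshold (strict).
#' @param per_year Use the per-year-minimum variant.
#' @return Sorted character vector of retained joined ids.
#' @export
filter_rare_causes <- function(records, years, min_mean_annual = 20,
                               per_year = FALSE) {
  if (length(years) == 0) abort("`years` must be non-empty")
  in_scope <- filter(records, .data$year %in% years)
  counts <- count(in_scope, .data$joined_id, .data$year)
  if (per_year) {
    full <- tidyr::complete(counts, .data$joined_id,
                            year = as.integer(years), fill = list(n = 0L))
    keep <- full |>
      group_by(.data$joined_id) |>
      summarise(ok = all(.data$n > min_mean_annual), .groups = "drop")
  } else {
    keep <- counts |>
      group_by(.data$joined_id) |>
      summarise(ok = sum(.data$n) / length(years) > min_mean_annual,
                .groups = "drop")
  }
  sort(keep$joined_id[keep$ok], method = "radix")
}

#' Harmonize records for analysis
#'
#' Appends the analysis columns used downstream: `era`, `icd_version`
#' (recomputed from year if absent) and `age_at_death_weeks`.
#'
#' @param records Record tibble (optionally already carrying `joined_id`).
#' @return The tibble with `era`, `icd_version`, `age_at_death_weeks`.
#' @export
harmonize_records <- function(records) {
  out <- mutate(records,
                icd_version = assign_icd_version(.data$year),
                era = assign_era(.data$year),
                age_at_death_weeks = days_to_weeks(.data$age_at_death_days))
  out
}
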