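#' Describe one synthetic cause of death
#'
#' A cause specification fixes everything the cohort generator needs to plant
#' known statistical structure: which raw ICD codes the cause is recorded
#' under in each coding era, how many deaths occur per calendar year, where
#' the weekly age-at-death distribution peaks and how dispersed it is, and how
#' strongly age at death is coupled to gestational age.
#'
#' @param name Human-readable label (bookkeeping only; the pipeline works on
#'   harmonized joined codes, not names).
#' @param icd9_codes Character vector of ICD-9 codes used in ICD-9 years.
#' @param icd10_codes Character vector of ICD-10 codes used in ICD-10 years.
#' @param annual_counts Named numeric vector, names are calendar years and
#'   values the expected death count for that year. Counts are realized as
#'   exact quotas, not Poisson draws, so downstream count-based tests are
#'   sharp.
#' @param profile_peak_week Age-at-death week (0-based, in `[0, 52]`) of modal
#'   mortality for a full-term (40-week) birth.
#' @param profile_spread Dispersion (SD, weeks) of the weekly death
#'   distribution. Must be positive.
#' @param gestage_slope Planted change in expected age at death (weeks) per
#'   additional week of gestation; negative values emulate the SIDS-like
#'   "preterms die later" pattern.
#' @param gestage_noise_sd Additional residual SD (weeks) of age at death
#'   around the gestational-age regression line.
#'
#' @return An object of class `cause_spec`.
#' @seealso [cohort_config()], [generate_cohort()]
#' @export
cause_spec <- function(name, icd9_codes = character(), icd10_codes = character(),
                       annual_counts, profile_peak_week, profile_spread,
                       gestage_slope = 0, gestage_noise_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  counts <- unlist(annual_counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`annual_counts` must be named by calendar year")
  }
  years <- as.integer(names(counts))
  if (anyNA(years)) abort("`annual_counts` names must be calendar years")
  if (any(counts < 0)) abort("`annual_counts` values must be >= 0")
  if (profile_peak_week < 0 || profile_peak_week > 52) {
    abort("`profile_peak_week` must lie in [0, 52]")
  }
  if (profile_spread <= 0) abort("`profile_spread` must be > 0")
  if (gestage_noise_sd < 0) abort("`gestage_noise_sd` must be >= 0")
  structure(
    list(
      name = name,
      icd9_codes = normalize_icd_code(icd9_codes),
      icd10_codes = normalize_icd_code(icd10_codes),
      annual_counts = stats::setNames(as.numeric(counts), years),
      profile_peak_week = profile_peak_week,
      profile_spread = profile_spread,
      gestage_slope = gestage_slope,
      gestage_noise_sd = gestage_noise_sd
    ),
    class = "cause_spec"
  )
}

#' Default gestational-age distribution for synthetic cohorts
#'
#' Discrete weights over completed gestational weeks 17-47: a mixture of a
#' dominant full-term component (mean 39, SD 1.8 weeks, weight 0.9) and a
#' preterm tail (mean 33, SD 3.5 weeks, weight 0.1), matching the roughly 10%
#' preterm fraction of US births. Overall SD is about 2.7 weeks.
#'
#' @return Named numeric vector of probabilities (names are weeks 17-47,
#'   values sum to 1).
#' @export
default_gestage_distribution <- function() {
  weeks <- 17:47
  w <- 0.9 * stats::dnorm(weeks, mean = 39, sd = 1.8) +
    0.1 * stats::dnorm(weeks, mean = 33, sd = 3.5)
  stats::setNames(w / sum(w), weeks)
}

#' Configure a synthetic linked birth-infant death cohort
#'
#' @param causes List of [cause_spec()] objects.
#' @param years Strictly increasing integer vector of calendar years to
#'   simulate; may contain a gap (e.g. omit 1992-1994). Years present in a
#'   cause's `annual_counts` but absent here are skipped.
#' @param gestage_distribution Named nonnegative weights over gestational-age
#'   weeks within `[17, 47]`; normalized to sum 1.
#' @param seed Integer seed; all sampling draws from one stream seeded here,
#'   in documented order (causes in list order, years ascending; per block:
#'   gestational ages, age noise, day-of-week offsets, cause codes).
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(causes, years,
                          gestage_distribution = default_gestage_distribution(),
                          seed = 1L) {
  if (!is.list(causes) || !all(vapply(causes, inherits, logical(1), "cause_spec"))) {
    abort("`causes` must be a list of cause_spec objects")
  }
  years <- as.integer(years)
  if (length(years) > 0 && any(diff(years) <= 0)) {
    abort("`years` must be strictly increasing")
  }
  w <- unlist(gestage_distribution)
  wk <- as.integer(names(w))
  if (anyNA(wk) || any(wk < 17) || any(wk > 47)) {
    abort("`gestage_distribution` must be named by weeks within [17, 47]")
  }
  if (any(w < 0) || sum(w) <= 0) {
    abort("`gestage_distribution` weights must be nonnegative with positive sum")
  }
  structure(
    list(
      causes = causes,
      years = years,
      gestage_distribution = stats::setNames(w / sum(w), wk),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort of linked birth-infant death records
#'
#' Realizes the configured counts as exact quotas: for each cause and each
#' in-scope year, exactly `annual_counts[year]` records are emitted.
#' Per record, gestational age `g` is drawn from the configured distribution;
#' the age-at-death week is `round(peak + slope * (g - 40) + e)` with
#' `e ~ N(0, sqrt(profile_spread^2 + gestage_noise_sd^2))`, clamped to
#' `[0, 52]`; the day of death is uniform within that week (capped at day
#' 364). The raw cause code is drawn from the cause's ICD-9 code list in
#' ICD-9 years (before 1999) and its ICD-10 list from 1999 on.
#'
#' @param config A [cohort_config()].
#' @return A tibble of death records with columns `year`,
#'   `gestational_age_weeks`, `age_at_death_days`, `cause_code`,
#'   `icd_version`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  gw <- as.integer(names(config$gestage_distribution))
  gp <- config$gestage_distribution
  blocks <- vector("list", length(config$causes))
  for (ci in seq_along(config$causes)) {
    cs <- config$causes[[ci]]
    yrs <- intersect(as.integer(names(cs$annual_counts)), config$years)
    yrs <- sort(yrs)
    if (length(yrs) == 0) next
    counts <- as.integer(round(cs$annual_counts[as.character(yrs)]))
    vers <- assign_icd_version(yrs)
    if (length(cs$icd9_codes) == 0 && any(counts[vers == 9L] > 0)) {
      abort(sprintf("cause '%s' has no ICD-9 codes but deaths requested in ICD-9 year %d",
                    cs$name, yrs[vers == 9L & counts > 0][1]))
    }
    if (length(cs$icd10_codes) == 0 && any(counts[vers == 10L] > 0)) {
      abort(sprintf("cause '%s' has no ICD-10 codes but deaths requested in ICD-10 year %d",
                    cs$name, yrs[vers == 10L & counts > 0][1]))
    }
    n <- sum(counts)
    if (n == 0) next
    year <- rep(yrs, counts)
    g <- sample(gw, n, replace = TRUE, prob = gp)
    total_sd <- sqrt(cs$profile_spread^2 + cs$gestage_noise_sd^2)
    wk <- round(cs$profile_peak_week + cs$gestage_slope * (g - 40) +
                  rnorm(n, 0, total_sd))
    wk <- pmin(pmax(wk, 0), 52)
    day <- wk * 7L + sample.int(7L, n, replace = TRUE) - 1L
    day <- pmin(day, 364L)
    ver <- assign_icd_version(year)
    code <- character(n)
    if (any(ver == 9L)) {
      code[ver == 9L] <- sample(cs$icd9_codes, sum(ver == 9L), replace = TRUE)
    }
    if (any(ver == 10L)) {
      code[ver == 10L] <- sample(cs$icd10_codes, sum(ver == 10L), replace = TRUE)
    }
    blocks[[ci]] <- tibble(
      year = as.integer(year),
      gestational_age_weeks = as.integer(g),
      age_at_death_days = as.integer(day),
      cause_code = code,
      icd_version = as.integer(ver)
    )
  }
  out <- list_rbind(blocks[!vapply(blocks, is.null, logical(1))])
  if (nrow(out) == 0) {
    out <- tibble(
      year = integer(), gestational_age_weeks = integer(),
      age_at_death_days = integer(), cause_code = character(),
      icd_version = integer()
    )
  }
  out
}

#' Generate synthetic GEM equivalence tables with known components
#'
#' Emits forward (ICD-10 to ICD-9) and backward (ICD-9 to ICD-10) mapping
#' entries whose induced undirected graph has exactly the specified connected
#' components. Within each component a spanning set of cross-version edges is
#' guaranteed (first ICD-10 code linked to every ICD-9 code and first ICD-9
#' code to every ICD-10 code); additional within-component edges are added at
#' random. No entry ever crosses two components, so the returned ground truth
#' is exact.
#'
#' @param components List of components, each a list with elements `icd9` and
#'   `icd10` (character vectors of codes). Codes must be disjoint across
#'   components within each version. A component with more than one code must
#'   contain at least one code of each version (GEM edges only join versions).
#' @param extra_edge_prob Probability of each additional (non-spanning)
#'   within-component cross pair being emitted.
#' @param seed Integer seed.
#'
#' @return List with `forward` and `backward` entry tibbles
#'   (`source_code`, `target_code`, `flags`) and `truth`, a tibble of the
#'   ground-truth membership (`component`, `code`, `icd_version`).
#' @export
generate_gem_tables <- function(components, extra_edge_prob = 0.3, seed = 1L) {
  all9 <- unlist(lapply(components, function(x) normalize_icd_code(x$icd9)))
  all10 <- unlist(lapply(components, function(x) normalize_icd_code(x$icd10)))
  if (anyDuplicated(all9) || anyDuplicated(all10)) {
    abort("component code subsets must be disjoint across components")
  }
  set.seed(seed)
  edges <- list()
  truth <- list()
  for (k in seq_along(components)) {
    c9 <- normalize_icd_code(components[[k]]$icd9)
    c10 <- normalize_icd_code(components[[k]]$icd10)
    nk <- length(c9) + length(c10)
    if (nk == 0) next
    if (nk > 1 && (length(c9) == 0 || length(c10) == 0)) {
      abort(sprintf(
        "component %d has %d codes but only one ICD version; GEM edges cannot connect it", k, nk))
    }
    truth[[k]] <- tibble(
      component = k,
      code = c(c9, c10),
      icd_version = rep(c(9L, 10L), c(length(c9), length(c10)))
    )
    if (length(c9) == 0 || length(c10) == 0) next
    span <- rbind(
      cbind(icd9 = c9, icd10 = c10[1]),
      cbind(icd9 = c9[1], icd10 = c10)
    )
    extra <- expand.grid(icd9 = c9, icd10 = c10,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    extra <- extra[stats::runif(nrow(extra)) < extra_edge_prob, , drop = FALSE]
    ek <- unique(rbind(as.data.frame(span, stringsAsFactors = FALSE), extra))
    edges[[k]] <- as_tibble(ek)
  }
  edges <- list_rbind(edges)
  if (nrow(edges) == 0) {
    fwd <- bwd <- tibble(source_code = character(), target_code = character(),
                         flags = character())
  } else {
    is_fwd <- stats::runif(nrow(edges)) < 0.5
    if (!any(is_fwd)) is_fwd[1] <- TRUE
    if (all(is_fwd)) is_fwd[1] <- FALSE
    fwd <- tibble(source_code = edges$icd10[is_fwd],
                  target_code = edges$icd9[is_fwd], flags = "00000")
    bwd <- tibble(source_code = edges$icd9[!is_fwd],
                  target_code = edges$icd10[!is_fwd], flags = "00000")
  }
  list(forward = fwd, backward = bwd, truth = list_rbind(truth))
}

#' Draw a random component specification for GEM simulation
#'
#' Partitions random ICD-9 and ICD-10 code universes of the given sizes into
#' disjoint components suitable for [generate_gem_tables()]. Component sizes
#' are drawn so that every multi-code component has codes of both versions.
#'
#' @param n_icd9,n_icd10 Sizes of the code universes to draw from.
#' @param n_components Number of components to attempt (capped by available
#'   codes).
#' @param seed Integer seed.
#' @return A list of components (each with `icd9` and `icd10` character
#'   vectors), usable as the `components` argument of [generate_gem_tables()].
#' @export
random_gem_spec <- function(n_icd9, n_icd10, n_components, seed = 1L) {
  set.seed(seed)
  pool9 <- sprintf("%04d", sample.int(9999L, n_icd9))
  pool10 <- paste0(sample(LETTERS, n_icd10, replace = TRUE),
                   sprintf("%03d", sample.int(999L, n_icd10)))
  pool10 <- make.unique(pool10, sep = "")
  comps <- list()
  for (k in seq_len(n_components)) {
    n9 <- sample(0:3, 1L)
    n10 <- sample(0:3, 1L)
    if (n9 + n10 == 0) n9 <- 1L
    if (n9 == 0 && n10 > 1) n10 <- 1L
    if (n10 == 0 && n9 > 1) n9 <- 1L
    n9 <- min(n9, length(pool9))
    n10 <- min(n10, length(pool10))
    if (n9 + n10 == 0) break
    if (n9 + n10 > 1 && (n9 == 0 || n10 == 0)) {
      if (n9 > 1) n9 <- 1L
      if (n10 > 1) n10 <- 1L
    }
    c9 <- head(pool9, n9); pool9 <- setdiff(pool9, c9)
    c10 <- head(pool10, n10); pool10 <- setdiff(pool10, c10)
    comps[[k]] <- list(icd9 = c9, icd10 = c10)
  }
  comps[!vapply(comps, function(x) length(x$icd9) + length(x$icd10) == 0, logical(1))]
}

#' Many-cause calibration cohort for the gestational-age screen
#'
#' Convenience builder for Monte-Carlo calibration of the regression screen:
#' `n_causes` independent causes, each with `n_per_cause` deaths in a single
#' year, all sharing one planted gestational-age slope and residual SD. The
#' peak is placed mid-axis (week 26 by default) so that clamping of the
#' age-at-death week to `[0, 52]` is negligible and does not bias the planted
#' slope.
#'
#' @param n_causes Number of causes (replicates).
#' @param n_per_cause Deaths per cause.
#' @param slope Planted slope (weeks age-at-death per week gestation).
#' @param noise_sd Residual SD in weeks.
#' @param seed Integer seed.
#' @param peak,spread Profile peak week and spread passed to each cause.
#' @param year Calendar year of all deaths.
#' @return A [cohort_config()]; generated records carry one ICD-10 code per
#'   cause (`C0001`, `C0002`, ...) usable directly as the cause grouping.
#' @export
calibration_cohort <- function(n_causes, n_per_cause, slope, noise_sd,
                               seed = 1L, peak = 26, spread = 1,
                               year = 2000L) {
  causes <- lapply(seq_len(n_causes), function(i) {
    cause_spec(sprintf("null%04d", i),
               icd9_codes = sprintf("%04d", i),
               icd10_codes = sprintf("C%04d", i),
               annual_counts = stats::setNames(n_per_cause, year),
               profile_peak_week = peak, profile_spread = spread,
               gestage_slope = slope, gestage_noise_sd = noise_sd)
  })
  cohort_config(causes, years = year, seed = seed)
}

#' Write GEM entries as a whitespace-separated text file
#'
#' One line per entry: `source target flags`, the dialect [parse_gem_file()]
#' reads.
#'
#' @param entries Tibble with `source_code`, `target_code`, `flags`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gem_file <- function(entries, path) {
  writeLines(sprintf("%s %s %s", entries$source_code, entries$target_code,
                     entries$flags), path)
  invisible(path)
}
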