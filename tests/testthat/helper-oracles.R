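# Independent oracles, deliberately written from first principles rather than
# through the code paths they check.

# Brute-force union-find over an edge list of node keys.
uf_components <- function(nodes, edges_from, edges_to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_from)) {
    ra <- find(edges_from[i]); rb <- find(edges_to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# Canonical form of a partition: sorted list of sorted member vectors.
canon_partition <- function(groups) {
  unname(lapply(groups, sort, method = "radix"))[
    order(vapply(groups, function(g) sort(g, method = "radix")[1], character(1)),
          method = "radix")
  ]
}

# Textbook Pearson correlation and its two-sided t-test p-value.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Closed-form simple OLS via the normal equations, with the slope t-test.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Partition induced by the package's component table, in canonical form.
components_as_partition <- function(components) {
  canon_partition(split(paste0(components$code, "|", components$icd_version),
                        components$joined_id))
}

# Ground-truth partition from generate_gem_tables()'s truth tibble.
truth_as_partition <- function(truth) {
  canon_partition(split(paste0(truth$code, "|", truth$icd_version),
                        truth$component))
}

# One-cause record builder for regression/profile unit tests.
records_tbl <- function(g, age_weeks, year = 2000L, joined_id = NULL) {
  tb <- tibble::tibble(
    year = year,
    gestational_age_weeks = as.integer(g),
    age_at_death_days = as.integer(age_weeks * 7L),
    cause_code = "R95",
    icd_version = sidscreen::assign_icd_version(year)
  )
  if (!is.null(joined_id)) tb$joined_id <- joined_id
  tb
}

one_cause_config <- function(n, peak, spread, slope, noise, seed,
                             year = 2000L) {
  cause <- sidscreen::cause_spec(
    "x", icd9_codes = "0001", icd10_codes = "X01",
    annual_counts = stats::setNames(n, year),
    profile_peak_week = peak, profile_spread = spread,
    gestage_slope = slope, gestage_noise_sd = noise
  )
  sidscreen::cohort_config(list(cause), years = year, seed = seed)
}
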