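test_that("weekly profiles tally counts and normalize to frequencies", {
  rec <- records_tbl(g = c(40, 40, 40), age_weeks = c(1, 1, 2))
  p <- weekly_profile(rec)
  expect_equal(nrow(p), 53L)
  expect_equal(p$count[p$week %in% 1:2], c(2L, 1L))
  expect_equal(p$frequency[p$week %in% 1:2], c(2 / 3, 1 / 3))
  expect_equal(sum(p$frequency), 1, tolerance = 1e-12)

  degen <- weekly_profile(records_tbl(g = rep(40, 10), age_weeks = rep(11, 10)))
  expect_equal(degen$frequency[degen$week == 11], 1)
  expect_equal(sum(degen$frequency[degen$week != 11]), 0)
  expect_error(weekly_profile(rec[0, ]), "no records")
})

test_that("a SIDS-like synthetic cause peaks near the third month", {
  rec <- generate_cohort(one_cause_config(5000, peak = 11, spread = 4,
                                          slope = 0, noise = 0, seed = 3))
  p <- weekly_profile(rec)
  mode_week <- p$week[which.max(p$frequency)]
  expect_gte(mode_week, 9)
  expect_lte(mode_week, 13)
})

test_that("profile screen uses inclusive Pearson threshold vs the reference", {
  # three hand-built profiles over the same records axis
  rec <- dplyr::bind_rows(
    records_tbl(g = rep(40, 4), age_weeks = c(10, 11, 11, 12), joined_id = "REF"),
    records_tbl(g = rep(40, 4), age_weeks = c(10, 11, 11, 12), joined_id = "SAME"),
    records_tbl(g = rep(40, 4), age_weeks = c(40, 41, 41, 42), joined_id = "FAR")
  )
  pr <- profile_screen(weekly_profiles(rec), "REF")
  expect_equal(pr$r_profile[pr$joined_id == "REF"], 1)
  expect_true(pr$in_profile_set[pr$joined_id == "SAME"])
  expect_false(pr$in_profile_set[pr$joined_id == "FAR"])
  expect_error(profile_screen(weekly_profiles(rec), "MISSING"), "reference")

  # r equal to an independent textbook Pearson implementation
  profs <- weekly_profiles(rec)
  m <- tidyr::pivot_wider(profs, id_cols = "week", names_from = "joined_id",
                          values_from = "frequency")
  want <- pearson_oracle(m$FAR, m$REF)$r
  expect_equal(pr$r_profile[pr$joined_id == "FAR"], want, tolerance = 1e-12)
})

test_that("a constructed pair at exactly r = 0.5 is included", {
  # orthogonal construction: y = 0.5 * x_std + sqrt(0.75) * z_std gives r = 0.5
  x <- as.numeric(scale(stats::dnorm(0:52, 11, 4)))
  z0 <- stats::dnorm(0:52, 30, 6)
  z <- as.numeric(scale(stats::residuals(stats::lm(z0 ~ x))))
  y <- 0.5 * x + sqrt(0.75) * z
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)
  profiles <- dplyr::bind_rows(
    tibble::tibble(joined_id = "REF", week = 0:52, count = 0L, frequency = x),
    tibble::tibble(joined_id = "HALF", week = 0:52, count = 0L, frequency = y)
  )
  pr <- profile_screen(profiles, "REF", threshold = 0.5)
  expect_true(pr$in_profile_set[pr$joined_id == "HALF"])
})

test_that("annual series normalize to percent of the cause's mean", {
  rec <- tibble::tibble(joined_id = "A",
                        year = rep(2001:2003, c(50L, 100L, 150L)))
  s <- annual_series(rec, 2001:2003)
  expect_equal(s$normalized, c(50, 100, 150))
  expect_equal(mean(s$normalized), 100, tolerance = 1e-9)

  const <- annual_series(tibble::tibble(joined_id = "B",
                                        year = rep(2001:2002, c(30L, 30L))),
                         2001:2002)
  expect_equal(const$normalized, c(100, 100))

  # gap years are simply absent from the axis; mean over non-gap years only
  gap <- annual_series(tibble::tibble(joined_id = "C",
                                      year = rep(c(1991L, 1995L), c(10L, 30L))),
                       c(1991L, 1995L))
  expect_equal(gap$normalized, c(100 * 10 / 20, 100 * 30 / 20))
  expect_error(annual_series(tibble::tibble(joined_id = "D", year = 1980L),
                             2001:2003), "all-zero")
})

test_that("trend screen requires positive r at strict alpha, vs oracle", {
  yrs <- 1996:2005
  ref_counts <- seq(100, 10, length.out = 10)
  mk <- function(id, counts) tibble::tibble(joined_id = id,
                                            year = rep(yrs, round(counts)))
  rec <- dplyr::bind_rows(
    mk("REF", ref_counts),
    mk("DECL", ref_counts * 0.5 + c(1, -1, 2, -2, 0, 1, -1, 2, -2, 0)),
    mk("FLAT", rep(50, 10) + c(3, -3, 1, -1, 2, -2, 3, -3, 1, -1)),
    mk("UP", seq(10, 100, length.out = 10))
  )
  s <- annual_series(rec, yrs)
  tr <- trend_screen(s, "REF", alpha = 0.005)
  expect_true(tr$in_trend_set[tr$joined_id == "REF"])
  expect_equal(tr$r_trend[tr$joined_id == "REF"], 1)
  expect_true(tr$in_trend_set[tr$joined_id == "DECL"])
  expect_false(tr$in_trend_set[tr$joined_id == "FLAT"])
  expect_false(tr$in_trend_set[tr$joined_id == "UP"])

  # r and p match the direct-formula oracle
  wide <- tidyr::pivot_wider(s, id_cols = "year", names_from = "joined_id",
                             values_from = "normalized")
  want <- pearson_oracle(wide$DECL, wide$REF)
  expect_equal(tr$r_trend[tr$joined_id == "DECL"], want$r, tolerance = 1e-12)
  expect_equal(tr$p_trend[tr$joined_id == "DECL"], want$p, tolerance = 1e-12)
})

test_that("constant series are excluded with a message, few years error", {
  yrs <- 2001:2004
  rec <- dplyr::bind_rows(
    tibble::tibble(joined_id = "REF", year = rep(yrs, c(40L, 30L, 20L, 10L))),
    tibble::tibble(joined_id = "CONST", year = rep(yrs, c(25L, 25L, 25L, 25L)))
  )
  s <- annual_series(rec, yrs)
  expect_message(tr <- trend_screen(s, "REF"), "constant")
  expect_false(tr$in_trend_set[tr$joined_id == "CONST"])
  expect_true(is.na(tr$r_trend[tr$joined_id == "CONST"]))
  expect_error(trend_screen(dplyr::filter(s, year <= 2002), "REF"),
               "at least 3")
})

test_that("screen set algebra and monotonicity hold", {
  expect_identical(intersect_screens(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  expect_identical(intersect_screens(c("A"), c("B")), character(0))

  rec <- generate_cohort(demo_cohort_config())
  gem <- generate_gem_tables(demo_gem_components(), seed = 11)
  comp <- connected_components(build_code_graph(
    dplyr::distinct(tibble::tibble(code = rec$cause_code,
                                   icd_version = rec$icd_version)),
    dplyr::bind_rows(dplyr::mutate(gem$forward, direction = "forward"),
                     dplyr::mutate(gem$backward, direction = "backward"))
  ))
  h <- harmonize_records(assign_joined_codes(rec, comp))
  profs <- weekly_profiles(h)
  loose <- profile_screen(profs, "7980", threshold = 0.3)
  tight <- profile_screen(profs, "7980", threshold = 0.7)
  expect_true(all(tight$joined_id[tight$in_profile_set] %in%
                    loose$joined_id[loose$in_profile_set]))
  s <- annual_series(h, demo_years())
  laxa <- trend_screen(s, "7980", alpha = 0.05)
  strict <- trend_screen(s, "7980", alpha = 0.001)
  expect_true(all(strict$joined_id[strict$in_trend_set] %in%
                    laxa$joined_id[laxa$in_trend_set]))
  # screens invariant to cause ordering
  reord <- profile_screen(dplyr::arrange(profs, dplyr::desc(joined_id)),
                          "7980", threshold = 0.5)
  expect_identical(profile_screen(profs, "7980", threshold = 0.5), reord)
})
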