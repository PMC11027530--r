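demo_trajectory <- function() {
  stats::setNames(
    c(rep(100, 6),                      # 1986-1991, before the campaign
      70, 65, 60, 55, 50,               # 1995-1999, the campaign-era drop
      45, 42, 40, 38, 36, 35),          # 2000-2005, settled low level
    demo_years()
  )
}

#' In-scope years of the bundled demo cohort
#'
#' 1986-2005 with the 1992-1994 data gap removed; exactly the union of the
#' before / during / after "Back to Sleep" eras.
#'
#' @return Integer vector of 17 years.
#' @export
demo_years <- function() c(1986:1991, 1995:2005)

#' Bundled synthetic demo cohort with planted screen truth
#'
#' An eight-cause synthetic cohort designed so that the full pipeline has a
#' known answer. The SIDS-like reference (codes 7980 / R95) peaks near week
#' 11, shows the campaign-era mortality drop, and carries a planted
#' gestational-age slope of -0.6 weeks/week. Two causes (cardiac arrest,
#' viral pneumonia) share both the weekly profile and the annual trend; one
#' cause shares only the profile (flat trend), one only the trend (perinatal
#' peak near week 1), two match neither, and one is too rare to survive the
#' more-than-20-cases-per-year filter. All non-reference causes have
#' gestational-age slope 0. See [demo_planted_truth()] for the expected
#' screen outcomes in joined-id terms.
#'
#' @param seed Documented fixed seed of the demo fixture (default 1983).
#' @return A [cohort_config()].
#' @export
demo_cohort_config <- function(seed = 1983L) {
  traj <- demo_trajectory()
  yrs <- demo_years()
  flat_up <- stats::setNames(seq(30, 46, length.out = 17), yrs)
  wiggle <- stats::setNames(35 + c(0, -2, 2, -1, 1, 0, 2, -2, 1, -1, 0, 2,
                                   -2, 0, 1, -1, 0), yrs)
  causes <- list(
    cause_spec("sids", "7980", "R95", traj,
               profile_peak_week = 11, profile_spread = 4,
               gestage_slope = -0.6, gestage_noise_sd = 5),
    cause_spec("cardiac_arrest", "4275", c("I460", "I469"), round(0.6 * traj),
               profile_peak_week = 11, profile_spread = 5,
               gestage_slope = 0, gestage_noise_sd = 6),
    cause_spec("viral_pneumonia", c("4800", "4809"), c("J120", "J129"),
               round(0.5 * traj),
               profile_peak_week = 12, profile_spread = 4,
               gestage_slope = 0, gestage_noise_sd = 6),
    cause_spec("perinatal_respiratory", "7700", "P270", round(0.8 * traj),
               profile_peak_week = 1, profile_spread = 1.5,
               gestage_slope = 0, gestage_noise_sd = 1),
    cause_spec("congenital_heart", "7460", "Q249", flat_up,
               profile_peak_week = 11, profile_spread = 4.5,
               gestage_slope = 0, gestage_noise_sd = 6),
    cause_spec("accidental_suffocation", "E9130", "W75", flat_up,
               profile_peak_week = 30, profile_spread = 10,
               gestage_slope = 0, gestage_noise_sd = 5),
    cause_spec("meningococcal", "0360", "A390", wiggle,
               profile_peak_week = 3, profile_spread = 2,
               gestage_slope = 0, gestage_noise_sd = 2),
    cause_spec("rare_metabolic", "2770", "E840", stats::setNames(rep(10, 17), yrs),
               profile_peak_week = 11, profile_spread = 4,
               gestage_slope = 0, gestage_noise_sd = 4)
  )
  cohort_config(causes, yrs, seed = seed)
}

#' GEM components matching the demo cohort's causes
#'
#' One component per demo cause, usable with [generate_gem_tables()] so that
#' harmonization recovers exactly the demo's cause structure.
#'
#' @return List of components (each with `icd9`, `icd10`).
#' @export
demo_gem_components <- function() {
  cfg <- demo_cohort_config()
  lapply(cfg$causes, function(cs) list(icd9 = cs$icd9_codes,
                                       icd10 = cs$icd10_codes))
}

#' Planted truth of the demo cohort, in joined-id terms
#'
#' Joined ids are the lexicographically smallest member code of each
#' harmonized group, so e.g. the SIDS group \{7980, R95\} has id "7980".
#'
#' @return List with the reference id, the causes planted to satisfy each
#'   screen (reference included where it qualifies by construction), the
#'   intersection, the gestational-age pass list, and the rare cause dropped
#'   by the frequency filter.
#' @export
demo_planted_truth <- function() {
  list(
    reference = "7980",
    profile_correlated = c("4275", "4800", "7460", "7980"),
    trend_correlated = c("4275", "4800", "7700", "7980"),
    intersection = c("4275", "4800", "7980"),
    intersection_non_reference = c("4275", "4800"),
    gestage_pass = "7980",
    filtered_out = "2770"
  )
}
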