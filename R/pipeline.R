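#' Configure a full screening pipeline run
#'
#' One object holds every threshold of the screening procedure so the
#' analysis constants can be audited (and overridden) in a single place:
#' profile correlation r >= 0.5, trend p < 0.005, regression p < 0.05,
#' rare-cause cutoff of more than 20 cases per year, "Back to Sleep" eras
#' 1986-1991 / 1995-1999 / 2000-2005 and the ICD-9/ICD-10 switch at 1999.
#'
#' @param mode `"synthetic"` (generate the cohort and GEM tables from
#'   `cohort` / `gem_components`) or `"files"` (read them from the given
#'   paths).
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param gem_components Component list for [generate_gem_tables()]
#'   (synthetic mode).
#' @param records_file Delimited record file (files mode), or a fixed-width
#'   file if `layout` is given.
#' @param gem_forward_file,gem_backward_file GEM table paths (files mode).
#' @param layout Optional [layout_spec()] for fixed-width `records_file`.
#' @param reference_code Raw ICD code identifying the reference (SIDS) group;
#'   resolved to a joined id after harmonization.
#' @param reference_icd_version ICD version of `reference_code`.
#' @param years_in_scope Years entering the trend screen and rare-cause
#'   filter.
#' @param profile_r,trend_alpha,regression_alpha,rare_cutoff Screen
#'   thresholds.
#' @param subsets Gestational-age screen subsets.
#' @param seed Seed for synthetic generation.
#' @param out_dir Output directory (created if needed).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = NULL, gem_components = NULL,
                            records_file = NULL, gem_forward_file = NULL,
                            gem_backward_file = NULL, layout = NULL,
                            reference_code = "R95",
                            reference_icd_version = 10L,
                            years_in_scope = demo_years(),
                            profile_r = 0.5, trend_alpha = 0.005,
                            regression_alpha = 0.05, rare_cutoff = 20,
                            subsets = gestage_subset_labels,
                            seed = 1L, out_dir = tempfile("sidscreen")) {
  mode <- match.arg(mode)
  if (!(profile_r > 0 && profile_r < 1)) abort("`profile_r` must lie in (0, 1)")
  if (!(trend_alpha > 0 && trend_alpha < 1)) abort("`trend_alpha` must lie in (0, 1)")
  if (!(regression_alpha > 0 && regression_alpha < 1)) {
    abort("`regression_alpha` must lie in (0, 1)")
  }
  if (rare_cutoff < 0) abort("`rare_cutoff` must be >= 0")
  if (mode == "synthetic" && is.null(cohort)) {
    abort("synthetic mode needs a `cohort` config")
  }
  if (mode == "files" && is.null(records_file)) {
    abort("files mode needs `records_file`")
  }
  eras <- list(before = 1986:1991, during = 1995:1999, after = 2000:2005)
  structure(list(
    mode = mode, cohort = cohort, gem_components = gem_components,
    records_file = records_file, gem_forward_file = gem_forward_file,
    gem_backward_file = gem_backward_file, layout = layout,
    reference_code = normalize_icd_code(reference_code),
    reference_icd_version = as.integer(reference_icd_version),
    years_in_scope = as.integer(years_in_scope),
    profile_r = profile_r, trend_alpha = trend_alpha,
    regression_alpha = regression_alpha, rare_cutoff = rare_cutoff,
    subsets = subsets, eras = eras,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Files-mode configuration as a structured text file; keys mirror the
#' arguments of [pipeline_config()] (`mode`, `records_file`,
#' `gem_forward_file`, `gem_backward_file`, `layout_file`, `reference_code`,
#' `reference_icd_version`, `years_in_scope`, `thresholds:` with
#' `profile_r` / `trend_alpha` / `regression_alpha` / `rare_cutoff`, `seed`,
#' `out_dir`). `mode: synthetic` runs the bundled demo cohort.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$thresholds %||% list()
  mode <- y$mode %||% "synthetic"
  pipeline_config(
    mode = mode,
    cohort = if (mode == "synthetic") demo_cohort_config(y$seed %||% 1983L),
    gem_components = if (mode == "synthetic") demo_gem_components(),
    records_file = y$records_file,
    gem_forward_file = y$gem_forward_file,
    gem_backward_file = y$gem_backward_file,
    layout = if (!is.null(y$layout_file)) read_layout(y$layout_file),
    reference_code = y$reference_code %||% "R95",
    reference_icd_version = y$reference_icd_version %||% 10L,
    years_in_scope = unlist(y$years_in_scope %||% demo_years()),
    profile_r = th$profile_r %||% 0.5,
    trend_alpha = th$trend_alpha %||% 0.005,
    regression_alpha = th$regression_alpha %||% 0.05,
    rare_cutoff = th$rare_cutoff %||% 20,
    seed = y$seed %||% 1983L,
    out_dir = y$out_dir %||% tempfile("sidscreen")
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full screening pipeline
#'
#' Executes simulate/read, harmonization, the rare-cause filter, the
#' profile and trend screens, and the gestational-age screen, writing every
#' intermediate and final table as delimited text under `config$out_dir`
#' together with a JSON manifest (package version, seed, thresholds,
#' per-stage counts, output md5 digests). Rerunning with the same config and
#' seed produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  log <- function(fmt, ...) message(sprintf(paste0("[sidscreen] ", fmt), ...))

  # -- stage: input ----------------------------------------------------------
  if (config$mode == "synthetic") {
    records <- pipeline_stage("simulate", {
      cohort <- config$cohort
      cohort$seed <- config$seed
      rec <- generate_cohort(cohort)
      gem <- generate_gem_tables(config$gem_components,
                                 seed = config$seed + 1L)
      write_records_delim(rec, out("records.tsv"))
      write_gem_file(gem$forward, out("gem_forward.txt"))
      write_gem_file(gem$backward, out("gem_backward.txt"))
      rec
    })
    gem_fwd_path <- out("gem_forward.txt")
    gem_bwd_path <- out("gem_backward.txt")
  } else {
    records <- pipeline_stage("read", {
      if (!is.null(config$layout)) {
        read_records_fwf(config$records_file, config$layout)
      } else {
        read_records_delim(config$records_file)
      }
    })
    gem_fwd_path <- config$gem_forward_file
    gem_bwd_path <- config$gem_backward_file
  }
  log("input: %d death records", nrow(records))

  # -- stage: harmonization --------------------------------------------------
  harmonized <- pipeline_stage("harmonize", {
    entries <- bind_rows(
      parse_gem_file(gem_fwd_path, "forward"),
      parse_gem_file(gem_bwd_path, "backward")
    )
    observed <- distinct(tibble(code = normalize_icd_code(records$cause_code),
                                icd_version = records$icd_version))
    graph <- build_code_graph(observed, entries)
    components <- connected_components(graph)
    write_components(components, out("components.tsv"))
    rec <- assign_joined_codes(records, components) |> harmonize_records()
    readr::write_tsv(
      select(rec, "year", "era", "icd_version", "gestational_age_weeks",
             "age_at_death_weeks", "joined_id"),
      out("harmonized_records.tsv"), progress = FALSE
    )
    rec
  })
  n_groups <- length(unique(harmonized$joined_id))
  log("harmonization: %d joined cause groups", n_groups)

  reference_id <- pipeline_stage("harmonize", {
    comp <- readr::read_tsv(out("components.tsv"),
                            col_types = "cci", progress = FALSE)
    hit <- comp$joined_id[comp$member_code == config$reference_code &
                            comp$icd_version == config$reference_icd_version]
    if (length(hit) != 1) {
      abort(sprintf("reference code %s (ICD-%d) not found in components",
                    config$reference_code, config$reference_icd_version))
    }
    hit
  })

  # -- stage: rare-cause filter ----------------------------------------------
  retained <- pipeline_stage("filter", {
    filter_rare_causes(harmonized, config$years_in_scope,
                       min_mean_annual = config$rare_cutoff)
  })
  log("filter: %d of %d causes exceed %g cases/year on average",
      length(retained), n_groups, config$rare_cutoff)
  if (!reference_id %in% retained) {
    abort(sprintf("reference group '%s' does not survive the rare-cause filter",
                  reference_id))
  }
  analysed <- filter(harmonized, .data$joined_id %in% retained,
                     .data$year %in% config$years_in_scope)

  # -- stage: profile & trend screens ----------------------------------------
  screens <- pipeline_stage("profiles", {
    profiles <- weekly_profiles(analysed)
    series <- annual_series(analysed, config$years_in_scope)
    readr::write_tsv(profiles, out("weekly_profiles.tsv"), progress = FALSE)
    readr::write_tsv(series, out("annual_series.tsv"), progress = FALSE)
    pr <- profile_screen(profiles, reference_id, threshold = config$profile_r)
    tr <- trend_screen(series, reference_id, alpha = config$trend_alpha)
    verdicts <- screen_verdicts(pr, tr)
    readr::write_tsv(verdicts, out("screen_verdicts.tsv"), progress = FALSE)
    list(sets = screen_sets(pr, tr), verdicts = verdicts)
  })
  log("screens: %d profile-correlated, %d trend-correlated, %d in intersection",
      length(screens$sets$profile_correlated),
      length(screens$sets$trend_correlated),
      length(screens$sets$intersection))

  # -- stage: gestational-age screen -----------------------------------------
  gest <- pipeline_stage("gestage", {
    res <- run_gestage_screen(analysed, subsets = config$subsets,
                              alpha = config$regression_alpha)
    readr::write_tsv(res, out("gestage_results.tsv"), progress = FALSE)
    readr::write_tsv(per_gestweek_summary(analysed),
                     out("gestweek_summary.tsv"), progress = FALSE)
    res
  })
  pass_all <- sort(gest$joined_id[gest$subset == "all" & gest$passes],
                   method = "radix")
  log("gestational-age screen: pass in subset 'all': %s",
      if (length(pass_all)) paste(pass_all, collapse = ", ") else "(none)")

  tables <- c("records.tsv", "gem_forward.txt", "gem_backward.txt",
              "components.tsv", "harmonized_records.tsv",
              "weekly_profiles.tsv", "annual_series.tsv",
              "screen_verdicts.tsv", "gestage_results.tsv",
              "gestweek_summary.tsv")
  tables <- tables[file.exists(file.path(config$out_dir, tables))]
  digests <- as.list(tools::md5sum(file.path(config$out_dir, tables)))
  names(digests) <- tables
  manifest <- list(
    package = "sidscreen",
    version = as.character(utils::packageVersion("sidscreen")),
    seed = config$seed,
    reference_id = reference_id,
    thresholds = list(profile_r = config$profile_r,
                      trend_alpha = config$trend_alpha,
                      regression_alpha = config$regression_alpha,
                      rare_cutoff = config$rare_cutoff),
    years_in_scope = config$years_in_scope,
    counts = list(records = nrow(records), joined_groups = n_groups,
                  retained_causes = length(retained)),
    screen_sets = screens$sets[c("profile_correlated", "trend_correlated",
                                 "intersection")],
    gestage_pass_all = pass_all,
    stages = c("input", "harmonize", "filter", "profiles", "gestage"),
    outputs = digests
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
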