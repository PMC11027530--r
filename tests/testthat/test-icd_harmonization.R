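test_that("GEM parsing extracts fields, skips blanks, and flags short lines", {
  f <- withr::local_tempfile(lines = c("R95 7980 10000", "",
                                       "# comment", "J12.0 480.9 00000"))
  entries <- parse_gem_file(f, "forward")
  expect_equal(nrow(entries), 2L)
  expect_equal(entries$source_code, c("R95", "J120"))
  expect_equal(entries$target_code, c("7980", "4809"))
  expect_equal(entries$flags[1], "10000")

  bad <- withr::local_tempfile(lines = c("R95 7980 10000", "oops",
                                         "J120 4809 00000"))
  expect_error(parse_gem_file(bad, "forward"), "line 2")
})

test_that("code normalization uppercases and strips periods only", {
  expect_equal(normalize_icd_code(c("j12.0", " e913.0 ", "0360")),
               c("J120", "E9130", "0360"))
})

test_that("graph edges are restricted to observed codes", {
  obs <- tibble::tibble(code = c("0A", "X"), icd_version = c(9L, 10L))
  ent <- tibble::tibble(source_code = "X", target_code = "0A",
                        flags = "00000", direction = "forward")
  g <- build_code_graph(obs, ent)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$n_dropped_entries, 0L)

  obs2 <- tibble::tibble(code = c("0A", "0B"), icd_version = c(9L, 9L))
  expect_message(g2 <- build_code_graph(obs2, ent), "dropped")
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(g2$n_dropped_entries, 1L)
})

test_that("graph edge sets match a brute-force restriction of the entries", {
  for (s in c(7, 8, 9)) {
    spec <- random_gem_spec(15, 15, 6, seed = s)
    gem <- generate_gem_tables(spec, seed = s)
    obs <- gem$truth[, c("code", "icd_version")]
    ent <- dplyr::bind_rows(
      dplyr::mutate(gem$forward, direction = "forward"),
      dplyr::mutate(gem$backward, direction = "backward")
    )
    g <- build_code_graph(obs, ent)
    # oracle: enumerate entry pairs restricted to observed (code, version)
    obs_key <- paste0(obs$code, "|", obs$icd_version)
    want <- unique(vapply(seq_len(nrow(ent)), function(i) {
      a <- paste0(ifelse(ent$direction[i] == "forward", ent$target_code[i],
                         ent$source_code[i]), "|9")
      b <- paste0(ifelse(ent$direction[i] == "forward", ent$source_code[i],
                         ent$target_code[i]), "|10")
      if (a %in% obs_key && b %in% obs_key) paste(min(a, b), max(a, b))
      else NA_character_
    }, character(1)))
    want <- sort(want[!is.na(want)])
    expect_equal(sort(paste(g$edges$from, g$edges$to)), want)
  }
})

test_that("components match simple hand-built cases", {
  obs <- tibble::tibble(code = c("0A", "0B", "X"),
                        icd_version = c(9L, 9L, 10L))
  ent <- tibble::tibble(source_code = c("X", "0B"), target_code = c("0A", "X"),
                        flags = "", direction = c("forward", "backward"))
  comp <- connected_components(build_code_graph(obs, ent))
  expect_equal(unique(comp$joined_id), "0A")
  expect_equal(nrow(comp), 3L)

  lone <- connected_components(
    build_code_graph(obs, ent[0, ])
  )
  expect_equal(sort(lone$joined_id), c("0A", "0B", "X"))
  expect_equal(nrow(lone), 3L)
})

test_that("component extraction matches the union-find oracle on random graphs", {
  for (s in 1:25) {
    spec <- random_gem_spec(20, 20, sample(3:8, 1), seed = s)
    gem <- generate_gem_tables(spec, extra_edge_prob = 0.4, seed = s + 500)
    obs <- gem$truth[, c("code", "icd_version")]
    ent <- dplyr::bind_rows(
      dplyr::mutate(gem$forward, direction = "forward"),
      dplyr::mutate(gem$backward, direction = "backward")
    )
    g <- build_code_graph(obs, ent)
    comp <- connected_components(g)
    nodes <- paste0(obs$code, "|", obs$icd_version)
    oracle <- canon_partition(uf_components(nodes, g$edges$from, g$edges$to))
    expect_equal(components_as_partition(comp), oracle)
    # partition invariants
    expect_equal(nrow(comp), length(nodes))
    expect_false(anyDuplicated(paste0(comp$code, "|", comp$icd_version)) > 0)
    # ids are the smallest member code
    by_id <- split(comp$code, comp$joined_id)
    expect_true(all(mapply(function(id, members)
      id == sort(members, method = "radix")[1], names(by_id), by_id)))
  }
})

test_that("joined-code assignment is total and merges cross-version codes", {
  obs <- tibble::tibble(code = c("7980", "R95"), icd_version = c(9L, 10L))
  ent <- tibble::tibble(source_code = "R95", target_code = "7980",
                        flags = "", direction = "forward")
  comp <- connected_components(build_code_graph(obs, ent))
  rec <- tibble::tibble(year = c(1990L, 2000L),
                        gestational_age_weeks = c(40L, 38L),
                        age_at_death_days = c(80L, 90L),
                        cause_code = c("798.0", "R95"),
                        icd_version = c(9L, 10L))
  out <- assign_joined_codes(rec, comp)
  expect_equal(out$joined_id, c("7980", "7980"))

  rec$cause_code[2] <- "Z99"
  expect_error(assign_joined_codes(rec, comp), "no component")
})

test_that("harmonization is idempotent on an already-harmonized stream", {
  gem <- generate_gem_tables(demo_gem_components(), seed = 11)
  obs <- gem$truth[, c("code", "icd_version")]
  ent <- dplyr::bind_rows(
    dplyr::mutate(gem$forward, direction = "forward"),
    dplyr::mutate(gem$backward, direction = "backward")
  )
  comp1 <- connected_components(build_code_graph(obs, ent))
  # re-harmonize using the same observed universe: identical partition
  comp2 <- connected_components(build_code_graph(comp1[, c("code", "icd_version")], ent))
  expect_identical(comp1, comp2)
})
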