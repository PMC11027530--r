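#' Normalize an ICD code string
#'
#' Uppercases and strips periods so that GEM-file and mortality-file
#' formatting differences ("J12.0" vs "J120") do not break code matching.
#' Leading characters (including leading zeros and E/V prefixes) are
#' preserved.
#'
#' @param code Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @export
normalize_icd_code <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

#' Parse a GEM equivalence table
#'
#' Reads the whitespace-separated dialect of the ICD General Equivalence
#' Mappings text files: one mapping per line as `source target flags`.
#' Blank lines and lines starting with `#` are skipped. The flag string is
#' retained as opaque text; it plays no role in edge construction (any listed
#' pair counts as an equivalence), though callers may filter entries on it.
#'
#' @param path File path (or connection) to read.
#' @param direction `"forward"` for ICD-10-to-ICD-9 tables, `"backward"` for
#'   ICD-9-to-ICD-10 tables.
#' @return Tibble of entries: `source_code`, `target_code`, `flags`,
#'   `direction`. Codes are normalized via [normalize_icd_code()].
#' @export
parse_gem_file <- function(path, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(keep & lengths(fields) < 2L)
  if (length(bad) > 0) {
    abort(sprintf("GEM line %d has fewer than 2 fields: '%s'",
                  bad[1], lines[bad[1]]))
  }
  fields <- fields[keep]
  tibble(
    source_code = normalize_icd_code(vapply(fields, `[`, character(1), 1L)),
    target_code = normalize_icd_code(vapply(fields, `[`, character(1), 2L)),
    flags = vapply(fields, function(f) {
      if (length(f) >= 3L) paste(f[-(1:2)], collapse = " ") else ""
    }, character(1)),
    direction = direction
  )
}

node_key <- function(code, icd_version) paste0(code, "|", icd_version)

#' Build the code-equivalence graph over observed codes
#'
#' Nodes are exactly the (code, ICD version) pairs observed in the cohort;
#' an undirected edge joins two nodes whenever any GEM entry (either
#' direction) lists the pair. Entries touching codes not observed in the
#' cohort contribute no edge: restricting to observed codes prevents
#' unobserved bridge codes from merging groups. The number of dropped entries
#' is recorded in the graph and reported via `message()`.
#'
#' @param observed_codes Tibble (or data frame) with columns `code` and
#'   `icd_version` listing the codes seen in the record set.
#' @param entries GEM entries as returned by [parse_gem_file()]; `direction`
#'   determines which endpoint is ICD-9 and which ICD-10.
#' @return An object of class `code_graph`: list with `nodes` (tibble of
#'   `code`, `icd_version`), `edges` (tibble of node-key pairs `from`, `to`),
#'   and `n_dropped_entries`.
#' @export
build_code_graph <- function(observed_codes, entries) {
  nodes <- distinct(tibble(
    code = normalize_icd_code(observed_codes$code),
    icd_version = as.integer(observed_codes$icd_version)
  ))
  if (nrow(nodes) == 0) abort("`observed_codes` must be non-empty")
  keys <- node_key(nodes$code, nodes$icd_version)
  if (nrow(entries) > 0) {
    icd10_end <- ifelse(entries$direction == "forward",
                        entries$source_code, entries$target_code)
    icd9_end <- ifelse(entries$direction == "forward",
                       entries$target_code, entries$source_code)
    a <- node_key(icd9_end, 9L)
    b <- node_key(icd10_end, 10L)
    ok <- a %in% keys & b %in% keys
    edges <- distinct(tibble(from = pmin(a[ok], b[ok]),
                             to = pmax(a[ok], b[ok])))
    edges <- filter(edges, .data$from != .data$to)
    n_dropped <- sum(!ok)
  } else {
    edges <- tibble(from = character(), to = character())
    n_dropped <- 0L
  }
  if (n_dropped > 0) {
    message(sprintf("build_code_graph: %d GEM entries touched unobserved codes and were dropped",
                    n_dropped))
  }
  structure(list(nodes = nodes, edges = edges, n_dropped_entries = n_dropped),
            class = "code_graph")
}

#' Extract harmonized cause groups as connected components
#'
#' Each connected component of the code-equivalence graph becomes one joined
#' cause group; codes with no equivalence edge form singleton groups. The
#' group id is the lexicographically smallest member code (C-locale radix
#' ordering, stable across platforms).
#'
#' @param graph A `code_graph` from [build_code_graph()].
#' @return Tibble with one row per member code: `joined_id`, `code`,
#'   `icd_version`; the rows partition the graph's node set.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "code_graph"))
  keys <- node_key(graph$nodes$code, graph$nodes$icd_version)
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = keys, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[keys]
  out <- tibble(
    code = graph$nodes$code,
    icd_version = graph$nodes$icd_version,
    .comp = as.integer(membership)
  )
  ids <- out |>
    group_by(.data$.comp) |>
    summarise(joined_id = sort(.data$code, method = "radix")[1],
              .groups = "drop")
  out <- left_join(out, ids, by = ".comp") |>
    select("joined_id", "code", "icd_version") |>
    arrange(.data$joined_id, .data$icd_version, .data$code)
  out
}

#' Assign harmonized joined codes to death records
#'
#' Maps every record's raw cause code (plus ICD version) to its harmonized
#' group. The mapping must be total: components are expected to have been
#' built from the same record set's observed codes, so an unmatched code is
#' an error, not a silent drop.
#'
#' @param records Death-record tibble with `cause_code` and `icd_version`.
#' @param components Component membership tibble from
#'   [connected_components()].
#' @return `records` with a `joined_id` column appended.
#' @export
assign_joined_codes <- function(records, components) {
  rec <- mutate(records, .code = normalize_icd_code(.data$cause_code))
  out <- left_join(
    rec,
    rename(components, .code = "code"),
    by = c(".code", "icd_version")
  )
  if (anyNA(out$joined_id)) {
    missing <- distinct(filter(out, is.na(.data$joined_id)),
                        .data$.code, .data$icd_version)
    abort(sprintf(
      "%d record code(s) appear in no component (components built from a different cohort?): %s",
      nrow(missing),
      paste(head(missing$.code, 5L), collapse = ", ")
    ))
  }
  select(out, -".code")
}

#' Write a component membership table as delimited text
#'
#' @param components Tibble from [connected_components()].
#' @param path Output TSV path (columns `joined_id`, `member_code`,
#'   `icd_version`).
#' @return `path`, invisibly.
#' @export
write_components <- function(components, path) {
  readr::write_tsv(rename(components, member_code = "code"), path)
  invisible(path)
}
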