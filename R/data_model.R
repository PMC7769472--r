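#' Read case-level interpretation data from CSV
#'
#' Reads one row per case: a rater identifier plus ordinal scores (1--3) for
#' the tubular, nuclear and mitotic components and the Nottingham grade, and
#' an optional free-text T stage. Score cells that are empty or unparseable,
#' or that hold a value outside \{1, 2, 3\}, become absent (`NA`) scores and
#' are tallied in the attached validation report; they are never silently
#' coerced to a legal score.
#'
#' @param path path to a CSV file (RFC 4180, UTF-8, header row required).
#' @param schema_map optional named character vector mapping canonical field
#'   names (`case_id`, `rater_id`, `ts`, `ns`, `ms`, `grade`, `t_stage`) to
#'   the column names actually present in the file. Unmapped fields fall back
#'   to the default column names `case_id`, `pathologist`, `tubular_score`,
#'   `nuclear_score`, `mitotic_score`, `grade`, `t_stage`.
#' @return a tibble with columns `case_id`, `rater_id`, `ts`, `ns`, `ms`,
#'   `grade` (integer or `NA`) and `t_stage` (character or `NA`), one row per
#'   data row in input order, with a `validation` attribute (see
#'   [validation_report()]).
#' @seealso [write_cases()] for the inverse, [validation_report()].
#' @export
read_cases <- function(path, schema_map = NULL) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())

  defaults <- c(case_id = "case_id", rater_id = "pathologist",
                ts = "tubular_score", ns = "nuclear_score",
                ms = "mitotic_score", grade = "grade", t_stage = "t_stage")
  map <- defaults
  if (!is.null(schema_map)) {
    bad <- setdiff(names(schema_map), names(defaults))
    if (length(bad)) {
      abort(sprintf("schema_map has unknown field(s): %s",
                    paste(bad, collapse = ", ")))
    }
    map[names(schema_map)] <- unlist(schema_map)
  }

  if (!map[["rater_id"]] %in% names(raw)) {
    abort(sprintf("required rater column '%s' not found in %s",
                  map[["rater_id"]], path))
  }
  score_fields <- c("ts", "ns", "ms", "grade")
  present_scores <- score_fields[map[score_fields] %in% names(raw)]
  if (!length(present_scores)) {
    abort(sprintf(
      "no score column found in %s (looked for: %s)", path,
      paste(map[score_fields], collapse = ", ")))
  }

  n <- nrow(raw)
  get_col <- function(field) {
    col <- map[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, n)
  }

  invalid <- list()
  parse_score <- function(field) {
    x <- trimws(get_col(field))
    out <- suppressWarnings(as.integer(x))
    blank <- is.na(x) | x == ""
    bad <- !blank & (is.na(out) | !out %in% 1:3)
    if (any(bad)) {
      warn(sprintf("%d %s cell(s) outside {1,2,3} treated as absent",
                   sum(bad), field))
    }
    out[bad | blank] <- NA_integer_
    invalid[[field]] <<- sum(bad)
    out
  }

  cases <- tibble::tibble(
    case_id  = trimws(get_col("case_id")),
    rater_id = trimws(get_col("rater_id")),
    ts    = parse_score("ts"),
    ns    = parse_score("ns"),
    ms    = parse_score("ms"),
    grade = parse_score("grade"),
    t_stage = {
      x <- trimws(get_col("t_stage"))
      ifelse(x == "", NA_character_, x)
    }
  )
  if (all(is.na(cases$case_id) | cases$case_id == "")) {
    cases$case_id <- as.character(seq_len(n))
  }

  empty_rater <- cases$rater_id == "" | is.na(cases$rater_id)
  if (any(empty_rater)) {
    warn(sprintf("%d row(s) with empty rater id dropped", sum(empty_rater)))
    cases <- cases[!empty_rater, , drop = FALSE]
  }

  attr(cases, "validation") <- list(
    rows_read = n,
    rows_kept = nrow(cases),
    rows_dropped_empty_rater = sum(empty_rater),
    invalid_score_cells = invalid,
    source = path
  )
  cases
}

#' Write case records to CSV
#'
#' Writes the same dialect [read_cases()] reads (default column names), so a
#' write/read round trip reproduces the records exactly.
#'
#' @param cases a case tibble as returned by [read_cases()] or
#'   [simulate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  out <- data.frame(
    case_id = cases$case_id,
    pathologist = cases$rater_id,
    tubular_score = cases$ts,
    nuclear_score = cases$ns,
    mitotic_score = cases$ms,
    grade = cases$grade,
    t_stage = cases$t_stage,
    check.names = FALSE
  )
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validation report for a case table
#'
#' Summarises parsing and consistency checks: rows read/kept/dropped, invalid
#' score cells per axis, and cases whose reported grade disagrees with the
#' grade recomputed from their components (the reported grade is kept for
#' analysis; the discordance is only reported).
#'
#' @param cases a case tibble.
#' @return a list suitable for `jsonlite::write_json()`.
#' @export
validation_report <- function(cases) {
  base <- attr(cases, "validation") %||%
    list(rows_read = nrow(cases), rows_kept = nrow(cases),
         rows_dropped_empty_rater = 0L, invalid_score_cells = list())
  derived <- grade_from_components(cases$ts, cases$ns, cases$ms)
  comparable <- !is.na(derived) & !is.na(cases$grade)
  base$grade_component_discordant <- sum(comparable & derived != cases$grade)
  base$grade_component_comparable <- sum(comparable)
  base$cases_with_grade <- sum(!is.na(cases$grade))
  base
}

#' Nottingham grade from component scores
#'
#' Standard Elston--Ellis cut-offs on the sum of tubular, nuclear and mitotic
#' scores: sum 3--5 is grade 1, 6--7 grade 2, 8--9 grade 3. Any absent
#' component yields an absent grade. Used as a consistency check on input
#' data and to derive grades in the synthetic generator.
#'
#' @param ts,ns,ms integer vectors of component scores in \{1, 2, 3\} (or
#'   `NA`); recycled to a common length.
#' @return integer vector of grades in \{1, 2, 3\} or `NA`.
#' @export
#' @examples
#' grade_from_components(1, 1, 1)  # 1
#' grade_from_components(2, 2, 2)  # sum 6 -> 2
#' grade_from_components(3, 3, 3)  # 3
grade_from_components <- function(ts, ns, ms) {
  ok <- function(x) is.na(x) | x %in% 1:3
  if (!all(ok(ts)) || !all(ok(ns)) || !all(ok(ms))) {
    abort("component scores must be in {1,2,3} or NA")
  }
  s <- ts + ns + ms
  g <- rep(NA_integer_, length(s))
  g[!is.na(s) & s <= 5] <- 1L
  g[!is.na(s) & s >= 6 & s <= 7] <- 2L
  g[!is.na(s) & s >= 8] <- 3L
  g
}

#' Cohort summary and rater eligibility
#'
#' Tallies the cohort and applies the volume eligibility filter: a rater is
#' eligible when their total case count (over all rows, any axis) is
#' *strictly greater* than `min_cases`.
#'
#' @param cases a case tibble.
#' @param min_cases eligibility threshold; raters with `> min_cases` total
#'   cases are retained. Default 35.
#' @return an object of class `cohort_summary`: a list with `total_cases`,
#'   `cases_with_grade`, `grade_counts` (length-3 integer), `volumes` (named,
#'   all raters), `eligible_rater_ids`, `eligible_case_total` and
#'   `min_cases`.
#' @export
summarize_cohort <- function(cases, min_cases = 35) {
  stopifnot(is.numeric(min_cases), length(min_cases) == 1L, min_cases >= 0)
  volumes <- table(cases$rater_id)
  volumes <- setNames(as.integer(volumes), names(volumes))
  eligible <- names(volumes)[volumes > min_cases]
  grade_counts <- vapply(1:3, function(k) sum(cases$grade == k, na.rm = TRUE),
                         integer(1))
  structure(list(
    total_cases = nrow(cases),
    cases_with_grade = sum(!is.na(cases$grade)),
    grade_counts = grade_counts,
    volumes = volumes,
    eligible_rater_ids = eligible,
    eligible_case_total = sum(volumes[eligible]),
    min_cases = min_cases
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d cases, %d with a grade (G1/G2/G3 = %s)\n",
              x$total_cases, x$cases_with_grade,
              paste(x$grade_counts, collapse = "/")))
  cat(sprintf("Raters: %d total, %d eligible (> %g cases), %d eligible cases\n",
              length(x$volumes), length(x$eligible_rater_ids), x$min_cases,
              x$eligible_case_total))
  invisible(x)
}

#' Per-rater score profiles on one grading axis
#'
#' Aggregates cases into per-rater counts of score 1/2/3 on one axis and the
#' derived pathologist interpretive rate (PIR) vector. Cases with an absent
#' score on the axis are excluded from that axis's denominator only, so an
#' axis denominator can be smaller than the rater's total volume.
#'
#' @param cases a case tibble.
#' @param axis one of `"TS"`, `"NS"`, `"MS"`, `"G"`.
#' @param rater_ids raters to profile; defaults to all raters present.
#' @return a tibble with one row per requested rater: `rater_id`, `axis`,
#'   `n1`, `n2`, `n3`, `n_axis`, `pir1`, `pir2`, `pir3`, `flagged`. Raters
#'   with no scored case on the axis get `n_axis = 0`, `NA` PIRs and
#'   `flagged = TRUE`; downstream consumers must skip or fail loudly on
#'   flagged profiles.
#' @export
profile_raters <- function(cases, axis, rater_ids = NULL) {
  axis <- check_axis(axis)
  col <- axis_column(axis)
  rater_ids <- rater_ids %||% sort(unique(cases$rater_id))

  counts <- vapply(rater_ids, function(r) {
    x <- cases[[col]][cases$rater_id == r]
    vapply(1:3, function(k) sum(x == k, na.rm = TRUE), integer(1))
  }, integer(3))

  n_axis <- unname(colSums(counts))
  counts <- unname(counts)
  pir <- sweep(counts, 2, ifelse(n_axis > 0, n_axis, NA_integer_), `/`)
  tibble::tibble(
    rater_id = unname(rater_ids),
    axis = axis,
    n1 = counts[1, ], n2 = counts[2, ], n3 = counts[3, ],
    n_axis = as.integer(n_axis),
    pir1 = pir[1, ], pir2 = pir[2, ], pir3 = pir[3, ],
    flagged = n_axis == 0L
  )
}
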