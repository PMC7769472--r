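#' Rate table for one score level
#'
#' Collects every usable rater's PIR for one score level of one axis,
#' together with the axis denominator, the group median interpretive rate
#' (GMIR) and the maximal denominator. The GMIR is the funnel-plot and
#' control-chart centre line. For an even number of raters the median is the
#' midpoint of the two central order statistics.
#'
#' @param profiles a profile tibble from [profile_raters()] (one axis).
#' @param score_level score level k in \{1, 2, 3\}.
#' @return an object of class `rate_table`: list with `axis`, `level`,
#'   `entries` (tibble `rater_id`, `pir`, `n_i`), `gmir`, `n_max`.
#' @export
rate_table <- function(profiles, score_level) {
  k <- check_score_level(score_level)
  usable <- profiles[!profiles$flagged & profiles$n_axis > 0, , drop = FALSE]
  if (nrow(usable) < 2L) {
    abort("need at least 2 raters with a non-empty axis denominator (GMIR undefined for a group of one)")
  }
  if (any(profiles$flagged)) {
    warn(sprintf("%d rater(s) with empty %s denominator excluded",
                 sum(profiles$flagged), unique(profiles$axis)))
  }
  entries <- tibble::tibble(
    rater_id = usable$rater_id,
    pir = usable[[paste0("pir", k)]],
    n_i = usable$n_axis
  )
  structure(list(
    axis = unique(usable$axis),
    level = k,
    entries = entries,
    gmir = median(entries$pir),
    n_max = max(entries$n_i)
  ), class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("Rate table %s%d: %d raters, GMIR %.4f, n_max %d\n",
              x$axis, x$level, nrow(x$entries), x$gmir, x$n_max))
  print(x$entries, ...)
  invisible(x)
}

#' All twelve score-level rate tables
#'
#' Builds the rate tables for TS1..TS3, NS1..NS3, MS1..MS3 and G1..G3 from a
#' case table, restricted to the given raters.
#'
#' @param cases a case tibble.
#' @param rater_ids raters to include (typically
#'   `summarize_cohort(cases)$eligible_rater_ids`); defaults to all.
#' @return a named list of 12 `rate_table` objects (`TS1`, ..., `G3`).
#' @export
rate_tables <- function(cases, rater_ids = NULL) {
  out <- list()
  for (axis in AXES) {
    prof <- profile_raters(cases, axis, rater_ids)
    for (k in 1:3) out[[paste0(axis, k)]] <- rate_table(prof, k)
  }
  out
}

#' Median PIR and normalized range summary
#'
#' One row per score level: the group median PIR and the range of
#' volume-normalized PIRs (see [normalize_pir()]), both in percent. Integer
#' percent display uses half-up rounding; full precision is kept in the
#' `*_raw` columns. The three medians of an axis need not sum to 100%: each
#' is a median taken separately across raters.
#'
#' @param tables named list of `rate_table` objects from [rate_tables()].
#' @return a tibble with columns `parameter`, `median_pir_pct`,
#'   `norm_lo_pct`, `norm_hi_pct` (half-up integer percent) and raw
#'   counterparts.
#' @export
median_pir_summary <- function(tables) {
  rows <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    npir <- normalize_pir(tb$entries$pir, tb$entries$n_i, tb$gmir, tb$n_max)
    tibble::tibble(
      parameter = nm,
      median_pir_raw = tb$gmir,
      norm_lo_raw = min(npir),
      norm_hi_raw = max(npir),
      median_pir_pct = round_half_up(100 * tb$gmir),
      norm_lo_pct = round_half_up(100 * min(npir)),
      norm_hi_pct = round_half_up(100 * max(npir))
    )
  })
  dplyr::bind_rows(rows)
}
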