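#' Binomial funnel-plot control limits
#'
#' Two-sided control limits around the group median interpretive rate for a
#' rater reading `n` cases, under the normal approximation to the binomial:
#' `gmir +/- z(1 - alpha/2) * sqrt(gmir * (1 - gmir) / n)`, truncated into
#' \[0, 1\]. Plotted against `n` these limits trace the funnel; at fixed `n`
#' they are the straight control-chart lines.
#'
#' @param gmir centre-line proportion, strictly inside (0, 1).
#' @param n case denominator(s); may be a vector.
#' @param alpha two-sided significance level in (0, 1).
#' @return a tibble with columns `n`, `lower`, `upper`.
#' @export
#' @examples
#' funnel_limits(0.5, 100, 0.05)  # (0.402, 0.598)
funnel_limits <- function(gmir, n, alpha) {
  stopifnot(length(gmir) == 1L, length(alpha) == 1L)
  if (!is.finite(gmir) || gmir <= 0 || gmir >= 1) {
    abort("`gmir` must lie strictly inside (0, 1); limits are degenerate at 0 or 1")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (any(n < 1)) abort("`n` must be >= 1")
  z <- qnorm(1 - alpha / 2)
  half <- z * sqrt(gmir * (1 - gmir) / n)
  tibble::tibble(
    n = n,
    lower = pmax(0, gmir - half),
    upper = pmin(1, gmir + half)
  )
}

#' Volume-normalize a PIR to the maximal denominator
#'
#' Re-expresses a rater's interpretive rate at the cohort's maximum case
#' volume while preserving its standard-deviation distance to the GMIR:
#' `norm = gmir + (pir - gmir) * sqrt(n_i / n_max)`. All raters then share
#' straight control limits computed at `n_max`, deviations from the centre
#' line shrink for low-volume raters (never changing sign or the z-score),
#' and a rate of exactly zero maps to the positive value
#' `gmir * (1 - sqrt(n_i / n_max))`.
#'
#' @param pir raw proportion(s).
#' @param n_i rater denominator(s), `1 <= n_i <= n_max`.
#' @param gmir group median interpretive rate, strictly inside (0, 1).
#' @param n_max maximal denominator in the group.
#' @return normalized proportion(s).
#' @export
#' @examples
#' normalize_pir(0, 36, 0.1, 441)  # 0.1 * (1 - 6/21) = 0.0714...
normalize_pir <- function(pir, n_i, gmir, n_max) {
  if (!is.finite(gmir) || gmir <= 0 || gmir >= 1) {
    abort("`gmir` must lie strictly inside (0, 1)")
  }
  if (any(n_i < 1)) abort("`n_i` must be >= 1")
  if (any(n_i > n_max)) abort("`n_i` must not exceed `n_max`")
  gmir + (pir - gmir) * sqrt(n_i / n_max)
}

# most extreme breached level for each |z|; levels strictly decreasing
.outlier_level_normal <- function(z, levels) {
  cut_z <- qnorm(1 - levels / 2)
  lev <- rep(NA_real_, length(z))
  for (i in seq_along(levels)) lev[abs(z) > cut_z[i]] <- levels[i]
  lev
}

# exact two-sided binomial tail probability of a count at least as extreme
.outlier_level_exact <- function(x, n, gmir, levels) {
  p <- vapply(seq_along(x), function(i) {
    lo <- pbinom(x[i], n[i], gmir)
    hi <- 1 - pbinom(x[i] - 1, n[i], gmir)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  lev <- rep(NA_real_, length(x))
  for (i in seq_along(levels)) lev[p < levels[i]] <- levels[i]
  lev
}

#' Classify raters against nested funnel limits
#'
#' Assesses every rater in a rate table against two-sided control limits at
#' each significance level, assigning the most extreme level breached.
#' Breaches are nested by construction: a rater outside the p < 0.001 limits
#' is also outside the p < 0.05 limits, so counts at the looser level are
#' cumulative.
#'
#' @param table a `rate_table` from [rate_table()].
#' @param levels strictly decreasing two-sided significance levels. Default
#'   `c(0.05, 1e-3, 1e-6, 1e-12)`, the four nested control-line levels.
#' @param exact use exact binomial tail probabilities instead of the normal
#'   approximation (relevant at small denominators); default `FALSE`.
#' @return a tibble of funnel assessments, one row per rater: `rater_id`,
#'   `axis`, `level` (score level), `pir`, `n_i`, `sd_i`, `z`, `norm_pir`,
#'   `outlier_level` (the most extreme breached alpha, or `NA` for none).
#'   Attributes `gmir`, `n_max`, `sd_max` and `alpha_levels` carry the
#'   chart geometry. If the GMIR is 0 or 1 the limits are degenerate: the
#'   table is returned with `NA` assessments and a warning.
#' @export
classify_outliers <- function(table, levels = c(0.05, 1e-3, 1e-6, 1e-12),
                              exact = FALSE) {
  stopifnot(inherits(table, "rate_table"))
  if (any(diff(levels) >= 0)) abort("`levels` must be strictly decreasing")
  e <- table$entries
  gmir <- table$gmir
  n_max <- table$n_max

  if (gmir <= 0 || gmir >= 1) {
    warn(sprintf(
      "GMIR for %s%d is %g; funnel limits are degenerate, outlier analysis skipped",
      table$axis, table$level, gmir))
    out <- tibble::tibble(
      rater_id = e$rater_id, axis = table$axis, level = table$level,
      pir = e$pir, n_i = e$n_i, sd_i = NA_real_, z = NA_real_,
      norm_pir = NA_real_, outlier_level = NA_real_
    )
    attr(out, "gmir") <- gmir
    attr(out, "n_max") <- n_max
    attr(out, "sd_max") <- NA_real_
    attr(out, "alpha_levels") <- levels
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  sd_i <- sqrt(gmir * (1 - gmir) / e$n_i)
  z <- (e$pir - gmir) / sd_i
  lev <- if (exact) {
    .outlier_level_exact(round(e$pir * e$n_i), e$n_i, gmir, levels)
  } else {
    .outlier_level_normal(z, levels)
  }
  out <- tibble::tibble(
    rater_id = e$rater_id, axis = table$axis, level = table$level,
    pir = e$pir, n_i = e$n_i, sd_i = sd_i, z = z,
    norm_pir = normalize_pir(e$pir, e$n_i, gmir, n_max),
    outlier_level = lev
  )
  attr(out, "gmir") <- gmir
  attr(out, "n_max") <- n_max
  attr(out, "sd_max") <- sqrt(gmir * (1 - gmir) / n_max)
  attr(out, "alpha_levels") <- levels
  attr(out, "degenerate") <- FALSE
  out
}

#' Cumulative outlier counts
#'
#' Number of raters breaching each significance level, counted cumulatively
#' (a breach at p < 0.001 also counts at p < 0.05), matching the convention
#' of summary tables that report "outliers p<0.05" alongside "p<0.001".
#'
#' @param assessments a funnel-assessment tibble from [classify_outliers()].
#' @param levels levels to count at; defaults to the assessment's own.
#' @return named integer vector of counts per level.
#' @export
outlier_counts <- function(assessments, levels = NULL) {
  levels <- levels %||% attr(assessments, "alpha_levels")
  vapply(levels, function(a) {
    sum(!is.na(assessments$outlier_level) & assessments$outlier_level <= a)
  }, integer(1)) |> setNames(paste0("p<", format(levels)))
}
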