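#' Render a control chart of normalized PIRs
#'
#' One point per rater (random left-to-right order under `seed`, so chart
#' position does not reveal identity or volume), a centre line at the GMIR,
#' and straight two-sided control lines at each significance level computed
#' from the binomial standard deviation at the maximal volume. Because every
#' point is volume-normalized, a point between two control lines is exactly
#' as many standard deviations from the GMIR as its raw rate was.
#'
#' @param assessments a funnel-assessment tibble from [classify_outliers()].
#' @param path optional output file; the device is chosen from the
#'   extension (`.svg`, `.png`, `.pdf`). `NULL` returns the plot only.
#' @param seed seed for the random rater ordering.
#' @param title optional plot title; defaults to "axis + level".
#' @return the ggplot object, invisibly if written to `path`.
#' @export
render_control_chart <- function(assessments, path = NULL, seed = 1L,
                                 title = NULL) {
  if (nrow(assessments) < 1L) abort("need at least one assessment")
  if (isTRUE(attr(assessments, "degenerate"))) {
    abort("degenerate GMIR: no control chart can be drawn")
  }
  gmir <- attr(assessments, "gmir")
  sd_max <- attr(assessments, "sd_max")
  alphas <- attr(assessments, "alpha_levels")

  ord <- withr::with_seed(seed, sample(nrow(assessments)))
  df <- assessments[ord, , drop = FALSE]
  df$position <- seq_len(nrow(df))

  lines <- tibble::tibble(
    alpha = rep(alphas, each = 2),
    y = as.vector(vapply(alphas, function(a) {
      gmir + c(-1, 1) * qnorm(1 - a / 2) * sd_max
    }, numeric(2))),
    style = ifelse(rep(alphas, each = 2) == 1e-3, "solid", "dashed")
  )

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$norm_pir)) +
    ggplot2::geom_hline(yintercept = gmir, colour = "black", linewidth = 0.8) +
    ggplot2::geom_hline(
      data = lines,
      ggplot2::aes(yintercept = .data$y, linetype = .data$style),
      colour = "blue", linewidth = 0.4, show.legend = FALSE
    ) +
    ggplot2::scale_linetype_identity() +
    ggplot2::geom_point(colour = "red", shape = 1, size = 2.5, stroke = 1) +
    ggplot2::scale_x_continuous(breaks = df$position) +
    ggplot2::labs(
      title = title %||% sprintf("%s%d", df$axis[1], df$level[1]),
      x = "pathologist (random order)", y = "normalized PIR"
    ) +
    ggplot2::theme_minimal()

  if (!is.null(path)) {
    save_chart(p, path)
    return(invisible(p))
  }
  p
}

#' Render a raw-PIR stacked bar chart for one axis
#'
#' Companion to the control charts: each rater's raw score-1/2/3 rates as a
#' stacked bar (score 1 green, 2 yellow, 3 red), raters in the same random
#' order convention as [render_control_chart()].
#'
#' @param profiles a profile tibble from [profile_raters()].
#' @param path optional output file.
#' @param seed seed for the random rater ordering.
#' @return the ggplot object, invisibly if written to `path`.
#' @export
render_pir_barchart <- function(profiles, path = NULL, seed = 1L) {
  usable <- profiles[!profiles$flagged, , drop = FALSE]
  if (nrow(usable) < 1L) abort("no rater with a usable profile")
  ord <- withr::with_seed(seed, sample(nrow(usable)))
  usable <- usable[ord, , drop = FALSE]
  usable$position <- seq_len(nrow(usable))

  long <- tidyr::pivot_longer(
    usable[, c("position", "pir1", "pir2", "pir3")],
    cols = c("pir1", "pir2", "pir3"),
    names_to = "score", values_to = "pir"
  )
  long$score <- factor(long$score, levels = c("pir3", "pir2", "pir1"),
                       labels = c("3", "2", "1"))

  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$pir,
                                          fill = .data$score)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_manual(values = c(`1` = "forestgreen",
                                          `2` = "gold", `3` = "firebrick"),
                               breaks = c("1", "2", "3"), name = "score") +
    ggplot2::scale_x_continuous(breaks = usable$position) +
    ggplot2::labs(title = usable$axis[1], x = "pathologist (random order)",
                  y = "raw PIR") +
    ggplot2::theme_minimal()

  if (!is.null(path)) {
    save_chart(p, path)
    return(invisible(p))
  }
  p
}

# write a ggplot using a device inferred from the file extension; SVG and
# PNG need cairo support in the running R build, PDF always works
save_chart <- function(plot, path, width = 6, height = 4) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    svg = function(f) grDevices::svg(f, width = width, height = height),
    png = function(f) grDevices::png(f, width = width * 100,
                                     height = height * 100, res = 100),
    pdf = function(f) grDevices::pdf(f, width = width, height = height),
    abort(sprintf("unsupported chart format '.%s' (use svg, png or pdf)", ext))
  )
  dev(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}
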