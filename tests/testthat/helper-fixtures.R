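# shared fixtures: tiny in-code cohorts and independent oracles

# profile tibble straight from a PIR matrix (rows = raters), bypassing case
# aggregation; counts are filled to be consistent with the rates
profile_from_pir <- function(pirs, n_axis, axis = "G") {
  pirs <- as.matrix(pirs)
  counts <- round(pirs * n_axis)
  tibble::tibble(
    rater_id = sprintf("P%02d", seq_len(nrow(pirs))),
    axis = axis,
    n1 = counts[, 1], n2 = counts[, 2], n3 = counts[, 3],
    n_axis = as.integer(n_axis),
    pir1 = pirs[, 1], pir2 = pirs[, 2], pir3 = pirs[, 3],
    flagged = FALSE
  )
}

# write a small case CSV with the default header; `...` are column vectors
write_case_csv <- function(path, rater, ts = NA, ns = NA, ms = NA,
                           grade = NA, t_stage = NA) {
  n <- length(rater)
  df <- data.frame(
    case_id = seq_len(n), pathologist = rater,
    tubular_score = rep_len(ts, n), nuclear_score = rep_len(ns, n),
    mitotic_score = rep_len(ms, n), grade = rep_len(grade, n),
    t_stage = rep_len(t_stage, n)
  )
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# independent oracle: maximal diagonal agreement over all 2x2 integer
# tables with fixed margins (a, n - a) x (b, n - b), by enumeration
brute_force_kappa_max <- function(a, b, n) {
  x11 <- max(0, a + b - n):min(a, b)
  diag_agree <- x11 + (n - a - b + x11)
  p_o <- max(diag_agree) / n
  p_e <- (a / n) * (b / n) + ((n - a) / n) * ((n - b) / n)
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

# independent oracle: latent-interval Monte Carlo for the ordered-category
# overlap kappa -- N uniform cases categorized by each rater's cumulative
# thresholds, agreement counted directly
latent_interval_kappa <- function(pir_a, pir_b, n_sim = 1e6) {
  u <- runif(n_sim)
  cat_a <- findInterval(u, cumsum(pir_a)[-3]) + 1L
  cat_b <- findInterval(u, cumsum(pir_b)[-3]) + 1L
  p_o <- mean(cat_a == cat_b)
  p_e <- sum(pir_a * pir_b)
  (p_o - p_e) / (1 - p_e)
}

# random probability 3-vector (uniform on the simplex)
random_pir <- function() {
  x <- -log(runif(3))
  x / sum(x)
}
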