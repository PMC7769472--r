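#' Pairwise in silico kappa under the maximal categorical overlap assumption
#'
#' MCOA treats a single score level as a binary call (level k vs rest) and
#' asks: given only the two raters' marginal rates `p_a` and `p_b`, what is
#' the largest agreement compatible with those margins? That maximum is
#' `p_o_max = min(p_a, p_b) + min(1 - p_a, 1 - p_b)`; chance agreement is the
#' Cohen-style product of the pair's own margins,
#' `p_e = p_a p_b + (1 - p_a)(1 - p_b)`, and the statistic is the
#' kappa-maximum `(p_o_max - p_e) / (1 - p_e)`. Two raters with identical
#' rates score exactly 1: the assumption is that equal rates mean agreement
#' on every case.
#'
#' When both raters are degenerate at the same pole (`p_e = 1`) agreement is
#' forced, not informative; the statistic is defined as 1 by convention and
#' the returned vector carries a `degenerate` attribute marking such pairs.
#'
#' @param p_a,p_b marginal rates in \[0, 1\]; recycled to a common length.
#' @return numeric vector of kappa-maximum values in \[-1, 1\], with
#'   attribute `degenerate` (logical).
#' @export
#' @examples
#' mcoa_pair_kappa(0.3, 0.3)  # 1
#' mcoa_pair_kappa(0.2, 0.4)  # 0.5455
mcoa_pair_kappa <- function(p_a, p_b) {
  if (any(p_a < 0 | p_a > 1 | p_b < 0 | p_b > 1, na.rm = TRUE)) {
    abort("marginal rates must lie in [0, 1]")
  }
  p_o <- pmin(p_a, p_b) + pmin(1 - p_a, 1 - p_b)
  p_e <- p_a * p_b + (1 - p_a) * (1 - p_b)
  degen <- p_e >= 1
  k <- ifelse(degen, 1, (p_o - p_e) / (1 - p_e))
  attr(k, "degenerate") <- degen
  k
}

#' Pairwise in silico kappa under the ordered mutually exclusive category
#' assumption
#'
#' OMECA models the three ordered score levels as adjacent intervals on a
#' latent severity axis: each rater partitions \[0, 1\] at the cumulative
#' sums of their PIR vector, and the two raters are assumed to order cases
#' identically, so only adjacent categories ever compete. The in silico
#' observed agreement is the total overlap of corresponding intervals,
#' `p_o = sum_k max(0, min(C_a(k), C_b(k)) - max(C_a(k-1), C_b(k-1)))`,
#' chance agreement is `p_e = sum_k pir_a(k) * pir_b(k)`, and
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param pir_a,pir_b non-negative numeric vectors of the same length
#'   (category probabilities) each summing to 1 within `tol`.
#' @param tol tolerance on the probability sums (default `1e-8`).
#' @return a single kappa in \[-1, 1\], with attribute `degenerate`
#'   (`TRUE` when `p_e = 1`, i.e. both raters put all mass on the same
#'   single category; kappa is then 1 by convention).
#' @export
#' @examples
#' omeca_pair_kappa(c(0.2, 0.5, 0.3), c(0.3, 0.4, 0.3))  # 0.8462
omeca_pair_kappa <- function(pir_a, pir_b, tol = 1e-8) {
  if (length(pir_a) != length(pir_b)) abort("PIR vectors must have equal length")
  if (any(pir_a < 0) || any(pir_b < 0)) abort("PIR vectors must be non-negative")
  if (abs(sum(pir_a) - 1) > tol || abs(sum(pir_b) - 1) > tol) {
    abort("PIR vectors must each sum to 1")
  }
  ca <- cumsum(pir_a); cb <- cumsum(pir_b)
  lo <- pmax(c(0, ca[-length(ca)]), c(0, cb[-length(cb)]))
  hi <- pmin(ca, cb)
  p_o <- sum(pmax(0, hi - lo))
  p_e <- sum(pir_a * pir_b)
  degen <- p_e >= 1 - tol
  k <- if (degen) 1 else (p_o - p_e) / (1 - p_e)
  attr(k, "degenerate") <- degen
  k
}

# all unordered pairs of rows of `pirs` (m x 3 matrix) -> OMECA kappas,
# vectorized over pairs (hot path of the bootstrap)
.omeca_pairs <- function(pirs, idx) {
  ca <- t(apply(pirs, 1, cumsum))  # m x 3 cumulative
  a <- idx[1, ]; b <- idx[2, ]
  ov1 <- pmax(0, pmin(ca[a, 1], ca[b, 1]))
  ov2 <- pmax(0, pmin(ca[a, 2], ca[b, 2]) - pmax(ca[a, 1], ca[b, 1]))
  ov3 <- pmax(0, pmin(ca[a, 3], ca[b, 3]) - pmax(ca[a, 2], ca[b, 2]))
  p_o <- ov1 + ov2 + ov3
  p_e <- rowSums(pirs[a, , drop = FALSE] * pirs[b, , drop = FALSE])
  ifelse(p_e >= 1 - 1e-8, 1, (p_o - p_e) / (1 - p_e))
}

# shared core: pairwise-mean group kappa from a PIR matrix
.group_isk_matrix <- function(pirs, n_i, assumption, score_level, weighting,
                              idx) {
  kap <- if (assumption == "MCOA") {
    p <- pirs[, score_level]
    as.numeric(mcoa_pair_kappa(p[idx[1, ]], p[idx[2, ]]))
  } else {
    .omeca_pairs(pirs, idx)
  }
  if (weighting == "volume") {
    w <- n_i[idx[1, ]] * n_i[idx[2, ]]
    sum(w * kap) / sum(w)
  } else {
    mean(kap)
  }
}

#' Group in silico kappa
#'
#' The group statistic is the unweighted arithmetic mean of the pairwise
#' kappa over all unordered rater pairs (45 pairs for 10 raters). Under
#' MCOA the pairwise statistic is [mcoa_pair_kappa()] on one score level
#' collapsed to binary; under OMECA it is [omeca_pair_kappa()] on the full
#' 3-level axis. A volume-weighted mean (weights `n_i * n_j`) is available
#' behind `weighting = "volume"`.
#'
#' @param profiles a profile tibble from [profile_raters()] (one axis).
#' @param assumption `"MCOA"` or `"OMECA"`.
#' @param score_level score level for MCOA; ignored (must be `NULL`) for
#'   OMECA, which always uses the whole axis.
#' @param weighting `"unweighted"` (default) or `"volume"`.
#' @return the group kappa (numeric scalar).
#' @export
group_isk <- function(profiles, assumption = c("MCOA", "OMECA"),
                      score_level = NULL,
                      weighting = c("unweighted", "volume")) {
  assumption <- match.arg(assumption)
  weighting <- match.arg(weighting)
  usable <- profiles[!profiles$flagged & profiles$n_axis > 0, , drop = FALSE]
  if (nrow(usable) < nrow(profiles)) {
    warn(sprintf("%d rater(s) with undefined PIR excluded",
                 nrow(profiles) - nrow(usable)))
  }
  m <- nrow(usable)
  if (m < 2L) abort("need at least 2 raters with defined PIRs")

  if (assumption == "MCOA") {
    score_level <- check_score_level(score_level)
  } else if (!is.null(score_level)) {
    abort("OMECA applies to the whole axis; leave `score_level` NULL")
  }
  idx <- combn(m, 2)
  pirs <- as.matrix(usable[, c("pir1", "pir2", "pir3")])
  .group_isk_matrix(pirs, usable$n_axis, assumption, score_level,
                    weighting, idx)
}

#' Parametric-bootstrap confidence interval for a group in silico kappa
#'
#' For each replicate, every rater's score counts are redrawn from a
#' multinomial at that rater's observed PIR and observed axis denominator;
#' the group kappa is recomputed on the resampled rates, and the interval is
#' the 2.5/97.5 percentile of the replicates. The reported point estimate is
#' the statistic on the observed data, not a bootstrap average. Resampling
#' cases within raters is the minimal scheme consistent with rates-only
#' data. Degenerate resamples (a rater with all mass on one level) follow
#' the pairwise `p_e = 1` convention.
#'
#' @inheritParams group_isk
#' @param n_boot number of bootstrap replicates (default 2000, minimum 200).
#' @param seed integer RNG seed; the interval is reproducible under it.
#' @param conf confidence level (default 0.95).
#' @return an object of class `kappa_estimate`: list with `statistic`,
#'   `assumption`, `target` (e.g. `"NS1"` or `"G"`), `ci_low`, `ci_high`,
#'   `n_boot`, `seed`, `replicates` (the bootstrap draws, for diagnostics).
#' @export
bootstrap_ci <- function(profiles, assumption = c("MCOA", "OMECA"),
                         score_level = NULL, n_boot = 2000, seed = 1L,
                         weighting = c("unweighted", "volume"),
                         conf = 0.95) {
  assumption <- match.arg(assumption)
  weighting <- match.arg(weighting)
  if (n_boot < 200) abort("`n_boot` must be at least 200")
  usable <- profiles[!profiles$flagged & profiles$n_axis > 0, , drop = FALSE]
  if (nrow(usable) < 2L) abort("need at least 2 raters with defined PIRs")

  point <- group_isk(usable, assumption, score_level, weighting)
  axis <- unique(usable$axis)
  target <- if (assumption == "MCOA") paste0(axis, score_level) else axis

  pirs <- as.matrix(usable[, c("pir1", "pir2", "pir3")])
  n_i <- usable$n_axis
  m <- nrow(usable)

  if (assumption == "MCOA") score_level <- check_score_level(score_level)
  idx <- combn(m, 2)
  reps <- withr::with_seed(seed, {
    # one multinomial stream per rater: 3 x n_boot resampled PIRs
    draws <- lapply(seq_len(m), function(i) {
      rmultinom(n_boot, n_i[i], pirs[i, ]) / n_i[i]
    })
    vapply(seq_len(n_boot), function(b) {
      pb <- t(vapply(draws, function(d) d[, b], numeric(3)))
      .group_isk_matrix(pb, n_i, assumption, score_level, weighting, idx)
    }, numeric(1))
  })

  qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE, type = 7)
  structure(list(
    statistic = point, assumption = assumption, target = target,
    ci_low = qs[1], ci_high = qs[2],
    n_boot = n_boot, seed = seed, conf = conf, replicates = reps
  ), class = "kappa_estimate")
}

#' @export
print.kappa_estimate <- function(x, ...) {
  cat(sprintf("In silico kappa [%s] %s: %.2f (%d%% CI %.2f-%.2f; B=%d, seed=%d)\n",
              x$assumption, x$target, x$statistic, round(100 * x$conf),
              x$ci_low, x$ci_high, x$n_boot, x$seed))
  invisible(x)
}
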