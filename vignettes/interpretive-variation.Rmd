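---
title: "Interpretive rates, control charts and the in silico kappa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretive rates, control charts and the in silico kappa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iskappa)
```

## The setting

A pathology service signs out many resections per year; each invasive
breast carcinoma receives a tubular score (TS), nuclear score (NS) and
mitotic score (MS), each 1–3, whose sum maps to the Nottingham grade
(3–5 → G1, 6–7 → G2, 8–9 → G3). No two pathologists read the same cases,
so classic inter-rater statistics do not apply directly. What *is*
observable is each pathologist's **interpretive rate** (PIR): the fraction
of their own cases assigned to each score level. If case mix is
approximately exchangeable across pathologists — plausible when cases are
allocated by rota rather than by subspecialty — systematic differences in
PIRs measure interpretive style, and a laboratory can monitor them the way
industry monitors process parameters.

This vignette records the package's model, its assumptions, and the design
decisions taken where more than one reasonable construction exists.

## Rates, medians and eligibility

For rater $i$ on one axis, the PIR vector is $p_{ik} = n_{ik}/n_i$, where
$n_i$ counts only that rater's cases with a *present* score on that axis:
an ungraded case drops out of the grade denominator without affecting the
component denominators. The group centre line is the **group median
interpretive rate** (GMIR), the median of the $p_{ik}$ across raters; for
an even group the midpoint of the two central order statistics is used
(the standard convention; nothing downstream is sensitive to it). The
median, not the mean, is used because a single divergent high-volume rater
should not drag the reference line.

Raters enter the analysis when their total case volume is *strictly*
greater than `min_cases` (default 35). The threshold is measured on total
cases read, so a rater can be eligible while having a smaller denominator
on one axis (missing scores); per-axis denominators as low as the
30-to-40 range still yield usable, if wide, funnel limits. The three
score-level medians of an axis are each computed marginally, so they need
not sum to exactly 100%.

## Funnel limits and volume normalization

Under the hypothesis that rater $i$ truly operates at the GMIR $m$, their
observed rate is approximately
$\mathcal N\!\left(m,\; m(1-m)/n_i\right)$, giving two-sided control
limits $m \pm z_{1-\alpha/2}\sqrt{m(1-m)/n_i}$, truncated into $[0,1]$.
Limits are drawn at the nested levels $\alpha \in \{0.05, 10^{-3},
10^{-6}, 10^{-12}\}$; a rater is assigned the most extreme level they
breach, and counts at looser levels are cumulative. The normal
approximation is the default because the whole normalization machinery
lives on the Gaussian (standard-deviation) scale; an exact-binomial mode
(`classify_outliers(..., exact = TRUE)`) exists for small denominators,
where the two can disagree at the extreme levels. If a level's GMIR is 0
or 1 the binomial variance vanishes; the package refuses to fabricate
limits and instead skips that level's outlier analysis with a warning.

Funnel plots are awkward to read (points overlap at similar volumes) and
display each rater's volume, which weakens anonymization. The package
therefore re-expresses every rate at the maximum volume:

$$p^{*} \;=\; m + (p - m)\sqrt{n_i/n_{\max}}.$$

This is the unique affine-in-$p$ map that (a) fixes the centre line, (b)
is the identity at $n_i = n_{\max}$, and (c) preserves each rater's
z-distance to the GMIR when re-measured with the $n_{\max}$ standard
deviation — so outlier classification is invariant under it, by
construction. Two consequences worth knowing: the normalized range is
contained in the raw range (every point moves toward the centre line), and
a raw rate of exactly zero becomes the positive value
$m(1-\sqrt{n_i/n_{\max}})$ — normalized charts do not show hard zeros.
Both are asserted in the test suite.

## The in silico kappa

The **in silico kappa** (ISK) asks: given only the marginal rate profiles,
how much agreement *could* this group have? It is a best-case statistic —
an upper envelope for the conventional kappa one would obtain if all
raters read all cases — and is computed pairwise, then averaged.

**MCOA** (maximal categorical overlap assumption) applies to a single
score level collapsed to binary (level $k$ vs rest). For rates $p_a, p_b$
the largest achievable agreement is
$p_o^{\max} = \min(p_a,p_b) + \min(1-p_a,1-p_b)$, chance agreement is the
Cohen-style product of the pair's own margins,
$p_e = p_a p_b + (1-p_a)(1-p_b)$, and
$\kappa = (p_o^{\max}-p_e)/(1-p_e)$. This is exactly the kappa-maximum of
a 2×2 table with those margins; the test suite verifies it against a
brute-force enumeration of all integer tables with $n \le 12$. One
algebraic fact surprises people: $p_o^{\max} - p_e =
2\min(p_a,p_b)\min(1-p_a,1-p_b) \ge 0$, so the MCOA ISK is never
negative — even totally disjoint margins give $\kappa = 0$, because their
chance agreement is also zero.

**OMECA** (ordered mutually exclusive category assumption) applies to the
whole 3-level axis. It strengthens the ordinal structure into a model:
both raters are assumed to rank cases identically on a latent severity
axis and differ only in where they cut it. Each rater's cuts are the
cumulative sums $C(k)$ of their PIR vector; corresponding categories are
the intervals between consecutive cuts, and the in silico observed
agreement is the total overlap

$$p_o = \sum_k \max\!\big(0,\; \min(C_a(k),C_b(k)) -
\max(C_a(k-1),C_b(k-1))\big),$$

with $p_e = \sum_k p_{ak}p_{bk}$ as usual. Under this model only adjacent
categories compete — a case near the 1/2 boundary can be called 1 or 2 but
never 3. The construction is validated against an independent latent-
interval Monte Carlo oracle (10⁶ uniform cases categorized by each
rater's cuts) in the test suite. OMECA kappa *can* be negative when both
raters put mass in a shared middle category but on disjoint sides
elsewhere, and it is always bounded above by the multi-category
kappa-maximum, whose numerator $\sum_k \min(p_{ak},p_{bk})$ ignores the
ordering constraint.

**Aggregation.** The group statistic is the unweighted arithmetic mean of
the pairwise kappa over all unordered pairs (45 for ten raters). The
unweighted mean matches the "mean pairwise kappa" convention of
multi-department agreement studies and treats each pathologist as one
member of the group regardless of throughput; a volume-weighted mean
(weights $n_i n_j$) is available behind `weighting = "volume"` for readers
who want the case-weighted view. MCOA is reported per score level and
OMECA per axis: collapsing to binary is only meaningful level-by-level,
while the ordered-overlap construction needs the whole axis.

**Uncertainty.** CIs come from a parametric bootstrap: each rater's counts
are redrawn from a multinomial at their observed PIR and observed
denominator, the group statistic is recomputed, and the 2.5/97.5
percentiles over `n_boot = 2000` replicates are reported. Resampling
within raters is the minimal scheme consistent with rates-only data — it
propagates sampling noise in each rater's rates but deliberately does not
model between-rater sampling, since the rater group is the population of
interest, not a sample. The point estimate is always the statistic on the
observed data. Degenerate draws (a rater with all mass on one level) fall
back on the $p_e = 1$ convention: kappa 1, flagged as forced rather than
informative agreement.

## The synthetic generator

`synthetic_config()` + `simulate_cohort()` produce case-level cohorts:
per-rater volumes (explicit or drawn from a range), per-rater true
multinomials for TS/NS/MS, and a grade *derived* from the sampled
components — so component/grade consistency holds by construction, and an
optional discordance fraction exists purely to exercise the validation
reporting. A configurable fraction of cases is blanked entirely (ungraded
resections, given a T-stage label instead). Each rater draws from an RNG
substream derived deterministically from the cohort seed, so enlarging the
group never perturbs existing raters' data.

`paper_like_preset()` emulates a published ten-pathologist grading study:
volumes uniform on 38–441, component rates centred on that study's group
medians (TS 9/23/66%, NS 5/57/37%, MS 57/21/20%, each normalized to sum
to 1), 6% of cases ungraded, and per-rater heterogeneity injected as
multiplicative log-normal jitter on each cell followed by renormalization.
The jitter default (0.3) was calibrated once so that the normalized grade
PIR ranges of generated cohorts are comparable in width to the published
ones, and then frozen.

What the generator deliberately does **not** model: case-mix differences
between raters (every rater draws from their own fixed multinomial —
there is no difficulty covariate), correlation between components beyond
what the grade derivation induces, drift over time, and rater behaviour
that depends on volume. Consequently, passing tests demonstrate that the
statistics behave correctly *when rate differences are purely
interpretive*; on real data, funnel outliers may still reflect case-mix,
and the ISK remains a best-case bound, not an estimate of a conventional
kappa.

## Numerical and edge-case choices

- Probability vectors must sum to 1 within 10⁻⁸; cumulative overlaps are
  clipped at 0 to absorb floating-point slack.
- `p_e = 1` (both raters degenerate at the same pole) yields kappa 1 with
  a degeneracy flag rather than 0/0.
- Unparseable or out-of-range score cells become absent scores with a
  warning and a validation-report entry — never silent coercion; a
  missing rater column is fatal.
- Reported grades that contradict their components are counted and
  reported, but the reported grade is analysed: the object of study is
  what pathologists signed out.
- Display rounding is half-up (integer percent, 2-decimal kappas) to
  mirror how such tables are printed; raw precision is kept in `*_raw`
  columns.
- Eligibility is strict (`> min_cases`); the boundary rater at exactly 35
  cases is excluded.

## Problem sizes in the validation suite

The suite exercises the estimators at sizes chosen to make the checks
sharp but quick: exhaustive kappa-maximum enumeration for all margins up
to $n = 12$; 100 random rate pairs against the 10⁶-case latent-interval
oracle; funnel calibration over 500 ten-rater cohorts with identical true
rates (flag rate at $p<0.05$ required to be within 0.03–0.07, and
$\le 0.005$ at $p<0.001$); and shared-truth OMECA recovery at 40,000
cases per rater, where sampling noise in the empirical rates is small
enough that the group ISK must exceed 0.98. At realistic volumes
(hundreds of cases) the same statistic sits visibly below 1 under
identical truth — that gap is sampling noise, and it is why the bootstrap
CIs matter at practice scale.

## Limitations

The method inherits the limits of observational rate data: it cannot
attribute a specific case to a specific disagreement, it presumes
comparable case mix, its resolution is bounded by the funnel width at each
rater's volume, and the best interpretive rate is unknown — the GMIR is a
peer reference, not a gold standard. The ISK should be read as an upper
bound on conventional agreement under explicit assumptions, most useful
for ranking axes and score levels against each other and for tracking a
group over time.
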