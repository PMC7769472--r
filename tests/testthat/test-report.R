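# pipeline tests use a small bootstrap (the CI method itself is exercised
# in test-isk.R); charts use the pdf device, which needs no cairo
run_small <- function(input, outdir, seed = 1L, ...) {
  run_report(input, outdir, n_boot = 200, seed = seed, chart_format = "pdf", ...)
}

test_that("the report bundle carries 16 statistic rows and all artifacts", {
  cases <- simulate_cohort(paper_like_preset(seed = 14))
  outdir <- withr::local_tempdir()
  res <- run_small(cases, outdir)

  expect_equal(nrow(res$summary), 16L)
  expect_equal(sum(res$summary$assumption == "OMECA"), 4L)
  expect_equal(sum(res$summary$assumption == "MCOA"), 12L)
  expect_setequal(res$summary$parameter[res$summary$assumption == "OMECA"],
                  c("TS", "NS", "MS", "G"))
  # axis rows carry no median/outlier columns; level rows carry all
  axis_rows <- res$summary[res$summary$assumption == "OMECA", ]
  expect_true(all(is.na(axis_rows$median_pir_pct)))
  level_rows <- res$summary[res$summary$assumption == "MCOA", ]
  expect_true(all(!is.na(level_rows$median_pir_pct)))
  expect_true(all(level_rows$outliers_p05 >= level_rows$outliers_p001))
  expect_true(all(res$summary$ci_low_raw <= res$summary$isk_raw + 1e-12))
  expect_true(all(res$summary$ci_high_raw >= res$summary$isk_raw - 1e-12))

  files <- list.files(outdir)
  expect_true(all(c("validation.json", "summary_table.tsv", "outliers.tsv",
                    "isk.json", "manifest.json") %in% files))
  expect_equal(sum(grepl("^cc_.*\\.pdf$", files)), 12L)
  expect_equal(sum(grepl("^pir_.*\\.pdf$", files)), 4L)

  tsv <- read.delim(file.path(outdir, "summary_table.tsv"))
  expect_equal(nrow(tsv), 16L)
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_equal(manifest$seed, 1L)
  expect_equal(manifest$n_boot, 200L)
})

test_that("the same input and seed give identical numeric outputs", {
  cases <- simulate_cohort(paper_like_preset(seed = 15))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_small(cases, d1, seed = 7, charts = FALSE)
  r2 <- run_small(cases, d2, seed = 7, charts = FALSE)
  expect_identical(r1$summary, r2$summary)
  expect_identical(
    readLines(file.path(d1, "summary_table.tsv")),
    readLines(file.path(d2, "summary_table.tsv")))
})

test_that("fewer than two eligible raters aborts and removes partial output", {
  cases <- tibble::tibble(
    case_id = as.character(1:40), rater_id = "solo",
    ts = 2L, ns = 2L, ms = 2L, grade = 2L, t_stage = NA_character_
  )
  outdir <- file.path(withr::local_tempdir(), "bundle")
  expect_error(run_small(cases, outdir), "fewer than 2 eligible")
  expect_false(dir.exists(outdir))
})

test_that("simulate-to-report round trip works from a CSV on disk", {
  cfg <- paper_like_preset(seed = 16)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_synthetic_cohort(cfg, csv)
  outdir <- withr::local_tempdir()
  res <- run_small(csv, outdir, charts = FALSE)
  expect_equal(nrow(res$summary), 16L)
  expect_equal(res$cohort$total_cases, nrow(read_cases(csv)))
})

test_that("control charts and bar charts render to file", {
  cases <- simulate_cohort(paper_like_preset(seed = 18))
  el <- summarize_cohort(cases)$eligible_rater_ids
  prof <- profile_raters(cases, "G", el)
  a <- classify_outliers(rate_table(prof, 2))

  f <- withr::local_tempfile(fileext = ".pdf")
  p <- render_control_chart(a, f, seed = 4)
  expect_true(file.size(f) > 0)
  expect_s3_class(p, "ggplot")
  # same seed, same rater ordering in the build data
  b1 <- ggplot2::ggplot_build(render_control_chart(a, seed = 9))
  b2 <- ggplot2::ggplot_build(render_control_chart(a, seed = 9))
  expect_equal(b1$data[[3]], b2$data[[3]])

  fb <- withr::local_tempfile(fileext = ".pdf")
  render_pir_barchart(prof, fb)
  expect_true(file.size(fb) > 0)
})

test_that("all raters at the GMIR sit on the centre line", {
  prof <- profile_from_pir(matrix(rep(c(0.3, 0.45, 0.25), 5), 5, byrow = TRUE),
                           c(50, 80, 120, 300, 441))
  a <- classify_outliers(rate_table(prof, 1))
  expect_true(all(a$norm_pir == attr(a, "gmir")))
  p <- render_control_chart(a)
  built <- ggplot2::ggplot_build(p)
  pts <- built$data[[3]]
  expect_true(all(pts$y == attr(a, "gmir")))
})

test_that("reproduction report is structured, not skipped, when data are absent", {
  rep0 <- reproduce_summary_table(NULL)
  expect_s3_class(rep0, "table1_reproduction")
  expect_equal(rep0$status, "unavailable")
  expect_match(rep0$reason, "case-level")
  expect_output(print(rep0), "UNAVAILABLE")

  repmissing <- reproduce_summary_table("no/such/file.csv")
  expect_equal(repmissing$status, "unavailable")
  expect_match(repmissing$reason, "not found")
})

test_that("the CLI wrapper simulates and reports end to end", {
  skip_if_not_installed("optparse")
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "cohort.csv")
  expect_equal(isk_main(c("simulate", "--output", csv, "--seed", "19")), 0L)
  expect_true(file.exists(csv))
  outdir <- file.path(tmp, "bundle")
  st <- isk_main(c("isk", "--input", csv, "--outdir", outdir,
                   "--n-boot", "200", "--seed", "3"))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(outdir, "summary_table.tsv")))
  expect_equal(isk_main("nonsense"), 1L)
})
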