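test_that("panel presets have the expected sizes and unique ids", {
  p18 <- panel_preset(18)
  p100 <- panel_preset(100)
  expect_equal(p18$K, 18)
  expect_equal(p100$K, 100)
  expect_false(anyDuplicated(p100$ids) > 0)
  expect_true(all(p18$ids %in% p100$ids))
  expect_error(population_panel("one"), "at least 2")
  expect_error(population_panel(c("a", "a", "b")), "unique")
})

test_that("cohort_set enforces profile invariants with informative errors", {
  panel <- population_panel(c("a", "b", "c"))
  meta <- data.frame(subject_id = c("s1", "s1"), cohort = "hiv_pos",
                     timepoint_days = 56L)
  counts <- rbind(c(10, 5, 1), c(2, 3, 4))
  colnames(counts) <- panel$ids
  expect_error(cohort_set(panel, meta, counts), "duplicate subject_id")
  meta$timepoint_days <- c(56L, 180L)
  meta$subject_id <- c("s1", "s2")
  expect_silent(cohort_set(panel, meta, counts))
  bad <- counts; bad[2, 2] <- -5
  expect_error(cohort_set(panel, meta, bad), "row 2, population 'b'")
  zero <- counts; zero[1, ] <- 0
  expect_error(cohort_set(panel, meta, zero), "all-zero")
  meta2 <- meta; meta2$cohort <- "patients"
  expect_error(cohort_set(panel, meta2, counts), "unknown cohort")
})

test_that("writer/reader round-trips counts exactly across random cohorts", {
  for (seed in c(1, 7, 23)) {
    cs <- toy_cohort(K = 5, seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_cohort(cs, path)
    back <- read_cohort(path)
    expect_equal(back$counts, cs$counts)
    expect_equal(back$meta$subject_id, cs$meta$subject_id)
    expect_equal(back$meta$timepoint_days, cs$meta$timepoint_days)
  }
  # file shape: n rows, K + 3 columns
  cs <- toy_cohort(K = 4, n_case = 1, n_ctrl = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cs, path)
  lines <- readLines(path)
  expect_equal(length(lines), n_profiles(cs) + 1)
  expect_equal(length(strsplit(lines[1], "\t")[[1]]), 4 + 3)
})

test_that("an empty cohort writes a header-only file", {
  panel <- population_panel(c("a", "b"))
  cs <- cohort_set(panel,
                   data.frame(subject_id = character(), cohort = character(),
                              timepoint_days = integer()),
                   matrix(numeric(), 0, 2, dimnames = list(NULL, panel$ids)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cs, path)
  expect_equal(length(readLines(path)), 1)
})

test_that("reader rejects malformed files with row-indexed diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tcohort\ta\tb", "s1\thiv_pos\t1\t2"), path)
  expect_error(read_cohort(path), "timepoint_days")
  writeLines(c("subject_id\tcohort\ttimepoint_days\ta\tb",
               "s1\thiv_pos\t56\t1\t2",
               "s2\thiv_pos\t56\t-5\t2"), path)
  expect_error(read_cohort(path), "row 2, population 'a'")
})

test_that("proportion files off unit sum are renormalized with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tcohort\ttimepoint_days\ta\tb\tc",
               "s1\tcontrol\tNA\t0.47\t0.3\t0.2",
               "s2\tcontrol\tNA\t0.5\t0.3\t0.2"), path)
  expect_warning(cs <- read_cohort(path, values = "proportions"),
                 "rows 1")
  expect_true(all(abs(rowSums(cs$counts) - 1) < 1e-9))
  # renormalization oracle: divide the stored row by its sum
  expect_equal(unname(cs$counts[1, ]), c(0.47, 0.3, 0.2) / 0.97)
})

test_that("to_absolute implements percent x total and is linear in total", {
  expect_equal(to_absolute(50, 2000), 1000)
  expect_equal(to_absolute(0, 12345), 0)
  expect_equal(to_absolute(12.5, 1600), 200)
  expect_error(to_absolute(120, 100), "\\[0, 100\\]")
  pct <- c(10, 25, 3.5)
  expect_equal(to_absolute(pct, 3000), 3 * to_absolute(pct, 1000))
})

test_that("proportion normalization is idempotent", {
  cs <- toy_cohort(seed = 3)
  p1 <- profile_matrix(cs, "proportions")
  expect_true(all(abs(rowSums(p1) - 1) < 1e-9))
  expect_equal(p1 / rowSums(p1), p1)
})

test_that("per-visit subsetting keeps the once-sampled controls", {
  cs <- toy_cohort(n_case = 2, n_ctrl = 3, seed = 4)
  d56 <- subset_cohort(cs, timepoint = 56, keep_controls = TRUE)
  expect_equal(sum(d56$meta$cohort == "control"), 3)
  expect_equal(sum(d56$meta$cohort == "hiv_pos"), 2)
  cases_only <- subset_cohort(cs, cohort = "hiv_pos", timepoint = 56)
  expect_equal(n_profiles(cases_only), 2)
})
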