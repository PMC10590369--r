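# Log reading, ISO week assignment, and the two preprocessing filters:
# general-use removal first, then the 25-event weekly activity threshold.

test_that("trace logs parse under both date dialects", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "dayfirst.csv")
  writeLines(c("actor_id,date,target_action",
               "id_54,17.6.2019,course_module>viewed"), p1)
  ev1 <- read_trace_log(p1, date_dialect = "dayfirst")
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$actor_id, "id_54")
  expect_equal(ev1$date, as.Date("2019-06-17"))
  expect_equal(ev1$target_action, "course_module>viewed")

  p2 <- file.path(d, "iso.csv")
  writeLines(c("actor_id,date,target_action",
               "id_54,2019-06-17,course_module>viewed"), p2)
  ev2 <- read_trace_log(p2, date_dialect = "iso")
  expect_identical(ev1, ev2, ignore_attr = TRUE)
})

test_that("empty files, malformed rows and missing columns are handled", {
  d <- withr::local_tempdir()
  p <- file.path(d, "empty.csv")
  writeLines("actor_id,date,target_action", p)
  expect_equal(nrow(read_trace_log(p)), 0L)

  p_bad <- file.path(d, "bad.csv")
  writeLines(c("actor_id,date,target_action",
               "id_1,17.6.2019,user>graded",
               "id_2,not-a-date,user>graded",
               "id_3,18.6.2019,nosep"), p_bad)
  ev <- read_trace_log(p_bad, max_error_fraction = 0.9)
  expect_equal(nrow(ev), 1L)
  expect_equal(attr(ev, "report")$rows_malformed, 2L)
  expect_error(read_trace_log(p_bad, max_error_fraction = 0.1), "malformed")

  p_cols <- file.path(d, "cols.csv")
  writeLines(c("actor,when,what", "id_1,17.6.2019,a>b"), p_cols)
  expect_error(read_trace_log(p_cols), "missing required columns")
})

test_that("tokens are whitespace-tolerant around the separator", {
  d <- withr::local_tempdir()
  p <- file.path(d, "ws.csv")
  writeLines(c("actor_id,date,target_action",
               "id_1,17.6.2019,course_module > viewed"), p)
  expect_equal(read_trace_log(p)$target_action, "course_module>viewed")
})

test_that("ISO week assignment follows the ISO-8601 calendar", {
  ev <- make_events(c("a", "a"), c("2019-01-07", "2019-12-30"), c("x>y", "x>y"))
  w <- assign_weeks(ev)
  expect_equal(w$year, c(2019L, 2020L))
  expect_equal(w$week, c(2L, 1L))
})

test_that("generated dates round-trip to the intended week indices", {
  cfg <- separated_config(4, 30, 2, 3, events_mean = 30, seed = 8)
  out <- generate_log(cfg)
  w <- assign_weeks(out$events)
  # Sequential index relative to ISO week 1 of the origin year must land in
  # 1..n_weeks, and each actor-week group's dates must share one index.
  seqw <- traceproc:::sequential_week(w$year, w$week, cfg$origin_year)
  expect_true(all(seqw >= 1 & seqw <= cfg$n_weeks))
  gt_counts <- out$ground_truth$weekly_counts
  tab <- table(w$actor_id[!w$target_action %in% general_use_tokens()],
               seqw[!w$target_action %in% general_use_tokens()])
  for (a in rownames(tab)) {
    got <- as.integer(tab[a, ])
    want <- gt_counts[a, as.integer(colnames(tab))]
    expect_equal(got, unname(want))
  }
})

test_that("general-use removal removes exactly the listed tokens", {
  ev <- make_events(c("a", "a"), "2019-06-17", c("course>viewed", "user>graded"))
  out <- remove_general_use(ev)
  expect_equal(out$target_action, "user>graded")
  expect_equal(attr(out, "removed_counts")[["course>viewed"]], 1L)
  # empty removal list is the identity
  expect_equal(nrow(remove_general_use(ev, character(0))), 2L)
})

test_that("the weekly threshold is strict at 25 and reports drops", {
  ev24 <- make_events(rep("a", 24), "2020-01-06", rep("x>y", 24))
  ev25 <- make_events(rep("b", 25), "2020-01-06", rep("x>y", 25))
  both <- assign_weeks(dplyr::bind_rows(ev24, ev25))
  out <- filter_low_activity_weeks(both)
  expect_setequal(unique(out$actor_id), "b")
  expect_equal(nrow(out), 25L)
  dropped <- attr(out, "dropped_weeks")
  expect_equal(dropped$actor_id, "a")
  expect_equal(dropped$n_events, 24L)
  # min_events = 1 is the identity on inputs with no empty groups
  expect_equal(nrow(filter_low_activity_weeks(both, min_events = 1)), 49L)
})

test_that("both filters are idempotent and never add events", {
  cfg <- separated_config(8, 6, 2, 3, events_mean = 40, seed = 13)
  ev <- assign_weeks(generate_log(cfg)$events)
  r1 <- remove_general_use(ev)
  expect_lte(nrow(r1), nrow(ev))
  expect_equal(nrow(remove_general_use(r1)), nrow(r1))
  f1 <- filter_low_activity_weeks(r1)
  expect_lte(nrow(f1), nrow(r1))
  expect_equal(nrow(filter_low_activity_weeks(f1)), nrow(f1))
})

test_that("general-use removal precedes the activity threshold", {
  # 30 events of which 10 are general use: only 20 task events remain, so
  # the whole actor-week must be dropped.
  ev <- make_events(rep("a", 30), "2019-03-04",
                    c(rep("course>viewed", 10), rep("user>graded", 20)))
  out <- preprocess_events(ev)
  expect_equal(nrow(out$events), 0L)
  expect_equal(out$report$general_use_removed[["course>viewed"]], 10L)
  expect_equal(out$report$low_activity_weeks_dropped, 1L)
})

test_that("removal on generator output is exact against injected counts", {
  cfg <- separated_config(10, 6, 2, 3, events_mean = 60, seed = 21,
                          general_use_rate = 0.3)
  out <- generate_log(cfg)
  filtered <- remove_general_use(assign_weeks(out$events))
  expect_equal(nrow(out$events) - nrow(filtered),
               sum(out$ground_truth$weekly_general))
})
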