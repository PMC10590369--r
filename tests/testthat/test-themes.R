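# Topic->theme aggregation (exact mass conservation, linearity) and weekly
# theme-process assembly over a window.

test_that("theme aggregation sums topic mass by theme", {
  map <- theme_map(list(A = c(1, 2), B = 3), n_topics = 3)
  out <- topics_to_themes(c(0.3, 0.2, 0.5), map)
  expect_equal(unname(out), c(0.5, 0.5, 0))
  expect_equal(names(out), c("A", "B", "Others"))
  # empty assignment puts everything in Others
  id0 <- theme_map(list(), n_topics = 4)
  expect_equal(unname(topics_to_themes(rep(0.25, 4), id0)), 1)
  # one topic per theme maps uniform to uniform
  map6 <- theme_map(setNames(as.list(1:6), paste0("T", 1:6)), 6)
  expect_equal(unname(topics_to_themes(rep(1 / 6, 6), map6)),
               c(rep(1 / 6, 6), 0))
})

test_that("theme maps validate their topic indices", {
  expect_error(theme_map(list(A = 5), n_topics = 3), "out of range")
  expect_error(theme_map(list(A = 1, B = 1), n_topics = 3), "more than one")
  d <- withr::local_tempdir()
  p <- file.path(d, "themes.yaml")
  writeLines(c("themes:", "  Evaluation: [1, 3]", "  Courses: [2]"), p)
  map <- read_theme_map(p, 4)
  expect_equal(map$topic_theme, c("Evaluation", "Courses", "Evaluation",
                                  "Others"))
})

test_that("aggregation conserves mass and commutes with averaging", {
  withr::with_seed(5, {
    K <- 7
    map <- theme_map(list(A = c(1, 4), B = c(2, 6), C = 3), K)
    topics <- t(replicate(20, rand_distribution(K)))
    themes <- topics_to_themes(topics, map)
    expect_equal(rowSums(themes), rowSums(topics), tolerance = 1e-15)
    expect_equal(topics_to_themes(colMeans(topics), map),
                 colMeans(themes), tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("processes mark active weeks and honor the window", {
  doc_topic <- matrix(c(0.7, 0.3,
                        0.2, 0.8,
                        0.5, 0.5), 3, 2, byrow = TRUE)
  meta <- tibble::tibble(actor_id = c("a", "a", "a"),
                         year = 2019L, week = c(3L, 5L, 30L),
                         total = c(40L, 60L, 50L))
  pr <- build_processes(doc_topic, meta, weeks = 1:22)
  p <- pr$processes[["a"]]
  expect_equal(unname(which(p$C > 0)), c(3L, 5L))
  expect_equal(unname(p$C[3]), 40L)
  expect_true(all(is.na(p$P[1, ])))
  expect_equal(sum(p$P[3, ]), 1)
  # the week-30 document is outside the 22-week window
  expect_false(any(p$C > 0 & seq_along(p$C) > 22))
  expect_error(build_processes(doc_topic, meta, weeks = integer(0)), "empty")
})

test_that("weekly means match direct arithmetic and handle one actor", {
  doc_topic <- matrix(c(0.9, 0.1,
                        0.5, 0.5,
                        0.3, 0.7), 3, 2, byrow = TRUE)
  meta <- tibble::tibble(actor_id = c("a", "b", "a"),
                         year = 2019L, week = c(1L, 1L, 2L),
                         total = c(30L, 90L, 40L))
  pr <- build_processes(doc_topic, meta, weeks = 1:2)
  m <- mean_weekly_theme_distribution(pr)
  w1 <- m[m$week == 1 & m$theme == "topic_1", ]
  expect_equal(w1$mean_probability, (0.9 + 0.5) / 2)
  expect_equal(w1$n_active, 2L)
  # weighted alternative
  mw <- mean_weekly_theme_distribution(pr, weighted = TRUE)
  expect_equal(mw$mean_probability[mw$week == 1 & mw$theme == "topic_1"],
               (0.9 * 30 + 0.5 * 90) / 120)
  # a single actor's mean is its own process
  solo <- pr
  solo$processes <- pr$processes["a"]
  ms <- mean_weekly_theme_distribution(solo)
  expect_equal(ms$mean_probability[ms$week == 2 & ms$theme == "topic_1"], 0.3)
})

test_that("cluster-mean processes track planted trajectories", {
  # Well-separated planted clusters, >= 300 tokens per document on average:
  # after matching learned topics to true topics, the per-cluster weekly
  # mean theme distribution stays within total variation 0.1 of the planted
  # trajectory.
  cfg <- separated_config(9, 8, 3, 3, events_mean = 400, seed = 77,
                          low_activity_week_prob = 0,
                          dominant_start = 0.75, dominant_end = 0.95)
  out <- generate_log(cfg)
  corp <- build_corpus(preprocess_events(out$events)$events)
  fit <- fit_lda(corp, 3, seed = 4)
  # match learned topics to true topics by minimal TV
  tw_true <- out$ground_truth$topic_word_true[, colnames(fit$topic_word)]
  match_idx <- apply(fit$topic_word, 1, function(row) {
    which.min(apply(tw_true, 1, function(tr) 0.5 * sum(abs(row - tr))))
  })
  expect_setequal(match_idx, 1:3) # one-to-one under good separation
  themes_true <- unname(out$ground_truth$theme_map_true)
  map <- theme_map(split(seq_len(3), themes_true[match_idx]), 3)
  pr <- build_processes(fit$doc_topic, corp$meta, map = map, weeks = 1:8)
  clus <- out$ground_truth$cluster_of_actor
  for (cl in 1:3) {
    sub <- pr
    sub$processes <- pr$processes[names(clus)[clus == cl][
      names(clus)[clus == cl] %in% names(pr$processes)]]
    m <- mean_weekly_theme_distribution(sub)
    traj <- out$ground_truth$theme_trajectory_true[[cl]]
    for (t in 1:8) {
      got <- m$mean_probability[m$week == t]
      names(got) <- m$theme[m$week == t]
      want <- traj[t, ]
      tv <- 0.5 * sum(abs(got[names(want)] - want))
      expect_lt(tv, 0.1)
    }
  }
})

test_that("processes export to long CSV with inactive weeks as zero", {
  doc_topic <- matrix(c(0.6, 0.4), 1, 2)
  meta <- tibble::tibble(actor_id = "a", year = 2019L, week = 2L, total = 30L)
  pr <- build_processes(doc_topic, meta, weeks = 1:3)
  d <- withr::local_tempdir()
  p <- write_processes(pr, file.path(d, "p.csv"))
  back <- read.csv(p)
  expect_equal(nrow(back), 3 * 3) # 3 weeks x (2 topics + Others)
  expect_equal(unique(back$events[back$week == 1]), 0L)
  expect_equal(back$probability[back$week == 2 & back$theme == "topic_1"], 0.6)
})
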