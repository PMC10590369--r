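# Cluster summaries, peak-week detection and figure/CSV emission.

# Build a process set with prescribed share series for theme "A" (the rest
# of the mass goes to "B"); one actor per series.
share_processes <- function(series_list, counts = NULL) {
  T <- length(series_list[[1]])
  processes <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    C <- if (is.null(counts)) rep(50L, T) else counts[[i]]
    P <- cbind(A = s, B = 1 - s)
    P[C == 0, ] <- NA_real_
    list(P = P, C = C)
  })
  names(processes) <- sprintf("a%02d", seq_along(series_list))
  structure(list(theme_names = c("A", "B"), weeks = seq_len(T), year = NULL,
                 processes = processes),
            class = "theme_process_set")
}

test_that("cluster summaries reproduce single-actor and identical-actor cases", {
  pr <- share_processes(list(c(0.2, 0.5, 0.2), c(0.2, 0.5, 0.2)))
  s1 <- summarize_clusters(pr, c(a01 = 1L))
  expect_equal(s1$mean_probability[s1$theme == "A"], c(0.2, 0.5, 0.2))
  s2 <- summarize_clusters(pr, c(a01 = 1L, a02 = 1L))
  expect_equal(s2$mean_probability[s2$theme == "A"], c(0.2, 0.5, 0.2))
  expect_equal(unique(s2$n_active), 2L)
  expect_error(summarize_clusters(pr, c(zz = 1L)), "without a process")
})

test_that("cluster-week means match direct arithmetic", {
  pr <- share_processes(list(c(0.1, 0.9), c(0.5, 0.3)))
  s <- summarize_clusters(pr, c(a01 = 1L, a02 = 1L))
  expect_equal(s$mean_probability[s$theme == "A"], c(0.3, 0.6))
  expect_equal(s$mean_probability[s$theme == "B"], c(0.7, 0.4))
  # inactive cluster-weeks are flagged, not averaged
  pr2 <- share_processes(list(c(0.1, 0.9)), counts = list(c(0L, 50L)))
  s2 <- summarize_clusters(pr2, c(a01 = 1L))
  expect_true(is.na(s2$mean_probability[s2$week == 1 & s2$theme == "A"]))
  expect_equal(s2$n_active[s2$week == 1][1], 0L)
})

test_that("peaks are strict interior maxima above the prominence floor", {
  mono <- share_processes(list(seq(0.1, 0.7, length.out = 6)))
  s_mono <- summarize_clusters(mono, c(a01 = 1L))
  expect_equal(nrow(detect_peaks(s_mono, "A", 0)$peaks), 0L)

  bump <- share_processes(list(c(0.2, 0.5, 0.2)))
  s_bump <- summarize_clusters(bump, c(a01 = 1L))
  pk <- detect_peaks(s_bump, "A", 0.05)
  expect_equal(pk$peaks$week, 2L)
  expect_equal(pk$peaks$prominence, 0.3)

  # two bumps with prominences 0.15 and 0.04: threshold 0.05 keeps only
  # the first
  two <- share_processes(list(c(0.10, 0.25, 0.10, 0.10, 0.14, 0.10, 0.10)))
  s_two <- summarize_clusters(two, c(a01 = 1L))
  pk2 <- detect_peaks(s_two, "A", 0.05)
  expect_equal(pk2$peaks$week, 2L)
  pk_all <- detect_peaks(s_two, "A", 0)
  expect_equal(pk_all$peaks$week, c(2L, 5L))
  expect_equal(pk_all$peaks$prominence, c(0.15, 0.04), tolerance = 1e-12)

  expect_error(detect_peaks(s_two, character(0)), "empty")
  expect_error(detect_peaks(s_two, "Nope"), "unknown theme")
})

test_that("peak locations are invariant to a constant share shift", {
  base <- c(0.10, 0.25, 0.10, 0.20, 0.10)
  pr1 <- share_processes(list(base))
  pr2 <- share_processes(list(base + 0.3))
  p1 <- detect_peaks(summarize_clusters(pr1, c(a01 = 1L)), "A", 0.01)
  p2 <- detect_peaks(summarize_clusters(pr2, c(a01 = 1L)), "A", 0.01)
  expect_equal(p1$peaks$week, p2$peaks$week)
  expect_equal(p1$peaks$prominence, p2$peaks$prominence, tolerance = 1e-12)
})

test_that("theme-group shares sum over the group's themes", {
  T <- 4
  P <- cbind(A = c(0.1, 0.3, 0.1, 0.1), B = c(0.1, 0.2, 0.1, 0.1))
  P <- cbind(P, C = 1 - rowSums(P))
  pr <- structure(list(theme_names = c("A", "B", "C"), weeks = 1:T,
                       year = NULL,
                       processes = list(a01 = list(P = P, C = rep(10L, T)))),
                  class = "theme_process_set")
  s <- summarize_clusters(pr, c(a01 = 1L))
  pk <- detect_peaks(s, c("A", "B"), 0)
  expect_equal(pk$peaks$week, 2L)
  expect_equal(pk$peaks$share, 0.5)
})

test_that("figures and their backing CSV are emitted and round-trip", {
  pr <- share_processes(list(c(0.2, 0.5, 0.2), c(0.6, 0.4, 0.5)))
  s <- summarize_clusters(pr, c(a01 = 1L, a02 = 2L))
  d <- withr::local_tempdir()
  files <- render_figures(s, d)
  expect_true(file.exists(file.path(d, "summary.csv")))
  expect_true(file.exists(file.path(d, "cluster_01.png")))
  expect_true(file.exists(file.path(d, "cluster_02.png")))
  expect_true(file.exists(file.path(d, "overall.png")))
  back <- read.csv(file.path(d, "summary.csv"))
  expect_equal(back$mean_probability, s$mean_probability, tolerance = 1e-12)
  expect_equal(back$n_active, s$n_active)
})

test_that("a cluster with no active weeks renders a no-data chart", {
  pr <- share_processes(list(c(0.2, 0.5, 0.2), c(0.3, 0.3, 0.3)),
                        counts = list(rep(50L, 3), rep(0L, 3)))
  s <- summarize_clusters(pr, c(a01 = 1L, a02 = 2L))
  d <- withr::local_tempdir()
  expect_no_error(render_figures(s, d))
  expect_true(file.exists(file.path(d, "cluster_02.png")))
})

test_that("peak reports serialize to JSON", {
  pr <- share_processes(list(c(0.2, 0.5, 0.2)))
  s <- summarize_clusters(pr, c(a01 = 1L))
  pk <- detect_peaks(s, "A", 0.05)
  d <- withr::local_tempdir()
  p <- write_peak_report(pk, file.path(d, "peaks.json"))
  js <- jsonlite::read_json(p)
  expect_equal(js$theme_group, "A")
  expect_equal(js$peaks[[1]]$week, 2L)
})
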