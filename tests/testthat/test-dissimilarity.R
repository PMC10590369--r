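# Jensen-Shannon distance, pairwise activity weights, and the weighted
# dissimilarity matrix, checked against direct-formula and brute-force
# oracles.

test_that("JS distance attains its bounds and matches the direct formula", {
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(js_distance(p, q), js_oracle(p, q), tolerance = 1e-12)
  # natural-log base rescales below 1
  expect_equal(js_distance(c(1, 0), c(0, 1), base = exp(1)), sqrt(log(2)))
  expect_error(js_distance(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  expect_error(js_distance(c(1, -0.1, 0.1), c(0.5, 0.25, 0.25)), "negative")
  expect_error(js_distance(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("JS distance behaves as a metric on random triples", {
  withr::with_seed(42, {
    for (i in 1:200) {
      H <- sample(2:8, 1)
      p <- rand_distribution(H); q <- rand_distribution(H)
      r <- rand_distribution(H)
      dpq <- js_distance(p, q)
      expect_gte(dpq, 0)
      expect_lte(dpq, 1)
      expect_equal(dpq, js_distance(q, p), tolerance = 1e-12)
      expect_lte(js_distance(p, r), dpq + js_distance(q, r) + 1e-12)
    }
  })
})

test_that("pair weights normalize over co-active weeks only", {
  expect_equal(pair_weights(c(10, 0, 5), c(2, 7, 0)), c(1, 0, 0))
  expect_equal(pair_weights(c(1, 1), c(1, 1)), c(0.5, 0.5))
  expect_equal(pair_weights(c(3, 4), c(5, 2)), c(15 / 23, 8 / 23))
  # no co-active week: all-zero weights signal the undefined pair
  expect_equal(pair_weights(c(1, 0), c(0, 1)), c(0, 0))
  expect_error(pair_weights(c(1, -1), c(1, 1)), "non-negative")
})

test_that("the dissimilarity matrix matches the brute-force oracle", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(3:10, 1)
      T <- sample(4:30, 1)
      H <- sample(2:6, 1)
      pr <- random_processes(n, T, H)
      dm <- suppressWarnings(pairwise_dissimilarity(pr))
      expect_equal(dm$D, dissim_brute(pr), tolerance = 1e-12)
      expect_true(isSymmetric(dm$D))
      expect_equal(unname(diag(dm$D)), rep(0, n))
      expect_true(all(dm$D >= 0 & dm$D <= 1 + 1e-12))
    }
  })
})

test_that("single co-active week pairs reduce to that week's JS distance", {
  pr <- random_processes(2, 4, 3, p_active = 1)
  pr$processes[[1]]$C <- c(0L, 9L, 0L, 0L)
  pr$processes[[2]]$C <- c(5L, 7L, 0L, 3L)
  dm <- pairwise_dissimilarity(pr)
  expect_equal(dm$D[1, 2],
               js_distance(pr$processes[[1]]$P[2, ], pr$processes[[2]]$P[2, ]))
  # identical theme vectors on all co-active weeks give zero
  pr$processes[[2]]$P[2, ] <- pr$processes[[1]]$P[2, ]
  expect_equal(pairwise_dissimilarity(pr)$D[1, 2], 0)
})

test_that("inactive weeks never influence the dissimilarity", {
  withr::with_seed(11, {
    pr <- random_processes(5, 8, 4, p_active = 0.6)
    d1 <- suppressWarnings(pairwise_dissimilarity(pr))$D
    pr2 <- pr
    for (a in seq_along(pr2$processes)) {
      off <- which(pr2$processes[[a]]$C == 0)
      for (t in off) pr2$processes[[a]]$P[t, ] <- rand_distribution(4)
    }
    d2 <- suppressWarnings(pairwise_dissimilarity(pr2))$D
    expect_identical(d1, d2)
  })
})

test_that("weights of every co-active pair sum to one", {
  withr::with_seed(13, {
    pr <- random_processes(6, 10, 3, p_active = 0.7)
    Cm <- vapply(pr$processes, `[[`, numeric(10), "C")
    for (i in 1:5) for (j in (i + 1):6) {
      w <- pair_weights(Cm[, i], Cm[, j])
      if (any(Cm[, i] * Cm[, j] > 0)) {
        expect_equal(sum(w), 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("pairs with no co-active week get the configured fallback", {
  pr <- random_processes(3, 2, 2, p_active = 1)
  pr$processes[[1]]$C <- c(4L, 0L)
  pr$processes[[2]]$C <- c(0L, 6L)
  pr$processes[[3]]$C <- c(2L, 2L)
  expect_warning(dm <- pairwise_dissimilarity(pr), "no co-active")
  expect_equal(dm$D[1, 2], 1)
  expect_equal(nrow(dm$undefined_pairs), 1L)
  expect_warning(dm2 <- pairwise_dissimilarity(pr, missing_pair = "drop"))
  expect_true(is.na(dm2$D[1, 2]))
})

test_that("the weighted average dissimilarity can violate the triangle inequality", {
  # Actor 2 is co-active with actor 1 mostly where they agree and with
  # actor 3 mostly where they agree, while actors 1 and 3 meet only where
  # they fully disagree: d13 > d12 + d23. This documents that the weighted
  # average is a dissimilarity, not a metric.
  a <- c(1, 0); b <- c(0, 1)
  pr <- structure(list(
    theme_names = c("X", "Y"), weeks = 1:2, year = NULL,
    processes = list(
      p1 = list(P = rbind(a, a), C = c(100L, 1L)),
      p2 = list(P = rbind(a, b), C = c(100L, 100L)),
      p3 = list(P = rbind(b, b), C = c(1L, 100L))
    )
  ), class = "theme_process_set")
  D <- pairwise_dissimilarity(pr)$D
  expect_gt(D["p1", "p3"], D["p1", "p2"] + D["p2", "p3"])
})

test_that("matrices write to square CSV and Phylip text", {
  pr <- random_processes(4, 5, 3, p_active = 1)
  dm <- pairwise_dissimilarity(pr)
  d <- withr::local_tempdir()
  p <- write_dissimilarity(dm, file.path(d, "D.csv"), phylip = TRUE)
  back <- read.csv(p, check.names = FALSE)
  expect_equal(back$actor_id, rownames(dm$D))
  expect_equal(as.matrix(back[, -1]), dm$D, ignore_attr = TRUE,
               tolerance = 1e-12)
  phy <- readLines(file.path(d, "D.phy"))
  expect_equal(phy[1], "4")
  expect_length(phy, 5)
})
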