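# Independent oracles and fixture builders used across the suite. Oracles
# are written as direct, naive evaluations of the defining formulas and
# share no code with the implementation paths they check.

# All permutations of 1..n as rows.
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- perms_all(n - 1L)
    cbind(rep(i, nrow(p)), matrix(seq_len(n)[-i][p], nrow(p)))
  }))
}

# Mean total-variation distance between estimated and true topic-word rows
# under the best bipartite (permutation) matching.
best_matched_tv <- function(est, true) {
  true <- true[, colnames(est), drop = FALSE]
  K <- nrow(true)
  P <- perms_all(K)
  min(apply(P, 1, function(p) {
    mean(vapply(seq_len(K), function(k) 0.5 * sum(abs(est[p[k], ] - true[k, ])),
                numeric(1)))
  }))
}

# Direct-formula Jensen-Shannon distance oracle.
js_oracle <- function(p, q, base = 2) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / b[i], base)
    s
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}

# Brute-force nested-loop evaluation of the activity-weighted dissimilarity
# matrix: for each pair, loop over weeks, accumulate C_i C_j and
# C_i C_j * JS week by week.
dissim_brute <- function(processes, base = 2, missing_value = 1) {
  actors <- names(processes$processes)
  n <- length(actors)
  D <- matrix(0, n, n, dimnames = list(actors, actors))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    pi <- processes$processes[[i]]
    pj <- processes$processes[[j]]
    denom <- 0
    num <- 0
    for (t in seq_along(processes$weeks)) {
      cc <- pi$C[[t]] * pj$C[[t]]
      if (cc > 0) {
        denom <- denom + cc
        num <- num + cc * js_oracle(pi$P[t, ], pj$P[t, ], base)
      }
    }
    D[i, j] <- if (denom == 0) missing_value else num / denom
  }
  D
}

# Naive complete-linkage agglomerator: at every step recompute every
# inter-cluster distance as the max over the original matrix, take the
# global minimum, ties broken by the lexicographically smallest pair of
# cluster creation indices (leaves 1..n in input order, merges n+1, ...).
naive_complete_linkage <- function(M) {
  n <- nrow(M)
  clusters <- lapply(seq_len(n), identity) # leaf sets, list position order
  heights <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    best_val <- Inf
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      v <- max(M[clusters[[a]], clusters[[b]]])
      if (v < best_val) {
        best_val <- v
        best <- c(a, b)
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    heights[step] <- best_val
    merges[[step]] <- sort(merged)
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Member sets implied by an hclust merge matrix, one per merge step.
hclust_merge_sets <- function(h) {
  n <- length(h$labels)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    grab <- function(e) if (e < 0) -e else sets[[e]]
    sets[[s]] <- sort(c(grab(h$merge[s, 1]), grab(h$merge[s, 2])))
  }
  sets
}

# A random distribution on the simplex.
rand_distribution <- function(H) {
  x <- stats::rgamma(H, shape = 1)
  x / sum(x)
}

# A random theme_process_set: n actors, T weeks, H themes; each actor-week
# is active with probability p_active, with counts 1..max_count.
random_processes <- function(n, T, H, p_active = 0.7, max_count = 200) {
  actors <- sprintf("a%02d", seq_len(n))
  processes <- lapply(actors, function(a) {
    C <- ifelse(stats::runif(T) < p_active, sample.int(max_count, T, replace = TRUE), 0L)
    P <- matrix(NA_real_, T, H)
    for (t in which(C > 0)) P[t, ] <- rand_distribution(H)
    colnames(P) <- paste0("theme_", seq_len(H))
    list(P = P, C = C)
  })
  names(processes) <- actors
  structure(list(theme_names = paste0("theme_", seq_len(H)),
                 weeks = seq_len(T), year = NULL, processes = processes),
            class = "theme_process_set")
}

# A random symmetric dissimilarity matrix with zero diagonal.
random_dissim <- function(n) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- stats::runif(n * (n - 1) / 2)
  M <- M + t(M)
  dimnames(M) <- list(sprintf("a%02d", 1:n), sprintf("a%02d", 1:n))
  M
}

# Small well-separated synthetic config used by several tests: `themes`
# labels double as one-topic themes so planted structure is easy to reason
# about.
separated_config <- function(n_actors, n_weeks, n_clusters, n_topics,
                             events_mean = 150, seed = 1,
                             general_use_rate = 0.3,
                             low_activity_week_prob = 0.05,
                             dominant_start = 0.7, dominant_end = 0.95,
                             vocabulary = default_vocabulary()) {
  themes <- LETTERS[seq_len(n_topics)]
  synthetic_config(
    n_actors = n_actors, n_weeks = n_weeks, n_clusters = n_clusters,
    vocabulary = vocabulary, n_topics_true = n_topics,
    theme_map_true = setNames(themes, seq_len(n_topics)),
    trajectory_spec = default_trajectories(n_clusters, n_weeks, themes,
                                           dominant_start, dominant_end),
    events_per_week_mean = events_mean, events_per_week_dispersion = 8,
    general_use_rate = general_use_rate,
    low_activity_week_prob = low_activity_week_prob, seed = seed
  )
}

# Corpus of ~200 documents of ~200 tokens from 4 disjoint-support topics
# over a 40-token task vocabulary (10 actors x 20 weeks, one dominant theme
# per planted cluster).
disjoint_topic_corpus <- function(seed) {
  vocab <- c(sprintf("t%02d>a", 1:40), general_use_tokens())
  cfg <- separated_config(
    n_actors = 10, n_weeks = 20, n_clusters = 4, n_topics = 4,
    events_mean = 200, seed = seed, general_use_rate = 0,
    low_activity_week_prob = 0, dominant_start = 0.9, dominant_end = 0.98,
    vocabulary = vocab
  )
  sim <- generate_log(cfg)
  pre <- preprocess_events(sim$events)
  list(corpus = build_corpus(pre$events), ground_truth = sim$ground_truth,
       config = cfg)
}

# Events tibble builder for ingest tests.
make_events <- function(actor_id, date, target_action) {
  tibble::tibble(actor_id = actor_id, date = as.Date(date),
                 target_action = target_action)
}
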