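# Synthetic event-log generator with planted cluster structure.
#
# Emulates the statistical shape of educational-platform trace logs: many
# actors, overdispersed weekly event counts, event tokens drawn from
# topic-word distributions whose mixture follows cluster-specific weekly
# theme trajectories, plus injected general-use events and occasional
# low-activity weeks that exercise the preprocessing filters.

#' The six general-use target-action tokens removed during preprocessing
#'
#' These tokens reflect general use of the platform (logging in, passively
#' viewing) rather than a specific work task, and are stripped before any
#' modeling.
#'
#' @return character vector of six `target>action` tokens.
#' @export
general_use_tokens <- function() {
  c(
    "user>loggedin", "user>loggedout",
    "notification>sent", "notification>viewed",
    "course>viewed", "course_module>viewed"
  )
}

#' Default synthetic vocabulary of target-action tokens
#'
#' Thirty-four task tokens in the style of a Moodle activity log plus the six
#' general-use tokens slated for removal.
#'
#' @return character vector of `target>action` tokens.
#' @export
default_vocabulary <- function() {
  task <- c(
    "assignment>created", "assignment>updated", "attempt>reviewed",
    "attempt>viewed", "calendar_event>created", "calendar_event>updated",
    "chapter>created", "chapter>updated", "chapter>viewed",
    "course>updated", "course_bin_item>created", "course_module>created",
    "course_module>deleted", "course_module>updated",
    "course_module_completion>updated", "course_section>created",
    "course_section>updated", "dashboard>viewed", "discussion>created",
    "discussion>viewed", "edit_page>viewed", "grade_deleted>deleted",
    "grade_item>updated", "grade_report>viewed", "grading_form>viewed",
    "grading_table>viewed", "group_member>added", "message>sent",
    "question>manually_graded", "report>viewed", "submission>graded",
    "submission_status>viewed", "user>graded", "user_list>viewed"
  )
  c(task, general_use_tokens())
}

#' Default theme names
#'
#' Five named work themes plus the catch-all `"Others"`.
#' @return character vector of six theme names.
#' @export
default_theme_names <- function() {
  c("Evaluation", "Courses", "Progress tracking", "Situation tracking",
    "Final grading", "Others")
}

# Internal: deterministic topic-word distributions over the task (non
# general-use) part of the vocabulary. Topic k is concentrated on its own
# block of tokens with geometrically decaying within-block weights, so topics
# are near-disjoint when n_topics divides the vocabulary evenly.
default_topic_word <- function(vocabulary, n_topics,
                               removal_list = general_use_tokens()) {
  task <- setdiff(vocabulary, removal_list)
  V <- length(task)
  if (V < n_topics) fail_field("vocabulary", "fewer task tokens than topics")
  block <- split(seq_len(V), rep(seq_len(n_topics), length.out = V))
  tw <- matrix(0, n_topics, V, dimnames = list(NULL, task))
  for (k in seq_len(n_topics)) {
    idx <- block[[k]]
    w <- 0.5^(seq_along(idx) - 1L)
    tw[k, idx] <- w / sum(w)
  }
  tw
}

# Internal: round-robin assignment of topics to themes; the last theme in
# `theme_names` (conventionally "Others") absorbs the remainder evenly.
default_theme_assignment <- function(n_topics,
                                     theme_names = default_theme_names()) {
  setNames(theme_names[((seq_len(n_topics) - 1L) %% length(theme_names)) + 1L],
           seq_len(n_topics))
}

#' Piecewise-linear cluster theme trajectories
#'
#' Builds per-cluster weekly theme-weight curves: cluster `c` has a dominant
#' theme (cycling through the non-"Others" themes) whose weight ramps
#' linearly from `dominant_start` to `dominant_end` over the weeks; the
#' remaining mass is split evenly over the other themes. Each weekly weight
#' vector is normalized to sum to one.
#'
#' @param n_clusters number of clusters.
#' @param n_weeks number of weeks.
#' @param theme_names character vector of theme names.
#' @param dominant_start,dominant_end weight of the dominant theme in week 1
#'   and week `n_weeks`.
#' @return list of `n_clusters` matrices (`n_weeks` x `length(theme_names)`),
#'   rows summing to 1.
#' @export
default_trajectories <- function(n_clusters, n_weeks,
                                 theme_names = default_theme_names(),
                                 dominant_start = 0.55, dominant_end = 0.85) {
  H <- length(theme_names)
  stopifnot(H >= 2, n_clusters >= 1, n_weeks >= 1)
  lapply(seq_len(n_clusters), function(cl) {
    dom <- ((cl - 1L) %% H) + 1L
    ramp <- if (n_weeks == 1L) dominant_start else
      seq(dominant_start, dominant_end, length.out = n_weeks)
    m <- matrix((1 - ramp) / (H - 1L), n_weeks, H,
                dimnames = list(NULL, theme_names))
    m[, dom] <- ramp
    m / rowSums(m)
  })
}

#' Configuration for the synthetic event-log generator
#'
#' Defaults mirror the scale of one real deployment: 423 actors observed for
#' 90 weeks at roughly 288 events per actor-week, with 6 planted clusters, 17
#' true topics and 6 themes. Tests and examples use much smaller configs.
#'
#' @param n_actors number of actors (0 allowed: vacuous generation).
#' @param n_weeks number of weeks, starting at ISO week 1 of `origin_year`.
#' @param n_clusters number of planted clusters (must be <= `n_actors` when
#'   `n_actors` > 0).
#' @param vocabulary tokens (`target>action`); must contain all six
#'   general-use tokens so the removal filter can be exercised.
#' @param n_topics_true number of true topics.
#' @param theme_map_true named character vector mapping topic index (names
#'   `"1"`..`"K"`) to theme label; default round-robin over
#'   [default_theme_names()].
#' @param trajectory_spec list of per-cluster weekly theme-weight matrices
#'   (`n_weeks` x themes, rows summing to 1); default
#'   [default_trajectories()].
#' @param topic_word_true optional matrix (`n_topics_true` x task tokens) of
#'   topic-word distributions; default [default_topic_word()] block structure.
#' @param events_per_week_mean,events_per_week_dispersion mean and dispersion
#'   (negative-binomial `size`) of the task-event count per actor-week.
#' @param general_use_rate expected fraction of the emitted log made up of
#'   injected general-use events, in `[0, 1)`.
#' @param low_activity_week_prob probability that an actor-week's task count
#'   is resampled uniformly below the 25-event filtering threshold.
#' @param low_activity_max largest task count a forced low-activity week may
#'   have (default 24, one below the canonical filter threshold).
#' @param origin_year ISO week-based year of week 1.
#' @param seed integer seed; generation is a pure function of the config.
#' @return a `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_actors = 423,
                             n_weeks = 90,
                             n_clusters = 6,
                             vocabulary = default_vocabulary(),
                             n_topics_true = 17,
                             theme_map_true = NULL,
                             trajectory_spec = NULL,
                             topic_word_true = NULL,
                             events_per_week_mean = 288,
                             events_per_week_dispersion = 2,
                             general_use_rate = 0.3,
                             low_activity_week_prob = 0.05,
                             low_activity_max = 24,
                             origin_year = 2019,
                             seed = 1) {
  if (is.null(theme_map_true)) {
    theme_map_true <- default_theme_assignment(n_topics_true)
  }
  theme_names <- unique(unname(theme_map_true))
  if (is.null(trajectory_spec)) {
    trajectory_spec <- default_trajectories(n_clusters, n_weeks, theme_names)
  }
  if (is.null(topic_word_true)) {
    topic_word_true <- default_topic_word(vocabulary, n_topics_true)
  }
  cfg <- structure(list(
    n_actors = n_actors, n_weeks = n_weeks, n_clusters = n_clusters,
    vocabulary = vocabulary, n_topics_true = n_topics_true,
    theme_map_true = theme_map_true, trajectory_spec = trajectory_spec,
    topic_word_true = topic_word_true,
    events_per_week_mean = events_per_week_mean,
    events_per_week_dispersion = events_per_week_dispersion,
    general_use_rate = general_use_rate,
    low_activity_week_prob = low_activity_week_prob,
    low_activity_max = low_activity_max,
    origin_year = origin_year, seed = seed
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Validate a synthetic generator configuration
#'
#' @param config a `synthetic_config`.
#' @return the config, invisibly; errors name the offending field.
#' @export
validate_synthetic_config <- function(config) {
  c_ <- config
  if (!is_count(c_$n_actors)) fail_field("n_actors", "must be a non-negative count")
  if (!is_count(c_$n_weeks, 1L)) fail_field("n_weeks", "must be a positive count")
  if (!is_count(c_$n_clusters, 1L)) fail_field("n_clusters", "must be a positive count")
  if (c_$n_actors > 0 && c_$n_clusters > c_$n_actors) {
    fail_field("n_clusters", "must not exceed n_actors")
  }
  if (!is.character(c_$vocabulary) || anyDuplicated(c_$vocabulary)) {
    fail_field("vocabulary", "must be a character vector of distinct tokens")
  }
  missing_gen <- setdiff(general_use_tokens(), c_$vocabulary)
  if (length(missing_gen)) {
    fail_field("vocabulary", paste("must include general-use tokens:",
                                   paste(missing_gen, collapse = ", ")))
  }
  if (!is_count(c_$n_topics_true, 1L)) fail_field("n_topics_true", "must be a positive count")
  if (length(c_$theme_map_true) != c_$n_topics_true) {
    fail_field("theme_map_true", "must assign every true topic a theme")
  }
  theme_names <- unique(unname(c_$theme_map_true))
  if (length(c_$trajectory_spec) != c_$n_clusters) {
    fail_field("trajectory_spec", "must have one trajectory matrix per cluster")
  }
  for (cl in seq_along(c_$trajectory_spec)) {
    m <- c_$trajectory_spec[[cl]]
    if (!is.matrix(m) || nrow(m) != c_$n_weeks || ncol(m) != length(theme_names)) {
      fail_field("trajectory_spec",
                 sprintf("cluster %d matrix must be n_weeks x n_themes", cl))
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
      fail_field("trajectory_spec",
                 sprintf("cluster %d weekly weights must be >= 0 and sum to 1", cl))
    }
  }
  tw <- c_$topic_word_true
  if (!is.matrix(tw) || nrow(tw) != c_$n_topics_true) {
    fail_field("topic_word_true", "must be an n_topics x n_tokens matrix")
  }
  if (any(tw < 0) || any(abs(rowSums(tw) - 1) > 1e-9)) {
    fail_field("topic_word_true", "rows must be distributions summing to 1")
  }
  if (!all(colnames(tw) %in% c_$vocabulary)) {
    fail_field("topic_word_true", "columns must be vocabulary tokens")
  }
  if (any(colnames(tw) %in% general_use_tokens() & colSums(tw) > 0)) {
    fail_field("topic_word_true", "topics must put no mass on general-use tokens")
  }
  if (!is.numeric(c_$events_per_week_mean) || c_$events_per_week_mean <= 0) {
    fail_field("events_per_week_mean", "must be a positive real")
  }
  if (!is.numeric(c_$events_per_week_dispersion) || c_$events_per_week_dispersion <= 0) {
    fail_field("events_per_week_dispersion", "must be a positive real")
  }
  if (!is_prob(c_$general_use_rate) || c_$general_use_rate >= 1) {
    fail_field("general_use_rate", "must be in [0, 1)")
  }
  if (!is_prob(c_$low_activity_week_prob)) {
    fail_field("low_activity_week_prob", "must be in [0, 1]")
  }
  if (!is_count(c_$low_activity_max)) fail_field("low_activity_max", "must be a non-negative count")
  if (!is_count(c_$seed) && !(is.numeric(c_$seed) && length(c_$seed) == 1L)) {
    fail_field("seed", "must be a single integer")
  }
  invisible(config)
}

#' Generate a synthetic trace log with planted cluster structure
#'
#' For each actor-week, a task-event count is drawn from a negative binomial
#' with the configured mean and dispersion (real weekly activity is strongly
#' overdispersed); with probability `low_activity_week_prob` the count is
#' instead drawn uniformly on `0..low_activity_max` so the low-activity
#' filter is exercised. Task tokens are drawn from the mixture law implied by
#' the actor's cluster trajectory for that week (theme weight x uniform topic
#' choice within theme x topic-word distribution). General-use events are
#' injected on top at a Poisson rate chosen so their expected share of the
#' whole log equals `general_use_rate`. Dates are day-resolved, uniform
#' within the ISO week.
#'
#' @param config a [synthetic_config()].
#' @return list with:
#'   * `events`: tibble `actor_id, date, target_action` (one row per event);
#'   * `ground_truth`: list with `cluster_of_actor` (named integer vector),
#'     `topic_word_true`, `theme_map_true`, `theme_trajectory_true`,
#'     `weekly_counts` (actors x weeks task counts), `weekly_general`
#'     (injected general-use counts), `low_activity` (logical matrix),
#'     `theme_names`, `origin_year`.
#' @export
generate_log <- function(config) {
  validate_synthetic_config(config)
  c_ <- config
  theme_names <- unique(unname(c_$theme_map_true))
  empty_events <- tibble::tibble(actor_id = character(), date = as.Date(character()),
                                 target_action = character())
  if (c_$n_actors == 0L) {
    return(list(events = empty_events, ground_truth = list(
      cluster_of_actor = integer(0), topic_word_true = c_$topic_word_true,
      theme_map_true = c_$theme_map_true,
      theme_trajectory_true = c_$trajectory_spec,
      weekly_counts = matrix(0L, 0, c_$n_weeks),
      weekly_general = matrix(0L, 0, c_$n_weeks),
      low_activity = matrix(FALSE, 0, c_$n_weeks),
      theme_names = theme_names, origin_year = c_$origin_year
    )))
  }

  withr::with_seed(c_$seed, {
    actor_ids <- sprintf("id_%03d", seq_len(c_$n_actors))
    cluster_of_actor <- setNames(
      rep(seq_len(c_$n_clusters), length.out = c_$n_actors), actor_ids
    )

    # Per-topic uniform-within-theme weights, then per-(cluster, week) token
    # law: p(token) = sum_theme traj * mean over the theme's topics of the
    # topic-word row. Marginalizing the hierarchy keeps generation exact and
    # one draw per actor-week.
    task_tokens <- colnames(c_$topic_word_true)
    theme_topic_mean <- do.call(rbind, lapply(theme_names, function(h) {
      ks <- which(unname(c_$theme_map_true) == h)
      if (!length(ks)) rep(0, length(task_tokens))
      else colMeans(c_$topic_word_true[ks, , drop = FALSE])
    }))
    rownames(theme_topic_mean) <- theme_names
    token_law <- lapply(seq_len(c_$n_clusters), function(cl) {
      c_$trajectory_spec[[cl]] %*% theme_topic_mean # n_weeks x tokens
    })

    gen_tokens <- general_use_tokens()
    g <- c_$general_use_rate
    week_starts <- week_start_date(seq_len(c_$n_weeks), c_$origin_year)

    weekly_counts <- matrix(0L, c_$n_actors, c_$n_weeks,
                            dimnames = list(actor_ids, NULL))
    weekly_general <- weekly_counts
    low_activity <- matrix(FALSE, c_$n_actors, c_$n_weeks,
                           dimnames = list(actor_ids, NULL))
    out <- vector("list", c_$n_actors * c_$n_weeks)
    idx <- 0L
    for (a in seq_len(c_$n_actors)) {
      cl <- cluster_of_actor[[a]]
      for (t in seq_len(c_$n_weeks)) {
        n_task <- rnbinom(1L, mu = c_$events_per_week_mean,
                          size = c_$events_per_week_dispersion)
        if (runif(1L) < c_$low_activity_week_prob) {
          n_task <- sample.int(c_$low_activity_max + 1L, 1L) - 1L
          low_activity[a, t] <- TRUE
        }
        n_gen <- if (g > 0) rpois(1L, n_task * g / (1 - g)) else 0L
        weekly_counts[a, t] <- n_task
        weekly_general[a, t] <- n_gen
        n_tot <- n_task + n_gen
        if (n_tot == 0L) next
        toks <- character(0)
        if (n_task > 0L) {
          toks <- sample(task_tokens, n_task, replace = TRUE,
                         prob = token_law[[cl]][t, ])
        }
        if (n_gen > 0L) {
          toks <- c(toks, sample(gen_tokens, n_gen, replace = TRUE))
        }
        dates <- week_starts[t] + sample.int(7L, n_tot, replace = TRUE) - 1L
        idx <- idx + 1L
        out[[idx]] <- tibble::tibble(
          actor_id = actor_ids[a], date = dates, target_action = toks
        )
      }
    }
    events <- if (idx) dplyr::bind_rows(out[seq_len(idx)]) else empty_events
    list(events = events, ground_truth = list(
      cluster_of_actor = cluster_of_actor,
      topic_word_true = c_$topic_word_true,
      theme_map_true = c_$theme_map_true,
      theme_trajectory_true = c_$trajectory_spec,
      weekly_counts = weekly_counts,
      weekly_general = weekly_general,
      low_activity = low_activity,
      theme_names = theme_names,
      origin_year = c_$origin_year
    ))
  })
}

#' Write a trace log as CSV
#'
#' Header `actor_id,date,target_action`, ISO-8601 dates.
#'
#' @param events tibble as produced by [generate_log()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_log <- function(events, path) {
  df <- data.frame(actor_id = events$actor_id,
                   date = format(events$date, "%Y-%m-%d"),
                   target_action = events$target_action)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param ground_truth the `ground_truth` element of [generate_log()] output.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  # jsonlite drops names of atomic vectors; listify keyed structures so the
  # sidecar keeps actor ids and topic indices.
  gt$cluster_of_actor <- as.list(gt$cluster_of_actor)
  gt$theme_map_true <- as.list(gt$theme_map_true)
  mat_by_actor <- function(m) {
    setNames(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])),
             rownames(m))
  }
  gt$weekly_counts <- mat_by_actor(gt$weekly_counts)
  gt$weekly_general <- mat_by_actor(gt$weekly_general)
  gt$low_activity <- mat_by_actor(gt$low_activity)
  gt$topic_word_true <- as.data.frame(gt$topic_word_true)
  gt$theme_trajectory_true <- lapply(gt$theme_trajectory_true, function(m) {
    m2 <- as.data.frame(m)
    names(m2) <- colnames(m)
    m2
  })
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
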