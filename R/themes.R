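# Topic -> theme aggregation and assembly of per-actor weekly theme
# processes. A theme is a manually defined group of topics; a document's
# theme distribution is the sum of its topic probabilities within each
# theme. Each actor's process is the sequence of weekly theme distributions
# P_i(t) together with the weekly event counts C_i(t).

#' Construct a topic-to-theme map
#'
#' Themes are user configuration: the grouping of topics into interpretable
#' themes is a manual, domain-knowledge step. Topics not assigned to any
#' named theme fall into the catch-all `"Others"` theme, which is always
#' present.
#'
#' @param assignment named list, theme name -> integer vector of topic
#'   indices (1-based). May be empty (everything -> `"Others"`).
#' @param n_topics number of topics in the fitted model.
#' @return a `theme_map`: list with `theme_names` (named themes in given
#'   order, `"Others"` last) and `topic_theme` (character vector of length
#'   `n_topics` giving each topic's theme).
#' @export
theme_map <- function(assignment, n_topics) {
  stopifnot(is.list(assignment))
  idx <- unlist(assignment, use.names = FALSE)
  if (length(idx)) {
    if (any(idx != round(idx)) || any(idx < 1) || any(idx > n_topics)) {
      stop("topic index out of range 1..", n_topics, " in theme map",
           call. = FALSE)
    }
    if (anyDuplicated(idx)) {
      stop("topic assigned to more than one theme: ",
           paste(unique(idx[duplicated(idx)]), collapse = ", "), call. = FALSE)
    }
  }
  named <- setdiff(names(assignment), "Others")
  theme_names <- c(named, "Others")
  topic_theme <- rep("Others", n_topics)
  for (h in names(assignment)) topic_theme[assignment[[h]]] <- h
  structure(list(theme_names = theme_names, topic_theme = topic_theme),
            class = "theme_map")
}

#' Identity theme map (each topic is its own theme)
#'
#' Used when the optional manual theme step is skipped: topics pass through
#' unaggregated (an empty `"Others"` theme is appended for type
#' consistency).
#'
#' @param n_topics number of topics.
#' @return a `theme_map` with themes `topic_1..topic_K` plus `"Others"`.
#' @export
identity_theme_map <- function(n_topics) {
  nm <- paste0("topic_", seq_len(n_topics))
  theme_map(setNames(as.list(seq_len(n_topics)), nm), n_topics)
}

#' Read a theme map from YAML
#'
#' Expected structure: `themes: {Evaluation: [9, 17], Courses: [4, 10, 12],
#' ...}` with 1-based topic indices.
#'
#' @param path YAML file path.
#' @param n_topics number of topics in the fitted model.
#' @return a `theme_map`.
#' @export
read_theme_map <- function(path, n_topics) {
  y <- yaml::read_yaml(path)
  if (is.null(y$themes)) stop("YAML must have a top-level `themes` mapping",
                              call. = FALSE)
  theme_map(y$themes, n_topics)
}

#' Aggregate topic distributions into theme distributions
#'
#' Each theme's probability is the sum of its topics' probabilities;
#' unassigned mass goes to `"Others"`. Probability mass is conserved
#' exactly, and the operation is linear in the topic vector.
#'
#' @param topic_probs a probability vector over topics, or a matrix with one
#'   distribution per row.
#' @param map a `theme_map` for the same number of topics.
#' @return vector (or matrix, one row per input row) over `map$theme_names`.
#' @export
topics_to_themes <- function(topic_probs, map) {
  stopifnot(inherits(map, "theme_map"))
  m <- if (is.matrix(topic_probs)) topic_probs else
    matrix(topic_probs, nrow = 1L)
  if (ncol(m) != length(map$topic_theme)) {
    stop("topic vector length ", ncol(m), " does not match theme map for ",
         length(map$topic_theme), " topics", call. = FALSE)
  }
  agg <- vapply(map$theme_names, function(h) {
    cols <- which(map$topic_theme == h)
    if (!length(cols)) rep(0, nrow(m)) else rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L && !is.matrix(topic_probs)) {
    out <- as.numeric(agg)
    names(out) <- map$theme_names
    out
  } else {
    matrix(agg, nrow = nrow(m), dimnames = list(rownames(m), map$theme_names))
  }
}

#' Assemble per-actor weekly theme processes
#'
#' For a window of weeks (e.g. the 22-week spring semester), builds one
#' process per actor with at least one active week in the window: the weekly
#' theme distribution `P` (rows for active weeks; `NA` rows for weeks with
#' no surviving document) and the weekly event count `C` (document totals;
#' 0 for inactive weeks).
#'
#' @param doc_topic matrix (documents x topics) as returned by
#'   [assign_topic_distributions()] or found in an `lda_fit`.
#' @param meta document metadata tibble (`actor_id, year, week, total`),
#'   aligned row-for-row with `doc_topic`.
#' @param map a `theme_map`; default [identity_theme_map()].
#' @param weeks integer vector of week numbers forming the window (default
#'   `1:22`); positions in this vector define the process time axis `t`.
#' @param year optional ISO year filter; `NULL` uses all years (only
#'   meaningful when weeks do not repeat across years in the data).
#' @return a `theme_process_set`: list with `theme_names`, `weeks`, `year`,
#'   and `processes` — a named list per actor of `list(P, C)` where `P` is a
#'   `length(weeks)` x themes matrix (`NA` rows where `C == 0`) and `C` an
#'   integer vector.
#' @export
build_processes <- function(doc_topic, meta, map = NULL, weeks = 1:22,
                            year = NULL) {
  if (length(weeks) == 0L) stop("empty week window", call. = FALSE)
  if (nrow(meta) != nrow(doc_topic)) {
    stop("meta and doc_topic are not aligned", call. = FALSE)
  }
  if (is.null(map)) map <- identity_theme_map(ncol(doc_topic))
  theme_rows <- topics_to_themes(doc_topic, map)
  keep <- meta$week %in% weeks
  if (!is.null(year)) keep <- keep & meta$year %in% year
  meta_w <- meta[keep, , drop = FALSE]
  theme_w <- theme_rows[keep, , drop = FALSE]
  actors <- sort(unique(meta_w$actor_id), method = "radix")
  H <- length(map$theme_names)
  Tn <- length(weeks)
  processes <- lapply(actors, function(a) {
    rows <- which(meta_w$actor_id == a)
    P <- matrix(NA_real_, Tn, H,
                dimnames = list(paste0("week_", weeks), map$theme_names))
    C <- setNames(integer(Tn), paste0("week_", weeks))
    t_idx <- match(meta_w$week[rows], weeks)
    P[t_idx, ] <- theme_w[rows, , drop = FALSE]
    C[t_idx] <- meta_w$total[rows]
    list(P = P, C = C)
  })
  names(processes) <- actors
  structure(list(theme_names = map$theme_names, weeks = weeks, year = year,
                 processes = processes),
            class = "theme_process_set")
}

#' @export
print.theme_process_set <- function(x, ...) {
  cat(sprintf("theme_process_set: %d actors, %d-week window, %d themes\n",
              length(x$processes), length(x$weeks), length(x$theme_names)))
  invisible(x)
}

#' Mean weekly theme distribution over actors
#'
#' For each week of the window, the mean of the actors' theme distributions.
#' By default the mean is unweighted over the actors active that week (the
#' mean of distributions is again a distribution, by linearity);
#' `weighted = TRUE` weights each actor by its event count `C`.
#'
#' @param processes a `theme_process_set`.
#' @param weighted weight actors by weekly activity counts?
#' @return tibble `week, theme, mean_probability, n_active`; weeks with no
#'   active actor have `NA` probabilities and `n_active = 0`.
#' @export
mean_weekly_theme_distribution <- function(processes, weighted = FALSE) {
  stopifnot(inherits(processes, "theme_process_set"))
  if (!length(processes$processes)) stop("no processes", call. = FALSE)
  H <- length(processes$theme_names)
  rows <- lapply(seq_along(processes$weeks), function(t) {
    P_t <- t(vapply(processes$processes, function(p) p$P[t, ], numeric(H)))
    C_t <- vapply(processes$processes, function(p) p$C[t], numeric(1))
    active <- C_t > 0
    mp <- if (!any(active)) rep(NA_real_, H) else if (weighted) {
      colSums(P_t[active, , drop = FALSE] * C_t[active]) / sum(C_t[active])
    } else {
      colMeans(P_t[active, , drop = FALSE])
    }
    tibble::tibble(week = processes$weeks[t], theme = processes$theme_names,
                   mean_probability = unname(mp), n_active = sum(active))
  })
  dplyr::bind_rows(rows)
}

#' Export processes as long-format CSV
#'
#' Columns `actor_id,week,theme,probability,events`; inactive weeks appear
#' with `events = 0` and empty probability.
#'
#' @param processes a `theme_process_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_processes <- function(processes, path) {
  rows <- lapply(names(processes$processes), function(a) {
    p <- processes$processes[[a]]
    tibble::tibble(
      actor_id = a,
      week = rep(processes$weeks, each = length(processes$theme_names)),
      theme = rep(processes$theme_names, length(processes$weeks)),
      probability = as.vector(t(p$P)),
      events = rep(unname(p$C), each = length(processes$theme_names))
    )
  })
  write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}
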