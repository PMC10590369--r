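# Cluster-level descriptive outputs: per-cluster average weekly theme
# distributions, overall weekly averages, peak-week detection for a theme
# group, and stacked-area figures with auditable CSV backing.

#' Per-cluster average weekly theme distributions
#'
#' For each cluster and week, the unweighted mean theme distribution over
#' the cluster's actors active that week (actors with no surviving document
#' that week do not enter the mean). Cluster-weeks with no active actor are
#' reported with `NA` probabilities and `n_active = 0`.
#'
#' @param processes a `theme_process_set`.
#' @param labels named integer vector (actor id -> cluster index), e.g. from
#'   [cut_clusters()]. Every labeled actor must have a process.
#' @return a `cluster_summary`: tibble
#'   `cluster, week, theme, mean_probability, n_active` with attribute
#'   `cluster_sizes`.
#' @export
summarize_clusters <- function(processes, labels) {
  stopifnot(inherits(processes, "theme_process_set"))
  missing <- setdiff(names(labels), names(processes$processes))
  if (length(missing)) {
    stop("labeled actors without a process: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(sort(unique(labels)), function(cl) {
    sub <- processes
    sub$processes <- processes$processes[names(labels)[labels == cl]]
    m <- mean_weekly_theme_distribution(sub)
    m$cluster <- cl
    m
  })
  res <- dplyr::bind_rows(out)[, c("cluster", "week", "theme",
                                   "mean_probability", "n_active")]
  attr(res, "cluster_sizes") <- table(labels)
  attr(res, "theme_names") <- processes$theme_names
  class(res) <- c("cluster_summary", class(res))
  res
}

# Internal: prominence of strict local maxima of a series. For each strict
# local maximum t, the base on each side is the minimum of the series
# between t and the nearest strictly higher point (or the series end);
# prominence = s(t) - max(left base, right base). Endpoints are never peaks.
local_peaks <- function(s) {
  n <- length(s)
  if (n < 3L) return(tibble::tibble(index = integer(), prominence = numeric()))
  idx <- which(vapply(2:(n - 1L), function(t) {
    !is.na(s[t]) && !is.na(s[t - 1]) && !is.na(s[t + 1]) &&
      s[t] > s[t - 1] && s[t] > s[t + 1]
  }, logical(1))) + 1L
  prom <- vapply(idx, function(t) {
    left <- s[seq_len(t - 1L)]
    higher_l <- which(left > s[t])
    lbase <- min(s[(if (length(higher_l)) max(higher_l) + 1L else 1L):(t - 1L)],
                 na.rm = TRUE)
    right <- s[(t + 1L):n]
    higher_r <- which(right > s[t])
    rend <- if (length(higher_r)) t + min(higher_r) - 1L else n
    rbase <- min(s[(t + 1L):rend], na.rm = TRUE)
    s[t] - max(lbase, rbase)
  }, numeric(1))
  tibble::tibble(index = idx, prominence = prom)
}

#' Detect peak weeks of a theme group per cluster
#'
#' A peak week is the climax of an increasing trend after which activity
#' decreases: week `t` is a peak of the group's share series `s` iff
#' `s(t) > s(t-1)`, `s(t) > s(t+1)` and its prominence is at least
#' `min_prominence`. Endpoints are never peaks. The group's share is the
#' sum of the group themes' mean probabilities.
#'
#' @param summary a `cluster_summary` from [summarize_clusters()].
#' @param theme_group character vector of theme names, e.g.
#'   `c("Evaluation", "Final grading")` — the grading demand.
#' @param min_prominence minimum peak prominence (default 0.02 on the
#'   probability-share scale; small bumps below it are noise).
#' @return a `peak_report`: list with `theme_group`, `min_prominence`,
#'   `peaks` (tibble `cluster, week, share, prominence`) and `by_cluster`
#'   (list cluster -> integer weeks).
#' @export
detect_peaks <- function(summary, theme_group = c("Evaluation", "Final grading"),
                         min_prominence = 0.02) {
  stopifnot(inherits(summary, "cluster_summary"))
  if (!length(theme_group)) stop("empty theme group", call. = FALSE)
  themes <- unique(summary$theme)
  bad <- setdiff(theme_group, themes)
  if (length(bad)) {
    stop("unknown theme(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  peaks <- lapply(sort(unique(summary$cluster)), function(cl) {
    sub <- summary[summary$cluster == cl & summary$theme %in% theme_group, ]
    share <- vapply(split(sub$mean_probability, sub$week), sum, numeric(1))
    weeks <- as.integer(names(share))
    ord <- order(weeks)
    share <- share[ord]; weeks <- weeks[ord]
    pk <- local_peaks(share)
    pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
    tibble::tibble(cluster = cl, week = weeks[pk$index],
                   share = unname(share[pk$index]), prominence = pk$prominence)
  })
  peaks <- dplyr::bind_rows(peaks)
  by_cluster <- split(peaks$week, peaks$cluster)
  structure(list(theme_group = theme_group, min_prominence = min_prominence,
                 peaks = peaks, by_cluster = by_cluster),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  cat("peak_report for theme group {", paste(x$theme_group, collapse = ", "),
      "}, min prominence ", x$min_prominence, "\n", sep = "")
  print(x$peaks)
  invisible(x)
}

#' Write a peak report as JSON
#'
#' @param report a `peak_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(report, path) {
  jsonlite::write_json(list(
    theme_group = report$theme_group,
    min_prominence = report$min_prominence,
    peaks = report$peaks
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render stacked-area figures of cluster processes
#'
#' One stacked-area chart per cluster plus one overall chart (mean over all
#' actors), with a fixed theme color order. The underlying numbers are also
#' emitted as `summary.csv` so every figure is auditable. Cluster-weeks with
#' no active actor render as gaps, with a "no data" annotation when a whole
#' cluster panel is empty.
#'
#' @param summary a `cluster_summary`.
#' @param out_dir output directory (created if needed).
#' @param device `"png"` (default) or `"svg"`, written via
#'   [ggplot2::ggsave()].
#' @param width,height figure size in inches.
#' @return invisible character vector of files written.
#' @export
render_figures <- function(summary, out_dir, device = c("png", "svg"),
                           width = 8, height = 4) {
  device <- match.arg(device)
  stopifnot(inherits(summary, "cluster_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  csv_path <- file.path(out_dir, "summary.csv")
  write.csv(as.data.frame(summary), csv_path, row.names = FALSE)
  files <- c(files, csv_path)

  theme_levels <- attr(summary, "theme_names")
  if (is.null(theme_levels)) theme_levels <- unique(summary$theme)
  plot_one <- function(df, title, path) {
    df$theme <- factor(df$theme, levels = theme_levels)
    df <- df[!is.na(df$mean_probability), , drop = FALSE]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$week,
                                          y = .data$mean_probability,
                                          fill = .data$theme)) +
      ggplot2::labs(title = title, x = "week", y = "share of activity",
                    fill = "theme") +
      ggplot2::theme_minimal()
    p <- if (nrow(df) == 0L) {
      p + ggplot2::annotate("text", x = 0.5, y = 0.5, label = "no data") +
        ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1)
    } else {
      p + ggplot2::geom_area(position = "stack")
    }
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
    path
  }

  for (cl in sort(unique(summary$cluster))) {
    path <- file.path(out_dir, sprintf("cluster_%02d.%s", cl, device))
    files <- c(files, plot_one(summary[summary$cluster == cl, ],
                               sprintf("Cluster %d: average weekly theme distribution", cl),
                               path))
  }
  overall <- dplyr::summarise(
    dplyr::group_by(summary[!is.na(summary$mean_probability), ],
                    .data$week, .data$theme),
    mean_probability = sum(.data$mean_probability * .data$n_active) /
      sum(.data$n_active),
    .groups = "drop"
  )
  overall_path <- file.path(out_dir, paste0("overall.", device))
  overall$cluster <- 0L
  files <- c(files, plot_one(overall,
                             "All actors: average weekly theme distribution",
                             overall_path))
  invisible(files)
}
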