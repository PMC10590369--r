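# End-to-end orchestration of the eight-step protocol: data (or synthetic
# generation), preprocessing, document construction, topic modeling with
# model selection, topic-distribution assignment, optional theme
# aggregation, pairwise dissimilarities, and clustering — plus reporting and
# a reproducibility manifest.

#' Build a pipeline configuration
#'
#' Either `input` (a trace-log CSV path) or `synthetic` (a
#' [synthetic_config()]) must be supplied. All values can equally come from
#' a YAML file via [read_pipeline_config()].
#'
#' @param input path to a trace-log CSV, or `NULL` to simulate.
#' @param synthetic a [synthetic_config()], or `NULL` to read `input`.
#' @param removal_list general-use tokens to remove.
#' @param min_events weekly activity threshold (default 25).
#' @param date_dialect `"dayfirst"` or `"iso"`.
#' @param weeks week window for processes/clustering (default `1:22`, the
#'   spring semester).
#' @param year optional ISO year filter for the window.
#' @param topic_range candidate topic numbers (canonical full-scale run:
#'   `10:20`).
#' @param n_inits random restarts per topic number (canonical: 50).
#' @param master_seed master seed for restarts.
#' @param force_n_topics optional pinned topic number (manual choice).
#' @param theme_map_path YAML theme map, or `NULL` to skip the optional
#'   manual theme step (topics pass through as themes, flagged in the
#'   manifest).
#' @param log_base JS logarithm base.
#' @param missing_pair `"max"` or `"drop"` policy for pairs with no
#'   co-active week.
#' @param k number of flat clusters (default 6).
#' @param theme_group themes whose joint share is scanned for peak weeks.
#' @param min_prominence peak prominence threshold.
#' @param out_dir output directory for all artifacts.
#' @param render_figures write figures (default TRUE)?
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            removal_list = general_use_tokens(),
                            min_events = 25, date_dialect = "dayfirst",
                            weeks = 1:22, year = NULL,
                            topic_range = 10:20, n_inits = 50L,
                            master_seed = 1L, force_n_topics = NULL,
                            theme_map_path = NULL,
                            log_base = 2, missing_pair = "max",
                            k = 6L,
                            theme_group = c("Evaluation", "Final grading"),
                            min_prominence = 0.02,
                            out_dir = tempfile("traceproc_run_"),
                            render_figures = TRUE) {
  structure(list(
    input = input, synthetic = synthetic, removal_list = removal_list,
    min_events = min_events, date_dialect = date_dialect,
    weeks = weeks, year = year, topic_range = topic_range,
    n_inits = n_inits, master_seed = master_seed,
    force_n_topics = force_n_topics, theme_map_path = theme_map_path,
    log_base = log_base, missing_pair = missing_pair, k = k,
    theme_group = theme_group, min_prominence = min_prominence,
    out_dir = out_dir, render_figures = render_figures
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `synthetic`
#' block is passed to [synthetic_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$weeks)) y$weeks <- do.call(seq, as.list(range(unlist(y$weeks))))
  if (!is.null(y$topic_range)) y$topic_range <- unlist(y$topic_range)
  do.call(pipeline_config, y)
}

#' Validate a pipeline configuration
#'
#' Collects every detectable problem at once instead of failing on the
#' first.
#'
#' @param config a `pipeline_config`.
#' @return character vector of issues; empty when clean.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(config$input) && is.null(config$synthetic)) {
    add("either `input` or `synthetic` must be supplied")
  }
  if (!is.null(config$input) && !file.exists(config$input)) {
    add(sprintf("input file not found: %s", config$input))
  }
  if (!is.null(config$synthetic)) {
    ok <- tryCatch({ validate_synthetic_config(config$synthetic); TRUE },
                   error = function(e) { add(conditionMessage(e)); FALSE })
  }
  if (!is_count(config$min_events, 1L)) add("min_events must be a positive count")
  if (!length(config$weeks)) add("empty week window")
  if (!length(config$topic_range) || any(config$topic_range < 1)) {
    add("empty range of topic numbers")
  }
  if (!is_count(config$n_inits, 1L)) add("n_inits must be >= 1")
  if (!is_count(config$k, 1L)) add("k must be >= 1")
  if (!is.null(config$theme_map_path) && !file.exists(config$theme_map_path)) {
    add(sprintf("theme map file not found: %s", config$theme_map_path))
  }
  if (!config$missing_pair %in% c("max", "drop")) {
    add("missing_pair must be \"max\" or \"drop\"")
  }
  issues
}

#' Run the full pipeline
#'
#' Executes, in order: (optional) synthetic generation, preprocessing
#' (general-use removal then the weekly activity threshold), actor-week
#' corpus construction, LDA fitting with BIC-based model selection,
#' document-topic assignment, (optional) theme aggregation, weekly process
#' assembly over the configured window, pairwise activity-weighted JS
#' dissimilarities, complete-linkage clustering cut at `k`, and cluster
#' summaries with peak detection. Every intermediate artifact is written
#' under `config$out_dir`; a manifest JSON records seeds, per-stage row
#' counts and the config hash.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the principal objects: `events`,
#'   `corpus`, `selection`, `theme_processes`, `dissimilarity`,
#'   `dendrogram`, `labels`, `summary`, `peaks`, `manifest`,
#'   `ground_truth` (when synthetic).
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop("invalid pipeline config:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), seeds = list(master_seed = config$master_seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # 1. Data: read or simulate.
  ground_truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- stage("simulate", generate_log(config$synthetic))
    raw_events <- sim$events
    ground_truth <- sim$ground_truth
    manifest$seeds$synthetic_seed <- config$synthetic$seed
    write_trace_log(raw_events, file.path(out_dir, "events.csv"))
    write_ground_truth(ground_truth, file.path(out_dir, "ground_truth.json"))
  } else {
    raw_events <- stage("read", read_trace_log(config$input,
                                               date_dialect = config$date_dialect))
  }
  manifest$stages$events_in <- nrow(raw_events)

  # 2. Preprocessing.
  pre <- stage("preprocess", preprocess_events(
    raw_events, removal_list = config$removal_list,
    min_events = config$min_events
  ))
  write_preprocessing_report(pre$report,
                             file.path(out_dir, "preprocessing_report.json"))
  manifest$stages$events_clean <- nrow(pre$events)
  if (nrow(pre$events) == 0L) {
    stop("pipeline stage `preprocess` failed: no events survive preprocessing",
         call. = FALSE)
  }

  # 3. Documents.
  corpus <- stage("documents", build_corpus(pre$events))
  write_corpus(corpus, file.path(out_dir, "corpus"))
  manifest$stages$documents <- nrow(corpus$counts)
  manifest$stages$vocabulary <- length(corpus$vocabulary)

  # 4-5. Topic modeling, model selection, topic assignment.
  selection <- stage("topic_model", model_selection(
    corpus, topic_range = config$topic_range, n_inits = config$n_inits,
    master_seed = config$master_seed, force_n_topics = config$force_n_topics
  ))
  write_model_report(selection, corpus, file.path(out_dir, "model"))
  fit <- selection$selected
  manifest$stages$selected_n_topics <- fit$n_topics
  manifest$seeds$selected_fit_seed <- fit$seed

  # 6. Optional manual theme step.
  if (!is.null(config$theme_map_path)) {
    map <- stage("themes", read_theme_map(config$theme_map_path, fit$n_topics))
    manifest$stages$theme_map <- "user-supplied"
  } else {
    map <- identity_theme_map(fit$n_topics)
    manifest$stages$theme_map <- "identity (manual theme step skipped)"
  }
  processes <- stage("themes", build_processes(
    fit$doc_topic, corpus$meta, map = map,
    weeks = config$weeks, year = config$year
  ))
  write_processes(processes, file.path(out_dir, "processes.csv"))
  manifest$stages$actors_in_window <- length(processes$processes)

  # 7. Dissimilarities.
  dm <- stage("dissimilarity", pairwise_dissimilarity(
    processes, log_base = config$log_base,
    missing_pair = config$missing_pair
  ))
  if (config$missing_pair == "drop" && nrow(dm$undefined_pairs)) {
    drop_actors <- unique(c(dm$undefined_pairs$actor_i,
                            dm$undefined_pairs$actor_j))
    keep <- setdiff(rownames(dm$D), drop_actors)
    dm$D <- dm$D[keep, keep]
    manifest$stages$actors_dropped_no_overlap <- length(drop_actors)
  }
  write_dissimilarity(dm, file.path(out_dir, "dissimilarity.csv"))
  manifest$stages$undefined_pairs <- nrow(dm$undefined_pairs)

  # 8. Clustering.
  dend <- stage("clustering", complete_linkage(dm))
  labels <- stage("clustering", cut_clusters(dend, k = min(config$k, nrow(dm$D))))
  write_newick(dend, file.path(out_dir, "dendrogram.nwk"))
  write.csv(data.frame(actor_id = names(labels), cluster = unname(labels)),
            file.path(out_dir, "labels.csv"), row.names = FALSE)
  manifest$stages$k <- length(unique(labels))

  # Reporting.
  summary <- stage("reporting", summarize_clusters(processes, labels))
  peaks <- if (all(config$theme_group %in% processes$theme_names)) {
    pk <- stage("reporting", detect_peaks(summary, config$theme_group,
                                          config$min_prominence))
    write_peak_report(pk, file.path(out_dir, "peaks.json"))
    pk
  } else NULL
  fig_files <- if (isTRUE(config$render_figures)) {
    stage("reporting", render_figures(summary, file.path(out_dir, "figures")))
  } else {
    csv_path <- file.path(out_dir, "summary.csv")
    write.csv(as.data.frame(summary), csv_path, row.names = FALSE)
    csv_path
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_dump <- config
  cfg_dump$synthetic <- if (!is.null(config$synthetic)) {
    c_ <- unclass(config$synthetic)
    c_[c("n_actors", "n_weeks", "n_clusters", "n_topics_true",
         "events_per_week_mean", "events_per_week_dispersion",
         "general_use_rate", "low_activity_week_prob", "origin_year", "seed")]
  } else NULL
  yaml::write_yaml(lapply(unclass(cfg_dump), function(x)
    if (is.null(x)) NULL else x), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$package_version <- as.character(utils::packageVersion("traceproc"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    events = pre$events, corpus = corpus, selection = selection,
    theme_processes = processes, dissimilarity = dm, dendrogram = dend,
    labels = labels, summary = summary, peaks = peaks,
    manifest = manifest, ground_truth = ground_truth, out_dir = out_dir
  ))
}
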