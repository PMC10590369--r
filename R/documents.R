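# Actor-week bag-of-words corpus construction. The collection of events, with
# occurrence counts, performed by one actor in one week is one document; the
# vocabulary is the set of target-action tokens.

#' Build the token vocabulary from events
#'
#' @param events tibble with a `target_action` column.
#' @return character vector of distinct tokens, sorted lexicographically
#'   (C locale) for determinism.
#' @export
build_vocabulary <- function(events) {
  if (nrow(events) == 0L) stop("cannot build a vocabulary from an empty corpus",
                               call. = FALSE)
  sort(unique(events$target_action), method = "radix")
}

#' Build the actor-week document corpus
#'
#' One document per distinct `(actor_id, year, week)` with at least one
#' event. Token counts are stored as a sparse documents-x-vocabulary matrix;
#' the sum of all document totals equals the number of input events (count
#' conservation). Documents with zero events are never materialized.
#'
#' @param events tibble with `actor_id`, `year`, `week`, `target_action`.
#' @param vocabulary token vector; default built from `events`. Every event
#'   token must be present.
#' @return a `doc_corpus`: list with `vocabulary`, `counts`
#'   (`dgCMatrix`, documents x tokens) and `meta` (tibble
#'   `actor_id, year, week, total`).
#' @export
build_corpus <- function(events, vocabulary = NULL) {
  if (is.null(vocabulary)) vocabulary <- build_vocabulary(events)
  unknown <- setdiff(unique(events$target_action), vocabulary)
  if (length(unknown)) {
    stop("tokens not in vocabulary: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(events$actor_id, events$year, events$week, sep = "\r")
  doc_key <- sort(unique(key), method = "radix")
  i <- match(key, doc_key)
  j <- match(events$target_action, vocabulary)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = rep(1, length(i)),
    dims = c(length(doc_key), length(vocabulary)),
    dimnames = list(NULL, vocabulary)
  )
  parts <- do.call(rbind, strsplit(doc_key, "\r", fixed = TRUE))
  meta <- tibble::tibble(
    actor_id = parts[, 1],
    year = as.integer(parts[, 2]),
    week = as.integer(parts[, 3]),
    total = as.integer(Matrix::rowSums(counts))
  )
  structure(list(vocabulary = vocabulary, counts = counts, meta = meta),
            class = "doc_corpus")
}

#' @export
print.doc_corpus <- function(x, ...) {
  cat(sprintf("doc_corpus: %d documents, %d tokens in vocabulary, %d events\n",
              nrow(x$counts), length(x$vocabulary), sum(x$meta$total)))
  invisible(x)
}

#' Write a corpus to disk
#'
#' Three plain-text artifacts in `dir`: `vocabulary.txt` (one token per
#' line), `counts.mtx` (MatrixMarket sparse matrix, documents x tokens) and
#' `documents.csv` (`actor_id,year,week,total`).
#'
#' @param corpus a `doc_corpus`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(corpus$vocabulary, file.path(dir, "vocabulary.txt"))
  Matrix::writeMM(corpus$counts, file.path(dir, "counts.mtx"))
  write.csv(corpus$meta, file.path(dir, "documents.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir directory holding `vocabulary.txt`, `counts.mtx`,
#'   `documents.csv`.
#' @return a `doc_corpus`.
#' @export
read_corpus <- function(dir) {
  vocabulary <- readLines(file.path(dir, "vocabulary.txt"))
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  colnames(counts) <- vocabulary
  meta <- tibble::as_tibble(read.csv(file.path(dir, "documents.csv"),
                                     colClasses = c(actor_id = "character")))
  structure(list(vocabulary = vocabulary, counts = counts, meta = meta),
            class = "doc_corpus")
}
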