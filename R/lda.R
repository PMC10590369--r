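# Latent Dirichlet allocation by batch variational Bayes, with BIC scoring
# and restart-based model selection over a range of topic numbers.
#
# The mean-field updates follow the standard batch VB scheme for LDA:
# q(theta_d) = Dirichlet(gamma_d), q(beta_k) = Dirichlet(lambda_k), and the
# per-word responsibilities are collapsed into the matrix identity
#   gamma = alpha + expElogtheta * ((N / Z) %*% t(expElogbeta))
#   lambda = eta + expElogbeta * (t(expElogtheta) %*% (N / Z))
# with Z = expElogtheta %*% expElogbeta, which avoids materializing phi.

# Internal: exp of E[log Dirichlet] rows.
dir_expectation <- function(m) {
  exp(digamma(m) - digamma(rowSums(m)))
}

# Internal: evidence lower bound (ELBO) in nats.
lda_elbo <- function(N, gamma, lambda, alpha, eta) {
  K <- ncol(gamma)
  V <- ncol(lambda)
  D <- nrow(gamma)
  Elogtheta <- digamma(gamma) - digamma(rowSums(gamma))
  Elogbeta <- digamma(lambda) - digamma(rowSums(lambda))
  Z <- exp(Elogtheta) %*% exp(Elogbeta)
  score <- sum(N@x * log(pmax(Z[cbind(N@i + 1L, N@j + 1L)], 1e-300)))
  # E[log p(theta)] - E[log q(theta)]
  score <- score + sum((alpha - gamma) * Elogtheta) +
    sum(lgamma(gamma)) - sum(lgamma(rowSums(gamma))) +
    D * (lgamma(K * alpha) - K * lgamma(alpha))
  # E[log p(beta)] - E[log q(beta)]
  score <- score + sum((eta - lambda) * Elogbeta) +
    sum(lgamma(lambda)) - sum(lgamma(rowSums(lambda))) +
    K * (lgamma(V * eta) - V * lgamma(eta))
  score
}

#' Fit an LDA topic model by batch variational Bayes
#'
#' Symmetric Dirichlet priors (defaults `alpha = 1/K` on document-topic,
#' `eta = 1/K` on topic-word). The fit is a deterministic function of the
#' corpus, seed and hyperparameters; the seed controls only the random
#' initialization of the topic-word variational parameters.
#'
#' @param corpus a `doc_corpus` from [build_corpus()].
#' @param n_topics number of topics K (>= 2; K = 1 is degenerate but
#'   permitted with a warning).
#' @param seed integer seed for the initialization.
#' @param alpha,eta symmetric Dirichlet hyperparameters; default `1/K`.
#' @param max_iter maximum variational EM iterations.
#' @param conv_tol relative ELBO change below which iteration stops.
#' @param e_max_iter,e_conv_tol inner (per-E-step) iteration cap and mean
#'   absolute change tolerance on gamma.
#' @return an `lda_fit`: list with `n_topics`, `topic_word` (K x V, rows sum
#'   to 1), `doc_topic` (D x K, rows sum to 1), `log_likelihood` (the ELBO,
#'   a variational lower bound, in nats), `bic`, `seed`, `alpha`, `eta`,
#'   `n_tokens`, `n_documents`, `vocabulary`, `n_iter`, `converged`.
#' @export
fit_lda <- function(corpus, n_topics, seed = 1L,
                    alpha = 1 / n_topics, eta = 1 / n_topics,
                    max_iter = 100L, conv_tol = 1e-5,
                    e_max_iter = 60L, e_conv_tol = 1e-4) {
  stopifnot(inherits(corpus, "doc_corpus"))
  if (!is_count(n_topics, 1L)) stop("n_topics must be a positive count", call. = FALSE)
  if (n_topics < 2L) warning("n_topics < 2 gives a degenerate single-topic fit")
  D <- nrow(corpus$counts)
  V <- length(corpus$vocabulary)
  if (D == 0L) stop("corpus has no documents", call. = FALSE)
  if (V == 1L) warning("single-token vocabulary: all topics are the point mass")
  if (n_topics > D) warning("more topics than documents; fit may be unstable")
  K <- as.integer(n_topics)
  N <- corpus$counts # dgCMatrix, D x V
  Ndense <- as.matrix(N)
  n_tokens <- sum(Ndense)

  # Initialization: each topic is seeded from the pooled token counts of a
  # few randomly chosen documents plus Gamma noise. Document-seeded starts
  # put the optimizer in a basin near empirically occurring co-occurrence
  # patterns, which is far more reliable than pure-noise starts.
  lambda <- withr::with_seed(seed, {
    l <- matrix(stats::rgamma(K * V, shape = 100, rate = 100), K, V)
    n_seed_docs <- min(D, K * 3L)
    picks <- sample.int(D, n_seed_docs)
    grp <- rep(seq_len(K), length.out = n_seed_docs)
    for (k in seq_len(K)) {
      sel <- picks[grp == k]
      if (length(sel)) l[k, ] <- l[k, ] + colSums(Ndense[sel, , drop = FALSE])
    }
    l
  })
  Nt <- methods::as(N, "TsparseMatrix")
  gamma <- matrix(1, D, K)
  bound_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    expElogbeta <- dir_expectation(lambda)
    # E-step: iterate gamma to convergence with topics fixed.
    gamma <- matrix(alpha + n_tokens / (D * K), D, K)
    expElogtheta <- dir_expectation(gamma)
    for (e in seq_len(e_max_iter)) {
      Z <- expElogtheta %*% expElogbeta + 1e-100
      gamma_new <- alpha + expElogtheta * ((Ndense / Z) %*% t(expElogbeta))
      delta <- mean(abs(gamma_new - gamma))
      gamma <- gamma_new
      expElogtheta <- dir_expectation(gamma)
      if (delta < e_conv_tol) break
    }
    # M-step.
    Z <- expElogtheta %*% expElogbeta + 1e-100
    lambda <- eta + expElogbeta * (t(expElogtheta) %*% (Ndense / Z))
    bound <- lda_elbo(Nt, gamma, lambda, alpha, eta)
    if (is.finite(bound_old) &&
        abs(bound - bound_old) / abs(bound_old) < conv_tol) {
      bound_old <- bound
      converged <- TRUE
      break
    }
    bound_old <- bound
  }
  topic_word <- lambda / rowSums(lambda)
  colnames(topic_word) <- corpus$vocabulary
  rownames(topic_word) <- paste0("topic_", seq_len(K))
  doc_topic <- gamma / rowSums(gamma)
  colnames(doc_topic) <- rownames(topic_word)

  fit <- structure(list(
    n_topics = K, topic_word = topic_word, doc_topic = doc_topic,
    log_likelihood = bound_old, seed = seed, alpha = alpha, eta = eta,
    n_tokens = n_tokens, n_documents = D, vocabulary = corpus$vocabulary,
    n_iter = it, converged = converged
  ), class = "lda_fit")
  fit$bic <- bic_score(fit, corpus)
  fit
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("lda_fit: K = %d topics, %d documents, %d tokens, ELBO = %.1f, BIC = %.1f\n",
              x$n_topics, x$n_documents, x$n_tokens, x$log_likelihood, x$bic))
  invisible(x)
}

#' Bayesian information criterion of an LDA fit
#'
#' `BIC = -2 * log_likelihood + k * log(n)`, lower is better, where the
#' log-likelihood is the fit's variational lower bound, `n` is the total
#' token count, and `k` counts free parameters. By default only the
#' topic-word parameters are counted, `k = K (V - 1)`: the per-document
#' topic proportions are latent quantities of the generative model, not
#' free parameters shared across observations. `mode = "full"` additionally
#' counts them (`k = K (V - 1) + D (K - 1)`).
#'
#' @param fit an `lda_fit` computed on `corpus`.
#' @param corpus the same `doc_corpus` the fit was computed on.
#' @param mode `"topic_word"` (default) or `"full"`.
#' @return the BIC value (finite real).
#' @export
bic_score <- function(fit, corpus, mode = c("topic_word", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "lda_fit"), inherits(corpus, "doc_corpus"))
  if (fit$n_documents != nrow(corpus$counts) ||
      !identical(fit$vocabulary, corpus$vocabulary) ||
      fit$n_tokens != sum(corpus$counts)) {
    stop("fit does not match corpus", call. = FALSE)
  }
  K <- fit$n_topics
  V <- length(fit$vocabulary)
  k <- K * (V - 1)
  if (mode == "full") k <- k + fit$n_documents * (K - 1)
  -2 * fit$log_likelihood + k * log(fit$n_tokens)
}

#' Fit LDA over a topic range with restarts and select by BIC
#'
#' Fits every combination of topic number in `topic_range` and restart seed
#' `master_seed + i`, `i = 0..n_inits - 1` (the same restart seeds are used
#' for every topic number). The selected model minimizes BIC; ties break
#' toward fewer topics, then the smaller seed. The report retains all
#' candidates sorted ascending by BIC, plus the top tokens of the selected
#' model's topics to support a manual-inspection step.
#'
#' @param corpus a `doc_corpus`.
#' @param topic_range integer vector of topic numbers (canonical full-scale
#'   choice: `10:20`).
#' @param n_inits restarts per topic number (canonical: 50).
#' @param master_seed integer; restart seeds are derived from it.
#' @param force_n_topics optionally pin the selected model to this topic
#'   number (min-BIC among its restarts), mirroring a manual choice.
#' @param n_top_tokens how many top tokens to report per topic.
#' @param bic_mode passed to [bic_score()].
#' @param ... further arguments to [fit_lda()].
#' @return a `model_selection`: list with `candidates` (tibble
#'   `n_topics, seed, log_likelihood, bic, converged`, sorted by `bic`),
#'   `selected` (`lda_fit`), `top_tokens` (list of character vectors),
#'   `master_seed`.
#' @export
model_selection <- function(corpus, topic_range = 10:20, n_inits = 50L,
                            master_seed = 1L, force_n_topics = NULL,
                            n_top_tokens = 5L, bic_mode = "topic_word", ...) {
  stopifnot(length(topic_range) >= 1L, n_inits >= 1L)
  seeds <- master_seed + seq_len(n_inits) - 1L
  fits <- list()
  rows <- list()
  for (K in sort(unique(as.integer(topic_range)))) {
    for (s in seeds) {
      fit <- fit_lda(corpus, K, seed = s, ...)
      fit$bic <- bic_score(fit, corpus, mode = bic_mode)
      fits[[length(fits) + 1L]] <- fit
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_topics = K, seed = s, log_likelihood = fit$log_likelihood,
        bic = fit$bic, converged = fit$converged
      )
    }
  }
  candidates <- dplyr::bind_rows(rows)
  pool <- seq_len(nrow(candidates))
  if (!is.null(force_n_topics)) {
    pool <- which(candidates$n_topics == force_n_topics)
    if (!length(pool)) stop("force_n_topics not in topic_range", call. = FALSE)
  }
  ord <- order(candidates$bic[pool], candidates$n_topics[pool],
               candidates$seed[pool])
  best <- pool[ord[1L]]
  selected <- fits[[best]]
  top_tokens <- apply(selected$topic_word, 1L, function(p) {
    names(sort(p, decreasing = TRUE))[seq_len(min(n_top_tokens, length(p)))]
  }, simplify = FALSE)
  structure(list(
    candidates = candidates[order(candidates$bic), ],
    selected = selected,
    top_tokens = top_tokens,
    master_seed = master_seed
  ), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("model_selection: %d candidates, selected K = %d (BIC = %.1f)\n",
              nrow(x$candidates), x$selected$n_topics, x$selected$bic))
  print(head(x$candidates, 5))
  invisible(x)
}

#' Write a model-selection report and the selected model to disk
#'
#' Emits `selection.json` (candidate table, selected K/seed, top tokens),
#' `topic_word.csv` (topics x tokens) and `doc_topic.csv` keyed by
#' `(actor_id, year, week)`.
#'
#' @param selection a `model_selection`.
#' @param corpus the corpus the selection was run on (for document keys).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_model_report <- function(selection, corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sel <- selection$selected
  jsonlite::write_json(list(
    master_seed = selection$master_seed,
    selected = list(n_topics = sel$n_topics, seed = sel$seed, bic = sel$bic,
                    log_likelihood = sel$log_likelihood),
    top_tokens = selection$top_tokens,
    candidates = selection$candidates
  ), file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  write.csv(data.frame(topic = rownames(sel$topic_word), sel$topic_word,
                       check.names = FALSE),
            file.path(dir, "topic_word.csv"), row.names = FALSE)
  write.csv(data.frame(corpus$meta[, c("actor_id", "year", "week")],
                       sel$doc_topic, check.names = FALSE),
            file.path(dir, "doc_topic.csv"), row.names = FALSE)
  invisible(dir)
}

#' Infer document-topic distributions for a corpus under a fitted model
#'
#' Runs the variational E-step with the topic-word distributions fixed at
#' the fit's values; deterministic (no random initialization).
#'
#' @param fit an `lda_fit`.
#' @param corpus a `doc_corpus` on the same vocabulary.
#' @return matrix (documents x topics), rows summing to 1.
#' @export
assign_topic_distributions <- function(fit, corpus) {
  stopifnot(inherits(fit, "lda_fit"), inherits(corpus, "doc_corpus"))
  if (!identical(fit$vocabulary, corpus$vocabulary)) {
    stop("vocabulary mismatch between fit and corpus", call. = FALSE)
  }
  K <- fit$n_topics
  D <- nrow(corpus$counts)
  Ndense <- as.matrix(corpus$counts)
  expElogbeta <- pmax(fit$topic_word, 1e-300) # posterior-mean topics, fixed
  gamma <- matrix(fit$alpha + mean(rowSums(Ndense)) / K, D, K)
  expElogtheta <- dir_expectation(gamma)
  for (e in seq_len(100L)) {
    Z <- expElogtheta %*% expElogbeta + 1e-100
    gamma_new <- fit$alpha + expElogtheta * ((Ndense / Z) %*% t(expElogbeta))
    delta <- mean(abs(gamma_new - gamma))
    gamma <- gamma_new
    expElogtheta <- dir_expectation(gamma)
    if (delta < 1e-6) break
  }
  out <- gamma / rowSums(gamma)
  colnames(out) <- rownames(fit$topic_word)
  out
}
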