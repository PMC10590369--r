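# Activity-weighted Jensen-Shannon dissimilarity between actors:
#
#   d_ij = sum_t w_ij(t) * JS(P_i(t) || P_j(t)),
#   w_ij(t) = C_i(t) C_j(t) / sum_tau C_i(tau) C_j(tau),
#
# a weighted average of weekly Jensen-Shannon distances between the two
# actors' theme distributions, weights proportional to the product of their
# weekly event counts: similarity is determined mostly by the weeks where
# both actors are highly active. Although the JS distance is a metric, this
# weighted average is not guaranteed to be a metric (the weights differ per
# pair), hence "dissimilarity".

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(p, q) = (KL(p || m) + KL(q || m)) / 2` with `m = (p + q) / 2`,
#' using the convention `0 log 0 = 0`. With base-2 logarithms the divergence
#' lies in `[0, 1]`.
#'
#' @param p,q probability vectors of equal length (non-negative, summing to
#'   1 within `tol`).
#' @param base logarithm base, 2 (default, bounded by 1) or `exp(1)`.
#' @param tol validation tolerance on the sums.
#' @return divergence value.
#' @export
js_divergence <- function(p, q, base = 2, tol = 1e-8) {
  if (length(p) != length(q)) stop("p and q must have equal length", call. = FALSE)
  check_distribution(p, "p", tol)
  check_distribution(q, "q", tol)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log(a[nz], base) - log(b[nz], base)))
  }
  max(0, (kl(p, m) + kl(q, m)) / 2)
}

#' Jensen-Shannon distance
#'
#' The square root of [js_divergence()] — the standard metric form, in
#' `[0, 1]` with base-2 logarithms. Zero iff `p == q`; 1 exactly for
#' distributions with disjoint support (base 2).
#'
#' @inheritParams js_divergence
#' @return distance value.
#' @export
js_distance <- function(p, q, base = 2, tol = 1e-8) {
  sqrt(js_divergence(p, q, base = base, tol = tol))
}

#' Pairwise weekly activity weights
#'
#' `w_ij(t) = C_i(t) C_j(t) / sum_tau C_i(tau) C_j(tau)`. Weights are zero
#' whenever either actor is inactive, and sum to 1 whenever at least one
#' co-active week exists. If no week has both actors active, the all-zero
#' vector is returned (the caller decides how to handle the undefined pair).
#'
#' @param C_i,C_j non-negative weekly event counts, equal length.
#' @return numeric weight vector of the same length.
#' @export
pair_weights <- function(C_i, C_j) {
  if (length(C_i) != length(C_j)) stop("count vectors must have equal length",
                                       call. = FALSE)
  if (any(C_i < 0) || any(C_j < 0)) stop("counts must be non-negative",
                                         call. = FALSE)
  prod <- as.numeric(C_i) * as.numeric(C_j)
  s <- sum(prod)
  if (s == 0) return(rep(0, length(prod)))
  prod / s
}

#' Activity-weighted JS dissimilarity matrix over all actor pairs
#'
#' For each pair of actors, computes the weighted average of weekly JS
#' distances between their theme distributions, with weights proportional to
#' the product of weekly event counts. Weeks where either actor is inactive
#' carry zero weight and never influence the value. Pairs with no co-active
#' week are recorded in `undefined_pairs` and assigned the `missing_pair`
#' fallback: `"max"` (default) sets the maximal dissimilarity 1 (such actors
#' share no observed behavior), `"drop"` leaves `NA` (exclude those actors
#' before clustering).
#'
#' @param processes a `theme_process_set` (all on the same week window and
#'   theme space).
#' @param log_base JS logarithm base (2 or `exp(1)`).
#' @param missing_pair `"max"` or `"drop"`.
#' @param sqrt_js use the JS distance (square root, default) rather than the
#'   raw divergence.
#' @return a `dissim_matrix`: list with `D` (symmetric matrix, zero
#'   diagonal, actor ids as dimnames) and `undefined_pairs` (tibble
#'   `actor_i, actor_j`).
#' @export
pairwise_dissimilarity <- function(processes, log_base = 2,
                                   missing_pair = c("max", "drop"),
                                   sqrt_js = TRUE) {
  stopifnot(inherits(processes, "theme_process_set"))
  missing_pair <- match.arg(missing_pair)
  actors <- names(processes$processes)
  n <- length(actors)
  if (n < 2L) stop("need at least 2 processes", call. = FALSE)
  Cmat <- vapply(processes$processes, function(p) as.numeric(p$C),
                 numeric(length(processes$weeks)))
  Plist <- lapply(processes$processes, `[[`, "P")
  # Precompute per-actor weekly JS building blocks lazily: loop over pairs,
  # vectorized over the (few) co-active weeks.
  D <- matrix(0, n, n, dimnames = list(actors, actors))
  undef <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      w <- pair_weights(Cmat[, i], Cmat[, j])
      if (sum(w) == 0) {
        undef[[length(undef) + 1L]] <- c(actors[i], actors[j])
        D[i, j] <- D[j, i] <- if (missing_pair == "max") 1 else NA_real_
        next
      }
      act <- which(w > 0)
      Pi <- Plist[[i]][act, , drop = FALSE]
      Pj <- Plist[[j]][act, , drop = FALSE]
      M <- (Pi + Pj) / 2
      xlx <- function(a, b) ifelse(a > 0, a * (log(a, log_base) - log(b, log_base)), 0)
      jsd <- (rowSums(xlx(Pi, M)) + rowSums(xlx(Pj, M))) / 2
      jsd <- pmax(jsd, 0)
      val <- if (sqrt_js) sqrt(jsd) else jsd
      D[i, j] <- D[j, i] <- sum(w[act] * val)
    }
  }
  undefined_pairs <- if (length(undef)) {
    m <- do.call(rbind, undef)
    tibble::tibble(actor_i = m[, 1], actor_j = m[, 2])
  } else {
    tibble::tibble(actor_i = character(), actor_j = character())
  }
  if (nrow(undefined_pairs)) {
    warning(nrow(undefined_pairs),
            " actor pair(s) share no co-active week; fallback = ",
            missing_pair, call. = FALSE)
  }
  structure(list(D = D, undefined_pairs = undefined_pairs,
                 log_base = log_base, sqrt_js = sqrt_js),
            class = "dissim_matrix")
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("dissim_matrix: %d actors, %d undefined pair(s)\n",
              nrow(x$D), nrow(x$undefined_pairs)))
  invisible(x)
}

#' Write a dissimilarity matrix as square CSV
#'
#' Actor ids form the header row and first column. With
#' `phylip = TRUE` additionally writes a Phylip-style lower-triangle file
#' alongside (same path with extension `.phy`).
#'
#' @param dm a `dissim_matrix` (or plain symmetric matrix).
#' @param path output CSV path.
#' @param phylip also emit lower-triangle Phylip format?
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(dm, path, phylip = FALSE) {
  D <- if (inherits(dm, "dissim_matrix")) dm$D else dm
  write.csv(data.frame(actor_id = rownames(D), D, check.names = FALSE),
            path, row.names = FALSE)
  if (phylip) {
    con <- file(sub("\\.[^.]*$", ".phy", path), "w")
    on.exit(close(con))
    writeLines(sprintf("%d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste(c(rownames(D)[i],
                         sprintf("%.10f", D[i, seq_len(i - 1)])),
                       collapse = " "), con)
    }
  }
  invisible(path)
}
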