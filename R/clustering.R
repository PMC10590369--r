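# Complete-linkage agglomerative clustering on a precomputed dissimilarity
# matrix. Implemented directly (Lance-Williams max-update) so the
# tie-breaking rule is explicit and results are bit-reproducible: when two
# pairs share the minimal dissimilarity, the pair with the lexicographically
# smallest cluster indices is merged, where leaves carry their input order
# 1..n and merged clusters take indices n+1, n+2, ... in creation order.
# The result is an `hclust`-compatible object, so stats::cutree() and
# ape::as.phylo() apply directly.

#' Complete-linkage agglomerative clustering
#'
#' Inter-cluster dissimilarity is the maximum pairwise dissimilarity between
#' members; merge heights are therefore non-decreasing for any input
#' dissimilarity.
#'
#' @param D a `dissim_matrix` from [pairwise_dissimilarity()], or a
#'   symmetric numeric matrix with zero diagonal.
#' @return an object of class `hclust` (`merge`, `height`, `order`,
#'   `labels`, `method = "complete"`).
#' @export
complete_linkage <- function(D) {
  M <- if (inherits(D, "dissim_matrix")) D$D else as.matrix(D)
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(is.na(M))) {
    stop("dissimilarity matrix has NA entries (undefined pairs); ",
         "use missing_pair = \"max\" or drop those actors", call. = FALSE)
  }
  if (!isSymmetric(unname(M), tol = 1e-12)) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(M) != 0)) stop("diagonal must be zero", call. = FALSE)
  labels <- rownames(M)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # Active clusters keyed by id: leaves are -1..-n (hclust convention uses
  # negative leaf ids in `merge`); internal ordering ids 1..n for leaves,
  # n+step for merges, used for the lexicographic tie-break.
  active <- seq_len(n)             # order ids of active clusters
  merge_ref <- -seq_len(n)         # hclust merge entry for each active cluster
  members <- as.list(seq_len(n))   # leaf sets, for `order` computation
  W <- M                           # current inter-cluster dissimilarities
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  member_sets <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    # Find the minimal off-diagonal entry; ties -> smallest (i, j) by the
    # order ids in `active`.
    best <- c(NA_integer_, NA_integer_)
    best_val <- Inf
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        v <- W[a, b]
        if (v < best_val) {
          best_val <- v
          best <- c(a, b)
        }
      }
    }
    a <- best[1L]; b <- best[2L]
    merge[step, ] <- c(merge_ref[a], merge_ref[b])
    height[step] <- best_val
    member_sets[[step]] <- c(members[[a]], members[[b]])
    # Lance-Williams complete-linkage update: d(new, x) = max(d(a,x), d(b,x)).
    new_row <- pmax(W[a, ], W[b, ])[-c(a, b)]
    keep <- setdiff(seq_len(k), c(a, b))
    W <- W[keep, keep, drop = FALSE]
    W <- rbind(cbind(W, new_row), c(new_row, 0))
    members <- c(members[keep], list(member_sets[[step]]))
    merge_ref <- c(merge_ref[keep], step)
    active <- c(active[keep], n + step)
  }
  # hclust orders merge entries so that singletons come first within a row
  # and earlier merges before later ones; also requires `order` such that
  # leaves of each merge are contiguous. member_sets of the last merge give
  # a valid leaf ordering.
  merge <- t(apply(merge, 1L, function(r) {
    if (r[1] > 0 && r[2] > 0) sort(r) else if (r[2] < 0 && r[1] > 0) rev(r)
    else if (r[1] < 0 && r[2] < 0) -sort(-r) else r
  }))
  structure(list(
    merge = merge, height = height,
    order = member_sets[[n - 1L]],
    labels = labels, method = "complete",
    call = match.call(), dist.method = "activity-weighted JS"
  ), class = "hclust")
}

#' Cut a dendrogram into flat clusters
#'
#' Either a fixed number of clusters `k` or a fixed dissimilarity threshold
#' `height` (clusters are merged at or below the threshold).
#'
#' @param dendrogram an `hclust` object from [complete_linkage()].
#' @param k number of clusters (1..n).
#' @param height dissimilarity threshold (used when `k` is `NULL`).
#' @return named integer vector: actor id -> cluster index in `1..k`.
#' @export
cut_clusters <- function(dendrogram, k = NULL, height = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (is.null(k) && is.null(height)) stop("supply k or height", call. = FALSE)
  if (!is.null(k)) {
    if (!is_count(k, 1L) || k > n) {
      stop("k must be an integer in 1..", n, call. = FALSE)
    }
    stats::cutree(dendrogram, k = k)
  } else {
    stats::cutree(dendrogram, h = height)
  }
}

#' Export a dendrogram as Newick text
#'
#' Leaf names are actor ids; branch lengths derive from merge heights
#' (ultrametric).
#'
#' @param dendrogram an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Mean silhouette width for a range of cluster counts
#'
#' A diagnostic only: the choice of the cluster count is left to the
#' analyst (the canonical analysis fixes six clusters); this report never
#' auto-selects.
#'
#' @param D a `dissim_matrix` or symmetric matrix.
#' @param dendrogram an `hclust` from [complete_linkage()] on `D`.
#' @param ks integer vector of candidate cluster counts (each in `2..n-1`).
#' @return tibble `k, mean_silhouette`.
#' @export
silhouette_by_k <- function(D, dendrogram, ks = 2:8) {
  M <- if (inherits(D, "dissim_matrix")) D$D else as.matrix(D)
  n <- nrow(M)
  ks <- ks[ks >= 2 & ks <= n - 1L]
  rows <- lapply(ks, function(k) {
    lab <- cut_clusters(dendrogram, k = k)
    s <- vapply(seq_len(n), function(i) {
      own <- lab == lab[i]
      a_i <- if (sum(own) > 1L) mean(M[i, own & seq_len(n) != i]) else 0
      b_i <- min(vapply(setdiff(unique(lab), lab[i]),
                        function(g) mean(M[i, lab == g]), numeric(1)))
      if (sum(own) > 1L) (b_i - a_i) / max(a_i, b_i) else 0
    }, numeric(1))
    tibble::tibble(k = k, mean_silhouette = mean(s))
  })
  dplyr::bind_rows(rows)
}
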