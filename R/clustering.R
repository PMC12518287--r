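# k-means and complete-linkage hierarchical clustering, automated k
# selection, and set-overlap concordance between partitions.

#' Construct a partition
#'
#' @param item_ids Character vector of item identifiers.
#' @param labels Integer cluster labels in 1..k, one per item; every
#'   cluster must be non-empty.
#' @return An object of class `"partition"` with `item_ids`, `labels`,
#'   `k`.
#' @export
partition <- function(item_ids, labels) {
  item_ids <- as.character(item_ids)
  labels <- as.integer(labels)
  if (length(item_ids) != length(labels))
    stop("item_ids and labels differ in length")
  k <- max(labels)
  if (min(labels) < 1L || !all(seq_len(k) %in% labels))
    stop("labels must cover 1..k with every cluster non-empty")
  structure(list(item_ids = item_ids, labels = labels, k = k),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d items in %d clusters (sizes %s)\n",
              length(x$item_ids), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

partition_sets <- function(p) {
  split(p$item_ids, p$labels)
}

# k-means++ seeding: first center uniform, subsequent centers sampled
# with probability proportional to squared distance to the nearest
# chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((X - matrix(X[centers[i + 1L], ], n, ncol(X),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

#' k-means clustering with seeded restarts
#'
#' Lloyd's algorithm started from k-means++ centers; `restarts`
#' independent seedings are run and the solution with the smallest total
#' within-cluster sum of squares is kept. Deterministic given `seed`.
#'
#' @param X Numeric items x features matrix (rownames are item ids).
#' @param k Number of clusters (<= number of items).
#' @param seed Integer random seed (required).
#' @param restarts Number of k-means++ restarts (default 10).
#' @return A [partition()] with attributes `wss` (total within-cluster
#'   sum of squares) and `centers`.
#' @export
kmeans_cluster <- function(X, k, seed, restarts = 10L) {
  if (missing(seed)) stop("seed is required for reproducibility")
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k cannot exceed the number of items")
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(X, k)
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, algorithm = "Lloyd",
                    iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  out <- partition(ids, best$cluster)
  attr(out, "wss") <- best$tot.withinss
  attr(out, "centers") <- best$centers
  out
}

#' Within-cluster sum-of-squares curve and elbow selection
#'
#' `wss_curve` computes the total within-cluster sum of squares for
#' k = 1..k_max; `select_k_elbow` picks the k maximizing the discrete
#' second difference WSS(k-1) - 2 WSS(k) + WSS(k+1), the automated
#' counterpart of reading the elbow off the curve. The curve is attached
#' so a human can override the choice.
#'
#' @param X Numeric items x features matrix.
#' @param k_max Largest k to evaluate (>= 3 for elbow selection).
#' @param seed Integer random seed.
#' @return `wss_curve`: numeric vector of WSS for k = 1..k_max.
#'   `select_k_elbow`: the chosen k (integer) with attribute `wss`.
#' @export
wss_curve <- function(X, k_max, seed) {
  X <- as.matrix(X)
  vapply(seq_len(k_max), function(k) {
    if (k == 1L) sum(sweep(X, 2L, colMeans(X))^2)
    else attr(kmeans_cluster(X, k, seed = seed + k), "wss")
  }, numeric(1))
}

#' @rdname wss_curve
#' @export
select_k_elbow <- function(X, k_max, seed) {
  X <- as.matrix(X)
  if (nrow(X) < 4L) {
    warning("fewer than 4 items; returning k = 2")
    return(structure(2L, wss = NULL))
  }
  if (k_max < 3L) stop("k_max must be at least 3")
  k_max <- min(k_max, nrow(X))
  wss <- wss_curve(X, k_max, seed)
  # second difference defined for k = 2..(k_max-1)
  ks <- 2:(k_max - 1L)
  curv <- wss[ks - 1L] - 2 * wss[ks] + wss[ks + 1L]
  structure(ks[which.max(curv)], wss = wss)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with the complete (maximum) linkage, cut
#' into k clusters.
#'
#' @param D Symmetric pairwise distance matrix with zero diagonal (or a
#'   `dist` object).
#' @param k Number of clusters.
#' @return A [partition()] with attribute `hclust` (the merge tree).
#' @export
hier_cluster <- function(D, k) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D), tol = 1e-8))
      stop("distance matrix must be symmetric")
    D <- stats::as.dist(D)
  }
  hc <- stats::hclust(D, method = "complete")
  labels <- stats::cutree(hc, k = k)
  ids <- hc$labels %||% as.character(seq_along(labels))
  out <- partition(ids, labels)
  attr(out, "hclust") <- hc
  out
}

#' Choose k by maximal mean silhouette width
#'
#' Cuts the complete-linkage tree at each k in 2..k_max and evaluates
#' the mean silhouette width; returns the arg-max (ties resolved to the
#' smallest k).
#'
#' @param D Distance matrix or `dist` object over >= 3 items.
#' @param k_max Largest k to consider.
#' @return The chosen k (integer) with attribute `silhouette` (mean
#'   width per k).
#' @export
select_k_silhouette <- function(D, k_max) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D), tol = 1e-8))
      stop("distance matrix must be symmetric")
    D <- stats::as.dist(D)
  }
  n <- attr(D, "Size")
  stopifnot(n >= 3L)
  ks <- 2:min(k_max, n - 1L)
  hc <- stats::hclust(D, method = "complete")
  widths <- vapply(ks, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), D)
    mean(sil[, "sil_width"])
  }, numeric(1))
  structure(ks[which.max(widths)], silhouette = stats::setNames(widths, ks))
}

#' Set-overlap coefficients
#'
#' Simpson: |A intersect B| / min(|A|, |B|); Jaccard:
#' |A intersect B| / |A union B|.
#'
#' @param A,B Non-empty vectors treated as sets.
#' @param mode `"simpson"` or `"jaccard"`.
#' @return Overlap coefficient in \[0, 1\].
#' @export
set_coefficient <- function(A, B, mode = c("simpson", "jaccard")) {
  mode <- match.arg(mode)
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B)) stop("sets must be non-empty")
  inter <- length(intersect(A, B))
  if (mode == "simpson") inter / min(length(A), length(B))
  else inter / length(union(A, B))
}

#' Concordance between two partitions
#'
#' The integral similarity between two clusterings of the same items:
#' for each cluster of the partition with more clusters (tie: the
#' first), the best-matching set coefficient against the clusters of the
#' other partition is taken, and the sum is divided by max(|P|, |Q|).
#' With the Simpson coefficient, S = 1 indicates that every smaller
#' cluster is embedded in some larger one; with Jaccard, S = 1 only for
#' identical partitions.
#'
#' @param P,Q [partition()]s over the same item set.
#' @param mode `"simpson"` or `"jaccard"`.
#' @return A list with `S`, `mode`, `per_cluster_terms`.
#' @export
partition_concordance <- function(P, Q, mode = c("simpson", "jaccard")) {
  mode <- match.arg(mode)
  sd_items <- c(setdiff(P$item_ids, Q$item_ids),
                setdiff(Q$item_ids, P$item_ids))
  if (length(sd_items))
    stop("partitions cover different items: ",
         paste(sd_items, collapse = ", "))
  larger <- if (Q$k > P$k) Q else P
  other <- if (Q$k > P$k) P else Q
  Ls <- partition_sets(larger)
  Os <- partition_sets(other)
  terms <- vapply(Ls, function(cl)
    max(vapply(Os, function(dl) set_coefficient(cl, dl, mode), numeric(1))),
    numeric(1))
  list(S = sum(terms) / max(P$k, Q$k), mode = mode,
       per_cluster_terms = unname(terms))
}
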