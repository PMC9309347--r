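#' Spectral embedding of a network
#'
#' Coordinates are the first `dim` nontrivial eigenvectors (smallest
#' eigenvalues, skipping the trivial one) of the symmetric normalized
#' Laplacian `I - D^{-1/2} A D^{-1/2}`, with rows normalized to unit
#' length. Eigenvector signs are fixed by making each vector's
#' largest-magnitude entry positive, so the embedding is deterministic.
#' Degree-0 nodes get zero coordinates.
#'
#' @param net an [build_network()] result or an igraph.
#' @param dim embedding dimension (>= 2, < number of nodes).
#' @return numeric matrix, one row per node (rownames = node ids).
#' @export
spectral_embedding <- function(net, dim = 12) {
  g <- if (inherits(net, "interaction_network")) net$graph else net
  n <- igraph::vcount(g)
  dim <- check_count(dim, "dim", min = 2L)
  if (dim >= n) stop("`dim` must be smaller than the number of nodes", call. = FALSE)

  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  k <- igraph::degree(g)
  dinv <- ifelse(k > 0, 1 / sqrt(k), 0)
  L <- diag(n) - (dinv %o% dinv) * A
  eg <- eigen(L, symmetric = TRUE)
  # eigen() returns eigenvalues in decreasing order; smallest is trivial
  idx <- rev(seq_len(n))[2:(dim + 1L)]
  U <- eg$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  nrm <- sqrt(rowSums(U^2))
  U <- U / ifelse(nrm > 0, nrm, 1)
  rownames(U) <- igraph::V(g)$name
  U
}

# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- colSums((t(x) - x[centers[1], ])^2)
    for (j in 2:k) {
      avail <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      w <- d2[avail]
      centers[j] <- if (sum(w) > 0) avail[sample.int(length(avail), 1, prob = w)]
                    else avail[sample.int(length(avail), 1)]
      d2 <- pmin(d2, colSums((t(x) - x[centers[j], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' K-means with k-means++ restarts
#'
#' Runs `n_restarts` Lloyd fits from k-means++ initializations and keeps
#' the lowest-inertia solution; deterministic for a fixed seed.
#'
#' @param coords numeric matrix of points (rownames kept as labels).
#' @param k number of clusters (1 <= k <= number of points).
#' @param n_restarts restarts (default 20).
#' @param seed integer seed.
#' @return list `assignment` (named integer vector, labels 1..k),
#'   `inertia` (total within-cluster sum of squares), `k`.
#' @export
kmeans_fit <- function(coords, k, n_restarts = 20, seed = 1) {
  k <- check_count(k, "k")
  n_restarts <- check_count(n_restarts, "n_restarts")
  if (k > nrow(coords)) stop("`k` exceeds the number of points", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(coords, k)
      km <- suppressWarnings(
        kmeans(coords, centers = centers, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(assignment = stats::setNames(best$cluster, rownames(coords)),
         inertia = best$tot.withinss, k = k)
  })
}

#' Select the cluster count at the elbow of an inertia curve
#'
#' The elbow is the interior K maximizing the discrete second difference
#' `I(K-1) - 2 I(K) + I(K+1)` of the inertia curve; ties go to the
#' smallest K. Invariant to affine rescaling of the curve.
#'
#' @param inertia_curve named numeric vector, names = contiguous K values,
#'   at least 4 points.
#' @return the selected K.
#' @export
elbow_select <- function(inertia_curve) {
  ks <- as.integer(names(inertia_curve))
  if (length(ks) < 4L) stop("need at least 4 points on the inertia curve", call. = FALSE)
  if (any(diff(ks) != 1L)) stop("K range must be contiguous", call. = FALSE)
  inner <- 2:(length(ks) - 1L)
  d2 <- inertia_curve[inner - 1L] - 2 * inertia_curve[inner] + inertia_curve[inner + 1L]
  ks[inner][which.max(d2)]
}

#' Partition a network into modules by spectral K-means with elbow K
#'
#' Embeds the network spectrally, sweeps K over `k_range` recording the
#' best K-means inertia at each K, picks K at the elbow, and returns the
#' assignment at the selected K.
#'
#' @param net an [build_network()] result or an igraph.
#' @param k_range candidate cluster counts (default 2:20).
#' @param dim embedding dimension (default 12).
#' @param n_restarts K-means restarts per K.
#' @param seed integer seed.
#' @return list of class `cluster_result`: `assignment`, `k_selected`,
#'   `inertia_curve`, `embedding_dim`, `seed`.
#' @export
cluster_network <- function(net, k_range = 2:20, dim = 12, n_restarts = 20,
                            seed = 1) {
  coords <- spectral_embedding(net, dim = dim)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(coords))
    stop("`k_range` exceeds the number of nodes", call. = FALSE)
  fits <- lapply(seq_along(k_range), function(i)
    kmeans_fit(coords, k_range[i], n_restarts = n_restarts, seed = seed + i))
  curve <- stats::setNames(vapply(fits, `[[`, numeric(1), "inertia"),
                           k_range)
  k_sel <- elbow_select(curve)
  structure(list(assignment = fits[[match(k_sel, k_range)]]$assignment,
                 k_selected = k_sel, inertia_curve = curve,
                 embedding_dim = dim, seed = seed),
            class = "cluster_result")
}
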