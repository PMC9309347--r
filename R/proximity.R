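# per-node proximity summaries against the signature: minimum ("closest")
# or mean ("average") hop distance to signature members, with unreachable
# pairs penalized at n_nodes (finite, larger than any real distance)
node_proximity_vector <- function(net, signature, metric = c("closest", "average")) {
  metric <- match.arg(metric)
  g <- net$graph
  penalty <- igraph::vcount(g)
  ds <- igraph::distances(g, v = signature, to = igraph::V(g))
  ds[is.infinite(ds)] <- penalty
  if (metric == "closest") apply(ds, 2, min) else colMeans(ds)
}

resolve_ids <- function(ids, net, what) {
  present <- intersect(unique(unlist(ids, use.names = FALSE)), net$nodes)
  absent <- setdiff(unique(unlist(ids, use.names = FALSE)), net$nodes)
  if (length(absent))
    message(length(absent), " ", what, " id(s) not in the network, scored on the rest")
  if (length(present) == 0L)
    stop("no ", what, " ids resolve in the network", call. = FALSE)
  present
}

#' Shortest-distance proximity between a target set and the signature
#'
#' The "closest" metric (default) averages, over targets, each target's
#' minimum hop distance to any signature member; "average" takes the mean
#' over all target-signature pairs. Unreachable pairs contribute the
#' penalty distance `n_nodes`. Ids absent from the network are logged and
#' the score is computed on the rest.
#'
#' @param net an [build_network()] result.
#' @param targets,signature character vectors of protein ids.
#' @param metric `"closest"` or `"average"`.
#' @return the observed proximity (hops).
#' @export
proximity_score <- function(net, targets, signature,
                            metric = c("closest", "average")) {
  metric <- match.arg(metric)
  stopifnot(inherits(net, "interaction_network"))
  targets <- resolve_ids(targets, net, "target")
  signature <- resolve_ids(signature, net, "signature")
  v <- node_proximity_vector(net, signature, metric)
  mean(v[targets])
}

# log2-width degree bins over the network's nodes, merged upward until each
# bin holds at least `min_bin` candidates (top bin merges downward)
degree_bins <- function(g, min_bin = 10L) {
  k <- igraph::degree(g)
  bin <- ifelse(k == 0, 0L, floor(log2(k)) + 1L)
  names(bin) <- igraph::V(g)$name
  lev <- sort(unique(bin))
  i <- 1L
  while (i < length(lev)) {
    if (sum(bin == lev[i]) < min_bin) {
      bin[bin == lev[i]] <- lev[i + 1L]
      lev <- lev[-i]
    } else i <- i + 1L
  }
  # top bin: merge downward if starved
  while (length(lev) > 1L && sum(bin == lev[length(lev)]) < min_bin) {
    bin[bin == lev[length(lev)]] <- lev[length(lev) - 1L]
    lev <- lev[-length(lev)]
  }
  if (any(table(bin) < min_bin))
    stop("network too small for degree-matched sampling (a bin has fewer than ",
         min_bin, " candidates after merging)", call. = FALSE)
  bin
}

#' Degree-matched permutation null for a proximity score
#'
#' Repeatedly redraws a target-sized node set matching the observed targets'
#' degrees (log2-width degree bins, merged upward when a bin has fewer than
#' 10 candidates; nodes drawn without replacement within a permutation) and
#' recomputes the proximity, yielding a z-score and an empirical one-sided
#' p-value with the (r + 1)/(n + 1) correction, where r counts null
#' proximities at or below the observed one (small = closer than chance).
#'
#' @inheritParams proximity_score
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; same seed gives identical output.
#' @return list `d_obs`, `null_mean`, `null_sd`, `z`, `p_emp`, `n_perm`,
#'   `degenerate` (TRUE when the null is constant, in which case `z` is NA
#'   but `p_emp` is still reported).
#' @export
degree_matched_null <- function(net, targets, signature, n_perm = 1000,
                                seed = 1, metric = c("closest", "average")) {
  metric <- match.arg(metric)
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  targets <- resolve_ids(targets, net, "target")
  signature <- resolve_ids(signature, net, "signature")
  v <- node_proximity_vector(net, signature, metric)
  d_obs <- mean(v[targets])

  bin <- degree_bins(net$graph)
  tbins <- bin[targets]
  groups <- split(targets, tbins)
  cand <- lapply(names(groups), function(b) names(bin)[bin == as.integer(b)])

  null_d <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      picked <- unlist(lapply(seq_along(groups), function(j)
        sample(cand[[j]], length(groups[[j]]))), use.names = FALSE)
      mean(v[picked])
    }, numeric(1))
  })
  null_mean <- mean(null_d)
  null_sd <- sd(null_d)
  degenerate <- null_sd == 0
  z <- if (degenerate) NA_real_ else (d_obs - null_mean) / null_sd
  p_emp <- (sum(null_d <= d_obs) + 1) / (n_perm + 1)
  list(d_obs = d_obs, null_mean = null_mean, null_sd = null_sd, z = z,
       p_emp = p_emp, n_perm = n_perm, degenerate = degenerate)
}

#' Rank every non-signature protein by proximity to the signature
#'
#' Scores each node outside the signature as a singleton target set against
#' its own degree-matched null and returns the list ordered by ascending
#' z (most disease-associated first), ties broken by id; nodes with a
#' degenerate (constant) null sort after all defined z values.
#'
#' @inheritParams degree_matched_null
#' @return data frame `id`, `d_obs`, `null_mean`, `null_sd`, `z`, `p_emp`,
#'   `rank`.
#' @export
rank_all_proteins <- function(net, signature, n_perm = 1000, seed = 1,
                              metric = c("closest", "average")) {
  metric <- match.arg(metric)
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  signature <- resolve_ids(signature, net, "signature")
  candidates <- sort(setdiff(net$nodes, signature))
  if (length(candidates) == 0L)
    return(data.frame(id = character(0), d_obs = numeric(0),
                      null_mean = numeric(0), null_sd = numeric(0),
                      z = numeric(0), p_emp = numeric(0), rank = integer(0)))
  v <- node_proximity_vector(net, signature, metric)
  bin <- degree_bins(net$graph)

  rows <- with_seed(seed, {
    lapply(candidates, function(id) {
      cand <- names(bin)[bin == bin[[id]]]
      vals <- v[sample(cand, n_perm, replace = TRUE)]
      mu <- mean(vals); s <- sd(vals)
      d <- unname(v[[id]])
      data.frame(id = id, d_obs = d, null_mean = mu, null_sd = s,
                 z = if (s == 0) NA_real_ else (d - mu) / s,
                 p_emp = (sum(vals <= d) + 1) / (n_perm + 1),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  o <- order(out$z, out$id, na.last = TRUE)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  row.names(out) <- NULL
  out
}

#' Neighborhood of a drug target within the disease network
#'
#' All nodes within `radius` hops of the target (including the target), a
#' working definition of the target's mechanism-of-action subnetwork.
#'
#' @param net an [build_network()] result.
#' @param target a node id.
#' @param radius hop radius (default 1: direct interactors).
#' @return character vector of node ids.
#' @export
mechanism_subnetwork <- function(net, target, radius = 1) {
  radius <- check_count(radius, "radius", min = 0L)
  if (!target %in% net$nodes)
    stop("unknown target id: ", target, call. = FALSE)
  sort(igraph::ego(net$graph, order = radius, nodes = target)[[1]]$name)
}

#' Mechanism overlap between two drugs' target neighborhoods
#'
#' Jaccard index of the unions of the two target sets' radius-r
#' neighborhoods, plus the shared nodes themselves.
#'
#' @param net an [build_network()] result.
#' @param targets_a,targets_b character vectors of target ids.
#' @param radius hop radius (default 1).
#' @return list `jaccard`, `shared_nodes`, `radius`.
#' @export
mechanism_overlap <- function(net, targets_a, targets_b, radius = 1) {
  ta <- resolve_ids(targets_a, net, "target")
  tb <- resolve_ids(targets_b, net, "target")
  na_ <- unique(unlist(lapply(ta, mechanism_subnetwork, net = net, radius = radius)))
  nb <- unique(unlist(lapply(tb, mechanism_subnetwork, net = net, radius = radius)))
  shared <- sort(intersect(na_, nb))
  list(jaccard = length(shared) / length(union(na_, nb)),
       shared_nodes = shared, radius = radius)
}
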