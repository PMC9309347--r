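#' Normalize and threshold a scored interaction table
#'
#' Accepts both score dialects in circulation for STRING-style exports:
#' probabilities in \[0, 1\] or integers in 0-1000 (auto-detected: any score
#' above 1 switches to the integer dialect, divided by 1000). Self
#' interactions are dropped (logged), symmetric and repeated pairs are
#' collapsed keeping the maximum score, and only edges with score at or
#' above `min_score` are retained ("minimum score" read as attainable,
#' hence inclusive).
#'
#' @param tab data frame whose first three columns are protein1, protein2,
#'   combined_score.
#' @param min_score confidence threshold in \[0, 1\] (default 0.9).
#' @return data frame `protein1`, `protein2`, `combined_score` of class
#'   `interaction_table`.
#' @export
interaction_table <- function(tab, min_score = 0.9) {
  check_prob(min_score, "min_score")
  stopifnot(ncol(tab) >= 3L)
  tab <- tab[, 1:3]
  names(tab) <- c("protein1", "protein2", "combined_score")
  score <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(!is.finite(score))
  if (length(bad))
    stop("unparseable score at row ", bad[1], call. = FALSE)
  if (any(score > 1)) {
    if (any(score > 1000 | score < 0))
      stop("scores outside both the [0,1] and 0-1000 dialect ranges", call. = FALSE)
    score <- score / 1000
  } else if (any(score < 0)) {
    stop("negative interaction scores", call. = FALSE)
  }
  tab$combined_score <- score

  self <- tab$protein1 == tab$protein2
  if (any(self)) {
    message(sum(self), " self-interaction(s) dropped")
    tab <- tab[!self, , drop = FALSE]
  }
  tab <- tab[tab$combined_score >= min_score, , drop = FALSE]

  # collapse symmetric duplicates, keep max score
  a <- pmin(tab$protein1, tab$protein2)
  b <- pmax(tab$protein1, tab$protein2)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -tab$combined_score)
  keep <- !duplicated(key[o])
  out <- data.frame(protein1 = a[o][keep], protein2 = b[o][keep],
                    combined_score = tab$combined_score[o][keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein1, out$protein2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Load a scored interaction file
#'
#' Whitespace- or tab-delimited, three or more columns, with header
#' auto-detection (a non-numeric third field on the first line is treated
#' as a header). See [interaction_table()] for dialect handling and
#' thresholding.
#'
#' @param path input file.
#' @param min_score confidence threshold (default 0.9).
#' @return an `interaction_table`.
#' @export
load_interactions <- function(path, min_score = 0.9) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  has_header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(first[3])))
  tab <- tryCatch(
    read.table(path, header = has_header, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (ncol(tab) < 3L) stop("expected at least 3 columns in ", path, call. = FALSE)
  interaction_table(tab, min_score = min_score)
}

#' Build the disease + drug-target interaction network
#'
#' The node set is the union of the disease signature and all drug-target
#' ids; members without any retained interaction stay in the graph as
#' degree-0 nodes so that node counts follow set arithmetic. Edges are the
#' thresholded interactions with both endpoints in the node set. The full
#' pre-subsetting graph over every protein in the table (the "universe") is
#' retained for null models.
#'
#' @param table an [interaction_table()].
#' @param disease character vector of signature protein ids (non-empty).
#' @param targets named character vector or list, drug class -> target ids.
#' @return object of class `interaction_network`: list with `graph`
#'   (igraph over the selected nodes), `universe` (igraph over all table
#'   proteins plus the selected nodes), `nodes`, `disease`, `targets`.
#' @export
build_network <- function(table, disease, targets = character(0)) {
  if (length(disease) == 0L) stop("disease signature is empty", call. = FALSE)
  target_ids <- unique(unlist(targets, use.names = FALSE))
  nodes <- sort(unique(c(disease, target_ids)))

  univ_nodes <- sort(unique(c(table$protein1, table$protein2, nodes)))
  universe <- igraph::graph_from_data_frame(table, directed = FALSE,
                                            vertices = univ_nodes)
  absent <- setdiff(target_ids, c(disease, table$protein1, table$protein2))
  if (length(absent))
    message(length(absent), " target id(s) absent from the interaction universe kept as isolated nodes: ",
            paste(absent, collapse = ", "))

  keep <- table$protein1 %in% nodes & table$protein2 %in% nodes
  graph <- igraph::graph_from_data_frame(table[keep, , drop = FALSE],
                                         directed = FALSE, vertices = nodes)
  structure(list(graph = graph, universe = universe, nodes = nodes,
                 disease = sort(unique(disease)), targets = targets),
            class = "interaction_network")
}

#' Expected number of edges among the selected nodes under a degree null
#'
#' Chung-Lu (degree-product) expectation: for the selected node set S, sums
#' min(1, k_i * k_j / (2m)) over unordered pairs in S, with degrees k and
#' edge count m taken from the retained universe graph. This is the
#' package's defined, reproducible stand-in for a database platform's
#' "expected number of random connections".
#'
#' @param net an [build_network()] result.
#' @return the expectation (a single number).
#' @export
expected_random_edges <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  m <- igraph::ecount(net$universe)
  if (igraph::vcount(net$universe) == 0L) stop("empty universe", call. = FALSE)
  if (m == 0L) return(0)
  k <- igraph::degree(net$universe)[net$nodes]
  pmat <- pmin(outer(k, k) / (2 * m), 1)
  (sum(pmat) - sum(diag(pmat))) / 2
}

#' Upper-tail Poisson enrichment p-value for an observed edge count
#'
#' P(X >= observed | lambda = expected), evaluated in log space through the
#' regularized incomplete gamma function so that extreme tails (far below
#' 1e-16) are still resolved.
#'
#' @param observed observed edge count (non-negative integer).
#' @param expected null expectation (> 0).
#' @return p-value in (0, 1].
#' @export
enrichment_pvalue <- function(observed, expected) {
  observed <- check_count(observed, "observed", min = 0L)
  check_positive(expected, "expected")
  if (observed == 0L) return(1)
  # P(Pois(lambda) >= k) = P(Gamma(k, 1) <= lambda)
  exp(pgamma(expected, shape = observed, lower.tail = TRUE, log.p = TRUE))
}

#' Descriptive and enrichment statistics of a disease network
#'
#' @param net an [build_network()] result.
#' @return list `n_nodes`, `n_edges`, `expected_edges`, `enrichment_p`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  n_edges <- igraph::ecount(net$graph)
  expected <- expected_random_edges(net)
  p <- if (expected > 0) enrichment_pvalue(n_edges, expected) else NA_real_
  list(n_nodes = igraph::vcount(net$graph), n_edges = n_edges,
       expected_edges = expected, enrichment_p = p)
}

#' Unweighted shortest-path distances from a source set
#'
#' Breadth-first hop counts from each source to every node of the disease
#' network. Unreachable pairs are reported as `Inf`, never as a silent
#' large number; callers decide how to penalize them.
#'
#' @param net an [build_network()] result (or an igraph).
#' @param sources character vector of source node ids.
#' @return numeric matrix, rows = sources, columns = all nodes.
#' @export
shortest_paths_from <- function(net, sources) {
  g <- if (inherits(net, "interaction_network")) net$graph else net
  unknown <- setdiff(sources, igraph::V(g)$name)
  if (length(unknown))
    stop("unknown source id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  igraph::distances(g, v = sources, to = igraph::V(g))
}

#' Read a protein set from GMT or a one-id-per-line file
#'
#' @param path input file; `.gmt` files are parsed as gene-set collections
#'   (the first set is returned unless `set` names one).
#' @param set optional set name inside a GMT file.
#' @return character vector of ids.
#' @export
read_signature <- function(path, set = NULL) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- fgsea::gmtPathways(path)
    nm <- set %||% names(sets)[1]
    if (!nm %in% names(sets)) stop("set '", nm, "' not found in ", path, call. = FALSE)
    unique(sets[[nm]])
  } else {
    unique(trimws(readLines(path)[nzchar(trimws(readLines(path)))]))
  }
}

#' Default post-MI drug-target map
#'
#' The four first-line heart-failure drug classes and their primary
#' targets: ACE inhibitors (ACE), angiotensin-receptor blockers (AGTR1),
#' beta-blockers (ADRB1), and mineralocorticoid-receptor antagonists
#' (NR3C2).
#'
#' @return named character vector, drug class -> target protein.
#' @export
default_drug_targets <- function() {
  c(ACEi = "ACE", ARB = "AGTR1", beta_blocker = "ADRB1", MRA = "NR3C2")
}
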