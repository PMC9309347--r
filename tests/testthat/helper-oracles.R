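# independent oracles used across the suite; deliberately naive

# BH step-up, written from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# all-pairs shortest paths by Floyd-Warshall on an adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# build an interaction_network from a two-column edge matrix (all scores
# pass the default 0.9 cut); disease defaults to every node
toy_network <- function(edges, nodes = NULL, disease = NULL,
                        targets = character(0)) {
  edges <- matrix(as.character(edges), ncol = 2)
  tab <- interaction_table(data.frame(protein1 = edges[, 1],
                                      protein2 = edges[, 2],
                                      combined_score = 0.95))
  nodes <- nodes %||% sort(unique(c(edges)))
  disease <- disease %||% nodes
  suppressMessages(build_network(tab, disease, targets))
}

# random G(n, p) graph as an interaction_network with named nodes
random_network <- function(n, p, seed, score = 0.95) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
    el <- igraph::as_edgelist(g)
    nodes <- sprintf("N%03d", seq_len(n))
    if (nrow(el) == 0) el <- matrix(character(0), ncol = 2)
    tab <- interaction_table(data.frame(protein1 = el[, 1],
                                        protein2 = el[, 2],
                                        combined_score = score))
    suppressMessages(build_network(tab, disease = nodes))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
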