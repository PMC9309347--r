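test_that("gen_expression plants the requested differential genes", {
  se <- gen_expression(1000, 3, frac_de = 0.05, seed = 1)
  expect_length(se$de_genes, 50)
  expect_true(all(se$de_genes %in% rownames(se$matrix$values)))

  expect_length(gen_expression(100, 3, frac_de = 0, seed = 1)$de_genes, 0)

  # zero effect size: planted genes carry no real shift
  se0 <- gen_expression(2000, 10, frac_de = 0.1, effect_size = 0, seed = 2)
  fit <- fit_groups(se0$matrix)
  shifts <- fit$logfc[fit$gene %in% se0$de_genes]
  expect_lt(max(abs(shifts)), 1)  # pure noise at n = 10/group
  expect_equal(mean(shifts), 0, tolerance = 0.1)

  # a real effect is centred on effect_size
  se2 <- gen_expression(2000, 10, frac_de = 0.1, effect_size = 2, seed = 3)
  fit2 <- fit_groups(se2$matrix)
  expect_equal(mean(fit2$logfc[fit2$gene %in% se2$de_genes]), 2,
               tolerance = 0.05)

  expect_error(gen_expression(5, 3), "n_genes")
  expect_error(gen_expression(100, 1), "n_per_group")
  expect_error(gen_expression(100, 3, frac_de = 1.5), "frac_de")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_expression(50, 3, seed = 9), gen_expression(50, 3, seed = 9))
  expect_identical(gen_hit_tables(10, 20, seed = 9), gen_hit_tables(10, 20, seed = 9))
  expect_identical(gen_interactome(4, 10, 0.5, 0.05, seed = 9),
                   gen_interactome(4, 10, 0.5, 0.05, seed = 9))
  si <- gen_interactome(4, 10, 0.5, 0.05, seed = 9)
  expect_identical(gen_signature_and_targets(si, 5, 2, 1, seed = 9),
                   gen_signature_and_targets(si, 5, 2, 1, seed = 9))
})

test_that("hit tables carry planted orthologs recoverable by RBH", {
  h0 <- gen_hit_tables(5, 0, seed = 1)
  r0 <- suppressMessages(reciprocal_best_hits(h0$ab, h0$ba))
  expect_identical(r0, h0$truth)

  h <- gen_hit_tables(5, 50, seed = 7)
  r <- suppressMessages(reciprocal_best_hits(h$ab, h$ba))
  expect_setequal(paste(r$id_a, r$id_b), paste(h$truth$id_a, h$truth$id_b))

  # recovery is exact for arbitrary seeds, not just a lucky one
  for (s in 1:10) {
    h <- gen_hit_tables(8, 80, seed = s)
    r <- suppressMessages(reciprocal_best_hits(h$ab, h$ba))
    expect_setequal(paste(r$id_a, r$id_b), paste(h$truth$id_a, h$truth$id_b))
  }

  expect_error(gen_hit_tables(0), "n_orthologs")
})

test_that("gen_interactome respects block structure and score channel", {
  tri <- gen_interactome(2, 3, p_in = 1, p_out = 0, seed = 1)
  expect_equal(nrow(tri$interactions), 6)  # two complete triangles
  g <- igraph::graph_from_data_frame(tri$interactions[, 1:2], directed = FALSE)
  expect_equal(igraph::count_components(g), 2)

  empty <- gen_interactome(2, 3, p_in = 0, p_out = 0, seed = 1)
  expect_equal(nrow(empty$interactions), 0)

  expect_error(gen_interactome(2, 3, p_in = 0.1, p_out = 0.5), "p_out")

  si <- gen_interactome(5, 10, 0.4, 0.02, seed = 3)
  expect_true(all(si$interactions$combined_score >= 0.9 &
                  si$interactions$combined_score <= 1))
  noisy <- gen_interactome(5, 10, 0.4, 0.02, seed = 3, noisy_scores = TRUE)
  expect_true(any(noisy$interactions$combined_score < 0.9))
  expect_equal(unname(table(si$block_of)), rep(10L, 5L), ignore_attr = TRUE)
})

test_that("edge counts concentrate on the binomial expectation", {
  n_blocks <- 10; bs <- 25; p_in <- 0.25; p_out <- 0.01
  within_pairs <- n_blocks * choose(bs, 2)
  between_pairs <- choose(n_blocks * bs, 2) - within_pairs
  mu <- within_pairs * p_in + between_pairs * p_out
  sdv <- sqrt(within_pairs * p_in * (1 - p_in) +
              between_pairs * p_out * (1 - p_out))
  for (s in 1:20) {
    m <- nrow(gen_interactome(n_blocks, bs, p_in, p_out, seed = s)$interactions)
    expect_lt(abs(m - mu), 4 * sdv)
  }
})

test_that("signature and targets are planted at the requested distance", {
  si <- gen_interactome(10, 25, 0.25, 0.01, seed = 42)
  st <- gen_signature_and_targets(si, sig_size = 10, n_targets = 4,
                                  target_distance = 1, seed = 1)
  expect_length(st$signature, 10)
  expect_length(unique(si$block_of[st$signature]), 1)  # one block

  g <- igraph::graph_from_data_frame(si$interactions[, 1:2], directed = FALSE,
                                     vertices = si$nodes)
  d <- igraph::distances(g, v = st$signature, to = st$targets)
  expect_equal(unname(apply(d, 2, min)), rep(1, 4))

  # distance 0 means containment, hence proximity 0
  st0 <- gen_signature_and_targets(si, 10, 2, target_distance = 0, seed = 1)
  expect_true(all(st0$targets %in% st0$signature))
  net <- suppressMessages(build_network(interaction_table(si$interactions),
                                        si$nodes))
  expect_equal(proximity_score(net, st0$targets, st0$signature), 0)

  # distance 2 on a path: verified by BFS
  path_tab <- data.frame(protein1 = c("a", "b", "c"),
                         protein2 = c("b", "c", "d"),
                         combined_score = 0.95)
  pi2 <- structure(list(interactions = path_tab,
                        block_of = setNames(rep("B01", 4), letters[1:4]),
                        nodes = letters[1:4], p_in = 1, p_out = 0,
                        n_blocks = 1, block_size = 4),
                   class = "synthetic_interactome")
  st2 <- gen_signature_and_targets(pi2, sig_size = 1, n_targets = 1,
                                   target_distance = 2, seed = 5)
  gp <- igraph::graph_from_data_frame(path_tab[, 1:2], directed = FALSE)
  expect_equal(unname(igraph::distances(gp, st2$signature, st2$targets)[1, 1]), 2)

  expect_error(gen_signature_and_targets(si, 10, 4, target_distance = 50,
                                         seed = 1), "infeasible")
  expect_error(gen_signature_and_targets(si, 26, 4, 1, seed = 1), "block size")
})

test_that("written pipeline datasets round-trip through the readers", {
  dir <- withr::local_tempdir()
  ds <- gen_pipeline_dataset(n_blocks = 4, block_size = 10, sig_size = 8,
                             n_genes = 60, seed = 3)
  paths <- write_pipeline_dataset(ds, dir)
  em <- read_expression(paths$expression, paths$samples)
  expect_equal(em$values, ds$expression$matrix$values)
  expect_identical(read_signature(paths$signature), ds$signature)
  tab <- load_interactions(paths$interactions)
  expect_equal(nrow(tab), nrow(ds$interactome$interactions))
  orth <- suppressMessages(reciprocal_best_hits(read_hit_table(paths$hits_ab),
                                                read_hit_table(paths$hits_ba)))
  expect_setequal(paste(orth$id_a, orth$id_b),
                  paste(ds$hits$truth$id_a, ds$hits$truth$id_b))
})
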