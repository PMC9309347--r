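#' Simulate a two-group log-intensity expression matrix with planted effects
#'
#' Draws gene-wise true variances from a scaled inverse-chi-square prior
#' (`s0sq_true * d0_true / chisq(d0_true)`), the same hierarchical model the
#' moderated-t estimator assumes, so the empirical-Bayes hyperparameters are
#' recoverable ground truth. A fixed fraction of genes carries an additive
#' log2 mean shift in group B.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_per_group samples per group (>= 2); groups are labelled "A"
#'   (control) and "B" (case).
#' @param frac_de fraction of genes planted as differentially expressed.
#' @param effect_size log2 shift added to group B for planted genes.
#' @param d0_true,s0sq_true degrees of freedom and scale of the variance
#'   prior.
#' @param seed integer seed; identical arguments and seed give identical
#'   output.
#' @param de_genes optional character vector of gene ids to plant instead of
#'   a random draw (must be a subset of the generated ids); overrides
#'   `frac_de`.
#'
#' @return A list of class `synthetic_expression` with elements `matrix`
#'   (an [expression_matrix()]), `de_genes`, `effect_size`,
#'   `variance_prior` (`d0_true`, `s0sq_true`) and `sigma2` (the true
#'   gene-wise variances).
#' @export
gen_expression <- function(n_genes, n_per_group, frac_de = 0.05,
                           effect_size = 1, d0_true = 4, s0sq_true = 0.05,
                           seed = 1, de_genes = NULL) {
  n_genes <- check_count(n_genes, "n_genes", min = 10L)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  frac_de <- check_prob(frac_de, "frac_de")
  check_positive(d0_true, "d0_true")
  check_positive(s0sq_true, "s0sq_true")

  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  sample_ids <- c(sprintf("A_%02d", seq_len(n_per_group)),
                  sprintf("B_%02d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("A", "B"), each = n_per_group), sample_ids)

  with_seed(seed, {
    if (is.null(de_genes)) {
      n_de <- round(frac_de * n_genes)
      de_genes <- if (n_de > 0) sort(sample(gene_ids, n_de)) else character(0)
    } else {
      if (!all(de_genes %in% gene_ids))
        stop("`de_genes` must be a subset of the generated gene ids", call. = FALSE)
      de_genes <- sort(unique(de_genes))
    }
    baseline <- rnorm(n_genes, mean = 7, sd = 1)
    sigma2 <- s0sq_true * d0_true / rchisq(n_genes, df = d0_true)
    delta <- ifelse(gene_ids %in% de_genes, effect_size, 0)

    mu <- cbind(matrix(baseline, n_genes, n_per_group),
                matrix(baseline + delta, n_genes, n_per_group))
    noise <- matrix(rnorm(n_genes * 2 * n_per_group, sd = sqrt(sigma2)),
                    nrow = n_genes)
    values <- mu + noise
    dimnames(values) <- list(gene_ids, sample_ids)

    structure(
      list(matrix = expression_matrix(values, groups),
           de_genes = de_genes,
           effect_size = effect_size,
           variance_prior = list(d0_true = d0_true, s0sq_true = s0sq_true),
           sigma2 = stats::setNames(sigma2, gene_ids)),
      class = "synthetic_expression")
  })
}

#' Simulate reciprocal hit tables with planted one-to-one orthologs
#'
#' Every planted pair is the unique mutual top-scoring hit in both search
#' directions. Decoy rows score strictly below every planted pair; decoy
#' queries may be extra ids with no ortholog, so reciprocal-best-hit
#' inference on the output recovers exactly the planted pairs.
#'
#' @param n_orthologs number of planted ortholog pairs (>= 1).
#' @param n_decoys decoy rows added to each direction.
#' @param seed integer seed.
#' @param ids_a,ids_b optional id vectors (length `n_orthologs`) to use for
#'   the planted pairs instead of generated "A00001"/"B00001"-style names.
#'
#' @return list with `ab` and `ba` hit tables (data frames `query`,
#'   `subject`, `score`) and `truth`, the planted ortholog map
#'   (`id_a`, `id_b`).
#' @export
gen_hit_tables <- function(n_orthologs, n_decoys = 0, seed = 1,
                           ids_a = NULL, ids_b = NULL) {
  n_orthologs <- check_count(n_orthologs, "n_orthologs", min = 1L)
  n_decoys <- check_count(n_decoys, "n_decoys", min = 0L)
  ids_a <- ids_a %||% sprintf("A%05d", seq_len(n_orthologs))
  ids_b <- ids_b %||% sprintf("B%05d", seq_len(n_orthologs))
  if (length(ids_a) != n_orthologs || length(ids_b) != n_orthologs)
    stop("`ids_a`/`ids_b` must have length `n_orthologs`", call. = FALSE)

  with_seed(seed, {
    pair_score <- runif(n_orthologs, 150, 200)
    ab <- data.frame(query = ids_a, subject = ids_b, score = pair_score,
                     stringsAsFactors = FALSE)
    ba <- data.frame(query = ids_b, subject = ids_a, score = pair_score,
                     stringsAsFactors = FALSE)
    if (n_decoys > 0) {
      # decoy subjects are planted partners only: an extra-id query's best
      # hit can then never be reciprocated, so RBH output is exactly truth
      extra_a <- sprintf("AX%04d", seq_len(max(1L, n_decoys %/% 2L)))
      extra_b <- sprintf("BX%04d", seq_len(max(1L, n_decoys %/% 2L)))
      dab <- data.frame(query = sample(c(ids_a, extra_a), n_decoys, replace = TRUE),
                        subject = sample(ids_b, n_decoys, replace = TRUE),
                        score = runif(n_decoys, 10, 100), stringsAsFactors = FALSE)
      dba <- data.frame(query = sample(c(ids_b, extra_b), n_decoys, replace = TRUE),
                        subject = sample(ids_a, n_decoys, replace = TRUE),
                        score = runif(n_decoys, 10, 100), stringsAsFactors = FALSE)
      ab <- rbind(ab, dab)
      ba <- rbind(ba, dba)
    }
    list(ab = ab, ba = ba,
         truth = data.frame(id_a = ids_a, id_b = ids_b, stringsAsFactors = FALSE))
  })
}

#' Simulate a modular scored interactome (stochastic block model)
#'
#' Edges are sampled independently per pair with within-block probability
#' `p_in` and between-block probability `p_out`; each present edge carries a
#' confidence score. By default scores are uniform on \[0.9, 1\] so a 0.9
#' confidence cut keeps every edge; `noisy_scores = TRUE` draws from
#' \[0, 1\] to exercise the threshold.
#'
#' @param n_blocks,block_size number and size of planted modules.
#' @param p_in,p_out edge probabilities; requires `p_out <= p_in`.
#' @param seed integer seed.
#' @param noisy_scores draw confidence scores from \[0, 1\] instead of
#'   \[0.9, 1\].
#'
#' @return list of class `synthetic_interactome` with `interactions`
#'   (data frame `protein1`, `protein2`, `combined_score`), `block_of`
#'   (named character: node -> block label), `nodes`, and the generating
#'   parameters.
#' @export
gen_interactome <- function(n_blocks, block_size, p_in, p_out, seed = 1,
                            noisy_scores = FALSE) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  block_size <- check_count(block_size, "block_size", min = 2L)
  p_in <- check_prob(p_in, "p_in")
  p_out <- check_prob(p_out, "p_out")
  if (p_out > p_in)
    stop("`p_out` must not exceed `p_in`", call. = FALSE)

  n <- n_blocks * block_size
  nodes <- sprintf("P%06d", seq_len(n))
  block_of <- stats::setNames(rep(sprintf("B%02d", seq_len(n_blocks)),
                                  each = block_size), nodes)

  with_seed(seed, {
    pref <- matrix(p_out, n_blocks, n_blocks)
    diag(pref) <- p_in
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = rep(block_size, n_blocks))
    igraph::V(g)$name <- nodes
    el <- igraph::as_edgelist(g, names = TRUE)
    m <- nrow(el)
    score <- if (noisy_scores) runif(m, 0, 1) else runif(m, 0.9, 1)
    structure(
      list(interactions = data.frame(protein1 = el[, 1], protein2 = el[, 2],
                                     combined_score = score,
                                     stringsAsFactors = FALSE),
           block_of = block_of, nodes = nodes,
           p_in = p_in, p_out = p_out,
           n_blocks = n_blocks, block_size = block_size),
      class = "synthetic_interactome")
  })
}

#' Plant a disease signature and drug targets at controlled distance
#'
#' Draws the signature inside a single block of a synthetic interactome and
#' places each drug target so that its shortest-path distance to the
#' signature equals `target_distance` (0 puts the target inside the
#' signature). Infeasible placements raise an error rather than silently
#' relocating the target.
#'
#' @param truth a `synthetic_interactome` from [gen_interactome()].
#' @param sig_size signature size (<= block size).
#' @param n_targets number of drug targets; the first four are labelled
#'   after the standard post-MI drug classes (ACEi, ARB, beta_blocker, MRA).
#' @param target_distance required hop distance from each target to the
#'   signature set.
#' @param seed integer seed.
#'
#' @return list with `signature` (character vector of node ids) and
#'   `targets` (named character vector: drug class -> target node).
#' @export
gen_signature_and_targets <- function(truth, sig_size, n_targets = 4,
                                      target_distance = 1, seed = 1) {
  stopifnot(inherits(truth, "synthetic_interactome"))
  sig_size <- check_count(sig_size, "sig_size")
  n_targets <- check_count(n_targets, "n_targets")
  target_distance <- check_count(target_distance, "target_distance", min = 0L)
  if (sig_size > truth$block_size)
    stop("`sig_size` exceeds the block size", call. = FALSE)

  g <- igraph::graph_from_data_frame(truth$interactions[, 1:2],
                                     directed = FALSE,
                                     vertices = truth$nodes)
  with_seed(seed, {
    block1 <- names(truth$block_of)[truth$block_of == truth$block_of[[1]]]
    signature <- sort(sample(block1, sig_size))
    d <- igraph::distances(g, v = signature, to = igraph::V(g))
    mind <- apply(d, 2, min)
    candidates <- if (target_distance == 0) signature
                  else names(mind)[is.finite(mind) & mind == target_distance]
    candidates <- setdiff(candidates, if (target_distance == 0) character(0) else signature)
    if (length(candidates) < n_targets)
      stop(sprintf(
        "infeasible placement: only %d nodes at distance %d from the signature (need %d)",
        length(candidates), target_distance, n_targets), call. = FALSE)
    target_ids <- sample(candidates, n_targets)
    labels <- c("ACEi", "ARB", "beta_blocker", "MRA")
    nm <- if (n_targets <= 4) labels[seq_len(n_targets)]
          else c(labels, sprintf("drug_%02d", seq_len(n_targets - 4)))
    list(signature = signature, targets = stats::setNames(target_ids, nm))
  })
}

#' Generate a complete, internally consistent pipeline dataset
#'
#' Ties the individual generators together: a modular interactome over
#' "human" proteins, a signature planted in one block with drug targets at a
#' controlled distance, a one-to-one ortholog layer mapping every human
#' protein to a "swine" protein, a swine gene-to-protein table, and an
#' expression matrix whose planted differential genes are exactly the genes
#' upstream of the signature proteins. Running the full pipeline on this
#' dataset should therefore re-derive the planted signature and find the
#' targets proximal.
#'
#' @param n_blocks,block_size,p_in,p_out interactome parameters
#'   (see [gen_interactome()]).
#' @param sig_size,n_targets,target_distance signature/target parameters
#'   (see [gen_signature_and_targets()]).
#' @param n_genes number of swine genes (>= number of interactome nodes).
#' @param n_per_group samples per expression group.
#' @param effect_size planted log2 shift for signature genes.
#' @param n_decoys decoy rows per hit-table direction.
#' @param seed integer master seed (stage seeds derived deterministically).
#'
#' @return list with the pieces: `interactome`, `signature`, `targets`,
#'   `hits` (ab/ba/truth), `gene2protein` (data frame gene, protein),
#'   `expression` (a `synthetic_expression`), and `de_genes`.
#' @export
gen_pipeline_dataset <- function(n_blocks = 10, block_size = 25,
                                 p_in = 0.25, p_out = 0.01,
                                 sig_size = 20, n_targets = 4,
                                 target_distance = 1,
                                 n_genes = 500, n_per_group = 4,
                                 effect_size = 1.5, n_decoys = 100,
                                 seed = 1) {
  n_nodes <- n_blocks * block_size
  if (n_genes < n_nodes)
    stop("`n_genes` must be at least the number of interactome nodes", call. = FALSE)
  seeds <- as.integer(seed) + 1:4

  interactome <- gen_interactome(n_blocks, block_size, p_in, p_out, seed = seeds[1])
  sig <- gen_signature_and_targets(interactome, sig_size, n_targets,
                                   target_distance, seed = seeds[2])

  # swine proteome mirrors the human one through a planted ortholog layer
  swine_prot <- sprintf("S%06d", seq_len(n_nodes))
  hits <- gen_hit_tables(n_nodes, n_decoys = n_decoys, seed = seeds[3],
                         ids_a = swine_prot, ids_b = interactome$nodes)
  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  gene2protein <- data.frame(gene = gene_ids[seq_len(n_nodes)],
                             protein = swine_prot, stringsAsFactors = FALSE)

  # plant DE exactly on the genes whose protein chain lands in the signature
  sig_swine <- hits$truth$id_a[match(sig$signature, hits$truth$id_b)]
  de_genes <- gene2protein$gene[match(sig_swine, gene2protein$protein)]
  expression <- gen_expression(n_genes, n_per_group, effect_size = effect_size,
                               seed = seeds[4], de_genes = de_genes)

  list(interactome = interactome, signature = sig$signature,
       targets = sig$targets, hits = hits, gene2protein = gene2protein,
       expression = expression, de_genes = sort(de_genes))
}

#' Write the synthetic inputs of a pipeline dataset to a directory
#'
#' Emits the plain-text exchange formats the pipeline reads: expression TSV,
#' sample sheet TSV, interaction TSV, hit-table TSVs, gene-to-protein map
#' TSV, the planted signature as GMT, and a JSON truth sidecar.
#'
#' @param dataset output of [gen_pipeline_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named list of written paths.
#' @export
write_pipeline_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    hits_ab = file.path(dir, "hits_swine_human.tsv"),
    hits_ba = file.path(dir, "hits_human_swine.tsv"),
    gene2protein = file.path(dir, "gene2protein.tsv"),
    signature = file.path(dir, "planted_signature.gmt"),
    truth = file.path(dir, "truth.json"))

  em <- dataset$expression$matrix
  write_tsv(data.frame(gene = rownames(em$values), em$values,
                       check.names = FALSE), p$expression)
  write_tsv(data.frame(sample = names(em$groups), group = unname(em$groups)),
            p$samples)
  write_tsv(dataset$interactome$interactions, p$interactions)
  write_tsv(dataset$hits$ab, p$hits_ab)
  write_tsv(dataset$hits$ba, p$hits_ba)
  write_tsv(dataset$gene2protein, p$gene2protein)
  write_gmt(list(planted_signature = dataset$signature), p$signature)
  jsonlite::write_json(
    list(signature = dataset$signature,
         targets = as.list(dataset$targets),
         de_genes = dataset$de_genes,
         block_of = as.list(dataset$interactome$block_of)),
    p$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(p)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
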