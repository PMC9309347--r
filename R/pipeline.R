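#' Assemble a pipeline configuration
#'
#' Collects the paths and tuning parameters of the full analysis. Two entry
#' modes: expression mode (expression + samples + hit tables + gene map
#' drive the signature) and curated-signature mode (`signature` points at a
#' GMT or id-list file and the differential-expression and orthology stages
#' are skipped).
#'
#' @param interactions path to the scored interaction TSV (required).
#' @param expression,samples expression matrix and sample sheet TSVs.
#' @param hits_ab,hits_ba,gene2protein orthology inputs.
#' @param signature curated signature file (GMT or one id per line);
#'   bypasses diffexpr + orthology when set.
#' @param targets named character vector or list, drug class -> target ids
#'   (default [default_drug_targets()]).
#' @param outdir output directory.
#' @param p_adj_max,lfc_min signature-filter thresholds.
#' @param min_score interaction confidence threshold.
#' @param metric proximity metric ("closest" or "average").
#' @param n_perm permutations for the proximity null.
#' @param radius mechanism-overlap neighborhood radius.
#' @param k_range,dim,n_restarts clustering controls.
#' @param rank_proteins also produce the full per-protein ranked list.
#' @param seed global seed, split deterministically into stage seeds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(interactions,
                            expression = NULL, samples = NULL,
                            hits_ab = NULL, hits_ba = NULL,
                            gene2protein = NULL, signature = NULL,
                            targets = default_drug_targets(),
                            outdir = "results",
                            p_adj_max = 0.01, lfc_min = 0.25,
                            min_score = 0.9,
                            metric = "closest", n_perm = 1000, radius = 1,
                            k_range = 2:20, dim = 12, n_restarts = 20,
                            rank_proteins = TRUE, seed = 1) {
  structure(list(interactions = interactions, expression = expression,
                 samples = samples, hits_ab = hits_ab, hits_ba = hits_ba,
                 gene2protein = gene2protein, signature = signature,
                 targets = targets, outdir = outdir,
                 p_adj_max = p_adj_max, lfc_min = lfc_min,
                 min_score = min_score, metric = metric, n_perm = n_perm,
                 radius = radius, k_range = k_range, dim = dim,
                 n_restarts = n_restarts, rank_proteins = rank_proteins,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Path fields are resolved relative to the YAML file's directory.
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("interactions", "expression", "samples", "hits_ab", "hits_ba",
              "gene2protein", "signature")) {
    if (!is.null(y[[f]]) && !startsWith(y[[f]], "/"))
      y[[f]] <- file.path(base, y[[f]])
  }
  if (!is.null(y$targets)) y$targets <- unlist(y$targets)
  if (!is.null(y$k_range) && length(y$k_range) == 2L)
    y$k_range <- seq(y$k_range[1], y$k_range[2])
  do.call(pipeline_config, y)
}

#' Validate a pipeline configuration
#'
#' Collects every detected problem (missing files, threshold range errors,
#' incomplete mode selection) rather than stopping at the first; an empty
#' return means the configuration is runnable.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems (empty if none).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)

  if (is.null(config$interactions)) add("no interactions path")
  for (f in c("interactions", "expression", "samples", "hits_ab", "hits_ba",
              "gene2protein", "signature")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      add(sprintf("missing file for `%s`: %s", f, config[[f]]))
  }
  expr_mode <- !is.null(config$expression)
  if (!expr_mode && is.null(config$signature))
    add("neither an expression matrix nor a curated signature is configured")
  if (expr_mode) {
    for (f in c("samples", "hits_ab", "hits_ba", "gene2protein"))
      if (is.null(config[[f]]))
        add(sprintf("expression mode requires `%s`", f))
  }
  if (config$min_score < 0 || config$min_score > 1)
    add("`min_score` must lie in [0, 1]")
  if (config$p_adj_max <= 0 || config$p_adj_max > 1)
    add("`p_adj_max` must lie in (0, 1]")
  if (config$lfc_min <= 0) add("`lfc_min` must be positive")
  if (config$n_perm < 100) add("`n_perm` must be at least 100")
  if (!config$metric %in% c("closest", "average"))
    add("`metric` must be 'closest' or 'average'")
  if (length(config$k_range) < 4) add("`k_range` needs at least 4 values")
  problems
}

#' Run the full analysis pipeline
#'
#' Stages run in order: differential expression, ortholog translation,
#' network construction and enrichment, proximity ranking with the
#' degree-matched null and pairwise mechanism overlap, and module
#' detection. A curated signature file skips the first two stages. All
#' tables are written as TSV and the run report as JSON under
#' `config$outdir`; identical configuration and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run report, invisibly also written to
#'   `outdir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- config$seed + 1:3  # proximity-null, ranking, clustering
  report <- list(schema = "remodnet-run-report/1",
                 version = as.character(utils::packageVersion("remodnet")),
                 seed = config$seed, counts = list())

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$signature)) {
    signature <- run_stage("signature", read_signature(config$signature))
  } else {
    de <- run_stage("diffexpr", {
      em <- read_expression(config$expression, config$samples)
      run_diffexpr(em, filter_params(config$p_adj_max, config$lfc_min))
    })
    write_tsv(de$table, file.path(config$outdir, "diffexpr.tsv"))
    report$counts$genes_in <- nrow(de$table)
    report$counts$genes_passing_filter <- length(de$signature)
    orth <- run_stage("orthology", reciprocal_best_hits(
      read_hit_table(config$hits_ab), read_hit_table(config$hits_ba)))
    write_tsv(orth, file.path(config$outdir, "orthologs.tsv"))
    report$counts$ortholog_pairs <- nrow(orth)
    signature <- run_stage("orthology", map_set(
      de$signature, read_gene_map(config$gene2protein), orth))
  }
  report$counts$signature_proteins <- length(signature)
  writeLines(signature, file.path(config$outdir, "signature.txt"))

  tab <- run_stage("network",
    load_interactions(config$interactions, min_score = config$min_score))
  # the disease network (signature + targets) carries the descriptive
  # statistics, mechanism overlap and module structure; proximity and the
  # ranked association list are scored on the full interactome so the
  # permutation null draws from all proteins, not the signature itself
  net <- run_stage("network", build_network(tab, signature, config$targets))
  net_prox <- run_stage("network", build_network(
    tab, unique(c(tab$protein1, tab$protein2, signature)), config$targets))
  stats_ <- network_stats(net)
  report$network <- stats_
  report$counts$nodes <- stats_$n_nodes
  report$counts$edges <- stats_$n_edges
  el <- igraph::as_edgelist(net$graph)
  write_tsv(data.frame(protein1 = el[, 1], protein2 = el[, 2]),
            file.path(config$outdir, "network_edges.tsv"))

  prox <- run_stage("proximity", {
    drugs <- lapply(config$targets, function(t)
      degree_matched_null(net_prox, t, signature, n_perm = config$n_perm,
                          seed = seeds[1], metric = config$metric))
    names(drugs) <- names(config$targets)
    drugs
  })
  report$proximity <- lapply(prox, function(x)
    x[c("d_obs", "null_mean", "null_sd", "z", "p_emp")])

  if (isTRUE(config$rank_proteins)) {
    ranked <- run_stage("proximity", rank_all_proteins(
      net_prox, signature, n_perm = config$n_perm, seed = seeds[2],
      metric = config$metric))
    write_tsv(ranked, file.path(config$outdir, "ranked_proteins.tsv"))
    report$counts$ranked_proteins <- nrow(ranked)
  }

  pairs <- utils::combn(names(config$targets), 2, simplify = FALSE)
  overlaps <- run_stage("proximity", lapply(pairs, function(p)
    c(list(drug_a = p[1], drug_b = p[2]),
      mechanism_overlap(net, config$targets[[p[1]]], config$targets[[p[2]]],
                        radius = config$radius))))
  report$overlap <- overlaps

  clust <- run_stage("clustering", cluster_network(
    net, k_range = config$k_range, dim = min(config$dim,
                                             length(net$nodes) - 1L),
    n_restarts = config$n_restarts, seed = seeds[3]))
  write_tsv(data.frame(node = names(clust$assignment),
                       cluster = unname(clust$assignment)),
            file.path(config$outdir, "clusters.tsv"))
  write_tsv(data.frame(k = as.integer(names(clust$inertia_curve)),
                       inertia = unname(clust$inertia_curve)),
            file.path(config$outdir, "inertia_curve.tsv"))
  report$clustering <- list(k_selected = clust$k_selected,
                            embedding_dim = clust$embedding_dim)

  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(unclass(config[!vapply(config, is.null, logical(1))]),
                   file.path(config$outdir, "config_used.yaml"))
  invisible(report)
}
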