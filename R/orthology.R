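#' Ingest a similarity hit table
#'
#' Normalizes a (query, subject, score) table: duplicate (query, subject)
#' pairs are collapsed keeping the maximum score (logged), non-finite
#' scores are rejected.
#'
#' @param tab data frame with columns `query`, `subject`, `score` (higher
#'   is better).
#' @return cleaned data frame.
#' @export
as_hit_table <- function(tab) {
  stopifnot(all(c("query", "subject", "score") %in% names(tab)))
  if (any(!is.finite(tab$score)))
    stop("hit scores must be finite", call. = FALSE)
  key <- paste(tab$query, tab$subject, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate (query, subject) pair(s) collapsed, keeping max score")
    o <- order(key, -tab$score)
    tab <- tab[o, ][!duplicated(key[o]), ]
  }
  tab[, c("query", "subject", "score")]
}

#' Best hit per query
#'
#' Returns each query's unique top-scoring subject. Queries whose top score
#' is tied between two or more subjects are omitted (and logged): a
#' deterministic no-winner rule rather than an arbitrary pick.
#'
#' @param tab a hit table (see [as_hit_table()]).
#' @return named character vector, query -> subject.
#' @export
best_hits <- function(tab) {
  tab <- as_hit_table(tab)
  if (nrow(tab) == 0L) stop("empty hit table", call. = FALSE)
  sp <- split(tab, tab$query)
  out <- vapply(sp, function(d) {
    top <- unique(d$subject[d$score == max(d$score)])
    if (length(top) == 1L) top else NA_character_
  }, character(1))
  ties <- sum(is.na(out))
  if (ties > 0) message(ties, " quer(y/ies) dropped for tied best hits")
  out[!is.na(out)]
}

#' Reciprocal best hits
#'
#' A pair (a, b) is an ortholog call iff a's best hit in the forward table
#' is b and b's best hit in the reverse table is a. The result is
#' one-to-one by construction.
#'
#' @param ab forward hit table (species A queries against B).
#' @param ba reverse hit table (B queries against A).
#' @return data frame `id_a`, `id_b`, sorted by `id_a`.
#' @export
reciprocal_best_hits <- function(ab, ba) {
  if (nrow(ba) == 0L || nrow(ab) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      stringsAsFactors = FALSE))
  fwd <- best_hits(ab)
  rev <- best_hits(ba)
  keep <- !is.na(rev[fwd]) & rev[fwd] == names(fwd)
  keep[is.na(keep)] <- FALSE
  out <- data.frame(id_a = names(fwd)[keep], id_b = unname(fwd[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Map a gene set to ortholog proteins, one-to-one
#'
#' Composes gene -> protein -> ortholog. Genes with zero or multiple
#' protein images are dropped, as are proteins claimed by more than one
#' gene and proteins without an ortholog call; every drop is logged. The
#' result is a deduplicated, sorted protein id set in the target species.
#'
#' @param genes character vector of gene ids.
#' @param gene2protein data frame with columns `gene`, `protein`.
#' @param orthologs ortholog map from [reciprocal_best_hits()]
#'   (`id_a` = source-species protein, `id_b` = target-species protein).
#' @return character vector of target-species protein ids.
#' @export
map_set <- function(genes, gene2protein, orthologs) {
  stopifnot(all(c("gene", "protein") %in% names(gene2protein)))
  g2p <- unique(gene2protein[gene2protein$gene %in% genes, c("gene", "protein")])

  n_img <- table(g2p$gene)
  multi <- names(n_img)[n_img > 1L]
  missing <- setdiff(genes, g2p$gene)
  if (length(missing)) message(length(missing), " gene(s) without a protein image dropped")
  if (length(multi)) message(length(multi), " gene(s) with multiple protein images dropped")
  g2p <- g2p[!g2p$gene %in% multi, , drop = FALSE]

  shared <- table(g2p$protein)
  collide <- names(shared)[shared > 1L]
  if (length(collide)) message(length(collide), " protein(s) claimed by multiple genes dropped")
  g2p <- g2p[!g2p$protein %in% collide, , drop = FALSE]

  o <- stats::setNames(orthologs$id_b, orthologs$id_a)
  mapped <- o[g2p$protein]
  n_noorth <- sum(is.na(mapped))
  if (n_noorth) message(n_noorth, " protein(s) without an ortholog call dropped")
  sort(unique(unname(mapped[!is.na(mapped)])))
}

#' Read a 3-column hit-table TSV (query, subject, score)
#' @param path input file.
#' @return a cleaned hit table.
#' @export
read_hit_table <- function(path) {
  tab <- read_tsv(path)
  names(tab)[1:3] <- c("query", "subject", "score")
  as_hit_table(tab)
}

#' Read a 2-column gene-to-protein mapping TSV
#' @param path input file.
#' @return data frame `gene`, `protein`.
#' @export
read_gene_map <- function(path) {
  tab <- read_tsv(path)
  names(tab)[1:2] <- c("gene", "protein")
  tab[, c("gene", "protein")]
}
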