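#' Construct a two-group expression matrix
#'
#' Container for a genes x samples log2-intensity table with a two-level
#' group factor. Rows containing missing values are dropped with a message;
#' each group must retain at least two samples.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param groups named character vector mapping every sample id to one of
#'   exactly two group labels; order of first appearance fixes the contrast
#'   direction (second level minus first).
#' @return object of class `expression_matrix` with elements `values` and
#'   `groups`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene rownames and sample colnames", call. = FALSE)
  if (!all(colnames(values) %in% names(groups)))
    stop("every sample must have a group label", call. = FALSE)
  groups <- groups[colnames(values)]
  lev <- unique(unname(groups))
  if (length(lev) != 2L)
    stop("exactly two group labels required, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  bad <- rowSums(is.na(values)) > 0
  if (any(bad)) {
    message(sum(bad), " gene(s) dropped for missing values")
    values <- values[!bad, , drop = FALSE]
  }
  if (min(table(factor(groups, levels = lev))) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  structure(list(values = values, groups = groups, levels = lev),
            class = "expression_matrix")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common distribution given by the
#' row-wise mean of the sorted columns; gene and sample ordering is
#' preserved. Background correction (the other half of the neqc recipe used
#' for Illumina arrays) needs control probes and is out of scope here.
#'
#' @param em an [expression_matrix()] or a plain numeric matrix with at
#'   least two columns.
#' @return the normalized object, same type as the input.
#' @export
quantile_normalize <- function(em) {
  plain <- is.matrix(em)
  vals <- if (plain) em else em$values
  if (ncol(vals) < 2L)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  out <- limma::normalizeQuantiles(vals)
  dimnames(out) <- dimnames(vals)
  if (plain) return(out)
  em$values <- out
  em
}

#' Gene-wise two-group fit: log fold change and pooled variance
#'
#' @param em an [expression_matrix()].
#' @return data frame with one row per gene: `gene`, `logfc` (second group
#'   mean minus first), `s2` (pooled residual variance), `df` (residual
#'   degrees of freedom, `n_A + n_B - 2`), and `zero_var` flagging genes
#'   with no within-group variance in either group.
#' @export
fit_groups <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  lev <- em$levels
  a <- em$values[, em$groups == lev[1], drop = FALSE]
  b <- em$values[, em$groups == lev[2], drop = FALSE]
  n_a <- ncol(a); n_b <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  rss <- rowSums((a - ma)^2) + rowSums((b - mb)^2)
  df <- n_a + n_b - 2L
  s2 <- rss / df
  data.frame(gene = rownames(em$values), logfc = mb - ma, s2 = s2, df = df,
             zero_var = s2 == 0, row.names = NULL, stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function, used by the moment estimator
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Estimate the variance-prior hyperparameters (empirical Bayes)
#'
#' Method-of-moments fit on log sample variances under the hierarchical
#' model s2 | sigma2 ~ sigma2 * chisq(df)/df, sigma2 ~ s0sq * d0 /
#' chisq(d0): the mean and variance of log s2 are matched to their
#' digamma/trigamma expressions. When the spread of log s2 does not exceed
#' what sampling noise alone implies, d0 is reported infinite (complete
#' shrinkage).
#'
#' @param s2 gene-wise sample variances (at least 10 must be positive).
#' @param df residual degrees of freedom (scalar or per-gene; may be `Inf`
#'   when the variances are noise-free draws from the prior).
#' @return object of class `prior_estimate`: list with `d0`, `s0sq`,
#'   `infinite`.
#' @export
estimate_prior <- function(s2, df) {
  if (all(s2 == 0)) stop("all variances are zero; cannot estimate a variance prior",
                         call. = FALSE)
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L)
    stop("need at least 10 genes with positive variance", call. = FALSE)
  s2 <- s2[ok]
  df <- if (length(df) > 1L) df[ok] else rep(df, length(s2))

  z <- log(s2)
  # sampling-layer contribution; vanishes when df is infinite
  bias <- ifelse(is.finite(df), digamma(df / 2) - log(df / 2), 0)
  noise <- ifelse(is.finite(df), trigamma(df / 2), 0)
  e <- z - bias
  evar <- var(e) - mean(noise)
  if (evar <= 0) {
    return(structure(list(d0 = Inf, s0sq = exp(mean(e)), infinite = TRUE),
                     class = "prior_estimate"))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0, s0sq = s0sq, infinite = FALSE),
            class = "prior_estimate")
}

#' Moderated t-statistics with empirical-Bayes variance shrinkage
#'
#' Shrinks each gene's variance toward the prior,
#' `s2_post = (d0 * s0sq + df * s2) / (d0 + df)`, and tests the log fold
#' change on `d0 + df` degrees of freedom. `d0 = 0` reproduces the ordinary
#' pooled two-sample t-test; `d0 = Inf` fixes every posterior variance at
#' `s0sq` and uses a normal reference.
#'
#' @param logfc,s2,df per-gene output of [fit_groups()].
#' @param prior a [estimate_prior()] result (or list with `d0`, `s0sq`).
#' @param n_a,n_b group sample sizes.
#' @return data frame with `t_mod`, `p_raw`, `s2_post` and `degenerate`
#'   (TRUE where `s2_post` is zero, giving an infinite t and p = 0).
#' @export
moderated_t <- function(logfc, s2, df, prior, n_a, n_b) {
  d0 <- prior$d0; s0sq <- prior$s0sq
  if (is.null(d0) || is.null(s0sq) || d0 < 0 || s0sq < 0)
    stop("invalid prior", call. = FALSE)
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  t_mod <- logfc / se
  df_tot <- d0 + df
  p_raw <- if (is.infinite(d0)) 2 * pnorm(-abs(t_mod))
           else 2 * pt(-abs(t_mod), df = df_tot)
  degenerate <- s2_post == 0
  p_raw[degenerate] <- 0
  data.frame(t_mod = t_mod, p_raw = p_raw, s2_post = s2_post,
             degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in the input order.
#'
#' @param p_raw vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_raw, method = "BH")
}

#' Signature filter thresholds
#'
#' Strict inequalities, as printed: adjusted p below `p_adj_max` and
#' absolute log2 fold change above `lfc_min`.
#'
#' @param p_adj_max adjusted-p threshold (default 0.01).
#' @param lfc_min absolute log2-fold-change threshold (default 0.25).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(p_adj_max = 0.01, lfc_min = 0.25) {
  check_positive(p_adj_max, "p_adj_max")
  check_positive(lfc_min, "lfc_min")
  structure(list(p_adj_max = p_adj_max, lfc_min = lfc_min),
            class = "filter_params")
}

#' Apply the disease-signature filter to a differential-expression table
#'
#' @param results data frame with columns `gene`, `logfc` (or `logFC`) and
#'   `p_adj` (or `adj.P.Val`).
#' @param params a [filter_params()].
#' @return character vector of signature gene ids, ordered by adjusted p
#'   then gene id.
#' @export
filter_signature <- function(results, params = filter_params()) {
  lfc <- results$logfc %||% results$logFC
  padj <- results$p_adj %||% results$adj.P.Val
  keep <- padj < params$p_adj_max & abs(lfc) > params$lfc_min
  sel <- results$gene[keep]
  sel[order(padj[keep], sel)]
}

#' Run the full differential-expression stage
#'
#' Quantile normalization, two-group fit, empirical-Bayes prior, moderated
#' t, BH adjustment, and the signature filter.
#'
#' @param em an [expression_matrix()].
#' @param params a [filter_params()].
#' @param normalize quantile-normalize first (default TRUE).
#' @return list with `table` (gene, logFC, t, P.Value, adj.P.Val, passes),
#'   `prior`, and `signature` (the gene ids passing the filter).
#' @export
run_diffexpr <- function(em, params = filter_params(), normalize = TRUE) {
  if (normalize) em <- quantile_normalize(em)
  fit <- fit_groups(em)
  prior <- estimate_prior(fit$s2, fit$df)
  n_a <- sum(em$groups == em$levels[1]); n_b <- sum(em$groups == em$levels[2])
  mt <- moderated_t(fit$logfc, fit$s2, fit$df, prior, n_a, n_b)
  p_adj <- bh_adjust(mt$p_raw)
  tab <- data.frame(gene = fit$gene, logFC = fit$logfc, t = mt$t_mod,
                    P.Value = mt$p_raw, adj.P.Val = p_adj,
                    passes = p_adj < params$p_adj_max &
                             abs(fit$logfc) > params$lfc_min,
                    stringsAsFactors = FALSE)
  list(table = tab, prior = prior,
       signature = filter_signature(
         data.frame(gene = tab$gene, logfc = tab$logFC, p_adj = tab$adj.P.Val),
         params))
}

#' Read an expression TSV and sample sheet
#'
#' Expression: first column gene id, remaining columns samples. Sample
#' sheet: columns `sample`, `group`.
#'
#' @param expression_path,samples_path input TSV paths.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(expression_path, samples_path) {
  expr <- read_tsv(expression_path)
  ss <- read_tsv(samples_path)
  vals <- as.matrix(expr[, -1, drop = FALSE])
  rownames(vals) <- expr[[1]]
  expression_matrix(vals, stats::setNames(ss$group, ss$sample))
}
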