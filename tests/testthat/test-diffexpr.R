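make_em <- function(a, b) {
  vals <- cbind(a, b)
  rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  colnames(vals) <- c(sprintf("A%d", seq_len(ncol(a))),
                      sprintf("B%d", seq_len(ncol(b))))
  groups <- setNames(rep(c("A", "B"), c(ncol(a), ncol(b))), colnames(vals))
  expression_matrix(vals, groups)
}

test_that("quantile normalization equalizes column distributions", {
  expect_equal(quantile_normalize(cbind(c(1, 3), c(2, 4))),
               cbind(c(1.5, 3.5), c(1.5, 3.5)))
  expect_error(quantile_normalize(cbind(c(1, 3))), "at least 2")

  # identical columns are a fixed point
  same <- make_em(matrix(c(1, 5, 2), 3, 2), matrix(c(1, 5, 2), 3, 2))
  expect_equal(quantile_normalize(same)$values, same$values)

  # column means agree after normalization of arbitrary input
  se <- gen_expression(200, 4, seed = 1)
  qn2 <- quantile_normalize(se$matrix)
  expect_equal(diff(range(colMeans(qn2$values))), 0, tolerance = 1e-12)
})

test_that("expression_matrix validates groups and drops NA rows", {
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4")))
  vals["g2", 1] <- NA
  groups <- setNames(c("A", "A", "B", "B"), colnames(vals))
  expect_message(em <- expression_matrix(vals, groups), "dropped")
  expect_equal(rownames(em$values), c("g1", "g3"))
  expect_error(expression_matrix(vals, setNames(rep("A", 4), colnames(vals))),
               "two group")
  expect_error(expression_matrix(vals[, 1:3],
                                 setNames(c("A", "A", "B"), colnames(vals)[1:3])),
               "at least 2")
})

test_that("fit_groups matches hand-computed pooled statistics", {
  em <- make_em(matrix(c(0, 0, 0, 2, 1, 1), 3, 2, byrow = TRUE),
                matrix(c(1, 1, 1, 3, 1, 1), 3, 2, byrow = TRUE))
  fit <- fit_groups(em)
  expect_equal(fit$logfc, c(1, 1, 0))
  expect_equal(fit$s2, c(0, 2, 0))  # ((0-1)^2+(2-1)^2+(1-2)^2+(3-2)^2)/2 = 2
  expect_equal(fit$df, rep(2L, 3))
  expect_true(fit$zero_var[1] && !fit$zero_var[2])
})

test_that("prior estimation recovers hyperparameters and flags degenerate spread", {
  # identical variances: no excess spread, infinite d0
  pr <- estimate_prior(rep(0.5, 100), df = 4)
  expect_true(pr$infinite)
  expect_true(is.infinite(pr$d0))

  expect_error(estimate_prior(rep(0, 50), df = 4), "zero")

  # noise-free draws from the prior (df = Inf): moment fit against a
  # grid-search oracle minimizing the same moment mismatch
  s2 <- withr::with_seed(5, 0.05 * 4 / rchisq(5000, 4))
  pr2 <- estimate_prior(s2, df = Inf)
  grid <- seq(2, 8, by = 0.001)
  mismatch <- abs(trigamma(grid / 2) - var(log(s2)))
  expect_equal(pr2$d0, grid[which.min(mismatch)], tolerance = 1e-3)
  expect_equal(pr2$d0, 4, tolerance = 0.15 * 4)
  expect_equal(pr2$s0sq, 0.05, tolerance = 0.1 * 0.05)

  # two distinct repeated variances give a finite positive d0
  pr3 <- estimate_prior(rep(c(0.2, 0.8), each = 50), df = 6)
  expect_false(pr3$infinite)
  expect_gt(pr3$d0, 0)

  # independent cross-check: limma's moment fit on the same model
  fit <- fit_groups(gen_expression(5000, 4, frac_de = 0, seed = 11)$matrix)
  ours <- estimate_prior(fit$s2, fit$df)
  ref <- limma::fitFDist(fit$s2, df1 = fit$df[1])
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0sq, ref$scale, tolerance = 1e-6)
})

test_that("prior hyperparameters are recovered across seeds at stated tolerance", {
  for (s in 1:20) {
    se <- gen_expression(20000, 4, frac_de = 0, d0_true = 4, s0sq_true = 0.05,
                         seed = s)
    fit <- fit_groups(se$matrix)
    pr <- estimate_prior(fit$s2, fit$df)
    expect_equal(pr$d0, 4, tolerance = 0.15)
    expect_equal(pr$s0sq, 0.05, tolerance = 0.10)
  }
})

test_that("moderated t interpolates between pooled t and full shrinkage", {
  # closed-form case
  mt <- moderated_t(logfc = 1, s2 = 1, df = 2,
                    prior = list(d0 = 2, s0sq = 1), n_a = 2, n_b = 2)
  expect_equal(mt$s2_post, 1)
  expect_equal(mt$t_mod, 1)
  expect_equal(mt$p_raw, 2 * pt(-1, df = 4))

  # d0 = 0: ordinary pooled two-sample t on 1000 random genes
  se <- gen_expression(1000, 3, frac_de = 0.2, seed = 4)
  fit <- fit_groups(se$matrix)
  mt0 <- moderated_t(fit$logfc, fit$s2, fit$df, list(d0 = 0, s0sq = 1), 3, 3)
  t_pooled <- fit$logfc / sqrt(fit$s2 * (1 / 3 + 1 / 3))
  expect_equal(mt0$t_mod, t_pooled, tolerance = 1e-12)
  expect_equal(mt0$p_raw, 2 * pt(-abs(t_pooled), df = 4), tolerance = 1e-12)

  # d0 = Inf: posterior variance pinned at s0sq, normal reference
  mtI <- moderated_t(fit$logfc, fit$s2, fit$df, list(d0 = Inf, s0sq = 0.3), 3, 3)
  expect_true(all(mtI$s2_post == 0.3))
  expect_equal(mtI$p_raw, 2 * pnorm(-abs(fit$logfc / sqrt(0.3 * 2 / 3))))

  # degenerate posterior variance
  mtd <- moderated_t(1, 0, 2, list(d0 = 2, s0sq = 0), 2, 2)
  expect_true(is.infinite(mtd$t_mod) && mtd$p_raw == 0 && mtd$degenerate)
})

test_that("moderated pipeline agrees with limma's eBayes", {
  se <- gen_expression(3000, 4, frac_de = 0.1, effect_size = 1, seed = 8)
  em <- quantile_normalize(se$matrix)
  fit <- fit_groups(em)
  prior <- estimate_prior(fit$s2, fit$df)
  mt <- moderated_t(fit$logfc, fit$s2, fit$df, prior, 4, 4)

  design <- cbind(1, em$groups == "B")
  lf <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(mt$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(mt$p_raw, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up oracle and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  for (s in 1:10) {
    p <- withr::with_seed(s, runif(200)^2)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup_oracle(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("signature filter applies strict thresholds in deterministic order", {
  res <- data.frame(gene = c("g3", "g1", "g2", "g4"),
                    logfc = c(0.3, 1.0, -0.5, 0.25),
                    p_adj = c(0.009, 0.01, 0.001, 0.005))
  out <- filter_signature(res, filter_params())
  expect_identical(out, c("g2", "g3"))  # g1 fails p boundary, g4 lfc boundary
})

test_that("null simulation keeps false positives below the nominal FDR", {
  any_hit <- logical(100)
  n_sel <- integer(100)
  for (r in 1:100) {
    se <- gen_expression(5000, 3, frac_de = 0, seed = 3000 + r)
    de <- run_diffexpr(se$matrix)
    n_sel[r] <- length(de$signature)
    any_hit[r] <- n_sel[r] > 0
  }
  expect_lte(mean(n_sel), 5000 * 0.01)
  # under the global null BH bounds P(any rejection) by alpha = 0.01
  expect_lte(mean(any_hit), 0.05)
})

test_that("planted effects are recovered with high sensitivity", {
  # under the heavy-tailed variance prior (d0 = 4), six samples per group
  # are needed for a one-log2-unit shift to clear 80% sensitivity; at the
  # minimal design (n = 4) the same shift sits near 55%
  sens <- vapply(1:20, function(r) {
    se <- gen_expression(2000, 6, frac_de = 0.05, effect_size = 1,
                         seed = 400 + r)
    de <- run_diffexpr(se$matrix)
    mean(se$de_genes %in% de$signature)
  }, numeric(1))
  expect_gte(mean(sens), 0.8)

  # sensitivity grows with the effect size at fixed n
  sens15 <- vapply(1:5, function(r) {
    se <- gen_expression(2000, 4, frac_de = 0.05, effect_size = 1.5,
                         seed = 400 + r)
    mean(se$de_genes %in% run_diffexpr(se$matrix)$signature)
  }, numeric(1))
  expect_gte(mean(sens15), 0.8)
})
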