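# signatures: ssGSEA, marker means, estimate-like scores, group tests,
# one-vs-rest DEG

# direct-summation ssGSEA oracle for one sample / one set
ssgsea_oracle <- function(e, genes, set, alpha = 0.25) {
  rnk <- rank(e)
  ord <- order(-e, genes)
  num <- den_in <- 0
  p_out_step <- 1 / sum(!(genes %in% set))
  den_in <- sum(rnk[genes %in% set]^alpha)
  acc <- 0; p_in <- 0; p_out <- 0
  for (g in ord) {
    if (genes[g] %in% set) p_in <- p_in + rnk[g]^alpha / den_in
    else p_out <- p_out + p_out_step
    acc <- acc + (p_in - p_out)
  }
  unname(acc)
}

test_that("ssgsea_score matches the direct-summation oracle", {
  em <- tiny_expr(n_genes = 10, n_samples = 5, seed = 2)
  set <- rownames(em$values)[c(2, 5, 9)]
  s <- ssgsea_score(em, list(sig = set), normalize = FALSE)
  for (j in seq_len(5))
    expect_equal(s["sig", j],
                 ssgsea_oracle(em$values[, j], rownames(em$values), set),
                 tolerance = 1e-10)
})

test_that("ssgsea extremes, rank invariance and normalization", {
  em <- tiny_expr(n_genes = 20, n_samples = 6, seed = 3)
  set <- paste0("top", 1:4)
  v <- rbind(em$values,
             matrix(0, 4, 6, dimnames = list(set, colnames(em$values))))
  v[set, 1] <- max(v) + 1:4  # sample 1: set genes occupy the top ranks
  em2 <- expression_matrix(v, stats::setNames(rep("mRNA", 24), rownames(v)))
  s <- ssgsea_score(em2, list(sig = set))
  expect_equal(unname(s["sig", 1]), 1.0)

  # strictly monotone per-sample transform leaves unnormalized scores
  s_raw <- ssgsea_score(em2, list(sig = set), normalize = FALSE)
  v2 <- v; v2[, 2] <- exp(v2[, 2] / 4)
  em3 <- expression_matrix(v2, gene_biotypes(em2))
  s_mono <- ssgsea_score(em3, list(sig = set), normalize = FALSE)
  expect_equal(s_mono["sig", 2], s_raw["sig", 2], tolerance = 1e-12)

  expect_warning(ssgsea_score(em2, list(bad = c("zz1", "top1"),
                                        sig = set)), "skipped")
  expect_error(suppressWarnings(
    ssgsea_score(em2, list(bad = c("zz1", "zz2")))), "no scorable")
})

test_that("marker_mean_score is the mean of marker rows", {
  em <- tiny_expr(n_genes = 12, n_samples = 5, seed = 4)
  g <- rownames(em$values)
  s <- marker_mean_score(em, list(one = g[3], many = g[c(1, 4, 9)]))
  expect_equal(s["one", ], em$values[g[3], ])
  expect_equal(s["many", ], colMeans(em$values[g[c(1, 4, 9)], ]))
  # linearity: +1 on all markers of one sample lifts its score by 1
  v <- em$values; v[g[c(1, 4, 9)], 2] <- v[g[c(1, 4, 9)], 2] + 1
  s2 <- marker_mean_score(expression_matrix(v, gene_biotypes(em)),
                          list(many = g[c(1, 4, 9)]))
  expect_equal(unname(s2["many", 2] - s["many", 2]), 1)
})

test_that("estimate_like_scores sum and recover a planted immune shift", {
  ch <- small_cohort(seed = 13)
  mrna <- rownames(mrna_values(ch$expr))
  stromal <- mrna[1:10]; immune <- mrna[11:25]
  labs <- ch$truth$subtype_labels
  v <- ch$expr$values
  v[immune, names(labs)[labs == 2]] <-
    v[immune, names(labs)[labs == 2]] + 2
  em <- expression_matrix(v, gene_biotypes(ch$expr))
  est <- estimate_like_scores(em, stromal, immune)
  expect_equal(est$combined, est$stromal + est$immune)
  means <- tapply(est$immune, labs[est$sample], mean)
  expect_equal(unname(which.max(means)), 2L)
  expect_lt(anova(lm(est$immune ~ factor(labs[est$sample])))$`Pr(>F)`[1],
            0.01)
  expect_error(suppressWarnings(
    estimate_like_scores(em, c("none1", "none2"), immune)))
})

test_that("compare_groups picks the right test and calibrates", {
  # two groups: Wilcoxon branch, checked against a manual rank-sum
  sc <- matrix(c(1.2, 3.1, 2.0, 5.5, 4.4, 6.6), 1,
               dimnames = list("sig", paste0("s", 1:6)))
  labs <- stats::setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  res <- compare_groups(sc, labs)
  ranks <- rank(sc[1, ])
  u_manual <- sum(ranks[1:3]) - 3 * 4 / 2
  expect_equal(res$statistic, u_manual)

  # three groups: ANOVA branch matches the F closed form
  set.seed(6)
  sc3 <- matrix(rnorm(18), 1, dimnames = list("sig", paste0("s", 1:18)))
  labs3 <- stats::setNames(rep(c("a", "b", "c"), each = 6),
                           colnames(sc3))
  res3 <- compare_groups(sc3, labs3)
  expect_equal(res3$pvalue,
               summary(aov(sc3[1, ] ~ factor(labs3)))[[1]]$`Pr(>F)`[1],
               tolerance = 1e-12)

  # separation is detected
  sc3[1, labs3 == "c"] <- sc3[1, labs3 == "c"] + 5
  expect_lt(compare_groups(sc3, labs3)$pvalue, 0.001)

  expect_error(compare_groups(sc, labs[c(1, 2, 3, 4)][c(1, 2, 3)]))
  labs_bad <- labs; labs_bad[6] <- "c"
  expect_error(compare_groups(sc, labs_bad), "singleton")

  # type-I calibration under label permutation
  set.seed(8)
  y <- matrix(rnorm(40), 1, dimnames = list("sig", paste0("s", 1:40)))
  rej <- mean(replicate(500, {
    l <- stats::setNames(sample(rep(c("a", "b"), 20)), colnames(y))
    compare_groups(y, l)$pvalue < 0.05
  }))
  expect_gte(rej, 0.02); expect_lte(rej, 0.08)
})

test_that("one_vs_rest_deg flags planted markers and controls the null", {
  ch <- generate_cohort(sim_config(seed = 14))
  labs <- ch$truth$subtype_labels
  deg <- one_vs_rest_deg(ch$expr, labs, 1)
  expect_s3_class(deg, "DegTable")
  expect_true(all(deg$fdr >= deg$pvalue))
  expect_identical(deg$direction, sign(deg$log2fc))
  m1 <- ch$truth$marker_lnc[["1"]]
  expect_true(all(deg$deg[deg$gene %in% m1]))
  expect_true(all(deg$log2fc[deg$gene %in% m1] > log2(1.2)))

  # null: permuted labels flag few genes
  set.seed(4)
  perm <- stats::setNames(sample(labs), names(labs))
  deg0 <- one_vs_rest_deg(ch$expr, perm, 1)
  expect_lt(mean(deg0$deg), 0.1)

  # constant gene excluded with warning
  v <- ch$expr$values; v[5, ] <- 3
  expect_warning(
    degc <- one_vs_rest_deg(expression_matrix(v, gene_biotypes(ch$expr)),
                            labs, 1), "constant")
  expect_equal(nrow(degc), nrow(v) - 1L)
  expect_error(one_vs_rest_deg(ch$expr, labs[1:5], 1))
})
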