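# Single-sample signature scoring and group comparisons: rank-based
# ssGSEA (Barbie-style, exponent alpha), marker-mean scores (MCP-counter
# style abundance on log2 values), ESTIMATE-like stromal/immune/combined
# scores, ANOVA/Wilcoxon group tests and one-vs-rest differential
# expression with the log2(1.2) / p < 0.05 screen.

# per-sample ssGSEA enrichment of one gene set.
# `rnk` are within-sample expression ranks (highest expression = N,
# average ranks on ties); `ord` is the strict walk order down the list
# (expression descending, gene id on ties). The score is the sum over
# list positions of the weighted in-set ECDF minus the out-of-set ECDF,
# with in-set weights rank^alpha.
.ssgsea_one <- function(rnk, ord, in_set, alpha) {
  r <- rnk[ord]
  hit <- in_set[ord]
  w <- r^alpha * hit
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!hit) / sum(!hit)
  sum(p_in - p_out)
}

#' ssGSEA signature scores
#'
#' Per sample, genes are ranked by expression (descending; average ranks
#' on ties) and each signature is scored by the difference of the
#' rank^alpha-weighted in-set ECDF and the unweighted out-of-set ECDF,
#' summed along the ranking. With `normalize = TRUE` scores are min-max
#' scaled to \[0, 1\] across samples per signature; unnormalized scores
#' are invariant to any strictly monotone per-sample transform of
#' expression.
#'
#' @param expr an [expression_matrix()] (all biotypes used).
#' @param sets named list of gene sets; sets sharing fewer than 2 genes
#'   with the matrix are skipped with a warning.
#' @param alpha rank weight exponent (0.25).
#' @param normalize min-max scale across samples per signature (TRUE).
#' @return signatures x samples matrix with attribute `method` =
#'   `"ssgsea"`.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  v <- expr$values
  genes <- rownames(v)
  keep <- vapply(sets, function(s) sum(genes %in% s) >= 2L, logical(1))
  if (!all(keep))
    warning("signature(s) with < 2 overlapping genes skipped: ",
            paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
  sets <- sets[keep]
  if (!length(sets)) stop("no scorable signature", call. = FALSE)
  n_genes <- nrow(v)
  memb <- lapply(sets, function(s) genes %in% s)
  scores <- matrix(0, length(sets), ncol(v),
                   dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(ncol(v))) {
    e <- v[, j]
    rnk <- rank(e)  # highest expression gets rank n_genes
    ord <- order(-e, genes)
    for (i in seq_along(sets))
      scores[i, j] <- .ssgsea_one(rnk, ord, memb[[i]], alpha)
  }
  if (normalize && ncol(scores) > 1L) {
    rng <- apply(scores, 1L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    scores <- (scores - rng[1L, ]) / span
  }
  structure(scores, method = "ssgsea")
}

#' Marker-mean signature scores
#'
#' MCP-counter-style abundance: the score of a signature in a sample is
#' the arithmetic mean of the log2 expression of its marker genes. Linear
#' in expression.
#'
#' @inheritParams ssgsea_score
#' @return signatures x samples matrix with attribute `method` =
#'   `"marker_mean"`.
#' @export
marker_mean_score <- function(expr, sets) {
  v <- expr$values
  genes <- rownames(v)
  keep <- vapply(sets, function(s) sum(genes %in% s) >= 1L, logical(1))
  if (!all(keep))
    warning("signature(s) with no overlapping gene skipped: ",
            paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
  sets <- sets[keep]
  if (!length(sets)) stop("no scorable signature", call. = FALSE)
  scores <- t(vapply(sets, function(s)
    colMeans(v[genes %in% s, , drop = FALSE]), numeric(ncol(v))))
  dimnames(scores) <- list(names(sets), colnames(v))
  structure(scores, method = "marker_mean")
}

#' ESTIMATE-like stromal / immune / combined scores
#'
#' Rank-based analogues of the ESTIMATE scores: stromal and immune scores
#' are unnormalized [ssgsea_score()] values of the two gene sets and the
#' combined score is their sum. These are NOT the published trained
#' ESTIMATE transform (tumor purity is a pipeline input, not derived
#' here); the method tag is `"estimate_like"`.
#'
#' @inheritParams ssgsea_score
#' @param stromal_set,immune_set character vectors of gene ids.
#' @return data.frame: sample, stromal, immune, combined.
#' @export
estimate_like_scores <- function(expr, stromal_set, immune_set,
                                 alpha = 0.25) {
  s <- ssgsea_score(expr, list(stromal = stromal_set, immune = immune_set),
                    alpha = alpha, normalize = FALSE)
  if (nrow(s) < 2L)
    stop("stromal and immune sets must both overlap the matrix",
         call. = FALSE)
  out <- data.frame(sample = colnames(s),
                    stromal = s["stromal", ],
                    immune = s["immune", ],
                    combined = s["stromal", ] + s["immune", ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- "estimate_like"
  out
}

#' Compare signature scores between sample groups
#'
#' One-way ANOVA for three or more groups, two-sided Wilcoxon rank-sum
#' for two, applied per signature row.
#'
#' @param scores signatures x samples matrix ([ssgsea_score()] /
#'   [marker_mean_score()] output).
#' @param labels named group labels covering the score columns.
#' @return data.frame: signature, statistic, pvalue, then one mean column
#'   per group.
#' @export
compare_groups <- function(scores, labels) {
  stopifnot(is.matrix(scores))
  labels <- labels[colnames(scores)]
  if (anyNA(labels)) stop("labels missing for some samples", call. = FALSE)
  g <- factor(labels)
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("singleton group: ", paste(names(sizes)[sizes < 2L], collapse = ", "),
         call. = FALSE)
  rows <- lapply(rownames(scores), function(sig) {
    y <- scores[sig, ]
    if (nlevels(g) == 2L) {
      ht <- stats::wilcox.test(y[g == levels(g)[1L]],
                               y[g == levels(g)[2L]], exact = FALSE)
      stat <- unname(ht$statistic)
      p <- ht$p.value
    } else {
      ft <- stats::anova(stats::lm(y ~ g))
      stat <- ft$`F value`[1L]
      p <- ft$`Pr(>F)`[1L]
    }
    mns <- tapply(y, g, mean)
    c(list(signature = sig, statistic = stat, pvalue = p),
      as.list(stats::setNames(as.numeric(mns),
                              paste0("mean_", names(mns)))))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' One-vs-rest differential expression
#'
#' Per gene: `log2fc` is the mean difference (group minus rest; values
#' are already log2) and the p-value a two-sided Welch t-test; FDR by
#' Benjamini-Hochberg. A gene is flagged `deg` when `|log2fc| > lfc_cut`
#' and the RAW p-value is below `p_cut` (the screen is on raw p; the FDR
#' column is reported alongside). Genes constant across all samples are
#' excluded with a warning.
#'
#' @param expr an [expression_matrix()].
#' @param labels named group labels covering the samples.
#' @param group the label defining the "one" group (>= 3 samples each
#'   side).
#' @param lfc_cut log2 fold-change threshold (`log2(1.2)`).
#' @param p_cut raw p-value threshold (0.05).
#' @return data.frame of class `DegTable`: gene, log2fc, pvalue, fdr,
#'   direction, deg.
#' @export
one_vs_rest_deg <- function(expr, labels, group, lfc_cut = log2(1.2),
                            p_cut = 0.05) {
  v <- expr$values
  labels <- labels[colnames(v)]
  if (anyNA(labels)) stop("labels missing for some samples", call. = FALSE)
  in_g <- labels == group
  if (sum(in_g) < 3L || sum(!in_g) < 3L)
    stop("need >= 3 samples in the group and in the rest", call. = FALSE)
  cst <- apply(v, 1L, stats::sd) == 0
  if (any(cst)) {
    warning(sum(cst), " constant gene(s) excluded", call. = FALSE)
    v <- v[!cst, , drop = FALSE]
  }
  n1 <- sum(in_g); n2 <- sum(!in_g)
  m1 <- rowMeans(v[, in_g, drop = FALSE])
  m2 <- rowMeans(v[, !in_g, drop = FALSE])
  s1 <- apply(v[, in_g, drop = FALSE], 1L, stats::var)
  s2 <- apply(v[, !in_g, drop = FALSE], 1L, stats::var)
  se2 <- s1 / n1 + s2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1  # equal within-group constants
  out <- data.frame(
    gene = rownames(v),
    log2fc = m1 - m2,
    pvalue = p,
    fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  out$direction <- sign(out$log2fc)
  out$deg <- abs(out$log2fc) > lfc_cut & out$pvalue < p_cut
  out <- out[order(out$pvalue, out$gene), ]
  rownames(out) <- NULL
  structure(out, class = c("DegTable", "data.frame"), group = group)
}
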