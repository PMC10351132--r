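# Purity-adjusted lncRNA-mRNA association. For a lncRNA i and mRNA j the
# first-order partial correlation removes the linear effect of tumor
# purity from the Pearson correlation; its two-sided p-value comes from
# the Fisher z transform with one adjusting covariate, and the signed rank
# index RI = -ln(P) * sign(PCC) orders mRNAs for enrichment testing.

#' First-order partial correlation given tumor purity
#'
#' Computes
#' \deqn{PCC = (R_{lm} - R_{lp} R_{mp}) /
#'   \sqrt{(1 - R_{lp}^2)(1 - R_{mp}^2)}}
#' where \eqn{R_{lm}}, \eqn{R_{lp}} and \eqn{R_{mp}} are the Pearson
#' correlations of lncRNA with mRNA, lncRNA with purity, and mRNA with
#' purity. Equals the Pearson correlation of the two residual vectors
#' after least-squares regression of each expression vector on purity.
#'
#' @param lnc,mrna numeric expression vectors over the same >= 5 samples.
#' @param purity numeric purity vector, same length.
#' @return the partial correlation, in \[-1, 1\].
#' @export
partial_correlation <- function(lnc, mrna, purity) {
  n <- length(purity)
  stopifnot(length(lnc) == n, length(mrna) == n)
  if (n < 5) stop("need >= 5 samples", call. = FALSE)
  if (stats::sd(lnc) == 0 || stats::sd(mrna) == 0 || stats::sd(purity) == 0)
    stop("correlation undefined: zero-variance input vector", call. = FALSE)
  r_lm <- stats::cor(lnc, mrna)
  r_lp <- stats::cor(lnc, purity)
  r_mp <- stats::cor(mrna, purity)
  if (abs(r_lp) >= 1 || abs(r_mp) >= 1)
    stop("degenerate adjustment: expression collinear with purity",
         call. = FALSE)
  pcc <- (r_lm - r_lp * r_mp) / sqrt((1 - r_lp^2) * (1 - r_mp^2))
  min(1, max(-1, pcc))
}

#' Two-sided p-value for a purity-adjusted correlation
#'
#' Fisher z normal approximation for a first-order partial correlation:
#' \eqn{z = \mathrm{atanh}(pcc) \sqrt{n - 4}} (the -4 reflecting one
#' adjusting covariate), \eqn{p = 2 \Phi(-|z|)}.
#'
#' @param pcc partial correlation, |pcc| < 1 (|pcc| = 1 returns the
#'   smallest positive double with a warning).
#' @param n number of samples (>= 5). Vectorized over `pcc`.
#' @return p-value in (0, 1\].
#' @export
association_pvalue <- function(pcc, n) {
  stopifnot(n >= 5)
  p <- 2 * stats::pnorm(-abs(atanh(pmin(1, pmax(-1, pcc)))) * sqrt(n - 4))
  sat <- abs(pcc) >= 1
  if (any(sat)) {
    warning("|pcc| = 1: p-value saturated at the smallest positive double",
            call. = FALSE)
    p[sat] <- .Machine$double.xmin
  }
  pmax(p, .Machine$double.xmin)
}

#' Signed rank index
#'
#' \eqn{RI = -\ln(P) \cdot \mathrm{sign}(PCC)}; 0 when the correlation is
#' 0. Large positive RI marks strong positive association.
#'
#' @param pvalue p-value(s) in (0, 1\].
#' @param pcc matching correlation(s).
#' @return numeric rank index, vectorized.
#' @export
rank_index <- function(pvalue, pcc) {
  if (any(pvalue <= 0) || any(pvalue > 1))
    stop("pvalue must lie in (0, 1]", call. = FALSE)
  -log(pvalue) * sign(pcc)
}

#' Rank all mRNAs against one lncRNA by purity-adjusted association
#'
#' Computes (PCC, P, RI) for every mRNA versus the given lncRNA, adjusting
#' for purity, and returns the table sorted by RI descending (ties broken
#' by mRNA id, lexicographically). Zero-variance mRNAs are excluded with a
#' warning; the result carries the lncRNA id and the sample count as
#' attributes.
#'
#' @param lncrna_id a gene id with biotype `"lncRNA"` in `expr`.
#' @param expr an [expression_matrix()].
#' @param purity named purity vector covering `sample_ids(expr)`.
#' @return a data.frame of class `AssociationRanking` with columns
#'   `mrna`, `pcc`, `pvalue`, `ri`.
#' @export
rank_mrnas <- function(lncrna_id, expr, purity) {
  if (!lncrna_id %in% gene_ids(expr) ||
      gene_biotypes(expr)[lncrna_id] != "lncRNA")
    stop(lncrna_id, " is not a lncRNA in this matrix", call. = FALSE)
  samples <- sample_ids(expr)
  if (!all(samples %in% names(purity)))
    stop("purity missing for some samples", call. = FALSE)
  pu <- purity[samples]
  y <- expr$values[lncrna_id, ]
  mm <- mrna_values(expr)
  if (nrow(mm) == 0L) stop("no mRNAs in matrix", call. = FALSE)
  keep <- apply(mm, 1L, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance mRNA(s) excluded", call. = FALSE)
    mm <- mm[keep, , drop = FALSE]
    if (nrow(mm) == 0L) stop("no mRNA with nonzero variance", call. = FALSE)
  }
  if (stats::sd(y) == 0)
    stop("lncRNA ", lncrna_id, " has zero variance", call. = FALSE)
  r_lm <- as.numeric(stats::cor(t(mm), y))
  r_mp <- as.numeric(stats::cor(t(mm), pu))
  r_lp <- stats::cor(y, pu)
  if (abs(r_lp) >= 1 || any(abs(r_mp) >= 1))
    stop("degenerate adjustment: expression collinear with purity",
         call. = FALSE)
  pcc <- pmin(1, pmax(-1, (r_lm - r_lp * r_mp) /
                        sqrt((1 - r_lp^2) * (1 - r_mp^2))))
  pv <- association_pvalue(pcc, length(samples))
  ri <- rank_index(pv, pcc)
  out <- data.frame(mrna = rownames(mm), pcc = pcc, pvalue = pv, ri = ri,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ri, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("AssociationRanking", "data.frame"),
            lncrna_id = lncrna_id, n_samples = length(samples))
}

#' Rank mRNAs for every lncRNA in a matrix
#'
#' @param expr an [expression_matrix()].
#' @param purity named purity vector.
#' @param lnc_ids lncRNAs to process (default: all lncRNA-biotype genes).
#' @return named list of [rank_mrnas()] results, one per lncRNA
#'   (zero-variance lncRNAs skipped with a warning).
#' @export
associate_all <- function(expr, purity, lnc_ids = NULL) {
  if (is.null(lnc_ids))
    lnc_ids <- gene_ids(expr)[gene_biotypes(expr) == "lncRNA"]
  ok <- apply(expr$values[lnc_ids, , drop = FALSE], 1L, stats::sd) > 0
  if (!all(ok))
    warning(sum(!ok), " zero-variance lncRNA(s) skipped", call. = FALSE)
  res <- lapply(lnc_ids[ok], rank_mrnas, expr = expr, purity = purity)
  stats::setNames(res, lnc_ids[ok])
}
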