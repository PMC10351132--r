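# Consensus clustering of samples on a lncRNA sub-matrix: PAM (k-medoids,
# build + swap via cluster::pam) on a Spearman-correlation distance, over
# bootstrap subsamples of the cohort; per-k consensus matrices, CDF area
# and PAC summaries, and a relative-delta-area rule for the number of
# clusters.

#' Spearman-correlation distance between samples
#'
#' \eqn{d(s, t) = 1 - \rho(s, t)} with \eqn{\rho} the Spearman correlation
#' of the two samples' feature vectors (average ranks on ties);
#' d in \[0, 2\], d(s, s) = 0.
#'
#' @param x an [expression_matrix()] (typically restricted to the screened
#'   lncRNAs) or a plain features x samples numeric matrix.
#' @return symmetric sample x sample distance matrix.
#' @export
spearman_distance <- function(x) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  stopifnot(is.matrix(v), nrow(v) >= 2L, ncol(v) >= 2L)
  cst <- apply(v, 2L, stats::sd) == 0
  if (any(cst))
    stop("constant feature vector for sample(s): ",
         paste(utils::head(colnames(v)[cst], 5), collapse = ", "),
         call. = FALSE)
  d <- 1 - stats::cor(v, method = "spearman")
  diag(d) <- 0
  d
}

#' Consensus clustering with PAM over bootstrap subsamples
#'
#' For each k in `k_min:k_max`, `n_boot` subsamples of
#' `floor(sample_frac * n)` samples (without replacement) are clustered by
#' PAM on the precomputed Spearman distance; the consensus matrix entry
#' (s, t) is the fraction of subsamples containing both s and t in which
#' they co-cluster (0/0 pairs, never co-sampled, score 0). Per k the area
#' under the CDF of the upper-triangle consensus values and the PAC
#' (proportion of ambiguous clustering: fraction of entries in
#' (0.1, 0.9)) are reported; the number of clusters is chosen by PAC
#' minimization (smallest k on ties), with the relative increase in CDF
#' area (for `k_min` the area itself) reported as the `delta_area`
#' diagnostic; `k` overrides the choice. Final labels come from PAM at
#' the chosen k on the full cohort, renumbered by decreasing cluster
#' size.
#'
#' @inheritParams spearman_distance
#' @param k_min,k_max range of cluster numbers (2..10).
#' @param n_boot bootstrap replicates per k (500).
#' @param sample_frac fraction of samples per replicate (0.8).
#' @param seed integer seed; replicate subsamples are drawn from a seed
#'   stream so results do not depend on sample order.
#' @param k optional override of the chosen number of clusters.
#' @return list of class `ConsensusResult`: `k_values`, `consensus`
#'   (named list of matrices), `cdf_area`, `pac`, `delta_area`,
#'   `chosen_k`, `labels` (named integer vector).
#' @export
consensus_cluster <- function(x, k_min = 2L, k_max = 10L, n_boot = 500L,
                              sample_frac = 0.8, seed = 1L, k = NULL) {
  d <- spearman_distance(x)
  n <- ncol(d)
  if (n < k_max + 2L)
    stop("need at least k_max + 2 samples", call. = FALSE)
  ks <- k_min:k_max
  nsub <- floor(sample_frac * n)
  # subsample by sorted sample id, not by column position, so the drawn
  # subsets (hence the consensus matrices) do not depend on input order
  id_order <- if (!is.null(colnames(d))) order(colnames(d)) else seq_len(n)
  set.seed(seed)
  consensus <- vector("list", length(ks))
  names(consensus) <- paste0("k", ks)
  for (ki in seq_along(ks)) {
    kk <- ks[[ki]]
    co <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    for (b in seq_len(n_boot)) {
      idx <- sort.int(id_order[sample.int(n, nsub)])
      if (length(idx) < kk) {
        warning("subsample smaller than k = ", kk, "; replicate skipped",
                call. = FALSE)
        next
      }
      cl <- cluster::pam(stats::as.dist(d[idx, idx]), kk,
                         cluster.only = TRUE)
      tog[idx, idx] <- tog[idx, idx] + 1
      same <- outer(cl, cl, `==`)
      co[idx, idx] <- co[idx, idx] + same
    }
    cm <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cm) <- 1
    dimnames(cm) <- dimnames(d)
    consensus[[ki]] <- cm
  }
  ut <- upper.tri(consensus[[1L]])
  vals <- lapply(consensus, function(m) m[ut])
  # area under the ECDF on [0, 1] equals 1 - mean for [0, 1]-valued data
  cdf_area <- vapply(vals, function(v) 1 - mean(v), numeric(1))
  pac <- vapply(vals, function(v) mean(v > 0.1 & v < 0.9), numeric(1))
  delta <- c(cdf_area[[1L]],
             diff(cdf_area) / utils::head(cdf_area, -1L))
  names(delta) <- names(cdf_area)
  chosen_k <- if (is.null(k)) ks[[which.min(pac)]] else as.integer(k)
  if (!chosen_k %in% ks) stop("k override outside k range", call. = FALSE)
  labels <- cluster::pam(stats::as.dist(d), chosen_k, cluster.only = TRUE)
  labels <- .renumber_by_size(labels)
  names(labels) <- colnames(d)
  structure(list(
    k_values = ks,
    consensus = consensus,
    cdf_area = stats::setNames(cdf_area, names(consensus)),
    pac = stats::setNames(pac, names(consensus)),
    delta_area = delta,
    chosen_k = chosen_k,
    labels = labels), class = "ConsensusResult")
}

# relabel clusters 1..k by decreasing size (ties: first occurrence)
.renumber_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult: k in", min(x$k_values), "..", max(x$k_values),
      "; chosen k =", x$chosen_k, "\n")
  cat("cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same
#' samples; 1 for identical partitions (up to relabeling), ~0 at random.
#'
#' @param a,b labeling vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  s_ij <- sum(comb2(tab))
  s_a <- sum(comb2(rowSums(tab)))
  s_b <- sum(comb2(colSums(tab)))
  s_n <- comb2(length(a))
  expected <- s_a * s_b / s_n
  denom <- (s_a + s_b) / 2 - expected
  if (denom == 0) return(1)
  (s_ij - expected) / denom
}
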