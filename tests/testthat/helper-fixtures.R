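# Shared fixtures and independent oracles. Everything is generated in
# code; no binary data.

# reduced cohort for unit tests (fast: ~1 s to generate and associate)
small_cohort <- function(seed = 1, ...) {
  args <- list(n_samples = 80L, n_mrna = 300L, n_lncrna = 40L,
               pathway_size = 30L, n_true_lnc = 5L, n_risk_lnc = 3L,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  generate_cohort(do.call(sim_config, args))
}

# tiny labelled expression matrix
tiny_expr <- function(n_genes = 10, n_samples = 6, seed = 1,
                      biotype = "mRNA") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, stats::setNames(rep(biotype, n_genes), rownames(m)))
}

# Brute-force enrichment-score oracle: literal running sum over the full
# ranking, independent of the package's position-based implementation.
es_oracle <- function(ranking, gene_set) {
  hit <- ranking$mrna %in% gene_set
  w <- abs(ranking$ri)
  if (sum(w[hit]) == 0) w[hit] <- 1
  inc <- w * hit / sum(w[hit])
  dec <- 1 / (nrow(ranking) - sum(hit))
  running <- cumsum(ifelse(hit, inc, -dec))
  hi <- max(running); lo <- min(running)
  if (hi >= -lo) hi else lo  # positive branch preferred on exact ties
}

# residual-regression oracle for the purity-adjusted correlation
partial_cor_oracle <- function(x, y, p) {
  rx <- stats::residuals(stats::lm(x ~ p))
  ry <- stats::residuals(stats::lm(y ~ p))
  stats::cor(rx, ry)
}

# a ranking data.frame in the shape rank_mrnas() returns
make_ranking <- function(ri, genes = sprintf("G%03d", seq_along(ri))) {
  d <- data.frame(mrna = genes, pcc = sign(ri), pvalue = exp(-abs(ri)),
                  ri = ri, stringsAsFactors = FALSE)
  d <- d[order(-d$ri, d$mrna), ]
  rownames(d) <- NULL
  d
}
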