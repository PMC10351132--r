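#' Construct an ExpressionMatrix
#'
#' The central expression container: a genes x samples numeric matrix of
#' log2-scale values together with a gene biotype map partitioning genes
#' into lncRNA, mRNA and other. Values are assumed already log2-normalized;
#' the pipeline performs no normalization of its own.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry unique, non-empty dimnames and contain only finite values.
#' @param biotype named character vector mapping gene id to one of
#'   `"lncRNA"`, `"mRNA"`, `"other"`. Genes absent from the map are
#'   labelled `"other"` (and excluded from analysis by the accessors).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `biotype` (character vector aligned to
#'   `rownames(values)`).
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' em <- expression_matrix(m, c(g1 = "lncRNA", g2 = "mRNA"))
#' gene_biotypes(em)
#' @export
expression_matrix <- function(values, biotype = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty", call. = FALSE)
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ",
         paste(utils::head(gid[duplicated(gid)], 3), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ",
         paste(utils::head(sid[duplicated(sid)], 3), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  bt <- rep("other", length(gid)); names(bt) <- gid
  if (length(biotype)) {
    biotype <- biotype[names(biotype) %in% gid]
    biotype[!biotype %in% c("lncRNA", "mRNA")] <- "other"
    bt[names(biotype)] <- unname(biotype)
  }
  structure(list(values = values, biotype = bt), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tab <- table(x$biotype)
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples (lncRNA %d, mRNA %d, other %d)\n",
    nrow(x$values), ncol(x$values),
    sum(x$biotype == "lncRNA"), sum(x$biotype == "mRNA"),
    sum(x$biotype == "other")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Accessors for ExpressionMatrix
#'
#' `gene_ids`/`sample_ids` return identifier vectors, `gene_biotypes` the
#' biotype map, `lnc_values`/`mrna_values` the sub-matrices restricted to
#' lncRNA or mRNA rows (genes with biotype `"other"` are never analyzed).
#'
#' @param x an `ExpressionMatrix`.
#' @name ExpressionMatrix-accessors
NULL

#' @rdname ExpressionMatrix-accessors
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname ExpressionMatrix-accessors
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname ExpressionMatrix-accessors
#' @export
gene_biotypes <- function(x) x$biotype

#' @rdname ExpressionMatrix-accessors
#' @export
lnc_values <- function(x)
  x$values[x$biotype == "lncRNA", , drop = FALSE]

#' @rdname ExpressionMatrix-accessors
#' @export
mrna_values <- function(x)
  x$values[x$biotype == "mRNA", , drop = FALSE]

#' Restrict an ExpressionMatrix to a subset of genes and/or samples
#'
#' @param x an `ExpressionMatrix`.
#' @param genes,samples character vectors of ids to keep (default: all).
#'   Unknown ids are an error.
#' @return an `ExpressionMatrix`.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  g <- if (is.null(genes)) gene_ids(x) else genes
  s <- if (is.null(samples)) sample_ids(x) else samples
  miss <- setdiff(g, gene_ids(x))
  if (length(miss))
    stop("unknown gene ids: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  miss <- setdiff(s, sample_ids(x))
  if (length(miss))
    stop("unknown sample ids: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  expression_matrix(x$values[g, s, drop = FALSE], x$biotype[g])
}
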