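# Readers/writers for the plain-text formats the pipeline exchanges:
# expression TSV (genes x samples), two-column biotype TSV, GMT gene sets,
# clinical TSV (sample, os_time, os_status, extra covariates) and purity TSV.

#' Read an expression matrix with its biotype annotation
#'
#' The expression file is a TSV whose header row holds sample ids and whose
#' first column holds gene ids; all remaining cells must be numeric
#' log2-scale values. The biotype file is a two-column TSV (`gene_id`,
#' `biotype`); genes absent from it are labelled `"other"` and excluded
#' from analysis. Duplicate gene rows keep the row with the highest mean
#' expression (a warning reports the count dropped).
#'
#' @param path path to the expression TSV.
#' @param biotype_path path to the biotype TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, biotype_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2L)
    stop("expression file ", path, ": need a gene-id column plus >=1 sample",
         call. = FALSE)
  gid <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("expression file ", path, ": non-numeric column(s) ",
         paste(utils::head(colnames(vals)[bad], 3), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- gid
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("expression file ", path, ": missing/non-numeric value at gene ",
         gid[idx[1L]], ", sample ", colnames(m)[idx[2L]], call. = FALSE)
  }
  if (anyDuplicated(gid)) {
    keep <- .dedupe_by_mean(m)
    warning(sprintf("dropped %d duplicate gene row(s), keeping highest mean",
                    nrow(m) - length(keep)), call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  bt <- read_biotypes(biotype_path)
  expression_matrix(m, bt)
}

# rows to keep when gene ids repeat: highest row mean wins, first on ties
.dedupe_by_mean <- function(m) {
  mu <- rowMeans(m)
  ord <- order(rownames(m), -mu)
  keep <- ord[!duplicated(rownames(m)[ord])]
  sort(keep)
}

#' @rdname read_expression
#' @export
read_biotypes <- function(biotype_path) {
  bt <- data.table::fread(biotype_path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("gene_id", "biotype")
  if (!all(need %in% colnames(bt)))
    stop("biotype file ", biotype_path, ": columns gene_id, biotype required",
         call. = FALSE)
  stats::setNames(as.character(bt$biotype), as.character(bt$gene_id))
}

#' Write an expression matrix (and its biotype map) to TSV
#'
#' @param x an `ExpressionMatrix`.
#' @param path,biotype_path output file paths; `biotype_path = NULL` skips
#'   the biotype file.
#' @return invisibly, `path`.
#' @export
write_expression <- function(x, path, biotype_path = NULL) {
  # %.17g gives shortest-lossless doubles: read-back is bit-exact
  df <- data.frame(gene_id = gene_ids(x),
                   apply(x$values, 2L, sprintf, fmt = "%.17g"),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  if (!is.null(biotype_path))
    data.table::fwrite(
      data.frame(gene_id = names(x$biotype), biotype = unname(x$biotype)),
      biotype_path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description (discarded), then member genes, all
#' tab-separated. Duplicate genes within a line are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors (class `GeneSetCollection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file ", path, " is empty", call. = FALSE)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT file ", path, " line ", i, ": fewer than 3 fields",
           call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set ", f[1L], ": duplicate genes removed", call. = FALSE)
      genes <- unique(genes)
    }
    if (!length(genes))
      stop("GMT file ", path, " line ", i, ": empty gene set", call. = FALSE)
    nms[i] <- f[1L]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  structure(sets, class = c("GeneSetCollection", "list"))
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description recycled description column (GMT field 2).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns `sample`, `os_time` (positive, days by default) and
#' `os_status` (0 censored / 1 event). Rows with missing time or status are
#' dropped with a message; any other column is carried along as a covariate.
#'
#' @param path path to a clinical TSV.
#' @return a data.frame with one row per sample.
#' @export
read_clinical <- function(path) {
  cl <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("sample", "os_time", "os_status")
  miss <- setdiff(need, colnames(cl))
  if (length(miss))
    stop("clinical file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  drop <- is.na(cl$os_time) | is.na(cl$os_status)
  if (any(drop)) {
    message(sum(drop), " clinical row(s) without survival information dropped")
    cl <- cl[!drop, , drop = FALSE]
  }
  validate_clinical(cl)
}

validate_clinical <- function(cl) {
  if (!all(cl$os_status %in% c(0, 1)))
    stop("os_status must be 0 (censored) or 1 (event)", call. = FALSE)
  if (!all(cl$os_time > 0))
    stop("os_time must be positive", call. = FALSE)
  if (anyDuplicated(cl$sample))
    stop("duplicate sample ids in clinical table", call. = FALSE)
  cl$sample <- as.character(cl$sample)
  rownames(cl) <- NULL
  cl
}

#' @rdname read_clinical
#' @param cl clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(cl, path) {
  num <- vapply(cl, is.double, logical(1))
  cl[num] <- lapply(cl[num], sprintf, fmt = "%.17g")
  data.table::fwrite(cl, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write per-sample tumor purity
#'
#' Two-column TSV (`sample`, `purity`), purity in \[0, 1\]. Returned as a
#' named numeric vector.
#'
#' @param path file path.
#' @return named numeric vector of purities.
#' @export
read_purity <- function(path) {
  pu <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample", "purity") %in% colnames(pu)))
    stop("purity file ", path, ": columns sample, purity required",
         call. = FALSE)
  v <- pu$purity
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("purity values must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(pu$sample))
    stop("duplicate sample ids in purity table", call. = FALSE)
  stats::setNames(as.numeric(v), as.character(pu$sample))
}

#' @rdname read_purity
#' @param purity named numeric vector.
#' @export
write_purity <- function(purity, path) {
  data.table::fwrite(
    data.frame(sample = names(purity),
               purity = sprintf("%.17g", unname(purity))),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Common-sample intersection across pipeline inputs
#'
#' All analyses run on the samples shared by the expression matrix, the
#' clinical table and the purity vector; the intersection is computed once
#' here (size reported via `message`) and reused downstream.
#'
#' @param expr an `ExpressionMatrix`.
#' @param clinical clinical data.frame (or `NULL`).
#' @param purity named purity vector (or `NULL`).
#' @return character vector of sample ids, in expression-matrix order.
#' @export
common_samples <- function(expr, clinical = NULL, purity = NULL) {
  ids <- sample_ids(expr)
  if (!is.null(clinical)) ids <- ids[ids %in% clinical$sample]
  if (!is.null(purity)) ids <- ids[ids %in% names(purity)]
  if (!length(ids)) stop("no samples shared across inputs", call. = FALSE)
  message("analysis set: ", length(ids), " shared sample(s)")
  ids
}
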