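#' Read an expression matrix from tab-separated text
#'
#' Expects sample ids on the first row, gene ids in the first column, and
#' real-valued (typically log-scale) expression values. Validation and
#' preprocessing, in order:
#' * ragged rows are a fatal parse error naming the first offending line;
#' * duplicate gene ids are collapsed by averaging their rows (warning);
#' * missing cells (`NA`/empty) are imputed with the gene's row mean
#'   (rows that are entirely missing are dropped);
#' * zero-variance rows are dropped with a warning, since a constant gene
#'   has no defined correlation with anything.
#'
#' @param path path to the matrix file.
#' @return Numeric matrix, genes x samples, with unique `rownames` (gene
#'   ids) and `colnames` (sample ids).
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression file needs a header and >= 1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading corner cell for the gene-id column
  nsamp <- length(fields[[2]]) - 1L
  samples <- utils::tail(header, nsamp)
  nf <- lengths(fields[-1])
  if (any(nf != nsamp + 1L))
    stop("ragged row at line ", which(nf != nsamp + 1L)[1] + 1L,
         ": expected ", nsamp + 1L, " fields, got ", nf[nf != nsamp + 1L][1])
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  genes <- vapply(fields[-1], `[`, "", 1L)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = nsamp,
                 dimnames = list(genes, samples))
  for (i in seq_along(genes)) {
    v <- fields[[i + 1L]][-1L]
    v[v %in% c("", "NA", "na", "NaN")] <- NA
    vals[i, ] <- suppressWarnings(as.numeric(v))
  }
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)), " duplicate gene id row(s) collapsed by mean")
    vals <- rowsum(vals, genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  validate_expression(vals)
}

#' Validate and clean an in-memory expression matrix
#'
#' Applies the same missing-value and zero-variance policy as
#' [load_expression()] to a matrix already in memory.
#'
#' @param x numeric matrix with gene `rownames` and sample `colnames`.
#' @return The cleaned matrix.
#' @export
validate_expression <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  all_na <- rowSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-missing gene row(s) dropped")
    x <- x[!all_na, , drop = FALSE]
  }
  if (anyNA(x)) {
    n_imp <- sum(is.na(x))
    rm <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm[idx[, 1]]
    message(n_imp, " missing cell(s) imputed with the gene row mean")
  }
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene row(s) dropped")
    x <- x[v > 0, , drop = FALSE]
  }
  x
}

#' Write an expression matrix as tab-separated text
#'
#' @param x numeric matrix, genes x samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = TRUE)
  invisible(path)
}

#' Build an absolute-correlation store over an expression matrix
#'
#' The store caches absolute pairwise Pearson correlations |cor(X, Y)|,
#' which every CSA score and every permutation null re-reads heavily. When
#' the gene count is at most `cache_genes`, the full genes x genes
#' absolute-correlation matrix is computed once; above that limit pairs are
#' computed on demand and memoized. The store is an environment, so the
#' dataset-global cutoff computed by [global_cutoff()] is recorded on it in
#' place.
#'
#' @param expr numeric matrix, genes x samples (see [load_expression()]).
#' @param cache_genes gene-count limit for computing the full correlation
#'   matrix up front (default 12000; ~1.1 GB at the limit).
#' @return An environment of class `correlation_store` with fields `expr`,
#'   `C` (cached |cor| matrix or `NULL`), `cutoff` (`NA` until
#'   [global_cutoff()] runs) and `genes`.
#' @export
correlation_store <- function(expr, cache_genes = 12000) {
  expr <- validate_expression(expr)
  store <- new.env(parent = emptyenv())
  store$expr <- expr
  store$genes <- rownames(expr)
  if (nrow(expr) <= cache_genes) {
    C <- abs(stats::cor(t(expr)))
    diag(C) <- 1
    store$C <- C
  } else {
    store$C <- NULL
    store$memo <- new.env(parent = emptyenv())
  }
  store$cutoff <- NA_real_
  class(store) <- "correlation_store"
  store
}

#' @export
print.correlation_store <- function(x, ...) {
  cat(sprintf("correlation_store: %d genes x %d samples, %s, cutoff = %s\n",
              nrow(x$expr), ncol(x$expr),
              if (is.null(x$C)) "on-demand" else "fully cached",
              if (is.na(x$cutoff)) "unset" else format(x$cutoff)))
  invisible(x)
}

#' Absolute Pearson correlation between two genes
#'
#' @param store a `correlation_store`.
#' @param x,y gene ids present in the store.
#' @return |cor(x, y)| in \[0, 1\]; symmetric in its arguments.
#' @export
abs_correlation <- function(store, x, y) {
  i <- match(x, store$genes)
  j <- match(y, store$genes)
  if (is.na(i)) stop("unknown gene: ", x)
  if (is.na(j)) stop("unknown gene: ", y)
  if (!is.null(store$C)) return(store$C[i, j])
  if (i == j) return(1)
  key <- paste(min(i, j), max(i, j))
  hit <- store$memo[[key]]
  if (!is.null(hit)) return(hit)
  v <- abs(stats::cor(store$expr[i, ], store$expr[j, ]))
  store$memo[[key]] <- v
  v
}

#' Dataset-global coherence cutoff
#'
#' The ratio score counts regulatee pairs whose absolute correlation exceeds
#' a dataset-global cutoff, fixed at the 95th percentile of the distribution
#' of all pairwise absolute correlations. When the number of gene pairs
#' exceeds `max_pairs`, the percentile is estimated from `n_sample`
#' uniformly sampled distinct pairs (seeded); the 95th percentile is stable
#' under subsampling at that scale. Percentiles use linear interpolation
#' between order statistics (R quantile type 7).
#'
#' The value is stored on the store (`store$cutoff`) and returned.
#'
#' @param store a `correlation_store` with at least 2 genes.
#' @param probs percentile to use (default 0.95).
#' @param max_pairs exhaustive-enumeration limit (default 5e6 pairs).
#' @param n_sample number of pairs sampled above the limit (default 1e6).
#' @param seed RNG seed for pair sampling.
#' @return The cutoff, a real in \[0, 1\].
#' @export
global_cutoff <- function(store, probs = 0.95, max_pairs = 5e6,
                          n_sample = 1e6, seed = 1L) {
  n <- length(store$genes)
  if (n < 2) stop("need at least 2 genes to compute a pairwise cutoff")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs && !is.null(store$C)) {
    vals <- store$C[upper.tri(store$C)]
  } else {
    set.seed(seed)
    m <- min(n_sample, n_pairs)
    # sample distinct unordered pairs by linear pair index
    pick <- if (n_pairs <= n_sample) seq_len(n_pairs) else
      sample(n_pairs, m)
    pr <- pair_from_index(pick, n)
    vals <- if (!is.null(store$C)) store$C[cbind(pr$i, pr$j)] else
      vapply(seq_along(pr$i), function(k) {
        abs(stats::cor(store$expr[pr$i[k], ], store$expr[pr$j[k], ]))
      }, 0)
  }
  store$cutoff <- unname(stats::quantile(vals, probs, type = 7))
  store$cutoff
}

# map linear index of an unordered pair (row-major over i < j) to (i, j)
pair_from_index <- function(k, n) {
  # i is the largest value with (i-1)*(2n-i)/2 < k
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  base <- (i - 1) * (2 * n - i) / 2
  j <- i + (k - base)
  list(i = as.integer(i), j = as.integer(j))
}
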