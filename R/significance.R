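#' Permutation-test configuration
#'
#' Bundles the settings of the two permutation null models. `method =
#' "gene"` scores randomly drawn regulatee sets of matched size; `method =
#' "graph"` re-scores each regulator on degree-preserving edge-switched
#' randomizations of the causal network. `switches_per_edge` is the
#' standard mixing rule of thumb for edge switching (an average of 3
#' accepted switches per edge); `initial_batch_K` is the starting number of
#' accepted switches between weak-connectivity checks (default |edges|/10,
#' doubled after a passed check, halved after a failed one).
#'
#' @param method `"gene"` or `"graph"`.
#' @param n_permutations number of null draws (>= 1); 1000 is a sensible
#'   analysis default, smaller values suit quick checks.
#' @param seed RNG seed used for all draws.
#' @param switches_per_edge accepted edge switches per edge (> 0).
#' @param initial_batch_K starting batch size between connectivity checks,
#'   or `NULL` for |edges|/10.
#' @param fdr_threshold FDR significance threshold used in reports.
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(method = c("graph", "gene"),
                               n_permutations = 1000, seed = 1L,
                               switches_per_edge = 3,
                               initial_batch_K = NULL,
                               fdr_threshold = 0.05) {
  method <- match.arg(method)
  stopifnot(n_permutations >= 1, switches_per_edge > 0,
            fdr_threshold > 0, fdr_threshold <= 1)
  structure(list(method = method,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 switches_per_edge = switches_per_edge,
                 initial_batch_K = initial_batch_K,
                 fdr_threshold = fdr_threshold),
            class = "permutation_config")
}

#' Read a permutation configuration from a key = value file
#'
#' Recognized keys match the arguments of [permutation_config()]; `#`
#' comments and blank lines are ignored; unknown keys raise an error.
#'
#' @param path path to the config file.
#' @return A `permutation_config`.
#' @export
read_permutation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- c("method", "n_permutations", "seed", "switches_per_edge",
             "initial_batch_K", "fdr_threshold")
  if (any(!trimws(keys) %in% known))
    stop("unknown config key(s): ",
         paste(setdiff(trimws(keys), known), collapse = ", "))
  args <- stats::setNames(as.list(vals), trimws(keys))
  for (k in setdiff(names(args), "method")) args[[k]] <- as.numeric(args[[k]])
  do.call(permutation_config, args)
}

#' Gene-permutation null distributions
#'
#' The gene-permutation null compares a regulator's score to the scores of
#' regulatee sets of the same size n drawn uniformly (without replacement)
#' from the measured gene universe. Because the null depends on n only,
#' draws are shared across regulators with equal regulatee counts.
#'
#' @param store a `correlation_store` with the full correlation matrix
#'   cached and a computed cutoff.
#' @param net a filtered `causal_network`.
#' @param score `"ratio"` or `"mean"`.
#' @param cfg a [permutation_config()] (its `method` is ignored here).
#' @return Numeric matrix of null scores, one row per regulator (rownames),
#'   `cfg$n_permutations` columns.
#' @export
gene_permutation_null <- function(store, net, score = c("ratio", "mean"), cfg) {
  score <- match.arg(score)
  sets <- regulatee_sets(net)
  ns <- lengths(sets)
  universe <- seq_along(store$genes)
  if (any(ns > length(universe)))
    stop("regulatee count exceeds the measured gene universe")
  if (is.na(store$cutoff)) global_cutoff(store)
  stopifnot(!is.null(store$C))
  set.seed(cfg$seed)
  by_n <- sort(unique(ns))
  null_by_n <- matrix(NA_real_, length(by_n), cfg$n_permutations,
                      dimnames = list(as.character(by_n), NULL))
  for (b in seq_len(cfg$n_permutations)) {
    draws <- lapply(by_n, function(n) sample(universe, n))
    s <- cpp_score_sets(store$C, draws, store$cutoff)
    null_by_n[, b] <- if (score == "mean") s$mu else
      2 * s$c_pairs / (s$n * (s$n - 1))
  }
  out <- null_by_n[as.character(ns), , drop = FALSE]
  rownames(out) <- names(sets)
  out
}

#' Propose a single edge switch
#'
#' Given distinct edges (a, b) and (c, d), the switch replaces them with
#' (a, d) and (c, b), preserving every node's in- and out-degree. The
#' proposal is rejected -- the network is returned unchanged with attribute
#' `accepted = FALSE` -- when either new edge would be a self-loop or
#' already exists (which also covers the degenerate a = c and b = d cases).
#' Each switched edge keeps the sign of the edge that contributed its
#' regulator endpoint.
#'
#' @param net a `causal_network`.
#' @param e1,e2 integer row indices into `net$edges`.
#' @return The (possibly unchanged) `causal_network`, with a logical
#'   attribute `accepted`.
#' @export
edge_switch <- function(net, e1, e2) {
  e <- net$edges
  stopifnot(e1 != e2, e1 >= 1, e2 >= 1, e1 <= nrow(e), e2 <= nrow(e))
  a <- e$regulator[e1]; b <- e$regulatee[e1]
  cc <- e$regulator[e2]; d <- e$regulatee[e2]
  reject <- function() { attr(net, "accepted") <- FALSE; net }
  if (a == d || cc == b) return(reject())
  key <- paste(e$regulator, e$regulatee, sep = "\r")
  if (paste(a, d, sep = "\r") %in% key || paste(cc, b, sep = "\r") %in% key)
    return(reject())
  e$regulatee[e1] <- d
  e$regulatee[e2] <- b
  net$edges <- e
  attr(net, "accepted") <- TRUE
  net
}

#' Degree-preserving randomization of a causal network
#'
#' Repeatedly applies random edge switches (see [edge_switch()]) until the
#' accepted-switch count reaches `switches_per_edge * |edges|`, the usual
#' mixing rule of thumb. Switches run in adaptive batches of K between
#' weak-connectivity checks: a batch that leaves the component count no
#' larger than the input's is committed and K doubles, otherwise the batch
#' is rolled back and K halves (minimum 1). For a weakly connected input
#' this is exactly the classical connectivity-preserving scheme; a
#' disconnected input is accepted with the check relaxed to "the number of
#' weak components does not increase". Every output preserves each node's
#' in- and out-degree and remains simple.
#'
#' @param net a simple `causal_network` (no self-loops, no parallel edges).
#' @param cfg a [permutation_config()]; only `switches_per_edge` and
#'   `initial_batch_K` are used. The caller controls the RNG state
#'   (`set.seed`) for reproducibility.
#' @return The randomized `causal_network`, with a `switch_stats` attribute
#'   (accepted, rejected, checks, failures).
#' @export
randomize_graph <- function(net, cfg = permutation_config()) {
  e <- net$edges
  if (any(e$regulator == e$regulatee)) stop("input network has self-loops")
  if (anyDuplicated(paste(e$regulator, e$regulatee, sep = "\r")))
    stop("input network has parallel edges")
  ids <- unique(c(e$regulator, e$regulatee))
  from <- match(e$regulator, ids)
  to <- match(e$regulatee, ids)
  ncomp <- cpp_weak_components(from, to, length(ids))
  k0 <- cfg$initial_batch_K %||% max(1L, nrow(e) %/% 10L)
  res <- cpp_randomize_graph(from, to, length(ids), cfg$switches_per_edge,
                             as.integer(k0), ncomp)
  if (isTRUE(res$exhausted))
    warning("edge switching stalled before reaching the target switch count")
  e$regulatee <- ids[res$to]
  net$edges <- e
  attr(net, "switch_stats") <- res[c("accepted", "rejected", "checks", "failures")]
  net
}

#' Graph-permutation null distributions
#'
#' Scores every regulator on `cfg$n_permutations` independent
#' degree-preserving randomizations of the causal network; regulator R's
#' null distribution is its own score across randomized networks. Unlike
#' the gene permutation, this null conditions on the full bipartite degree
#' structure: each regulator keeps its regulatee count and each regulatee
#' keeps the number of regulators controlling it.
#'
#' @inheritParams gene_permutation_null
#' @return Numeric matrix of null scores, regulators x permutations.
#' @export
graph_permutation_null <- function(store, net, score = c("ratio", "mean"), cfg) {
  score <- match.arg(score)
  if (is.na(store$cutoff)) global_cutoff(store)
  stopifnot(!is.null(store$C))
  regs <- sort(unique(net$edges$regulator))
  null <- matrix(NA_real_, length(regs), cfg$n_permutations,
                 dimnames = list(regs, NULL))
  set.seed(cfg$seed)
  for (b in seq_len(cfg$n_permutations)) {
    rnet <- randomize_graph(net, cfg)
    sets <- split(match(rnet$edges$regulatee, store$genes),
                  rnet$edges$regulator)
    if (anyNA(unlist(sets, use.names = FALSE)))
      stop("regulatee(s) missing from expression data")
    s <- cpp_score_sets(store$C, sets, store$cutoff)
    null[names(sets), b] <- if (score == "mean") s$mu else
      2 * s$c_pairs / (s$n * (s$n - 1))
  }
  null
}

#' Empirical permutation p-value
#'
#' Add-one estimator p = (1 + #\{null >= observed\}) / (1 + N), which is never
#' zero and counts ties as exceedances (conservative).
#'
#' @param observed observed score(s); a named vector aligned with the rows
#'   of `null`, or a single value when `null` is a vector.
#' @param null numeric matrix of null scores (regulators x permutations) or
#'   a vector for a single regulator.
#' @return p-value(s) in (0, 1\].
#' @export
empirical_pvalue <- function(observed, null) {
  if (is.vector(null)) null <- matrix(null, nrow = 1)
  stopifnot(length(observed) == nrow(null), ncol(null) >= 1)
  (1 + rowSums(null >= observed)) / (1 + ncol(null))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]); output order matches
#' the input, values are monotone in the p-value ranks, each adjusted value
#' is at least its raw p, capped at 1.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return Vector of BH-adjusted p-values (estimated FDR at each cut).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
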