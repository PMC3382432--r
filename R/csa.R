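#' Run a full Correlation Set Analysis
#'
#' End-to-end pipeline: filters the causal network against the measured
#' genes, builds the absolute-correlation store, fixes the dataset-global
#' cutoff at the 95th percentile of all pairwise correlations, scores every
#' regulator with the chosen scoring function, assesses significance with
#' the chosen permutation null, and applies Benjamini-Hochberg FDR
#' adjustment. The result is a rank-ordered table of candidate active
#' regulators.
#'
#' @param expr numeric expression matrix, genes x samples (see
#'   [load_expression()]); genes absent from the causal network are allowed
#'   and simply never scored.
#' @param net a `causal_network` (filtered internally).
#' @param score `"ratio"` or `"mean"` scoring function.
#' @param method permutation null: `"graph"` (degree-preserving network
#'   randomization), `"gene"` (size-matched random regulatee sets) or
#'   `"none"` (scores only, no p-values).
#' @param n_permutations number of permutations (default 1000).
#' @param seed RNG seed for all permutation draws.
#' @param fdr_threshold FDR threshold recorded on the result (default 0.05).
#' @param include_chemical include chemical/environmental regulators
#'   (`CHEM:`/`ENV:` prefixes)? Default `FALSE`.
#' @param restrict_to_network drop expression rows for genes outside the
#'   causal network before computing correlations and the cutoff (default
#'   `TRUE`, matching the practice of discarding genes the network does not
#'   cover).
#' @return A `csa_results` data frame (see [score_all()]) ordered by
#'   p-value then descending score, with attributes `cutoff`, `method`,
#'   `score`, `n_permutations` and `fdr_threshold`.
#' @examples
#' net <- synthesize_network(20, 80, d_max = 8, seed = 1)
#' expr <- synthesize_baseline(regulatees(net), m_samples = 60, seed = 2)
#' res <- run_csa(expr, net, score = "ratio", method = "gene",
#'                n_permutations = 50, seed = 3)
#' head(res[, c("regulator", "n", "mu_R", "F_R", "p_value", "fdr")])
#' @export
run_csa <- function(expr, net, score = c("ratio", "mean"),
                    method = c("graph", "gene", "none"),
                    n_permutations = 1000, seed = 1L,
                    fdr_threshold = 0.05, include_chemical = FALSE,
                    restrict_to_network = TRUE) {
  score <- match.arg(score)
  method <- match.arg(method)
  expr <- validate_expression(expr)
  if (restrict_to_network) {
    keep <- rownames(expr) %in% unique(c(net$edges$regulator, net$edges$regulatee))
    if (!any(keep)) stop("no measured gene matches the causal network")
    expr <- expr[keep, , drop = FALSE]
  }
  fnet <- filter_network(net, rownames(expr))
  if (!nrow(fnet$edges)) {
    warning("network is empty after filtering")
    return(empty_results())
  }
  if (!include_chemical && any(fnet$edges$chemical)) {
    fnet$edges <- fnet$edges[!fnet$edges$chemical, , drop = FALSE]
    fnet <- filter_network(fnet, rownames(expr))
  }
  store <- correlation_store(expr)
  global_cutoff(store)
  res <- score_all(store, fnet, include_chemical = include_chemical)
  if (method != "none" && nrow(res)) {
    cfg <- permutation_config(method = method,
                              n_permutations = n_permutations, seed = seed,
                              fdr_threshold = fdr_threshold)
    null <- if (method == "gene")
      gene_permutation_null(store, fnet, score, cfg)
    else
      graph_permutation_null(store, fnet, score, cfg)
    obs <- if (score == "mean") res$mu_R else res$F_R
    names(obs) <- res$regulator
    res$p_value <- empirical_pvalue(obs, null[res$regulator, , drop = FALSE])
    res$fdr <- bh_fdr(res$p_value)
    res <- res[order(res$p_value, -if (score == "mean") res$mu_R else res$F_R), ,
               drop = FALSE]
  } else {
    res <- res[order(-if (score == "mean") res$mu_R else res$F_R), , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "cutoff") <- store$cutoff
  attr(res, "score") <- score
  attr(res, "method") <- method
  attr(res, "n_permutations") <- if (method == "none") 0L else as.integer(n_permutations)
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}

#' Ranking scores for ROC evaluation
#'
#' Returns the per-regulator quantity used to rank candidates on a ROC
#' curve: 1 - p-value when permutation p-values are available, otherwise
#' the raw coherence score.
#'
#' @param results a `csa_results` data frame.
#' @return Named numeric vector (higher = stronger candidate).
#' @export
ranking_scores <- function(results) {
  v <- if (all(is.na(results$p_value))) {
    if (identical(attr(results, "score"), "mean")) results$mu_R else results$F_R
  } else 1 - results$p_value
  stats::setNames(v, results$regulator)
}
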