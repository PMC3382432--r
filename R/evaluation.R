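#' ROC curve over regulator rankings
#'
#' Builds the receiver-operating characteristic of a scored regulator list
#' against a ground-truth set of active regulators. Regulators are called
#' positive at score >= threshold; one point is emitted per distinct score
#' (ties collapse into a single threshold), with TPR = TP / (TP + FN) and
#' FPR = FP / (FP + TN), endpoints (0,0) and (1,1) included, and AUC by the
#' trapezoid rule.
#'
#' @param scores named numeric vector, one score per regulator (higher =
#'   more likely active).
#' @param truth character vector of truly active regulator ids (a subset of
#'   `names(scores)`, with both classes non-empty).
#' @return A list of class `csa_roc`: `points` (data frame with columns
#'   `threshold`, `tpr`, `fpr`) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(!is.null(names(scores)), all(truth %in% names(scores)))
  pos <- names(scores) %in% truth
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be non-empty")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)[seq_along(s)] # last index of each tie block
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  pts <- data.frame(threshold = c(Inf, unname(s[last])),
                    tpr = c(0, tp / n_pos),
                    fpr = c(0, fp / n_neg))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "csa_roc")
}

#' @export
print.csa_roc <- function(x, ...) {
  cat(sprintf("csa_roc: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Selects the curve point maximizing Youden's J = TPR - FPR (first such
#' point, i.e. the strictest threshold, on ties) and reports it together
#' with min(TPR, TNR), the balanced-recovery summary used when quoting a
#' single operating point.
#'
#' @param roc a `csa_roc` from [roc_curve()].
#' @return One-row data frame with `threshold`, `tpr`, `fpr`, `tnr`,
#'   `youden_j`, `min_tpr_tnr`.
#' @export
youden_point <- function(roc) {
  p <- roc$points
  j <- p$tpr - p$fpr
  i <- which.max(j)
  data.frame(threshold = p$threshold[i], tpr = p$tpr[i], fpr = p$fpr[i],
             tnr = 1 - p$fpr[i], youden_j = j[i],
             min_tpr_tnr = min(p$tpr[i], 1 - p$fpr[i]))
}

#' Empirical FDR-control check against ground truth
#'
#' Selects regulators with estimated FDR below `threshold` and tallies the
#' realized false-discovery proportion (false selections over selections;
#' 0 when nothing is selected) and the false-positive rate
#' FP / (FP + TN).
#'
#' @param results a `csa_results` data frame carrying an `fdr` column.
#' @param truth character vector of truly active regulator ids.
#' @param threshold FDR selection threshold (default 0.05).
#' @return List with `empirical_fdp`, `fpr`, `n_reported` and the selected
#'   ids `reported`.
#' @export
fdr_control_check <- function(results, truth, threshold = 0.05) {
  sel <- results$regulator[!is.na(results$fdr) & results$fdr < threshold]
  fp <- sum(!sel %in% truth)
  n_neg <- sum(!results$regulator %in% truth)
  list(empirical_fdp = fp / max(1L, length(sel)),
       fpr = if (n_neg) fp / n_neg else 0,
       n_reported = length(sel),
       reported = sel)
}

#' Out-degree baseline ranking
#'
#' The comparison baseline that ranks candidate regulators by their
#' out-degree (descending; ties broken by regulator id for determinism).
#' With `results` supplied, the degree counted is the number of targets the
#' regulator *coherently* regulates (`n_c`), which folds in the expression
#' data but skips normalization and significance; without `results` the raw
#' network out-degree is used, a ranking that ignores the data entirely.
#'
#' @param net a filtered `causal_network`.
#' @param results optional `csa_results` table; when given, rank by its
#'   `n_c` column instead of the raw out-degree.
#' @return Data frame with columns `regulator`, `out_degree`, `rank`,
#'   ordered by rank.
#' @export
degree_rank_baseline <- function(net, results = NULL) {
  if (is.null(results)) {
    deg <- table(net$edges$regulator)
    df <- data.frame(regulator = names(deg), out_degree = as.integer(deg),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(regulator = results$regulator,
                     out_degree = as.integer(results$n_c),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(-df$out_degree, df$regulator), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Signature enrichment of regulatee sets
#'
#' One-sided (over-representation) Fisher's exact test of the overlap
#' between each regulator's regulatee set and a gene signature, over a
#' common gene universe. Used to ask whether the regulatees of significant
#' regulators are enriched for, e.g., outcome-predictive signatures.
#'
#' @param results a `csa_results` data frame (typically pre-filtered to
#'   significant regulators).
#' @param net the `causal_network` the results were computed on.
#' @param signature non-empty character vector of signature gene ids, a
#'   subset of `universe`.
#' @param universe character vector of all measured gene ids.
#' @return Data frame with columns `regulator`, `n_regulatees`, `overlap`
#'   and `p_value`.
#' @export
signature_enrichment <- function(results, net, signature, universe) {
  if (!length(signature)) stop("empty signature")
  stopifnot(all(signature %in% universe))
  sets <- regulatee_sets(net)
  do.call(rbind, lapply(results$regulator, function(r) {
    tg <- intersect(sets[[r]], universe)
    a <- length(intersect(tg, signature))
    b <- length(tg) - a
    cc <- length(signature) - a
    d <- length(universe) - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(regulator = r, n_regulatees = length(tg), overlap = a,
               p_value = p, stringsAsFactors = FALSE)
  }))
}
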