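#' Mean coherence score of a regulatee set
#'
#' The mean score of a regulator is the average absolute Pearson correlation
#' over all n(n-1)/2 unordered pairs of its n regulatees. A regulator that
#' is active in the population should leave a coordinated footprint on its
#' regulatees, raising this mean above its value for random gene sets.
#'
#' @param store a `correlation_store`.
#' @param regulatees character vector of >= 2 gene ids present in the store.
#' @return The mean score, a real in \[0, 1\].
#' @export
mean_score <- function(store, regulatees) {
  score_set(store, regulatees, cutoff = 1)$mu
}

#' Ratio coherence score of a regulatee set
#'
#' The ratio score is the fraction of regulatee pairs whose absolute
#' correlation strictly exceeds the dataset-global cutoff (by default the
#' 95th percentile of all pairwise correlations, see [global_cutoff()]):
#' F = 2 c / (n (n - 1)) where c counts supra-cutoff pairs. It targets
#' regulators for which a small subset of regulatees is strongly
#' co-expressed, a pattern a shift in the mean can miss. Ties at the cutoff
#' are not coherent.
#'
#' @inheritParams mean_score
#' @param cutoff correlation cutoff in \[0, 1\]; defaults to the cutoff
#'   stored on `store`.
#' @return List with elements `F_R` (the ratio score) and `c_pairs` (the
#'   supra-cutoff pair count).
#' @export
ratio_score <- function(store, regulatees, cutoff = store$cutoff) {
  stopifnot(!is.na(cutoff), cutoff >= 0, cutoff <= 1)
  s <- score_set(store, regulatees, cutoff)
  list(F_R = s$F_R, c_pairs = s$c_pairs)
}

# shared single pass over regulatee pairs: mean, exceedance count, coherent
# membership
score_set <- function(store, regulatees, cutoff) {
  idx <- match(regulatees, store$genes)
  if (anyNA(idx)) stop("unknown gene(s): ",
                       paste(utils::head(regulatees[is.na(idx)], 5), collapse = ", "))
  n <- length(idx)
  if (n < 2) stop("need >= 2 regulatees to score")
  if (!is.null(store$C)) {
    s <- cpp_score_sets(store$C, list(idx), cutoff)
    mu <- s$mu[1]
    cp <- s$c_pairs[1]
    coh <- NULL
  } else {
    mu <- 0
    cp <- 0L
    coh <- logical(n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v <- abs_correlation(store, regulatees[i], regulatees[j])
        mu <- mu + v
        if (v > cutoff) {
          cp <- cp + 1L
          coh[i] <- TRUE
          coh[j] <- TRUE
        }
      }
    }
    mu <- mu / (n * (n - 1) / 2)
  }
  list(mu = mu, c_pairs = cp, F_R = 2 * cp / (n * (n - 1)), n = n, coherent = coh)
}

#' Partition a regulator's regulatees by coherence
#'
#' A regulatee is *coherent* if it participates in at least one regulatee
#' pair with absolute correlation strictly above the cutoff. Coherent
#' regulatees are split by the sign of their regulation edge into
#' coherently up- and down-regulated sets; the remainder are non-coherent.
#' The number of coherent regulatees is n_c = |up| + |down|.
#'
#' @param store a `correlation_store`.
#' @param net a filtered `causal_network`.
#' @param regulator a regulator id in `net`.
#' @param cutoff correlation cutoff; defaults to the store's global cutoff.
#' @return List with character vectors `coherent_up`, `coherent_down`,
#'   `non_coherent` (a disjoint partition of the regulatee set) and the
#'   count `n_c`.
#' @export
coherence_partition <- function(store, net, regulator, cutoff = store$cutoff) {
  e <- net$edges[net$edges$regulator == regulator, , drop = FALSE]
  if (!nrow(e)) stop("unknown regulator: ", regulator)
  regulatees <- e$regulatee
  idx <- match(regulatees, store$genes)
  n <- length(regulatees)
  coh <- logical(n)
  if (!is.null(store$C) && !anyNA(idx)) {
    sub <- store$C[idx, idx, drop = FALSE]
    hit <- sub > cutoff
    diag(hit) <- FALSE
    coh <- rowSums(hit) > 0
  } else {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (abs_correlation(store, regulatees[i], regulatees[j]) > cutoff)
          coh[i] <- coh[j] <- TRUE
      }
    }
  }
  list(coherent_up = regulatees[coh & e$sign == "up"],
       coherent_down = regulatees[coh & e$sign == "down"],
       non_coherent = regulatees[!coh],
       n_c = sum(coh))
}

#' Mean regulator-to-regulatee correlation
#'
#' The average absolute correlation between the regulator's own transcript
#' and its regulatees. Unlike the coherence scores this quantity requires
#' the regulator itself to be measured; regulators acting at the protein or
#' modification level are often not, in which case `NA` is returned and
#' reported as missing. A regulator can be confidently active with a low
#' value here: coherence among regulatees, not regulator co-expression, is
#' the activity signal.
#'
#' @inheritParams coherence_partition
#' @return Mean |cor| in \[0, 1\], or `NA` when the regulator (or every
#'   regulatee) is absent from the expression data.
#' @export
regulator_regulatee_correlation <- function(store, net, regulator) {
  e <- net$edges[net$edges$regulator == regulator, , drop = FALSE]
  if (!nrow(e)) stop("unknown regulator: ", regulator)
  if (!regulator %in% store$genes) return(NA_real_)
  present <- e$regulatee[e$regulatee %in% store$genes]
  if (!length(present)) return(NA_real_)
  mean(vapply(present, function(g) abs_correlation(store, regulator, g), 0))
}

#' Score every regulator in a causal network
#'
#' Computes, for each regulator of a filtered network, the mean score, the
#' ratio score (with its supra-cutoff pair count), the coherent-regulatee
#' partition, and the regulator-to-regulatee correlation, in a single pass
#' over regulatee pairs. Significance columns (`p_value`, `fdr`) are `NA`
#' here; [run_csa()] fills them from a permutation null.
#'
#' @param store a `correlation_store` with its global cutoff computed.
#' @param net a filtered `causal_network` whose regulatees are all present
#'   in the store.
#' @param include_chemical keep chemical/environmental regulators
#'   (ids prefixed `CHEM:`/`ENV:`) in the report? Default `FALSE`.
#' @return A data frame of class `csa_results`, one row per regulator,
#'   with columns `regulator`, `n`, `mu_R`, `F_R`, `c_pairs`, `n_c`,
#'   `mu_RR`, `p_value`, `fdr`, `coherent_up`, `coherent_down`,
#'   `non_coherent` (id lists joined with `;`).
#' @export
score_all <- function(store, net, include_chemical = FALSE) {
  e <- net$edges
  if (!include_chemical && any(e$chemical %||% FALSE))
    e <- e[!e$chemical, , drop = FALSE]
  if (!nrow(e)) {
    warning("no regulators to score")
    return(empty_results())
  }
  if (is.na(store$cutoff)) global_cutoff(store)
  sets <- split(e$regulatee, e$regulator)
  regs <- names(sets)
  idx_sets <- lapply(sets, function(g) {
    i <- match(g, store$genes)
    if (anyNA(i)) stop("regulatee(s) missing from expression data; ",
                       "run filter_network() against rownames(expr) first")
    i
  })
  stopifnot(!is.null(store$C)) # score_all requires the cached matrix
  s <- cpp_score_sets(store$C, idx_sets, store$cutoff)
  parts <- lapply(regs, function(r) coherence_partition(store, net, r, store$cutoff))
  res <- data.frame(
    regulator = regs,
    n = s$n,
    mu_R = s$mu,
    F_R = 2 * s$c_pairs / (s$n * (s$n - 1)),
    c_pairs = s$c_pairs,
    n_c = s$n_c,
    mu_RR = vapply(regs, function(r) regulator_regulatee_correlation(store, net, r), 0),
    p_value = NA_real_,
    fdr = NA_real_,
    coherent_up = vapply(parts, function(p) paste(p$coherent_up, collapse = ";"), ""),
    coherent_down = vapply(parts, function(p) paste(p$coherent_down, collapse = ";"), ""),
    non_coherent = vapply(parts, function(p) paste(p$non_coherent, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("csa_results", "data.frame")
  res
}

empty_results <- function() {
  res <- data.frame(regulator = character(), n = integer(), mu_R = numeric(),
                    F_R = numeric(), c_pairs = integer(), n_c = integer(),
                    mu_RR = numeric(), p_value = numeric(), fdr = numeric(),
                    coherent_up = character(), coherent_down = character(),
                    non_coherent = character(), stringsAsFactors = FALSE)
  class(res) <- c("csa_results", "data.frame")
  res
}

#' Write a CSA results table as tab-separated text
#'
#' @param results a `csa_results` data frame from [score_all()] or
#'   [run_csa()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
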