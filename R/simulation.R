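#' Simulation configuration for spike-in benchmarks
#'
#' Parameters of the simulated benchmark: `n_regulators` active regulators
#' are embedded in a no-signal baseline by inducing a pairwise Pearson
#' correlation of `r_target` among enough of each one's regulatees to cover
#' at least `p_fraction` of its regulatee pairs.
#'
#' @param n_regulators number of embedded active regulators (default 100).
#' @param p_fraction target fraction of correlated regulatee pairs in
#'   \[0, 1\] (default 0.5).
#' @param r_target target pairwise correlation in (0, 1) (default 0.5).
#' @param m_samples number of samples (default 391; >= 3).
#' @param seed RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_regulators = 100, p_fraction = 0.5,
                              r_target = 0.5, m_samples = 391, seed = 1L) {
  stopifnot(p_fraction >= 0, p_fraction <= 1,
            r_target > 0, r_target < 1, m_samples >= 3, n_regulators >= 1)
  structure(list(n_regulators = as.integer(n_regulators),
                 p_fraction = p_fraction, r_target = r_target,
                 m_samples = as.integer(m_samples), seed = as.integer(seed)),
            class = "simulation_config")
}

#' No-signal baseline by per-gene label permutation
#'
#' Independently permutes each gene's values across samples. Every row
#' keeps its exact multiset of values -- hence its mean and standard
#' deviation -- while correlations between genes are destroyed in
#' expectation, leaving a dataset with realistic marginals and no
#' co-expression signal.
#'
#' @param expr numeric matrix, genes x samples.
#' @param seed RNG seed.
#' @return Matrix of the same shape and dimnames.
#' @export
permute_baseline <- function(expr, seed = 1L) {
  set.seed(seed)
  m <- ncol(expr)
  out <- t(apply(expr, 1L, function(v) v[sample.int(m)]))
  dimnames(out) <- dimnames(expr)
  out
}

#' Synthetic no-signal baseline matrix
#'
#' Generates independent gene vectors with realistic log-scale marginal
#' spread: per-gene means drawn uniformly from `mean_range` and per-gene
#' standard deviations drawn log-normally (median `exp(sd_meanlog)`,
#' log-scale spread `sd_sdlog`), with Gaussian values around them. This
#' stands in for a label-permuted real cohort when none is supplied:
#' independent rows, heterogeneous marginals, no co-expression.
#'
#' @param gene_ids character vector of gene ids (rows).
#' @param m_samples number of samples (columns).
#' @param mean_range range of per-gene means (default c(6, 12), a log2
#'   microarray intensity scale).
#' @param sd_meanlog,sd_sdlog log-normal parameters of per-gene standard
#'   deviations (defaults give a median sd of 0.7 with moderate spread).
#' @param seed RNG seed.
#' @return Matrix, genes x samples, samples named `S1..Sm`.
#' @export
synthesize_baseline <- function(gene_ids, m_samples,
                                mean_range = c(6, 12),
                                sd_meanlog = log(0.7), sd_sdlog = 0.35,
                                seed = 1L) {
  set.seed(seed)
  g <- length(gene_ids)
  mu <- stats::runif(g, mean_range[1], mean_range[2])
  sdv <- stats::rlnorm(g, sd_meanlog, sd_sdlog)
  x <- matrix(stats::rnorm(g * m_samples, mean = mu, sd = sdv),
              nrow = g, ncol = m_samples,
              dimnames = list(gene_ids, paste0("S", seq_len(m_samples))))
  x
}

#' Induce a target pairwise correlation among regulatee profiles
#'
#' Cholesky spike-in in the style of Iman and Conover: the selected rows
#' are standardized, premultiplied by the Cholesky factor L of the
#' equicorrelation target matrix (unit diagonal, off-diagonal `rho`, so
#' Sigma = L L'), and rescaled to each row's original mean and standard
#' deviation. On rows that start out (approximately) independent the
#' transformed rows have pairwise sample correlations concentrating around
#' `rho`; the per-row rescaling restores each original mean and variance
#' exactly without touching correlations.
#'
#' @param expr numeric matrix, genes x samples.
#' @param regulatees character vector of >= 2 row ids to correlate.
#' @param rho target pairwise correlation in (0, 1).
#' @param seed unused source of randomness kept for interface symmetry; the
#'   transform itself is deterministic given `expr`.
#' @return The matrix with the selected rows replaced by their correlated
#'   versions.
#' @export
spike_in <- function(expr, regulatees, rho, seed = NULL) {
  stopifnot(rho > 0, rho < 1, length(regulatees) >= 2,
            all(regulatees %in% rownames(expr)))
  T0 <- expr[regulatees, , drop = FALSE]
  n <- nrow(T0)
  mu <- rowMeans(T0)
  sdv <- apply(T0, 1L, stats::sd)
  if (any(sdv == 0)) stop("cannot spike a zero-variance row")
  Z <- (T0 - mu) / sdv
  Sigma <- matrix(rho, n, n)
  diag(Sigma) <- 1
  L <- t(chol(Sigma))
  Y <- L %*% Z
  # exact marginal restoration; per-row affine maps leave correlations alone
  ym <- rowMeans(Y)
  ys <- apply(Y, 1L, stats::sd)
  Y <- (Y - ym) / ys * sdv + mu
  expr[regulatees, ] <- Y
  expr
}

#' Build a spiked simulation dataset with ground truth
#'
#' Reproduces the simulated benchmark: the input matrix is first reduced to
#' a no-signal baseline by per-gene label permutation; `cfg$n_regulators`
#' regulators are then sampled (without replacement) from the filtered
#' network and, for each, a random subset of its regulatees is replaced by
#' profiles correlated at `cfg$r_target` via [spike_in()]. The subset size
#' k is the smallest with k(k-1)/2 >= p * n(n-1)/2, so the correlated
#' pairs cover at least `cfg$p_fraction` of the regulator's regulatee
#' pairs. When embedded regulators share regulatees, spikes are applied
#' sequentially in regulator-id order and later spikes overwrite earlier
#' rows (a message reports how many rows were re-spiked). With
#' `p_fraction = 0` no rows are touched and the embedded set behaves like
#' any null regulator.
#'
#' @param expr numeric baseline source matrix, genes x samples.
#' @param net a filtered `causal_network`; all regulatees must be rows of
#'   `expr`.
#' @param cfg a [simulation_config()].
#' @return List with `expr` (the spiked matrix), `embedded` (ground-truth
#'   active regulator ids) and `spiked_genes` (named list of the spiked
#'   regulatee subset per embedded regulator).
#' @export
build_simulated_dataset <- function(expr, net, cfg) {
  sets <- regulatee_sets(net)
  eligible <- names(sets)[lengths(sets) >= 2]
  if (cfg$n_regulators > length(eligible))
    stop("n_regulators exceeds the ", length(eligible),
         " regulators available in the network")
  base <- permute_baseline(expr, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  embedded <- sort(sample(eligible, cfg$n_regulators))
  spiked <- list()
  touched <- character()
  overwritten <- 0L
  for (r in embedded) {
    tg <- sets[[r]]
    n <- length(tg)
    k <- spike_subset_size(n, cfg$p_fraction)
    if (k < 2) { spiked[[r]] <- character(); next }
    sub <- sample(tg, k)
    overwritten <- overwritten + sum(sub %in% touched)
    touched <- union(touched, sub)
    base <- spike_in(base, sub, cfg$r_target)
    spiked[[r]] <- sub
  }
  if (overwritten)
    message(overwritten, " regulatee row(s) re-spiked by a later regulator")
  list(expr = base, embedded = embedded, spiked_genes = spiked)
}

# smallest k with k(k-1)/2 >= p * n(n-1)/2 (0 when p = 0)
spike_subset_size <- function(n, p) {
  if (p <= 0) return(0L)
  target <- p * n * (n - 1) / 2
  k <- ceiling((1 + sqrt(1 + 8 * target)) / 2)
  while (k > 2 && (k - 1) * (k - 2) / 2 >= target) k <- k - 1
  as.integer(min(max(k, 2), n))
}

#' Generate a synthetic causal network
#'
#' Stands in for a licensed literature-derived network: a simple directed
#' graph with heavy-tailed out-degrees. Out-degrees are drawn from a
#' discrete power law P(k) proportional to k^-gamma truncated to
#' \[`d_min`, min(`d_max`, pool size)\]; regulatee sets are sampled
#' uniformly without replacement, excluding self-loops. A fraction of
#' regulators also appears in the regulatee pool, mirroring genes that are
#' both targets and drivers. The network is re-wired until weakly
#' connected, and always passes [filter_network()] unchanged.
#'
#' @param n_regulators number of regulator nodes.
#' @param n_regulatees number of pure regulatee nodes.
#' @param d_min,d_max out-degree range (set equal for a fixed degree).
#' @param gamma power-law exponent (default 2).
#' @param overlap fraction of regulators that can also be regulatees.
#' @param seed RNG seed.
#' @return A `causal_network` with random `up`/`down` signs.
#' @export
synthesize_network <- function(n_regulators, n_regulatees, d_min = 2,
                               d_max = 100, gamma = 2, overlap = 0.05,
                               seed = 1L) {
  stopifnot(n_regulators >= 1, n_regulatees >= 2, d_min >= 2, d_max >= d_min)
  set.seed(seed)
  regs <- sprintf("R%04d", seq_len(n_regulators))
  tgts <- sprintf("G%05d", seq_len(n_regulatees))
  pool <- c(tgts, sample(regs, floor(overlap * n_regulators)))
  dmax <- min(d_max, length(pool) - 1L)
  if (dmax < d_min) stop("degree demand infeasible for this regulatee pool")
  ks <- d_min:dmax
  deg <- if (length(ks) == 1L) rep(ks, n_regulators) else
    sample(ks, n_regulators, replace = TRUE, prob = ks^(-gamma))
  edges <- data.frame(
    regulator = rep(regs, deg),
    regulatee = unlist(lapply(seq_along(regs), function(i)
      sample(setdiff(pool, regs[i]), deg[i]))),
    stringsAsFactors = FALSE
  )
  edges$sign <- sample(c("up", "down"), nrow(edges), replace = TRUE)
  net <- causal_network(edges)
  # repair connectivity: re-target one edge of a small component into the
  # largest component until one weak component remains
  for (it in seq_len(100L)) {
    comp <- component_membership(net)
    if (max(comp$comp) == 1L) break
    sizes <- table(comp$comp)
    main <- as.integer(names(sizes)[which.max(sizes)])
    off <- comp$id[comp$comp != main]
    r <- intersect(net$edges$regulator, off)[1]
    mine <- which(net$edges$regulator == r)
    candidates <- setdiff(comp$id[comp$comp == main],
                          c(r, net$edges$regulatee[mine]))
    net$edges$regulatee[mine[1]] <- sample(candidates, 1L)
  }
  net
}

component_membership <- function(net) {
  e <- net$edges
  ids <- unique(c(e$regulator, e$regulatee))
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  fi <- match(e$regulator, ids)
  ti <- match(e$regulatee, ids)
  for (k in seq_along(fi)) {
    a <- find(fi[k]); b <- find(ti[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 1L)
  list(id = ids, comp = match(roots, unique(roots)))
}

#' Subsample patients (columns) from an expression matrix
#'
#' Retains `k` sample columns chosen uniformly without replacement, in
#' their original order.
#'
#' @param expr numeric matrix, genes x samples.
#' @param k number of samples to keep (<= ncol).
#' @param seed RNG seed.
#' @return Matrix with `k` columns.
#' @export
subsample_patients <- function(expr, k, seed = 1L) {
  m <- ncol(expr)
  if (k > m) stop("k exceeds the number of samples")
  set.seed(seed)
  expr[, sort(sample.int(m, k)), drop = FALSE]
}
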