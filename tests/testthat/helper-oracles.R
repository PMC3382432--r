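# Independent brute-force oracles used to check the package's fast paths.
# These deliberately re-derive each quantity from first principles and never
# call the implementation under test.

naive_pearson <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# mean |cor| over all unordered pairs, by explicit double loop on rows
naive_mean_score <- function(expr, ids) {
  n <- length(ids)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + abs(naive_pearson(expr[ids[i], ], expr[ids[j], ]))
    }
  }
  tot / (n * (n - 1) / 2)
}

# (c_pairs, F_R, n_c) by explicit enumeration
naive_ratio_score <- function(expr, ids, cutoff) {
  n <- length(ids)
  cp <- 0L
  coh <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (abs(naive_pearson(expr[ids[i], ], expr[ids[j], ])) > cutoff) {
        cp <- cp + 1L
        coh[i] <- coh[j] <- TRUE
      }
    }
  }
  list(c_pairs = cp, F_R = 2 * cp / (n * (n - 1)), n_c = sum(coh))
}

# textbook step-up BH: sort, adjust p_(i) * m / i, enforce monotonicity from
# the largest p downwards, cap at 1, return in input order
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(0, m - 1))) {
    adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# three-pass network filter, written independently of filter_network()
naive_filter <- function(edges, expressed) {
  e <- edges[edges$regulator != edges$regulatee, , drop = FALSE]
  e <- e[e$regulatee %in% expressed, , drop = FALSE]
  keep <- names(which(table(e$regulator) >= 2))
  e[e$regulator %in% keep, , drop = FALSE]
}

# upper-tail hypergeometric by direct summation over the 2x2 table
# (a = overlap, with fixed margins a+b, a+c and total N)
hyper_tail <- function(a, b, cc, d) {
  N <- a + b + cc + d
  K <- a + cc     # signature size
  n <- a + b      # regulatee-set size
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# ROC by exhaustive confusion matrices at every distinct score
naive_roc <- function(scores, truth) {
  pos <- names(scores) %in% truth
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) sum(scores >= t & pos) / sum(pos), 0))
  fpr <- c(0, vapply(th, function(t) sum(scores >= t & !pos) / sum(!pos), 0))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(tpr = tpr, fpr = fpr, auc = auc)
}

# small seeded fixtures ------------------------------------------------------

toy_edges <- function() {
  data.frame(
    regulator = c("A", "A", "A", "B", "B", "D"),
    regulatee = c("g1", "g2", "g3", "g2", "g4", "g5"),
    sign      = c("up", "up", "down", "down", "up", "up"),
    stringsAsFactors = FALSE
  )
}

toy_expr <- function(genes = paste0("g", 1:8), m = 30, seed = 42) {
  synthesize_baseline(genes, m, seed = seed)
}

random_edges <- function(n_reg, n_tgt, n_edges, seed) {
  set.seed(seed)
  regs <- paste0("r", seq_len(n_reg))
  tgts <- paste0("t", seq_len(n_tgt))
  e <- unique(data.frame(
    regulator = sample(regs, n_edges, replace = TRUE),
    regulatee = sample(tgts, n_edges, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  e$sign <- sample(c("up", "down"), nrow(e), replace = TRUE)
  e
}
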