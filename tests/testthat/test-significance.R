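sig_fixture <- function(n_genes = 40, m = 30, seed = 51) {
  x <- toy_expr(paste0("g", seq_len(n_genes)), m = m, seed = seed)
  store <- correlation_store(x)
  global_cutoff(store)
  store
}

sig_net <- function(store, n_reg = 8, seed = 52) {
  e <- random_edges(n_reg, nrow(store$expr), n_reg * 6, seed = seed)
  e$regulatee <- paste0("g", match(e$regulatee, paste0("t", seq_len(nrow(store$expr)))))
  filter_network(causal_network(e), rownames(store$expr))
}

test_that("the empirical p-value uses the add-one estimator with ties as exceedances", {
  expect_equal(empirical_pvalue(100, seq_len(99)), 1 / 100)  # above all nulls
  expect_equal(empirical_pvalue(0, seq_len(99)), 1)          # below all nulls
  nulls <- seq_len(999)
  expect_equal(empirical_pvalue(500, nulls), (1 + 500) / 1000)  # ~ median
  # ties count: observed equal to every null
  expect_equal(empirical_pvalue(1, rep(1, 9)), 1)
  # monotone non-increasing in the observed score
  obs <- seq(0, 1, by = 0.1)
  ps <- vapply(obs, empirical_pvalue, 0, null = runif(200))
  expect_true(all(diff(ps) <= 0))
})

test_that("BH adjustment matches the textbook step-up on fixed and random inputs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(77)
  for (k in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("edge switches rewire targets, preserve degrees, and reject conflicts", {
  net <- causal_network(data.frame(regulator = c("a", "c"),
                                   regulatee = c("b", "d"), sign = "up"))
  sw <- edge_switch(net, 1, 2)
  expect_true(attr(sw, "accepted"))
  expect_setequal(paste(sw$edges$regulator, sw$edges$regulatee),
                  c("a d", "c b"))
  # proposal creating a self-loop is rejected
  net2 <- causal_network(data.frame(regulator = c("a", "c"),
                                    regulatee = c("b", "a"), sign = "up"))
  sw2 <- edge_switch(net2, 1, 2)
  expect_false(attr(sw2, "accepted"))
  expect_equal(sw2$edges, net2$edges)
  # proposal duplicating an existing edge is rejected
  net3 <- causal_network(data.frame(regulator = c("a", "c", "a"),
                                    regulatee = c("b", "d", "d"), sign = "up"))
  expect_false(attr(edge_switch(net3, 1, 2), "accepted"))
})

test_that("randomize_graph preserves degree sequences, simplicity and connectivity class", {
  e <- random_edges(20, 60, 250, seed = 61)
  net <- filter_network(causal_network(e), unique(e$regulatee))
  cfg <- permutation_config(n_permutations = 1, seed = 1)
  set.seed(1)
  rnet <- randomize_graph(net, cfg)
  # exact per-node in- and out-degrees (direct edge tally oracle)
  lv <- sort(unique(c(e$regulator, e$regulatee)))
  tally <- function(x) as.vector(table(factor(x, levels = lv)))
  expect_equal(tally(rnet$edges$regulator), tally(net$edges$regulator))
  expect_equal(tally(rnet$edges$regulatee), tally(net$edges$regulatee))
  # simple: no self-loops, no parallel edges
  expect_false(any(rnet$edges$regulator == rnet$edges$regulatee))
  expect_equal(anyDuplicated(paste(rnet$edges$regulator, rnet$edges$regulatee)), 0L)
  # components do not increase
  expect_lte(weak_components(rnet), weak_components(net))
  # the mixing rule of thumb: >= 3 accepted switches per edge
  st <- attr(rnet, "switch_stats")
  expect_gte(st$accepted, 3 * nrow(net$edges))
  # determinism under a fixed seed
  set.seed(1)
  rnet2 <- randomize_graph(net, cfg)
  expect_equal(rnet2$edges, rnet$edges)
})

test_that("a 2-edge graph only reaches itself and its single switch partner", {
  net <- causal_network(data.frame(regulator = c("a", "c"),
                                   regulatee = c("b", "d"), sign = "up"))
  state <- function(r) paste(sort(paste(r$edges$regulator, r$edges$regulatee)),
                             collapse = "|")
  seen <- character()
  # an accepted switch toggles between the two simple states, so the parity
  # of the accepted-switch target decides where the walk ends
  for (spe in c(3, 2.5)) {  # targets 6 (even) and 5 (odd)
    set.seed(spe * 10)
    r <- randomize_graph(net, permutation_config(switches_per_edge = spe))
    seen <- union(seen, state(r))
  }
  expect_setequal(seen, c("a b|c d", "a d|c b"))
})

test_that("gene permutation shares nulls by size, is seeded, and handles the full universe", {
  store <- sig_fixture()
  net <- sig_net(store)
  cfg <- permutation_config("gene", n_permutations = 50, seed = 9)
  null1 <- gene_permutation_null(store, net, "ratio", cfg)
  null2 <- gene_permutation_null(store, net, "ratio", cfg)
  expect_identical(null1, null2)              # bit-identical under the seed
  expect_equal(dim(null1), c(length(regulators(net)), 50))
  expect_true(all(null1 >= 0 & null1 <= 1))
  ns <- lengths(regulatee_sets(net))
  same_n <- names(ns)[ns == ns[1]]
  if (length(same_n) > 1) {
    expect_equal(null1[same_n[1], ], null1[same_n[2], ]) # shared draws
  }
  # n = whole universe -> every draw scores the same set
  ids <- rownames(store$expr)
  net_all <- filter_network(causal_network(data.frame(
    regulator = "R", regulatee = ids, sign = "up")), ids)
  null_all <- gene_permutation_null(store, net_all, "mean",
                                    permutation_config("gene", n_permutations = 5, seed = 2))
  expect_equal(var(as.vector(null_all)), 0)
  expect_equal(unname(null_all[1, 1]), mean_score(store, ids), tolerance = 1e-12)
})

test_that("graph permutation is reproducible and scores regulators on randomized nets", {
  store <- sig_fixture()
  net <- sig_net(store)
  cfg <- permutation_config("graph", n_permutations = 20, seed = 3)
  null1 <- graph_permutation_null(store, net, "ratio", cfg)
  null2 <- graph_permutation_null(store, net, "ratio", cfg)
  expect_identical(null1, null2)
  expect_true(all(null1 >= 0 & null1 <= 1))
  expect_setequal(rownames(null1), regulators(net))
})

test_that("on a star network the graph null equals the gene null restricted to its targets", {
  # one regulator owning every regulatee: the randomized graph is always the
  # identical star, so its null is degenerate at the observed score
  store <- sig_fixture()
  ids <- rownames(store$expr)[1:10]
  star <- filter_network(causal_network(data.frame(
    regulator = "R", regulatee = ids, sign = "up")), ids)
  cfg <- permutation_config("graph", n_permutations = 5, seed = 4)
  # no alternative degree-preserving simple graph exists, so switching stalls
  null <- suppressWarnings(graph_permutation_null(store, star, "ratio", cfg))
  expect_equal(var(as.vector(null)), 0)
  expect_equal(unname(null[1, 1]), ratio_score(store, ids)$F_R, tolerance = 1e-12)
})

test_that("p-values on independent data are approximately uniform", {
  # under the global null the empirical p-value quantiles track the uniform
  store <- sig_fixture(n_genes = 60, m = 40, seed = 71)
  net <- sig_net(store, n_reg = 30, seed = 72)
  cfg <- permutation_config("gene", n_permutations = 200, seed = 5)
  null <- gene_permutation_null(store, net, "mean", cfg)
  sets <- regulatee_sets(net)
  obs <- vapply(names(sets), function(r) mean_score(store, sets[[r]]), 0)
  p <- empirical_pvalue(obs[rownames(null)], null)
  expect_gt(mean(p), 0.25)  # not concentrated near 0
  expect_lt(mean(p), 0.85)  # not concentrated near 1
  # ties are inherent to permutation p-values; the KS statistic is still a
  # valid flatness summary
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("pure-noise data yields no discoveries and graph specificity is competitive", {
  store <- sig_fixture(n_genes = 50, m = 35, seed = 81)
  net <- sig_net(store, n_reg = 15, seed = 82)
  res_gene <- run_csa(store$expr, net, score = "ratio", method = "gene",
                      n_permutations = 150, seed = 6)
  res_graph <- run_csa(store$expr, net, score = "ratio", method = "graph",
                       n_permutations = 150, seed = 6)
  chk_gene <- fdr_control_check(res_gene, truth = "none-of-them")
  chk_graph <- fdr_control_check(res_graph, truth = "none-of-them")
  expect_equal(chk_gene$n_reported + chk_graph$n_reported, 0L)
  expect_lte(chk_graph$fpr, chk_gene$fpr + 0.02)
})

test_that("the key = value config reader round-trips a configuration", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# permutation settings", "method = graph",
               "n_permutations = 250", "seed = 11",
               "switches_per_edge = 3", "fdr_threshold = 0.05"), f)
  cfg <- read_permutation_config(f)
  expect_equal(cfg$method, "graph")
  expect_equal(cfg$n_permutations, 250L)
  expect_equal(cfg$seed, 11L)
  writeLines("bogus = 1", f)
  expect_error(read_permutation_config(f), "unknown config key")
})
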