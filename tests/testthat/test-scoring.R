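# fixed store shared across scoring tests
scoring_fixture <- function(n_genes = 30, m = 40, seed = 21) {
  x <- toy_expr(paste0("g", seq_len(n_genes)), m = m, seed = seed)
  correlation_store(x)
}

test_that("the mean score averages pairwise |cor| (known values and oracle)", {
  # construct three genes with prescribed pairwise |cor| via direct vectors
  store <- scoring_fixture()
  ids <- sample(rownames(store$expr), 6)
  expect_equal(mean_score(store, ids), naive_mean_score(store$expr, ids),
               tolerance = 1e-12)

  # all regulatees copies of one vector -> exactly 1
  base <- rnorm(20)
  mat <- rbind(a = base, b = base * 3 + 1, c = -base + 2)
  colnames(mat) <- paste0("s", 1:20)
  st <- correlation_store(mat)
  expect_equal(mean_score(st, c("a", "b", "c")), 1)
  expect_error(mean_score(store, "g1"), ">= 2")
})

test_that("the ratio score counts strict exceedances over the cutoff", {
  store <- scoring_fixture()
  ids <- sample(rownames(store$expr), 7)
  cors <- combn(ids, 2, function(p) abs_correlation(store, p[1], p[2]))
  cutoff <- unname(sort(cors)[floor(length(cors) / 2)])  # an attained value
  r <- ratio_score(store, ids, cutoff)
  o <- naive_ratio_score(store$expr, ids, cutoff)
  expect_equal(r$c_pairs, o$c_pairs)
  expect_equal(r$F_R, o$F_R, tolerance = 1e-12)
  # a tie at the cutoff is NOT coherent (strict inequality)
  expect_equal(r$c_pairs, sum(cors > cutoff))
  # cutoff 1 on non-degenerate data -> empty exceedance
  expect_equal(ratio_score(store, ids, 1)$F_R, 0)
})

test_that("three regulatees with known pairwise correlations give textbook scores", {
  # pairwise |cor| {0.2-ish, mid, high}: check F_R = 2c/(n(n-1)) arithmetic
  store <- scoring_fixture(seed = 4)
  ids <- sample(rownames(store$expr), 3)
  cors <- sort(combn(ids, 2, function(p) abs_correlation(store, p[1], p[2])))
  cutoff <- mean(cors[2:3])  # exactly one pair above
  r <- ratio_score(store, ids, cutoff)
  expect_equal(r$c_pairs, 1L)
  expect_equal(r$F_R, 1 / 3, tolerance = 1e-12)
  expect_equal(mean_score(store, ids), mean(cors), tolerance = 1e-12)
})

test_that("coherence partitions split by sign and match the membership oracle", {
  store <- scoring_fixture(seed = 31)
  e <- random_edges(8, 20, 45, seed = 8)
  e$regulatee <- paste0("g", match(e$regulatee, paste0("t", 1:20)))
  net <- filter_network(causal_network(e), rownames(store$expr))
  cutoff <- global_cutoff(store, probs = 0.7)  # low cutoff so pairs exceed it
  for (r in regulators(net)) {
    part <- coherence_partition(store, net, r, cutoff)
    tg <- net$edges$regulatee[net$edges$regulator == r]
    expect_setequal(c(part$coherent_up, part$coherent_down, part$non_coherent), tg)
    expect_length(intersect(part$coherent_up, part$coherent_down), 0)
    o <- naive_ratio_score(store$expr, tg, cutoff)
    expect_equal(part$n_c, o$n_c)
    signs <- net$edges$sign[net$edges$regulator == r]
    expect_true(all(part$coherent_up %in% tg[signs == "up"]))
    expect_true(all(part$coherent_down %in% tg[signs == "down"]))
  }
  # no pair above cutoff 1 -> everything non-coherent
  r1 <- regulators(net)[1]
  part1 <- coherence_partition(store, net, r1, 1)
  expect_equal(part1$n_c, 0L)
  expect_length(part1$coherent_up, 0)
})

test_that("regulator-regulatee correlation averages rows and handles absent regulators", {
  store <- scoring_fixture(seed = 17)
  net <- filter_network(causal_network(data.frame(
    regulator = c("g1", "g1", "g1", "PROT", "PROT"),
    regulatee = c("g2", "g3", "g4", "g5", "g6"),
    sign = "up")), rownames(store$expr))
  expect_equal(regulator_regulatee_correlation(store, net, "g1"),
               mean(sapply(c("g2", "g3", "g4"), function(g)
                 abs(naive_pearson(store$expr["g1", ], store$expr[g, ])))),
               tolerance = 1e-12)
  # protein-level regulator absent from the matrix -> NA
  expect_true(is.na(regulator_regulatee_correlation(store, net, "PROT")))
  # regulator row identical to every regulatee -> 1
  base <- rnorm(15)
  mat <- rbind(R = base, a = base, b = 2 * base)
  colnames(mat) <- paste0("s", 1:15)
  st2 <- correlation_store(mat)
  net2 <- filter_network(causal_network(data.frame(
    regulator = "R", regulatee = c("a", "b"), sign = "up")), c("a", "b"))
  expect_equal(regulator_regulatee_correlation(st2, net2, "R"), 1)
})

test_that("score_all composes the single-regulator operations deterministically", {
  store <- scoring_fixture(seed = 23)
  e <- random_edges(10, 25, 60, seed = 12)
  e$regulatee <- paste0("g", match(e$regulatee, paste0("t", 1:25)))
  net <- filter_network(causal_network(e), rownames(store$expr))
  global_cutoff(store)
  res <- score_all(store, net)
  expect_setequal(res$regulator, regulators(net))
  for (i in seq_len(nrow(res))) {
    r <- res$regulator[i]
    tg <- net$edges$regulatee[net$edges$regulator == r]
    expect_equal(res$mu_R[i], mean_score(store, tg), tolerance = 1e-12)
    rs <- ratio_score(store, tg)
    expect_equal(res$F_R[i], rs$F_R, tolerance = 1e-12)
    expect_equal(res$c_pairs[i], rs$c_pairs)
    expect_equal(res$n_c[i],
                 coherence_partition(store, net, r)$n_c)
  }
  # identical regulatee sets -> identical scores; determinism across calls
  res2 <- score_all(store, net)
  expect_equal(res, res2)
  expect_true(all(res$F_R >= 0 & res$F_R <= 1))
  expect_true(all(res$mu_R >= 0 & res$mu_R <= 1))
  count_ids <- function(s) lengths(regmatches(s, gregexpr("[^;]+", s)))
  expect_equal(res$n_c, count_ids(res$coherent_up) + count_ids(res$coherent_down))
})

test_that("scores are invariant to regulatee order and to common sample permutation", {
  store <- scoring_fixture(seed = 29)
  ids <- sample(rownames(store$expr), 8)
  expect_equal(mean_score(store, ids), mean_score(store, rev(ids)),
               tolerance = 1e-12)
  perm <- sample(ncol(store$expr))
  store_p <- correlation_store(store$expr[, perm])
  expect_equal(mean_score(store_p, ids), mean_score(store, ids),
               tolerance = 1e-12)
  expect_equal(ratio_score(store_p, ids, 0.4)$c_pairs,
               ratio_score(store, ids, 0.4)$c_pairs)
})

test_that("the results table round-trips through the TSV writer", {
  store <- scoring_fixture(seed = 37)
  e <- random_edges(6, 15, 30, seed = 14)
  e$regulatee <- paste0("g", match(e$regulatee, paste0("t", 1:15)))
  net <- filter_network(causal_network(e), rownames(store$expr))
  global_cutoff(store)
  res <- score_all(store, net)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, f)
  back <- read.delim(f, colClasses = c(coherent_up = "character",
                                       coherent_down = "character",
                                       non_coherent = "character"))
  expect_equal(back$regulator, res$regulator)
  expect_equal(back$F_R, res$F_R, tolerance = 1e-9)
  expect_equal(back$n_c, res$n_c)
})
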