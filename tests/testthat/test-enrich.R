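test_that("sets are restricted to the measured universe", {
  db <- structure(list(assoc = toy_assoc(rep(c("K1", "K2"), c(10, 2)),
                                         sprintf("G%02d", 1:12), "S", 1:12),
                       synonyms = NULL), class = "ksdb")
  uni <- sprintf("G%02d_S%d_m1", 1:3, 1:3)  # 3 of K1's substrates, 0 of K2's
  sets <- build_sets(db, uni)
  expect_equal(names(sets), "K1")
  expect_equal(length(sets$K1), 3)
  # a kinase with one measured substrate is dropped at min_set_size = 2
  uni2 <- c(uni, "G11_S11_m1")
  sets2 <- suppressMessages(build_sets(db, uni2))
  expect_false("K2" %in% names(sets2))
  expect_error(build_sets(db, "ZZZ_S1_m1"), "no kinase")
})

test_that("top-ranked members give the minimal hypergeometric statistic", {
  ranked <- structure(sprintf("s%02d", 1:10), class = "ranked_sites")
  r <- primary_set_pvalue(ranked, c("s01", "s02", "s03"))
  expect_equal(r$stat, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(r$p, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(r$t_star, 3)
  expect_setequal(r$leading, c("s01", "s02", "s03"))
  # bottom placement is not enriched
  expect_gte(primary_set_pvalue(ranked, c("s08", "s09", "s10"))$p, 0.5)
  expect_error(primary_set_pvalue(ranked, character()), "empty")
  expect_error(primary_set_pvalue(ranked, "nope"), "missing from")
})

test_that("exact p equals exhaustive enumeration over placements", {
  for (N in c(6, 9)) for (K in 2:3) {
    or <- oracle_mhg_pvalues(N, K)
    ranked <- structure(sprintf("s%02d", 1:N), class = "ranked_sites")
    for (j in seq_len(ncol(or$combs))) {
      members <- sprintf("s%02d", or$combs[, j])
      expect_equal(primary_set_pvalue(ranked, members)$p, or$p[j],
                   tolerance = 1e-10)
    }
  }
})

test_that("overlap elimination discards sets explained by another set", {
  N <- 100
  ranked <- structure(sprintf("s%03d", 1:N), class = "ranked_sites")
  setA <- sprintf("s%03d", 1:8)
  setB <- c(setA, "s050")          # decoy: A plus one mid-ranked site
  setC <- sprintf("s%03d", 9:16)   # disjoint from A, also significant
  sets <- list(A = setA, B = setB, C = setC)
  pp <- vapply(sets, function(m) primary_set_pvalue(ranked, m)$p, numeric(1))
  expect_true(all(pp <= 0.01))
  g <- eliminate_overlaps(sets, ranked, pp, set_p_cutoff = 0.01)
  expect_true(any(g$edges$from == "A" & g$edges$to == "B"))
  nb <- g$nodes[g$nodes$kinase == "B", ]
  expect_false(nb$retained)
  expect_equal(nb$explained_by, "A")
  expect_true(g$nodes$retained[g$nodes$kinase == "A"])
  expect_true(g$nodes$retained[g$nodes$kinase == "C"])
  # disjoint pair has no edges between them
  expect_false(any(g$edges$from == "A" & g$edges$to == "C"))
  expect_false(any(g$edges$from == "C" & g$edges$to == "A"))
  # verify the edge decision by direct recomputation
  redB <- setdiff(setB, setA)
  uni <- ranked[!(ranked %in% setA)]
  expect_gt(primary_set_pvalue(structure(uni, class = "ranked_sites"), redB)$p,
            0.01)
  # order independence
  g2 <- eliminate_overlaps(sets[c(3, 1, 2)], ranked, pp[c(3, 1, 2)],
                           set_p_cutoff = 0.01)
  expect_equal(g2$nodes, g$nodes)
  # single significant set: one node, retained, no edges
  g3 <- eliminate_overlaps(sets["A"], ranked, pp["A"], set_p_cutoff = 0.01)
  expect_equal(nrow(g3$nodes), 1)
  expect_true(g3$nodes$retained)
  expect_equal(nrow(g3$edges), 0)
})

test_that("dependence-graph scores are a proper PageRank", {
  # edgeless graph: uniform scores
  nodes <- data.frame(kinase = c("a", "b", "c", "d"), primary_p = 0.001,
                      retained = TRUE, explained_by = "",
                      stringsAsFactors = FALSE)
  g0 <- list(nodes = nodes, edges = data.frame(from = character(),
                                               to = character(),
                                               p_reduced = numeric()))
  s0 <- rank_score(g0)
  expect_equal(unname(s0), rep(0.25, 4))
  # chain a -> b -> c, compared against an independent implementation
  g1 <- list(nodes = nodes[1:3, ],
             edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                p_reduced = 0.5, stringsAsFactors = FALSE))
  s1 <- rank_score(g1)
  expect_equal(sum(s1), 1, tolerance = 1e-9)
  ig <- igraph::graph_from_edgelist(cbind(c("b", "c"), c("a", "b")))
  pr <- igraph::page_rank(ig, damping = 0.85)$vector
  expect_equal(s1[names(pr)], pr, tolerance = 1e-8)
  # explaining node accumulates the most score
  expect_gt(s1[["a"]], s1[["b"]])
  expect_equal(length(rank_score(list(nodes = nodes[0, ], edges = g0$edges))), 0)
})

test_that("Bonferroni correction and permutation FDR behave as specified", {
  N <- 200
  set.seed(5)
  ranked <- structure(sprintf("s%03d", 1:N), class = "ranked_sites")
  sets <- list(top = sprintf("s%03d", 1:5),
               rand = sprintf("s%03d", sort(sample(6:200, 5))))
  pp <- vapply(sets, function(m) primary_set_pvalue(ranked, m)$p, numeric(1))
  cf <- correct_and_fdr(pp, sets, ranked, B_null = 50, seed = 3)
  expect_equal(cf$corrected_p, pmin(1, cf$primary_p * length(sets)))
  expect_true(all(cf$corrected_p >= cf$primary_p))
  expect_true(all(cf$fdr >= 0 & cf$fdr <= 1))
  expect_lt(cf$fdr[cf$kinase == "top"], 0.05)
  expect_warning(correct_and_fdr(pp, sets, ranked, B_null = 5, seed = 3),
                 "unstable")
  # deterministic for a fixed seed
  cf2 <- correct_and_fdr(pp, sets, ranked, B_null = 50, seed = 3)
  expect_equal(cf, cf2)
})

test_that("random rankings produce the nominal rate of p <= 0.01 sets", {
  set.seed(31)
  N <- 500; K <- 8; n_sets <- 30; B <- 200
  hits <- numeric(B)
  for (b in seq_len(B)) {
    ranks <- replicate(n_sets, sort(sample.int(N, K)))
    hits[b] <- sum(phosact:::mhg_exact_batch(ranks, N) <= 0.01)
  }
  expected <- 0.01 * n_sets
  se <- sd(hits) / sqrt(B)
  expect_lt(abs(mean(hits) - expected), 3 * se + 0.05 * expected + 0.02)
})

test_that("planted overactive kinases are recovered and direction is symmetric", {
  run <- run_planted(seed = 11)
  over <- run$res$over
  expect_true(all(run$sim$truth$active$kinase %in%
                    over$kinase[over$primary_p <= 0.01]))
  decoys <- setdiff(names(run$sim$truth$membership),
                    run$sim$truth$active$kinase)
  expect_lte(sum(over$reported & over$kinase %in% decoys), 1)
  expect_equal(run$recovery$sensitivity, 1)
  expect_equal(run$recovery$direction_accuracy, 1)
  # negating all fold changes swaps the over and under tables exactly
  neg <- run$diff
  neg$log2fc <- -neg$log2fc
  neg$t_stat <- -neg$t_stat
  res_neg <- kinase_activity(neg, run$sim$db, seed = 11)
  drop_dir <- function(tab) tab[setdiff(names(tab), "direction")]
  expect_equal(drop_dir(res_neg$over), drop_dir(run$res$under))
  expect_equal(drop_dir(res_neg$under), drop_dir(run$res$over))
})

test_that("planting an underactive shift moves kinases to the under table", {
  run <- run_planted(seed = 12, direction = "under")
  expect_true(all(run$sim$truth$active$kinase %in%
                    run$res$under$kinase[run$res$under$reported]))
  expect_equal(run$recovery$direction_accuracy, 1)
})
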