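# Overlap-aware two-directional kinase enrichment on ranked site lists.
#
# Primary statistic: exact minimum-hypergeometric (mHG) over the ranked
# list — the minimum hypergeometric upper tail across all list prefixes,
# with its exact null probability computed by a dynamic program, so no
# expression cutoff is ever applied. Significant kinase sets then enter a
# set-dependence graph: an edge A -> B records that B stops being
# significant once A's substrates are removed from both B and the universe;
# kinases whose whole significance is explained this way are discarded.

#' Restrict database kinase sets to the measured universe
#'
#' @param db a `ksdb`.
#' @param universe character vector of measured site keys (the differential
#'   universe); multiplicity suffixes are ignored when matching substrates.
#' @param min_set_size smallest measured-substrate set retained (default 2,
#'   mirroring the database's single-entry rule).
#' @return named list of member site-key vectors, one per kinase.
#' @export
build_sets <- function(db, universe, min_set_size = 2) {
  stopifnot(inherits(db, "ksdb"))
  if (!length(universe)) stop("empty site universe")
  base <- base_site_key(universe)
  subs <- split(db$assoc$substrate_key, db$assoc$kinase)
  sets <- lapply(subs, function(s) universe[base %in% s])
  sizes <- lengths(sets)
  if (any(sizes > 0 & sizes < min_set_size))
    message(sprintf("build_sets: dropping %d set(s) below min_set_size = %d",
                    sum(sizes > 0 & sizes < min_set_size), min_set_size))
  sets <- sets[sizes >= min_set_size]
  if (!length(sets)) stop("no kinase has enough measured substrates")
  sets[order(names(sets))]
}

#' Exact mHG enrichment p-value of one kinase set on a ranked list
#'
#' @param ranked ranked site keys from [rank_sites()] (rank 1 first).
#' @param members site keys of the kinase set; must all occur in `ranked`.
#' @return list with `p` (exact p-value), `stat` (minimum hypergeometric
#'   tail), `t_star` (prefix length attaining it) and `leading` (members
#'   within that prefix).
#' @export
primary_set_pvalue <- function(ranked, members) {
  if (!length(members)) stop("empty kinase set")
  ranks <- match(members, ranked)
  if (anyNA(ranks)) stop("kinase set members missing from the ranked universe")
  ranks <- sort(ranks)
  res <- mhg_exact(as.integer(ranks), length(ranked))
  res$leading <- ranked[ranks[ranks <= res$t_star]]
  res
}

#' Build the set-dependence graph among significant kinase sets
#'
#' Nodes are the sets with primary p-value at or below `set_p_cutoff`. For
#' every pair (A, B) of overlapping nodes, each set's p-value is recomputed
#' with the other's members removed from both the set and the ranked
#' universe. An edge A -> B ("A explains B") is added when the reduced B is
#' no longer significant while the reduced A still is; when both reductions
#' destroy significance (mutually overlap-dependent sets, e.g. nested ones),
#' the set with the smaller primary p-value explains the other (ties broken
#' by smaller set size, then name). A node is discarded only when removing
#' the union of all its in-neighbors' members destroys its significance; the
#' procedure is order-independent.
#'
#' @param sets named list of member vectors (see [build_sets()]).
#' @param ranked ranked site keys.
#' @param primary_p named numeric vector of primary p-values for `sets`.
#' @param set_p_cutoff significance cutoff defining graph nodes
#'   (default 0.01).
#' @return list with `nodes` (data.frame: kinase, primary_p, retained,
#'   explained_by) and `edges` (data.frame: from, to, p_reduced).
#' @export
eliminate_overlaps <- function(sets, ranked, primary_p, set_p_cutoff = 0.01) {
  node_names <- sort(names(sets)[primary_p[names(sets)] <= set_p_cutoff])
  edges <- data.frame(from = character(), to = character(),
                      p_reduced = numeric(), stringsAsFactors = FALSE)
  if (!length(node_names))
    return(list(nodes = data.frame(kinase = character(), primary_p = numeric(),
                                   retained = logical(),
                                   explained_by = character(),
                                   stringsAsFactors = FALSE),
                edges = edges))
  reduced_p <- function(set_b, remove) {
    b <- setdiff(set_b, remove)
    if (length(b) < 1) return(1)
    uni <- ranked[!(ranked %in% remove)]
    primary_set_pvalue(uni, b)$p
  }
  add_edge <- function(from, to, p_red) {
    edges <<- rbind(edges, data.frame(from = from, to = to, p_reduced = p_red,
                                      stringsAsFactors = FALSE))
  }
  if (length(node_names) > 1) {
    for (i in seq_len(length(node_names) - 1)) for (j in (i + 1):length(node_names)) {
      a <- node_names[i]; b <- node_names[j]
      if (!length(intersect(sets[[a]], sets[[b]]))) next
      p_b <- reduced_p(sets[[b]], sets[[a]])
      p_a <- reduced_p(sets[[a]], sets[[b]])
      a_dead <- p_a > set_p_cutoff
      b_dead <- p_b > set_p_cutoff
      if (b_dead && !a_dead) add_edge(a, b, p_b)
      else if (a_dead && !b_dead) add_edge(b, a, p_a)
      else if (a_dead && b_dead) {
        # mutual dependence: the stronger set explains the weaker one
        a_wins <- primary_p[[a]] < primary_p[[b]] ||
          (primary_p[[a]] == primary_p[[b]] &&
             (length(sets[[a]]) < length(sets[[b]]) ||
                (length(sets[[a]]) == length(sets[[b]]) && a < b)))
        if (a_wins) add_edge(a, b, p_b) else add_edge(b, a, p_a)
      }
    }
  }
  retained <- setNames(rep(TRUE, length(node_names)), node_names)
  explained <- setNames(rep("", length(node_names)), node_names)
  for (b in node_names) {
    innb <- edges$from[edges$to == b]
    if (!length(innb)) next
    p_u <- reduced_p(sets[[b]], unique(unlist(sets[innb])))
    if (p_u > set_p_cutoff) {
      retained[b] <- FALSE
      explained[b] <- paste(sort(innb), collapse = ";")
    }
  }
  nodes <- data.frame(kinase = node_names,
                      primary_p = unname(primary_p[node_names]),
                      retained = unname(retained),
                      explained_by = unname(explained),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

#' PageRank scores on the reversed set-dependence graph
#'
#' Sets that explain the significance of others accumulate score. Power
#' iteration on the reversed dependence graph with uniform teleportation;
#' dangling mass is redistributed uniformly; scores sum to 1 over nodes.
#'
#' @param graph output of [eliminate_overlaps()].
#' @param damping damping factor (default 0.85).
#' @param tol convergence tolerance on the L1 change (default 1e-10).
#' @return named numeric vector of scores (empty for an empty graph).
#' @export
rank_score <- function(graph, damping = 0.85, tol = 1e-10) {
  nodes <- graph$nodes$kinase
  n <- length(nodes)
  if (n == 0) return(setNames(numeric(0), character(0)))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges))
    for (i in seq_len(nrow(graph$edges)))
      A[graph$edges$to[i], graph$edges$from[i]] <- 1  # reversed edge to -> from
  out_deg <- rowSums(A)
  v <- rep(1 / n, n)
  for (iter in 1:10000) {
    contrib <- colSums(A * ifelse(out_deg > 0, v / out_deg, 0))
    dangling <- sum(v[out_deg == 0])
    v_new <- (1 - damping) / n + damping * (contrib + dangling / n)
    if (sum(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  setNames(v / sum(v), nodes)
}

#' Bonferroni correction and permutation FDR for kinase sets
#'
#' The corrected p multiplies the primary p by the number of sets tested.
#' The FDR per kinase is estimated by Monte-Carlo: the ranked list is
#' permuted `B_null` times, every set's exact mHG p-value is recomputed on
#' each permutation, and the FDR at a kinase's observed p is the mean number
#' of null set p-values at or below it divided by the number of observed set
#' p-values at or below it, clipped to `[0, 1]`.
#'
#' @param primary_p named numeric vector of observed primary p-values.
#' @param sets named list of member vectors (same names as `primary_p`).
#' @param ranked ranked site keys.
#' @param B_null number of null permutations (default 100; fewer than 10
#'   triggers an instability warning).
#' @param seed integer seed for the permutations.
#' @return data.frame with columns `kinase`, `primary_p`, `corrected_p`,
#'   `fdr`.
#' @export
correct_and_fdr <- function(primary_p, sets, ranked, B_null = 100, seed = NULL) {
  kin <- names(sets)
  n_sets <- length(kin)
  if (B_null < 10)
    warning("B_null < 10: FDR estimate is unstable")
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- length(ranked)
  member_flag <- lapply(sets, function(m) {
    f <- logical(N)
    f[match(m, ranked)] <- TRUE
    f
  })
  null_p <- matrix(NA_real_, nrow = n_sets, ncol = B_null,
                   dimnames = list(kin, NULL))
  perms <- replicate(B_null, sample.int(N), simplify = FALSE)
  for (i in seq_len(n_sets)) {
    flag <- member_flag[[i]]
    ranks_mat <- vapply(perms, function(p) which(flag[p]),
                        integer(sum(flag)))
    null_p[i, ] <- mhg_exact_batch(ranks_mat, N)
  }
  obs <- primary_p[kin]
  fdr <- vapply(kin, function(k) {
    thr <- obs[[k]]
    e_null <- mean(colSums(null_p <= thr))
    n_obs <- sum(obs <= thr)
    min(1, e_null / n_obs)
  }, numeric(1))
  data.frame(kinase = kin, primary_p = unname(obs),
             corrected_p = pmin(1, unname(obs) * n_sets),
             fdr = unname(fdr), stringsAsFactors = FALSE)
}

.direction_table <- function(diff, sets, direction, set_p_cutoff, p_threshold,
                             fdr_threshold, B_null, damping, seed) {
  ranked <- rank_sites(diff, direction)
  prim <- lapply(sets, function(m) primary_set_pvalue(ranked, m))
  primary_p <- vapply(prim, `[[`, numeric(1), "p")
  graph <- eliminate_overlaps(sets, ranked, primary_p, set_p_cutoff)
  scores <- rank_score(graph, damping = damping)
  cf <- correct_and_fdr(primary_p, sets, ranked, B_null = B_null, seed = seed)
  tab <- cf
  tab$direction <- direction
  tab$n_members <- lengths(sets)[tab$kinase]
  tab$rank_score <- unname(scores[tab$kinase])
  node_idx <- match(tab$kinase, graph$nodes$kinase)
  tab$retained <- ifelse(is.na(node_idx), TRUE, graph$nodes$retained[node_idx])
  tab$explained_by <- ifelse(is.na(node_idx), "",
                             graph$nodes$explained_by[node_idx])
  tab$leading_members <- vapply(prim[tab$kinase], function(x)
    paste(x$leading, collapse = ";"), character(1))
  tab$reported <- tab$retained & tab$primary_p <= p_threshold &
    tab$fdr <= fdr_threshold
  ord <- order(-tab$reported, tab$primary_p,
               -ifelse(is.na(tab$rank_score), -Inf, tab$rank_score),
               tab$kinase)
  tab <- tab[ord, c("kinase", "direction", "n_members", "primary_p",
                    "corrected_p", "fdr", "rank_score", "retained",
                    "explained_by", "leading_members", "reported")]
  rownames(tab) <- NULL
  attr(tab, "graph") <- graph
  tab
}

#' Two-directional kinase activity enrichment
#'
#' Runs the full enrichment for both directions: direction-specific ranking
#' of the differential sites, exact mHG primary p-values per kinase set,
#' overlap elimination on the set-dependence graph, PageRank scoring, and
#' Bonferroni/permutation-FDR control. A kinase is `reported` when it is
#' retained after overlap elimination and satisfies both the primary-p and
#' FDR thresholds. The same seed drives both directions, so negating all
#' fold changes exactly swaps the two result tables.
#'
#' @param diff differential table from [welch_test()] or [one_vs_rest()].
#' @param db a `ksdb`.
#' @param p_threshold primary p-value threshold for reporting (default 0.01).
#' @param fdr_threshold FDR threshold for reporting (default 0.05).
#' @param set_p_cutoff significance cutoff for set-dependence-graph nodes
#'   (default 0.01).
#' @param min_set_size smallest measured-substrate set tested (default 2).
#' @param B_null permutations for the FDR estimate (default 100).
#' @param damping PageRank damping (default 0.85).
#' @param seed integer seed making the FDR permutations reproducible.
#' @return object of class `kinase_enrichment`: list with `over` and `under`
#'   result data.frames (columns kinase, direction, n_members, primary_p,
#'   corrected_p, fdr, rank_score, retained, explained_by, leading_members,
#'   reported), plus `n_sets_tested` and `universe_size`.
#' @export
kinase_activity <- function(diff, db, p_threshold = 0.01, fdr_threshold = 0.05,
                            set_p_cutoff = 0.01, min_set_size = 2,
                            B_null = 100, damping = 0.85, seed = 1) {
  stopifnot(inherits(db, "ksdb"))
  sets <- build_sets(db, diff$site, min_set_size = min_set_size)
  res <- lapply(c(over = "over", under = "under"), function(dir)
    .direction_table(diff, sets, dir, set_p_cutoff, p_threshold,
                     fdr_threshold, B_null, damping, seed))
  structure(list(over = res$over, under = res$under,
                 n_sets_tested = length(sets),
                 universe_size = nrow(diff)),
            class = "kinase_enrichment")
}

#' @export
print.kinase_enrichment <- function(x, ...) {
  cat(sprintf("kinase_enrichment: %d sets tested on %d sites\n",
              x$n_sets_tested, x$universe_size))
  cat(sprintf("  overactive reported: %d | underactive reported: %d\n",
              sum(x$over$reported), sum(x$under$reported)))
  invisible(x)
}
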