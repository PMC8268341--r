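# In-code fixtures shared across test files.

# quick phospho_set from a plain matrix; two conditions A/B unless a design
# is supplied
toy_set <- function(E, design = NULL, stage = "filtered", log2 = TRUE) {
  if (is.null(rownames(E)))
    rownames(E) <- sprintf("G%03d_S%d_m1", seq_len(nrow(E)), seq_len(nrow(E)))
  if (is.null(colnames(E)))
    colnames(E) <- sprintf("s%d", seq_len(ncol(E)))
  if (is.null(design)) {
    half <- ceiling(ncol(E) / 2)
    design <- data.frame(
      sample = colnames(E),
      condition = rep(c("A", "B"), c(half, ncol(E) - half)),
      stringsAsFactors = FALSE
    )
  }
  phospho_set(E, design, stage = stage, log2 = log2)
}

# minimal MaxQuant-dialect file writer for hand-built parser tests
write_mq_fixture <- function(path, rows, samples, mults = 1:2) {
  header <- c("Proteins", "Gene names", "Amino acid", "Position",
              "Localization prob", "Reverse", "Potential contaminant",
              as.vector(t(outer(samples, mults,
                                function(s, k) sprintf("Intensity %s___%d", s, k)))))
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  path
}

# independent mHG oracles: statistic by direct tail scan, p by exhaustive
# enumeration over all placements
oracle_mhg_stat <- function(ranks, N) {
  K <- length(ranks)
  min(vapply(seq_along(ranks), function(i)
    phyper(i - 1, K, N - K, ranks[i], lower.tail = FALSE), numeric(1)))
}

oracle_mhg_pvalues <- function(N, K) {
  combs <- combn(N, K)
  stats <- apply(combs, 2, oracle_mhg_stat, N = N)
  list(combs = combs,
       p = vapply(seq_len(ncol(combs)), function(j)
         mean(stats <= stats[j] * (1 + 1e-12)), numeric(1)))
}

# association table for database tests
toy_assoc <- function(kinase, gene, residue, position,
                      evidence = "experimental", sources = "PSP",
                      score = NA_real_) {
  data.frame(kinase = kinase, gene = gene, residue = residue,
             position = position,
             substrate_key = make_site_key(gene, residue, position),
             evidence = evidence, sources = sources, score = score,
             stringsAsFactors = FALSE)
}

# planted-activity scenario used by the recovery checks: 3 active kinases
# with 20 substrates each among 40 decoys, +1.5 log2 shift, noise sd 0.5,
# triplicates
planted_cfg <- function(seed, n_active = 3, direction = "over") {
  simulation_config(n_sites = 1000, n_kinases = 43, substrates_per_kinase = 20,
                    n_active = n_active, active_direction = direction,
                    effect_size = 1.5, noise_sd = 0.5, seed = seed)
}

run_planted <- function(seed, B_null = 100, direction = "over") {
  sim <- simulate_dataset(planted_cfg(seed, direction = direction))
  ps <- assemble_matrix(sim$records, sim$design)
  ps <- suppressMessages(preprocess(ps, seed = seed))
  diff <- suppressMessages(welch_test(ps, "DRG", "CTRL"))
  res <- kinase_activity(diff, sim$db, B_null = B_null, seed = seed)
  list(sim = sim, diff = diff, res = res,
       recovery = evaluate_recovery(res, sim$truth))
}
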