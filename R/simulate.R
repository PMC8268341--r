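# Synthetic MaxQuant-like datasets with planted kinase activities, matching
# synthetic kinase-substrate databases, and recovery scoring.
#
# The generator emulates the data model the preprocessing assumes: log-normal
# site intensities, condition-dependent shifts on the substrates of planted
# kinases, sporadic (MAR) dropout plus intensity-dependent left-censoring
# (MNAR, logistic in log2 intensity), and injected contaminant / reverse /
# poorly-localized rows that the filters must remove.

#' Simulation configuration
#'
#' @param n_sites number of genuine phosphosites.
#' @param conditions two condition labels; effects are planted in the second
#'   (test) condition.
#' @param n_replicates replicates per condition.
#' @param n_kinases total kinases in the synthetic database (planted +
#'   decoys).
#' @param substrates_per_kinase measured substrates per kinase (disjoint
#'   across kinases).
#' @param n_active number of planted active kinases.
#' @param active_direction `"over"`, `"under"`, or a vector of length
#'   `n_active`.
#' @param effect_size planted shift in log2 units.
#' @param noise_sd replicate noise standard deviation (log2 units).
#' @param baseline_mean,baseline_sd log2-intensity baseline distribution.
#' @param mar_rate per-cell probability of sporadic (MAR) dropout.
#' @param mnar_mid_sd centre of the left-censoring logistic, in baseline SDs
#'   below the baseline mean.
#' @param mnar_scale scale (steepness) of the left-censoring logistic, log2
#'   units.
#' @param frac_contaminant,frac_reverse,frac_low_locprob fractions (of
#'   `n_sites`) of injected contaminant / reverse / poorly-localized rows.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_sites = 2000, conditions = c("CTRL", "DRG"),
                              n_replicates = 3, n_kinases = 50,
                              substrates_per_kinase = 15, n_active = 3,
                              active_direction = "over", effect_size = 1.5,
                              noise_sd = 0.5, baseline_mean = 23,
                              baseline_sd = 2, mar_rate = 0.03,
                              mnar_mid_sd = 2.5, mnar_scale = 0.3,
                              frac_contaminant = 0.02, frac_reverse = 0.02,
                              frac_low_locprob = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  rates <- c(mar_rate, frac_contaminant, frac_reverse, frac_low_locprob)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  if (length(conditions) != 2) stop("exactly two conditions are supported")
  if (n_kinases * substrates_per_kinase > n_sites)
    stop("infeasible config: n_kinases * substrates_per_kinase exceeds n_sites")
  if (length(active_direction) == 1)
    active_direction <- rep(active_direction, n_active)
  if (n_active > 0 && length(active_direction) != n_active)
    stop("active_direction must have length 1 or n_active")
  structure(as.list(environment()), class = "sim_config")
}

.num17 <- function(x) sprintf("%.17g", x)

#' Generate a synthetic phosphoproteomics dataset
#'
#' Returns (and optionally writes) a MaxQuant-style Phospho (STY)Sites
#' table, a design CSV, a kinase-substrate database bundle, and the ground
#' truth. Emitted files round-trip exactly through [parse_phosphosty()] and
#' [read_ksdb()]: intensities are integers and localization probabilities
#' are written at full precision.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory; when given, writes
#'   `phospho_sites.txt`, `design.csv`, the db bundle (`ksdb_*`) and
#'   `ground_truth.json`.
#' @return list with `records` (parser-format record table), `design`, `db`
#'   (a `ksdb`), `truth` (active kinases, membership, per-site condition
#'   means, per-cell missingness mechanisms, truth matrix), and `paths` when
#'   `dir` was given.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed))
  samples <- paste0(rep(cfg$conditions, each = cfg$n_replicates), "_",
                    rep(seq_len(cfg$n_replicates), times = 2))
  design <- data.frame(
    sample = samples,
    condition = rep(cfg$conditions, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = 2),
    stringsAsFactors = FALSE
  )
  test_cond <- cfg$conditions[2]

  # genuine sites: several sites per gene, unique (gene, residue, position)
  n <- cfg$n_sites
  n_genes <- max(1L, ceiling(n / 3))
  gene <- sprintf("GENE%04d", sample.int(n_genes, n, replace = TRUE))
  within_idx <- stats::ave(seq_len(n), gene, FUN = seq_along)
  residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                    prob = c(0.805, 0.158, 0.0375))
  position <- within_idx * 7L + sample.int(6L, n, replace = TRUE)
  multiplicity <- sample(1:3, n, replace = TRUE, prob = c(0.80, 0.15, 0.05))
  locprob <- round(runif(n, 0.85, 1), 6)

  # kinase membership: disjoint substrate blocks
  kin_names <- sprintf("KIN%03d", seq_len(cfg$n_kinases))
  sub_idx <- sample.int(n, cfg$n_kinases * cfg$substrates_per_kinase)
  membership <- split(sub_idx,
                      rep(kin_names, each = cfg$substrates_per_kinase))
  membership <- membership[kin_names]
  active <- if (cfg$n_active > 0)
    data.frame(kinase = kin_names[seq_len(cfg$n_active)],
               direction = cfg$active_direction, stringsAsFactors = FALSE)
  else data.frame(kinase = character(), direction = character(),
                  stringsAsFactors = FALSE)

  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  shift <- numeric(n)
  if (cfg$n_active > 0) {
    for (i in seq_len(cfg$n_active)) {
      s <- if (active$direction[i] == "over") cfg$effect_size else -cfg$effect_size
      shift[membership[[active$kinase[i]]]] <- s
    }
  }
  true_means <- cbind(baseline, baseline + shift)
  colnames(true_means) <- cfg$conditions

  vals <- matrix(NA_real_, n, length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    cc <- design$condition[j]
    vals[, j] <- true_means[, cc] + rnorm(n, 0, cfg$noise_sd)
  }

  # missingness: sporadic MAR, then logistic left-censoring (MNAR)
  mechanism <- matrix("observed", n, length(samples),
                      dimnames = list(NULL, samples))
  mar <- matrix(runif(n * length(samples)) < cfg$mar_rate, n)
  mid <- cfg$baseline_mean - cfg$mnar_mid_sd * cfg$baseline_sd
  p_censor <- plogis((mid - vals) / cfg$mnar_scale)
  mnar <- matrix(runif(n * length(samples)) < p_censor, n)
  mechanism[mar] <- "mar"
  mechanism[mnar] <- "mnar"
  intens <- round(2^vals)
  intens[mechanism != "observed"] <- NA_real_
  intens[!is.na(intens) & intens < 1] <- 1

  keys <- make_site_key(gene, residue, position, multiplicity)
  rownames(mechanism) <- keys
  good <- data.frame(
    protein_id = sprintf("P%05d", as.integer(factor(gene))),
    gene_symbol = gene, residue = residue, position = position,
    localization_prob = locprob, multiplicity = multiplicity,
    is_reverse = FALSE, is_contaminant = FALSE, stringsAsFactors = FALSE
  )

  junk_row <- function(n_junk, prefix, reverse = FALSE, contaminant = FALSE,
                       low_loc = FALSE) {
    if (n_junk == 0) return(NULL)
    g <- sprintf("%s%03d", prefix, seq_len(n_junk))
    v <- rnorm(n_junk, cfg$baseline_mean, cfg$baseline_sd)
    df <- data.frame(
      protein_id = sprintf("X%s", g), gene_symbol = g,
      residue = sample(c("S", "T", "Y"), n_junk, replace = TRUE),
      position = sample.int(500L, n_junk, replace = TRUE),
      localization_prob = if (low_loc) round(runif(n_junk, 0, 0.749), 6)
                          else round(runif(n_junk, 0.85, 1), 6),
      multiplicity = 1L, is_reverse = reverse, is_contaminant = contaminant,
      stringsAsFactors = FALSE
    )
    ints <- round(2^(v + matrix(rnorm(n_junk * length(samples), 0, cfg$noise_sd),
                                n_junk)))
    colnames(ints) <- samples
    cbind(df, as.data.frame(ints, optional = TRUE))
  }
  good_full <- cbind(good, as.data.frame(intens, optional = TRUE))
  junk <- rbind(
    junk_row(round(cfg$frac_contaminant * n), "CONT", contaminant = TRUE),
    junk_row(round(cfg$frac_reverse * n), "REV", reverse = TRUE),
    junk_row(round(cfg$frac_low_locprob * n), "LOWLOC", low_loc = TRUE)
  )
  all_rows <- rbind(good_full, junk)
  all_rows <- all_rows[sample.int(nrow(all_rows)), , drop = FALSE]
  rownames(all_rows) <- NULL
  # records in parser output shape: drop rows with no quantified value
  has_val <- rowSums(!is.na(all_rows[, samples, drop = FALSE])) > 0
  records <- all_rows[has_val,
                      c("protein_id", "gene_symbol", "residue", "position",
                        "localization_prob", "multiplicity", "is_reverse",
                        "is_contaminant", samples)]
  rownames(records) <- NULL

  assoc <- do.call(rbind, lapply(kin_names, function(k) {
    i <- membership[[k]]
    data.frame(kinase = k, gene = gene[i], residue = residue[i],
               position = position[i],
               substrate_key = make_site_key(gene[i], residue[i], position[i]),
               evidence = "experimental", sources = "synthetic",
               score = NA_real_, stringsAsFactors = FALSE)
  }))
  db <- structure(list(assoc = assoc, synonyms = NULL), class = "ksdb")

  truth_matrix <- intens
  rownames(truth_matrix) <- keys
  truth <- list(cfg = cfg, active = active,
                membership = lapply(membership, function(i) keys[i]),
                site_keys = keys, true_means = true_means,
                mechanism = mechanism, truth_matrix = truth_matrix)

  out <- list(records = records, design = design, db = db, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f_sites <- file.path(dir, "phospho_sites.txt")
    .write_maxquant(all_rows, samples, f_sites)
    f_design <- file.path(dir, "design.csv")
    write.csv(design, f_design, row.names = FALSE, quote = FALSE)
    db_prefix <- file.path(dir, "ksdb")
    write_ksdb(db, db_prefix)
    f_truth <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(active = truth$active, membership = truth$membership,
           n_sites = cfg$n_sites, seed = cfg$seed),
      f_truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$paths <- c(phospho = f_sites, design = f_design,
                   db_prefix = db_prefix, truth = f_truth)
  }
  out
}

# write rows in the MaxQuant Phospho (STY)Sites dialect; one intensity
# column block per multiplicity, zeros for not-quantified cells.
.write_maxquant <- function(rows, samples, path) {
  n <- nrow(rows)
  out <- data.frame(
    Proteins = rows$protein_id,
    `Gene names` = rows$gene_symbol,
    `Amino acid` = rows$residue,
    Position = rows$position,
    `Localization prob` = .num17(rows$localization_prob),
    Reverse = ifelse(rows$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(rows$is_contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (k in 1:3) {
    for (s in samples) {
      col <- sprintf("Intensity %s___%d", s, k)
      v <- ifelse(rows$multiplicity == k & !is.na(rows[[s]]), rows[[s]], 0)
      out[[col]] <- sprintf("%.0f", v)
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association table in a public source dialect
#'
#' Emits fixture files in the column layouts [parse_source()] expects, for
#' round-trip testing and documentation.
#'
#' @param assoc association data.frame (`kinase`, `gene`, `residue`,
#'   `position`).
#' @param name target dialect (`PSP`, `HPRD`, `RegPhos`, `Signor`, `ELM`).
#' @param path output file.
#' @export
write_source_fixture <- function(assoc, name, path) {
  aa1to3 <- c(S = "Ser", T = "Thr", Y = "Tyr")
  tab <- switch(
    name,
    PSP = data.frame(GENE = assoc$kinase, KIN_ORGANISM = "human",
                     SUB_GENE = assoc$gene, SUB_ORGANISM = "human",
                     SUB_MOD_RSD = paste0(assoc$residue, assoc$position),
                     IN_VIVO_RXN = "X", IN_VITRO_RXN = "",
                     check.names = FALSE, stringsAsFactors = FALSE),
    HPRD = data.frame(substrate_gene_symbol = assoc$gene,
                      site = assoc$position, residue = assoc$residue,
                      enzyme_name = assoc$kinase,
                      modification_type = "Phosphorylation",
                      stringsAsFactors = FALSE),
    RegPhos = data.frame(GENE = assoc$gene, position = assoc$position,
                         code = assoc$residue,
                         catalytic_kinase = assoc$kinase,
                         check.names = FALSE, stringsAsFactors = FALSE),
    Signor = data.frame(ENTITYA = assoc$kinase, ENTITYB = assoc$gene,
                        RESIDUE = paste0(aa1to3[assoc$residue], assoc$position),
                        MECHANISM = "phosphorylation", TAX_ID = "9606",
                        check.names = FALSE, stringsAsFactors = FALSE),
    ELM = data.frame(gene = assoc$gene, position = assoc$position,
                     code = assoc$residue, kinases = assoc$kinase,
                     species = "Homo sapiens", stringsAsFactors = FALSE),
    stop(sprintf("unknown source name '%s'", name))
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score recovery of planted kinase activities
#'
#' @param results a `kinase_enrichment` object.
#' @param truth the `truth` element of [simulate_dataset()] output.
#' @return list with `sensitivity` (planted kinases reported / planted),
#'   `specificity` (1 - decoy false-positive rate), `fp_rate`,
#'   `direction_accuracy` (among recovered planted kinases; `NA` when none),
#'   and `n_recovered`.
#' @export
evaluate_recovery <- function(results, truth) {
  stopifnot(inherits(results, "kinase_enrichment"))
  all_kin <- names(truth$membership)
  res_kin <- unique(c(results$over$kinase, results$under$kinase))
  if (!all(res_kin %in% all_kin))
    stop("kinase name mismatch between results and ground truth")
  planted <- truth$active$kinase
  decoys <- setdiff(all_kin, planted)
  rep_over <- results$over$kinase[results$over$reported]
  rep_under <- results$under$kinase[results$under$reported]
  recovered <- unique(c(rep_over, rep_under))
  sens <- if (length(planted)) mean(planted %in% recovered) else NA_real_
  fp <- if (length(decoys)) mean(decoys %in% recovered) else 0
  rec_planted <- intersect(planted, recovered)
  dir_acc <- if (length(rec_planted)) {
    truth_dir <- setNames(truth$active$direction, truth$active$kinase)
    mean(vapply(rec_planted, function(k) {
      want <- truth_dir[[k]]
      (want == "over" && k %in% rep_over && !(k %in% rep_under)) ||
        (want == "under" && k %in% rep_under && !(k %in% rep_over))
    }, logical(1)))
  } else NA_real_
  list(sensitivity = sens, specificity = 1 - fp, fp_rate = fp,
       direction_accuracy = dir_acc, n_recovered = length(recovered))
}
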