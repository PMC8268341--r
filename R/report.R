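# Waterfall data and plot, tumor-suppressor/oncogene annotation, network
# table export, YAML config handling and the end-to-end pipeline driver.

#' Waterfall table of reported kinases
#'
#' One row per reported kinase with signed height `-log10(primary_p)`,
#' positive for overactive and negative for underactive kinases; overactive
#' kinases come first, sorted by descending height, then underactive sorted
#' by descending absolute height.
#'
#' @param results a `kinase_enrichment` object.
#' @return data.frame with columns `kinase`, `direction`, `signed_height`
#'   (and `ts_role` after [annotate_ts()]).
#' @export
waterfall_data <- function(results) {
  stopifnot(inherits(results, "kinase_enrichment"))
  rows <- rbind(results$over[results$over$reported, , drop = FALSE],
                results$under[results$under$reported, , drop = FALSE])
  if (nrow(rows) == 0) {
    warning("no reported kinases; waterfall table is empty")
    return(data.frame(kinase = character(), direction = character(),
                      signed_height = numeric(), stringsAsFactors = FALSE))
  }
  h <- -log10(rows$primary_p)
  wf <- data.frame(kinase = rows$kinase, direction = rows$direction,
                   signed_height = ifelse(rows$direction == "over", h, -h),
                   stringsAsFactors = FALSE)
  over <- wf[wf$direction == "over", , drop = FALSE]
  under <- wf[wf$direction == "under", , drop = FALSE]
  wf <- rbind(over[order(-over$signed_height, over$kinase), , drop = FALSE],
              under[order(-abs(under$signed_height), under$kinase), , drop = FALSE])
  rownames(wf) <- NULL
  wf
}

#' Waterfall plot of over-/under-active kinases
#'
#' Bars of signed `-log10 p`, red for overactive and blue for underactive
#' kinases.
#'
#' @param wf table from [waterfall_data()].
#' @param file optional output path (e.g. PNG or SVG) written via
#'   [ggplot2::ggsave()].
#' @return the ggplot object, invisibly.
#' @export
plot_waterfall <- function(wf, file = NULL) {
  wf$kinase <- factor(wf$kinase, levels = wf$kinase)
  lab <- if ("ts_role" %in% names(wf))
    ifelse(is.na(wf$ts_role) | wf$ts_role == "", as.character(wf$kinase),
           paste0(wf$kinase, " (", wf$ts_role, ")"))
  else as.character(wf$kinase)
  p <- ggplot2::ggplot(wf, ggplot2::aes(x = kinase, y = signed_height,
                                        fill = direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(over = "#c0392b", under = "#2980b9")) +
    ggplot2::scale_x_discrete(labels = lab) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ italic(p)),
                  fill = "activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 8, height = 4.5)
  invisible(p)
}

#' Annotate kinases with tumor-suppressor / oncogene roles
#'
#' Left-joins a literature-mined role table (columns `gene`, `role`) onto the
#' result tables; kinases absent from the table stay unlabeled.
#'
#' @param x a `kinase_enrichment`, or any data.frame with a `kinase` column.
#' @param path annotation TSV with columns `gene` and `role`.
#' @return the input with an added `ts_role` column.
#' @export
annotate_ts <- function(x, path) {
  ann <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!all(c("gene", "role") %in% names(ann)))
    stop("format error: annotation file must have columns 'gene' and 'role'")
  add_role <- function(df) {
    df$ts_role <- ann$role[match(df$kinase, ann$gene)]
    df$ts_role[is.na(df$ts_role)] <- ""
    df
  }
  if (inherits(x, "kinase_enrichment")) {
    x$over <- add_role(x$over)
    x$under <- add_role(x$under)
    x
  } else add_role(x)
}

#' Decouple composite kinase names
#'
#' Composite entries such as `MEK1/2` become individual gene symbols
#' (`MEK1`, `MEK2`): short slash-separated suffixes inherit the stem of the
#' first name, while full alternative names are kept as-is.
#'
#' @param x character vector of kinase names.
#' @return list of character vectors, one per input name.
#' @export
decouple_kinase_names <- function(x) {
  lapply(as.character(x), function(nm) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    if (length(parts) == 1) return(parts)
    first <- parts[1]
    stem <- sub("[0-9]+$", "", first)
    vapply(seq_along(parts), function(i) {
      p <- parts[i]
      if (i == 1) p
      else if (nchar(p) <= 2 && grepl("^[0-9]+[A-Za-z]?$", p)) paste0(stem, p)
      else p
    }, character(1))
  })
}

#' Export node and edge-request tables for external network analysis
#'
#' Writes a node table (one row per individual gene symbol after decoupling
#' composite names) and an edge-request manifest recording the minimum
#' overall interaction-confidence score the user should request when
#' importing the nodes into STRING/Cytoscape. No network API is called.
#'
#' @param results a `kinase_enrichment` object.
#' @param dir output directory.
#' @param min_confidence minimum overall edge confidence recorded in the
#'   manifest (default 0.8).
#' @return paths of the two files, invisibly.
#' @export
export_network_table <- function(results, dir, min_confidence = 0.8) {
  stopifnot(inherits(results, "kinase_enrichment"))
  rows <- rbind(results$over[results$over$reported, , drop = FALSE],
                results$under[results$under$reported, , drop = FALSE])
  nodes <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    genes <- decouple_kinase_names(rows$kinase[i])[[1]]
    data.frame(gene = genes, kinase = rows$kinase[i],
               direction = rows$direction[i],
               signed_log10_p = (-log10(rows$primary_p[i])) *
                 ifelse(rows$direction[i] == "over", 1, -1),
               rank_score = rows$rank_score[i], stringsAsFactors = FALSE)
  }))
  if (is.null(nodes))
    nodes <- data.frame(gene = character(), kinase = character(),
                        direction = character(), signed_log10_p = numeric(),
                        rank_score = numeric(), stringsAsFactors = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_nodes <- file.path(dir, "network_nodes.tsv")
  f_edges <- file.path(dir, "network_edge_request.tsv")
  write.table(nodes, f_nodes, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    parameter = c("min_overall_confidence", "species", "query_type"),
    value = c(format(min_confidence), "9606", "protein"),
    stringsAsFactors = FALSE
  )
  write.table(manifest, f_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes = f_nodes, edge_request = f_edges))
}

.config_defaults <- list(
  params = list(loc_prob_min = 0.75, impute = TRUE, seed = 1,
                minprob_q = 0.01, minprob_sigma_scale = 0.3,
                merge_multiplicity = FALSE, p_threshold = 0.01,
                fdr_threshold = 0.05, set_p_cutoff = 0.01, min_set_size = 2,
                B_null = 100, networkin_score_min = 2,
                reference = "pooled", fractions = "combine"),
  report = list(waterfall_plot = FALSE, min_confidence = 0.8,
                ts_annotation = NULL)
)

#' Read and validate a pipeline configuration
#'
#' @param path YAML file. Required keys: `input.phospho` (one or more site
#'   tables), `input.design`, `output.dir`, `comparison` (either `test` and
#'   `ref`, or `one_vs_rest`), and `db` (either `bundle` or a `sources`
#'   map). Optional: `db.networkin`, `params.*`, `report.*`.
#' @return validated config list with defaults filled in.
#' @export
read_config <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path)) stop(sprintf("config error: file '%s' not found", path))
    cfg <- yaml::read_yaml(path)
  } else cfg <- path
  missing_keys <- character()
  get2 <- function(a, b) if (is.null(cfg[[a]][[b]])) NULL else cfg[[a]][[b]]
  if (is.null(get2("input", "phospho"))) missing_keys <- c(missing_keys, "input.phospho")
  if (is.null(get2("input", "design"))) missing_keys <- c(missing_keys, "input.design")
  if (is.null(get2("output", "dir"))) missing_keys <- c(missing_keys, "output.dir")
  comp <- cfg$comparison
  if (is.null(comp) ||
      (is.null(comp$one_vs_rest) && (is.null(comp$test) || is.null(comp$ref))))
    missing_keys <- c(missing_keys, "comparison.test/comparison.ref or comparison.one_vs_rest")
  dbc <- cfg$db
  if (is.null(dbc) || (is.null(dbc$bundle) && is.null(dbc$sources)))
    missing_keys <- c(missing_keys, "db.bundle or db.sources")
  if (length(missing_keys))
    stop(sprintf("config error: missing key(s): %s",
                 paste(missing_keys, collapse = "; ")))
  cfg$params <- modifyList(.config_defaults$params, cfg$params %||% list())
  cfg$report <- modifyList(.config_defaults$report, cfg$report %||% list())
  cfg
}

#' Run the full pipeline from a YAML configuration
#'
#' Executes parsing, preprocessing, differential testing, database loading,
#' enrichment and reporting, writing every stage output, the resolved
#' configuration and a machine-readable summary into the run directory. With
#' a fixed seed the run is fully reproducible.
#'
#' @param config path to a YAML file or an equivalent list (see
#'   [read_config()]).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  p <- cfg$params
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output$dir, "log.txt")
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  design <- read_design(cfg$input$design)
  paths <- unlist(cfg$input$phospho)
  say("parsing %d phosphosite table(s)", length(paths))
  recs <- lapply(paths, parse_phosphosty, design = design)
  records <- if (identical(p$fractions, "combine")) combine_fractions(recs)
             else do.call(rbind, recs)
  ps <- assemble_matrix(records, design,
                        merge_multiplicity = isTRUE(p$merge_multiplicity))
  n_raw <- nrow(ps$E)
  write_phospho_tsv(ps, file.path(cfg$output$dir, "matrix_raw.tsv"))

  ps <- filter_sites(ps, loc_prob_min = p$loc_prob_min)
  n_filtered <- nrow(ps$E)
  ps <- log2_transform(ps)
  ps <- quantile_normalize(ps)
  ps <- drop_underquantified(ps)
  n_tested <- nrow(ps$E)
  ps <- impute_missing(ps, mode = if (isTRUE(p$impute)) "impute" else "zero",
                       seed = p$seed, minprob_q = p$minprob_q,
                       minprob_sigma_scale = p$minprob_sigma_scale)
  write_phospho_tsv(ps, file.path(cfg$output$dir, "matrix_imputed.tsv"))
  say("matrix: %d raw -> %d filtered -> %d tested sites", n_raw, n_filtered,
      n_tested)

  db <- .load_config_db(cfg, universe = rownames(ps$E))
  cov <- coverage_report(db, ps)
  say("database: %d kinases; coverage of measured sites %.1f%%",
      length(unique(db$assoc$kinase)), 100 * cov$coverage)

  comp <- cfg$comparison
  if (!is.null(comp$one_vs_rest)) {
    diff <- one_vs_rest(ps, comp$one_vs_rest, reference = p$reference)
    label <- sprintf("%s_vs_rest", comp$one_vs_rest)
  } else {
    diff <- welch_test(ps, comp$test, comp$ref)
    label <- sprintf("%s_vs_%s", comp$test, comp$ref)
  }
  volcano <- diff[, c("site", "log2fc", "p_value")]
  volcano$minus_log10_p <- -log10(pmax(volcano$p_value, .Machine$double.xmin))
  write.table(volcano, file.path(cfg$output$dir, sprintf("diff_%s.tsv", label)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  res <- kinase_activity(diff, db, p_threshold = p$p_threshold,
                         fdr_threshold = p$fdr_threshold,
                         set_p_cutoff = p$set_p_cutoff,
                         min_set_size = p$min_set_size,
                         B_null = p$B_null, seed = p$seed)
  if (!is.null(cfg$report$ts_annotation))
    res <- annotate_ts(res, cfg$report$ts_annotation)
  for (dir_ in c("over", "under"))
    write.table(res[[dir_]],
                file.path(cfg$output$dir, sprintf("enrichment_%s.tsv", dir_)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  wf <- waterfall_data(res)
  write.table(wf, file.path(cfg$output$dir, "waterfall.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (isTRUE(cfg$report$waterfall_plot) && nrow(wf))
    plot_waterfall(wf, file.path(cfg$output$dir, "waterfall.png"))
  export_network_table(res, cfg$output$dir,
                       min_confidence = cfg$report$min_confidence)

  summary <- list(
    comparison = label,
    n_records = nrow(records), n_sites_raw = n_raw,
    n_sites_filtered = n_filtered, n_sites_tested = n_tested,
    db_kinases = length(unique(db$assoc$kinase)),
    db_associations = nrow(db$assoc),
    coverage = cov$coverage,
    n_sets_tested = res$n_sets_tested,
    n_over_reported = sum(res$over$reported),
    n_under_reported = sum(res$under$reported),
    over_reported = res$over$kinase[res$over$reported],
    under_reported = res$under$kinase[res$under$reported],
    seed = p$seed
  )
  jsonlite::write_json(summary, file.path(cfg$output$dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(cfg, file.path(cfg$output$dir, "config_resolved.yaml"))
  say("reported kinases: %d overactive, %d underactive",
      summary$n_over_reported, summary$n_under_reported)
  writeLines(log_lines, logf)
  invisible(summary)
}

.load_config_db <- function(cfg, universe) {
  dbc <- cfg$db
  if (!is.null(dbc$bundle)) {
    db <- read_ksdb(dbc$bundle)
  } else if (!is.null(dbc$sources)) {
    assoc <- lapply(names(dbc$sources), function(nm)
      parse_source(nm, dbc$sources[[nm]]))
    syn_path <- dbc$synonyms
    syn <- if (is.null(syn_path)) read_kinase_synonyms()
           else read_kinase_synonyms(syn_path)
    db <- build_metadb(assoc, synonyms = syn)
  } else {
    stop("config error: db.bundle or db.sources required at run time")
  }
  if (!is.null(dbc$networkin)) {
    pred <- load_networkin(dbc$networkin,
                           score_min = cfg$params$networkin_score_min,
                           universe = universe)
    db <- merge_db(db, pred)
  }
  db
}
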