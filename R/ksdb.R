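# Kinase-substrate meta-database: parsing of public source dialects,
# kinase-name unification, merging, NetworKIN augmentation and coverage.

# Per-source column mappings. Each entry describes where the kinase name,
# substrate gene, residue and position live and how species are filtered;
# `rsd` columns combine residue+position ("Y207" or "Tyr207"). Snapshot
# format drift is absorbed by overriding these mappings, not by code edits.
ks_source_dialects <- list(
  PSP = list(sep = "\t", kinase = "GENE", gene = "SUB_GENE",
             rsd = "SUB_MOD_RSD", rsd_style = "short",
             species_cols = c("KIN_ORGANISM", "SUB_ORGANISM"),
             species_value = "human",
             in_vivo = "IN_VIVO_RXN", in_vitro = "IN_VITRO_RXN"),
  HPRD = list(sep = "\t", kinase = "enzyme_name", gene = "substrate_gene_symbol",
              residue = "residue", position = "site",
              type_col = "modification_type", type_value = "Phosphorylation"),
  RegPhos = list(sep = "\t", kinase = "catalytic_kinase", gene = "GENE",
                 residue = "code", position = "position"),
  Signor = list(sep = "\t", kinase = "ENTITYA", gene = "ENTITYB",
                rsd = "RESIDUE", rsd_style = "three",
                species_cols = "TAX_ID", species_value = "9606",
                type_col = "MECHANISM", type_value = "phosphorylation"),
  ELM = list(sep = "\t", kinase = "kinases", gene = "gene",
             residue = "code", position = "position",
             species_cols = "species", species_value = "Homo sapiens")
)

.aa3to1 <- c(Ser = "S", Thr = "T", Tyr = "Y")

.parse_rsd <- function(x, style) {
  x <- trimws(as.character(x))
  if (style == "three") {
    res <- .aa3to1[substr(x, 1, 3)]
    pos <- suppressWarnings(as.integer(substring(x, 4)))
  } else {
    res <- substr(x, 1, 1)
    pos <- suppressWarnings(as.integer(substring(x, 2)))
  }
  list(residue = unname(res), position = pos)
}

#' Parse a kinase-substrate source table
#'
#' Reads one of the five supported experimental source dialects
#' (`PSP`, `HPRD`, `RegPhos`, `Signor`, `ELM`), keeps human entries where the
#' source is multi-species, optionally drops in-vitro-only reactions, and
#' skips malformed rows (bad residue, missing position, empty names) with a
#' logged count.
#'
#' @param name source name; one of `names(ks_source_dialects)`.
#' @param path path to the source file.
#' @param dialect optional override of the column mapping (see
#'   `ks_source_dialects`).
#' @param in_vivo_only for sources with reaction-type flags: keep only
#'   associations with in-vivo evidence (default `FALSE`).
#' @return data.frame of associations: `kinase`, `gene`, `residue`,
#'   `position`, `substrate_key`, `evidence`, `sources`, `score`.
#' @export
parse_source <- function(name, path, dialect = NULL, in_vivo_only = FALSE) {
  if (!name %in% names(ks_source_dialects))
    stop(sprintf("unknown source name '%s' (expected one of %s)", name,
                 paste(names(ks_source_dialects), collapse = ", ")))
  d <- if (is.null(dialect)) ks_source_dialects[[name]] else dialect
  tab <- read.delim(path, sep = d$sep, check.names = FALSE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- unlist(d[intersect(names(d), c("kinase", "gene", "rsd", "residue",
                                         "position", "type_col"))],
                 use.names = FALSE)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("format error in %s file: missing column(s): %s", name,
                 paste(miss, collapse = ", ")))
  n0 <- nrow(tab)
  if (!is.null(d$species_cols)) {
    for (sc in d$species_cols)
      tab <- tab[tolower(trimws(as.character(tab[[sc]]))) ==
                   tolower(d$species_value), , drop = FALSE]
  }
  if (!is.null(d$type_col))
    tab <- tab[tolower(trimws(as.character(tab[[d$type_col]]))) ==
                 tolower(d$type_value), , drop = FALSE]
  if (in_vivo_only && !is.null(d$in_vivo))
    tab <- tab[trimws(as.character(tab[[d$in_vivo]])) != "", , drop = FALSE]
  if (nrow(tab) == 0)
    return(data.frame(kinase = character(), gene = character(),
                      residue = character(), position = integer(),
                      substrate_key = character(), evidence = character(),
                      sources = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  if (!is.null(d$rsd)) {
    rp <- .parse_rsd(tab[[d$rsd]], d$rsd_style)
    residue <- rp$residue; position <- rp$position
  } else {
    residue <- toupper(trimws(as.character(tab[[d$residue]])))
    position <- suppressWarnings(as.integer(tab[[d$position]]))
  }
  kinase <- trimws(as.character(tab[[d$kinase]]))
  gene <- toupper(trimws(as.character(tab[[d$gene]])))
  ok <- !is.na(residue) & residue %in% c("S", "T", "Y") &
    !is.na(position) & position >= 1 & nzchar(kinase) & nzchar(gene)
  if (any(!ok))
    message(sprintf("parse_source(%s): skipped %d malformed row(s)", name, sum(!ok)))
  assoc <- data.frame(
    kinase = kinase[ok], gene = gene[ok], residue = residue[ok],
    position = position[ok],
    substrate_key = make_site_key(gene[ok], residue[ok], position[ok]),
    evidence = "experimental", sources = name, score = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(assoc) <- NULL
  assoc
}

#' Read the shipped (or a user-supplied) kinase synonym table
#'
#' @param path TSV with columns `raw`, `canonical`; defaults to the curated
#'   table shipped with the package.
#' @return named character vector mapping raw to canonical names.
#' @export
read_kinase_synonyms <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinase_synonyms.tsv", package = "phosact")
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!all(c("raw", "canonical") %in% names(tab)))
    stop("synonym table must have columns 'raw' and 'canonical'")
  setNames(tab$canonical, tab$raw)
}

#' Unify kinase names across source databases
#'
#' Replaces raw kinase names by their canonical gene symbols using a synonym
#' map; names absent from the map pass through unchanged (with a logged
#' count). Applying the map twice is a no-op.
#'
#' @param assoc association data.frame (see [parse_source()]).
#' @param synonyms named character vector `raw -> canonical`; defaults to the
#'   shipped table.
#' @return the association table with unified kinase names.
#' @export
unify_kinase_names <- function(assoc, synonyms = read_kinase_synonyms()) {
  hit <- assoc$kinase %in% names(synonyms)
  n_unmapped <- length(unique(assoc$kinase[!hit]))
  if (any(!hit) && n_unmapped > 0)
    message(sprintf("unify_kinase_names: %d kinase name(s) not in the synonym map passed through unchanged",
                    n_unmapped))
  assoc$kinase[hit] <- unname(synonyms[assoc$kinase[hit]])
  assoc
}

.dedup_assoc <- function(assoc) {
  id <- paste(assoc$kinase, assoc$substrate_key, sep = "\r")
  grp <- split(seq_len(nrow(assoc)), id)
  grp <- grp[order(vapply(grp, min, integer(1)))]
  out <- lapply(grp, function(i) {
    r <- assoc[i[1], , drop = FALSE]
    # experimental evidence takes precedence over predictions
    if (any(assoc$evidence[i] == "experimental")) {
      r <- assoc[i[which(assoc$evidence[i] == "experimental")[1]], , drop = FALSE]
      r$evidence <- "experimental"
    }
    srcs <- sort(unique(unlist(strsplit(assoc$sources[i], ";", fixed = TRUE))))
    r$sources <- paste(srcs, collapse = ";")
    sc <- assoc$score[i]
    r$score <- if (all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE)
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.drop_single_entry <- function(assoc) {
  n <- table(assoc$kinase)
  assoc[assoc$kinase %in% names(n)[n >= 2], , drop = FALSE]
}

#' Build the kinase-substrate meta-database
#'
#' Concatenates per-source association lists, unifies kinase names, merges
#' duplicate (kinase, substrate) pairs with a union of their sources, and
#' removes kinases left with a single entry.
#'
#' @param assoc_lists list of association data.frames from [parse_source()]
#'   (a single data.frame is also accepted).
#' @param synonyms synonym map applied via [unify_kinase_names()]; `NULL`
#'   skips unification.
#' @return object of class `ksdb`: list with elements `assoc` (merged
#'   association table) and `synonyms`.
#' @export
build_metadb <- function(assoc_lists, synonyms = NULL) {
  if (is.data.frame(assoc_lists)) assoc_lists <- list(assoc_lists)
  if (!length(assoc_lists)) stop("at least one association list is required")
  assoc <- do.call(rbind, assoc_lists)
  if (is.null(assoc) || nrow(assoc) == 0) stop("no associations to merge")
  if (!is.null(synonyms)) assoc <- unify_kinase_names(assoc, synonyms)
  assoc <- .dedup_assoc(assoc)
  assoc <- .drop_single_entry(assoc)
  if (nrow(assoc) == 0) stop("meta-database empty after single-entry removal")
  rownames(assoc) <- NULL
  db <- structure(list(assoc = assoc, synonyms = synonyms), class = "ksdb")
  message(sprintf("meta-database: %d associations, %d kinases, %d unique substrate sites",
                  nrow(assoc), length(unique(assoc$kinase)),
                  length(unique(assoc$substrate_key))))
  db
}

#' @export
print.ksdb <- function(x, ...) {
  cat(sprintf("ksdb: %d associations | %d kinases | %d substrate sites (%d predicted)\n",
              nrow(x$assoc), length(unique(x$assoc$kinase)),
              length(unique(x$assoc$substrate_key)),
              sum(x$assoc$evidence == "predicted")))
  invisible(x)
}

#' Load NetworKIN predictions restricted to the measured sites
#'
#' @param path NetworKIN output TSV with columns `gene`, `position`,
#'   `residue`, `kinase` and `networkin_score` (override via `cols`).
#' @param score_min minimum prediction score retained (default 2).
#' @param universe character vector of measured site keys (multiplicity
#'   suffixes are ignored for matching).
#' @param cols named list overriding the column mapping.
#' @return association data.frame with `evidence = "predicted"`.
#' @export
load_networkin <- function(path, score_min = 2, universe, cols = list()) {
  cmap <- modifyList(list(gene = "gene", position = "position",
                          residue = "residue", kinase = "kinase",
                          score = "networkin_score"), cols)
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (!cmap$score %in% names(tab))
    stop(sprintf("format error: NetworKIN file lacks score column '%s'", cmap$score))
  miss <- setdiff(unlist(cmap), names(tab))
  if (length(miss))
    stop(sprintf("format error: NetworKIN file lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  gene <- toupper(trimws(as.character(tab[[cmap$gene]])))
  residue <- toupper(trimws(as.character(tab[[cmap$residue]])))
  position <- suppressWarnings(as.integer(tab[[cmap$position]]))
  score <- as.numeric(tab[[cmap$score]])
  kinase <- trimws(as.character(tab[[cmap$kinase]]))
  ok <- residue %in% c("S", "T", "Y") & !is.na(position) & nzchar(kinase) &
    nzchar(gene) & !is.na(score)
  key <- rep(NA_character_, length(gene))
  key[ok] <- make_site_key(gene[ok], residue[ok], position[ok])
  base_universe <- unique(base_site_key(universe))
  keep <- which(ok & score >= score_min & key %in% base_universe)
  out <- data.frame(kinase = kinase, gene = gene, residue = residue,
                    position = position, substrate_key = key,
                    evidence = "predicted", sources = "NetworKIN",
                    score = score, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge predicted associations into an experimental meta-database
#'
#' Union of the two sets; on conflicts the experimental evidence wins while
#' the prediction's source is recorded. The single-entry-kinase rule is
#' re-applied after the merge.
#'
#' @param db a `ksdb` of experimental associations.
#' @param predicted association data.frame from [load_networkin()].
#' @return a merged `ksdb`.
#' @export
merge_db <- function(db, predicted) {
  stopifnot(inherits(db, "ksdb"))
  if (is.null(predicted) || nrow(predicted) == 0) return(db)
  if (!is.null(db$synonyms)) predicted <- unify_kinase_names(predicted, db$synonyms)
  assoc <- .dedup_assoc(rbind(db$assoc, predicted))
  assoc <- .drop_single_entry(assoc)
  rownames(assoc) <- NULL
  structure(list(assoc = assoc, synonyms = db$synonyms), class = "ksdb")
}

#' Coverage of measured phosphosites by the database
#'
#' @param db a `ksdb`.
#' @param ps a filtered [phospho_set()].
#' @return list with `coverage` (fraction of measured sites annotated with at
#'   least one kinase) and `per_kinase` (data.frame of measured-substrate
#'   counts).
#' @export
coverage_report <- function(db, ps) {
  stopifnot(inherits(db, "ksdb"), inherits(ps, "phospho_set"))
  measured <- unique(base_site_key(rownames(ps$E)))
  if (!length(measured)) stop("empty matrix")
  covered <- measured %in% db$assoc$substrate_key
  per_kinase <- db$assoc[db$assoc$substrate_key %in% measured, , drop = FALSE]
  if (nrow(per_kinase)) {
    counts <- as.data.frame(table(per_kinase$kinase), stringsAsFactors = FALSE)
  } else {
    counts <- data.frame(character(), integer(), stringsAsFactors = FALSE)
  }
  names(counts) <- c("kinase", "n_measured_substrates")
  counts <- counts[order(-counts$n_measured_substrates, counts$kinase), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  list(coverage = mean(covered), per_kinase = counts)
}

#' Serialize / load a meta-database as a two-file TSV bundle
#'
#' @param db a `ksdb`.
#' @param prefix path prefix; writes `<prefix>_associations.tsv` and
#'   `<prefix>_synonyms.tsv`, each with a version header line.
#' @return `write_ksdb` the file paths (invisibly); `read_ksdb` a `ksdb`.
#' @export
write_ksdb <- function(db, prefix) {
  stopifnot(inherits(db, "ksdb"))
  fa <- paste0(prefix, "_associations.tsv")
  fs <- paste0(prefix, "_synonyms.tsv")
  for (f in list(list(fa, db$assoc),
                 list(fs, data.frame(raw = names(db$synonyms %||% character()),
                                     canonical = unname(db$synonyms %||% character()),
                                     stringsAsFactors = FALSE)))) {
    con <- file(f[[1]], "w")
    writeLines("# phosact kinase-substrate db v1", con)
    write.table(f[[2]], con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(c(associations = fa, synonyms = fs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_ksdb
#' @export
read_ksdb <- function(prefix) {
  fa <- paste0(prefix, "_associations.tsv")
  fs <- paste0(prefix, "_synonyms.tsv")
  assoc <- read.delim(fa, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "#")
  assoc$score <- as.numeric(assoc$score)
  syn <- NULL
  if (file.exists(fs)) {
    st <- read.delim(fs, sep = "\t", stringsAsFactors = FALSE,
                     comment.char = "#")
    if (nrow(st)) syn <- setNames(st$canonical, st$raw)
  }
  structure(list(assoc = assoc, synonyms = syn), class = "ksdb")
}

#' Export the database in GMT format
#'
#' One line per kinase: name, description, then its substrate site keys.
#'
#' @param db a `ksdb`.
#' @param path output file.
#' @export
export_gmt <- function(db, path) {
  stopifnot(inherits(db, "ksdb"))
  lines <- vapply(split(db$assoc$substrate_key, db$assoc$kinase),
                  function(s) paste(sort(unique(s)), collapse = "\t"),
                  character(1))
  writeLines(paste(names(lines), "phosact_ksdb", lines, sep = "\t"), path)
  invisible(path)
}
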