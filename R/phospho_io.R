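# Reading MaxQuant Phospho (STY)Sites tables and assembling the raw matrix.
#
# Dialect: tab-separated with a header; intensity columns follow
# "Intensity <sample>___<k>" where k in 1..3 is the peptide multiplicity
# (number of phosphate groups); the reverse / contaminant flag columns carry
# "+" for true and are empty otherwise; zero intensities mean not quantified.

.mq_required <- c("Localization prob", "Reverse", "Potential contaminant",
                  "Amino acid", "Position", "Gene names", "Proteins")

.leading_entry <- function(x) {
  # MaxQuant protein groups list entries ';'-separated; keep the leader
  vapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(p) if (length(p)) trimws(p[[1]]) else "", character(1))
}

#' Read a sample design table
#'
#' @param path CSV with columns `sample`, `condition` and optionally
#'   `replicate`.
#' @return data.frame
#' @export
read_design <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(d)))
    stop("design table must have columns 'sample' and 'condition'")
  d$sample <- as.character(d$sample)
  d$condition <- as.character(d$condition)
  d
}

#' Parse a MaxQuant Phospho (STY)Sites table
#'
#' Produces one record per (site row, multiplicity) pair that carries at
#' least one quantified intensity among the design samples. Zero intensities
#' in the file are read as missing; multi-protein groups are reduced to their
#' leading entry.
#'
#' @param path path to the tab-separated sites table.
#' @param design data.frame with columns `sample`, `condition`; every sample
#'   must have matching `Intensity <sample>___k` columns in the file.
#' @return data.frame of records: `protein_id`, `gene_symbol`, `residue`,
#'   `position`, `localization_prob`, `multiplicity`, `is_reverse`,
#'   `is_contaminant`, followed by one intensity column per design sample.
#' @export
parse_phosphosty <- function(path, design) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop(sprintf("format error: '%s' contains no site rows", path))
  miss <- setdiff(.mq_required, names(tab))
  if (length(miss))
    stop(sprintf("format error: missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  int_cols <- grep("^Intensity .+___[123]$", names(tab), value = TRUE)
  if (!length(int_cols))
    stop("format error: no 'Intensity <sample>___k' columns found")
  m <- regmatches(int_cols, regexec("^Intensity (.+)___([123])$", int_cols))
  int_samples <- vapply(m, `[`, character(1), 2)
  int_mult <- as.integer(vapply(m, `[`, character(1), 3))
  samples <- design$sample
  absent <- setdiff(samples, unique(int_samples))
  if (length(absent))
    stop(sprintf("design sample(s) not found in file header: %s",
                 paste(absent, collapse = ", ")))

  residue <- as.character(tab[["Amino acid"]])
  bad_res <- !(residue %in% c("S", "T", "Y"))
  if (any(bad_res)) {
    message(sprintf("parse_phosphosty: skipping %d row(s) with residue outside S/T/Y",
                    sum(bad_res)))
    tab <- tab[!bad_res, , drop = FALSE]
    residue <- residue[!bad_res]
    if (nrow(tab) == 0) stop("format error: no S/T/Y site rows left")
  }

  base <- data.frame(
    protein_id = .leading_entry(tab[["Proteins"]]),
    gene_symbol = .leading_entry(tab[["Gene names"]]),
    residue = residue,
    position = as.integer(tab[["Position"]]),
    localization_prob = as.numeric(tab[["Localization prob"]]),
    is_reverse = as.character(tab[["Reverse"]]) == "+",
    is_contaminant = as.character(tab[["Potential contaminant"]]) == "+",
    stringsAsFactors = FALSE
  )

  pieces <- list()
  for (k in sort(unique(int_mult))) {
    cols <- int_cols[int_mult == k]
    cols_samp <- int_samples[int_mult == k]
    keep <- match(samples, cols_samp)
    if (anyNA(keep)) next
    ints <- as.matrix(tab[, cols[keep], drop = FALSE])
    storage.mode(ints) <- "double"
    ints[ints == 0] <- NA_real_
    colnames(ints) <- samples
    has_val <- rowSums(!is.na(ints)) > 0
    if (!any(has_val)) next
    rec <- cbind(base[has_val, , drop = FALSE],
                 multiplicity = k,
                 as.data.frame(ints[has_val, , drop = FALSE], optional = TRUE),
                 row.names = NULL)
    rec$.row <- which(has_val)
    pieces[[length(pieces) + 1L]] <- rec
  }
  if (!length(pieces)) stop("no quantified records in file")
  rec <- do.call(rbind, pieces)
  # order: input row order, then multiplicity
  rec <- rec[order(rec$.row, rec$multiplicity), , drop = FALSE]
  rec$.row <- NULL
  rec <- rec[, c("protein_id", "gene_symbol", "residue", "position",
                 "localization_prob", "multiplicity", "is_reverse",
                 "is_contaminant", samples)]
  rownames(rec) <- NULL
  rec
}

#' Build a canonical phosphosite key
#'
#' Keys have the form `GENE_<residue><position>` with an optional
#' multiplicity suffix `_m<k>` (e.g. `CRKL_Y207_m1`). The gene symbol is
#' uppercased; when absent, the protein accession is used instead.
#'
#' @param gene gene symbol (may be empty).
#' @param residue one of S, T, Y.
#' @param position 1-based residue position on the protein.
#' @param multiplicity optional integer in 1..3; `NULL` omits the suffix.
#' @param protein_id fallback identifier when `gene` is empty.
#' @return character vector of site keys.
#' @export
make_site_key <- function(gene, residue, position, multiplicity = NULL,
                          protein_id = "") {
  if (!all(residue %in% c("S", "T", "Y")))
    stop("residue must be one of S, T, Y")
  gene <- toupper(trimws(as.character(gene)))
  protein_id <- toupper(trimws(as.character(protein_id)))
  name <- ifelse(nzchar(gene), gene, protein_id)
  if (any(!nzchar(name)))
    stop("gene symbol and protein_id are both empty; cannot build a site key")
  key <- sprintf("%s_%s%d", name, residue, as.integer(position))
  if (!is.null(multiplicity)) key <- sprintf("%s_m%d", key, as.integer(multiplicity))
  key
}

#' Strip the multiplicity suffix from site keys
#'
#' @param key character vector of site keys.
#' @return keys without the `_m<k>` suffix.
#' @export
base_site_key <- function(key) sub("_m[0-9]+$", "", key)

#' Sum intensities of records parsed from fraction files
#'
#' Two-stage phosphopeptide enrichments are commonly acquired as separate
#' fraction runs per sample; this sums their intensities per site and sample
#' before matrix assembly.
#'
#' @param record_list list of record data.frames from [parse_phosphosty()]
#'   sharing the same design samples.
#' @return a single record data.frame.
#' @export
combine_fractions <- function(record_list) {
  stopifnot(length(record_list) >= 1)
  if (length(record_list) == 1) return(record_list[[1]])
  rec <- do.call(rbind, record_list)
  meta <- c("protein_id", "gene_symbol", "residue", "position",
            "localization_prob", "multiplicity", "is_reverse", "is_contaminant")
  samples <- setdiff(names(rec), meta)
  id <- paste(rec$gene_symbol, rec$protein_id, rec$residue, rec$position,
              rec$multiplicity, sep = "\r")
  grp <- split(seq_len(nrow(rec)), id)
  # keep first-appearance order
  grp <- grp[order(vapply(grp, min, integer(1)))]
  out <- lapply(grp, function(i) {
    r <- rec[i[1], , drop = FALSE]
    r$localization_prob <- max(rec$localization_prob[i])
    for (s in samples) {
      v <- rec[i, s]
      r[[s]] <- if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble the raw intensity matrix of unique phosphosites
#'
#' Records collapsing to the same site key have their intensities summed on
#' the linear scale (preserving total ion signal); flags are OR-combined and
#' the best localization probability is kept. Values stay linear at this
#' stage.
#'
#' @param records record data.frame from [parse_phosphosty()].
#' @param design data.frame with columns `sample`, `condition`.
#' @param merge_multiplicity if `TRUE`, multiplicity variants of a site are
#'   collapsed into one row (no `_m<k>` suffix); default keeps them distinct.
#' @return a [phospho_set()] at stage `raw`.
#' @export
assemble_matrix <- function(records, design, merge_multiplicity = FALSE) {
  if (is.null(records) || nrow(records) == 0)
    stop("no records to assemble")
  samples <- design$sample
  if (!all(samples %in% names(records)))
    stop("records lack intensity columns for some design samples")
  keys <- make_site_key(records$gene_symbol, records$residue, records$position,
                        multiplicity = if (merge_multiplicity) NULL else records$multiplicity,
                        protein_id = records$protein_id)
  ukeys <- unique(keys)
  E <- matrix(NA_real_, nrow = length(ukeys), ncol = length(samples),
              dimnames = list(ukeys, samples))
  sites <- data.frame(key = ukeys, gene_symbol = NA_character_,
                      protein_id = NA_character_, residue = NA_character_,
                      position = NA_integer_, multiplicity = NA_integer_,
                      localization_prob = NA_real_, is_reverse = NA,
                      is_contaminant = NA, stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(records)), factor(keys, levels = ukeys))
  for (j in seq_along(ukeys)) {
    i <- idx[[j]]
    vals <- as.matrix(records[i, samples, drop = FALSE])
    if (length(i) == 1) {
      E[j, ] <- vals
    } else {
      cs <- colSums(vals, na.rm = TRUE)
      cs[colSums(!is.na(vals)) == 0] <- NA_real_
      E[j, ] <- cs
    }
    sites$gene_symbol[j] <- records$gene_symbol[i[1]]
    sites$protein_id[j] <- records$protein_id[i[1]]
    sites$residue[j] <- records$residue[i[1]]
    sites$position[j] <- records$position[i[1]]
    sites$multiplicity[j] <- if (merge_multiplicity) NA_integer_ else records$multiplicity[i[1]]
    sites$localization_prob[j] <- max(records$localization_prob[i])
    sites$is_reverse[j] <- any(records$is_reverse[i])
    sites$is_contaminant[j] <- any(records$is_contaminant[i])
  }
  phospho_set(E, design, sites = sites, stage = "raw", log2 = FALSE)
}
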