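#' Phosphosite expression set
#'
#' Lightweight container for a unique-phosphosite by sample intensity matrix,
#' in the spirit of the matrix-plus-targets containers used in expression
#' analysis. Holds the value matrix (`NA` = missing), per-site annotation,
#' the sample design, the mask of originally observed cells, and a
#' processing-stage tag that only moves forward
#' (`raw -> filtered -> normalized -> imputed`).
#'
#' @param E numeric matrix, sites x samples; `NA` encodes a missing value.
#' @param design data.frame with columns `sample` and `condition`
#'   (a `replicate` column is optional). Every column of `E` must appear.
#' @param sites optional data.frame of per-site annotation, one row per row
#'   of `E` (columns such as `gene_symbol`, `residue`, `position`,
#'   `localization_prob`, `is_reverse`, `is_contaminant`).
#' @param stage processing stage tag.
#' @param log2 logical; are values on the log2 scale?
#' @param obs optional logical matrix marking originally observed cells;
#'   defaults to `!is.na(E)`.
#' @return object of class `phospho_set`.
#' @export
phospho_set <- function(E, design, sites = NULL,
                        stage = c("raw", "filtered", "normalized", "imputed"),
                        log2 = FALSE, obs = NULL) {
  stage <- match.arg(stage)
  E <- as.matrix(E)
  if (is.null(rownames(E))) stop("E must have site keys as rownames")
  if (anyDuplicated(rownames(E))) stop("site keys (rownames of E) must be unique")
  if (!is.data.frame(design) || !all(c("sample", "condition") %in% names(design)))
    stop("design must be a data.frame with columns sample and condition")
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  if (!all(colnames(E) %in% design$sample))
    stop("every sample column of E must appear in the design")
  design <- design[design$sample %in% colnames(E), , drop = FALSE]
  E <- E[, design$sample, drop = FALSE]
  if (is.null(sites)) {
    sites <- data.frame(key = rownames(E), stringsAsFactors = FALSE)
  }
  if (nrow(sites) != nrow(E)) stop("sites annotation must have one row per site")
  sites$key <- rownames(E)
  rownames(sites) <- NULL
  if (is.null(obs)) obs <- !is.na(E)
  structure(
    list(E = E, obs = obs, sites = sites, design = design,
         stage = stage, log2 = log2),
    class = "phospho_set"
  )
}

.stage_rank <- c(raw = 1L, filtered = 2L, normalized = 3L, imputed = 4L)

.advance_stage <- function(ps, to) {
  if (.stage_rank[[to]] < .stage_rank[[ps$stage]])
    stop(sprintf("stage can only move forward (current '%s', requested '%s')",
                 ps$stage, to))
  ps$stage <- to
  ps
}

.subset_sites <- function(ps, keep) {
  ps$E <- ps$E[keep, , drop = FALSE]
  ps$obs <- ps$obs[keep, , drop = FALSE]
  ps$sites <- ps$sites[keep, , drop = FALSE]
  rownames(ps$sites) <- NULL
  ps
}

#' @export
print.phospho_set <- function(x, ...) {
  cat(sprintf("phospho_set: %d sites x %d samples [stage %s, %s scale]\n",
              nrow(x$E), ncol(x$E), x$stage,
              if (x$log2) "log2" else "linear"))
  cat(sprintf("conditions: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$design$condition)),
                            as.integer(table(x$design$condition))),
                    collapse = ", ")))
  cat(sprintf("missing cells: %d (%.1f%%)\n", sum(is.na(x$E)),
              100 * mean(is.na(x$E))))
  invisible(x)
}

#' @export
dim.phospho_set <- function(x) dim(x$E)

#' Write the value matrix of a phospho_set as TSV
#'
#' @param ps a [phospho_set()]
#' @param path output file; first column `site`, then one column per sample.
#' @export
write_phospho_tsv <- function(ps, path) {
  out <- data.frame(site = rownames(ps$E), ps$E, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
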