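# Per-site Welch testing between conditions and the two direction-specific
# ranked site lists used by the enrichment.

.rowVars <- function(x) {
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  rowSums((x - mu)^2, na.rm = TRUE) / (n - 1)
}

.welch_from_groups <- function(X, Y) {
  nx <- rowSums(!is.na(X)); ny <- rowSums(!is.na(Y))
  mx <- rowMeans(X, na.rm = TRUE); my <- rowMeans(Y, na.rm = TRUE)
  vx <- .rowVars(X); vy <- .rowVars(Y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  zero <- !is.na(se2) & se2 == 0
  t_stat[zero] <- 0
  df[zero] <- nx[zero] + ny[zero] - 2
  p <- 2 * pt(-abs(t_stat), df)
  list(mean_test = mx, mean_ref = my, log2fc = mx - my,
       t_stat = t_stat, df = df, p_value = p)
}

.diff_table <- function(ps, X, Y) {
  usable <- rowSums(!is.na(X)) >= 2 & rowSums(!is.na(Y)) >= 2
  if (!all(usable))
    message(sprintf("welch test: dropping %d site(s) with < 2 usable values in a group",
                    sum(!usable)))
  if (!any(usable)) stop("no site has >= 2 usable values in both groups")
  X <- X[usable, , drop = FALSE]; Y <- Y[usable, , drop = FALSE]
  w <- .welch_from_groups(X, Y)
  res <- data.frame(site = rownames(X), mean_test = w$mean_test,
                    mean_ref = w$mean_ref, log2fc = w$log2fc,
                    t_stat = w$t_stat, df = w$df, p_value = w$p_value,
                    stringsAsFactors = FALSE)
  # transparency: fraction of imputed cells feeding each test (columns that
  # are derived summaries, e.g. per-condition means, are not counted)
  cols <- intersect(c(colnames(X), colnames(Y)), colnames(ps$obs))
  res$imputed_frac <- rowMeans(!ps$obs[res$site, cols, drop = FALSE])
  rownames(res) <- NULL
  res
}

#' Per-site Welch test between two conditions
#'
#' Standard two-sided unequal-variance t-test per phosphosite with
#' Welch-Satterthwaite degrees of freedom. Sites with fewer than two usable
#' values in either group are dropped with a logged count. The log2 fold
#' change is `mean(test) - mean(ref)`.
#'
#' @param ps a [phospho_set()] on the log2 scale.
#' @param test_cond,ref_cond condition labels from the design.
#' @return data.frame with columns `site`, `mean_test`, `mean_ref`,
#'   `log2fc`, `t_stat`, `df`, `p_value`, `imputed_frac`.
#' @export
welch_test <- function(ps, test_cond, ref_cond) {
  stopifnot(inherits(ps, "phospho_set"))
  conds <- unique(ps$design$condition)
  for (cc in c(test_cond, ref_cond))
    if (!cc %in% conds) stop(sprintf("unknown condition label '%s'", cc))
  X <- ps$E[, ps$design$sample[ps$design$condition == test_cond], drop = FALSE]
  Y <- ps$E[, ps$design$sample[ps$design$condition == ref_cond], drop = FALSE]
  .diff_table(ps, X, Y)
}

#' Welch test of one condition against all others
#'
#' Compares the target condition's replicates with the remaining conditions
#' used as a common reference. The default pools all other replicates into
#' one Welch group (preserving within-group variance); the alternative uses
#' the per-condition means of the other conditions as the reference values.
#'
#' @param ps a [phospho_set()] on the log2 scale.
#' @param target_cond condition to contrast against the rest.
#' @param reference `"pooled"` or `"mean_of_means"`.
#' @return data.frame as in [welch_test()].
#' @export
one_vs_rest <- function(ps, target_cond, reference = c("pooled", "mean_of_means")) {
  stopifnot(inherits(ps, "phospho_set"))
  reference <- match.arg(reference)
  conds <- unique(ps$design$condition)
  if (!target_cond %in% conds)
    stop(sprintf("unknown condition label '%s'", target_cond))
  others <- setdiff(conds, target_cond)
  if (length(others) < 1) stop("one_vs_rest needs more than one condition")
  X <- ps$E[, ps$design$sample[ps$design$condition == target_cond], drop = FALSE]
  if (reference == "pooled") {
    Y <- ps$E[, ps$design$sample[ps$design$condition %in% others], drop = FALSE]
  } else {
    if (length(others) < 2)
      stop("mean_of_means reference needs >= 2 non-target conditions")
    Y <- vapply(others, function(cc) {
      rowMeans(ps$E[, ps$design$sample[ps$design$condition == cc], drop = FALSE],
               na.rm = TRUE)
    }, numeric(nrow(ps$E)))
    Y[is.nan(Y)] <- NA_real_
    rownames(Y) <- rownames(ps$E)
  }
  .diff_table(ps, X, Y)
}

#' Direction-specific ranking of differential sites
#'
#' Each site receives the signed score `sign(log2fc) * (-log10 p)`. The
#' over-ranking sorts the score descending (strongly over-expressed sites
#' first), the under-ranking sorts it ascending; no significance cutoff is
#' applied, so both directions rank the full site universe. Ties are broken
#' by larger absolute fold change, then lexicographically by site key, making
#' the order deterministic and independent of input row order.
#'
#' @param diff differential table from [welch_test()] or [one_vs_rest()].
#' @param direction `"over"` or `"under"`.
#' @return character vector of site keys (rank 1 first) of class
#'   `ranked_sites`, with the scores attached as attribute `score`.
#' @export
rank_sites <- function(diff, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (nrow(diff) == 0) stop("empty differential table")
  p <- pmax(diff$p_value, .Machine$double.xmin)
  score <- sign(diff$log2fc) * (-log10(p))
  ord <- if (direction == "over") {
    order(-score, -abs(diff$log2fc), diff$site)
  } else {
    order(score, -abs(diff$log2fc), diff$site)
  }
  structure(diff$site[ord], score = score[ord], direction = direction,
            class = "ranked_sites")
}
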