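# Filtering, log2 transform, quantile normalization, missingness
# classification and imputation of the phosphosite matrix.

#' Filter contaminants, reverse hits and poorly localized sites
#'
#' Removes rows flagged as potential contaminant or reverse-database hits and
#' rows whose localization probability falls below `loc_prob_min`; the
#' boundary value itself is kept.
#'
#' @param ps a [phospho_set()] at stage `raw`.
#' @param loc_prob_min minimum localization probability retained (default
#'   0.75).
#' @return a `phospho_set` at stage `filtered`.
#' @export
filter_sites <- function(ps, loc_prob_min = 0.75) {
  stopifnot(inherits(ps, "phospho_set"))
  if (ps$stage != "raw") stop("filter_sites expects a raw-stage matrix")
  s <- ps$sites
  flag <- (!is.na(s$is_contaminant) & s$is_contaminant) |
    (!is.na(s$is_reverse) & s$is_reverse)
  lowloc <- !is.na(s$localization_prob) & s$localization_prob < loc_prob_min
  keep <- !(flag | lowloc)
  if (!any(keep)) stop("empty matrix after filtering")
  ps <- .subset_sites(ps, keep)
  .advance_stage(ps, "filtered")
}

#' Log2-transform the intensity matrix
#'
#' @param ps a [phospho_set()] on the linear scale; all non-missing values
#'   must be positive (zeros should have been mapped to missing upstream).
#' @return the set with `log2 = TRUE`; missing values stay missing.
#' @export
log2_transform <- function(ps) {
  stopifnot(inherits(ps, "phospho_set"))
  if (ps$log2) stop("matrix is already log2-transformed")
  if (any(!is.na(ps$E) & ps$E <= 0))
    stop("non-missing values <= 0 found; zeros must be mapped to missing upstream")
  ps$E <- log2(ps$E)
  ps$log2 <- TRUE
  ps
}

#' Quantile-normalize the log2 matrix
#'
#' Classic sort/row-mean/restore quantile normalization across samples.
#' Missing values are left missing and excluded from rank computation; ranks
#' are computed among each column's observed values against a reference
#' distribution interpolated to that column's observed count, with ties
#' receiving the mean of tied reference values
#' (delegated to [limma::normalizeQuantiles()]).
#'
#' @param ps a log2-scale [phospho_set()] at stage `filtered`.
#' @return a `phospho_set` at stage `normalized`; a single-sample matrix is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(ps) {
  stopifnot(inherits(ps, "phospho_set"))
  if (!ps$log2) stop("quantile normalization expects log2-scale values")
  if (ncol(ps$E) < 2) {
    warning("single-sample matrix: quantile normalization skipped")
    return(.advance_stage(ps, "normalized"))
  }
  dn <- dimnames(ps$E)
  ps$E <- limma::normalizeQuantiles(ps$E, ties = TRUE)
  dimnames(ps$E) <- dn
  .advance_stage(ps, "normalized")
}

#' Classify per-condition missingness as complete / MAR / MNAR
#'
#' Within each condition of n replicates, a site is `complete` when all
#' replicates are observed, `MAR` (missing at random, sporadic dropout) when
#' exactly one replicate is missing, and `MNAR` (missing not at random,
#' left-censored absence) when two or more are missing. For the standard
#' triplicate design this is the 1-of-3 versus 2-or-3-of-3 rule.
#'
#' @param ps a [phospho_set()]; every condition must have at least two
#'   replicates.
#' @return data.frame with columns `site`, `condition`, `n_replicates`,
#'   `n_missing`, `label`.
#' @export
classify_missingness <- function(ps) {
  stopifnot(inherits(ps, "phospho_set"))
  conds <- unique(ps$design$condition)
  nrep <- table(ps$design$condition)
  if (any(nrep < 2))
    stop("every condition needs >= 2 replicates to classify missingness")
  out <- lapply(conds, function(cc) {
    cols <- ps$design$sample[ps$design$condition == cc]
    nm <- rowSums(is.na(ps$E[, cols, drop = FALSE]))
    data.frame(site = rownames(ps$E), condition = cc,
               n_replicates = length(cols), n_missing = as.integer(nm),
               label = ifelse(nm == 0, "complete",
                              ifelse(nm == 1, "MAR", "MNAR")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Drop sites quantified at most once across all samples
#'
#' Sites carrying no more than one originally observed value over all
#' conditions hold no usable quantitative information and are excluded from
#' the statistical evaluation.
#'
#' @param ps a [phospho_set()] past the filtering stage.
#' @return the set without under-quantified rows.
#' @export
drop_underquantified <- function(ps) {
  stopifnot(inherits(ps, "phospho_set"))
  if (ps$stage == "raw") stop("drop_underquantified expects a filtered matrix")
  keep <- rowSums(ps$obs) > 1
  if (!all(keep)) {
    message(sprintf("drop_underquantified: removing %d site(s) with <= 1 observed value",
                    sum(!keep)))
    ps <- .subset_sites(ps, keep)
  }
  ps
}

# EM fit of a multivariate normal over the replicate columns of one
# condition, tolerating rows with missing entries. Returns mu, Sigma.
.em_mvn <- function(X, max_iter = 100, tol = 1e-6, ridge = 1e-6) {
  d <- ncol(X)
  cc <- complete.cases(X)
  if (sum(cc) >= max(5, d + 2)) {
    mu <- colMeans(X[cc, , drop = FALSE])
    Sigma <- stats::cov(X[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
  } else {
    mu <- colMeans(X, na.rm = TRUE)
    v <- apply(X, 2, var, na.rm = TRUE)
    v[!is.finite(v) | v <= 0] <- 1
    Sigma <- diag(v, d)
  }
  Sigma <- Sigma + diag(ridge, d)
  use <- rowSums(!is.na(X)) >= 1
  X <- X[use, , drop = FALSE]
  n <- nrow(X)
  if (n < d + 2) return(list(mu = mu, Sigma = Sigma))
  miss_pat <- is.na(X)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    S1 <- numeric(d)
    S2 <- matrix(0, d, d)
    ll <- 0
    for (i in seq_len(n)) {
      m <- miss_pat[i, ]
      x <- X[i, ]
      if (!any(m)) {
        xe <- x
        V <- matrix(0, d, d)
      } else {
        o <- !m
        Soo <- Sigma[o, o, drop = FALSE]
        Smo <- Sigma[m, o, drop = FALSE]
        W <- Smo %*% solve(Soo)
        xe <- x
        xe[m] <- mu[m] + as.vector(W %*% (x[o] - mu[o]))
        V <- matrix(0, d, d)
        V[m, m] <- Sigma[m, m, drop = FALSE] - W %*% t(Smo)
      }
      S1 <- S1 + xe
      S2 <- S2 + tcrossprod(xe) + V
      o <- !m
      Soo <- Sigma[o, o, drop = FALSE]
      r <- x[o] - mu[o]
      ll <- ll - 0.5 * (determinant(Soo, logarithm = TRUE)$modulus +
                          sum(r * solve(Soo, r)) + sum(o) * log(2 * pi))
    }
    mu <- S1 / n
    Sigma <- S2 / n - tcrossprod(mu)
    Sigma <- Sigma + diag(ridge, d)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma)
}

.conditional_mean <- function(x, mu, Sigma) {
  m <- is.na(x)
  o <- !m
  W <- Sigma[m, o, drop = FALSE] %*% solve(Sigma[o, o, drop = FALSE])
  mu[m] + as.vector(W %*% (x[o] - mu[o]))
}

#' Impute missing phosphosite intensities
#'
#' Observed values are never altered. Sporadic missing values (MAR cells,
#' exactly one replicate missing in a condition) are filled by the
#' conditional mean under a multivariate-normal model over that condition's
#' replicates, fitted by maximum likelihood with an EM algorithm.
#' Left-censored missing values (MNAR cells, two or more replicates missing)
#' are drawn independently from a Gaussian centred at the 0.01-quantile of
#' the sample's observed distribution (MinProb). With `mode = "zero"` the
#' MNAR cells are instead set to 0, which gives enhanced weight to sites
#' absent in one condition but present in the other; MAR cells are still
#' EM-imputed.
#'
#' @param ps a [phospho_set()] at stage `normalized`.
#' @param mode `"impute"` (MinProb draws for MNAR) or `"zero"`.
#' @param seed integer seed; required for `mode = "impute"` so that runs are
#'   reproducible.
#' @param minprob_q probability of the per-sample quantile at which MinProb
#'   draws are centred (default 0.01).
#' @param minprob_sigma_scale width of the MinProb Gaussian as a fraction of
#'   the per-sample standard deviation of observed values (default 0.3).
#' @param labels optional precomputed [classify_missingness()] table.
#' @param em_max_iter,em_tol EM iteration cap and log-likelihood tolerance.
#' @return a `phospho_set` at stage `imputed`.
#' @export
impute_missing <- function(ps, mode = c("impute", "zero"), seed = NULL,
                           minprob_q = 0.01, minprob_sigma_scale = 0.3,
                           labels = NULL, em_max_iter = 100, em_tol = 1e-6) {
  stopifnot(inherits(ps, "phospho_set"))
  mode <- match.arg(mode)
  if (ps$stage != "normalized")
    stop("impute_missing expects a normalized-stage matrix")
  if (mode == "impute" && is.null(seed))
    stop("mode = 'impute' draws random values; a seed is required")
  if (!anyNA(ps$E)) return(.advance_stage(ps, "imputed"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(labels)) labels <- classify_missingness(ps)
  E <- ps$E

  conds <- unique(ps$design$condition)
  # MAR: EM-based conditional means per condition
  for (cc in conds) {
    cols <- ps$design$sample[ps$design$condition == cc]
    sub <- E[, cols, drop = FALSE]
    nmiss <- rowSums(is.na(sub))
    mar_rows <- which(nmiss == 1)
    if (!length(mar_rows)) next
    fit_rows <- which(nmiss <= 1)
    fit <- .em_mvn(sub[fit_rows, , drop = FALSE],
                   max_iter = em_max_iter, tol = em_tol)
    for (i in mar_rows) {
      x <- sub[i, ]
      x[is.na(x)] <- .conditional_mean(sub[i, ], fit$mu, fit$Sigma)
      sub[i, ] <- x
    }
    E[, cols] <- sub
  }

  # MNAR: per-sample MinProb draws (or zeros)
  mnar <- labels[labels$label == "MNAR", , drop = FALSE]
  if (nrow(mnar)) {
    mnar_cells <- matrix(FALSE, nrow(E), ncol(E), dimnames = dimnames(E))
    for (j in seq_len(nrow(mnar))) {
      cols <- ps$design$sample[ps$design$condition == mnar$condition[j]]
      r <- mnar$site[j]
      mnar_cells[r, cols] <- is.na(E[r, cols])
    }
    if (mode == "zero") {
      E[mnar_cells] <- 0
    } else {
      for (s in colnames(E)) {
        cells <- which(mnar_cells[, s])
        if (!length(cells)) next
        obs_vals <- ps$E[ps$obs[, s], s]
        obs_vals <- obs_vals[!is.na(obs_vals)]
        if (length(obs_vals) < 2)
          stop(sprintf("sample '%s' has fewer than 2 observed values; MinProb quantile undefined", s))
        centre <- quantile(obs_vals, probs = minprob_q, names = FALSE)
        width <- minprob_sigma_scale * sd(obs_vals)
        E[cells, s] <- rnorm(length(cells), mean = centre, sd = width)
      }
    }
  }

  # never touch observed cells
  E[ps$obs] <- ps$E[ps$obs]
  ps$E <- E
  .advance_stage(ps, "imputed")
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: [filter_sites()] then [log2_transform()],
#' [quantile_normalize()], [drop_underquantified()] and, optionally,
#' [impute_missing()].
#'
#' @param ps a raw-stage [phospho_set()].
#' @param loc_prob_min passed to [filter_sites()].
#' @param impute logical; `TRUE` uses MinProb draws for MNAR cells, `FALSE`
#'   uses the zero mode.
#' @param seed,minprob_q,minprob_sigma_scale passed to [impute_missing()].
#' @return an imputed-stage `phospho_set`.
#' @export
preprocess <- function(ps, loc_prob_min = 0.75, impute = TRUE, seed = NULL,
                       minprob_q = 0.01, minprob_sigma_scale = 0.3) {
  ps <- filter_sites(ps, loc_prob_min = loc_prob_min)
  ps <- log2_transform(ps)
  ps <- quantile_normalize(ps)
  ps <- drop_underquantified(ps)
  impute_missing(ps, mode = if (impute) "impute" else "zero", seed = seed,
                 minprob_q = minprob_q, minprob_sigma_scale = minprob_sigma_scale)
}
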