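make_raw <- function(E, sites = NULL, design = NULL) {
  if (is.null(colnames(E))) colnames(E) <- sprintf("s%d", seq_len(ncol(E)))
  if (is.null(design))
    design <- data.frame(sample = colnames(E),
                         condition = rep(c("A", "B"),
                                         length.out = ncol(E)),
                         stringsAsFactors = FALSE)
  phospho_set(E, design, sites = sites, stage = "raw", log2 = FALSE)
}

test_that("filtering keeps the localization boundary and drops flagged rows", {
  E <- matrix(100, 4, 2, dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
  sites <- data.frame(
    key = rownames(E),
    localization_prob = c(0.75, 0.749, 1, 1),
    is_reverse = c(FALSE, FALSE, TRUE, FALSE),
    is_contaminant = FALSE, stringsAsFactors = FALSE
  )
  ps <- filter_sites(make_raw(E, sites))
  expect_setequal(rownames(ps$E), c("a", "d"))
  expect_equal(ps$stage, "filtered")
  # identity case: nothing flagged, all probabilities 1
  sites2 <- sites; sites2$localization_prob <- 1; sites2$is_reverse <- FALSE
  expect_equal(rownames(filter_sites(make_raw(E, sites2))$E), rownames(E))
  # everything removed -> error
  sites3 <- sites; sites3$localization_prob <- 0
  expect_error(filter_sites(make_raw(E, sites3)), "empty matrix")
})

test_that("filtering is monotone: added rows never evict survivors", {
  E <- matrix(100, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sites <- data.frame(key = rownames(E),
                      localization_prob = c(0.8, 0.9, 0.2),
                      is_reverse = FALSE, is_contaminant = FALSE,
                      stringsAsFactors = FALSE)
  kept1 <- rownames(filter_sites(make_raw(E, sites))$E)
  E2 <- rbind(E, matrix(100, 2, 2, dimnames = list(c("d", "e"), colnames(E))))
  sites2 <- rbind(sites, data.frame(key = c("d", "e"),
                                    localization_prob = c(1, 0.1),
                                    is_reverse = FALSE, is_contaminant = FALSE))
  kept2 <- rownames(filter_sites(make_raw(E2, sites2))$E)
  expect_true(all(kept1 %in% kept2))
})

test_that("log2 transform maps values and inverts cleanly", {
  E <- matrix(c(1024, NA, 2, 8), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  ps <- log2_transform(make_raw(E))
  expect_equal(ps$E["a", "s1"], 10)
  expect_true(is.na(ps$E["b", "s1"]))
  expect_equal(2^ps$E, E, tolerance = 1e-9)
  Ebad <- E; Ebad[1] <- 0
  expect_error(log2_transform(make_raw(Ebad)), "<= 0")
  expect_error(log2_transform(ps), "already")
})

test_that("quantile normalization matches the sort/average/restore oracle", {
  E <- cbind(s1 = c(1, 3), s2 = c(2, 4))
  rownames(E) <- c("a", "b")
  ps <- quantile_normalize(toy_set(E))
  expect_equal(unname(ps$E), cbind(c(1.5, 3.5), c(1.5, 3.5)))
  # identical columns are a fixed point
  E2 <- cbind(s1 = c(5, 1, 3), s2 = c(5, 1, 3)); rownames(E2) <- letters[1:3]
  expect_equal(quantile_normalize(toy_set(E2))$E, toy_set(E2)$E)
})

test_that("quantile normalization equalizes column distributions and is idempotent", {
  set.seed(42)
  E <- matrix(rnorm(400, 20, c(1, 2, 3, 4)), 100, 4)
  rownames(E) <- sprintf("r%03d", 1:100)
  ps1 <- quantile_normalize(toy_set(E))
  sorted <- apply(ps1$E, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
  ps2 <- quantile_normalize(toy_set(ps1$E))
  expect_equal(ps2$E, ps1$E, tolerance = 1e-12)
  # single sample: unchanged with warning
  expect_warning(qn1 <- quantile_normalize(toy_set(E[, 1, drop = FALSE],
    design = data.frame(sample = "s1", condition = "A"))), "single-sample")
  expect_equal(unname(qn1$E), unname(E[, 1, drop = FALSE]))
})

test_that("missingness labels follow the 1-of-3 / 2-or-3-of-3 rule", {
  E <- rbind(
    full = c(12.1, 11.8, 12.0, 10, 10, 10),
    mar  = c(12.1, 11.8, NA,   10, 10, 10),
    mnar = c(12.1, NA,   NA,   10, 10, 10),
    gone = c(NA,   NA,   NA,   10, 10, 10)
  )
  colnames(E) <- sprintf("s%d", 1:6)
  des <- data.frame(sample = colnames(E), condition = rep(c("A", "B"), each = 3),
                    stringsAsFactors = FALSE)
  lab <- classify_missingness(toy_set(E, design = des))
  labA <- lab$label[lab$condition == "A"]
  names(labA) <- lab$site[lab$condition == "A"]
  expect_equal(labA[["full"]], "complete")
  expect_equal(labA[["mar"]], "MAR")
  expect_equal(labA[["mnar"]], "MNAR")
  expect_equal(labA[["gone"]], "MNAR")
  expect_true(all(lab$label[lab$condition == "B"] == "complete"))
  # labels partition all (site, condition) pairs
  expect_equal(nrow(lab), 8)
  expect_true(all(lab$label %in% c("complete", "MAR", "MNAR")))
})

test_that("under-quantified rows (<= 1 observed value) are dropped", {
  E <- rbind(one = c(12, NA, NA, NA), two = c(12, 13, NA, NA),
             all = c(1, 2, 3, 4))
  colnames(E) <- sprintf("s%d", 1:4)
  ps <- toy_set(E)
  out <- suppressMessages(drop_underquantified(ps))
  expect_setequal(rownames(out$E), c("two", "all"))
  full <- toy_set(matrix(1:8, 2, 4, dimnames = list(c("a", "b"), sprintf("s%d", 1:4))))
  expect_equal(rownames(drop_underquantified(full)$E), c("a", "b"))
})

sim_norm_set <- function(n, seed, miss_rows = integer(), miss_cond = "B") {
  set.seed(seed)
  E <- matrix(rnorm(n * 6, 20, 2), n, 6)
  rownames(E) <- sprintf("r%05d", seq_len(n))
  colnames(E) <- sprintf("s%d", 1:6)
  des <- data.frame(sample = colnames(E),
                    condition = rep(c("A", "B"), each = 3),
                    stringsAsFactors = FALSE)
  cols <- which(des$condition == miss_cond)
  E[miss_rows, cols] <- NA
  phospho_set(E, des, stage = "normalized", log2 = TRUE)
}

test_that("imputation is seeded, deterministic, and never touches observed cells", {
  ps <- sim_norm_set(500, seed = 3, miss_rows = 1:100)
  # also plant sporadic MAR cells
  ps$E[201:260, 2] <- NA
  ps$obs <- !is.na(ps$E)
  a <- impute_missing(ps, "impute", seed = 9)
  b <- impute_missing(ps, "impute", seed = 9)
  expect_identical(a$E, b$E)
  expect_false(anyNA(a$E))
  expect_equal(a$E[ps$obs], ps$E[ps$obs])
  d <- impute_missing(ps, "impute", seed = 10)
  expect_equal(d$E[ps$obs], ps$E[ps$obs])
  expect_false(identical(a$E, d$E))
  # complete matrix: identity
  full <- sim_norm_set(50, seed = 4)
  expect_equal(impute_missing(full, "impute", seed = 1)$E, full$E)
  # seed mandatory in draw mode
  expect_error(impute_missing(ps, "impute"), "seed")
})

test_that("MNAR draws centre on the sample 0.01-quantile; zero mode writes zeros", {
  n <- 12000
  ps <- sim_norm_set(n, seed = 5, miss_rows = 1:10000)
  imp <- impute_missing(ps, "impute", seed = 21)
  s4 <- "s4"  # first replicate of condition B
  obs_vals <- ps$E[ps$obs[, s4], s4]
  q <- quantile(obs_vals, 0.01, names = FALSE)
  sig <- 0.3 * sd(obs_vals)
  drawn <- imp$E[1:10000, s4]
  se <- sig / sqrt(length(drawn))
  expect_lt(abs(mean(drawn) - q), 3 * se)
  z <- impute_missing(ps, "zero", seed = 21)
  expect_true(all(z$E[1:10000, s4] == 0))
  expect_equal(z$E[ps$obs], ps$E[ps$obs])
})

test_that("EM fills sporadic gaps near the conditional expectation", {
  # strongly correlated replicates: conditional mean ~ mean of the others
  set.seed(8)
  n <- 400
  base <- rnorm(n, 20, 3)
  E <- cbind(s1 = base + rnorm(n, 0, 0.1), s2 = base + rnorm(n, 0, 0.1),
             s3 = base + rnorm(n, 0, 0.1))
  rownames(E) <- sprintf("r%03d", seq_len(n))
  des <- data.frame(sample = colnames(E), condition = "A",
                    stringsAsFactors = FALSE)
  ps <- phospho_set(E, des, stage = "normalized", log2 = TRUE)
  ps$E[1:50, 1] <- NA
  ps$obs <- !is.na(ps$E)
  imp <- impute_missing(ps, "zero")  # MAR cells EM-imputed, no draws needed
  pred <- rowMeans(E[1:50, 2:3])
  expect_lt(max(abs(imp$E[1:50, 1] - pred)), 0.5)
})
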