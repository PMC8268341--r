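test_that("source parsing filters species and skips malformed rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "GENE\tKIN_ORGANISM\tSUB_GENE\tSUB_ORGANISM\tSUB_MOD_RSD\tIN_VIVO_RXN\tIN_VITRO_RXN",
    "ABL1\thuman\tCRKL\thuman\tY207\tX\t",
    "SRC\thuman\tCTNNB1\thuman\tY86\t\tX",
    "CSNK2A1\thuman\tTOP2A\thuman\tS1377\tX\t",
    "ABL1\tmouse\tCRKL\tmouse\tY207\tX\t"
  ), f)
  a <- parse_source("PSP", f)
  expect_equal(nrow(a), 3)
  expect_true(all(a$substrate_key %in% c("CRKL_Y207", "CTNNB1_Y86", "TOP2A_S1377")))
  # in-vitro-only row honored on request
  expect_equal(nrow(parse_source("PSP", f, in_vivo_only = TRUE)), 2)
  # malformed residue skipped with a log line
  writeLines(c(
    "GENE\tKIN_ORGANISM\tSUB_GENE\tSUB_ORGANISM\tSUB_MOD_RSD\tIN_VIVO_RXN\tIN_VITRO_RXN",
    "ABL1\thuman\tCRKL\thuman\tB207\tX\t",
    "ABL1\thuman\tCRKL\thuman\tY207\tX\t"
  ), f)
  expect_message(a2 <- parse_source("PSP", f), "skipped 1 malformed")
  expect_equal(nrow(a2), 1)
  expect_error(parse_source("NOPE", f), "unknown source")
})

test_that("all five source dialects round-trip through their fixtures", {
  assoc <- toy_assoc(c("ABL1", "ABL1", "SRC", "SRC"),
                     c("CRKL", "CBL", "CTNNB1", "EGFR"),
                     c("Y", "Y", "Y", "Y"), c(207, 700, 86, 845))
  for (src in c("PSP", "HPRD", "RegPhos", "Signor", "ELM")) {
    f <- tempfile(fileext = ".tsv")
    write_source_fixture(assoc, src, f)
    got <- parse_source(src, f)
    expect_equal(got$kinase, assoc$kinase, label = src)
    expect_equal(got$substrate_key, assoc$substrate_key, label = src)
    expect_true(all(got$evidence == "experimental"), label = src)
    expect_true(all(got$sources == src), label = src)
  }
})

test_that("kinase names unify idempotently via the synonym map", {
  a <- toy_assoc(c("CK2A1", "CSNK2A1", "WEIRDK"), c("G1", "G2", "G3"),
                 "S", c(1, 2, 3))
  syn <- c(CK2A1 = "CSNK2A1")
  u1 <- suppressMessages(unify_kinase_names(a, syn))
  expect_equal(u1$kinase, c("CSNK2A1", "CSNK2A1", "WEIRDK"))
  u2 <- suppressMessages(unify_kinase_names(u1, syn))
  expect_equal(u2, u1)
  shipped <- read_kinase_synonyms()
  expect_equal(unname(shipped[["CK2A1"]]), "CSNK2A1")
})

test_that("meta-database merges duplicates and drops single-entry kinases", {
  a1 <- toy_assoc(c("KIN1", "KIN1", "KIN2"), c("A", "B", "C"), "S",
                  c(10, 20, 30), sources = "PSP")
  a2 <- toy_assoc("KIN1", "A", "S", 10, sources = "Signor")
  db <- suppressMessages(build_metadb(list(a1, a2)))
  expect_equal(sort(unique(db$assoc$kinase)), "KIN1")  # KIN2 single entry
  dup <- db$assoc[db$assoc$substrate_key == "A_S10", ]
  expect_equal(dup$sources, "PSP;Signor")
  expect_equal(nrow(db$assoc), 2)
  # 3 kinases x 2 substrates, all distinct -> 6 entries, 3 kinases
  a3 <- toy_assoc(rep(c("K1", "K2", "K3"), each = 2),
                  sprintf("G%d", 1:6), "S", 1:6)
  db3 <- suppressMessages(build_metadb(a3))
  expect_equal(nrow(db3$assoc), 6)
  expect_equal(length(unique(db3$assoc$kinase)), 3)
  expect_error(suppressMessages(build_metadb(a2)), "empty")
})

test_that("NetworKIN predictions honor score and universe restrictions", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tposition\tresidue\tkinase\tnetworkin_score",
    "CRKL\t207\tY\tABL1\t5.1",
    "CBL\t700\tY\tABL1\t1.2",
    "EGFR\t845\tY\tSRC\t0.5",
    "CTNNB1\t86\tY\tSRC\t3.0",
    "NOPE\t1\tS\tSRC\t9.9"
  ), f)
  uni <- c("CRKL_Y207_m1", "CBL_Y700_m1", "CTNNB1_Y86_m2", "EGFR_Y845_m1")
  got <- load_networkin(f, score_min = 2, universe = uni)
  expect_setequal(got$substrate_key, c("CRKL_Y207", "CTNNB1_Y86"))
  expect_true(all(got$evidence == "predicted"))
  expect_equal(nrow(load_networkin(f, score_min = 2, universe = character())), 0)
  writeLines(c("gene\tposition\tresidue\tkinase", "CRKL\t207\tY\tABL1"), f)
  expect_error(load_networkin(f, universe = uni), "score column")
})

test_that("merging predictions keeps experimental precedence and is monotone", {
  exp_a <- toy_assoc(c("K1", "K1", "K2", "K2"), c("A", "B", "C", "D"),
                     "S", c(1, 2, 3, 4))
  db <- suppressMessages(build_metadb(exp_a))
  pred <- toy_assoc(c("K1", "K3", "K3"), c("A", "E", "F"), "S", c(1, 5, 6),
                    evidence = "predicted", sources = "NetworKIN",
                    score = c(3, 4, 5))
  m <- merge_db(db, pred)
  conflict <- m$assoc[m$assoc$kinase == "K1" & m$assoc$substrate_key == "A_S1", ]
  expect_equal(conflict$evidence, "experimental")
  expect_equal(conflict$sources, "NetworKIN;PSP")
  k3 <- m$assoc[m$assoc$kinase == "K3", ]
  expect_equal(nrow(k3), 2)
  expect_true(all(k3$evidence == "predicted"))
  # monotone: every experimental association survives
  expect_true(all(paste(db$assoc$kinase, db$assoc$substrate_key) %in%
                    paste(m$assoc$kinase, m$assoc$substrate_key)))
  # empty prediction list is the identity
  expect_equal(merge_db(db, pred[0, ]), db)
})

test_that("coverage is the fraction of measured sites with a kinase", {
  E <- matrix(10, 20, 2,
              dimnames = list(sprintf("G%02d_S%d_m1", 1:20, 1:20),
                              c("s1", "s2")))
  ps <- toy_set(E)
  db1 <- structure(list(assoc = toy_assoc(c("K1", "K1"), c("G01", "ZZZ"),
                                          "S", c(1, 99)), synonyms = NULL),
                   class = "ksdb")
  expect_equal(coverage_report(db1, ps)$coverage, 0.05)
  db0 <- structure(list(assoc = toy_assoc(c("K1", "K1"), c("Q1", "Q2"),
                                          "S", c(1, 2)), synonyms = NULL),
                   class = "ksdb")
  expect_equal(coverage_report(db0, ps)$coverage, 0)
  # generator-controlled 25% coverage
  db25 <- structure(list(assoc = toy_assoc(rep("K1", 5),
                                           sprintf("G%02d", 1:5), "S", 1:5),
                         synonyms = NULL), class = "ksdb")
  expect_equal(coverage_report(db25, ps)$coverage, 0.25)
  # with predictions coverage never decreases
  expect_gte(coverage_report(merge_db(db1, toy_assoc(
    c("K9", "K9"), c("G02", "G03"), "S", c(2, 3),
    evidence = "predicted", sources = "NetworKIN", score = 3)), ps)$coverage,
    coverage_report(db1, ps)$coverage)
})

test_that("database bundle and GMT serialization round-trip", {
  a <- toy_assoc(rep(c("K1", "K2"), each = 2), sprintf("G%d", 1:4), "S", 1:4)
  db <- suppressMessages(build_metadb(a, synonyms = c(RAW1 = "K1")))
  prefix <- tempfile()
  write_ksdb(db, prefix)
  back <- read_ksdb(prefix)
  expect_equal(back$assoc, db$assoc)
  expect_equal(back$synonyms, db$synonyms)
  g <- tempfile(fileext = ".gmt")
  export_gmt(db, g)
  lines <- readLines(g)
  expect_equal(length(lines), 2)
  expect_match(lines[1], "^K1\t")
})
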