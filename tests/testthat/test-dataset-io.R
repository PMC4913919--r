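test_that("expression TSV round-trips values and annotations exactly", {
  set.seed(11)
  vals <- matrix(round(rnorm(80, 8, 2), 6), 10, 8)
  es <- make_es(vals, list(a_normal = 4L, a_cancer = 4L),
                experiment = rep(c("E1", "E2"), 4L))
  mp <- tempfile(fileext = ".tsv"); ap <- tempfile(fileext = ".tsv")
  writeExpressionTSV(es, mp, ap)
  back <- readExpressionTSV(mp, ap)
  expect_equal(exprValues(back), exprValues(es))
  expect_identical(biologicalGroup(back), biologicalGroup(es))
  expect_identical(diseaseStatus(back), diseaseStatus(es))
  expect_identical(experimentId(back), experimentId(es))
})

test_that("malformed expression input is rejected, not coerced", {
  dir <- tempfile(); dir.create(dir)
  mp <- file.path(dir, "m.tsv"); ap <- file.path(dir, "a.tsv")
  writeLines(c("probeset_id\ts1\ts9", "p1\t1.5\t2.5", "p2\t0.1\t0.2"), mp)
  writeLines(c("sample_id\tbiological_group\ttissue\texperiment\tdisease_status",
               "s1\tg\tliver\tE1\tnormal"), ap)
  expect_error(readExpressionTSV(mp, ap), "s9")

  writeLines(c("probeset_id\ts1", "p1\t1.5", "p2\tNOTANUMBER"), mp)
  writeLines(c("sample_id\tbiological_group\ttissue\texperiment\tdisease_status",
               "s1\tg\tliver\tE1\tnormal"), ap)
  expect_error(readExpressionTSV(mp, ap), "NOTANUMBER")

  writeLines(c("probeset_id\ts1", "p1\t1.5", "p1\t2.0"), mp)
  expect_error(readExpressionTSV(mp, ap), "duplicate probeset")
})

test_that("minimum-group-size filter keeps exactly the qualifying groups", {
  set.seed(2)
  sizes <- list(g1_other = 25L, g2_other = 19L, g3_other = 20L)
  es <- make_es(matrix(rnorm(3 * 64), 3, 64), sizes)
  kept <- filterMinGroupSize(es, 20L)
  expect_equal(ncol(kept), 45L)
  expect_setequal(unique(biologicalGroup(kept)), c("g1_other", "g3_other"))
  expect_identical(exprValues(filterMinGroupSize(es, 1L)), exprValues(es))
  expect_error(filterMinGroupSize(es, 100L), "no biological group")

  # brute-force recount oracle on random group sizes, plus idempotence
  set.seed(3)
  gs <- sample(5:40, 12L, replace = TRUE)
  sizes <- as.list(gs)
  names(sizes) <- sprintf("grp%02d_other", seq_along(gs))
  es2 <- make_es(matrix(rnorm(2 * sum(gs)), 2, sum(gs)), sizes)
  out <- filterMinGroupSize(es2, 20L)
  keep_expected <- names(sizes)[gs >= 20L]
  expect_setequal(unique(biologicalGroup(out)), keep_expected)
  expect_equal(ncol(out), sum(gs[gs >= 20L]))
  expect_identical(exprValues(filterMinGroupSize(out, 20L)), exprValues(out))
})

test_that("paired-tissue selection needs both statuses above threshold", {
  set.seed(4)
  groups <- list(A_normal = 22L, A_cancer = 21L, B_normal = 30L, B_cancer = 5L)
  es <- make_es(matrix(rnorm(2 * 78), 2, 78), groups)
  out <- selectPairedTissues(es, 20L)
  expect_equal(ncol(out), 43L)
  expect_setequal(unique(tissueType(out)), "A")
  expect_error(selectPairedTissues(es, 50L), "no tissue")

  # disease_status 'other' never survives; output tissues sorted
  groups2 <- list(C_normal = 25L, C_cancer = 25L, C_other = 10L,
                  B_normal = 25L, B_cancer = 25L)
  es2 <- make_es(matrix(rnorm(2 * 110), 2, 110), groups2)
  out2 <- selectPairedTissues(es2, 20L)
  expect_false("other" %in% diseaseStatus(out2))
  expect_equal(ncol(out2), 100L)
  expect_identical(unique(tissueType(out2)), c("B", "C"))
  # idempotence
  expect_identical(exprValues(selectPairedTissues(out2, 20L)),
                   exprValues(out2))

  # randomized double-count oracle (first tissue forced to qualify so the
  # non-empty contract holds)
  set.seed(5)
  tn <- sprintf("t%02d", 1:6)
  nc <- c(25L, sample(5:30, 5L, replace = TRUE))
  nn <- c(25L, sample(5:30, 5L, replace = TRUE))
  sizes <- as.list(as.vector(rbind(nc, nn)))
  names(sizes) <- as.vector(rbind(paste0(tn, "_cancer"), paste0(tn, "_normal")))
  es3 <- make_es(matrix(rnorm(2 * sum(unlist(sizes))), 2, sum(unlist(sizes))),
                 sizes)
  out3 <- selectPairedTissues(es3, 20L)
  expected <- tn[nc >= 20L & nn >= 20L]
  expect_setequal(unique(tissueType(out3)), expected)
  expect_equal(ncol(out3), sum((nc + nn)[nc >= 20L & nn >= 20L]))
})

test_that("most-variable selection matches a sort-by-variance oracle", {
  vals <- rbind(rep(5, 4), c(0, 4, 0, 4), c(1, 2, 1, 2))
  es <- make_es(vals, list(g_other = 4L))
  out <- selectMostVariable(es, 2L)
  expect_identical(probesetIds(out), c("p002", "p003"))
  expect_identical(exprValues(selectMostVariable(es, 3L)), exprValues(es))
  expect_error(selectMostVariable(es, 4L), "exceeds")

  set.seed(6)
  es2 <- make_es(matrix(rnorm(50 * 20, sd = rep(runif(50, 0.1, 3), 20)),
                        50, 20), list(g_other = 20L))
  out2 <- selectMostVariable(es2, 10L)
  v <- apply(exprValues(es2), 1L, var)
  oracle <- sort(names(sort(v, decreasing = TRUE)[1:10]))
  expect_setequal(probesetIds(out2), oracle)
  # nesting: reducing twice equals reducing once (no ties here)
  expect_identical(
    exprValues(selectMostVariable(selectMostVariable(es2, 20L), 5L)),
    exprValues(selectMostVariable(es2, 5L)))
})

test_that("GMT files parse, deduplicate and round-trip", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("L1\tAtlas\tBRCA1\tBRCA2",
               "L2\tsecond\tTP53\tTP53\tEGFR",
               "L3\tthird\tMYC"), p)
  sets <- readGeneSetsGMT(p)
  expect_named(sets, c("L1", "L2", "L3"))
  expect_length(sets$L1, 2L)
  expect_identical(as.character(sets$L2), c("TP53", "EGFR"))  # deduplicated

  p2 <- tempfile(fileext = ".gmt")
  writeGeneSetsGMT(sets, p2)
  back <- readGeneSetsGMT(p2)
  expect_identical(lapply(back, as.character), lapply(sets, as.character))

  writeLines(c("ok\tdesc\tG1", "bad\tonlydesc"), p)
  expect_error(readGeneSetsGMT(p), "line 2")
})

test_that("gene mapping reader handles multi-matchings and empty symbols", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("probeset_id\tgene", "a\tG1", "b\tG1", "c\t", "d\tG2", "d\tG3"), p)
  map <- readGeneMapping(p)
  expect_identical(map$a, "G1")
  expect_length(map$c, 0L)
  expect_setequal(map$d, c("G2", "G3"))
})
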