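## small fixture: one gene, three isoforms, exon e1 in iso1+iso2 only
isoFixtureMap <- function() {
  FeatureMap(data.frame(
    gene_id = "g1",
    feature_kind = c("cpg", "exon", "exon", "isoform", "isoform", "isoform",
                     "exon", "exon", "exon", "exon"),
    feature_id = c("cg1", "chr1:10-20:+", "chr1:30-40:+", "iso1", "iso2",
                   "iso3", "chr1:10-20:+", "chr1:30-40:+", "chr1:10-20:+",
                   "chr1:30-40:+"),
    parent_isoform_id = c("", "", "", "", "", "", "iso1", "iso1", "iso2",
                          "iso3"),
    stringsAsFactors = FALSE))
}

isoRecords <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  d$target_kind <- "isoform"
  d$n <- 20L
  d$p <- 1e-5
  d$p_adj <- 1e-4
  d
}

test_that("candidateIsoforms filters by membership, cancer and significance", {
  map <- isoFixtureMap()
  recs <- isoRecords(cancer = c("a", "a", "a", "b"),
                     gene = "g1", cpg = "cg1",
                     target = c("iso1", "iso2", "iso3", "iso1"),
                     r = c(0.4, -0.3, 0.9, 0.8),
                     significant = c(TRUE, TRUE, TRUE, TRUE))
  cand <- candidateIsoforms("chr1:10-20:+", "cg1", "a", recs, map)
  expect_identical(sort(cand$isoform), c("iso1", "iso2"))  # iso3 lacks the exon
  ## significance and same-cancer requirements
  recs$significant[1] <- FALSE
  cand <- candidateIsoforms("chr1:10-20:+", "cg1", "a", recs, map)
  expect_identical(cand$isoform, "iso2")
  cand <- candidateIsoforms("chr1:10-20:+", "cg1", "zzz", recs, map)
  expect_identical(nrow(cand), 0L)
})

test_that("selectMatched picks the strongest direction-consistent isoform", {
  cands <- data.frame(isoform = c("i1", "i2"), r = c(0.4, -0.3))
  expect_identical(selectMatched(0.6, cands)$isoform, "i1")
  expect_equal(selectMatched(0.6, cands)$r, 0.4)

  cands <- data.frame(isoform = c("i1", "i2", "i3"), r = c(-0.5, -0.2, 0.7))
  expect_equal(selectMatched(-0.6, cands)$r, -0.5)

  expect_null(selectMatched(0.6, data.frame(isoform = "i1", r = -0.3)))
  ## |r| ties resolve to the lexicographically smallest isoform id
  tie <- data.frame(isoform = c("iB", "iA"), r = c(0.5, 0.5))
  expect_identical(selectMatched(0.9, tie)$isoform, "iA")
  expect_error(selectMatched(0, cands), "non-zero")
})

test_that("diffDistribution counts strict exceedances and fixed-width bins", {
  d <- diffDistribution(c(0.2, 0.05, -0.2))
  expect_equal(d$fracPositive, 2 / 3)
  expect_equal(d$fracAbove0.1, 1 / 3)
  expect_equal(d$fracBelowMinus0.1, 1 / 3)
  expect_identical(sum(d$histogram$count), 3L)
  expect_equal(d$histogram$binEnd - d$histogram$binStart,
               rep(0.05, nrow(d$histogram)))

  z <- diffDistribution(rep(0, 5))
  expect_equal(c(z$fracPositive, z$fracAbove0.1, z$fracBelowMinus0.1),
               c(0, 0, 0))
  expect_error(diffDistribution(numeric()), "no differences")
  ## fraction ordering is structural
  set.seed(3)
  d <- diffDistribution(runif(200, -1, 1))
  expect_lte(d$fracAbove0.1, d$fracPositive)
})

test_that("compareExonIsoform selections satisfy the membership and sign filters", {
  sim <- simulateDataset(tinyConfig(nGenes = 25L, samplesPerCancer = 60L,
                                    isoformsPerGene = 3L, seed = 29L))
  strat <- stratifyExpression(exprMatrix(sim$dataset, "gene"))
  ex <- runScreen(sim$dataset, "exon", stratification = strat)
  iso <- runScreen(sim$dataset, "isoform", stratification = strat)
  map <- featureMap(sim$dataset)
  cmp <- compareExonIsoform(ex$records, iso$records, map)
  expect_gt(nrow(cmp$records), 10)
  rec <- cmp$records
  ## post-hoc re-check of every chosen isoform
  members <- isoformMembers(map)
  expect_true(all(mapply(function(e, i) e %in% members[[i]],
                         rec$exon, rec$isoform)))
  expect_true(all(sign(rec$r_isoform) == sign(rec$r_exon)))
  expect_equal(rec$diff, abs(rec$r_exon) - abs(rec$r_isoform))
  ## and each chosen isoform is the best same-sign significant candidate
  for (i in seq_len(min(nrow(rec), 20L))) {
    cand <- candidateIsoforms(rec$exon[i], rec$cpg[i], rec$cancer[i],
                              iso$records, map)
    best <- selectMatched(rec$r_exon[i], cand)
    expect_identical(best$isoform, rec$isoform[i])
  }
  expect_identical(cmp$summary$n, nrow(rec))
})

test_that("identity isoforms (one exon, no noise) give differences near zero", {
  sim <- simulateDataset(tinyConfig(nGenes = 20L, nCancers = 1L,
                                    samplesPerCancer = 100L,
                                    exonsPerGene = 3L, seed = 37L))
  ds <- sim$dataset
  ## replace isoforms by exact single-exon copies of each exon
  exon <- exprMatrix(ds, "exon")
  isoIdsNew <- paste0("iso_", seq_len(nrow(exon)))
  isoExpr <- exon
  rownames(isoExpr) <- isoIdsNew
  base <- featureMap(ds)@map
  base <- base[!(base$feature_kind == "isoform" |
                   nzchar(base$parent_isoform_id)), ]
  exonRows <- base[base$feature_kind == "exon", ]
  idx <- match(exonRows$feature_id, rownames(exon))
  mapNew <- FeatureMap(rbind(
    base,
    data.frame(gene_id = exonRows$gene_id, feature_kind = "isoform",
               feature_id = isoIdsNew[idx], parent_isoform_id = "",
               stringsAsFactors = FALSE),
    data.frame(gene_id = exonRows$gene_id, feature_kind = "exon",
               feature_id = exonRows$feature_id,
               parent_isoform_id = isoIdsNew[idx],
               stringsAsFactors = FALSE)))
  ds2 <- MethSpliceDataSet(methBeta(ds), exprMatrix(ds, "gene"), exon,
                           isoExpr, sampleTable(ds), clinicalTable(ds),
                           mapNew)
  strat <- stratifyExpression(exprMatrix(ds2, "gene"))
  ex <- runScreen(ds2, "exon", stratification = strat)
  iso <- runScreen(ds2, "isoform", stratification = strat)
  cmp <- compareExonIsoform(ex$records, iso$records, featureMap(ds2))
  expect_gt(nrow(cmp$records), 10)
  expect_lt(abs(median(cmp$records$diff)), 0.02)
})
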