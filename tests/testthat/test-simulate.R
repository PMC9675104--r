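test_that("the generator is deterministic and respects value domains", {
  cfg <- tinyConfig(seed = 42L)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(methBeta(a$dataset), methBeta(b$dataset))
  expect_identical(exprMatrix(a$dataset, "exon"), exprMatrix(b$dataset, "exon"))
  expect_identical(clinicalTable(a$dataset), clinicalTable(b$dataset))
  expect_identical(a$truth@plantedPairs, b$truth@plantedPairs)

  beta <- methBeta(a$dataset)
  expect_true(all(beta >= 0 & beta <= 1, na.rm = TRUE))
  for (kind in c("gene", "exon", "isoform"))
    expect_true(all(exprMatrix(a$dataset, kind) >= 0))
  expect_true(all(clinicalTable(a$dataset)$time >= 0))
  expect_true(all(clinicalTable(a$dataset)$event %in% 0:1))
  ## planted structure is registered in the declared feature map
  pp <- a$truth@plantedPairs
  map <- featureMap(a$dataset)
  expect_true(all(mapply(function(g, c) c %in% cpgIds(map, g), pp$gene, pp$cpg)))
  expect_true(all(mapply(function(g, e) e %in% exonIds(map, g), pp$gene, pp$exon)))
  ## default driver mode draws drivers among planted CpGs
  expect_true(all(a$truth@driverCpgs$cpg %in% pp$cpg))
  expect_warning(simConfig(samplesPerCancer = 5L), "minimum-cohort")
})

test_that("without planted effects the CpG-exon correlations are null", {
  sim <- simulateDataset(tinyConfig(nGenes = 100L, nCancers = 1L,
                                    samplesPerCancer = 80L, cpgsPerGene = 4L,
                                    exonsPerGene = 5L, fracPlanted = 0,
                                    fracDriverCpgs = 0, seed = 8L))
  scr <- runScreen(sim$dataset, "exon")
  expect_gte(nrow(scr$records), 2000L)
  ## raw p-values roughly uniform: about 5% below 0.05
  expect_lt(abs(mean(scr$records$p < 0.05) - 0.05), 0.02)
  expect_equal(nrow(sim$truth@plantedPairs), 0L)
})

test_that("planted effects reach the configured correlation strength", {
  sim <- simulateDataset(tinyConfig(nGenes = 50L, nCancers = 1L,
                                    samplesPerCancer = 200L,
                                    fracExpressed = 0.5, effectR = 0.8,
                                    cpgsPerGene = 4L, exonsPerGene = 4L,
                                    fracPlanted = 0.15, seed = 9L))
  ## >= 100 planted pairs at cohort ~100 samples
  pp <- sim$truth@plantedPairs
  expect_gte(nrow(pp), 100L)
  scr <- runScreen(sim$dataset, "exon")
  m <- merge(pp, scr$records, by.x = c("cancer", "cpg", "exon"),
             by.y = c("cancer", "cpg", "target"))
  expect_gte(nrow(m), 0.95 * nrow(pp))
  expect_lt(abs(mean(abs(m$r)) - 0.8), 0.1)
  expect_true(all(sign(m$r) == m$sign))
})

test_that("isoform expression dilutes planted CpG correlations", {
  sim <- simulateDataset(tinyConfig(nGenes = 40L, nCancers = 1L,
                                    samplesPerCancer = 200L,
                                    fracExpressed = 0.6, effectR = 0.8,
                                    isoformsPerGene = 3L,
                                    isoformNoiseSd = 0.5, seed = 13L))
  strat <- stratifyExpression(exprMatrix(sim$dataset, "gene"))
  ex <- runScreen(sim$dataset, "exon", stratification = strat)$records
  iso <- runScreen(sim$dataset, "isoform", stratification = strat)$records
  pp <- sim$truth@plantedPairs
  map <- featureMap(sim$dataset)
  members <- isoformMembers(map)
  ## for each planted (cpg, exon): compare |r| with each containing isoform
  exKey <- paste(ex$cancer, ex$cpg, ex$target)
  isoKey <- paste(iso$cancer, iso$cpg, iso$target)
  diffs <- unlist(lapply(seq_len(nrow(pp)), function(i) {
    holders <- names(members)[vapply(members, function(m)
      pp$exon[i] %in% m, logical(1))]
    holders <- intersect(holders, isoformIds(map, pp$gene[i]))
    rex <- ex$r[match(paste(pp$cancer[i], pp$cpg[i], pp$exon[i]), exKey)]
    riso <- iso$r[match(paste(pp$cancer[i], pp$cpg[i], holders), isoKey)]
    abs(rex) - abs(riso)
  }))
  diffs <- diffs[!is.na(diffs)]
  expect_gte(length(diffs), 50L)
  expect_gt(mean(diffs > 0), 0.8)    # dilution: exon correlation stronger
})

test_that("sim truth round-trips through its TSV format", {
  sim <- simulateDataset(tinyConfig(nGenes = 5L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTruth(sim$truth, path)
  back <- readTruth(path)
  expect_identical(back@plantedPairs, sim$truth@plantedPairs)
  expect_identical(back@driverCpgs, sim$truth@driverCpgs)
  expect_identical(back@modeLabels, sim$truth@modeLabels)
  expect_identical(back@genes, sim$truth@genes)

  empty <- new("SimTruth",
               plantedPairs = sim$truth@plantedPairs[0, ],
               driverCpgs = sim$truth@driverCpgs[0, ],
               modeLabels = matrix(FALSE, 0, 0), genes = "g0001")
  writeTruth(empty, path)
  back <- readTruth(path)
  expect_identical(nrow(back@plantedPairs), 0L)
  expect_identical(back@genes, "g0001")

  ## referential integrity: truth may not cite genes outside its universe
  bad <- sim$truth@plantedPairs
  bad$gene[1] <- "not_a_gene"
  expect_error(new("SimTruth", plantedPairs = bad,
                   driverCpgs = sim$truth@driverCpgs,
                   modeLabels = sim$truth@modeLabels,
                   genes = sim$truth@genes), "not_a_gene")
})

test_that("datasets round-trip through the on-disk directory layout", {
  sim <- simulateDataset(tinyConfig(nGenes = 4L, samplesPerCancer = 15L,
                                    seed = 21L))
  dir <- withr::local_tempdir()
  writeDataset(sim$dataset, dir)
  back <- readDataset(dir)
  expect_equal(methBeta(back), methBeta(sim$dataset))
  expect_equal(exprMatrix(back, "isoform"), exprMatrix(sim$dataset, "isoform"))
  expect_identical(sampleTable(back), sampleTable(sim$dataset))
  expect_equal(clinicalTable(back), clinicalTable(sim$dataset))
  expect_identical(featureMap(back)@map, featureMap(sim$dataset)@map)
})
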