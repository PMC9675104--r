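test_that("binarizeMethylation splits bimodal betas and skips constant ones", {
  lab <- binarizeMethylation(rep(c(0.1, 0.9), each = 5))
  expect_identical(sum(lab), 5L)
  expect_equal(attr(lab, "fit")@threshold, 0.5)
  expect_null(binarizeMethylation(rep(0.4, 12)))

  set.seed(33)
  truth <- rbinom(50, 1, 0.5) == 1
  beta <- ifelse(truth, rnorm(50, 0.8, 0.05), rnorm(50, 0.2, 0.05))
  beta <- pmin(pmax(beta, 0), 1)
  lab <- binarizeMethylation(beta)
  expect_gte(mean(lab == truth), 0.95)
})

test_that("logrankTest matches the worked example and is symmetric", {
  ## identical groups: exchangeable, chi2 = 0
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  same <- logrankTest(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 4))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  ## A dies at t=1,2; B dies at t=3,4 -> chi2 = 2.882 by direct summation
  lr <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  oracle <- logrankOracle(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(lr$chi2, oracle$chi2, tolerance = 1e-8)
  expect_equal(lr$chi2, 2.88, tolerance = 0.01)

  ## swapping group labels leaves the statistic unchanged
  sw <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(sw$chi2, lr$chi2)

  ## no events at all: flagged, chi2 0 / p 1
  ne <- logrankTest(c(1, 2, 3), c(0, 0, 0), c("a", "a", "b"))
  expect_true(ne$noEvents)
  expect_equal(c(ne$chi2, ne$p), c(0, 1))
})

test_that("logrank statistic equals per-event-time summation on random data", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    time <- sample(1:8, n, replace = TRUE)          # ties on purpose
    event <- rbinom(n, 1, 0.7)
    group <- c("a", "b", sample(c("a", "b"), n - 2, replace = TRUE))
    if (sum(event) == 0) next
    lr <- logrankTest(time, event, group)
    expect_equal(lr$chi2, logrankOracle(time, event, group)$chi2,
                 tolerance = 1e-8)
  }
})

test_that("survivalScan honours the cohort floor and adjusts per cancer", {
  sim <- simulateDataset(tinyConfig(nGenes = 8L, samplesPerCancer = 30L,
                                    fracDriverCpgs = 0.5, seed = 25L))
  strat <- stratifyExpression(exprMatrix(sim$dataset, "gene"))
  sv <- survivalScan(sim$dataset, strat)
  expect_true(all(sv$records$n_methylated + sv$records$n_unmethylated >= 10))
  expect_true(all(sv$records$fdr >= sv$records$p))
  expect_true(all(sv$records$chi2 >= 0))

  ## cohorts below the floor produce skips, never records
  tiny <- survivalScan(sim$dataset, strat, minCohort = 500L)
  expect_identical(nrow(tiny$records), 0L)
  expect_true(all(tiny$skips$reason %in%
                    c("cohort below minimum", "degenerate step fit")))

  ## samples without clinical rows are dropped and logged
  ds <- sim$dataset
  clip <- clinicalTable(ds)[-(1:5), ]
  ds2 <- MethSpliceDataSet(methBeta(ds), exprMatrix(ds, "gene"),
                           exprMatrix(ds, "exon"), exprMatrix(ds, "isoform"),
                           sampleTable(ds), clip, featureMap(ds))
  sv2 <- survivalScan(ds2, strat)
  expect_true("samples without clinical data" %in% sv2$skips$reason)
})

test_that("isolated driver CpGs at hazard ratio 3 are detected by the scan", {
  ## one or two drivers per replicate and cohorts of ~100: with few
  ## simultaneous drivers the marginal effect stays near the nominal
  ## hazard ratio and the scan should recover >= 80% of them
  found <- 0L; total <- 0L
  for (s in 1:8) {
    sim <- simulateDataset(simConfig(
      nGenes = 10L, nCancers = 1L, samplesPerCancer = 170L,
      cpgsPerGene = 5L, exonsPerGene = 3L, isoformsPerGene = 1L,
      fracExpressed = 0.6, effectR = 0.7, fracPlanted = 0.2,
      fracDriverCpgs = 0.05, hazardRatio = 3, censorRate = 0.02,
      seed = 500L + s))
    drv <- sim$truth@driverCpgs
    if (!nrow(drv)) next
    sv <- survivalScan(sim$dataset)$records
    hits <- sv[sv$significant & sv$cpg %in% drv$cpg, ]
    total <- total + nrow(drv)
    found <- found + length(unique(hits$cpg))
  }
  expect_gte(total, 3L)
  expect_gte(found / total, 0.8)
})

test_that("enrichment arithmetic handles rates, folds and degenerate cases", {
  e <- enrichmentFromCounts(31045, 485577, 33, 65949, 643)
  expect_equal(e$ratePct, 100 * 31045 / (485577 * 33))
  expect_equal(round(e$ratePct, 2), 0.19)
  expect_equal(e$expected, 65949 * 31045 / (485577 * 33))
  expect_equal(e$expected, 127.8, tolerance = 0.1)
  expect_equal(foldEnrichment(643, 124), 5.185, tolerance = 1e-3)
  expect_warning(expect_identical(foldEnrichment(3, 0), Inf), "infinite")
  expect_true(is.nan(foldEnrichment(0, 0)))

  ov <- overlapEnrichment(c("a|cg1", "a|cg2", "b|cg1"),
                          c("a|cg2", "b|cg9"), nCpgTotal = 100, nCancers = 2)
  expect_identical(ov$observed, 1L)
  expect_equal(ov$rate, 2 / 200)
  expect_equal(ov$expected, 3 * 2 / 200)
  expect_identical(ov$observedUniqueCpgs, 1L)
  expect_lte(ov$observed, min(ov$nExonCorrelated, ov$nSigSurvival))
})

test_that("CpG-panel stratification recovers separated methylation blocks", {
  set.seed(41)
  n <- 30
  blockA <- matrix(runif(4 * n, 0.05, 0.25), 4, n)
  blockB <- matrix(runif(4 * n, 0.75, 0.95), 4, n)
  beta <- cbind(blockA, blockB)
  colnames(beta) <- sprintf("s%02d", 1:(2 * n))
  rownames(beta) <- sprintf("cg%d", 1:4)
  clinical <- data.frame(sample_id = colnames(beta),
                         time = c(rexp(n, 0.4), rexp(n, 0.1)),
                         event = 1L, stringsAsFactors = FALSE)
  out <- stratifyByCpgPanel(beta, clinical)
  ## the partition covers every patient, disjointly, and recovers the blocks
  expect_identical(sort(names(out$groups)), sort(colnames(beta)))
  expect_identical(length(unique(out$groups)), 2L)
  expect_identical(length(unique(out$groups[1:n])), 1L)
  expect_identical(length(unique(out$groups[(n + 1):(2 * n)])), 1L)
  expect_lt(out$p, 0.05)
  expect_true(all(c("group", "time", "surv") %in% names(out$km)))
  ## group labels are arbitrary: swapping them leaves the test unchanged
  lr <- logrankTest(clinical$time, clinical$event, out$groups)
  sw <- logrankTest(clinical$time, clinical$event, 3 - out$groups)
  expect_equal(lr$chi2, sw$chi2)

  flat <- matrix(0.5, 3, 12, dimnames = list(NULL, sprintf("x%d", 1:12)))
  expect_error(stratifyByCpgPanel(flat, clinical), "identical")
})
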