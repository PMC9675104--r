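test_that("pearsonCor matches closed forms and cor.test", {
  expect_equal(pearsonCor(c(1, 2, 3), c(2, 4, 6))[["r"]], 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(-1, -2, -3))[["r"]], -1)
  ## hand computation: cov 4/3, variances 5/3 -> r = 0.8
  expect_equal(pearsonCor(c(1, 2, 3, 4), c(1, 3, 2, 4))[["r"]], 0.8)

  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(length(x)) + 0.5 * x
    ct <- cor.test(x, y)
    pc <- pearsonCor(x, y)
    expect_equal(pc[["r"]], unname(ct$estimate))
    expect_equal(pc[["p"]], ct$p.value)
  }
  ## pairwise-complete handling equals dropping incomplete pairs up front
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, 1, 3, NA, 4, 7)
  ok <- complete.cases(x, y)
  expect_equal(pearsonCor(x, y)[["r"]], cor(x[ok], y[ok]))
  expect_equal(pearsonCor(x, y)[["n"]], sum(ok))

  expect_error(pearsonCor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonCor(c(1, NA, NA, 2), c(1, 2, 3, NA)), ">= 3")
})

test_that("correlateGene applies the minimum-cohort rule and emits the cartesian set", {
  sim <- simulateDataset(tinyConfig(nGenes = 3L, cpgsPerGene = 2L,
                                    exonsPerGene = 3L, samplesPerCancer = 40L,
                                    seed = 2L))
  ds <- sim$dataset
  map <- featureMap(ds)
  gene <- mapGenes(map)[1]
  all_samples <- sampleTable(ds)$sample_id

  out <- correlateGene("cancer01", gene, all_samples[1:9], map, methBeta(ds),
                       exprMatrix(ds, "exon"), "exon")
  expect_identical(nrow(out$records), 0L)
  expect_identical(out$skips$reason, "cohort below minimum")
  expect_identical(out$skips$n, 9L)

  out <- correlateGene("cancer01", gene, all_samples[1:20], map, methBeta(ds),
                       exprMatrix(ds, "exon"), "exon")
  expect_identical(nrow(out$records), 6L)          # 2 CpGs x 3 exons
  expect_true(all(out$records$n >= 10))
  expect_true(all(abs(out$records$r) <= 1))
  expect_true(all(out$records$p >= 0 & out$records$p <= 1))

  expect_error(correlateGene("cancer01", "nope", all_samples, map,
                             methBeta(ds), exprMatrix(ds, "exon"), "exon"),
               "absent")
})

test_that("missing betas are removed pairwise and the floor applies after removal", {
  sim <- simulateDataset(tinyConfig(nGenes = 2L, cpgsPerGene = 2L,
                                    exonsPerGene = 2L, samplesPerCancer = 30L,
                                    nCancers = 1L, seed = 6L))
  ds <- sim$dataset
  meth <- methBeta(ds)
  gene <- mapGenes(featureMap(ds))[1]
  cpgs <- cpgIds(featureMap(ds), gene)
  cohort <- sampleTable(ds)$sample_id[1:15]
  meth[cpgs[1], cohort[1:7]] <- NA        # leaves 8 complete pairs (< 10)
  out <- correlateGene("cancer01", gene, cohort, featureMap(ds), meth,
                       exprMatrix(ds, "exon"), "exon")
  expect_true(all(out$records$cpg != cpgs[1]))
  expect_true(all(out$records$n >= 10))
  kept <- out$records[out$records$cpg == cpgs[2], ]
  expect_identical(unique(kept$n), 15L)
})

test_that("per-cancer adjustment reproduces BH and Bonferroni by hand", {
  rec <- data.frame(cancer = "a", p = c(0.01, 0.02, 0.03, 0.04))
  adj <- adjustPerCancer(rec, "bh")
  expect_equal(adj$p_adj, rep(0.04, 4))              # manual BH
  expect_true(all(adj$significant))

  one <- adjustPerCancer(data.frame(cancer = "a", p = 0.03), "bh")
  expect_equal(one$p_adj, 0.03)                      # m = 1
  expect_equal(adjustPerCancer(data.frame(cancer = "a", p = 0.03),
                               "bonferroni")$p_adj, 0.03)

  bon <- adjustPerCancer(data.frame(cancer = "a", p = c(0.01, 0.5)),
                         "bonferroni")
  expect_equal(bon$p_adj, c(0.02, 1.0))              # x m, capped at 1

  ## families are per cancer, and p_adj is monotone in p within each
  set.seed(4)
  rec <- data.frame(cancer = rep(c("a", "b"), each = 50),
                    p = runif(100))
  adj <- adjustPerCancer(rec, "bh")
  expect_true(all(adj$p_adj >= adj$p))
  for (ca in c("a", "b")) {
    d <- adj[adj$cancer == ca, ]
    d <- d[order(d$p), ]
    expect_true(all(diff(d$p_adj) >= -1e-12))
    expect_equal(d$p_adj, p.adjust(sort(rec$p[rec$cancer == ca]), "BH"))
  }
})

test_that("the screen is invariant to sample order and recovers planted pairs", {
  cfg <- tinyConfig(nGenes = 15L, samplesPerCancer = 50L, effectR = 0.8,
                    seed = 17L)
  sim <- simulateDataset(cfg)
  ds <- sim$dataset
  scr <- runScreen(ds, "exon")
  ## consistent permutation of the sample axis changes nothing
  perm <- sample(ncol(methBeta(ds)))
  ds2 <- MethSpliceDataSet(methBeta(ds)[, perm],
                           exprMatrix(ds, "gene")[, perm],
                           exprMatrix(ds, "exon")[, perm],
                           exprMatrix(ds, "isoform")[, perm],
                           sampleTable(ds), clinicalTable(ds),
                           featureMap(ds))
  scr2 <- runScreen(ds2, "exon")
  expect_equal(scr$records, scr2$records)
  expect_identical(scr$summary, scr2$summary)

  ## planted pairs at |r| = 0.8, cohort ~30: essentially all recovered
  sig <- scr$records[scr$records$significant, ]
  recall <- mean(plantedKeys(sim$truth) %in%
                   paste(sig$cancer, sig$cpg, sig$target))
  expect_gt(recall, 0.9)
  ## every emitted record respects the cohort floor
  expect_true(all(scr$records$n >= 10))
  ## exon and isoform screens share cohorts via the common stratification
  iso <- runScreen(ds, "isoform", stratification = scr$stratification)
  exN <- tapply(scr$records$n, paste(scr$records$cancer, scr$records$gene),
                max)
  isoN <- tapply(iso$records$n, paste(iso$records$cancer, iso$records$gene),
                 max)
  shared <- intersect(names(exN), names(isoN))
  expect_gt(length(shared), 0)
  expect_equal(exN[shared], isoN[shared])
})
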