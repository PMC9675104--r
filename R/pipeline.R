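## End-to-end orchestration: stratify -> exon/isoform screens -> multi-cancer
## aggregation -> survival scan + overlap enrichment -> exon-vs-isoform
## comparison, from one configuration, writing every stage output plus a
## deterministic run report.

#' Default pipeline configuration
#'
#' Thresholds default to the analysis' standard values (significance 0.05,
#' minimum cohort 10, Benjamini-Hochberg adjustment) and the input block is
#' the demo simulation of [simConfig()].
#'
#' @param simulate named list of [simConfig()] overrides, or NULL to read
#'   real inputs from \code{inputs}.
#' @param inputs named list of file paths (the seven files of
#'   [readDataset()]'s directory layout), used when \code{simulate} is NULL.
#' @param method,alpha,minCohort,minGroup screen/scan parameters.
#' @param seed integer seed applied to the simulation block.
#' @return a validated config list for [runPipeline()].
#' @export
pipelineConfig <- function(simulate = list(), inputs = NULL, method = "bh",
                           alpha = 0.05, minCohort = 10L, minGroup = 2L,
                           seed = 1L) {
  config <- list(simulate = simulate, inputs = inputs, method = method,
                 alpha = alpha, minCohort = as.integer(minCohort),
                 minGroup = as.integer(minGroup), seed = as.integer(seed))
  validatePipelineConfig(config)
  config
}

validatePipelineConfig <- function(config) {
  assertThat(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
             "alpha must be in (0,1), got %s", format(config$alpha))
  assertThat(config$minCohort >= 3L, "minCohort must be >= 3, got %d",
             config$minCohort)
  assertThat(config$method %in% c("bh", "bonferroni"),
             "method must be 'bh' or 'bonferroni'")
  assertThat(!is.null(config$simulate) || !is.null(config$inputs),
             "config needs either a simulate block or input paths")
  invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: \code{simulate} (a mapping of [simConfig()]
#' arguments), \code{inputs} (a mapping of the seven input file paths),
#' \code{method}, \code{alpha}, \code{minCohort}, \code{minGroup},
#' \code{seed}.  Missing keys take the [pipelineConfig()] defaults.
#'
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y[intersect(names(y),
                                      names(formals(pipelineConfig)))])
}

#' Run the full methylation-splicing pipeline
#'
#' Executes all stages in dependency order and writes each stage's output
#' to \code{outDir}: the stratification labels, both screen record tables,
#' the ranked multi-cancer pair table, the survival records, the enrichment
#' summary, the exon-vs-isoform difference records/summary and a plain-text
#' run report of record counts, skip tallies and thresholds.  Identical
#' config and seed give byte-identical outputs.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()].
#' @param outDir output directory (created if missing).
#' @param verbose print per-stage progress.
#' @return invisibly, a list with every stage result (\code{dataset},
#'   \code{truth} when simulated, \code{stratification}, \code{exonScreen},
#'   \code{isoformScreen}, \code{pairs}, \code{survival},
#'   \code{enrichment}, \code{comparison}, \code{reportLines}).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        verbose = FALSE) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("stage data")
  truth <- NULL
  dataset <- stage("data", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- config$seed
      sim <- simulateDataset(do.call(simConfig, args))
      truth <- sim$truth
      writeTruth(truth, file.path(outDir, "truth.tsv"))
      sim$dataset
    } else {
      dirOrPaths <- config$inputs
      MethSpliceDataSet(
        meth = readOmicsMatrix(dirOrPaths$methylation, "methylation"),
        geneExpr = readOmicsMatrix(dirOrPaths$gene_expr, "gene"),
        exonExpr = readOmicsMatrix(dirOrPaths$exon_expr, "exon"),
        isoformExpr = readOmicsMatrix(dirOrPaths$isoform_expr, "isoform"),
        samples = readSampleTable(dirOrPaths$samples),
        clinical = readClinicalTable(dirOrPaths$clinical),
        map = readFeatureMap(dirOrPaths$feature_map))
    }
  })

  say("stage stratify")
  strat <- stage("stratify", stratifyExpression(exprMatrix(dataset, "gene")))
  labs <- strat$labels
  stratOut <- data.frame(
    gene_id = rep(rownames(labs), times = ncol(labs)),
    sample_id = rep(colnames(labs), each = nrow(labs)),
    label = ifelse(as.vector(labs), "high", "low"),
    threshold = rep(strat$thresholds, times = ncol(labs)),
    stringsAsFactors = FALSE)
  utils::write.table(stratOut, file.path(outDir, "stratification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

  say("stage screen (exon)")
  exonScreen <- stage("screen_exon",
    runScreen(dataset, "exon", method = config$method, alpha = config$alpha,
              minCohort = config$minCohort, stratification = strat))
  writeRecords(exonScreen$records, file.path(outDir, "exon_screen.tsv"))
  say("stage screen (isoform)")
  isoScreen <- stage("screen_isoform",
    runScreen(dataset, "isoform", method = config$method,
              alpha = config$alpha, minCohort = config$minCohort,
              stratification = strat))
  writeRecords(isoScreen$records, file.path(outDir, "isoform_screen.tsv"))

  say("stage aggregate")
  pairs <- stage("aggregate", rankPairs(collectPairs(exonScreen$records)))
  writeRecords(pairs, file.path(outDir, "multicancer_pairs.tsv"))

  say("stage survival")
  surv <- stage("survival",
    survivalScan(dataset, stratification = strat,
                 minCohort = config$minCohort, minGroup = config$minGroup,
                 alpha = config$alpha))
  writeRecords(surv$records, file.path(outDir, "survival_records.tsv"))
  sigEx <- exonScreen$records[exonScreen$records$significant, , drop = FALSE]
  sigSv <- surv$records[surv$records$significant, , drop = FALSE]
  enrichment <- stage("enrichment", overlapEnrichment(
    paste(sigEx$cancer, sigEx$cpg, sep = "|"),
    paste(sigSv$cancer, sigSv$cpg, sep = "|"),
    nCpgTotal = nrow(methBeta(dataset)),
    nCancers = length(unique(sampleTable(dataset)$cancer_type))))
  enrichOut <- data.frame(
    key = c("n_exon_correlated", "n_sig_survival", "rate", "expected",
            "observed", "observed_unique_cpgs", "fold"),
    value = c(enrichment$nExonCorrelated, enrichment$nSigSurvival,
              enrichment$rate, enrichment$expected, enrichment$observed,
              enrichment$observedUniqueCpgs, enrichment$fold),
    stringsAsFactors = FALSE)
  writeRecords(enrichOut, file.path(outDir, "enrichment.tsv"))

  say("stage compare")
  comparison <- stage("compare",
    compareExonIsoform(exonScreen$records, isoScreen$records,
                       featureMap(dataset)))
  writeRecords(comparison$records, file.path(outDir, "isoform_diff.tsv"))
  if (!is.null(comparison$summary)) {
    s <- comparison$summary
    writeRecords(data.frame(key = c("n_matched", "frac_positive",
                                    "frac_above_0.1", "frac_below_-0.1",
                                    "n_unmatched"),
                            value = c(s$n, s$fracPositive, s$fracAbove0.1,
                                      s$fracBelowMinus0.1,
                                      comparison$nUnmatched),
                            stringsAsFactors = FALSE),
                 file.path(outDir, "diff_summary.tsv"))
    writeRecords(s$histogram, file.path(outDir, "diff_histogram.tsv"))
  }

  report <- c(
    "methSplice pipeline report",
    sprintf("seed: %d | adjust: %s | alpha: %g | minCohort: %d",
            config$seed, config$method, config$alpha, config$minCohort),
    sprintf("samples: %d in %d cancers | genes: %d | CpGs: %d | exons: %d | isoforms: %d",
            nrow(sampleTable(dataset)),
            length(unique(sampleTable(dataset)$cancer_type)),
            nrow(exprMatrix(dataset, "gene")), nrow(methBeta(dataset)),
            nrow(exprMatrix(dataset, "exon")),
            nrow(exprMatrix(dataset, "isoform"))),
    sprintf("degenerate genes: %d", sum(strat$degenerate)),
    sprintf("exon screen: %d tests, %d significant (%d CpGs, %d exons, %d genes), %d skips",
            exonScreen$summary$nTests, exonScreen$summary$nSignificant,
            exonScreen$summary$nUniqueCpgs, exonScreen$summary$nUniqueTargets,
            exonScreen$summary$nUniqueGenes, nrow(exonScreen$skips)),
    sprintf("isoform screen: %d tests, %d significant (%d CpGs, %d isoforms, %d genes), %d skips",
            isoScreen$summary$nTests, isoScreen$summary$nSignificant,
            isoScreen$summary$nUniqueCpgs, isoScreen$summary$nUniqueTargets,
            isoScreen$summary$nUniqueGenes, nrow(isoScreen$skips)),
    sprintf("multi-cancer pairs: %d (perfect consistency: %s)",
            nrow(pairs),
            if (nrow(pairs)) sprintf("%.4f", mean(pairs$consistency == 1))
            else "NA"),
    sprintf("survival scan: %d records, %d significant, %d skips",
            nrow(surv$records), sum(surv$records$significant),
            nrow(surv$skips)),
    sprintf("enrichment: observed %d vs expected %.3f (fold %.3f)",
            enrichment$observed, enrichment$expected, enrichment$fold),
    sprintf("exon-vs-isoform: %d matched, frac diff>0 %s",
            nrow(comparison$records),
            if (!is.null(comparison$summary))
              sprintf("%.4f", comparison$summary$fracPositive) else "NA"))
  writeLines(report, file.path(outDir, "report.txt"))

  invisible(list(dataset = dataset, truth = truth, stratification = strat,
                 exonScreen = exonScreen, isoformScreen = isoScreen,
                 pairs = pairs, survival = surv, enrichment = enrichment,
                 comparison = comparison, reportLines = report,
                 outDir = outDir))
}

## deterministic TSV writer for result tables
writeRecords <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
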