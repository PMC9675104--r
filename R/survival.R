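## Per-CpG log-rank survival scan over gene-specific high-expression
## cohorts, Benjamini-Hochberg correction per cancer, the observed-vs-
## expected overlap enrichment between exon-correlated and survival-
## associated CpGs, and CpG-panel patient stratification with Kaplan-Meier
## coordinates.

#' Split a cohort into methylated/unmethylated by a step fit on beta values
#'
#' Reuses the same StepMiner-style binarization applied to expression: a
#' one-step fit on the CpG's beta values over the cohort, labeling samples
#' above the threshold methylated.  A degenerate fit (constant betas) means
#' the CpG cannot define groups and is skipped by the scan.
#'
#' @param beta numeric vector of beta values (one CpG over the cohort).
#' @return logical vector (TRUE = methylated) with the [StepFit-class] as
#'   attribute \code{"fit"}, or NULL for a degenerate fit.
#' @export
binarizeMethylation <- function(beta) {
  fit <- fitStep(beta[!is.na(beta)])
  if (fit@degenerate) return(NULL)
  structure(binarize(beta, fit), fit = fit)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic comparing the survival
#' curves of two groups, computed with \code{survival::survdiff}.  With no
#' events at all the statistic is undefined; the function returns chi2 = 0,
#' p = 1 flagged \code{noEvents}.
#'
#' @param time non-negative survival/censoring times.
#' @param event 1 = death observed, 0 = censored.
#' @param group two-level grouping vector.
#' @return list(chi2, p, n1, n2, noEvents).
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(as.character(group))
  assertThat(nlevels(group) == 2L, "logrankTest needs exactly 2 groups, got %d",
             nlevels(group))
  n <- table(group)
  if (sum(event) == 0)
    return(list(chi2 = 0, p = 1, n1 = unname(n[1L]), n2 = unname(n[2L]),
                noEvents = TRUE))
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n1 = unname(n[1L]), n2 = unname(n[2L]), noEvents = FALSE)
}

#' Scan every CpG for survival association within high-expression cohorts
#'
#' For each cancer, gene and mapped CpG: restrict to the gene's
#' high-expression cohort with clinical follow-up (samples without clinical
#' rows are dropped and logged), dichotomize the CpG's beta values with
#' [binarizeMethylation()], and log-rank test the two groups.  P-values are
#' Benjamini-Hochberg adjusted per cancer.  The minimum-cohort rule (>= 10)
#' is applied as in the correlation screen, plus a small per-group floor.
#'
#' @param dataset a [MethSpliceDataSet-class].
#' @param stratification result of [stratifyExpression()] on the gene
#'   matrix (computed when missing).
#' @param minCohort minimum cohort with clinical data (default 10).
#' @param minGroup minimum size of each methylation group (default 2).
#' @param alpha FDR threshold (default 0.05).
#' @return list with \code{records} (cancer, gene, cpg, n_methylated,
#'   n_unmethylated, chi2, p, fdr, significant) and \code{skips}.
#' @export
survivalScan <- function(dataset, stratification = NULL, minCohort = 10L,
                         minGroup = 2L, alpha = 0.05) {
  if (is.null(stratification))
    stratification <- stratifyExpression(exprMatrix(dataset, "gene"))
  map <- featureMap(dataset)
  meth <- methBeta(dataset)
  samples <- sampleTable(dataset)
  clin <- clinicalTable(dataset)
  clinTime <- stats::setNames(clin$time, clin$sample_id)
  clinEvent <- stats::setNames(clin$event, clin$sample_id)
  cancers <- sort(unique(samples$cancer_type))
  genes <- intersect(mapGenes(map), rownames(stratification$labels))
  recs <- list(); skips <- list(); i <- 0L; j <- 0L
  logSkip <- function(cancer, gene, cpg, reason, n) {
    j <<- j + 1L
    skips[[j]] <<- data.frame(cancer = cancer, gene = gene, cpg = cpg,
                              reason = reason, n = n,
                              stringsAsFactors = FALSE)
  }
  for (cancer in cancers) {
    for (gene in genes) {
      if (stratification$degenerate[gene]) {
        logSkip(cancer, gene, NA_character_, "degenerate step fit",
                NA_integer_)
        next
      }
      cohort <- highCohort(stratification, gene, samples, cancer)
      noClin <- setdiff(cohort, clin$sample_id)
      if (length(noClin))
        logSkip(cancer, gene, NA_character_, "samples without clinical data",
                length(noClin))
      cohort <- intersect(cohort, clin$sample_id)
      if (length(cohort) < minCohort) {
        logSkip(cancer, gene, NA_character_, "cohort below minimum",
                length(cohort))
        next
      }
      cpgs <- intersect(cpgIds(map, gene), rownames(meth))
      for (cpg in cpgs) {
        beta <- meth[cpg, cohort]
        ok <- !is.na(beta)
        if (sum(ok) < minCohort) {
          logSkip(cancer, gene, cpg, "too many missing betas", sum(ok))
          next
        }
        lab <- binarizeMethylation(beta[ok])
        if (is.null(lab)) {
          logSkip(cancer, gene, cpg, "degenerate methylation split", sum(ok))
          next
        }
        if (min(sum(lab), sum(!lab)) < minGroup) {
          logSkip(cancer, gene, cpg, "methylation group below minimum",
                  min(sum(lab), sum(!lab)))
          next
        }
        keep <- cohort[ok]
        lr <- logrankTest(clinTime[keep], clinEvent[keep],
                          ifelse(lab, "methylated", "unmethylated"))
        i <- i + 1L
        recs[[i]] <- list(cancer, gene, cpg, sum(lab), sum(!lab),
                          lr$chi2, lr$p, lr$noEvents)
      }
    }
  }
  records <- if (i) data.frame(
    cancer = vapply(recs, `[[`, "", 1L), gene = vapply(recs, `[[`, "", 2L),
    cpg = vapply(recs, `[[`, "", 3L),
    n_methylated = vapply(recs, function(x) as.integer(x[[4L]]), 0L),
    n_unmethylated = vapply(recs, function(x) as.integer(x[[5L]]), 0L),
    chi2 = vapply(recs, `[[`, 0, 6L), p = vapply(recs, `[[`, 0, 7L),
    no_events = vapply(recs, `[[`, NA, 8L), stringsAsFactors = FALSE)
  else data.frame(cancer = character(), gene = character(),
                  cpg = character(), n_methylated = integer(),
                  n_unmethylated = integer(), chi2 = numeric(),
                  p = numeric(), no_events = logical(),
                  stringsAsFactors = FALSE)
  if (nrow(records)) {
    records$fdr <- stats::ave(records$p, records$cancer,
                              FUN = function(p) stats::p.adjust(p, "BH"))
    records$significant <- records$fdr < alpha
  } else {
    records$fdr <- numeric()
    records$significant <- logical()
  }
  skips <- do.call(rbind, skips)
  if (is.null(skips))
    skips <- data.frame(cancer = character(), gene = character(),
                        cpg = character(), reason = character(),
                        n = integer(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  rownames(skips) <- NULL
  list(records = records, skips = skips)
}

#' Fold enrichment of an observed overlap over an expected one
#'
#' @param observed,expected non-negative counts; \code{expected = 0} with a
#'   positive observed count yields \code{Inf} with a warning.
#' @export
foldEnrichment <- function(observed, expected) {
  assertThat(observed >= 0 && expected >= 0, "counts must be >= 0")
  if (expected == 0) {
    if (observed > 0) warning("expected overlap is 0; fold is infinite")
    return(if (observed > 0) Inf else NaN)
  }
  observed / expected
}

#' Enrichment arithmetic from plain counts
#'
#' Computes the background rate of survival association
#' (\code{nSigSurvival / (nCpgTotal * nCancers)}), the overlap expected if
#' exon correlation and survival association were independent
#' (\code{rate * nExonCorrelated}) and the fold enrichment of the observed
#' overlap.
#'
#' @param nSigSurvival number of significant CpG-survival relationships.
#' @param nCpgTotal CpG sites on the platform.
#' @param nCancers number of cancer types scanned.
#' @param nExonCorrelated size of the exon-correlated CpG set.
#' @param observed observed overlap count.
#' @return list(rate, ratePct, expected, observed, fold).
#' @examples
#' ## the 450K-scale arithmetic: rate ~0.19%, expectation ~128 of 65,949
#' enrichmentFromCounts(31045, 485577, 33, 65949, 643)
#' @export
enrichmentFromCounts <- function(nSigSurvival, nCpgTotal, nCancers,
                                 nExonCorrelated, observed) {
  assertThat(all(c(nSigSurvival, nCpgTotal, nCancers, nExonCorrelated,
                   observed) >= 0), "counts must be >= 0")
  rate <- nSigSurvival / (nCpgTotal * nCancers)
  expected <- rate * nExonCorrelated
  list(rate = rate, ratePct = 100 * rate, expected = expected,
       observed = observed, fold = foldEnrichment(observed, expected))
}

#' Overlap enrichment between exon-correlated and survival-associated CpGs
#'
#' Units are (cancer, CpG) keys, matching the per-cancer scans; the result
#' also reports the collapsed unique-CpG overlap since published overlap
#' counts are sometimes quoted per CpG site.
#'
#' @param exonKeys character keys \code{"cancer|cpg"} of significant
#'   CpG-exon correlations (unique-ified internally).
#' @param survivalKeys same-format keys of significant CpG-survival
#'   relationships.
#' @param nCpgTotal total CpGs on the platform/dataset.
#' @param nCancers number of cancer types.
#' @return the [enrichmentFromCounts()] list plus \code{observedUniqueCpgs}.
#' @export
overlapEnrichment <- function(exonKeys, survivalKeys, nCpgTotal, nCancers) {
  exonKeys <- unique(exonKeys)
  survivalKeys <- unique(survivalKeys)
  ov <- intersect(exonKeys, survivalKeys)
  res <- enrichmentFromCounts(length(survivalKeys), nCpgTotal, nCancers,
                              length(exonKeys), length(ov))
  res$observedUniqueCpgs <- length(unique(sub("^.*\\|", "", ov)))
  res$nExonCorrelated <- length(exonKeys)
  res$nSigSurvival <- length(survivalKeys)
  res
}

#' Stratify patients by a CpG panel and compare survival
#'
#' Clusters patients on the beta profiles of a small CpG panel
#' (average-linkage hierarchical clustering on Euclidean distance, cut at
#' k = 2), then log-rank tests the two groups and returns Kaplan-Meier
#' curve coordinates for each.
#'
#' @param beta CpG x sample beta matrix (>= 2 CpGs, >= 10 samples).
#' @param clinical data.frame(sample_id, time, event) covering the samples.
#' @param k number of groups (fixed to 2-group comparisons downstream).
#' @return list(groups, chi2, p, km) where \code{groups} is a named integer
#'   vector of cluster labels and \code{km} a data.frame(group, time, surv,
#'   n_risk).
#' @export
stratifyByCpgPanel <- function(beta, clinical, k = 2L) {
  assertThat(is.matrix(beta) && nrow(beta) >= 2L,
             "need >= 2 CpGs in the panel")
  assertThat(ncol(beta) >= 10L, "need a cohort of >= 10 samples, got %d",
             ncol(beta))
  d <- stats::dist(t(beta))
  if (all(d == 0)) stop("all methylation profiles identical; cannot cluster")
  groups <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  rownames(clinical) <- clinical$sample_id
  cc <- clinical[colnames(beta), ]
  lr <- logrankTest(cc$time, cc$event, groups)
  fit <- survival::survfit(survival::Surv(cc$time, cc$event) ~ groups)
  strata <- rep(names(fit$strata) %||% "groups=1", fit$strata %||% length(fit$time))
  km <- data.frame(group = sub("^groups=", "", strata), time = fit$time,
                   surv = fit$surv, n_risk = fit$n.risk,
                   stringsAsFactors = FALSE)
  list(groups = groups, chi2 = lr$chi2, p = lr$p, km = km)
}
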