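## Per-cancer Pearson correlation screen between CpG beta values and exon or
## isoform expression over gene-specific high-expression cohorts, with the
## minimum-cohort rule (>= 10 patients by default) and per-cancer
## multiple-testing control.

#' Pearson correlation with a two-sided p-value
#'
#' Pairs with a missing value in either vector are dropped (pairwise
#' complete); at least 3 complete pairs are required and both vectors must
#' be non-constant.  The p-value comes from the t transform of r with n - 2
#' degrees of freedom, as in \code{cor.test}.
#'
#' @param x,y numeric vectors of equal length.
#' @return named numeric \code{c(r=, p=, n=)}.
#' @export
pearsonCor <- function(x, y) {
  assertThat(length(x) == length(y), "x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assertThat(n >= 3L, "need >= 3 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  p <- corPValue(r, n)
  c(r = r, p = p, n = n)
}

## two-sided p from the t transform; vectorized
corPValue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) >= 1
  p[exact] <- 0
  rest <- !is.na(r) & !exact & n > 2
  tt <- r[rest] * sqrt((n[rest] - 2) / (1 - r[rest]^2))
  p[rest] <- 2 * stats::pt(-abs(tt), n[rest] - 2)
  p
}

#' Correlate every CpG of a gene with every exon or isoform of that gene
#'
#' Runs the Pearson screen for one (cancer, gene) over the supplied
#' high-expression cohort.  Cohorts below \code{minN} skip the gene
#' entirely; individual CpG-target combinations are emitted only when the
#' pairwise-complete sample count is still >= \code{minN} and neither vector
#' is constant.
#'
#' @param cancer,gene labels recorded in the output.
#' @param cohort character vector of sample ids (the gene's high-expression
#'   cohort in this cancer).
#' @param map a [FeatureMap-class].
#' @param meth CpG x sample beta matrix.
#' @param expr target x sample expression matrix (exon or isoform kind).
#' @param targetKind \code{"exon"} or \code{"isoform"}.
#' @param minN minimum cohort / pairwise-complete size (default 10).
#' @return list with \code{records} (data.frame cancer, gene, cpg, target,
#'   target_kind, n, r, p) and \code{skips} (data.frame cancer, gene,
#'   reason, n).
#' @export
correlateGene <- function(cancer, gene, cohort, map, meth, expr,
                          targetKind = c("exon", "isoform"), minN = 10L) {
  targetKind <- match.arg(targetKind)
  assertThat(gene %in% mapGenes(map), "gene '%s' absent from feature map",
             gene)
  emptyRec <- data.frame(cancer = character(), gene = character(),
                         cpg = character(), target = character(),
                         target_kind = character(), n = integer(),
                         r = numeric(), p = numeric(),
                         stringsAsFactors = FALSE)
  skip <- function(reason, n) list(records = emptyRec,
                                   skips = data.frame(cancer = cancer,
                                                      gene = gene,
                                                      reason = reason, n = n,
                                                      stringsAsFactors = FALSE))
  if (length(cohort) < minN)
    return(skip("cohort below minimum", length(cohort)))
  cpgs <- intersect(cpgIds(map, gene), rownames(meth))
  targets <- intersect(
    if (targetKind == "exon") exonIds(map, gene) else isoformIds(map, gene),
    rownames(expr))
  if (!length(cpgs) || !length(targets))
    return(skip("no mapped features with data", length(cohort)))
  M <- t(meth[cpgs, cohort, drop = FALSE])
  E <- t(expr[targets, cohort, drop = FALSE])
  R <- suppressWarnings(stats::cor(M, E, use = "pairwise.complete.obs"))
  N <- crossprod(!is.na(M) + 0, !is.na(E) + 0)
  rec <- data.frame(cancer = cancer, gene = gene,
                    cpg = rep(cpgs, times = length(targets)),
                    target = rep(targets, each = length(cpgs)),
                    target_kind = targetKind,
                    n = as.integer(N), r = as.vector(R),
                    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$r) & rec$n >= minN, , drop = FALSE]
  rec$r <- pmax(-1, pmin(1, rec$r))
  rec$p <- corPValue(rec$r, rec$n)
  rownames(rec) <- NULL
  list(records = rec, skips = data.frame(cancer = character(),
                                         gene = character(),
                                         reason = character(), n = integer(),
                                         stringsAsFactors = FALSE))
}

#' Adjust screen p-values within each cancer
#'
#' The adjustment family is all tests of one target kind within one cancer
#' type, pooling the genes of that cancer.  The default is
#' Benjamini-Hochberg (the 5% FDR threshold of the screen); Bonferroni is
#' available as an alternative.
#'
#' @param records data.frame with at least \code{cancer} and \code{p}.
#' @param method \code{"bh"} or \code{"bonferroni"}.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return \code{records} with added \code{p_adj} and \code{significant}.
#' @export
adjustPerCancer <- function(records, method = c("bh", "bonferroni"),
                            alpha = 0.05) {
  method <- match.arg(method)
  stat_method <- c(bh = "BH", bonferroni = "bonferroni")[[method]]
  if (!nrow(records)) {
    records$p_adj <- numeric()
    records$significant <- logical()
    return(records)
  }
  records$p_adj <- stats::ave(records$p, records$cancer,
                              FUN = function(p) stats::p.adjust(p, stat_method))
  records$significant <- records$p_adj < alpha
  records
}

#' Run the full CpG-vs-exon (or isoform) correlation screen
#'
#' For every cancer type and gene: derive the gene's high-expression cohort
#' from the global step-fit stratification, apply the minimum-cohort rule,
#' correlate every mapped CpG with every mapped target, and adjust p-values
#' per cancer.  Exon and isoform screens run from the same stratification
#' and therefore use identical cohorts per (cancer, gene).
#'
#' @param dataset a [MethSpliceDataSet-class].
#' @param targetKind \code{"exon"} or \code{"isoform"}.
#' @param method,alpha multiple-testing method and threshold, see
#'   [adjustPerCancer()].
#' @param minCohort minimum high-expression cohort size (default 10).
#' @param stratification optional precomputed result of
#'   [stratifyExpression()] on the gene matrix (computed when missing);
#'   pass the same object to both screens to share cohorts.
#' @return list with \code{records} (one row per emitted test, with
#'   \code{p_adj} and \code{significant}), \code{skips}, \code{summary}
#'   (counts of significant records and unique significant CpGs / targets /
#'   genes) and the \code{stratification} used.
#' @export
runScreen <- function(dataset, targetKind = c("exon", "isoform"),
                      method = "bh", alpha = 0.05, minCohort = 10L,
                      stratification = NULL) {
  targetKind <- match.arg(targetKind)
  if (is.null(stratification))
    stratification <- stratifyExpression(exprMatrix(dataset, "gene"))
  map <- featureMap(dataset)
  meth <- methBeta(dataset)
  expr <- exprMatrix(dataset, targetKind)
  samples <- sampleTable(dataset)
  cancers <- sort(unique(samples$cancer_type))
  genes <- intersect(mapGenes(map), rownames(stratification$labels))
  recs <- list(); skips <- list(); i <- 0L
  for (cancer in cancers) {
    for (gene in genes) {
      if (stratification$degenerate[gene]) {
        i <- i + 1L
        skips[[i]] <- data.frame(cancer = cancer, gene = gene,
                                 reason = "degenerate step fit", n = NA_integer_,
                                 stringsAsFactors = FALSE)
        next
      }
      cohort <- highCohort(stratification, gene, samples, cancer)
      out <- correlateGene(cancer, gene, cohort, map, meth, expr,
                           targetKind, minN = minCohort)
      i <- i + 1L
      recs[[i]] <- out$records
      skips[[i]] <- out$skips
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(cancer = character(), gene = character(),
                          cpg = character(), target = character(),
                          target_kind = character(), n = integer(),
                          r = numeric(), p = numeric(),
                          stringsAsFactors = FALSE)
  records <- adjustPerCancer(records, method = method, alpha = alpha)
  sig <- records[records$significant, , drop = FALSE]
  summary <- list(nTests = nrow(records), nSignificant = nrow(sig),
                  nUniqueCpgs = length(unique(sig$cpg)),
                  nUniqueTargets = length(unique(sig$target)),
                  nUniqueGenes = length(unique(sig$gene)))
  skips <- do.call(rbind, skips)
  if (is.null(skips))
    skips <- data.frame(cancer = character(), gene = character(),
                        reason = character(), n = integer(),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  rownames(skips) <- NULL
  list(records = records, skips = skips, summary = summary,
       stratification = stratification)
}
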