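## Direction-matched comparison of CpG-exon versus CpG-isoform correlation
## strength: for every significant CpG-exon correlation, find the strongest
## same-sign significant CpG-isoform correlation among isoforms containing
## the exon, and summarize the distribution of |r_exon| - |r_isoform|.

#' Candidate isoform correlations for one CpG-exon correlation
#'
#' Isoforms qualify when their member-exon list contains the exon and their
#' CpG-isoform correlation is significant for the same CpG in the same
#' cancer.
#'
#' @param exonId,cpgId,cancer the CpG-exon correlation's coordinates.
#' @param isoformRecords isoform screen records (see [runScreen()]).
#' @param map a [FeatureMap-class].
#' @return data.frame(isoform, r), possibly empty.
#' @export
candidateIsoforms <- function(exonId, cpgId, cancer, isoformRecords, map) {
  members <- isoformMembers(map)
  holders <- names(members)[vapply(members, function(m) exonId %in% m,
                                   logical(1))]
  sub <- isoformRecords[isoformRecords$significant &
                          isoformRecords$cancer == cancer &
                          isoformRecords$cpg == cpgId &
                          isoformRecords$target %in% holders, , drop = FALSE]
  data.frame(isoform = sub$target, r = sub$r, stringsAsFactors = FALSE)
}

#' Select the direction-matched strongest isoform correlation
#'
#' Among candidates sharing the sign of the CpG-exon correlation, pick the
#' one with the largest |r| (for a negative exon correlation this is the
#' most negative isoform correlation).  Ties in |r| go to the
#' lexicographically smallest isoform id.  Returns NULL when no same-sign
#' candidate exists.
#'
#' @param rExon the CpG-exon correlation value (non-zero).
#' @param candidates data.frame(isoform, r) from [candidateIsoforms()].
#' @return list(isoform, r) or NULL.
#' @export
selectMatched <- function(rExon, candidates) {
  assertThat(rExon != 0, "rExon must be non-zero")
  same <- candidates[sign(candidates$r) == sign(rExon), , drop = FALSE]
  if (!nrow(same)) return(NULL)
  same <- same[order(-abs(same$r), same$isoform), , drop = FALSE]
  list(isoform = same$isoform[1L], r = same$r[1L])
}

#' Compare exon and isoform correlation strengths per CpG
#'
#' Applies [selectMatched()] to every significant CpG-exon correlation and
#' computes \code{diff = |r_exon| - |r_isoform|} (positive = exon stronger,
#' for either correlation direction).  Pairs without a direction-consistent
#' significant isoform correlation are excluded from the distribution.
#'
#' @param exonRecords,isoformRecords screen records of the two kinds (see
#'   [runScreen()]); both should come from the same stratification so the
#'   cohorts match.
#' @param map a [FeatureMap-class].
#' @return list with \code{records} (cancer, gene, cpg, exon, isoform,
#'   r_exon, r_isoform, diff; one row per matched (cancer, pair)),
#'   \code{summary} from [diffDistribution()] over those records,
#'   \code{summaryPerPair} over per-pair mean diffs (each (cpg, exon) pair
#'   counted once), and \code{nUnmatched}.
#' @export
compareExonIsoform <- function(exonRecords, isoformRecords, map) {
  ex <- exonRecords[exonRecords$significant & exonRecords$r != 0, ,
                    drop = FALSE]
  iso <- isoformRecords[isoformRecords$significant & isoformRecords$r != 0, ,
                        drop = FALSE]
  empty <- data.frame(cancer = character(), gene = character(),
                      cpg = character(), exon = character(),
                      isoform = character(), r_exon = numeric(),
                      r_isoform = numeric(), diff = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(ex) || !nrow(iso))
    return(list(records = empty, summary = NULL, summaryPerPair = NULL,
                nUnmatched = nrow(ex)))
  ## exon -> holding isoforms membership table
  members <- isoformMembers(map)
  memTab <- data.frame(isoform = rep(names(members), lengths(members)),
                       exon = unlist(members, use.names = FALSE),
                       stringsAsFactors = FALSE)
  ex$recordId <- seq_len(nrow(ex))
  cand <- merge(ex[c("recordId", "cancer", "gene", "cpg", "target", "r")],
                memTab, by.x = "target", by.y = "exon")
  cand <- merge(cand,
                iso[c("cancer", "cpg", "target", "r")],
                by.x = c("cancer", "cpg", "isoform"),
                by.y = c("cancer", "cpg", "target"),
                suffixes = c("_exon", "_isoform"))
  cand <- cand[sign(cand$r_isoform) == sign(cand$r_exon), , drop = FALSE]
  if (nrow(cand)) {
    cand <- cand[order(cand$recordId, -abs(cand$r_isoform), cand$isoform), ,
                 drop = FALSE]
    best <- cand[!duplicated(cand$recordId), , drop = FALSE]
    records <- data.frame(cancer = best$cancer, gene = best$gene,
                          cpg = best$cpg, exon = best$target,
                          isoform = best$isoform, r_exon = best$r_exon,
                          r_isoform = best$r_isoform,
                          diff = abs(best$r_exon) - abs(best$r_isoform),
                          stringsAsFactors = FALSE)
    records <- records[order(records$cancer, records$gene, records$cpg,
                             records$exon), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- empty
  }
  perPair <- if (nrow(records))
    tapply(records$diff, paste(records$cpg, records$exon, sep = "\r"), mean)
  else numeric()
  list(records = records,
       summary = if (nrow(records)) diffDistribution(records$diff) else NULL,
       summaryPerPair = if (length(perPair))
         diffDistribution(as.numeric(perPair)) else NULL,
       nUnmatched = nrow(ex) - nrow(records))
}

#' Summarize a correlation-difference distribution
#'
#' Fractions of differences strictly above 0, above 0.1 and below -0.1
#' (strict inequalities), plus a fixed-width histogram (bin width 0.05 over
#' [-1, 1], right-closed bins).
#'
#' @param diffs numeric vector of |r_exon| - |r_isoform| values, length >= 1.
#' @return list(fracPositive, fracAbove0.1, fracBelowMinus0.1, n, histogram).
#' @export
diffDistribution <- function(diffs) {
  assertThat(length(diffs) >= 1L, "no differences to summarize")
  assertThat(all(diffs >= -1 - 1e-9 & diffs <= 1 + 1e-9),
             "differences must lie in [-1, 1]")
  breaks <- seq(-1, 1, by = 0.05)
  h <- graphics::hist(diffs, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  list(fracPositive = mean(diffs > 0),
       fracAbove0.1 = mean(diffs > 0.1),
       fracBelowMinus0.1 = mean(diffs < -0.1),
       n = length(diffs),
       histogram = data.frame(binStart = breaks[-length(breaks)],
                              binEnd = breaks[-1L], count = h$counts))
}
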