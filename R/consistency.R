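## Multi-cancer aggregation of significant CpG-exon correlations: pairs
## significant in two or more cancer types get a consistency score (fraction
## of correlations sharing the majority direction, range 0.5-1), a majority
## sign, and a ranking by mean absolute correlation.

#' Consistency score of a set of signed correlations
#'
#' The fraction of correlations in the larger sign group:
#' \code{max(n_pos, n_neg) / total}, which lies in [0.5, 1] for two or more
#' inputs.  A zero correlation has no sign and is an error.
#'
#' @param r numeric vector of signed correlations, length >= 2, none zero.
#' @export
consistencyScore <- function(r) {
  assertThat(length(r) >= 2L, "need >= 2 correlations, got %d", length(r))
  if (any(r == 0)) stop("correlation of 0 has no sign")
  max(sum(r > 0), sum(r < 0)) / length(r)
}

#' Majority sign of a set of signed correlations
#'
#' Sign of the larger sign group; an even split is broken toward the group
#' with the larger summed |r|.
#'
#' @param r numeric vector of signed correlations, none zero.
#' @return \code{"+"} or \code{"-"}.
#' @export
majoritySign <- function(r) {
  if (any(r == 0)) stop("correlation of 0 has no sign")
  nPos <- sum(r > 0); nNeg <- sum(r < 0)
  if (nPos != nNeg) return(if (nPos > nNeg) "+" else "-")
  if (sum(r[r > 0]) >= sum(abs(r[r < 0]))) "+" else "-"
}

#' Aggregate significant CpG-exon correlations across cancers
#'
#' Keeps every (CpG, exon) pair significant in at least two cancer types
#' and summarizes its per-cancer correlations: number of cancers,
#' consistency score, majority sign (with a tie flag for even splits) and
#' the mean of absolute correlation values.
#'
#' @param records screen records (see [runScreen()]); only rows with
#'   \code{significant == TRUE} enter the aggregation.
#' @return data.frame with one row per multi-cancer pair: \code{cpg},
#'   \code{exon}, \code{gene}, \code{cancers} (semicolon-joined),
#'   \code{correlations} (semicolon-joined, cancer order), \code{n_cancers},
#'   \code{consistency}, \code{majority_sign}, \code{sign_tie},
#'   \code{mean_abs_r}.  Empty when no pair recurs.
#' @export
collectPairs <- function(records) {
  sig <- records[records$significant & records$r != 0, , drop = FALSE]
  if (!nrow(sig)) return(emptyPairTable())
  key <- paste(sig$cpg, sig$target, sep = "\r")
  keep <- key %in% names(which(table(key) >= 2L))
  sig <- sig[keep, , drop = FALSE]
  if (!nrow(sig)) return(emptyPairTable())
  sig <- sig[order(sig$cpg, sig$target, sig$cancer), , drop = FALSE]
  out <- lapply(split(sig, paste(sig$cpg, sig$target, sep = "\r")),
                function(d) data.frame(
                  cpg = d$cpg[1L], exon = d$target[1L], gene = d$gene[1L],
                  cancers = paste(d$cancer, collapse = ";"),
                  correlations = paste(signif(d$r, 6), collapse = ";"),
                  n_cancers = nrow(d),
                  consistency = consistencyScore(d$r),
                  majority_sign = majoritySign(d$r),
                  sign_tie = sum(d$r > 0) == sum(d$r < 0),
                  mean_abs_r = mean(abs(d$r)),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

emptyPairTable <- function() {
  data.frame(cpg = character(), exon = character(), gene = character(),
             cancers = character(), correlations = character(),
             n_cancers = integer(), consistency = numeric(),
             majority_sign = character(), sign_tie = logical(),
             mean_abs_r = numeric(), stringsAsFactors = FALSE)
}

#' Rank multi-cancer pairs by mean absolute correlation
#'
#' Stable descending sort on \code{mean_abs_r}; exact ties fall back to
#' lexicographic (cpg, exon) order so the output is deterministic.
#'
#' @param pairs table from [collectPairs()].
#' @export
rankPairs <- function(pairs) {
  pairs[order(-pairs$mean_abs_r, pairs$cpg, pairs$exon), , drop = FALSE]
}

#' Summarize consistency scores of the multi-cancer pairs
#'
#' @param pairs non-empty table from [collectPairs()].
#' @return named numeric: \code{fracPerfect} (score exactly 1) and
#'   \code{fracAbove0.7} (score > 0.7).
#' @export
consistencySummary <- function(pairs) {
  assertThat(nrow(pairs) > 0L, "no multi-cancer pairs to summarize")
  c(fracPerfect = mean(pairs$consistency == 1),
    fracAbove0.7 = mean(pairs$consistency > 0.7))
}
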