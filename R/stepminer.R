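## StepMiner-style binarization: fit a one-step function to sorted values,
## minimizing the squared error of a two-segment mean fit, and take the
## midpoint of the two segment means as the binarization threshold.  The
## global threshold per gene is fit on all samples of all cancers at once,
## which is what makes per-cancer high-expression cohorts comparable.

#' Fit a one-step function to a numeric vector
#'
#' The vector is sorted internally; among all split points k in 1..n-1 the
#' one minimizing the sum of squared errors of the two segment means is
#' chosen (smallest k on ties).  The threshold is the midpoint of the two
#' segment means.  When no split improves on the flat single-mean fit
#' (constant data) the fit is flagged degenerate and the threshold is NA.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @return A [StepFit-class].
#' @examples
#' fitStep(c(1, 2, 3, 10, 11))   # split after 3 values, threshold 6.25
#' @export
fitStep <- function(values) {
  assertThat(is.numeric(values) && length(values) >= 2L,
             "fitStep needs a numeric vector of length >= 2")
  assertThat(all(is.finite(values)), "fitStep requires finite values")
  x <- sort(values)
  n <- length(x)
  S <- cumsum(x)
  tot <- S[n]
  ss <- sum(x^2)
  k <- seq_len(n - 1L)
  sse <- ss - (S[k]^2 / k + (tot - S[k])^2 / (n - k))
  sseFlat <- ss - tot^2 / n
  best <- which.min(sse)              # which.min takes the smallest k on ties
  improvement <- sseFlat - sse[best]
  tol <- 1e-10 * max(1, abs(sseFlat))
  if (improvement <= tol) {
    return(new("StepFit", splitIndex = NA_integer_, lowMean = mean(x),
               highMean = mean(x), threshold = NA_real_,
               sse = max(sseFlat, 0), degenerate = TRUE, n = n))
  }
  lowMean <- S[best] / best
  highMean <- (tot - S[best]) / (n - best)
  new("StepFit", splitIndex = as.integer(best), lowMean = lowMean,
      highMean = highMean, threshold = (lowMean + highMean) / 2,
      sse = max(sse[best], 0), degenerate = FALSE, n = n)
}

#' Binarize values against a step fit
#'
#' Labels a value high iff it lies strictly above the fit's threshold;
#' values exactly at the threshold are low (conservative high cohort).  A
#' degenerate fit labels everything low.
#'
#' @param values numeric vector.
#' @param fit a [StepFit-class] from [fitStep()].
#' @return logical vector, TRUE = high.
#' @export
binarize <- function(values, fit) {
  if (fit@degenerate) return(rep(FALSE, length(values)))
  !is.na(values) & values > fit@threshold
}

#' Stratify every gene into high/low expression cohorts
#'
#' Fits one global step threshold per gene on the expression values of all
#' samples of all cancers pooled, then labels each sample high or low for
#' each gene.  Per-cancer high-expression cohorts are obtained downstream by
#' intersecting the high labels with cancer membership; pooling is what
#' makes the threshold robust across cohorts.
#'
#' @param expr gene x sample log-scale expression matrix.
#' @return list with \code{labels} (logical gene x sample matrix, TRUE =
#'   high), \code{thresholds} (named numeric, NA for degenerate genes) and
#'   \code{degenerate} (named logical).  Degenerate (constant) genes get
#'   all-low labels and are expected to be skipped downstream.
#' @export
stratifyExpression <- function(expr) {
  assertThat(is.matrix(expr) && ncol(expr) >= 2L,
             "stratifyExpression needs a matrix with >= 2 samples")
  genes <- rownames(expr)
  thresholds <- stats::setNames(rep(NA_real_, length(genes)), genes)
  degenerate <- stats::setNames(rep(TRUE, length(genes)), genes)
  labels <- matrix(FALSE, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (g in genes) {
    v <- expr[g, ]
    ok <- is.finite(v)
    if (sum(ok) < 2L) next
    fit <- fitStep(v[ok])
    degenerate[g] <- fit@degenerate
    if (fit@degenerate) next
    thresholds[g] <- fit@threshold
    labels[g, ] <- binarize(v, fit)
  }
  list(labels = labels, thresholds = thresholds, degenerate = degenerate)
}

#' High-expression cohort of one gene in one cancer
#'
#' @param stratification result of [stratifyExpression()].
#' @param gene gene id.
#' @param samples data.frame(sample_id, cancer_type).
#' @param cancer cancer type label.
#' @return character vector of sample ids labeled high for the gene within
#'   the cancer (empty for degenerate genes).
#' @export
highCohort <- function(stratification, gene, samples, cancer) {
  inCancer <- samples$sample_id[samples$cancer_type == cancer]
  lab <- stratification$labels[gene, ]
  intersect(inCancer, colnames(stratification$labels)[lab])
}
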