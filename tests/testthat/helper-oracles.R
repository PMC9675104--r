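## Independent oracles used to cross-check the package's implementations.

## Exhaustive enumeration of all two-segment splits of a sorted vector;
## returns the split with minimal SSE (smallest split index on ties).
bruteStepFit <- function(values) {
  x <- sort(values)
  n <- length(x)
  best <- NULL
  for (k in seq_len(n - 1L)) {
    lo <- x[seq_len(k)]
    hi <- x[(k + 1L):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(k = k, sse = sse,
                   lowMean = mean(lo), highMean = mean(hi))
  }
  best$flatSse <- sum((x - mean(x))^2)
  best
}

## Direct per-event-time log-rank summation: observed minus expected events
## in group 1 with the hypergeometric variance at each distinct event time.
logrankOracle <- function(time, event, group) {
  g <- as.integer(as.factor(as.character(group)))
  stopifnot(all(g %in% 1:2))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  list(chi2 = chi2, O = O, E = E, V = V)
}

## Small simulated datasets reused across test files.
tinyConfig <- function(...) {
  args <- list(nGenes = 20L, nCancers = 2L, samplesPerCancer = 40L,
               cpgsPerGene = 4L, exonsPerGene = 4L, isoformsPerGene = 2L,
               fracExpressed = 0.6, effectR = 0.8, fracPlanted = 0.15,
               signConsistency = 1, fracDriverCpgs = 0.3, hazardRatio = 3,
               seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

## keys identifying planted effects at the (cancer, cpg, exon) level
plantedKeys <- function(truth) {
  pp <- truth@plantedPairs
  paste(pp$cancer, pp$cpg, pp$exon)
}
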