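#' @import methods
NULL

## ---------------------------------------------------------------------------
## ExonLocus
## ---------------------------------------------------------------------------

#' Genomic location of one exon
#'
#' Exon identifiers of the form \code{"chr3:118864997-118866434:+"} are used
#' as opaque feature keys throughout the pipeline; this class holds their
#' parsed form.  Coordinates are 1-based, fully closed intervals.
#'
#' @slot exonId character(1), the canonical \code{chrom:start-end:strand} id.
#' @slot chrom character(1) chromosome name.
#' @slot start,end integer base positions, \code{start <= end}.
#' @slot strand character(1), \code{"+"} or \code{"-"}.
#'
#' @seealso [parseExonId()], [formatExonId()]
#' @export
setClass("ExonLocus",
  representation(exonId = "character", chrom = "character",
                 start = "integer", end = "integer", strand = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@start) != 1L || length(object@end) != 1L)
      msg <- c(msg, "start and end must be scalars")
    else if (object@start > object@end)
      msg <- c(msg, sprintf("start > end (%d > %d)", object@start, object@end))
    if (!object@strand %in% c("+", "-"))
      msg <- c(msg, sprintf("strand must be '+' or '-', got '%s'", object@strand))
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## FeatureMap
## ---------------------------------------------------------------------------

#' Gene-centric map linking CpGs, exons and isoforms
#'
#' The map is stored in the long on-disk format: one row per
#' (gene, feature) relation with columns \code{gene_id}, \code{feature_kind}
#' (\code{"cpg"}, \code{"exon"} or \code{"isoform"}), \code{feature_id} and
#' \code{parent_isoform_id}.  An exon row with a non-empty
#' \code{parent_isoform_id} declares exon membership in that isoform; the row
#' order of membership rows defines the ordered member-exon list.  Lookup
#' tables are precomputed at construction so downstream screens can query
#' features per gene cheaply.
#'
#' @slot map data.frame in the long format described above.
#' @slot cpgsByGene,exonsByGene,isoformsByGene named lists of character
#'   vectors, one element per gene.
#' @slot membersByIsoform named list: isoform id -> ordered member exon ids.
#' @slot geneOfIsoform named character: isoform id -> gene id.
#'
#' @seealso [FeatureMap()], [readFeatureMap()]
#' @export
setClass("FeatureMap",
  representation(map = "data.frame",
                 cpgsByGene = "list", exonsByGene = "list",
                 isoformsByGene = "list", membersByIsoform = "list",
                 geneOfIsoform = "character"),
  validity = function(object) validFeatureMapFrame(object@map))

## Checks the long-format frame; shared by the class validity and the reader.
validFeatureMapFrame <- function(map) {
  msg <- character()
  need <- c("gene_id", "feature_kind", "feature_id", "parent_isoform_id")
  if (!all(need %in% names(map)))
    return(paste("feature map must have columns",
                 paste(need, collapse = ", ")))
  bad <- setdiff(unique(map$feature_kind), c("cpg", "exon", "isoform"))
  if (length(bad))
    msg <- c(msg, paste("unknown feature_kind:", paste(bad, collapse = ", ")))
  parent <- ifelse(is.na(map$parent_isoform_id), "", map$parent_isoform_id)
  if (any(map$feature_kind != "exon" & nzchar(parent)))
    msg <- c(msg, "parent_isoform_id is only allowed on exon rows")
  key <- paste(map$gene_id, map$feature_kind, map$feature_id, parent, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, paste("duplicated feature map row:",
                        key[duplicated(key)][1L]))
  ## isoform membership referential integrity
  isoKey <- paste(map$gene_id, map$feature_id, sep = "\r")[
    map$feature_kind == "isoform"]
  exonKey <- paste(map$gene_id, map$feature_id, sep = "\r")[
    map$feature_kind == "exon" & !nzchar(parent)]
  mem <- map[map$feature_kind == "exon" & nzchar(parent), , drop = FALSE]
  if (nrow(mem)) {
    miss <- !(paste(mem$gene_id, mem$parent_isoform_id, sep = "\r") %in% isoKey)
    if (any(miss))
      msg <- c(msg, sprintf(
        "isoform '%s' referenced as parent but not declared for gene '%s'",
        mem$parent_isoform_id[miss][1L], mem$gene_id[miss][1L]))
    lost <- !(paste(mem$gene_id, mem$feature_id, sep = "\r") %in% exonKey)
    if (any(lost))
      msg <- c(msg, sprintf(
        "member exon '%s' of isoform '%s' is not an exon of gene '%s'",
        mem$feature_id[lost][1L], mem$parent_isoform_id[lost][1L],
        mem$gene_id[lost][1L]))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

## ---------------------------------------------------------------------------
## MethSpliceDataSet
## ---------------------------------------------------------------------------

#' Container for one multi-cancer methylation/expression/survival dataset
#'
#' Bundles the five inputs every downstream stage consumes: a CpG beta-value
#' matrix, log-scale gene/exon/isoform expression matrices (features in rows,
#' samples in columns), the sample-to-cancer table, the clinical
#' time/event table and the [FeatureMap-class].  Validity enforces the
#' invariants the screens rely on: beta values in [0, 1], non-negative finite
#' expression, unique labels, and column/sample agreement across tables.
#'
#' @slot meth numeric matrix of beta values (CpG x sample), NAs allowed.
#' @slot geneExpr,exonExpr,isoformExpr numeric matrices of log-scale
#'   expression (feature x sample).
#' @slot samples data.frame with columns \code{sample_id}, \code{cancer_type}.
#' @slot clinical data.frame with columns \code{sample_id}, \code{time},
#'   \code{event}.
#' @slot map a [FeatureMap-class].
#'
#' @seealso [MethSpliceDataSet()], [simulateDataset()]
#' @export
setClass("MethSpliceDataSet",
  representation(meth = "matrix", geneExpr = "matrix", exonExpr = "matrix",
                 isoformExpr = "matrix", samples = "data.frame",
                 clinical = "data.frame", map = "FeatureMap"),
  validity = function(object) {
    msg <- character()
    sid <- object@samples$sample_id
    if (is.null(sid) || anyDuplicated(sid))
      msg <- c(msg, "sample_ids must be present and unique")
    if (is.null(object@samples$cancer_type) ||
        anyNA(object@samples$cancer_type))
      msg <- c(msg, "every sample needs a cancer_type")
    for (nm in c("meth", "geneExpr", "exonExpr", "isoformExpr")) {
      m <- slot(object, nm)
      if (anyDuplicated(rownames(m)))
        msg <- c(msg, sprintf("duplicated feature ids in %s", nm))
      if (!setequal(colnames(m), sid))
        msg <- c(msg, sprintf("%s columns do not match the sample table", nm))
    }
    v <- object@meth
    if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, "beta values outside [0,1]")
    for (nm in c("geneExpr", "exonExpr", "isoformExpr")) {
      m <- slot(object, nm)
      if (any(!is.finite(m) & !is.na(m)) || any(m < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("%s must be finite and >= 0", nm))
    }
    cl <- object@clinical
    if (nrow(cl)) {
      if (!all(c("sample_id", "time", "event") %in% names(cl)))
        msg <- c(msg, "clinical needs sample_id, time, event")
      else {
        if (any(cl$time < 0, na.rm = TRUE))
          msg <- c(msg, "clinical time must be >= 0")
        if (!all(cl$event %in% c(0, 1)))
          msg <- c(msg, "clinical event must be 0/1")
        if (!all(cl$sample_id %in% sid))
          msg <- c(msg, "clinical rows refer to unknown samples")
      }
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic multi-omics generator
#'
#' See [simConfig()] for the user-facing constructor and the meaning and
#' default of every field.
#'
#' @export
setClass("SimConfig",
  representation(nCancers = "integer", samplesPerCancer = "integer",
                 nGenes = "integer", cpgsPerGene = "integer",
                 exonsPerGene = "integer", isoformsPerGene = "integer",
                 fracExpressed = "numeric", effectR = "numeric",
                 fracPlanted = "numeric", signConsistency = "numeric",
                 fracDriverCpgs = "numeric", hazardRatio = "numeric",
                 censorRate = "numeric", isoformNoiseSd = "numeric",
                 driversFromPlanted = "logical", seed = "integer"),
  prototype(nCancers = 3L, samplesPerCancer = 60L, nGenes = 200L,
            cpgsPerGene = 22L, exonsPerGene = 10L, isoformsPerGene = 4L,
            fracExpressed = 0.6, effectR = 0.7, fracPlanted = 0.05,
            signConsistency = 0.8, fracDriverCpgs = 0.005,
            hazardRatio = 3, censorRate = 0.02, isoformNoiseSd = 0.5,
            driversFromPlanted = TRUE, seed = 1L),
  validity = function(object) {
    msg <- character()
    fr <- c(fracExpressed = object@fracExpressed,
            fracPlanted = object@fracPlanted,
            signConsistency = object@signConsistency,
            fracDriverCpgs = object@fracDriverCpgs)
    bad <- fr < 0 | fr > 1
    if (any(bad))
      msg <- c(msg, paste(names(fr)[bad][1L], "must be in [0,1]"))
    cnt <- c(nCancers = object@nCancers,
             samplesPerCancer = object@samplesPerCancer,
             nGenes = object@nGenes, cpgsPerGene = object@cpgsPerGene,
             exonsPerGene = object@exonsPerGene,
             isoformsPerGene = object@isoformsPerGene)
    if (any(cnt < 1L))
      msg <- c(msg, paste(names(cnt)[cnt < 1L][1L], "must be >= 1"))
    if (object@effectR <= 0 || object@effectR >= 1)
      msg <- c(msg, "effectR must be in (0,1)")
    if (object@hazardRatio <= 0) msg <- c(msg, "hazardRatio must be > 0")
    if (object@censorRate < 0) msg <- c(msg, "censorRate must be >= 0")
    if (object@isoformNoiseSd < 0) msg <- c(msg, "isoformNoiseSd must be >= 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

## ---------------------------------------------------------------------------
## SimTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated dataset
#'
#' Records everything the generator planted so downstream stages can be
#' scored: the per-cancer planted CpG-exon effects with their signs, the
#' survival-driver CpGs, and the per-sample high/low expression-mode labels
#' for every gene.
#'
#' @slot plantedPairs data.frame(cancer, gene, cpg, exon, sign) with sign
#'   +1/-1, one row per planted effect per cancer.
#' @slot driverCpgs data.frame(gene, cpg) of CpGs whose methylation scales
#'   the hazard.
#' @slot modeLabels logical matrix (gene x sample), TRUE = high-expression
#'   mode.
#' @slot genes character vector, the gene universe of the simulated map.
#'
#' @seealso [simulateDataset()], [writeTruth()], [readTruth()]
#' @export
setClass("SimTruth",
  representation(plantedPairs = "data.frame", driverCpgs = "data.frame",
                 modeLabels = "matrix", genes = "character"),
  validity = function(object) {
    msg <- character()
    pp <- object@plantedPairs
    if (nrow(pp) && !all(pp$gene %in% object@genes))
      msg <- c(msg, sprintf("planted pair references unknown gene '%s'",
                            setdiff(pp$gene, object@genes)[1L]))
    dc <- object@driverCpgs
    if (nrow(dc) && !all(dc$gene %in% object@genes))
      msg <- c(msg, sprintf("driver CpG references unknown gene '%s'",
                            setdiff(dc$gene, object@genes)[1L]))
    if (nrow(pp) && !all(abs(pp$sign) == 1))
      msg <- c(msg, "planted signs must be +1/-1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })

## ---------------------------------------------------------------------------
## StepFit
## ---------------------------------------------------------------------------

#' One-step (two-level) fit to sorted values
#'
#' Result of [fitStep()].  \code{splitIndex} counts the values assigned to
#' the low segment of the sorted vector; \code{threshold} is the midpoint of
#' the two segment means.  A fit is \code{degenerate} when no split improves
#' on the flat single-mean fit (constant data), in which case the threshold
#' is \code{NA} and [binarize()] labels everything low.
#'
#' @export
setClass("StepFit",
  representation(splitIndex = "integer", lowMean = "numeric",
                 highMean = "numeric", threshold = "numeric",
                 sse = "numeric", degenerate = "logical", n = "integer"),
  validity = function(object) {
    if (object@degenerate) return(TRUE)
    msg <- character()
    if (object@splitIndex < 1L || object@splitIndex > object@n - 1L)
      msg <- c(msg, "splitIndex out of range")
    if (object@lowMean > object@highMean)
      msg <- c(msg, "lowMean must be <= highMean")
    if (object@sse < -1e-8) msg <- c(msg, "sse must be >= 0")
    if (!(object@threshold > object@lowMean &&
          object@threshold < object@highMean))
      msg <- c(msg, "threshold must lie strictly between the segment means")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
  })
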