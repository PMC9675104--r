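## Constructors, generics, accessors and show methods.

#' Construct a FeatureMap from the long-format frame
#'
#' @param map data.frame with columns \code{gene_id}, \code{feature_kind}
#'   (\code{cpg}/\code{exon}/\code{isoform}), \code{feature_id},
#'   \code{parent_isoform_id} (\code{""} or \code{NA} when none).  Exon rows
#'   with a parent isoform declare membership; their row order gives the
#'   ordered member-exon list of the isoform.
#' @return A [FeatureMap-class] with precomputed per-gene lookups.
#' @examples
#' fm <- FeatureMap(data.frame(
#'   gene_id = c("g1", "g1", "g1", "g1"),
#'   feature_kind = c("cpg", "exon", "isoform", "exon"),
#'   feature_id = c("cg00000001", "chr1:100-200:+", "iso1", "chr1:100-200:+"),
#'   parent_isoform_id = c("", "", "", "iso1")))
#' exonIds(fm, "g1")
#' @export
FeatureMap <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$parent_isoform_id <- ifelse(is.na(map$parent_isoform_id), "",
                                  as.character(map$parent_isoform_id))
  for (col in c("gene_id", "feature_kind", "feature_id"))
    map[[col]] <- as.character(map[[col]])
  chk <- validFeatureMapFrame(map)
  if (!isTRUE(chk)) stop(chk)
  ## validate exon id syntax once, up front
  exon_ids <- unique(map$feature_id[map$feature_kind == "exon"])
  for (eid in exon_ids) parseExonId(eid)
  base <- map[!nzchar(map$parent_isoform_id), , drop = FALSE]
  mem <- map[nzchar(map$parent_isoform_id), , drop = FALSE]
  splitBy <- function(kind) {
    sub <- base[base$feature_kind == kind, , drop = FALSE]
    lapply(split(sub$feature_id, sub$gene_id), unique)
  }
  membersByIsoform <- lapply(split(mem$feature_id, mem$parent_isoform_id),
                             identity)
  iso <- base[base$feature_kind == "isoform", , drop = FALSE]
  geneOfIsoform <- stats::setNames(iso$gene_id, iso$feature_id)
  new("FeatureMap", map = map,
      cpgsByGene = splitBy("cpg"), exonsByGene = splitBy("exon"),
      isoformsByGene = splitBy("isoform"),
      membersByIsoform = membersByIsoform, geneOfIsoform = geneOfIsoform)
}

#' @rdname featureMapAccessors
#' @export
setGeneric("mapGenes", function(x) standardGeneric("mapGenes"))
#' @rdname featureMapAccessors
#' @export
setGeneric("cpgIds", function(x, gene) standardGeneric("cpgIds"))
#' @rdname featureMapAccessors
#' @export
setGeneric("exonIds", function(x, gene) standardGeneric("exonIds"))
#' @rdname featureMapAccessors
#' @export
setGeneric("isoformIds", function(x, gene) standardGeneric("isoformIds"))
#' @rdname featureMapAccessors
#' @export
setGeneric("isoformMembers", function(x, isoform) {
  standardGeneric("isoformMembers")
})

#' Query a FeatureMap
#'
#' Accessors for the per-gene feature lookups: \code{mapGenes} lists all
#' genes, \code{cpgIds}/\code{exonIds}/\code{isoformIds} the features of one
#' gene, and \code{isoformMembers} the ordered member-exon ids of one
#' isoform (or of every isoform when \code{isoform} is missing).
#'
#' @param x a [FeatureMap-class].
#' @param gene,isoform character(1) feature keys.
#' @name featureMapAccessors
NULL

#' @rdname featureMapAccessors
setMethod("mapGenes", "FeatureMap", function(x) {
  sort(unique(x@map$gene_id))
})
#' @rdname featureMapAccessors
setMethod("cpgIds", "FeatureMap", function(x, gene) {
  x@cpgsByGene[[gene]] %||% character()
})
#' @rdname featureMapAccessors
setMethod("exonIds", "FeatureMap", function(x, gene) {
  x@exonsByGene[[gene]] %||% character()
})
#' @rdname featureMapAccessors
setMethod("isoformIds", "FeatureMap", function(x, gene) {
  x@isoformsByGene[[gene]] %||% character()
})
#' @rdname featureMapAccessors
setMethod("isoformMembers", "FeatureMap", function(x, isoform) {
  if (missing(isoform)) return(x@membersByIsoform)
  x@membersByIsoform[[isoform]] %||% character()
})

setMethod("show", "FeatureMap", function(object) {
  k <- table(factor(object@map$feature_kind[
    !nzchar(object@map$parent_isoform_id)],
    levels = c("cpg", "exon", "isoform")))
  cat(sprintf("FeatureMap: %d genes | %d CpGs, %d exons, %d isoforms\n",
              length(unique(object@map$gene_id)), k[["cpg"]], k[["exon"]],
              k[["isoform"]]))
})

## ---------------------------------------------------------------------------

#' Construct a MethSpliceDataSet
#'
#' @param meth CpG x sample beta-value matrix (values in [0,1], NAs allowed).
#' @param geneExpr,exonExpr,isoformExpr feature x sample log-scale expression
#'   matrices sharing the sample set of \code{meth}.
#' @param samples data.frame(sample_id, cancer_type).
#' @param clinical data.frame(sample_id, time, event); may be empty.
#' @param map a [FeatureMap-class].
#' @return A validated [MethSpliceDataSet-class].
#' @export
MethSpliceDataSet <- function(meth, geneExpr, exonExpr, isoformExpr,
                              samples, clinical, map) {
  new("MethSpliceDataSet", meth = meth, geneExpr = geneExpr,
      exonExpr = exonExpr, isoformExpr = isoformExpr,
      samples = as.data.frame(samples), clinical = as.data.frame(clinical),
      map = map)
}

#' @rdname datasetAccessors
#' @export
setGeneric("methBeta", function(x) standardGeneric("methBeta"))
#' @rdname datasetAccessors
#' @export
setGeneric("exprMatrix", function(x, kind = "gene") {
  standardGeneric("exprMatrix")
})
#' @rdname datasetAccessors
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))
#' @rdname datasetAccessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @rdname datasetAccessors
#' @export
setGeneric("featureMap", function(x) standardGeneric("featureMap"))

#' Access the parts of a MethSpliceDataSet
#'
#' @param x a [MethSpliceDataSet-class].
#' @param kind which expression matrix: \code{"gene"}, \code{"exon"} or
#'   \code{"isoform"}.
#' @name datasetAccessors
NULL

#' @rdname datasetAccessors
setMethod("methBeta", "MethSpliceDataSet", function(x) x@meth)
#' @rdname datasetAccessors
setMethod("exprMatrix", "MethSpliceDataSet", function(x, kind = "gene") {
  kind <- match.arg(kind, c("gene", "exon", "isoform"))
  slot(x, paste0(kind, "Expr"))
})
#' @rdname datasetAccessors
setMethod("sampleTable", "MethSpliceDataSet", function(x) x@samples)
#' @rdname datasetAccessors
setMethod("clinicalTable", "MethSpliceDataSet", function(x) x@clinical)
#' @rdname datasetAccessors
setMethod("featureMap", "MethSpliceDataSet", function(x) x@map)

setMethod("show", "MethSpliceDataSet", function(object) {
  ct <- table(object@samples$cancer_type)
  cat("MethSpliceDataSet\n")
  cat(sprintf("  %d samples in %d cancer types (%s)\n",
              nrow(object@samples), length(ct),
              paste(sprintf("%s: %d", names(ct), ct), collapse = ", ")))
  cat(sprintf("  methylation: %d CpGs | expression: %d genes, %d exons, %d isoforms\n",
              nrow(object@meth), nrow(object@geneExpr),
              nrow(object@exonExpr), nrow(object@isoformExpr)))
  cat(sprintf("  clinical follow-up for %d samples\n", nrow(object@clinical)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d cancers x %d samples, %d genes (%d CpGs, %d exons, %d isoforms each)\n",
    object@nCancers, object@samplesPerCancer, object@nGenes,
    object@cpgsPerGene, object@exonsPerGene, object@isoformsPerGene))
  cat(sprintf(
    "  fracExpressed=%.2f effectR=%.2f fracPlanted=%.3f signConsistency=%.2f\n",
    object@fracExpressed, object@effectR, object@fracPlanted,
    object@signConsistency))
  cat(sprintf(
    "  drivers: frac=%.3f from %s CpGs, hazardRatio=%.2f censorRate=%.3f | seed=%d\n",
    object@fracDriverCpgs,
    if (object@driversFromPlanted) "planted" else "non-planted",
    object@hazardRatio, object@censorRate, object@seed))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d planted CpG-exon effects (%d unique pairs), %d driver CpGs, %d genes\n",
    nrow(object@plantedPairs),
    nrow(unique(object@plantedPairs[c("cpg", "exon")])),
    nrow(object@driverCpgs), length(object@genes)))
})

setMethod("show", "StepFit", function(object) {
  if (object@degenerate) {
    cat(sprintf("StepFit (degenerate): n=%d, flat mean %.4g\n",
                object@n, object@lowMean))
  } else {
    cat(sprintf(
      "StepFit: n=%d, split=%d, means %.4g / %.4g, threshold %.4g, sse %.4g\n",
      object@n, object@splitIndex, object@lowMean, object@highMean,
      object@threshold, object@sse))
  }
})

setMethod("show", "ExonLocus", function(object) {
  cat(sprintf("ExonLocus %s (%s:%d-%d, strand %s)\n", object@exonId,
              object@chrom, object@start, object@end, object@strand))
})

## ---------------------------------------------------------------------------

#' Configure the synthetic multi-omics generator
#'
#' Builds a [SimConfig-class] for [simulateDataset()].  Defaults describe the
#' package's demo conditions: 3 cancer cohorts of 60 samples, 200 genes with
#' 22 CpGs and 10 exons each (the 450K-array averages of ~22 CpGs and ~9.65
#' exons per gene, rounded to an integer exon count), bimodal gene
#' expression with 60% of samples in the high mode, planted CpG-exon effects
#' of |r| = 0.7 on 5% of pairs keeping their sign across cancers with
#' probability 0.8, and a small set of survival-driver CpGs at hazard ratio 3.
#'
#' @param nCancers,samplesPerCancer,nGenes,cpgsPerGene,exonsPerGene,isoformsPerGene
#'   cohort and annotation sizes (integers >= 1).
#' @param fracExpressed fraction of samples per gene drawn from the
#'   high-expression mode.
#' @param effectR target absolute Pearson correlation of planted CpG-exon
#'   effects, in (0,1).
#' @param fracPlanted fraction of CpG-exon pairs per gene that receive a
#'   planted effect (at most one planted CpG per exon).
#' @param signConsistency probability that a planted pair keeps its base
#'   sign in each cancer beyond the first.
#' @param fracDriverCpgs fraction of eligible CpGs whose methylation scales
#'   the hazard (eligible = planted by default, with a balanced methylated
#'   fraction).
#' @param hazardRatio hazard multiplier per methylated driver CpG.
#' @param censorRate exponential censoring rate (per time unit).
#' @param isoformNoiseSd sd of the independent noise added to isoform
#'   expression (the dilution knob).
#' @param driversFromPlanted if \code{FALSE}, drivers are drawn from
#'   non-planted CpGs instead (independence control for enrichment checks).
#' @param seed integer master seed; the generator is bit-reproducible.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(nCancers = 3L, samplesPerCancer = 60L, nGenes = 200L,
                      cpgsPerGene = 22L, exonsPerGene = 10L,
                      isoformsPerGene = 4L, fracExpressed = 0.6,
                      effectR = 0.7, fracPlanted = 0.05,
                      signConsistency = 0.8, fracDriverCpgs = 0.005,
                      hazardRatio = 3, censorRate = 0.02,
                      isoformNoiseSd = 0.5, driversFromPlanted = TRUE,
                      seed = 1L) {
  cfg <- new("SimConfig", nCancers = as.integer(nCancers),
             samplesPerCancer = as.integer(samplesPerCancer),
             nGenes = as.integer(nGenes),
             cpgsPerGene = as.integer(cpgsPerGene),
             exonsPerGene = as.integer(exonsPerGene),
             isoformsPerGene = as.integer(isoformsPerGene),
             fracExpressed = fracExpressed, effectR = effectR,
             fracPlanted = fracPlanted, signConsistency = signConsistency,
             fracDriverCpgs = fracDriverCpgs, hazardRatio = hazardRatio,
             censorRate = censorRate, isoformNoiseSd = isoformNoiseSd,
             driversFromPlanted = driversFromPlanted, seed = as.integer(seed))
  if (cfg@samplesPerCancer < 10L)
    warning("samplesPerCancer < 10: downstream screens will skip all genes ",
            "(minimum-cohort rule)")
  cfg
}
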