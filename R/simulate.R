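## Synthetic multi-cancer multi-omics generator.  Emits the structural
## assumptions the analysis exploits -- bimodal gene expression so a step fit
## separates high/low cohorts, per-CpG bimodal beta values in [0,1], planted
## linear CpG->exon effects with configurable cross-cancer sign consistency,
## isoforms as noisy means of their member exons (which dilutes CpG-isoform
## correlation), and methylation-dependent survival hazards with exponential
## censoring -- together with a SimTruth object recording everything planted.
## One master seed governs all draws; per-gene substreams are derived
## deterministically from (seed, gene index) so gene subsets reproduce.

#' Simulate a multi-cancer methylation/expression/survival dataset
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return list with \code{dataset} (a [MethSpliceDataSet-class]) and
#'   \code{truth} (a [SimTruth-class]).
#' @details
#' Gene expression per sample is a two-component mixture: a low mode near 0
#' and a high mode near 8 (log2 scale), separated widely enough that the
#' step fit recovers mode membership.  Beta values are logistic-transformed
#' Gaussians around per-CpG methylated/unmethylated states, giving the
#' largely bimodal per-probe distributions typical of 450K arrays.  For each
#' planted (CpG, exon) pair and cancer, exon expression of high-mode samples
#' gains a linear term in the CpG's beta value scaled so the within-cohort
#' correlation is approximately +/- \code{effectR}; the first cancer carries
#' the pair's base sign and every further cancer keeps it with probability
#' \code{signConsistency}.  At most one CpG is planted per exon so planted
#' effects do not stack.  Driver CpGs multiply each sample's exponential
#' hazard by \code{hazardRatio} whenever their beta value exceeds 0.5;
#' drivers are drawn among planted CpGs (or non-planted ones when
#' \code{driversFromPlanted} is FALSE) whose methylated fraction is between
#' 0.2 and 0.8, since a near-constant CpG cannot define survival groups.
#' @examples
#' sim <- simulateDataset(simConfig(nGenes = 5L, nCancers = 2L,
#'                                  samplesPerCancer = 20L,
#'                                  cpgsPerGene = 4L, exonsPerGene = 3L,
#'                                  isoformsPerGene = 2L, seed = 7L))
#' sim$dataset
#' @export
simulateDataset <- function(config = simConfig()) {
  validObject(config)
  nC <- config@nCancers
  spc <- config@samplesPerCancer
  nS <- nC * spc
  nG <- config@nGenes
  nCpg <- config@cpgsPerGene
  nEx <- config@exonsPerGene
  nIso <- config@isoformsPerGene

  cancers <- sprintf("cancer%02d", seq_len(nC))
  sampleIds <- sprintf("s%05d", seq_len(nS))
  samples <- data.frame(sample_id = sampleIds,
                        cancer_type = rep(cancers, each = spc),
                        stringsAsFactors = FALSE)
  genes <- sprintf("g%04d", seq_len(nG))
  cancerIdx <- split(seq_len(nS), samples$cancer_type)

  meth <- matrix(NA_real_, nG * nCpg, nS,
                 dimnames = list(NULL, sampleIds))
  geneExpr <- matrix(0, nG, nS, dimnames = list(genes, sampleIds))
  exonExpr <- matrix(0, nG * nEx, nS, dimnames = list(NULL, sampleIds))
  isoExpr <- matrix(0, nG * nIso, nS, dimnames = list(NULL, sampleIds))
  modeLabels <- matrix(FALSE, nG, nS, dimnames = list(genes, sampleIds))
  methRowNames <- character(nG * nCpg)
  exonRowNames <- character(nG * nEx)
  isoRowNames <- character(nG * nIso)

  mapRows <- vector("list", nG)
  plantedRows <- vector("list", nG)
  driverRows <- vector("list", nG)
  qByCpg <- numeric(0)          # methylated fraction per CpG, for drivers

  effR <- config@effectR
  slope <- sqrt(effR^2 / (1 - effR^2))

  for (gi in seq_len(nG)) {
    set.seed(deriveSeed(config@seed, gi))
    g <- genes[gi]
    chrom <- sprintf("chr%d", (gi - 1L) %% 22L + 1L)
    strand <- if (gi %% 2L) "+" else "-"
    base <- 1e6 * gi
    exStart <- as.integer(base + (seq_len(nEx) - 1L) * 1000L)
    exIds <- sprintf("%s:%d-%d:%s", chrom, exStart, exStart + 150L, strand)
    cpgIdsG <- sprintf("cg%08d", (gi - 1L) * nCpg + seq_len(nCpg))
    isoIdsG <- sprintf("iso_%s_%d", g, seq_len(nIso))

    ## expression modes and gene expression
    high <- stats::runif(nS) < config@fracExpressed
    gv <- numeric(nS)
    gv[!high] <- abs(stats::rnorm(sum(!high), 0.3, 0.2))
    gv[high] <- pmax(0, stats::rnorm(sum(high), 8, 1))
    modeLabels[gi, ] <- high
    geneExpr[gi, ] <- gv

    ## beta values: per-CpG bimodal around methylated/unmethylated states
    q <- stats::runif(nCpg, 0.15, 0.85)
    B <- matrix(NA_real_, nCpg, nS)
    for (ci in seq_len(nCpg)) {
      state <- stats::runif(nS) < q[ci]
      B[ci, ] <- stats::plogis(stats::rnorm(nS, ifelse(state, 1.5, -1.5),
                                            0.7))
    }
    qByCpg[cpgIdsG] <- q

    ## exon baselines: follow the gene in the high mode, near zero otherwise
    E <- matrix(0, nEx, nS)
    off <- stats::rnorm(nEx, 0, 0.5)
    for (ei in seq_len(nEx)) {
      v <- numeric(nS)
      v[!high] <- abs(stats::rnorm(sum(!high), 0.2, 0.15))
      v[high] <- pmax(0, gv[high] + off[ei] + stats::rnorm(sum(high), 0, 0.8))
      E[ei, ] <- v
    }

    ## planted CpG->exon effects (at most one CpG per exon)
    nPlant <- min(nEx, nCpg, round(config@fracPlanted * nCpg * nEx))
    planted <- NULL
    if (nPlant > 0L) {
      exSel <- sample.int(nEx, nPlant)
      cpgSel <- sample.int(nCpg, nPlant)
      baseSign <- sample(c(-1, 1), nPlant, replace = TRUE)
      rows <- vector("list", nC * nPlant)
      ri <- 0L
      for (ci in seq_len(nC)) {
        keep <- if (ci == 1L) rep(TRUE, nPlant) else
          stats::runif(nPlant) < config@signConsistency
        sgn <- ifelse(keep, baseSign, -baseSign)
        idx <- intersect(cancerIdx[[cancers[ci]]], which(high))
        for (pi in seq_len(nPlant)) {
          if (length(idx) < 3L) next
          m <- B[cpgSel[pi], idx]
          bvals <- E[exSel[pi], idx]
          if (stats::sd(m) == 0 || stats::sd(bvals) == 0) next
          coef <- sgn[pi] * slope * stats::sd(bvals) / stats::sd(m)
          E[exSel[pi], idx] <- pmax(0, bvals + coef * (m - mean(m)))
          ri <- ri + 1L
          rows[[ri]] <- data.frame(cancer = cancers[ci], gene = g,
                                   cpg = cpgIdsG[cpgSel[pi]],
                                   exon = exIds[exSel[pi]], sign = sgn[pi],
                                   stringsAsFactors = FALSE)
        }
      }
      planted <- if (ri) do.call(rbind, rows[seq_len(ri)]) else NULL
    }
    plantedRows[[gi]] <- planted

    ## driver CpGs
    plantedCpgs <- if (is.null(planted)) character() else unique(planted$cpg)
    balanced <- cpgIdsG[q >= 0.2 & q <= 0.8]
    if (config@driversFromPlanted) {
      elig <- intersect(plantedCpgs, balanced)
      pDrive <- config@fracDriverCpgs
    } else {
      elig <- setdiff(balanced, plantedCpgs)
      nPlantedElig <- length(intersect(plantedCpgs, balanced))
      pDrive <- config@fracDriverCpgs * nPlantedElig / max(1L, length(elig))
    }
    drv <- elig[stats::runif(length(elig)) < pDrive]
    if (length(drv))
      driverRows[[gi]] <- data.frame(gene = g, cpg = drv,
                                     stringsAsFactors = FALSE)

    ## isoforms: noisy means of contiguous member-exon windows
    members <- vector("list", nIso)
    for (ii in seq_len(nIso)) {
      len <- sample.int(nEx, 1L)
      st <- if (len < nEx) sample.int(nEx - len + 1L, 1L) else 1L
      members[[ii]] <- exIds[st:(st + len - 1L)]
      v <- colMeans(E[st:(st + len - 1L), , drop = FALSE]) +
        stats::rnorm(nS, 0, config@isoformNoiseSd)
      isoExpr[(gi - 1L) * nIso + ii, ] <- pmax(0, v)
    }

    meth[(gi - 1L) * nCpg + seq_len(nCpg), ] <- B
    exonExpr[(gi - 1L) * nEx + seq_len(nEx), ] <- E
    methRowNames[(gi - 1L) * nCpg + seq_len(nCpg)] <- cpgIdsG
    exonRowNames[(gi - 1L) * nEx + seq_len(nEx)] <- exIds
    isoRowNames[(gi - 1L) * nIso + seq_len(nIso)] <- isoIdsG

    mapRows[[gi]] <- rbind(
      data.frame(gene_id = g, feature_kind = "cpg", feature_id = cpgIdsG,
                 parent_isoform_id = "", stringsAsFactors = FALSE),
      data.frame(gene_id = g, feature_kind = "exon", feature_id = exIds,
                 parent_isoform_id = "", stringsAsFactors = FALSE),
      data.frame(gene_id = g, feature_kind = "isoform", feature_id = isoIdsG,
                 parent_isoform_id = "", stringsAsFactors = FALSE),
      data.frame(gene_id = g, feature_kind = "exon",
                 feature_id = unlist(members),
                 parent_isoform_id = rep(isoIdsG, lengths(members)),
                 stringsAsFactors = FALSE))
  }
  rownames(meth) <- methRowNames
  rownames(exonExpr) <- exonRowNames
  rownames(isoExpr) <- isoRowNames

  planted <- do.call(rbind, c(plantedRows[!vapply(plantedRows, is.null,
                                                  logical(1))],
                              list(data.frame(cancer = character(),
                                              gene = character(),
                                              cpg = character(),
                                              exon = character(),
                                              sign = numeric()))))
  drivers <- do.call(rbind, c(driverRows[!vapply(driverRows, is.null,
                                                 logical(1))],
                              list(data.frame(gene = character(),
                                              cpg = character()))))

  ## survival: exponential hazard scaled by hazardRatio per methylated driver
  set.seed(deriveSeed(config@seed, nG + 1L))
  h0 <- 0.1
  mult <- rep(1, nS)
  if (nrow(drivers)) {
    methylated <- meth[drivers$cpg, , drop = FALSE] > 0.5
    mult <- config@hazardRatio ^ colSums(methylated)
  }
  tDeath <- stats::rexp(nS, rate = h0 * mult)
  tCens <- if (config@censorRate > 0)
    stats::rexp(nS, rate = config@censorRate) else rep(Inf, nS)
  clinical <- data.frame(sample_id = sampleIds,
                         time = pmin(tDeath, tCens),
                         event = as.integer(tDeath <= tCens),
                         stringsAsFactors = FALSE)

  map <- FeatureMap(do.call(rbind, mapRows))
  dataset <- MethSpliceDataSet(meth = meth, geneExpr = geneExpr,
                               exonExpr = exonExpr, isoformExpr = isoExpr,
                               samples = samples, clinical = clinical,
                               map = map)
  truth <- new("SimTruth", plantedPairs = planted, driverCpgs = drivers,
               modeLabels = modeLabels, genes = genes)
  list(dataset = dataset, truth = truth)
}

## ---------------------------------------------------------------------------
## truth round-trip
## ---------------------------------------------------------------------------

#' Write or read a SimTruth as tab-separated text
#'
#' One long file with a \code{record_type} column: \code{gene} rows list the
#' gene universe, \code{planted} rows the per-cancer planted effects,
#' \code{driver} rows the driver CpGs and \code{mode} rows the per-sample
#' expression-mode labels.  The round trip is lossless.
#'
#' @param truth a [SimTruth-class].
#' @param path file path.
#' @export
writeTruth <- function(truth, path) {
  validObject(truth)
  empty <- function(...) rep(NA_character_, ...)
  pp <- truth@plantedPairs
  dc <- truth@driverCpgs
  ml <- truth@modeLabels
  rows <- list(
    data.frame(record_type = "gene", cancer = NA_character_,
               gene = truth@genes, cpg = NA_character_,
               exon = NA_character_, sign = NA_real_,
               sample = NA_character_, high = NA, stringsAsFactors = FALSE))
  if (nrow(pp))
    rows <- c(rows, list(data.frame(
      record_type = "planted", cancer = pp$cancer, gene = pp$gene,
      cpg = pp$cpg, exon = pp$exon, sign = pp$sign, sample = NA_character_,
      high = NA, stringsAsFactors = FALSE)))
  if (nrow(dc))
    rows <- c(rows, list(data.frame(
      record_type = "driver", cancer = NA_character_, gene = dc$gene,
      cpg = dc$cpg, exon = NA_character_, sign = NA_real_,
      sample = NA_character_, high = NA, stringsAsFactors = FALSE)))
  if (length(ml))
    rows <- c(rows, list(data.frame(
      record_type = "mode", cancer = NA_character_,
      gene = rep(rownames(ml), times = ncol(ml)), cpg = NA_character_,
      exon = NA_character_, sign = NA_real_,
      sample = rep(colnames(ml), each = nrow(ml)),
      high = as.vector(ml), stringsAsFactors = FALSE)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genes <- df$gene[df$record_type == "gene"]
  pp <- df[df$record_type == "planted",
           c("cancer", "gene", "cpg", "exon", "sign")]
  pp$sign <- as.numeric(pp$sign)
  dc <- df[df$record_type == "driver", c("gene", "cpg")]
  md <- df[df$record_type == "mode", c("gene", "sample", "high")]
  if (nrow(md)) {
    gl <- unique(md$gene)
    sl <- unique(md$sample)
    ml <- matrix(FALSE, length(gl), length(sl), dimnames = list(gl, sl))
    ml[cbind(md$gene, md$sample)] <- md$high
  } else {
    ml <- matrix(FALSE, 0L, 0L)
  }
  rownames(pp) <- NULL
  rownames(dc) <- NULL
  truth <- new("SimTruth", plantedPairs = pp, driverCpgs = dc,
               modeLabels = ml, genes = genes)
  validObject(truth)
  truth
}

#' Write a full dataset as the pipeline's on-disk formats
#'
#' Emits \code{methylation.tsv}, \code{gene_expr.tsv}, \code{exon_expr.tsv},
#' \code{isoform_expr.tsv}, \code{feature_map.tsv}, \code{samples.tsv} and
#' \code{clinical.tsv} into \code{dir}.
#'
#' @param dataset a [MethSpliceDataSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    methylation = file.path(dir, "methylation.tsv"),
    gene_expr = file.path(dir, "gene_expr.tsv"),
    exon_expr = file.path(dir, "exon_expr.tsv"),
    isoform_expr = file.path(dir, "isoform_expr.tsv"),
    feature_map = file.path(dir, "feature_map.tsv"),
    samples = file.path(dir, "samples.tsv"),
    clinical = file.path(dir, "clinical.tsv"))
  writeOmicsMatrix(methBeta(dataset), paths[["methylation"]], "cpg_id")
  writeOmicsMatrix(exprMatrix(dataset, "gene"), paths[["gene_expr"]],
                   "gene_id")
  writeOmicsMatrix(exprMatrix(dataset, "exon"), paths[["exon_expr"]],
                   "exon_id")
  writeOmicsMatrix(exprMatrix(dataset, "isoform"), paths[["isoform_expr"]],
                   "isoform_id")
  writeFeatureMap(featureMap(dataset), paths[["feature_map"]])
  writeSampleTable(sampleTable(dataset), paths[["samples"]])
  writeClinicalTable(clinicalTable(dataset), paths[["clinical"]])
  invisible(paths)
}

#' Read a full dataset from a directory written by [writeDataset()]
#'
#' @param dir directory containing the seven pipeline input files.
#' @return a [MethSpliceDataSet-class].
#' @export
readDataset <- function(dir) {
  MethSpliceDataSet(
    meth = readOmicsMatrix(file.path(dir, "methylation.tsv"), "methylation"),
    geneExpr = readOmicsMatrix(file.path(dir, "gene_expr.tsv"), "gene"),
    exonExpr = readOmicsMatrix(file.path(dir, "exon_expr.tsv"), "exon"),
    isoformExpr = readOmicsMatrix(file.path(dir, "isoform_expr.tsv"),
                                  "isoform"),
    samples = readSampleTable(file.path(dir, "samples.tsv")),
    clinical = readClinicalTable(file.path(dir, "clinical.tsv")),
    map = readFeatureMap(file.path(dir, "feature_map.tsv")))
}
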