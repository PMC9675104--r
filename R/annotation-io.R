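## Readers/writers for the delimited on-disk formats, exon-id parsing and the
## expression log transform.  All files are tab-separated text with headers;
## missing cells are written as "NA" and read back as NA (never as zero).

#' Read a feature-by-sample matrix from tab-separated text
#'
#' The first column holds feature ids, the header row sample ids.  For
#' \code{kind = "methylation"} every non-missing value must be a beta value
#' in [0, 1]; for expression kinds values must be finite and >= 0.
#' Duplicated feature or sample ids are a hard error naming the duplicate.
#'
#' @param path file path.
#' @param kind \code{"methylation"}, \code{"gene"}, \code{"exon"} or
#'   \code{"isoform"}; controls the value checks only.
#' @return numeric matrix with feature rownames and sample colnames.
#' @seealso [writeOmicsMatrix()]
#' @export
readOmicsMatrix <- function(path,
                            kind = c("methylation", "gene", "exon",
                                     "isoform")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  assertThat(ncol(df) >= 2L, "matrix file '%s' needs >= 2 columns", path)
  ids <- as.character(df[[1L]])
  sids <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stop(sprintf("duplicated feature id '%s' in %s",
                 ids[duplicated(ids)][1L], path))
  if (anyDuplicated(sids))
    stop(sprintf("duplicated sample id '%s' in %s",
                 sids[duplicated(sids)][1L], path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, sids)
  checkMatrixValues(m, kind)
  m
}

## value-domain checks shared by reader and dataset construction; errors name
## the offending cell
checkMatrixValues <- function(m, kind) {
  if (kind == "methylation") {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("beta value %g outside [0,1] at CpG '%s', sample '%s'",
                   m[bad[1L, 1L], bad[1L, 2L]],
                   rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  } else {
    bad <- which(!is.na(m) & (!is.finite(m) | m < 0), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "expression value %g not finite/non-negative at '%s', sample '%s'",
        m[bad[1L, 1L], bad[1L, 2L]],
        rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  invisible(TRUE)
}

#' Write a feature-by-sample matrix as tab-separated text
#'
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output file path.
#' @param idColumn header of the feature-id column.
#' @export
writeOmicsMatrix <- function(m, path, idColumn = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Parse and format exon identifiers
#'
#' Exon ids follow the \code{chrom:start-end:strand} convention, e.g.
#' \code{"chr3:118864997-118866434:+"}; coordinates are 1-based closed
#' intervals.  \code{formatExonId(parseExonId(x))} is the identity on valid
#' ids; malformed strings, \code{start > end} and strands outside
#' \code{+/-} are errors naming the offending token.
#'
#' @param exonId character(1) exon identifier.
#' @return \code{parseExonId}: an [ExonLocus-class];
#'   \code{formatExonId}: character(1).
#' @examples
#' loc <- parseExonId("chr11:2170356-2170833:-")
#' formatExonId(loc)
#' @export
parseExonId <- function(exonId) {
  assertThat(is.character(exonId) && length(exonId) == 1L,
             "exonId must be a single string")
  m <- regmatches(exonId,
                  regexec("^([^:]+):([0-9]+)-([0-9]+):([+-])$", exonId))[[1L]]
  if (length(m) != 5L)
    stop(sprintf("malformed exon id '%s' (expected chrom:start-end:strand)",
                 exonId))
  loc <- new("ExonLocus", exonId = exonId, chrom = m[2L],
             start = as.integer(m[3L]), end = as.integer(m[4L]),
             strand = m[5L])
  validObject(loc)
  loc
}

#' @param locus an [ExonLocus-class].
#' @rdname parseExonId
#' @export
formatExonId <- function(locus) {
  sprintf("%s:%d-%d:%s", locus@chrom, locus@start, locus@end, locus@strand)
}

#' Log-transform non-negative expression values
#'
#' Applies the conventional \code{log2(x + 1)} map for FPKM-like data, so 0
#' stays 0 and the transform is monotone.  Negative input is an error; NAs
#' pass through.
#'
#' @param x numeric vector/matrix of non-negative values.
#' @export
logTransform <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop(sprintf("negative expression value %g cannot be log-transformed",
                 min(x, na.rm = TRUE)))
  log2(x + 1)
}

## ---------------------------------------------------------------------------
## FeatureMap / sample / clinical tables
## ---------------------------------------------------------------------------

#' Read or write a FeatureMap in the long tab-separated format
#'
#' Columns: \code{gene_id}, \code{feature_kind}, \code{feature_id},
#' \code{parent_isoform_id} (blank when none).
#'
#' @param path file path.
#' @return \code{readFeatureMap}: a [FeatureMap-class].
#' @export
readFeatureMap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  FeatureMap(df)
}

#' @param map a [FeatureMap-class].
#' @rdname readFeatureMap
#' @export
writeFeatureMap <- function(map, path) {
  utils::write.table(map@map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write the sample table (sample_id, cancer_type)
#'
#' @param path file path.
#' @export
readSampleTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  assertThat(all(c("sample_id", "cancer_type") %in% names(df)),
             "sample table needs columns sample_id, cancer_type")
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicated sample_id '%s' in %s",
                 df$sample_id[duplicated(df$sample_id)][1L], path))
  df
}

#' @param samples data.frame(sample_id, cancer_type).
#' @rdname readSampleTable
#' @export
writeSampleTable <- function(samples, path) {
  utils::write.table(samples[c("sample_id", "cancer_type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write the clinical table (sample_id, time, event)
#'
#' \code{time} is a non-negative survival or censoring time; \code{event} is
#' 1 for an observed death and 0 for censoring.
#'
#' @param path file path.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assertThat(all(c("sample_id", "time", "event") %in% names(df)),
             "clinical table needs columns sample_id, time, event")
  df$sample_id <- as.character(df$sample_id)
  assertThat(all(df$time >= 0, na.rm = TRUE), "clinical time must be >= 0")
  assertThat(all(df$event %in% c(0, 1)), "clinical event must be 0/1")
  df
}

#' @param clinical data.frame(sample_id, time, event).
#' @rdname readClinicalTable
#' @export
writeClinicalTable <- function(clinical, path) {
  utils::write.table(clinical[c("sample_id", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-cancer CpG-exon pair table
#'
#' Parses the aggregated pair table produced by [collectPairs()] /
#' [rankPairs()] (tab-separated with at least the CpG, exon, gene, cancer
#' list, mean |r|, majority sign and consistency columns).  Published
#' supplementary pair tables in the same schema can be ingested through this
#' reader as well.
#'
#' @param path file path.
#' @return data.frame, one row per multi-cancer CpG-exon pair.
#' @export
readMultiCancerPairs <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(gsub("[^A-Za-z0-9]+", "_", names(df)))
  need <- c("cpg", "exon")
  assertThat(all(need %in% names(df)),
             "pair table needs at least columns CpG and Exon")
  if (anyDuplicated(df[c("cpg", "exon")]))
    warning("duplicated (cpg, exon) rows in pair table")
  df
}
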