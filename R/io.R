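#' Read an expression matrix from TSV
#'
#' Expects a dense tab-separated table: first column \code{feature_id}
#' (probe or gene identifiers), header row of sample ids, numeric body of
#' positive processed intensities. Gzip-compressed files are read
#' transparently. Values must be strictly positive after loading — relative
#' orderings need well-defined comparisons — so zeros are rejected unless a
#' pseudo-value \code{floor} is supplied to be added to every cell. Missing
#' or non-finite cells are always rejected rather than imputed.
#'
#' @param path TSV (optionally .gz) file path.
#' @param floor optional non-negative pseudo-value added to all cells before
#'   the positivity check.
#' @return numeric matrix, features x samples, dimnames from the file,
#'   row/column order preserved.
#' @seealso \code{\link{writeExpressionMatrix}}
#' @export
readExpressionMatrix <- function(path, floor = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    data.table::fread(text = readLines(gzfile(path)), sep = "\t",
                      header = TRUE, colClasses = list(character = 1L),
                      data.table = FALSE, showProgress = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = 1L),
                      data.table = FALSE, showProgress = FALSE)
  }
  if (ncol(dt) < 2L) stop("expected a feature_id column plus >=1 sample column")
  if (names(dt)[1L] != "feature_id")
    stop(sprintf("first column must be named 'feature_id', found '%s'",
                 names(dt)[1L]))
  ids <- dt[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate feature id: %s", ids[duplicated(ids)][1L]))
  samp <- names(dt)[-1L]
  if (anyDuplicated(samp))
    stop(sprintf("duplicate sample id: %s", samp[duplicated(samp)][1L]))
  for (j in seq_along(samp)) {
    col <- dt[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      if (is.na(bad)) bad <- which(is.na(col))[1L]
      stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                   ids[bad], samp[j]))
    }
  }
  x <- as.matrix(dt[, -1L, drop = FALSE])
  dimnames(x) <- list(ids, samp)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-finite value at feature '%s', sample '%s'",
                 ids[bad[1L]], samp[bad[2L]]))
  }
  if (!is.null(floor)) {
    stopifnot(is.numeric(floor), length(floor) == 1L, floor >= 0)
    x <- x + floor
  }
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-positive value at feature '%s', sample '%s'; supply 'floor' to add a pseudo-value",
      ids[bad[1L]], samp[bad[2L]]))
  }
  x
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}: first column
#' \code{feature_id}, one column per sample. Numbers are written at full
#' (round-trippable) precision.
#'
#' @param x genes x samples matrix with dimnames.
#' @param path output file path (.gz writes compressed).
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  x <- .asExprMatrix(x)
  out <- data.table::data.table(feature_id = rownames(x))
  # %.17g is the shortest representation guaranteed to round-trip a double
  for (j in seq_len(ncol(x)))
    out[[colnames(x)[j]]] <- sprintf("%.17g", x[, j])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV (\code{probe_id}, \code{gene_id}), one gene per row; a
#' probe listed on multiple rows has its gene assignments unioned before any
#' cardinality rule is applied.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{probe_id}, \code{gene_id},
#'   deduplicated.
#' @seealso \code{\link{collapseProbes}}
#' @export
readProbeGeneMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(dt)))
    stop("probe map must have columns 'probe_id' and 'gene_id'")
  unique(dt[, c("probe_id", "gene_id")])
}

#' Collapse probe-level measurements to gene level
#'
#' Each gene's value per sample is the arithmetic mean of all probes mapping
#' uniquely to it. Probes mapping to zero genes or to more than one gene are
#' discarded and contribute nothing. Every probe in the matrix must appear in
#' the map (a probe may appear with zero genes by mapping to the empty
#' string or NA).
#'
#' @param x probe-level expression matrix (probes x samples).
#' @param map data.frame with columns \code{probe_id}, \code{gene_id}
#'   (repeated probe rows allowed and unioned); empty-string or NA
#'   \code{gene_id} encodes "maps to no gene".
#' @return gene-level matrix, rows sorted by gene id.
#' @export
collapseProbes <- function(x, map) {
  x <- .asExprMatrix(x)
  stopifnot(is.data.frame(map),
            all(c("probe_id", "gene_id") %in% names(map)))
  map <- unique(map[, c("probe_id", "gene_id")])
  probes <- rownames(x)
  # a probe absent from the map altogether is an annotation error; a probe
  # whose only rows carry an empty/NA gene is a legitimate zero-gene probe
  missing <- setdiff(probes, unique(map$probe_id))
  if (length(missing))
    stop(sprintf("probe absent from map: %s", missing[1L]))
  map <- map[!is.na(map$gene_id) & map$gene_id != "", , drop = FALSE]
  ngenes <- table(map$probe_id)[probes]
  ngenes[is.na(ngenes)] <- 0L
  unique_probes <- probes[ngenes == 1L]
  if (!length(unique_probes))
    stop("no probe maps uniquely to a gene; nothing to collapse")
  gene_of <- map$gene_id[match(unique_probes, map$probe_id)]
  sums <- rowsum(x[unique_probes, , drop = FALSE], group = gene_of)
  counts <- as.vector(table(gene_of)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}

#' Read a sample annotation table
#'
#' TSV with required columns \code{sample_id} and \code{phenotype}, optional
#' \code{stage} (ordinal severity label) and \code{dataset_id}.
#'
#' @param path TSV file path.
#' @return data.frame, one row per sample.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(dt)))
    stop("annotation must have columns 'sample_id' and 'phenotype'")
  if (anyDuplicated(dt$sample_id))
    stop(sprintf("duplicate sample_id: %s",
                 dt$sample_id[duplicated(dt$sample_id)][1L]))
  dt
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line — name, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  fgsea::gmtPathways(path)
}

#' Write / read a signature file
#'
#' The signature file is the pipeline's single source of truth for scoring:
#' a TSV with columns \code{gene_a}, \code{gene_b}, \code{normal_direction},
#' \code{cancer_direction} (plus any support columns), preceded by
#' '#'-prefixed header lines carrying the build configuration and report as
#' JSON. \code{readSignature} restores the object losslessly.
#'
#' @param sig a \code{\link{PairSignature}}.
#' @param path file path.
#' @return \code{writeSignature}: \code{path} invisibly;
#'   \code{readSignature}: a \code{PairSignature}.
#' @export
writeSignature <- function(sig, path) {
  stopifnot(is(sig, "PairSignature"))
  hdr <- c(
    "# reosig signature v1",
    paste0("# build_config: ",
           jsonlite::toJSON(sig@buildConfig, auto_unbox = TRUE, digits = NA)),
    paste0("# build_report: ",
           jsonlite::toJSON(sig@buildReport, auto_unbox = TRUE, digits = NA)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(sig@pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  .json_of <- function(tag) {
    ln <- hdr[startsWith(hdr, paste0("# ", tag, ":"))]
    if (!length(ln)) return(list())
    jsonlite::fromJSON(sub(paste0("^# ", tag, ": "), "", ln[1L]),
                       simplifyDataFrame = FALSE)
  }
  pairs <- utils::read.table(text = body, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  new("PairSignature", pairs = pairs,
      buildConfig = .json_of("build_config"),
      buildReport = .json_of("build_report"))
}

#' Serialize a pair set to TSV
#'
#' Writes the pair table with '#' header lines recording the threshold,
#' sample count and phenotype (for a \code{StablePairSet}) or the group
#' labels (for a \code{ReversalPairSet}).
#'
#' @param object a \code{StablePairSet} or \code{ReversalPairSet}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writePairSet <- function(object, path) {
  hdr <- if (is(object, "StablePairSet")) {
    sprintf("# StablePairSet threshold=%g strict=%s n_samples=%d phenotype=%s",
            object@threshold, object@strict, object@nSamples,
            object@phenotype)
  } else if (is(object, "ReversalPairSet")) {
    sprintf("# ReversalPairSet group1=%s group2=%s",
            object@groupLabels[1L], object@groupLabels[2L])
  } else stop("unsupported object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(object@pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
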