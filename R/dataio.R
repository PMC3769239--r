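#' Read a genes x samples expression matrix from TSV
#'
#' The file must have a header row of sample ids, a first column named
#' \code{gene_id}, and numeric cells. The literal token \code{"NA"} denotes a
#' missing value; an empty cell is a format error (missingness must be
#' explicit), as is any other non-numeric cell.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene ids as rownames, sample ids as colnames
#'   and \code{NA} where the file had \code{"NA"}.
#' @export
readExpressionTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (nrow(df) == 0L) stop("format error: no data rows (header only)")
  if (ncol(df) < 2L) stop("format error: no sample columns")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("format error: duplicate gene id: ", dup[1L])
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("format error: duplicate sample id: ", dup[1L])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("format error: non-numeric cell '%s' at row %d (gene %s), column %s",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  }
  if (any(is.infinite(vals))) stop("format error: non-finite value")
  dimnames(vals) <- list(genes, samples)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{readExpressionTSV}}: full \code{\%.17g} precision so
#' the round trip is lossless, missing values written as \code{"NA"}.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @export
writeExpressionTSV <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  chr <- ifelse(is.na(mat), "NA", sprintf("%.17g", mat))
  dim(chr) <- dim(mat)
  lines <- c(
    paste(c("gene_id", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i)
      paste(c(rownames(mat)[i], chr[i, ]), collapse = "\t"), "")
  )
  writeLines(lines, path)
  invisible(NULL)
}

.parseMembership <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE), function(m) {
    m <- m[m != ""]
    bad <- setdiff(m, .DATASETS)
    if (length(bad))
      stop("validation error: unknown dataset token: ", bad[1L])
    sort(unique(m))
  })
}

#' Read a sample annotation manifest
#'
#' TSV with columns \code{sample_id}, \code{platform}, \code{cell_class},
#' \code{dataset_membership}, \code{study_id}. Membership is \code{"A"},
#' \code{"B"}, \code{"A|B"} or empty.
#'
#' @param path path to the manifest.
#' @return data frame with one row per sample; \code{dataset_membership} is a
#'   list column of character vectors (subsets of \{A, B\}).
#' @export
readAnnotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  need <- c("sample_id", "platform", "cell_class", "dataset_membership",
            "study_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing annotation columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$platform), .PLATFORMS)
  if (length(bad)) stop("validation error: unknown platform: ", bad[1L])
  bad <- setdiff(unique(df$cell_class), .CELL_CLASSES)
  if (length(bad)) stop("validation error: unknown cell_class: ", bad[1L])
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("validation error: duplicate sample id: ", dup[1L])
  data.frame(
    sample_id = df$sample_id,
    platform = df$platform,
    cell_class = df$cell_class,
    dataset_membership = I(.parseMembership(df$dataset_membership)),
    study_id = df$study_id,
    stringsAsFactors = FALSE
  )
}

#' @rdname readAnnotations
#' @param annotations data frame as returned by \code{readAnnotations}.
#' @export
writeAnnotations <- function(annotations, path) {
  out <- annotations
  out$dataset_membership <- vapply(annotations$dataset_membership,
                                   paste, collapse = "|", FUN.VALUE = "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Which samples belong to a named dataset
#'
#' @param annotations annotation data frame.
#' @param dataset \code{"A"} or \code{"B"}.
#' @return logical vector along the rows of \code{annotations}.
#' @export
inDataset <- function(annotations, dataset) {
  vapply(annotations$dataset_membership, function(m) dataset %in% m, NA)
}

#' Canonicalise gene symbols
#'
#' Upper-cases, removes all whitespace, and splits compound labels on commas
#' (a printed label like \code{"LAMC1, LAMB2"} denotes two genes sharing a
#' probe).
#'
#' @param x character vector of raw symbols.
#' @return character vector of canonical symbols (possibly longer than the
#'   input when compound labels were split).
#' @export
canonicalizeSymbols <- function(x) {
  parts <- unlist(strsplit(toupper(x), ",", fixed = TRUE), use.names = FALSE)
  parts <- gsub("[[:space:]]+", "", parts)
  parts[parts != ""]
}

#' Read per-study marker gene lists
#'
#' CSV with columns \code{study_id}, \code{vessel_class}, \code{gene}. Rows
#' are grouped by (study, class); symbols are canonicalised with
#' \code{\link{canonicalizeSymbols}} and duplicates collapse to one set member.
#'
#' @param path path to the CSV file.
#' @return list of \linkS4class{MarkerList} objects.
#' @export
readMarkerLists <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("study_id", "vessel_class", "gene")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing marker columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$vessel_class), c("BEC", "LEC"))
  if (length(bad)) stop("validation error: unknown vessel_class: ", bad[1L])
  keys <- unique(df[, c("study_id", "vessel_class")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$study_id == keys$study_id[i] &
      df$vessel_class == keys$vessel_class[i]
    new("MarkerList", studyId = keys$study_id[i],
        vesselClass = keys$vessel_class[i],
        genes = unique(canonicalizeSymbols(df$gene[sel])))
  })
}

#' Marker lists as Venn input
#'
#' @param lists list of \linkS4class{MarkerList} objects.
#' @param vesselClass \code{"BEC"} or \code{"LEC"}.
#' @return named list study id -> gene set, ready for
#'   \code{\link{vennPartition}}.
#' @export
markerSets <- function(lists, vesselClass) {
  sel <- Filter(function(l) l@vesselClass == vesselClass, lists)
  if (!length(sel)) stop("no marker lists for class ", vesselClass)
  stats::setNames(lapply(sel, function(l) l@genes),
                  vapply(sel, function(l) l@studyId, ""))
}

#' Read a probe/label to canonical gene id map
#'
#' TSV with columns \code{source} and \code{gene_id}; each source label maps
#' to at most one canonical id.
#'
#' @param path path to the map.
#' @return named character vector (source -> canonical id).
#' @export
readGeneIdMap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("source", "gene_id") %in% colnames(df)))
    stop("gene map needs columns 'source' and 'gene_id'")
  if (any(df$gene_id == "")) stop("empty canonical gene id in map")
  dup <- df$source[duplicated(df$source)]
  if (length(dup)) stop("source label maps to multiple ids: ", dup[1L])
  stats::setNames(df$gene_id, df$source)
}

#' Write a Venn partition report as JSON
#'
#' The report lists every region with its membership label, size and member
#' genes, in the partition's canonical order.
#'
#' @param partition a \linkS4class{VennPartition}.
#' @param path output path.
#' @export
writeVennReport <- function(partition, path) {
  regs <- regions(partition)
  report <- list(regions = lapply(names(regs), function(lab) {
    list(label = lab, size = length(regs[[lab]]),
         genes = as.list(sort(regs[[lab]])))
  }))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
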