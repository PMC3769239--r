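#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Controlled vocabularies shared across the package.
.PLATFORMS <- c("GPL570", "GPL571", "GPL5188")
.CELL_CLASSES <- c("BEC", "LEC", "HMEC1", "TIME", "CONTROL")
.DATASETS <- c("A", "B")

#' Platform and cell-class vocabularies
#'
#' The three Affymetrix platform identifiers and the five sample classes the
#' pipeline recognises. \code{BEC}/\code{LEC} are primary blood and lymphatic
#' endothelial cells, \code{HMEC1}/\code{TIME} are immortalised microvascular
#' cell lines with a hybrid phenotype, and \code{CONTROL} is a non-endothelial
#' tissue outgroup (prostate in the original data).
#'
#' @return Character vector of valid tokens.
#' @export
validPlatforms <- function() .PLATFORMS

#' @rdname validPlatforms
#' @export
validCellClasses <- function() .CELL_CLASSES

#' EndoSet: combined multi-platform expression container
#'
#' An \code{EndoSet} extends \linkS4class{SummarizedExperiment} and carries a
#' single \code{"exprs"} assay of log2 intensities (genes x samples, \code{NA}
#' for unobserved cells), per-sample annotation in \code{colData} (columns
#' \code{platform}, \code{cell_class}, \code{dataset_membership},
#' \code{study_id}), and a provenance log in \code{metadata(x)$provenance}
#' recording genes dropped at each processing step.
#'
#' @slot standardized logical; \code{TRUE} after gene-wise median/SD scaling.
#' @seealso \code{\link{mergePlatforms}}, \code{\link{standardizeGenes}}
#' @export
setClass("EndoSet",
  contains = "SummarizedExperiment",
  representation(standardized = "logical"),
  prototype(standardized = FALSE)
)

setValidity("EndoSet", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  cd <- SummarizedExperiment::colData(object)
  if ("platform" %in% colnames(cd)) {
    bad <- setdiff(unique(cd$platform), .PLATFORMS)
    if (length(bad))
      msg <- c(msg, paste0("unknown platform: ", paste(bad, collapse = ", ")))
  }
  if ("cell_class" %in% colnames(cd)) {
    bad <- setdiff(unique(cd$cell_class), .CELL_CLASSES)
    if (length(bad))
      msg <- c(msg, paste0("unknown cell_class: ", paste(bad, collapse = ", ")))
  }
  a <- SummarizedExperiment::assay(object, "exprs")
  if (any(is.infinite(a)))
    msg <- c(msg, "non-missing expression values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EndoSet from a matrix and annotations
#'
#' @param exprs numeric matrix, genes x samples, \code{NA} = missing.
#' @param annotations optional data frame as returned by
#'   \code{\link{readAnnotations}}; matched to columns of \code{exprs} by
#'   \code{sample_id}.
#' @param standardized logical flag, see \linkS4class{EndoSet}.
#' @param provenance list of provenance records.
#' @return An \linkS4class{EndoSet}.
#' @export
EndoSet <- function(exprs, annotations = NULL, standardized = FALSE,
                    provenance = list()) {
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)), !is.null(colnames(exprs)))
  if (!is.null(annotations)) {
    miss <- setdiff(colnames(exprs), annotations$sample_id)
    if (length(miss))
      stop("samples without annotation: ", paste(miss, collapse = ", "))
    annotations <- annotations[match(colnames(exprs), annotations$sample_id), ,
                               drop = FALSE]
    cd <- DataFrame(
      platform = annotations$platform,
      cell_class = annotations$cell_class,
      dataset_membership = vapply(annotations$dataset_membership,
                                  paste, collapse = "|", FUN.VALUE = ""),
      study_id = annotations$study_id,
      row.names = colnames(exprs)
    )
  } else {
    cd <- DataFrame(row.names = colnames(exprs))
  }
  se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
  out <- new("EndoSet", se, standardized = standardized)
  metadata(out)$provenance <- provenance
  out
}

#' @describeIn EndoSet expression matrix accessor.
#' @param x an EndoSet.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn EndoSet provenance accessor: list of records, each with
#'   \code{step}, \code{reason} and \code{genes}.
#' @export
provenance <- function(x) {
  p <- metadata(x)$provenance
  if (is.null(p)) list() else p
}

setMethod("show", "EndoSet", function(object) {
  cat("EndoSet with", nrow(object), "genes and", ncol(object), "samples\n")
  cat("  standardized:", object@standardized, "\n")
  cc <- SummarizedExperiment::colData(object)$cell_class
  if (!is.null(cc)) {
    tab <- table(cc)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  nd <- sum(vapply(provenance(object), function(r) length(r$genes), 0L))
  cat("  provenance: ", length(provenance(object)), " steps, ",
      nd, " genes dropped\n", sep = "")
})

#' VennPartition: disjoint regions of an n-way gene-set intersection
#'
#' Regions are keyed by canonical membership labels: the study ids in the
#' region, sorted, joined with \code{"&"}. Every non-empty subset of the input
#' studies gets a region (possibly empty), so printed zero counts are
#' represented faithfully. Region order is by label cardinality (descending),
#' then lexicographic.
#'
#' @slot inputs named list of character vectors (study id -> gene set).
#' @slot regions named list of character vectors keyed by membership label.
#' @seealso \code{\link{vennPartition}}
#' @export
setClass("VennPartition",
  representation(inputs = "list", regions = "list"))

setValidity("VennPartition", function(object) {
  msg <- character()
  if (is.null(names(object@inputs)) || any(names(object@inputs) == ""))
    msg <- c(msg, "inputs must be a named list")
  all_regions <- unlist(object@regions, use.names = FALSE)
  if (anyDuplicated(all_regions))
    msg <- c(msg, "regions must be pairwise disjoint")
  if (!setequal(all_regions, unique(unlist(object@inputs, use.names = FALSE))))
    msg <- c(msg, "union of regions must equal union of inputs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VennPartition", function(object) {
  cat("VennPartition of", length(object@inputs), "gene sets:",
      paste(names(object@inputs), collapse = ", "), "\n")
  sizes <- vapply(object@regions, length, 0L)
  for (i in seq_along(sizes))
    cat(sprintf("  %-40s %d\n", names(sizes)[i], sizes[i]))
})

#' @describeIn VennPartition region accessor (named list of gene sets).
#' @param x a VennPartition.
#' @export
regions <- function(x) x@regions

#' @describeIn VennPartition input-set accessor.
#' @export
vennInputs <- function(x) x@inputs

#' MarkerList: one study's vessel-class-specific gene set
#'
#' @slot studyId study identifier (e.g. first-author label).
#' @slot vesselClass \code{"BEC"} or \code{"LEC"}.
#' @slot genes character vector of canonical (upper-case) gene symbols.
#' @export
setClass("MarkerList",
  representation(studyId = "character", vesselClass = "character",
                 genes = "character"))

setValidity("MarkerList", function(object) {
  if (!object@vesselClass %in% c("BEC", "LEC"))
    return("vesselClass must be 'BEC' or 'LEC'")
  if (anyDuplicated(object@genes)) return("genes must be a set (no duplicates)")
  TRUE
})

setMethod("show", "MarkerList", function(object) {
  cat("MarkerList:", object@studyId, object@vesselClass, "-",
      length(object@genes), "genes\n")
})

#' EmbeddingResult: classical MDS coordinates
#'
#' @slot sampleIds character vector of embedded samples.
#' @slot coords numeric matrix, samples x k; per-dimension mean is zero.
#' @slot eigenvalues the k leading eigenvalues of the double-centred matrix,
#'   non-increasing; a negative value marks a dimension that was zeroed.
#' @export
setClass("EmbeddingResult",
  representation(sampleIds = "character", coords = "matrix",
                 eigenvalues = "numeric"))

setValidity("EmbeddingResult", function(object) {
  msg <- character()
  if (nrow(object@coords) != length(object@sampleIds))
    msg <- c(msg, "coords rows must match sampleIds")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EmbeddingResult", function(object) {
  cat("EmbeddingResult:", length(object@sampleIds), "samples in",
      ncol(object@coords), "dimensions\n")
  cat("  eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = " "),
      "\n")
})
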