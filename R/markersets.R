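.regionLabel <- function(studies) paste(sort(studies), collapse = "&")

## All non-empty subsets of study ids, as canonical labels ordered by
## cardinality (descending) then lexicographically.
.allLabels <- function(studies) {
  n <- length(studies)
  subsets <- unlist(lapply(seq(n, 1L), function(k)
    utils::combn(sort(studies), k, simplify = FALSE)), recursive = FALSE)
  vapply(subsets, paste, collapse = "&", FUN.VALUE = "")
}

#' Exact n-way Venn partition of gene sets
#'
#' Splits the union of the input sets into disjoint regions: gene g lies in
#' the region labelled by exactly the studies whose set contains g. All
#' non-empty study subsets are represented, so empty intersections appear
#' with size zero. The partition is invariant to the order in which studies
#' are supplied.
#'
#' @param inputs named list, study id -> character vector of gene symbols.
#' @return A \linkS4class{VennPartition}.
#' @export
vennPartition <- function(inputs) {
  if (!length(inputs)) stop("empty study set")
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    stop("inputs must be named by study id")
  if (length(inputs) < 2L) stop("need at least two studies")
  if (length(inputs) > 5L)
    warning("more than 5 sets: partition computed, report-only scale")
  inputs <- lapply(inputs, function(g) unique(as.character(g)))
  universe <- unique(unlist(inputs, use.names = FALSE))
  membership <- vapply(names(inputs), function(s) universe %in% inputs[[s]],
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, names(inputs)))
  labels <- apply(membership, 1L, function(row)
    .regionLabel(names(inputs)[row]))
  regs <- split(universe, labels)
  all_labels <- .allLabels(names(inputs))
  regions <- stats::setNames(lapply(all_labels, function(l) {
    g <- regs[[l]]
    if (is.null(g)) character() else sort(g)
  }), all_labels)
  new("VennPartition", inputs = inputs, regions = regions)
}

#' Total gene count of one study inside a partition
#'
#' Sums the sizes of every region whose label contains the study; by the
#' partition laws this equals the cardinality of that study's input set.
#'
#' @param partition a \linkS4class{VennPartition}.
#' @param studyId study identifier.
#' @return integer count.
#' @export
studyTotal <- function(partition, studyId) {
  if (!studyId %in% names(partition@inputs))
    stop("unknown study: ", studyId)
  sel <- vapply(names(partition@regions), function(l)
    studyId %in% strsplit(l, "&", fixed = TRUE)[[1L]], NA)
  sum(vapply(partition@regions[sel], length, 0L))
}

#' Cross-study concordance report
#'
#' Tabulates region sizes per vessel class together with per-study totals
#' and pairwise overlap counts.
#'
#' @param partitions named list (vessel class -> \linkS4class{VennPartition})
#'   sharing the same study ids.
#' @return list with data frames \code{region_sizes} (label x class),
#'   \code{study_totals} and \code{pairwise_overlaps}.
#' @export
concordanceReport <- function(partitions) {
  stopifnot(length(partitions) >= 1L)
  studies <- names(partitions[[1L]]@inputs)
  for (p in partitions)
    if (!setequal(names(p@inputs), studies))
      stop("partitions must share study ids")
  region_sizes <- do.call(rbind, lapply(names(partitions), function(cl) {
    regs <- regions(partitions[[cl]])
    data.frame(vessel_class = cl, label = names(regs),
               size = vapply(regs, length, 0L), row.names = NULL)
  }))
  study_totals <- do.call(rbind, lapply(names(partitions), function(cl) {
    data.frame(vessel_class = cl, study_id = studies,
               total = vapply(studies, function(s)
                 studyTotal(partitions[[cl]], s), 0L), row.names = NULL)
  }))
  pairs <- utils::combn(sort(studies), 2L, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(names(partitions), function(cl) {
    ins <- partitions[[cl]]@inputs
    do.call(rbind, lapply(pairs, function(pr)
      data.frame(vessel_class = cl, study_1 = pr[1L], study_2 = pr[2L],
                 overlap = length(intersect(ins[[pr[1L]]], ins[[pr[2L]]])),
                 row.names = NULL)))
  }))
  list(region_sizes = region_sizes, study_totals = study_totals,
       pairwise_overlaps = pairwise)
}
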