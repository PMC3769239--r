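.addProvenance <- function(x, step, reason, genes) {
  p <- provenance(x)
  p[[length(p) + 1L]] <- list(step = step, reason = reason, genes = genes)
  metadata(x)$provenance <- p
  x
}

#' Merge per-platform expression matrices on canonical gene ids
#'
#' Source gene labels are translated through \code{geneMap} (identity when
#' \code{NULL}); labels the map does not cover are dropped and logged. When
#' several labels on one platform map to the same canonical gene, their
#' values are collapsed per sample (mean by default, missing ignored). The
#' merged matrix holds the union of canonical genes over the concatenated
#' samples; a cell is \code{NA} when the gene is absent from that sample's
#' platform.
#'
#' @param matrices named list of genes x samples matrices (one per platform).
#' @param geneMap optional named character vector (source label -> canonical
#'   id), see \code{\link{readGeneIdMap}}.
#' @param annotations optional annotation data frame covering all samples.
#' @param collapse how to combine multiple source labels mapping to one gene.
#' @return An \linkS4class{EndoSet}.
#' @export
mergePlatforms <- function(matrices, geneMap = NULL, annotations = NULL,
                           collapse = c("mean", "max", "first")) {
  collapse <- match.arg(collapse)
  if (!length(matrices)) stop("empty input collection")
  stopifnot(all(vapply(matrices, is.matrix, NA)))
  all_samples <- unlist(lapply(matrices, colnames), use.names = FALSE)
  dup <- all_samples[duplicated(all_samples)]
  if (length(dup)) stop("duplicate sample id across platforms: ", dup[1L])

  unmapped <- character()
  mapped <- lapply(matrices, function(m) {
    src <- rownames(m)
    if (is.null(geneMap)) {
      canon <- src
    } else {
      canon <- unname(geneMap[src])
      drop <- is.na(canon)
      if (any(drop)) {
        unmapped <<- union(unmapped, src[drop])
        m <- m[!drop, , drop = FALSE]
        canon <- canon[!drop]
      }
    }
    if (anyDuplicated(canon)) {
      grp <- split(seq_along(canon), canon)
      m <- do.call(rbind, lapply(grp, function(i) {
        block <- m[i, , drop = FALSE]
        switch(collapse,
          mean = colMeans(block, na.rm = TRUE),
          max = suppressWarnings(apply(block, 2L, max, na.rm = TRUE)),
          first = block[1L, ])
      }))
      m[is.nan(m) | is.infinite(m)] <- NA_real_
    } else {
      rownames(m) <- canon
    }
    m
  })

  genes <- sort(unique(unlist(lapply(mapped, rownames), use.names = FALSE)))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(all_samples),
                dimnames = list(genes, all_samples))
  for (m in mapped) out[rownames(m), colnames(m)] <- m
  es <- EndoSet(out, annotations = annotations)
  if (length(unmapped))
    es <- .addProvenance(es, "merge", "no canonical gene id", unmapped)
  es
}

setGeneric("filterMissingness", function(x, minFrac = 0.4)
  standardGeneric("filterMissingness"))

#' Remove genes observed in too few samples
#'
#' Retains exactly the genes whose fraction of non-missing values over all
#' samples is at least \code{minFrac} (inclusive boundary: a gene observed in
#' 40\% of samples survives the default filter). The sample set is unchanged;
#' dropped genes are recorded in provenance.
#'
#' @param x an \linkS4class{EndoSet} or a plain genes x samples matrix.
#' @param minFrac minimum observed fraction, in (0, 1]; default 0.4.
#' @return object of the same type with low-coverage genes removed.
#' @export
setMethod("filterMissingness", "matrix", function(x, minFrac = 0.4) {
  stopifnot(minFrac > 0, minFrac <= 1)
  frac <- rowMeans(!is.na(x))
  x[frac >= minFrac, , drop = FALSE]
})

#' @rdname filterMissingness-matrix-method
#' @export
setMethod("filterMissingness", "EndoSet", function(x, minFrac = 0.4) {
  stopifnot(minFrac > 0, minFrac <= 1)
  frac <- rowMeans(!is.na(exprsMatrix(x)))
  keep <- frac >= minFrac
  out <- x[keep, ]
  if (any(!keep))
    out <- .addProvenance(out, "filter_missingness",
                          sprintf("observed in < %g%% of samples",
                                  100 * minFrac),
                          rownames(x)[!keep])
  out
})

setGeneric("standardizeGenes", function(x) standardGeneric("standardizeGenes"))

.standardizeMatrix <- function(m) {
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
  n_obs <- rowSums(!is.na(m))
  too_few <- n_obs < 2L
  zero_var <- !too_few & (is.na(sd) | sd == 0)
  keep <- !too_few & !zero_var
  z <- (m[keep, , drop = FALSE] - med[keep]) / sd[keep]
  list(z = z, too_few = rownames(m)[too_few], zero_var = rownames(m)[zero_var])
}

#' Gene-wise median centering and SD scaling
#'
#' For each gene, subtracts the median of its non-missing values and divides
#' by their standard deviation (n - 1 denominator), removing additive
#' inter-platform differences in location and scale. Computed over the
#' complete combined matrix, i.e. across all samples from all platforms at
#' once. Genes with fewer than two observed values or zero variance are
#' dropped and logged. Missing values propagate.
#'
#' @param x an \linkS4class{EndoSet} or a plain genes x samples matrix.
#' @return standardized object of the same type; every retained gene has
#'   median 0 and SD 1 over its observed values.
#' @export
setMethod("standardizeGenes", "matrix", function(x) {
  .standardizeMatrix(x)$z
})

#' @rdname standardizeGenes-matrix-method
#' @export
setMethod("standardizeGenes", "EndoSet", function(x) {
  res <- .standardizeMatrix(exprsMatrix(x))
  out <- x[rownames(res$z), ]
  SummarizedExperiment::assay(out, "exprs") <- res$z
  out@standardized <- TRUE
  if (length(res$too_few))
    out <- .addProvenance(out, "standardize", "fewer than 2 observed values",
                          res$too_few)
  if (length(res$zero_var))
    out <- .addProvenance(out, "standardize", "zero variance", res$zero_var)
  out
})
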