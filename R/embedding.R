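#' Euclidean distances between samples
#'
#' Distances are computed over genes, per pair of samples. With the default
#' \code{"complete_genes"} policy only genes observed in every sample are
#' used (the result is exactly Euclidean). With \code{"pairwise_complete"}
#' each pair uses its mutually observed genes, rescaled by
#' \code{sqrt(n_total / n_observed)} to keep magnitudes comparable; such a
#' matrix is only approximately Euclidean.
#'
#' @param x an \linkS4class{EndoSet} or genes x samples matrix.
#' @param genePolicy missing-data policy, see Details.
#' @return symmetric samples x samples distance matrix with zero diagonal.
#' @export
euclideanDistances <- function(x, genePolicy = c("complete_genes",
                                                 "pairwise_complete")) {
  genePolicy <- match.arg(genePolicy)
  m <- if (is(x, "EndoSet")) exprsMatrix(x) else x
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  if (genePolicy == "complete_genes") {
    complete <- !apply(is.na(m), 1L, any)
    if (!any(complete)) stop("no genes observed in every sample")
    d <- as.matrix(stats::dist(t(m[complete, , drop = FALSE])))
  } else {
    n <- ncol(m)
    ntot <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    obs <- !is.na(m)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      both <- obs[, i] & obs[, j]
      nobs <- sum(both)
      if (nobs == 0L) stop("no mutually observed genes for a sample pair")
      dij <- sqrt(sum((m[both, i] - m[both, j])^2) * ntot / nobs)
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, \code{B = -1/2 J D^2 J},
#' takes the k leading eigenpairs, and scales each eigenvector by the square
#' root of its eigenvalue. A dimension whose eigenvalue is negative (the
#' distances are not Euclidean in that direction) is zeroed and its
#' eigenvalue reported as found.
#'
#' @param d symmetric distance matrix (e.g. from
#'   \code{\link{euclideanDistances}}).
#' @param k number of output dimensions, default 3; must be < nrow(d).
#' @return An \linkS4class{EmbeddingResult}.
#' @export
classicalMds <- function(d, k = 3L) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  b <- d^2
  b <- sweep(b, 1L, rowMeans(b))
  b <- sweep(b, 2L, colMeans(b))
  b <- -b / 2
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lambda <- eig$values[seq_len(k)]
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  scale <- sqrt(pmax(lambda, 0))
  coords <- sweep(vec, 2L, scale, `*`)
  coords[, lambda < 0] <- 0
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("dim", seq_len(k))
  ids <- if (is.null(rownames(d))) as.character(seq_len(n)) else rownames(d)
  new("EmbeddingResult", sampleIds = ids, coords = coords,
      eigenvalues = lambda)
}

#' @describeIn classicalMds coordinate accessor.
#' @param emb an \linkS4class{EmbeddingResult}.
#' @export
embeddingCoords <- function(emb) emb@coords

#' Class separation summary of an embedding
#'
#' Computes per-class centroids and, for every HMEC1/TIME cell-line sample,
#' its distance to the BEC, LEC and CONTROL centroids; a sample is "outside"
#' a class when that distance exceeds the class's hull radius (the maximum
#' distance of a class member from its own centroid). Classes with a single
#' sample get an undefined (NA) hull radius.
#'
#' @param emb an \linkS4class{EmbeddingResult}.
#' @param annotations annotation data frame covering every embedded sample.
#' @return list with \code{centroids} (class x dim matrix),
#'   \code{hull_radius} (named numeric) and \code{cell_lines} (data frame
#'   with per-sample centroid distances and outside flags).
#' @export
clusterSeparation <- function(emb, annotations) {
  co <- emb@coords
  cls <- annotations$cell_class[match(emb@sampleIds, annotations$sample_id)]
  if (anyNA(cls)) stop("every embedded sample must be annotated")
  classes <- unique(cls)
  centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(co[cls == cl, , drop = FALSE])))
  rownames(centroids) <- classes
  hull <- vapply(classes, function(cl) {
    pts <- co[cls == cl, , drop = FALSE]
    if (nrow(pts) < 2L) return(NA_real_)
    max(sqrt(rowSums(sweep(pts, 2L, centroids[cl, ])^2)))
  }, 0)
  dist_to <- function(pts, cl) {
    if (!cl %in% classes) return(rep(NA_real_, nrow(pts)))
    sqrt(rowSums(sweep(pts, 2L, centroids[cl, ])^2))
  }
  line_sel <- cls %in% c("HMEC1", "TIME")
  pts <- co[line_sel, , drop = FALSE]
  cell_lines <- data.frame(
    sample_id = emb@sampleIds[line_sel],
    cell_class = cls[line_sel],
    dist_bec = dist_to(pts, "BEC"),
    dist_lec = dist_to(pts, "LEC"),
    dist_control = dist_to(pts, "CONTROL"),
    row.names = NULL
  )
  cell_lines$outside_bec <- cell_lines$dist_bec > hull[["BEC"]]
  cell_lines$outside_lec <- cell_lines$dist_lec > hull[["LEC"]]
  list(centroids = centroids, hull_radius = hull, cell_lines = cell_lines)
}
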