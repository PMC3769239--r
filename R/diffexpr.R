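#' Welch two-sample t-test (unequal variance, two-tailed)
#'
#' @param a,b numeric vectors (missing values removed internally).
#' @return list with \code{t}, \code{df} and two-tailed \code{p}. Degenerate
#'   inputs are flagged rather than erroring: fewer than two observations in
#'   a group, or two exactly constant groups with unequal means, give
#'   \code{NA} statistics (\code{untestable = TRUE}); two constant groups
#'   with equal means give \code{t = 0}, \code{p = 1}.
#' @export
welchT <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, untestable = TRUE))
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (d == 0)
      return(list(t = 0, df = NA_real_, p = 1, untestable = FALSE))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, untestable = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), untestable = FALSE)
}

#' Log2 fold change as a difference of group means
#'
#' On log2-transformed data a fold change of at least 2 corresponds to an
#' absolute difference of group means of at least 1.
#'
#' @param a,b numeric vectors on the log2 scale.
#' @return mean(a) - mean(b); \code{NA} when a group has no observed value.
#' @export
log2FoldChange <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  mean(a) - mean(b)
}

#' Robust false discovery rate estimation
#'
#' Estimates the null proportion as \code{pi0 = min(1, 2 * mean(p))} and
#' computes step-up q-values \code{q_(i) = min_{j >= i} pi0 * m * p_(j) / j}
#' over the sorted p-values, clipped to 1. With \code{method = "bh"} the
#' plain Benjamini-Hochberg correction (\code{pi0 = 1}) is used instead.
#'
#' @param p numeric vector of p-values in [0, 1] (no missing values).
#' @param method \code{"robust"} (default) or \code{"bh"}.
#' @return list with \code{pi0} and \code{q} (aligned to the input order).
#' @export
robustFdr <- function(p, method = c("robust", "bh")) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("validation error: p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- if (method == "robust") min(1, 2 * mean(p)) else 1
  o <- order(p)
  q_sorted <- pmin(1, pi0 * m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  list(pi0 = pi0, q = q)
}

## Row-wise Welch statistics over a genes x samples matrix; NA-aware and
## vectorised. Degenerate rows are handled exactly as welchT().
.rowWelch <- function(xa, xb) {
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  d <- ma - mb
  se2 <- va / na + vb / nb
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / pmax(na - 1, 1) + (vb / nb)^2 / pmax(nb - 1, 1))
  p <- 2 * stats::pt(-abs(t), df)
  both_const <- va == 0 & vb == 0
  t[which(both_const & d == 0)] <- 0
  p[which(both_const & d == 0)] <- 1
  df[which(both_const)] <- NA_real_
  untestable <- na < 2L | nb < 2L | (both_const & !is.na(d) & d != 0)
  t[untestable] <- NA_real_
  df[untestable] <- NA_real_
  p[untestable] <- NA_real_
  ma[na == 0L] <- NA_real_
  mb[nb == 0L] <- NA_real_
  list(n_a = na, n_b = nb, mean_a = ma, mean_b = mb, t = t, df = df, p = p,
       untestable = untestable)
}

#' Genewise two-group differential expression table
#'
#' Runs the Welch t-test and log2 fold change for every gene between two
#' annotated sample classes, applies \code{\link{robustFdr}} once across all
#' testable genes, and calls a gene significant when (inclusively)
#' \code{|log2fc| >= log2(fcThreshold)} and \code{q <= qThreshold}.
#' Direction \code{A_UP} means higher in \code{classA}.
#'
#' @param x an \linkS4class{EndoSet} (annotations taken from
#'   \code{colData}) or a genes x samples matrix with \code{annotations}
#'   supplied.
#' @param annotations annotation data frame (required for matrix input).
#' @param classA,classB cell classes to contrast (defaults BEC vs LEC).
#' @param fcThreshold fold-change threshold on the natural scale (default 2).
#' @param qThreshold corrected p-value threshold (default 0.05).
#' @param fdrMethod passed to \code{\link{robustFdr}}.
#' @return \code{\link[S4Vectors]{DataFrame}} with one row per gene and
#'   columns \code{gene_id}, \code{mean_a}, \code{mean_b}, \code{log2fc},
#'   \code{t}, \code{df}, \code{p}, \code{q}, \code{n_a}, \code{n_b},
#'   \code{untestable}, \code{significant}, \code{direction}; the estimated
#'   \code{pi0} and the thresholds are stored in \code{metadata()}.
#' @export
differentialTable <- function(x, annotations = NULL, classA = "BEC",
                              classB = "LEC", fcThreshold = 2,
                              qThreshold = 0.05,
                              fdrMethod = c("robust", "bh")) {
  fdrMethod <- match.arg(fdrMethod)
  if (is(x, "EndoSet")) {
    cd <- SummarizedExperiment::colData(x)
    classes <- stats::setNames(cd$cell_class, rownames(cd))
    m <- exprsMatrix(x)
  } else {
    stopifnot(is.matrix(x), !is.null(annotations))
    classes <- stats::setNames(annotations$cell_class, annotations$sample_id)
    m <- x
  }
  for (cl in c(classA, classB))
    if (sum(classes[colnames(m)] == cl, na.rm = TRUE) < 2L)
      stop("class absent or too small in annotations: ", cl)
  xa <- m[, classes[colnames(m)] == classA, drop = FALSE]
  xb <- m[, classes[colnames(m)] == classB, drop = FALSE]
  w <- .rowWelch(xa, xb)
  log2fc <- w$mean_a - w$mean_b

  q <- rep(NA_real_, nrow(m))
  pi0 <- NA_real_
  testable <- !w$untestable
  if (any(testable)) {
    fdr <- robustFdr(w$p[testable], method = fdrMethod)
    q[testable] <- fdr$q
    pi0 <- fdr$pi0
  }
  significant <- testable & !is.na(log2fc) &
    abs(log2fc) >= log2(fcThreshold) & q <= qThreshold
  direction <- rep("NONE", nrow(m))
  direction[significant & log2fc > 0] <- "A_UP"
  direction[significant & log2fc < 0] <- "B_UP"

  ## stable order: by gene id, for deterministic reports
  res <- DataFrame(
    gene_id = rownames(m), mean_a = w$mean_a, mean_b = w$mean_b,
    log2fc = log2fc, t = w$t, df = w$df, p = w$p, q = q,
    n_a = w$n_a, n_b = w$n_b, untestable = w$untestable,
    significant = significant, direction = direction,
    row.names = rownames(m)
  )
  metadata(res) <- list(pi0 = pi0, class_a = classA, class_b = classB,
                        fc_threshold = fcThreshold, q_threshold = qThreshold,
                        fdr_method = fdrMethod)
  res
}

#' Significant marker genes from a differential table
#'
#' @param tab result of \code{\link{differentialTable}}.
#' @param direction \code{"A_UP"}, \code{"B_UP"} or \code{"any"}.
#' @return character vector of gene ids.
#' @export
markerGenes <- function(tab, direction = c("A_UP", "B_UP", "any")) {
  direction <- match.arg(direction)
  sel <- tab$significant
  if (direction != "any") sel <- sel & tab$direction == direction
  sort(tab$gene_id[sel])
}

#' Write a differential table as TSV
#'
#' @param tab result of \code{\link{differentialTable}}.
#' @param path output path.
#' @export
writeDifferentialTSV <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
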