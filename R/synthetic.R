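#' SimulationConfig: parameters for the multi-platform expression simulator
#'
#' Describes a seeded generative model for pooled cross-platform endothelial
#' expression data: per-gene log2 baselines, symmetric planted marker effects
#' between BEC and LEC, per-gene per-platform additive offsets, hybrid
#' cell-line profiles (convex BEC/LEC mixtures plus line-specific drift
#' genes), a divergent tissue outgroup, partial per-platform gene coverage,
#' and missing-completely-at-random dropout.
#'
#' @slot nGenes number of genes in the union universe.
#' @slot nMarkerBec,nMarkerLec planted marker counts per class.
#' @slot effectLog2 planted BEC-vs-LEC group difference (log2 scale); markers
#'   get +/- effectLog2/2 in their favoured/disfavoured class.
#' @slot samplesPerPlatform named list: platform -> named integer vector of
#'   sample counts per cell class.
#' @slot datasetA named list with elements \code{platforms} and
#'   \code{classes}: primary samples on those platforms and of those classes
#'   are additionally labelled as Dataset A (Dataset B is every primary
#'   BEC/LEC sample).
#' @slot platformOffsetSd SD of the per-gene per-platform additive shift.
#' @slot baselineMean,baselineSdMean mean and SD of the per-gene baseline.
#' @slot noiseSd observation noise SD.
#' @slot missingRate per-platform MCAR dropout probability (named, or scalar
#'   recycled).
#' @slot geneCoverage per-platform fraction of the gene universe present on
#'   the array (named, or scalar recycled); absent genes are structurally
#'   missing, unlike dropout.
#' @slot hybridMix cell-line mixture weight: line mean = mix * BEC mean +
#'   (1 - mix) * LEC mean.
#' @slot driftNGenes,driftLog2 number of line-specific aberrant genes per
#'   cell line and the shift added on them.
#' @slot controlSd SD of the per-gene shift of the CONTROL outgroup relative
#'   to the endothelial baseline.
#' @slot seed integer RNG seed; mandatory.
#' @export
setClass("SimulationConfig", representation(
  nGenes = "integer", nMarkerBec = "integer", nMarkerLec = "integer",
  effectLog2 = "numeric", samplesPerPlatform = "list", datasetA = "list",
  platformOffsetSd = "numeric", baselineMean = "numeric",
  baselineSdMean = "numeric", noiseSd = "numeric", missingRate = "numeric",
  geneCoverage = "numeric", hybridMix = "numeric", driftNGenes = "integer",
  driftLog2 = "numeric", controlSd = "numeric", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nMarkerBec + object@nMarkerLec > object@nGenes)
    msg <- c(msg, "marker counts exceed nGenes")
  if (object@effectLog2 < 0) msg <- c(msg, "effectLog2 must be >= 0")
  bad <- setdiff(names(object@samplesPerPlatform), .PLATFORMS)
  if (length(bad)) msg <- c(msg, paste("unknown platform:", bad[1L]))
  for (p in names(object@samplesPerPlatform)) {
    cls <- names(object@samplesPerPlatform[[p]])
    if (length(setdiff(cls, .CELL_CLASSES)))
      msg <- c(msg, paste("unknown cell class under platform", p))
  }
  if (any(object@missingRate < 0 | object@missingRate > 1))
    msg <- c(msg, "missingRate must lie in [0, 1]")
  if (any(object@geneCoverage <= 0 | object@geneCoverage > 1))
    msg <- c(msg, "geneCoverage must lie in (0, 1]")
  if (object@hybridMix < 0 || object@hybridMix > 1)
    msg <- c(msg, "hybridMix must lie in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a scalar integer seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nGenes,nMarkerBec,nMarkerLec,effectLog2,samplesPerPlatform,datasetA
#'   see slots.
#' @param platformOffsetSd,baselineMean,baselineSdMean,noiseSd,missingRate
#'   see slots.
#' @param geneCoverage,hybridMix,driftNGenes,driftLog2,controlSd,seed see
#'   slots.
#' @export
simulationConfig <- function(nGenes, nMarkerBec = 0L, nMarkerLec = 0L,
                             effectLog2 = 2, samplesPerPlatform,
                             datasetA = list(platforms = character(),
                                             classes = c("BEC", "LEC")),
                             platformOffsetSd = 0.5, baselineMean = 6,
                             baselineSdMean = 2, noiseSd = 0.5,
                             missingRate = 0.02, geneCoverage = 1,
                             hybridMix = 0.5, driftNGenes = 0L,
                             driftLog2 = 2, controlSd = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory (reproducibility)")
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nMarkerBec = as.integer(nMarkerBec),
      nMarkerLec = as.integer(nMarkerLec), effectLog2 = effectLog2,
      samplesPerPlatform = samplesPerPlatform, datasetA = datasetA,
      platformOffsetSd = platformOffsetSd, baselineMean = baselineMean,
      baselineSdMean = baselineSdMean, noiseSd = noiseSd,
      missingRate = missingRate, geneCoverage = geneCoverage,
      hybridMix = hybridMix, driftNGenes = as.integer(driftNGenes),
      driftLog2 = driftLog2, controlSd = controlSd, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  n <- sum(unlist(object@samplesPerPlatform))
  cat("SimulationConfig:", object@nGenes, "genes,", n, "samples on",
      length(object@samplesPerPlatform), "platforms\n")
  cat("  markers:", object@nMarkerBec, "BEC /", object@nMarkerLec,
      "LEC at effect", object@effectLog2, "log2; seed", object@seed, "\n")
})

#' Default configuration emulating the pooled-GEO study design
#'
#' 47 primary endothelial samples (33 BEC + 14 LEC) spread over three
#' platforms, with the 24 GPL570 primary samples (14 BEC + 10 LEC) doubling
#' as the restricted Dataset A; four replicates each of the HMEC1 and TIME
#' hybrid cell lines and three non-endothelial CONTROL samples sit on GPL570
#' outside both datasets. 100 markers are planted per class at a 4-fold
#' (2 log2 unit) effect.
#'
#' @param seed integer RNG seed.
#' @param nGenes size of the gene universe (default 19081).
#' @return A \linkS4class{SimulationConfig}.
#' @export
defaultPaperlikeConfig <- function(seed, nGenes = 19081L) {
  simulationConfig(
    nGenes = nGenes, nMarkerBec = 100L, nMarkerLec = 100L, effectLog2 = 2,
    samplesPerPlatform = list(
      GPL570 = c(BEC = 14L, LEC = 10L, HMEC1 = 4L, TIME = 4L, CONTROL = 3L),
      GPL571 = c(BEC = 9L, LEC = 2L),
      GPL5188 = c(BEC = 10L, LEC = 2L)
    ),
    datasetA = list(platforms = "GPL570", classes = c("BEC", "LEC")),
    platformOffsetSd = 0.5, baselineMean = 6, baselineSdMean = 2,
    noiseSd = 0.5, missingRate = 0.02,
    geneCoverage = c(GPL570 = 1, GPL571 = 0.6, GPL5188 = 0.9),
    hybridMix = 0.5, driftNGenes = 200L, driftLog2 = 2, controlSd = 1.5,
    seed = seed
  )
}

.perPlatform <- function(x, platforms) {
  if (is.null(names(x))) stats::setNames(rep_len(x, length(platforms)),
                                         platforms)
  else x[platforms]
}

#' Generate a seeded multi-platform expression dataset
#'
#' Draws from the generative model described in
#' \linkS4class{SimulationConfig}: gene baselines are
#' Normal(baselineMean, baselineSdMean^2); BEC markers get +effectLog2/2 in
#' BEC samples and -effectLog2/2 in LEC samples (LEC markers mirrored);
#' HMEC1/TIME means are the hybridMix convex combination of the BEC and LEC
#' means plus a line-specific shift on that line's drift genes; CONTROL means
#' add an independent Normal(0, controlSd^2) per-gene shift; every sample on
#' a platform shares a per-gene Normal(0, platformOffsetSd^2) offset;
#' observations add Normal(0, noiseSd^2) noise. Each platform carries a
#' seeded random subset of round(geneCoverage * nGenes) genes and retained
#' cells drop out independently at missingRate. Identical configs (including
#' the seed) give bitwise-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{matrices} (named list of per-platform
#'   genes x samples matrices), \code{annotations} (data frame in
#'   \code{\link{readAnnotations}} layout) and \code{truth} (list with
#'   \code{bec_markers}, \code{lec_markers}, \code{drift_genes},
#'   \code{platform_offsets}, \code{group_means}).
#' @export
simulateExpression <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  ng <- config@nGenes
  genes <- sprintf("G%05d", seq_len(ng))
  platforms <- names(config@samplesPerPlatform)

  ## planted effects
  idx <- sample.int(ng, config@nMarkerBec + config@nMarkerLec)
  bec_idx <- idx[seq_len(config@nMarkerBec)]
  lec_idx <- idx[config@nMarkerBec + seq_len(config@nMarkerLec)]
  baseline <- stats::rnorm(ng, config@baselineMean, config@baselineSdMean)
  half <- config@effectLog2 / 2
  mean_bec <- baseline
  mean_lec <- baseline
  mean_bec[bec_idx] <- mean_bec[bec_idx] + half
  mean_lec[bec_idx] <- mean_lec[bec_idx] - half
  mean_bec[lec_idx] <- mean_bec[lec_idx] - half
  mean_lec[lec_idx] <- mean_lec[lec_idx] + half
  mean_hybrid <- config@hybridMix * mean_bec + (1 - config@hybridMix) * mean_lec

  cell_lines <- c("HMEC1", "TIME")
  free_idx <- setdiff(seq_len(ng), c(bec_idx, lec_idx))
  drift <- list()
  mean_line <- list()
  for (cl in cell_lines) {
    d <- if (config@driftNGenes > 0L)
      sample(free_idx, min(config@driftNGenes, length(free_idx)))
    else integer()
    free_idx <- setdiff(free_idx, d)
    m <- mean_hybrid
    m[d] <- m[d] + config@driftLog2
    drift[[cl]] <- genes[d]
    mean_line[[cl]] <- m
  }
  mean_control <- baseline + stats::rnorm(ng, 0, config@controlSd)

  group_means <- cbind(BEC = mean_bec, LEC = mean_lec,
                       HMEC1 = mean_line[["HMEC1"]],
                       TIME = mean_line[["TIME"]], CONTROL = mean_control)
  rownames(group_means) <- genes

  offsets <- matrix(stats::rnorm(ng * length(platforms), 0,
                                 config@platformOffsetSd),
                    nrow = ng, dimnames = list(genes, platforms))
  coverage <- .perPlatform(config@geneCoverage, platforms)
  miss_rate <- .perPlatform(config@missingRate, platforms)

  matrices <- list()
  ann <- list()
  counter <- 0L
  for (p in platforms) {
    keep <- sort(sample.int(ng, round(coverage[[p]] * ng)))
    counts <- config@samplesPerPlatform[[p]]
    counts <- counts[counts > 0L]
    classes <- rep(names(counts), counts)
    nsamp <- length(classes)
    ids <- sprintf("S%03d_%s", counter + seq_len(nsamp), p)
    counter <- counter + nsamp
    mu <- group_means[keep, classes, drop = FALSE] + offsets[keep, p]
    x <- mu + stats::rnorm(length(mu), 0, config@noiseSd)
    if (miss_rate[[p]] > 0)
      x[stats::runif(length(x)) < miss_rate[[p]]] <- NA_real_
    dimnames(x) <- list(genes[keep], ids)
    matrices[[p]] <- x
    in_a <- p %in% config@datasetA$platforms &
      classes %in% config@datasetA$classes
    in_b <- classes %in% c("BEC", "LEC")
    membership <- mapply(function(a, b) c(if (a) "A", if (b) "B"),
                         in_a, in_b, SIMPLIFY = FALSE)
    ann[[p]] <- data.frame(
      sample_id = ids, platform = p, cell_class = classes,
      dataset_membership = I(membership),
      study_id = paste0("sim_", p), stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  list(
    matrices = matrices,
    annotations = annotations,
    truth = list(
      bec_markers = genes[bec_idx],
      lec_markers = genes[lec_idx],
      drift_genes = drift,
      platform_offsets = offsets,
      group_means = group_means
    )
  )
}
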