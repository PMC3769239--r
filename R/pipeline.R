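#' Run the pooled meta-analysis pipeline end-to-end
#'
#' Simulates (or accepts) multi-platform expression data, merges and filters
#' it, calls BEC-vs-LEC differential expression separately for the
#' restricted Dataset A and the full Dataset B, intersects the resulting
#' marker sets per vessel class, standardizes the combined matrix, and
#' embeds the Dataset-A + cell-line + control samples by classical MDS.
#' Differential testing and fold changes use the merged-but-unstandardized
#' log2 matrix (a 2-fold threshold is meaningful on that scale, not after
#' per-gene SD scaling); the standardized matrix is produced alongside as
#' the harmonized artifact. All randomness comes from the config seed, so a
#' rerun with the same config reproduces every output byte for byte.
#'
#' @param config a \linkS4class{SimulationConfig}, or a list with elements
#'   \code{matrices} and \code{annotations} for pre-existing data.
#' @param outDir optional directory; when given, per-stage TSV/JSON outputs
#'   and a manifest with content hashes are written there.
#' @param minFrac missingness filter threshold (default 0.4).
#' @param fcThreshold,qThreshold marker-calling thresholds (defaults 2 and
#'   0.05).
#' @param k MDS dimensions (default 3).
#' @param markerFixtures optional list of \linkS4class{MarkerList} objects
#'   (e.g. from \code{\link{readMarkerLists}}) joined into a three-way
#'   comparison with the Dataset-B calls.
#' @return list with the merged \code{endoset}, the standardized
#'   \code{harmonized} set, per-dataset \code{tables}, \code{markers},
#'   \code{venn} partitions per class, \code{embedding},
#'   \code{separation}, the simulation \code{truth} (when simulated) and a
#'   run \code{manifest}.
#' @export
runPipeline <- function(config, outDir = NULL, minFrac = 0.4,
                        fcThreshold = 2, qThreshold = 0.05, k = 3L,
                        markerFixtures = NULL) {
  stages <- list()
  outputs <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      if (!is.null(outDir))
        unlink(file.path(outDir, outputs))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- "ok"
    res
  }

  truth <- NULL
  sim <- stage("simulate", {
    if (is(config, "SimulationConfig")) {
      s <- simulateExpression(config)
      truth <- s$truth
      s
    } else {
      stopifnot(is.list(config), !is.null(config$matrices),
                !is.null(config$annotations))
      config
    }
  })

  es <- stage("harmonize", {
    merged <- mergePlatforms(sim$matrices, annotations = sim$annotations)
    filterMissingness(merged, minFrac = minFrac)
  })
  harmonized <- stage("standardize", standardizeGenes(es))

  ann <- sim$annotations
  dataset_samples <- list(
    A = ann$sample_id[inDataset(ann, "A")],
    B = ann$sample_id[inDataset(ann, "B")]
  )
  tables <- stage("de", {
    lapply(dataset_samples, function(ids) {
      differentialTable(es[, intersect(colnames(es), ids)],
                        classA = "BEC", classB = "LEC",
                        fcThreshold = fcThreshold, qThreshold = qThreshold)
    })
  })
  markers <- stage("markers", {
    lapply(tables, function(tab)
      list(BEC = markerGenes(tab, "A_UP"), LEC = markerGenes(tab, "B_UP")))
  })
  venn <- stage("venn", {
    out <- lapply(c(BEC = "BEC", LEC = "LEC"), function(cl) {
      inputs <- list(A = markers$A[[cl]], B = markers$B[[cl]])
      if (!is.null(markerFixtures)) {
        ext <- Filter(function(l) l@vesselClass == cl, markerFixtures)
        for (l in ext) inputs[[l@studyId]] <- l@genes
      }
      vennPartition(inputs)
    })
    out
  })

  embedding_samples <- ann$sample_id[
    inDataset(ann, "A") | ann$cell_class %in% c("HMEC1", "TIME", "CONTROL")]
  emb <- stage("mds", {
    d <- euclideanDistances(es[, intersect(colnames(es), embedding_samples)])
    classicalMds(d, k = k)
  })
  separation <- stage("separation", clusterSeparation(emb, ann))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage("write", {
      writeExpressionTSV(exprsMatrix(es), file.path(outDir, "merged.tsv"))
      writeExpressionTSV(exprsMatrix(harmonized),
                         file.path(outDir, "harmonized.tsv"))
      writeAnnotations(ann, file.path(outDir, "annotations.tsv"))
      for (ds in names(tables))
        writeDifferentialTSV(tables[[ds]],
                             file.path(outDir, paste0("de_", ds, ".tsv")))
      for (cl in names(venn))
        writeVennReport(venn[[cl]],
                        file.path(outDir, paste0("venn_", tolower(cl),
                                                 ".json")))
      utils::write.table(
        data.frame(sample_id = emb@sampleIds, emb@coords),
        file.path(outDir, "mds_coords.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c("merged.tsv", "harmonized.tsv", "annotations.tsv",
                    paste0("de_", names(tables), ".tsv"),
                    paste0("venn_", tolower(names(venn)), ".json"),
                    "mds_coords.tsv")
      NULL
    })
  }

  manifest <- list(
    seed = if (is(config, "SimulationConfig")) config@seed else NA_integer_,
    thresholds = list(min_frac = minFrac, fc_threshold = fcThreshold,
                      q_threshold = qThreshold, k = k),
    stages = stages,
    n_genes_merged = nrow(es),
    n_genes_harmonized = nrow(harmonized),
    n_markers = lapply(markers, function(m) lapply(m, length)),
    outputs = if (!is.null(outDir))
      as.list(tools::md5sum(file.path(outDir, outputs)))
    else list()
  )
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  list(endoset = es, harmonized = harmonized, tables = tables,
       markers = markers, venn = venn, embedding = emb,
       separation = separation, truth = truth, manifest = manifest)
}
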