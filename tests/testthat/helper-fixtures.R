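# Shared fixture builders. Everything is generated in code; the only files
# on disk are the packaged Table 1 marker CSVs.

table1Path <- function(which) {
  system.file("extdata", paste0("table1_", which, ".csv"),
              package = "vesselmark")
}

# tiny deterministic expression matrix with optional missing cells
tinyMatrix <- function(nr = 3, nc = 4, na_cells = NULL, seed = 42) {
  set.seed(seed)
  m <- matrix(round(rnorm(nr * nc, 8, 2), 3), nr, nc,
              dimnames = list(paste0("g", seq_len(nr)),
                              paste0("s", seq_len(nc))))
  if (!is.null(na_cells)) m[na_cells] <- NA
  m
}

# small simulation config: quick to generate, still multi-platform
smallConfig <- function(seed = 7, nGenes = 400L, ...) {
  args <- list(
    nGenes = nGenes, nMarkerBec = 20L, nMarkerLec = 20L, effectLog2 = 2,
    samplesPerPlatform = list(
      GPL570 = c(BEC = 8L, LEC = 6L, HMEC1 = 3L, TIME = 3L, CONTROL = 2L),
      GPL571 = c(BEC = 4L, LEC = 2L)
    ),
    datasetA = list(platforms = "GPL570", classes = c("BEC", "LEC")),
    noiseSd = 0.4, missingRate = 0.01,
    geneCoverage = c(GPL570 = 1, GPL571 = 0.8),
    driftNGenes = 20L, seed = seed)
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

writeTempTSV <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
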