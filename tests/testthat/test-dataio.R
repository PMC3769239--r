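test_that("expression TSV parsing handles missing values and preserves order", {
  path <- writeTempTSV(c("gene_id\ts1\ts2",
                         "g1\t1.5\tNA",
                         "g2\t-2\t3.25"))
  m <- readExpressionTSV(path)
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(rownames(m), c("g1", "g2"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_identical(sum(is.na(m)), 1L)
  expect_true(is.na(m["g1", "s2"]))
  expect_equal(m["g2", "s2"], 3.25)
})

test_that("malformed expression files give informative format errors", {
  expect_error(readExpressionTSV(writeTempTSV("gene_id\ts1\ts2")),
               "header only")
  expect_error(
    readExpressionTSV(writeTempTSV(c("gene_id\ts1", "g1\t1", "g1\t2"))),
    "duplicate gene id: g1")
  expect_error(
    readExpressionTSV(writeTempTSV(c("gene_id\ts1\ts1", "g1\t1\t2"))),
    "duplicate sample id: s1")
  # non-numeric cell is named with its position; empty cells are errors too
  expect_error(
    readExpressionTSV(writeTempTSV(c("gene_id\ts1\ts2", "g1\t1\toops"))),
    "'oops'.*gene g1.*column s2")
  expect_error(
    readExpressionTSV(writeTempTSV(c("gene_id\ts1\ts2", "g1\t1\t"))),
    "non-numeric")
})

test_that("expression TSV round trip is lossless", {
  for (seed in 1:5) {
    m <- tinyMatrix(nr = 6, nc = 5, seed = seed)
    m[sample(length(m), 4)] <- NA
    m[] <- m + pi * 1e-8  # non-representable decimals survive the trip
    path <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTSV(m, path)
    expect_identical(readExpressionTSV(path), m)
  }
})

test_that("annotation manifests parse memberships and reject bad tokens", {
  path <- writeTempTSV(c(
    "sample_id\tplatform\tcell_class\tdataset_membership\tstudy_id",
    "s1\tGPL570\tBEC\tA|B\tstudy1",
    "s2\tGPL571\tLEC\tB\tstudy2",
    "s3\tGPL570\tHMEC1\t\tstudy1"))
  ann <- readAnnotations(path)
  expect_identical(nrow(ann), 3L)
  expect_identical(ann$dataset_membership[[1]], c("A", "B"))
  expect_identical(ann$dataset_membership[[2]], "B")
  expect_identical(ann$dataset_membership[[3]], character(0))
  expect_identical(inDataset(ann, "A"), c(TRUE, FALSE, FALSE))
  expect_identical(inDataset(ann, "B"), c(TRUE, TRUE, FALSE))

  bad <- writeTempTSV(c(
    "sample_id\tplatform\tcell_class\tdataset_membership\tstudy_id",
    "s1\tGPL999\tBEC\tA\tstudy1"))
  expect_error(readAnnotations(bad), "GPL999")
  bad2 <- writeTempTSV(c(
    "sample_id\tplatform\tcell_class\tdataset_membership\tstudy_id",
    "s1\tGPL570\tFIBROBLAST\tA\tstudy1"))
  expect_error(readAnnotations(bad2), "FIBROBLAST")
})

test_that("annotation round trip preserves all fields", {
  path <- writeTempTSV(c(
    "sample_id\tplatform\tcell_class\tdataset_membership\tstudy_id",
    "s1\tGPL570\tBEC\tA|B\tstudy1",
    "s2\tGPL5188\tCONTROL\t\tstudy3"))
  ann <- readAnnotations(path)
  out <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(ann, out)
  expect_identical(readAnnotations(out), ann)
})

test_that("marker lists group by study and class with set semantics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,vessel_class,gene",
               "Hirakawa,LEC,pdpn",
               "Hirakawa,LEC,PROX1",
               "Hirakawa,LEC,RELN",
               "Hirakawa,LEC,PROX1"), path)  # duplicate collapses
  lists <- readMarkerLists(path)
  expect_length(lists, 1L)
  expect_setequal(lists[[1]]@genes, c("PDPN", "PROX1", "RELN"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,vessel_class,gene", "x,VSMC,ACTA2"), bad)
  expect_error(readMarkerLists(bad), "VSMC")
})

test_that("symbol canonicalization upper-cases, trims and splits compounds", {
  expect_identical(canonicalizeSymbols(" pdpn "), "PDPN")
  expect_identical(canonicalizeSymbols("LAMC1, LAMB2"), c("LAMC1", "LAMB2"))
  expect_identical(canonicalizeSymbols("SEC 61B"), "SEC61B")
  expect_identical(canonicalizeSymbols("FN 1"), "FN1")
})

test_that("packaged marker fixtures parse into three studies per class", {
  for (cls in c("bec", "lec")) {
    lists <- readMarkerLists(table1Path(cls))
    expect_length(lists, 3L)
    expect_setequal(vapply(lists, function(l) l@studyId, ""),
                    c("Keuschnigg", "Petrova", "Hirakawa"))
  }
  bec <- readMarkerLists(table1Path("bec"))
  sets <- markerSets(bec, "BEC")
  # compound probe labels were split into separate symbols
  expect_true(all(c("C17ORF72", "ICAM2") %in% sets$Petrova))
  expect_true(all(c("LAMC1", "LAMB2", "FN1") %in% sets$Hirakawa))
})

test_that("venn reports record labels, sizes and members consistently", {
  part <- vennPartition(list(A = c("x", "y"), B = c("y", "z")))
  path <- withr::local_tempfile(fileext = ".json")
  writeVennReport(part, path)
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(rep$regions, 3L)
  for (r in rep$regions) {
    expect_identical(r$size, length(r$genes))
    expect_setequal(unlist(r$genes), regions(part)[[r$label]])
  }

  # two empty input sets: a report with only zero-size regions
  empty <- vennPartition(list(A = character(), B = character()))
  writeVennReport(empty, path)
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_true(all(vapply(rep$regions, function(r) r$size == 0L, NA)))

  # the printed BEC table has an empty Keuschnigg-Hirakawa-exclusive region
  bec <- markerSets(readMarkerLists(table1Path("bec")), "BEC")
  writeVennReport(vennPartition(bec), path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  kh <- rep$regions[rep$regions$label == "Hirakawa&Keuschnigg", ]
  expect_identical(kh$size, 0L)
})

test_that("gene id maps are functions from source label to canonical id", {
  path <- writeTempTSV(c("source\tgene_id", "p1\tPDPN", "p2\tPDPN",
                         "p3\tPROX1"))
  map <- readGeneIdMap(path)
  expect_identical(unname(map[c("p1", "p2", "p3")]),
                   c("PDPN", "PDPN", "PROX1"))
  bad <- writeTempTSV(c("source\tgene_id", "p1\tPDPN", "p1\tPROX1"))
  expect_error(readGeneIdMap(bad), "multiple ids")
})
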