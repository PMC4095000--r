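test_that("compound table reading aggregates links and is order-independent", {
  header <- "compound_id\tname\tcompound_class\ttarget_id\tlink_type"
  rows <- c("c1\ting a\therbal_ingredient\tT1\tdirect",
            "c1\ting a\therbal_ingredient\tT2\tdirect")
  ct <- readCompoundTable(writeTempTsv(c(header, rows)))
  expect_identical(compoundIds(ct), "c1")
  expect_identical(directTargets(ct), c("T1", "T2"))
  expect_identical(nrow(compoundLinks(ct)), 2L)

  # header-only file gives an empty table
  empty <- readCompoundTable(writeTempTsv(header))
  expect_length(compoundIds(empty), 0)

  # shuffling data rows yields an identical object
  more <- c("c2\tdrug b\twestern_drug\tT3\tdirect",
            "c1\ting a\therbal_ingredient\tT3\tindirect")
  a <- readCompoundTable(writeTempTsv(c(header, rows, more)))
  b <- readCompoundTable(writeTempTsv(c(header, rev(c(rows, more)))))
  expect_identical(compoundLinks(a), compoundLinks(b))
})

test_that("compound table reader rejects malformed input precisely", {
  header <- "compound_id\tname\tcompound_class\ttarget_id\tlink_type"
  expect_error(
    readCompoundTable(writeTempTsv(
      c("compound_id\tname\tcompound_class\ttarget_id",
        "c1\tx\therbal_ingredient\tT1"))),
    "link_type")
  expect_error(
    readCompoundTable(writeTempTsv(
      c(header, "c1\tx\tmystery_class\tT1\tdirect"))),
    "compound_class")
  expect_error(
    readCompoundTable(writeTempTsv(
      c(header, "c1\tx\therbal_ingredient\tT1\tsideways"))),
    "link_type")
  expect_error(
    readCompoundTable(writeTempTsv(
      c(header, "c1\tname one\therbal_ingredient\tT1\tdirect",
        "c1\tname two\therbal_ingredient\tT2\tdirect"))),
    "conflicting")
  # western drugs cannot carry indirect links
  expect_error(
    readCompoundTable(writeTempTsv(
      c(header, "w1\tx\twestern_drug\tT1\tindirect"))),
    "direct")
})

test_that("the shipped census fixture has 118 distinct herbal direct targets", {
  ds <- paperFixture()
  f <- tempfile(fileext = ".tsv")
  writeCompoundTable(datasetCompounds(ds), f)
  ct <- readCompoundTable(f)
  expect_length(directTargets(ct, "herbal_ingredient"), 118)
})

test_that("annotation table parsing handles list cells and defaults", {
  header <- paste("target_id", "name", "ttd_status", "diseases",
                  "domain_ids", "family", "locations", "is_tf",
                  "tf_gene_count", sep = "\t")
  f <- writeTempTsv(c(
    header,
    "P05412\tc-Jun\tsuccessful\td1; d2\tPF1\tfactor_regulator\tnucleus\t1\t19",
    "T9\tplain\tabsent\t\t\tother\t\t0\t0"))
  ann <- readAnnotationTable(f)
  tb <- annotationTable(ann)
  j <- tb[tb$target_id == "P05412", ]
  expect_identical(j$tf_gene_count, 19L)
  expect_true(j$is_tf)
  expect_identical(j$diseases[[1]], c("d1", "d2"))   # whitespace stripped
  expect_identical(tb$diseases[tb$target_id == "T9"][[1]], character(0))

  expect_error(readAnnotationTable(writeTempTsv(c(
    header, "T1\tx\tabsent\t\t\tother\t\tmaybe\t0"))), "boolean")
  expect_error(readAnnotationTable(writeTempTsv(c(
    header,
    "T1\tx\tabsent\t\t\tother\t\t0\t0",
    "T1\ty\tresearch\t\t\tenzyme\t\t0\t0"))), "conflicting")
})

test_that("annotation write-then-read round-trips random records", {
  g <- generateDataset(syntheticConfig(seed = 7, nTargetsPerClass = 25,
                                       nSharedTargets = 0))
  ann <- datasetAnnotations(g$dataset)
  f <- tempfile(fileext = ".tsv")
  writeAnnotationTable(ann, f)
  back <- readAnnotationTable(f)
  tb1 <- annotationTable(ann)
  tb2 <- annotationTable(back)
  # list cells are unordered collections on disk; compare as sets
  expect_identical(tb1$target_id, tb2$target_id)
  expect_identical(tb1$ttd_status, tb2$ttd_status)
  expect_identical(tb1$is_tf, tb2$is_tf)
  expect_identical(tb1$tf_gene_count, tb2$tf_gene_count)
  expect_identical(lapply(tb1$diseases, sort), lapply(tb2$diseases, sort))
  expect_identical(tb1$domain_ids, tb2$domain_ids)
  expect_identical(lapply(tb1$locations, sort), lapply(tb2$locations, sort))
})

test_that("GMT parsing reads ids, categories and members", {
  f <- writeTempTsv(c("hsa04020\tbasic Calcium signaling\tT1\tT2",
                      "hsa05410\tdisease Hypertrophic cardiomyopathy\tT2\tT3\tT2"))
  pc <- readGmt(f)
  expect_identical(length(pc), 2L)
  expect_identical(pathwayMembers(pc)[["hsa04020"]], c("T1", "T2"))
  expect_identical(unname(pathwayCategory(pc)), c("basic", "disease"))
  # duplicate members deduplicated
  expect_length(pathwayMembers(pc)[["hsa05410"]], 2)
  expect_error(readGmt(writeTempTsv("only\ttwo")), "line 1")

  # 35 basic + 30 disease lines -> 65 sets, 35 basic
  lines <- c(sprintf("b%02d\tbasic set %d\tT1\tT2", 1:35, 1:35),
             sprintf("d%02d\tdisease set %d\tT3", 1:30, 1:30))
  big <- readGmt(writeTempTsv(lines))
  expect_identical(length(big), 65L)
  expect_identical(sum(pathwayCategory(big) == "basic"), 35L)
})

test_that("GMT write-then-read round-trips including categories", {
  g <- generateDataset(syntheticConfig(seed = 3, nTargetsPerClass = 30,
                                       nPathways = 12))
  pc <- datasetPathways(g$dataset)
  f <- tempfile(fileext = ".gmt")
  writeGmt(pc, f)
  back <- readGmt(f)
  expect_identical(pathwayIds(back), pathwayIds(pc))
  expect_identical(pathwayCategory(back), pathwayCategory(pc))
  expect_identical(pathwayMembers(back), pathwayMembers(pc))
})

test_that("compound table round-trip is lossless over random datasets", {
  for (s in 1:5) {
    g <- generateDataset(syntheticConfig(seed = s, nTargetsPerClass = 20,
                                         nCompoundsPerClass = 8))
    ct <- datasetCompounds(g$dataset)
    f <- tempfile(fileext = ".tsv")
    writeCompoundTable(ct, f)
    expect_identical(compoundLinks(readCompoundTable(f)),
                     compoundLinks(ct))
  }
})

test_that("dataset validation reports problems without throwing", {
  ds <- tinyDataset()
  expect_identical(nrow(validateDataset(ds)), 0L)

  links <- compoundLinks(datasetCompounds(ds))
  links <- rbind(links, data.frame(
    compound_id = "h1", name = "ing one",
    compound_class = "herbal_ingredient", target_id = "TX",
    link_type = "direct", stringsAsFactors = FALSE))
  broken <- CvdDataset(CompoundTable(links), datasetAnnotations(ds),
                       datasetPathways(ds), universeSize = 4)
  rep <- validateDataset(broken)
  expect_identical(rep$kind, "dangling_compound_target")
  expect_identical(rep$id, "TX")

  small <- CvdDataset(datasetCompounds(ds), datasetAnnotations(ds),
                      datasetPathways(ds), universeSize = 2)
  expect_true("universe_too_small" %in% validateDataset(small)$kind)
})

test_that("container validity methods reject inconsistent objects", {
  expect_error(PathwayCollection("P1", members = list(character(0))),
               "empty member")
  expect_error(TargetAnnotations(data.frame(
    target_id = c("T1", "T1"), name = "x", ttd_status = "absent",
    diseases = "", domain_ids = "", family = "other", locations = "",
    is_tf = "0", tf_gene_count = "0", stringsAsFactors = FALSE)),
    "duplicate")
})
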