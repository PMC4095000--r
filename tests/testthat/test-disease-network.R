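chainFixture <- function() {
  nodes <- data.frame(node_id = c("A", "B", "C"),
                      compartment = c("plasma_membrane", "cytoplasm",
                                      "nucleus"),
                      position = c("upstream", "upstream", "downstream"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source_id = c("A", "B"), target_id = c("B", "C"),
                      effect = c("activation", "inhibition"),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

test_that("subnetwork assembly validates endpoints and round-trips", {
  fx <- chainFixture()
  ef <- tempfile(fileext = ".tsv"); nf <- tempfile(fileext = ".tsv")
  utils::write.table(fx$edges, ef, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$nodes, nf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sn <- assembleSubnetwork(ef, nf, "chain")
  expect_identical(nrow(subnetworkNodes(sn)), 3L)

  # dangling endpoint names the offending node
  bad <- rbind(fx$edges, data.frame(source_id = "C", target_id = "GHOST",
                                    effect = "activation"))
  utils::write.table(bad, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(assembleSubnetwork(ef, nf, "chain"), "GHOST")

  # write/read round-trip preserves structure
  e2 <- tempfile(fileext = ".tsv"); n2 <- tempfile(fileext = ".tsv")
  writeSubnetwork(sn, e2, n2)
  back <- assembleSubnetwork(e2, n2, "chain")
  expect_identical(subnetworkNodes(back), subnetworkNodes(sn))
  expect_identical(subnetworkEdges(back), subnetworkEdges(sn))
})

test_that("regulator annotation marks herbal, western and common nodes", {
  fx <- chainFixture()
  sn <- DiseaseSubnetwork("chain", fx$nodes, fx$edges)
  links <- data.frame(
    compound_id = c("h1", "h1", "w1", "h2"),
    name = c("ing", "ing", "drug", "ing2"),
    compound_class = c("herbal_ingredient", "herbal_ingredient",
                       "western_drug", "herbal_ingredient"),
    target_id = c("C", "B", "B", "A"),
    link_type = c("direct", "direct", "direct", "indirect"),
    stringsAsFactors = FALSE)
  ann <- annotateRegulators(sn, CompoundTable(links))
  regs <- subnetworkRegulators(ann)
  expect_identical(regs[["C"]], "herbal")
  expect_setequal(regs[["B"]], c("herbal", "western"))   # common target
  expect_null(regs[["A"]])   # indirect links never annotate

  cov <- coverageSummary(ann)
  expect_identical(cov$n_herbal_targets, 2L)
  expect_identical(cov$n_western_targets, 1L)
  expect_identical(cov$n_common_targets, 1L)
})

test_that("coverage accounting is conserved and relabel-invariant", {
  for (s in 1:5) {
    g <- generateSubnetwork(syntheticConfig(seed = s), nNodes = 60)
    cov <- coverageSummary(g$subnetwork)
    regs <- subnetworkRegulators(g$subnetwork)
    expect_identical(length(regs),
                     cov$n_herbal_targets + cov$n_western_targets -
                       cov$n_common_targets)
    # position and compartment counts sum to the class totals
    expect_identical(sum(cov$per_position$herbal), cov$n_herbal_targets)
    expect_identical(sum(cov$per_compartment$western),
                     cov$n_western_targets)

    # relabeling nodes leaves every count unchanged
    sn <- g$subnetwork
    map <- stats::setNames(paste0("XX_", subnetworkNodes(sn)$node_id),
                           subnetworkNodes(sn)$node_id)
    nodes2 <- transform(subnetworkNodes(sn),
                        node_id = unname(map[node_id]))
    edges2 <- transform(subnetworkEdges(sn),
                        source_id = unname(map[source_id]),
                        target_id = unname(map[target_id]))
    regs2 <- stats::setNames(regs, unname(map[names(regs)]))
    cov2 <- coverageSummary(DiseaseSubnetwork("relabel", nodes2, edges2,
                                              regs2))
    expect_identical(cov2$n_herbal_targets, cov$n_herbal_targets)
    expect_identical(cov2$per_position$herbal, cov$per_position$herbal)
  }
})

test_that("position preference reports class fractions over assigned nodes", {
  nodes <- data.frame(node_id = paste0("N", 1:6),
                      compartment = "cytoplasm",
                      position = c("downstream", "downstream", "upstream",
                                   "downstream", "upstream", "unassigned"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source_id = character(0), target_id = character(0),
                      effect = character(0))
  regs <- list(N1 = "herbal", N2 = "herbal", N3 = "western",
               N4 = "western", N5 = "western", N6 = "herbal")
  sn <- DiseaseSubnetwork("pp", nodes, edges, regs)
  pref <- positionPreference(coverageSummary(sn))
  # N6 is unassigned and excluded from the herbal denominator
  expect_equal(pref$herbal_downstream_fraction, 1)
  expect_equal(pref$western_upstream_fraction, 2 / 3)

  # equal split gives one half
  regsEq <- list(N1 = "herbal", N3 = "herbal")
  prefEq <- positionPreference(coverageSummary(
    DiseaseSubnetwork("eq", nodes, edges, regsEq)))
  expect_equal(prefEq$herbal_downstream_fraction, 0.5)
  # a class with no positioned regulated node yields NA
  expect_true(is.na(prefEq$western_upstream_fraction))
})

test_that("position preference ignores edge orientation", {
  g <- generateSubnetwork(syntheticConfig(seed = 8), nNodes = 40)
  sn <- g$subnetwork
  rev <- DiseaseSubnetwork(sn@name, subnetworkNodes(sn),
                           transform(subnetworkEdges(sn),
                                     source_id = target_id,
                                     target_id = source_id),
                           subnetworkRegulators(sn))
  expect_identical(positionPreference(coverageSummary(sn)),
                   positionPreference(coverageSummary(rev)))
})

test_that("shipped subnetwork fixtures reproduce the class asymmetry", {
  fx <- cvdsSubnetworkFixtures()
  apo <- coverageSummary(fx$apoptosis)
  vecc <- coverageSummary(fx$vecc)
  # apoptosis cascade: many herbal targets, exactly two western
  expect_identical(apo$n_western_targets, 2L)
  expect_gt(apo$n_herbal_targets, 5L)
  # contraction cascade: many western targets, exactly two herbal
  expect_identical(vecc$n_herbal_targets, 2L)
  expect_gt(vecc$n_western_targets, 5L)
  # directionality: herbal skews downstream in apoptosis, western
  # upstream in the contraction cascade
  expect_gt(positionPreference(apo)$herbal_downstream_fraction, 0.5)
  expect_gt(positionPreference(vecc)$western_upstream_fraction, 0.5)
})
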