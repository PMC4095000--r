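randomMembershipCollection <- function(nTargets, nPathways, p, seed) {
  set.seed(seed)
  targets <- sprintf("T%03d", seq_len(nTargets))
  members <- lapply(seq_len(nPathways), function(i) {
    m <- targets[stats::runif(nTargets) < p]
    if (length(m) == 0) m <- sample(targets, 1)
    m
  })
  list(targets = targets,
       pathways = PathwayCollection(sprintf("P%03d", seq_len(nPathways)),
                                    members = members))
}

test_that("target-pathway edges mirror pathway membership", {
  pw <- PathwayCollection(c("P1", "P2", "P3"),
                          members = list("T1", "T2",
                                         c("T1", "T2", "T3")))
  net <- buildTargetPathwayNetwork(c("T1", "T2"), pw)
  # two targets, each in its own pathway plus the shared one
  expect_identical(unname(nodeDegrees(net, "left")), c(2L, 2L))
  expect_identical(sum(nodeDegrees(net, "right")), 4L)
  # T3 is not in the target set: P3 still appears via T1/T2
  expect_true("P3" %in% networkNodes(net, "right"))

  # a target in 3 pathways has degree 3; unmapped targets stay, degree 0
  net2 <- buildTargetPathwayNetwork(c("T1", "T2", "T9"), pw)
  expect_identical(nodeDegrees(net2, "left")[["T9"]], 0L)

  # enrichment attributes propagate to pathway nodes
  uni <- c("T1", "T2", "T3", "T4")
  enr <- enrichPathways(c("T1", "T2"), pw, uni)
  net3 <- buildTargetPathwayNetwork(c("T1", "T2"), pw, enr)
  at <- networkNodeAttrs(net3)
  expect_false(anyNA(at$p_value[at$node_kind == "pathway"]))
})

test_that("degree conservation holds on random bipartite networks", {
  rc <- randomMembershipCollection(200, 35, 0.05, seed = 4)
  net <- buildTargetPathwayNetwork(rc$targets, rc$pathways)
  expect_identical(sum(nodeDegrees(net, "left")), nrow(networkEdges(net)))
  expect_identical(sum(nodeDegrees(net, "right")), nrow(networkEdges(net)))
  # construction is deterministic and idempotent
  net2 <- buildTargetPathwayNetwork(rc$targets, rc$pathways)
  expect_identical(networkEdges(net), networkEdges(net2))
})

test_that("compound-pathway network links via direct targets only", {
  links <- data.frame(
    compound_id = c("h1", "h1", "w1"),
    name = c("ing", "ing", "drug"),
    compound_class = c("herbal_ingredient", "herbal_ingredient",
                       "western_drug"),
    target_id = c("T1", "T2", "T3"),
    link_type = c("direct", "indirect", "direct"),
    stringsAsFactors = FALSE)
  pw <- PathwayCollection(c("P1", "P2"),
                          members = list("T2", c("T1", "T3")))
  net <- buildCompoundPathwayNetwork(CompoundTable(links), pw)
  ed <- networkEdges(net)
  # the indirect T2 link must not create an edge to P1
  expect_identical(nrow(ed[ed$right == "P1", ]), 0L)
  expect_setequal(ed$left[ed$right == "P2"], c("h1", "w1"))
  expect_identical(sum(nodeDegrees(net, "left")), nrow(ed))
})

test_that("degree distribution frequencies sum to one per side", {
  # star: one pathway linked to five targets
  pw <- PathwayCollection("hub", members = list(paste0("T", 1:5)))
  star <- buildTargetPathwayNetwork(paste0("T", 1:5), pw)
  ddL <- degreeDistribution(star, "left")
  ddR <- degreeDistribution(star, "right")
  expect_identical(ddL$points$x, 1L)
  expect_equal(ddL$points$f_x, 1)
  expect_identical(ddR$points$x, 5L)
  expect_equal(ddR$points$f_x, 1)

  # all isolated nodes: the whole mass sits at x = 0
  iso <- buildTargetPathwayNetwork(paste0("Z", 1:4), pw)
  ddI <- degreeDistribution(iso, "left")
  expect_identical(ddI$points$x, 0L)
  expect_equal(ddI$points$f_x, 1)

  rc <- randomMembershipCollection(150, 25, 0.04, seed = 9)
  net <- buildTargetPathwayNetwork(rc$targets, rc$pathways)
  for (side in c("left", "right", "both")) {
    expect_equal(sum(degreeDistribution(net, side)$points$f_x), 1)
  }
})

test_that("power-law fit is exact on noiseless input and flat on uniform", {
  f <- (1:10)^(-2)
  dd <- structure(list(points = data.frame(x = 1:10, count = 1L,
                                           f_x = f / sum(f)),
                       n_nodes = 10L, side = "left"),
                  class = "DegreeDistribution")
  fit <- suppressWarnings(fitPowerLaw(dd))
  expect_equal(fit$exponent, 2, tolerance = 1e-9)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-9)

  flat <- structure(list(points = data.frame(x = 1:10, count = 1L,
                                             f_x = rep(0.1, 10)),
                         n_nodes = 10L, side = "left"),
                    class = "DegreeDistribution")
  expect_lt(abs(suppressWarnings(fitPowerLaw(flat))$exponent), 1e-9)

  two <- structure(list(points = data.frame(x = 1:2, count = 1L,
                                            f_x = c(0.5, 0.5)),
                        n_nodes = 2L, side = "left"),
                   class = "DegreeDistribution")
  expect_error(fitPowerLaw(two), "unfittable")
})

test_that("sampled power-law degree sequences are recovered by the fit", {
  net <- samplePowerLawNetwork(2000, 2.5, xMax = 100, seed = 31)
  fit <- fitPowerLaw(degreeDistribution(net, "left"))
  expect_lt(abs(fit$exponent - 2.5), 0.4)
})

test_that("network serialization round-trips in both formats", {
  rc <- randomMembershipCollection(40, 8, 0.1, seed = 6)
  uni <- rc$targets
  enr <- enrichPathways(uni[1:20], rc$pathways, uni)
  net <- buildTargetPathwayNetwork(uni[1:20], rc$pathways, enr)

  g <- tempfile(fileext = ".graphml")
  writeNetwork(net, g, "graphml")
  back <- readNetwork(g, "graphml")
  expect_setequal(networkNodes(back, "left"), networkNodes(net, "left"))
  expect_identical(networkEdges(back), networkEdges(net))
  expect_equal(
    networkNodeAttrs(back)$p_value[match(networkNodeAttrs(net)$node_id,
                                         networkNodeAttrs(back)$node_id)],
    networkNodeAttrs(net)$p_value, tolerance = 1e-9)

  e <- tempfile(fileext = ".tsv")
  writeNetwork(net, e, "edgelist")
  back2 <- readNetwork(e, "edgelist")
  expect_identical(networkEdges(back2), networkEdges(net))

  # empty network writes a valid zero-edge file
  empty <- buildTargetPathwayNetwork(character(0), rc$pathways)
  writeNetwork(empty, g, "graphml")
  expect_identical(nrow(networkEdges(readNetwork(g, "graphml"))), 0L)
})
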