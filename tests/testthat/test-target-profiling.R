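test_that("TTD tallies partition the group and obey the rounding convention", {
  ds <- paperFixture()
  tw <- tallyTtd(allTargets(ds, "western_drug"), ds, "western")
  # conservation: status counts sum to the in-TTD total, and the absent
  # remainder completes the denominator
  expect_identical(sum(unlist(tw$per_status_count)), tw$in_ttd_count)
  expect_identical(tw$in_ttd_count + tw$absent_count, tw$denominator)
  # percentages are half-up at one decimal
  expect_equal(tw$per_status_pct$successful,
               roundHalfUp(100 * tw$per_status_count$successful /
                             tw$denominator, 1))
  expect_error(tallyTtd(character(0), ds), "empty")

  # all-absent group
  tb <- annotationTable(ds)
  absent <- tb$target_id[tb$ttd_status == "absent"][1:5]
  expect_equal(tallyTtd(absent, ds, "abs")$in_ttd_pct, 0)
})

test_that("d/t sums disease associations per target, not the disease union", {
  # two targets sharing one disease name still contribute two associations
  ann <- TargetAnnotations(data.frame(
    target_id = c("A", "B", "C"), name = "p",
    ttd_status = "successful",
    diseases = I(list(c("hypertension", "stroke"), "hypertension",
                      c("x", "y", "z"))),
    domain_ids = "", family = "enzyme", locations = "cytoplasm",
    is_tf = FALSE, tf_gene_count = 0L, stringsAsFactors = FALSE))
  dt <- computeDt(c("A", "B", "C"), ann, "successful")
  expect_identical(dt$n_disease_associations, 6L)
  expect_equal(dt$dt_value, 2)
  expect_error(computeDt(c("A", "B"), ann, "research"), "no target")

  # constant case: every target with exactly 3 diseases gives d/t 3
  ann3 <- TargetAnnotations(data.frame(
    target_id = paste0("T", 1:4), name = "p", ttd_status = "research",
    diseases = I(replicate(4, paste0("d", 1:3), simplify = FALSE)),
    domain_ids = "", family = "enzyme", locations = "cytoplasm",
    is_tf = FALSE, tf_gene_count = 0L, stringsAsFactors = FALSE))
  expect_equal(computeDt(paste0("T", 1:4), ann3, "research")$dt_value, 3)
})

test_that("d/t of a merged group is the weighted mean of its parts", {
  ds <- paperFixture()
  w <- allTargets(ds, "western_drug")
  h <- directTargets(ds, "herbal_ingredient")
  h <- setdiff(h, w)  # disjoint parts
  dw <- computeDt(w, ds, "successful")
  dh <- computeDt(h, ds, "successful")
  dm <- computeDt(c(w, h), ds, "successful")
  expect_equal(dm$dt_value,
               (dw$n_targets * dw$dt_value + dh$n_targets * dh$dt_value) /
                 (dw$n_targets + dh$n_targets))
})

test_that("domain-count profile bins every target exactly once", {
  ann <- TargetAnnotations(data.frame(
    target_id = c("A", "B", "C"), name = "p", ttd_status = "absent",
    diseases = "", domain_ids = I(list("PF1", "PF2", c("PF1", "PF3"))),
    family = "enzyme", locations = "cytoplasm",
    is_tf = FALSE, tf_gene_count = 0L, stringsAsFactors = FALSE))
  pr <- domainCountProfile(c("A", "B", "C"), ann)
  expect_identical(pr$count[pr$bin_label == "1"], 2L)
  expect_identical(pr$count[pr$bin_label == "2"], 1L)
  expect_equal(sum(pr$fraction), 1)

  # all domainless: a single zero bin
  ann0 <- TargetAnnotations(data.frame(
    target_id = c("A", "B"), name = "p", ttd_status = "absent",
    diseases = "", domain_ids = "", family = "enzyme",
    locations = "cytoplasm", is_tf = FALSE, tf_gene_count = 0L,
    stringsAsFactors = FALSE))
  pr0 <- domainCountProfile(c("A", "B"), ann0)
  expect_identical(pr0$bin_label, "0")
  expect_equal(pr0$fraction, 1)
})

test_that("planted domain-count gap separates the class profiles", {
  g <- generateDataset(syntheticConfig(seed = 11, nTargetsPerClass = 300,
                                       nSharedTargets = 0))
  tb <- annotationTable(g$dataset)
  h <- tb$target_id[startsWith(tb$target_id, "SYNH")]
  w <- tb$target_id[startsWith(tb$target_id, "SYNW")]
  meanOf <- function(pr) {
    sum(as.numeric(pr$bin_label) * pr$fraction)
  }
  mh <- meanOf(domainCountProfile(h, g$dataset))
  mw <- meanOf(domainCountProfile(w, g$dataset))
  expect_gt(mh, mw)              # 2.5 vs 1.5 planted means
  expect_lt(abs(mh - 2.5), 0.4)
  expect_lt(abs(mw - 1.5), 0.4)
})

test_that("family profile counts each target once and recovers planted mix", {
  ann <- TargetAnnotations(data.frame(
    target_id = c("A", "B", "C"), name = "p", ttd_status = "absent",
    diseases = "", domain_ids = "",
    family = c("enzyme", "enzyme", "receptor"), locations = "cytoplasm",
    is_tf = FALSE, tf_gene_count = 0L, stringsAsFactors = FALSE))
  pr <- familyProfile(c("A", "B", "C"), ann)
  expect_equal(pr$fraction[pr$bin_label == "enzyme"], 2 / 3)
  expect_equal(pr$fraction[pr$bin_label == "receptor"], 1 / 3)
  expect_equal(sum(pr$fraction), 1)

  # planted 60% enzyme fraction, n = 500: recovered within 5 points
  fw <- list(herbal = c(enzyme = 0.60, channel_transporter = 0.08,
                        receptor = 0.08, factor_regulator = 0.08,
                        structure = 0.06, binding = 0.05, other = 0.05),
             western = c(enzyme = 0.18, channel_transporter = 0.28,
                         receptor = 0.30, factor_regulator = 0.06,
                         structure = 0.04, binding = 0.08, other = 0.06))
  g <- generateDataset(syntheticConfig(seed = 5, nTargetsPerClass = 500,
                                       nSharedTargets = 0,
                                       familyWeights = fw))
  tb <- annotationTable(g$dataset)
  h <- tb$target_id[startsWith(tb$target_id, "SYNH")]
  pr <- familyProfile(h, g$dataset)
  expect_lt(abs(pr$fraction[pr$bin_label == "enzyme"] - 0.6), 0.05)
})

test_that("location profile counts a target once per compartment", {
  ann <- TargetAnnotations(data.frame(
    target_id = c("A", "B"), name = "p", ttd_status = "absent",
    diseases = "", domain_ids = "", family = "enzyme",
    locations = I(list(c("cytoplasm", "nucleus"), "cytoplasm")),
    is_tf = FALSE, tf_gene_count = 0L, stringsAsFactors = FALSE))
  pr <- locationProfile(c("A", "B"), ann)
  expect_identical(pr$count[pr$bin_label == "cytoplasm"], 2L)
  expect_identical(pr$count[pr$bin_label == "nucleus"], 1L)
  # multi-compartment targets push the fraction total above 1
  expect_equal(sum(pr$fraction), 1.5)
})

test_that("TF enrichment behaves as a right tail in the TF count", {
  ann <- TargetAnnotations(data.frame(
    target_id = paste0("T", 1:20), name = "p", ttd_status = "absent",
    diseases = "", domain_ids = "", family = "enzyme",
    locations = "cytoplasm",
    is_tf = rep(c(TRUE, FALSE), c(4, 16)), tf_gene_count = 0L,
    stringsAsFactors = FALSE))
  # zero observed TFs -> p = 1
  none <- tfEnrichment(paste0("T", 5:20), ann, 1000, 50)
  expect_equal(none$p_value, 1)
  # p non-increasing as the group gains TFs with the group size fixed
  ps <- vapply(0:4, function(k) {
    ts <- c(head(paste0("T", 1:4), k), paste0("T", 5:(14 - k)))
    tfEnrichment(ts, ann, 1000, 50)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(tfEnrichment(paste0("T", 1:20), ann, 10, 5), "smaller")
})

test_that("multi-target compound classification follows its precedence", {
  ann <- TargetAnnotations(data.frame(
    target_id = c("T1", "T2", "T3", "T4"), name = "p",
    ttd_status = "absent", diseases = "", domain_ids = "",
    family = c("channel_transporter", "channel_transporter", "enzyme",
               "receptor"),
    locations = "cytoplasm", is_tf = FALSE, tf_gene_count = 0L,
    stringsAsFactors = FALSE))
  pw <- PathwayCollection("P1", members = list(c("T3", "T4")))
  links <- data.frame(
    compound_id = c("single", "famdup", "famdup", "proc", "proc",
                    "loner", "loner"),
    name = c("s", "f", "f", "p", "p", "l", "l"),
    compound_class = "western_drug",
    target_id = c("T1", "T1", "T2", "T3", "T4", "T1", "T3"),
    link_type = "direct", stringsAsFactors = FALSE)
  cls <- classifyMultiTargetCompounds(CompoundTable(links), ann, pw)
  expect_identical(cls[["single"]], "single_target")
  expect_identical(cls[["famdup"]], "same_family_multi")   # both channels
  expect_identical(cls[["proc"]], "same_process_multi")    # share P1
  expect_identical(cls[["loner"]], "other")

  # zero-direct-target compound -> other, with a warning
  links0 <- rbind(links, data.frame(
    compound_id = "ghost", name = "g",
    compound_class = "herbal_ingredient", target_id = "T1",
    link_type = "indirect", stringsAsFactors = FALSE))
  expect_warning(
    cls0 <- classifyMultiTargetCompounds(CompoundTable(links0), ann, pw),
    "zero direct")
  expect_identical(cls0[["ghost"]], "other")
})
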