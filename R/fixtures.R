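# Deterministic fixture encoding the published marginal counts: TTD status
# tallies, per-status disease-association totals and the TF census of the
# two target groups. Individual disease identities are synthetic labels and
# per-target disease counts are a fixed composition realizing the printed
# totals; only the marginals are faithful.

tfCensus <- function() {
  data.frame(
    target_id = c("P10275", "P05412", "P04150", "P08235", "P10827",
                  "P10828", "P35869", "Q07869", "Q03181", "P51843",
                  "P03372", "Q04206", "Q00613", "Q09472", "P40763",
                  "O75469", "Q92731"),
    name = c("AR", "c-Jun", "GR-alpha", "MR", "T3R-alpha", "T3R-beta1",
             "AhR", "PPAR-alpha", "PPAR-beta", "DAX1", "ER-alpha", "RelA",
             "HSF1", "p300", "STAT3", "PXR-1/SXR", "ER-beta"),
    tf_gene_count = c(3L, 19L, 5L, 0L, 4L, 5L, 7L, 0L, 1L, 0L,
                      8L, 12L, 1L, 15L, 3L, 0L, 1L),
    stringsAsFactors = FALSE)
}

# ids of the TFs reported for each group; four are common to both
westernTfIds <- function() {
  c("P10275", "P05412", "P04150", "P08235", "P10827", "P10828", "P35869",
    "Q07869", "Q03181", "P51843")
}
herbalTfIds <- function() {
  c("P05412", "P35869", "Q07869", "Q03181", "P03372", "Q04206", "Q00613",
    "Q09472", "P40763", "O75469", "Q92731")
}
sharedTfIds <- function() intersect(westernTfIds(), herbalTfIds())

fixtureDiseases <- function(ids, counts) {
  stopifnot(length(ids) == length(counts))
  lapply(seq_along(ids), function(i) {
    if (counts[i] == 0) character(0) else
      paste0(ids[i], "_d", seq_len(counts[i]))
  })
}

# deterministic class-flavoured annotation fields (no RNG)
fixtureFlavour <- function(ids, flavour) {
  n <- length(ids)
  i <- seq_len(n)
  if (flavour == "western") {
    family <- c("receptor", "channel_transporter", "enzyme",
                "receptor", "channel_transporter", "other")[1 + (i %% 6)]
    locations <- lapply(i, function(k) {
      if (k %% 3 == 0) c("plasma_membrane", "cytoplasm") else
        "plasma_membrane"
    })
    domains <- lapply(i, function(k) paste0("PF", 100 + (k %% 4),
                                            seq_len(1 + (k %% 2))))
  } else {
    family <- c("enzyme", "factor_regulator", "enzyme", "binding",
                "factor_regulator", "structure")[1 + (i %% 6)]
    locations <- lapply(i, function(k) {
      if (k %% 3 == 0) c("cytoplasm", "nucleus") else
        c("cytoplasm", "nucleus")[1 + (k %% 2)]
    })
    domains <- lapply(i, function(k) paste0("PF", 200 + (k %% 5),
                                            seq_len(2 + (k %% 2))))
  }
  list(family = family, locations = locations, domains = domains)
}

fixtureAnnotationBlock <- function(ids, status, diseaseCounts, flavour) {
  fl <- fixtureFlavour(ids, flavour)
  census <- tfCensus()
  idx <- match(ids, census$target_id)
  isTf <- !is.na(idx)
  domains <- fl$domains
  domains[isTf] <- rep(list(c("PF0104", "PF0105")), sum(isTf))
  locations <- fl$locations
  locations[isTf] <- rep(list("nucleus"), sum(isTf))
  family <- fl$family
  family[isTf] <- "factor_regulator"
  data.frame(
    target_id = ids,
    name = ifelse(isTf, census$name[idx], paste0("protein ", ids)),
    ttd_status = status,
    diseases = I(fixtureDiseases(ids, diseaseCounts)),
    domain_ids = I(domains),
    family = family,
    locations = I(locations),
    is_tf = isTf,
    tf_gene_count = ifelse(isTf, census$tf_gene_count[idx], 0L),
    stringsAsFactors = FALSE)
}

#' Deterministic dataset encoding the published target-census marginals
#'
#' A download-free dataset whose profiling outputs reproduce the published
#' status tallies and diseases-per-target table exactly: 204 western-drug
#' targets (81 successful / 15 clinical trial / 29 research /
#' 2 discontinued; disease-association totals 221 / 45 / 56), 118 herbal
#' direct targets (32 / 10 / 32 / 3; totals 160 / 39 / 76) and 744
#' additional indirect-only herbal targets bringing the herbal all-target
#' group to 862 with 358 targets in TTD. Ten western and eleven herbal
#' direct targets are transcription factors, with the reported
#' transcriptional-gene counts; four TFs are common to both groups.
#' Per-target disease counts are a fixed composition summing to the printed
#' totals; disease identities are synthetic labels. Compounds partition the
#' target groups deterministically and a small deterministic pathway
#' collection is attached for pipeline exercises.
#'
#' @return a [CvdDataset-class].
#' @examples
#' ds <- paperFixture()
#' tallyTtd(allTargets(ds, "western_drug"), ds, "western")
#' @export
paperFixture <- function() {
  shared <- sharedTfIds()           # successful in both groups, 3 diseases
  wTfOnly <- setdiff(westernTfIds(), shared)
  hTfOnly <- setdiff(herbalTfIds(), shared)

  ## western group: 204 targets
  wPlain <- sprintf("TW%03d", seq_len(194))
  wSucc <- c(shared, wTfOnly, wPlain[1:71])              # 81
  wSuccDis <- c(rep(3L, 59), rep(2L, 22))                # 221
  wClin <- wPlain[72:86]                                 # 15
  wClinDis <- rep(3L, 15)                                # 45
  wRes <- wPlain[87:115]                                 # 29
  wResDis <- c(rep(2L, 27), rep(1L, 2))                  # 56
  wDisc <- wPlain[116:117]                               # 2
  wAbs <- wPlain[118:194]                                # 77

  ## herbal direct group: 118 targets (4 shared with western)
  hPlain <- sprintf("TH%03d", seq_len(107))
  hSucc <- c(shared, hTfOnly, hPlain[1:21])              # 32
  # shared 4 carry 3 diseases each (counted in both groups' totals);
  # remaining 28 sum to 148 so the group totals 160
  hSuccDis <- c(rep(3L, 4), rep(5L, 20), rep(6L, 8))
  hClin <- hPlain[22:31]                                 # 10
  hClinDis <- c(rep(4L, 9), 3L)                          # 39
  hRes <- hPlain[32:63]                                  # 32
  hResDis <- c(rep(3L, 12), rep(2L, 20))                 # 76
  hDisc <- hPlain[64:66]                                 # 3
  hAbs <- hPlain[67:107]                                 # 41

  ## herbal indirect-only targets: 744, in-TTD 281 so the all-target
  ## group (862) has 358 in TTD
  hi <- sprintf("HI%04d", seq_len(744))
  hiSucc <- hi[1:52]
  hiClin <- hi[53:130]
  hiRes <- hi[131:270]
  hiDisc <- hi[271:281]
  hiAbs <- hi[282:744]

  ann <- rbind(
    fixtureAnnotationBlock(wSucc, "successful", wSuccDis, "western"),
    fixtureAnnotationBlock(wClin, "clinical_trial", wClinDis, "western"),
    fixtureAnnotationBlock(wRes, "research", wResDis, "western"),
    fixtureAnnotationBlock(wDisc, "discontinued", rep(1L, 2), "western"),
    fixtureAnnotationBlock(wAbs, "absent", rep(1L, 77), "western"),
    fixtureAnnotationBlock(setdiff(hSucc, shared), "successful",
                           hSuccDis[-(1:4)], "herbal"),
    fixtureAnnotationBlock(hClin, "clinical_trial", hClinDis, "herbal"),
    fixtureAnnotationBlock(hRes, "research", hResDis, "herbal"),
    fixtureAnnotationBlock(hDisc, "discontinued", rep(1L, 3), "herbal"),
    fixtureAnnotationBlock(hAbs, "absent", rep(1L, 41), "herbal"),
    fixtureAnnotationBlock(hiSucc, "successful", rep(1L, 52), "herbal"),
    fixtureAnnotationBlock(hiClin, "clinical_trial", rep(1L, 78), "herbal"),
    fixtureAnnotationBlock(hiRes, "research", rep(1L, 140), "herbal"),
    fixtureAnnotationBlock(hiDisc, "discontinued", rep(1L, 11), "herbal"),
    fixtureAnnotationBlock(hiAbs, "absent", rep(1L, 463), "herbal"))
  annotations <- TargetAnnotations(ann)

  westernTargets <- c(wSucc, wClin, wRes, wDisc, wAbs)          # 204
  herbalDirect <- c(hSucc, hClin, hRes, hDisc, hAbs)            # 118

  roundRobin <- function(x, n) split(x, rep(seq_len(n),
                                            length.out = length(x)))
  links <- list()
  wChunks <- roundRobin(westernTargets, 20)
  for (j in seq_along(wChunks)) {
    links[[length(links) + 1L]] <- data.frame(
      compound_id = sprintf("wd_%03d", j),
      name = sprintf("western drug %03d", j),
      compound_class = "western_drug",
      target_id = wChunks[[j]], link_type = "direct",
      stringsAsFactors = FALSE)
  }
  hChunks <- roundRobin(herbalDirect, 20)
  iChunks <- roundRobin(hi, 20)
  for (j in seq_along(hChunks)) {
    links[[length(links) + 1L]] <- data.frame(
      compound_id = sprintf("hi_%03d", j),
      name = sprintf("herbal ingredient %03d", j),
      compound_class = "herbal_ingredient",
      target_id = c(hChunks[[j]], iChunks[[j]]),
      link_type = c(rep("direct", length(hChunks[[j]])),
                    rep("indirect", length(iChunks[[j]]))),
      stringsAsFactors = FALSE)
  }
  compounds <- CompoundTable(do.call(rbind, links))

  # small deterministic pathway collection for pipeline exercises
  pool <- c(herbalDirect, westernTargets)
  nP <- 10
  members <- lapply(seq_len(nP), function(i) {
    idx <- seq.int(i, length(pool), by = nP)
    pool[idx[seq_len(min(30, length(idx)))]]
  })
  pathways <- PathwayCollection(
    sprintf("FIXPW%02d", seq_len(nP)),
    paste0("fixture pathway ", seq_len(nP)),
    c(rep("basic", 7), rep("disease", 3)),
    members)

  CvdDataset(compounds, annotations, pathways,
             universeSize = nrow(annotations@tbl))
}

#' Illustrative cardiovascular disease subnetwork fixtures
#'
#' Loads the two synthetic illustrative subnetworks shipped with the
#' package: an apoptosis-centred cascade in which herbal ingredients
#' regulate many (mostly downstream) nodes while western drugs act on
#' exactly two, and a vascular endothelial cell contraction (VECC) cascade
#' in which western drugs regulate many (mostly upstream) nodes while
#' herbal ingredients act on exactly two. The topologies are illustrative
#' stand-ins constructed for this package, not transcriptions of any
#' curated database; regulator annotation comes from the companion
#' compound fixture.
#'
#' @return list with elements `apoptosis` and `vecc` (annotated
#'   [DiseaseSubnetwork-class] objects) and `compounds` (the companion
#'   [CompoundTable-class]).
#' @export
cvdsSubnetworkFixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "PharmNetCompare",
                                 mustWork = TRUE)
  compounds <- readCompoundTable(ext("subnetwork_compounds_synthetic.tsv"))
  apo <- assembleSubnetwork(ext("cvds_apoptosis_synthetic_edges.tsv"),
                            ext("cvds_apoptosis_synthetic_nodes.tsv"),
                            name = "CVDs-Apoptosis (synthetic)")
  vecc <- assembleSubnetwork(ext("cvds_vecc_synthetic_edges.tsv"),
                             ext("cvds_vecc_synthetic_nodes.tsv"),
                             name = "CVDs-VECC (synthetic)")
  list(apoptosis = annotateRegulators(apo, compounds),
       vecc = annotateRegulators(vecc, compounds),
       compounds = compounds)
}
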