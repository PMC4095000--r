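# Synthetic-data generator: datasets with the statistical structure the
# comparative analysis assumes -- two compound classes with planted
# target-property biases, planted pathway-enrichment odds, a planted
# diseases-per-target gap, planted TF fractions and planted cascade-position
# preferences -- so every stage is testable without any database download.

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions the generator emulates: TTD status
#' mixes and TF fractions close to the published target-census proportions,
#' a diseases-per-target gap of 5 vs 2.5, class-specific family and
#' location biases (herbal: enzymes / factors-regulators in cytoplasm and
#' nucleus; western: receptors / channels on the plasma membrane), five
#' planted enriched pathways at odds 8, and downstream-position bias 0.8
#' for herbal against 0.2 for western targets.
#'
#' @param seed integer RNG seed.
#' @param nTargetsPerClass class-exclusive targets per class.
#' @param nSharedTargets targets shared by both classes.
#' @param nCompoundsPerClass compounds per class.
#' @param targetsPerCompoundMean mean targets per compound (>= 1).
#' @param indirectFraction fraction of herbal links that are indirect.
#' @param nPathways number of pathways.
#' @param pathwaySizeMean mean pathway size (Poisson, floored at 3).
#' @param diseasePathwayFraction fraction of pathways labelled `disease`.
#' @param nPlantedEnriched pathways planted enriched for the herbal class.
#' @param enrichmentOdds sampling-odds ratio favouring herbal-class targets
#'   in planted pathways.
#' @param ttdStatusProbs named list of per-class probabilities over
#'   `ttdStatuses()`.
#' @param diseaseCountMean named vector: per-class Poisson mean of diseases
#'   per target (applied uniformly across TTD statuses).
#' @param tfFraction named vector: per-class TF probability.
#' @param domainCountMean named vector: per-class Poisson mean of domains.
#' @param familyWeights named list of per-class simplex weights over
#'   `proteinFamilies()`.
#' @param locationWeights named list of per-class simplex weights over
#'   `subcellularLocations()`.
#' @param positionBias named vector: per-class probability that a regulated
#'   subnetwork node is downstream.
#' @return a `SyntheticConfig` list.
#' @export
syntheticConfig <- function(
    seed = 1,
    nTargetsPerClass = 200,
    nSharedTargets = 20,
    nCompoundsPerClass = 50,
    targetsPerCompoundMean = 5,
    indirectFraction = 0.2,
    nPathways = 50,
    pathwaySizeMean = 20,
    diseasePathwayFraction = 0.35,
    nPlantedEnriched = 5,
    enrichmentOdds = 8,
    ttdStatusProbs = list(
      herbal = c(successful = 0.271, clinical_trial = 0.085,
                 research = 0.271, discontinued = 0.025, absent = 0.348),
      western = c(successful = 0.397, clinical_trial = 0.074,
                  research = 0.142, discontinued = 0.010, absent = 0.377)),
    diseaseCountMean = c(herbal = 5, western = 2.5),
    tfFraction = c(herbal = 0.093, western = 0.049),
    domainCountMean = c(herbal = 2.5, western = 1.5),
    familyWeights = list(
      herbal = c(enzyme = 0.40, channel_transporter = 0.05,
                 receptor = 0.12, factor_regulator = 0.20,
                 structure = 0.05, binding = 0.10, other = 0.08),
      western = c(enzyme = 0.18, channel_transporter = 0.28,
                  receptor = 0.30, factor_regulator = 0.06,
                  structure = 0.04, binding = 0.08, other = 0.06)),
    locationWeights = list(
      herbal = c(plasma_membrane = 0.15, cytoplasm = 0.40, nucleus = 0.30,
                 blood = 0.05, other = 0.10),
      western = c(plasma_membrane = 0.50, cytoplasm = 0.20, nucleus = 0.10,
                  blood = 0.10, other = 0.10)),
    positionBias = c(herbal = 0.8, western = 0.2)) {
  cfg <- list(seed = seed, nTargetsPerClass = nTargetsPerClass,
              nSharedTargets = nSharedTargets,
              nCompoundsPerClass = nCompoundsPerClass,
              targetsPerCompoundMean = targetsPerCompoundMean,
              indirectFraction = indirectFraction, nPathways = nPathways,
              pathwaySizeMean = pathwaySizeMean,
              diseasePathwayFraction = diseasePathwayFraction,
              nPlantedEnriched = nPlantedEnriched,
              enrichmentOdds = enrichmentOdds,
              ttdStatusProbs = ttdStatusProbs,
              diseaseCountMean = diseaseCountMean,
              tfFraction = tfFraction,
              domainCountMean = domainCountMean,
              familyWeights = familyWeights,
              locationWeights = locationWeights,
              positionBias = positionBias)
  for (cl in c("herbal", "western")) {
    if (abs(sum(familyWeights[[cl]]) - 1) > 1e-9)
      fail("familyWeights$", cl, " must sum to 1")
    if (abs(sum(locationWeights[[cl]]) - 1) > 1e-9)
      fail("locationWeights$", cl, " must sum to 1")
    if (abs(sum(ttdStatusProbs[[cl]]) - 1) > 1e-9)
      fail("ttdStatusProbs$", cl, " must sum to 1")
  }
  probs <- c(indirectFraction, tfFraction, positionBias,
             diseasePathwayFraction)
  if (any(probs < 0 | probs > 1)) fail("probabilities must lie in [0, 1]")
  if (nPlantedEnriched > nPathways)
    fail("nPlantedEnriched exceeds nPathways")
  if (enrichmentOdds <= 0) fail("enrichmentOdds must be positive")
  structure(cfg, class = "SyntheticConfig")
}

sampleAnnotations <- function(ids, cls, cfg) {
  n <- length(ids)
  status <- sample(ttdStatuses(), n, replace = TRUE,
                   prob = cfg$ttdStatusProbs[[cls]])
  nDis <- stats::rpois(n, cfg$diseaseCountMean[[cls]])
  diseases <- lapply(seq_len(n), function(i) {
    if (nDis[i] == 0) character(0) else
      paste0("disease_", sample.int(500, nDis[i]))
  })
  nDom <- stats::rpois(n, cfg$domainCountMean[[cls]])
  domains <- lapply(nDom, function(k) {
    if (k == 0) character(0) else paste0("PF", sample.int(300, k,
                                                          replace = TRUE))
  })
  family <- sample(proteinFamilies(), n, replace = TRUE,
                   prob = cfg$familyWeights[[cls]])
  nLoc <- 1 + stats::rbinom(n, 1, 0.3)
  locations <- lapply(seq_len(n), function(i) {
    sample(subcellularLocations(), nLoc[i], replace = FALSE,
           prob = cfg$locationWeights[[cls]])
  })
  isTf <- stats::runif(n) < cfg$tfFraction[[cls]]
  data.frame(target_id = ids, name = paste0("protein ", ids),
             ttd_status = status,
             diseases = I(diseases), domain_ids = I(domains),
             family = family, locations = I(locations),
             is_tf = isTf,
             tf_gene_count = ifelse(isTf, stats::rpois(n, 5), 0L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic dataset with planted class differences
#'
#' Draws targets for the two classes (plus a shared pool), annotates them
#' from the per-class distributions in the config, assembles compounds with
#' direct (and, for herbal ingredients, indirect) links, and samples
#' pathway member sets; the planted pathways over-sample herbal-class
#' targets at the configured odds ratio while the rest sample uniformly.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [syntheticConfig()].
#' @return list with `dataset` (a [CvdDataset-class]) and `truth`
#'   (planted enriched pathway ids, per-class disease-count means, TF
#'   fractions, position biases, family weights).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  nT <- config$nTargetsPerClass
  nS <- config$nSharedTargets
  herbalIds <- sprintf("SYNH%04d", seq_len(nT))
  westernIds <- sprintf("SYNW%04d", seq_len(nT))
  sharedIds <- if (nS > 0) sprintf("SYNS%04d", seq_len(nS)) else character(0)

  annH <- sampleAnnotations(herbalIds, "herbal", config)
  annW <- sampleAnnotations(westernIds, "western", config)
  # shared targets: drawn half-and-half from the two class distributions
  annS <- if (nS > 0) {
    k <- floor(nS / 2)
    rbind(sampleAnnotations(sharedIds[seq_len(k)], "herbal", config),
          sampleAnnotations(sharedIds[setdiff(seq_len(nS), seq_len(k))],
                            "western", config))
  } else NULL
  ann <- TargetAnnotations(rbind(annH, annW, annS))

  herbalPool <- c(herbalIds, sharedIds)
  westernPool <- c(westernIds, sharedIds)
  links <- list()
  for (cl in c("herbal", "western")) {
    pool <- if (cl == "herbal") herbalPool else westernPool
    cc <- if (cl == "herbal") "herbal_ingredient" else "western_drug"
    for (j in seq_len(config$nCompoundsPerClass)) {
      cid <- sprintf("%s_cmp_%03d", cl, j)
      k <- 1 + stats::rpois(1, max(config$targetsPerCompoundMean - 1, 0))
      ts <- sample(pool, min(k, length(pool)))
      lt <- if (cl == "herbal") {
        ifelse(stats::runif(length(ts)) < config$indirectFraction,
               "indirect", "direct")
      } else rep("direct", length(ts))
      links[[length(links) + 1L]] <- data.frame(
        compound_id = cid, name = paste0(cl, " compound ", j),
        compound_class = cc, target_id = ts, link_type = lt,
        stringsAsFactors = FALSE)
    }
  }
  compounds <- CompoundTable(do.call(rbind, links))

  allIds <- c(herbalIds, westernIds, sharedIds)
  if (config$pathwaySizeMean >= length(allIds))
    fail("infeasible config: pathway sizes exceed the target pool")
  nP <- config$nPathways
  planted <- sprintf("PWP%03d", seq_len(config$nPlantedEnriched))
  background <- sprintf("PWB%03d",
                        seq_len(nP - config$nPlantedEnriched))
  pids <- c(planted, background)
  w <- ifelse(allIds %in% herbalPool, config$enrichmentOdds, 1)
  members <- lapply(seq_len(nP), function(i) {
    size <- max(3, stats::rpois(1, config$pathwaySizeMean))
    size <- min(size, length(allIds))
    if (i <= config$nPlantedEnriched) {
      sample(allIds, size, prob = w)
    } else {
      sample(allIds, size)
    }
  })
  nDisease <- round(config$diseasePathwayFraction * nP)
  category <- rep("basic", nP)
  if (nDisease > 0)
    category[sample.int(nP, nDisease)] <- "disease"
  pathways <- PathwayCollection(pids, paste0("pathway ", pids), category,
                                members)

  dataset <- CvdDataset(compounds, ann, pathways,
                        universeSize = length(allIds))
  truth <- list(planted_enriched = planted,
                herbal_pool = herbalPool, western_pool = westernPool,
                dt_mean = config$diseaseCountMean,
                tf_fraction = config$tfFraction,
                position_bias = config$positionBias,
                family_weights = config$familyWeights,
                enrichment_odds = config$enrichmentOdds)
  list(dataset = dataset, truth = truth)
}

#' Generate a synthetic disease subnetwork with planted position bias
#'
#' Nodes are assigned a regulating class (herbal, western, both or none),
#' a cascade position drawn from the class's downstream bias, and a
#' compartment from the class's location weights; edges form a random
#' tree with sampled activation/inhibition effects.
#'
#' @param config a [syntheticConfig()] (uses `seed`, `positionBias`,
#'   `locationWeights`).
#' @param nNodes number of nodes (default 100).
#' @param classProbs probabilities of a node being regulated by herbal
#'   only, western only, both, or none.
#' @return list with `subnetwork` (a [DiseaseSubnetwork-class], regulators
#'   filled) and `truth` (the position biases).
#' @export
generateSubnetwork <- function(config, nNodes = 100,
                               classProbs = c(herbal = 0.45,
                                              western = 0.45,
                                              both = 0.05, none = 0.05)) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  ids <- sprintf("SN%03d", seq_len(nNodes))
  cls <- sample(names(classProbs), nNodes, replace = TRUE,
                prob = classProbs)
  pDown <- vapply(cls, function(cl) {
    switch(cl,
           herbal = config$positionBias[["herbal"]],
           western = config$positionBias[["western"]],
           both = mean(config$positionBias),
           none = 0.5)
  }, numeric(1))
  position <- ifelse(stats::runif(nNodes) < pDown, "downstream", "upstream")
  lw <- (config$locationWeights$herbal + config$locationWeights$western) / 2
  compartment <- sample(subcellularLocations(), nNodes, replace = TRUE,
                        prob = lw)
  nodes <- data.frame(node_id = ids, compartment = compartment,
                      position = position, stringsAsFactors = FALSE)
  edges <- if (nNodes > 1) {
    data.frame(source_id = ids[vapply(2:nNodes,
                                      function(i) sample.int(i - 1, 1),
                                      integer(1))],
               target_id = ids[2:nNodes],
               effect = sample(c("activation", "inhibition"), nNodes - 1,
                               replace = TRUE, prob = c(0.7, 0.3)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(source_id = character(0), target_id = character(0),
               effect = character(0))
  }
  regs <- list()
  for (i in seq_len(nNodes)) {
    r <- switch(cls[i], herbal = "herbal", western = "western",
                both = c("herbal", "western"), none = NULL)
    if (!is.null(r)) regs[[ids[i]]] <- r
  }
  sn <- DiseaseSubnetwork("synthetic-subnetwork", nodes, edges, regs)
  list(subnetwork = sn, truth = list(position_bias = config$positionBias))
}

#' Write a dataset's exchange files to a directory
#'
#' Writes `compounds.tsv`, `annotations.tsv` and `pathways.gmt` (the
#' formats the readers consume), plus `ground_truth.json` when a truth
#' record is supplied.
#'
#' @param dataset a [CvdDataset-class].
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list to serialize alongside.
#' @return invisibly, the directory.
#' @export
writeDataset <- function(dataset, dir, truth = NULL) {
  stopifnot(is(dataset, "CvdDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCompoundTable(dataset@compounds, file.path(dir, "compounds.tsv"))
  writeAnnotationTable(dataset@annotations,
                       file.path(dir, "annotations.tsv"))
  writeGmt(dataset@pathways, file.path(dir, "pathways.gmt"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset from a directory written by [writeDataset()]
#'
#' @param dir directory holding `compounds.tsv`, `annotations.tsv`,
#'   `pathways.gmt`.
#' @param universeSize optional explicit universe size.
#' @return a [CvdDataset-class].
#' @export
readDataset <- function(dir, universeSize = NULL) {
  CvdDataset(readCompoundTable(file.path(dir, "compounds.tsv")),
             readAnnotationTable(file.path(dir, "annotations.tsv")),
             readGmt(file.path(dir, "pathways.gmt")),
             universeSize = universeSize)
}

#' Sample a bipartite network with a power-law left degree sequence
#'
#' Draws left-node degrees from a discrete power law P(x) proportional to
#' x^(-exponent) on 1..xMax and realizes each degree by linking to
#' distinct, uniformly chosen right nodes. Used to validate degree
#' distribution estimation and power-law fitting on data with a known
#' exponent.
#'
#' @param nLeft number of left nodes.
#' @param exponent power-law exponent (> 1).
#' @param xMax largest admissible degree.
#' @param nRight right-node pool size (defaults to `2 * xMax`).
#' @param seed integer seed.
#' @return a [BipartiteNetwork-class].
#' @export
samplePowerLawNetwork <- function(nLeft, exponent = 2.5, xMax = 100,
                                  nRight = 2 * xMax, seed = 1) {
  if (exponent <= 1) fail("exponent must exceed 1")
  if (nRight < xMax) fail("nRight must be at least xMax")
  set.seed(seed)
  x <- seq_len(xMax)
  deg <- sample(x, nLeft, replace = TRUE, prob = x^(-exponent))
  left <- sprintf("L%05d", seq_len(nLeft))
  right <- sprintf("R%05d", seq_len(nRight))
  edges <- data.frame(
    left = rep(left, deg),
    right = unlist(lapply(deg, function(k) sample(right, k))),
    stringsAsFactors = FALSE)
  makeBipartite(left, right, edges, "target", "pathway")
}
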