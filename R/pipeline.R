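# End-to-end orchestration: profile -> enrich -> networks -> disease
# coverage, from a single configuration, with a consolidated
# machine-readable report.

#' Pipeline configuration
#'
#' Builds (and checks) the configuration consumed by [runPipeline()]. All
#' thresholds are surfaced here; the defaults mirror the comparative
#' analysis the package implements (significance at raw p < 0.01, direct
#' herbal targets only).
#'
#' @param compounds,annotations,gmt input file paths (ignored when a
#'   dataset object is passed to [runPipeline()] directly).
#' @param subnetworks optional list of lists with elements `name`, `edges`,
#'   `nodes` (paths to subnetwork tables).
#' @param alpha significance level in (0, 1).
#' @param universeMode `"pathway-union"`, `"annotated"`, or an explicit id
#'   vector (see [makeUniverse()]).
#' @param directOnly use only direct herbal links for the class comparison.
#' @param perCompound also run per-compound enrichment.
#' @param tfUniverseSize,nTfUniverse TF-enrichment background (see
#'   [tfEnrichment()]).
#' @param outputDir directory for report and artifacts (`NULL` = no files
#'   written).
#' @param seed integer seed for any stochastic step.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(compounds = NULL, annotations = NULL, gmt = NULL,
                           subnetworks = list(), alpha = 0.01,
                           universeMode = "pathway-union",
                           directOnly = TRUE, perCompound = FALSE,
                           tfUniverseSize = 20000, nTfUniverse = 618,
                           outputDir = NULL, seed = 1) {
  if (!(alpha > 0 && alpha < 1)) fail("invalid config: alpha not in (0,1)")
  structure(list(compounds = compounds, annotations = annotations,
                 gmt = gmt, subnetworks = subnetworks, alpha = alpha,
                 universeMode = universeMode, directOnly = directOnly,
                 perCompound = perCompound,
                 tfUniverseSize = tfUniverseSize,
                 nTfUniverse = nTfUniverse,
                 outputDir = outputDir, seed = seed),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipelineConfig()] arguments
#'   (snake_case keys `universe_mode`, `direct_only`, `per_compound`,
#'   `output_dir`, `tf_universe_size`, `n_tf_universe` are accepted too).
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  alias <- c(universe_mode = "universeMode", direct_only = "directOnly",
             per_compound = "perCompound", output_dir = "outputDir",
             tf_universe_size = "tfUniverseSize",
             n_tf_universe = "nTfUniverse")
  for (k in names(alias)) {
    if (!is.null(raw[[k]])) {
      raw[[alias[[k]]]] <- raw[[k]]
      raw[[k]] <- NULL
    }
  }
  do.call(pipelineConfig, raw)
}

dtRow <- function(x) {
  data.frame(group = x$group_label, ttd_status = x$ttd_status,
             n_targets = x$n_targets,
             n_disease_associations = x$n_disease_associations,
             dt = roundHalfUp(x$dt_value, 2),
             stringsAsFactors = FALSE)
}

#' Run the full comparative pipeline
#'
#' Executes the analysis sequence on one dataset: per-group TTD tallies and
#' diseases-per-target statistics, domain/family/location profiles, TF
#' enrichment, pooled (and optionally per-compound) pathway enrichment
#' with the basic/disease split, target-pathway and compound-pathway
#' networks with degree-distribution summaries and power-law fits, and
#' coverage of any configured disease subnetworks. Deterministic given the
#' inputs and seed; inputs are never mutated. Missing subnetwork files
#' degrade gracefully with a warning.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()], or a path to a YAML config.
#' @param dataset optional [CvdDataset-class]; when `NULL`, read from the
#'   config paths.
#' @return a `Report` list: `tallies`, `dt_table`, `profiles`,
#'   `tf_enrichments`, `enrichment`, `networks`, `coverage`, `provenance`.
#'   With `outputDir` set, also writes `report.json`, `report.md` and the
#'   TSV/GraphML artifacts.
#' @export
runPipeline <- function(config, dataset = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fail("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  if (is.null(dataset)) {
    if (is.null(config$compounds) || is.null(config$annotations) ||
        is.null(config$gmt))
      fail("invalid config: need compounds, annotations and gmt paths ",
           "(or pass a dataset)")
    dataset <- stage("load", CvdDataset(
      readCompoundTable(config$compounds),
      readAnnotationTable(config$annotations),
      readGmt(config$gmt)))
  }
  validation <- validateDataset(dataset)
  if (nrow(validation) > 0)
    warning(nrow(validation), " dataset validation issue(s); see report",
            call. = FALSE)

  ann <- dataset@annotations
  herbalSet <- if (config$directOnly) {
    directTargets(dataset, "herbal_ingredient")
  } else allTargets(dataset, "herbal_ingredient")
  westernSet <- allTargets(dataset, "western_drug")
  herbalAll <- allTargets(dataset, "herbal_ingredient")

  tallies <- stage("profile", list(
    western = tallyTtd(westernSet, ann, "western_drug"),
    herbal_direct = tallyTtd(herbalSet, ann, "herbal_direct"),
    herbal_all = tallyTtd(herbalAll, ann, "herbal_all")))

  # statuses with no target in a group are skipped rather than fatal
  dtStatuses <- c("successful", "clinical_trial", "research")
  dtRows <- c(
    lapply(dtStatuses, function(s)
      tryCatch(dtRow(computeDt(westernSet, ann, s, "western_drug")),
               error = function(e) NULL)),
    lapply(dtStatuses, function(s)
      tryCatch(dtRow(computeDt(herbalSet, ann, s, "herbal_direct")),
               error = function(e) NULL)))
  dtTable <- do.call(rbind, dtRows[!vapply(dtRows, is.null, logical(1))])

  profiles <- stage("profile", list(
    domain = rbind(domainCountProfile(herbalSet, ann, "herbal_direct"),
                   domainCountProfile(westernSet, ann, "western_drug")),
    family = rbind(familyProfile(herbalSet, ann, "herbal_direct"),
                   familyProfile(westernSet, ann, "western_drug")),
    location = rbind(locationProfile(herbalSet, ann, "herbal_direct"),
                     locationProfile(westernSet, ann, "western_drug"))))

  tf <- stage("profile", list(
    herbal_direct = tfEnrichment(herbalSet, ann, config$tfUniverseSize,
                                 config$nTfUniverse, "herbal_direct"),
    western = tfEnrichment(westernSet, ann, config$tfUniverseSize,
                           config$nTfUniverse, "western_drug")))

  universe <- makeUniverse(dataset, config$universeMode)
  enr <- stage("enrich", {
    hU <- intersect(herbalSet, universe)
    wU <- intersect(westernSet, universe)
    out <- list()
    if (length(hU) > 0) {
      out$herbal_direct <- enrichPathways(hU, dataset@pathways, universe,
                                          alpha = config$alpha)
      if (any(out$herbal_direct$significant))
        out$herbal_split <- splitBasicDisease(out$herbal_direct,
                                              significantOnly = TRUE)
    }
    if (length(wU) > 0) {
      out$western <- enrichPathways(wU, dataset@pathways, universe,
                                    alpha = config$alpha)
      if (any(out$western$significant))
        out$western_split <- splitBasicDisease(out$western,
                                               significantOnly = TRUE)
    }
    if (config$perCompound) {
      out$per_compound <- enrichPerCompound(dataset, dataset@pathways,
                                            universe,
                                            alpha = config$alpha)
    }
    out
  })

  networks <- stage("network", {
    describeNet <- function(net) {
      dd <- degreeDistribution(net, "left")
      fit <- tryCatch(fitPowerLaw(dd), error = function(e) NULL)
      list(n_left = length(net@leftNodes),
           n_right = length(net@rightNodes),
           n_edges = nrow(net@edges),
           mean_left_degree = mean(nodeDegrees(net, "left")),
           power_law = fit, network = net)
    }
    list(
      target_pathway_herbal = describeNet(buildTargetPathwayNetwork(
        herbalSet, dataset@pathways, enr$herbal_direct)),
      target_pathway_western = describeNet(buildTargetPathwayNetwork(
        westernSet, dataset@pathways, enr$western)),
      compound_pathway = describeNet(buildCompoundPathwayNetwork(
        dataset@compounds, dataset@pathways)))
  })

  coverage <- list()
  for (sn in config$subnetworks) {
    if (!file.exists(sn$edges %||% "") || !file.exists(sn$nodes %||% "")) {
      warning("subnetwork '", sn$name %||% "?",
              "' skipped: missing file(s)", call. = FALSE)
      next
    }
    sub <- stage("disease", {
      s <- assembleSubnetwork(sn$edges, sn$nodes, sn$name %||% "subnetwork")
      annotateRegulators(s, dataset@compounds)
    })
    cov <- coverageSummary(sub)
    coverage[[cov$subnetwork_name]] <-
      list(summary = cov, preference = positionPreference(cov))
  }

  report <- list(
    tallies = tallies, dt_table = dtTable, profiles = profiles,
    tf_enrichments = tf, enrichment = enr, networks = networks,
    coverage = coverage, validation = validation,
    provenance = list(
      alpha = config$alpha, universe_mode = config$universeMode,
      universe_size = length(universe),
      direct_only = config$directOnly, seed = config$seed,
      package_version = as.character(utils::packageVersion(
        "PharmNetCompare"))))
  class(report) <- "PipelineReport"

  if (!is.null(config$outputDir)) writeReport(report, config$outputDir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reportJson <- function(report) {
  tallyJson <- function(t) {
    list(group = t$group_label, denominator = t$denominator,
         counts = t$per_status_count, percentages = t$per_status_pct,
         in_ttd_count = t$in_ttd_count, in_ttd_pct = t$in_ttd_pct)
  }
  tfJson <- function(t) {
    list(group = t$group_label, n_targets = t$n_targets,
         n_tf_targets = t$n_tf_targets, p_value = t$p_value)
  }
  netJson <- function(n) {
    list(n_left = n$n_left, n_right = n$n_right, n_edges = n$n_edges,
         mean_left_degree = n$mean_left_degree,
         power_law = if (is.null(n$power_law)) NULL else n$power_law)
  }
  covJson <- function(cv) {
    list(n_herbal = cv$summary$n_herbal_targets,
         n_western = cv$summary$n_western_targets,
         n_common = cv$summary$n_common_targets,
         herbal_downstream_fraction =
           cv$preference$herbal_downstream_fraction,
         western_upstream_fraction =
           cv$preference$western_upstream_fraction)
  }
  list(tallies = lapply(report$tallies, tallyJson),
       dt_table = report$dt_table,
       tf_enrichments = lapply(report$tf_enrichments, tfJson),
       enrichment = list(
         herbal_significant =
           if (is.null(report$enrichment$herbal_direct)) NULL else
             sum(report$enrichment$herbal_direct$significant),
         western_significant =
           if (is.null(report$enrichment$western)) NULL else
             sum(report$enrichment$western$significant),
         herbal_disease_fraction =
           report$enrichment$herbal_split$disease_fraction %||% NULL,
         western_disease_fraction =
           report$enrichment$western_split$disease_fraction %||% NULL),
       networks = lapply(report$networks, netJson),
       coverage = lapply(report$coverage, covJson),
       validation_issues = nrow(report$validation),
       provenance = report$provenance)
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (machine-readable), `report.md` (human-readable
#' summary) and the per-stage artifacts (enrichment TSVs, profile TSVs and
#' GraphML networks) into a directory.
#'
#' @param report a `PipelineReport` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "PipelineReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(reportJson(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(report$profiles)) {
    writeProfile(report$profiles[[nm]],
                 file.path(dir, paste0("profile_", nm, ".tsv")))
  }
  for (nm in c("herbal_direct", "western")) {
    if (!is.null(report$enrichment[[nm]]))
      writeEnrichmentResults(report$enrichment[[nm]],
                             file.path(dir, paste0("enrichment_", nm,
                                                   ".tsv")),
                             entityId = nm)
  }
  for (nm in names(report$networks)) {
    writeNetwork(report$networks[[nm]]$network,
                 file.path(dir, paste0(nm, ".graphml")), "graphml")
  }
  md <- c("# Comparative pipeline report", "",
          "## TTD tallies", "")
  for (t in report$tallies) {
    md <- c(md, sprintf("- %s: %d targets, %d in TTD (%.1f%%)",
                        t$group_label, t$denominator, t$in_ttd_count,
                        t$in_ttd_pct))
  }
  md <- c(md, "", "## Diseases per target (d/t)", "",
          utils::capture.output(print(report$dt_table,
                                      row.names = FALSE)),
          "", "## TF enrichment", "")
  for (t in report$tf_enrichments) {
    md <- c(md, sprintf("- %s: %d TFs of %d targets, p = %.3g",
                        t$group_label, t$n_tf_targets, t$n_targets,
                        t$p_value))
  }
  if (length(report$coverage) > 0) {
    md <- c(md, "", "## Disease subnetwork coverage", "")
    for (nm in names(report$coverage)) {
      cv <- report$coverage[[nm]]
      md <- c(md, sprintf("- %s: herbal %d, western %d, common %d", nm,
                          cv$summary$n_herbal_targets,
                          cv$summary$n_western_targets,
                          cv$summary$n_common_targets))
    }
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport\n")
  for (t in x$tallies) {
    cat(sprintf("  %-13s %4d targets, %5.1f%% in TTD\n", t$group_label,
                t$denominator, t$in_ttd_pct))
  }
  cat("  d/t rows:", nrow(x$dt_table), "; networks:",
      length(x$networks), "; subnetworks:", length(x$coverage), "\n")
  invisible(x)
}
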