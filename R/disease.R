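# Curated disease-subnetwork assembly, regulator annotation and coverage /
# position-preference summaries.

#' Construct a DiseaseSubnetwork
#'
#' @param name subnetwork label.
#' @param nodes data.frame with columns `node_id`, `compartment`,
#'   `position` (missing `position` entries become `"unassigned"`).
#' @param edges data.frame with columns `source_id`, `target_id`, `effect`.
#' @param regulators optional named list node_id -> classes.
#' @return a validated [DiseaseSubnetwork-class].
#' @export
DiseaseSubnetwork <- function(name, nodes, edges, regulators = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"position" %in% names(nodes)) nodes$position <- "unassigned"
  nodes$position[is.na(nodes$position) | !nzchar(nodes$position)] <-
    "unassigned"
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(edges) <- NULL
  new("DiseaseSubnetwork", name = name, nodes = nodes, edges = edges,
      regulators = regulators)
}

#' Assemble a disease subnetwork from TSV tables
#'
#' Reads a signed edge list (`source_id`, `target_id`, `effect` with effect
#' `activation` or `inhibition`) and a node table (`node_id`,
#' `compartment`, `position`). Every edge endpoint must appear in the node
#' table; a dangling endpoint raises an error naming the node.
#'
#' @param edgePath edge table TSV.
#' @param nodePath node table TSV.
#' @param name subnetwork label.
#' @return a [DiseaseSubnetwork-class] with no regulator annotation yet.
#' @export
assembleSubnetwork <- function(edgePath, nodePath, name = "subnetwork") {
  nodes <- readTsv(nodePath)
  requireColumns(nodes, c("node_id", "compartment"), nodePath)
  edges <- readTsv(edgePath)
  requireColumns(edges, c("source_id", "target_id", "effect"), edgePath)
  DiseaseSubnetwork(name, nodes, edges)
}

#' Write a disease subnetwork to TSV tables
#'
#' @param subnetwork a [DiseaseSubnetwork-class].
#' @param edgePath,nodePath output paths.
#' @return invisibly, `c(edgePath, nodePath)`.
#' @export
writeSubnetwork <- function(subnetwork, edgePath, nodePath) {
  stopifnot(is(subnetwork, "DiseaseSubnetwork"))
  utils::write.table(subnetwork@edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(subnetwork@nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edgePath, nodePath))
}

#' Annotate subnetwork nodes with the compound classes targeting them
#'
#' A node is marked `"herbal"` when at least one herbal ingredient links to
#' it directly (indirect links do not count) and `"western"` when at least
#' one western drug targets it. Nodes carrying both classes are the
#' "common" targets.
#'
#' @param subnetwork a [DiseaseSubnetwork-class].
#' @param compounds a [CompoundTable-class] or [CvdDataset-class].
#' @return the subnetwork with its `regulators` slot filled.
#' @export
annotateRegulators <- function(subnetwork, compounds) {
  stopifnot(is(subnetwork, "DiseaseSubnetwork"))
  if (is(compounds, "CvdDataset")) compounds <- compounds@compounds
  stopifnot(is(compounds, "CompoundTable"))
  lk <- compounds@links
  lk <- lk[lk$link_type == "direct", , drop = FALSE]
  herbal <- unique(lk$target_id[lk$compound_class == "herbal_ingredient"])
  western <- unique(lk$target_id[lk$compound_class == "western_drug"])
  regs <- list()
  for (id in subnetwork@nodes$node_id) {
    cls <- c(if (id %in% herbal) "herbal", if (id %in% western) "western")
    if (length(cls) > 0) regs[[id]] <- cls
  }
  subnetwork@regulators <- regs
  validObject(subnetwork)
  subnetwork
}

#' Per-class coverage of a disease subnetwork
#'
#' Counts, for each compound class, the regulated nodes overall, per
#' cascade position and per compartment, plus the common (both-class)
#' targets.
#'
#' @param subnetwork a [DiseaseSubnetwork-class] with regulators annotated
#'   (see [annotateRegulators()]).
#' @return object of class `CoverageSummary`: list with `subnetwork_name`,
#'   `n_herbal_targets`, `n_western_targets`, `n_common_targets`,
#'   `per_position` (data.frame position x class counts), and
#'   `per_compartment`.
#' @export
coverageSummary <- function(subnetwork) {
  stopifnot(is(subnetwork, "DiseaseSubnetwork"))
  nd <- subnetwork@nodes
  regs <- subnetwork@regulators
  isH <- vapply(nd$node_id, function(id) "herbal" %in% regs[[id]],
                logical(1))
  isW <- vapply(nd$node_id, function(id) "western" %in% regs[[id]],
                logical(1))
  positions <- c("upstream", "downstream", "unassigned")
  perPos <- data.frame(
    position = positions,
    herbal = vapply(positions, function(p) sum(isH & nd$position == p),
                    integer(1)),
    western = vapply(positions, function(p) sum(isW & nd$position == p),
                     integer(1)),
    stringsAsFactors = FALSE)
  comps <- subcellularLocations()
  perComp <- data.frame(
    compartment = comps,
    herbal = vapply(comps, function(cp) sum(isH & nd$compartment == cp),
                    integer(1)),
    western = vapply(comps, function(cp) sum(isW & nd$compartment == cp),
                     integer(1)),
    stringsAsFactors = FALSE)
  structure(list(
    subnetwork_name = subnetwork@name,
    n_herbal_targets = sum(isH),
    n_western_targets = sum(isW),
    n_common_targets = sum(isH & isW),
    per_position = perPos,
    per_compartment = perComp
  ), class = "CoverageSummary")
}

#' @export
print.CoverageSummary <- function(x, ...) {
  cat("Coverage of '", x$subnetwork_name, "': herbal ", x$n_herbal_targets,
      ", western ", x$n_western_targets, ", common ", x$n_common_targets,
      "\n", sep = "")
  print(x$per_position, row.names = FALSE)
  invisible(x)
}

#' Cascade-position preference of the two compound classes
#'
#' The fraction of herbal-regulated nodes lying downstream and of
#' western-regulated nodes lying upstream, among regulated nodes with an
#' assigned position. A class with no positioned regulated node yields
#' `NA`.
#'
#' @param summary a `CoverageSummary` from [coverageSummary()].
#' @return list with `herbal_downstream_fraction` and
#'   `western_upstream_fraction`.
#' @export
positionPreference <- function(summary) {
  pp <- summary$per_position
  hPos <- pp$herbal[pp$position %in% c("upstream", "downstream")]
  wPos <- pp$western[pp$position %in% c("upstream", "downstream")]
  hDown <- pp$herbal[pp$position == "downstream"]
  wUp <- pp$western[pp$position == "upstream"]
  list(
    herbal_downstream_fraction =
      if (sum(hPos) == 0) NA_real_ else hDown / sum(hPos),
    western_upstream_fraction =
      if (sum(wPos) == 0) NA_real_ else wUp / sum(wPos)
  )
}
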