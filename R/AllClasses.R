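#' @import methods
NULL

#' CompoundTable: compounds and their target links
#'
#' Holds one row per compound-target link with the compound's class
#' (herbal ingredient or western drug) and the link type (direct or
#' indirect). Herbal ingredients may carry both direct and indirect target
#' links; western-drug links are always direct, and the validity method
#' enforces this.
#'
#' @slot links data.frame with columns `compound_id`, `name`,
#'   `compound_class`, `target_id`, `link_type`.
#' @seealso [readCompoundTable()], [compoundIds()], [directTargets()]
#' @export
setClass("CompoundTable", representation(links = "data.frame"))

setValidity("CompoundTable", function(object) {
  lk <- object@links
  need <- c("compound_id", "name", "compound_class", "target_id", "link_type")
  miss <- setdiff(need, names(lk))
  if (length(miss) > 0)
    return(paste("missing link column(s):", paste(miss, collapse = ", ")))
  if (nrow(lk) == 0) return(TRUE)
  if (any(!nzchar(lk$compound_id))) return("empty compound_id")
  bad <- setdiff(unique(lk$compound_class), compoundClasses())
  if (length(bad) > 0)
    return(paste("unknown compound_class:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(lk$link_type), linkTypes())
  if (length(bad) > 0)
    return(paste("unknown link_type:", paste(bad, collapse = ", ")))
  if (any(lk$compound_class == "western_drug" & lk$link_type == "indirect"))
    return("western_drug compounds may only have direct target links")
  key <- paste(lk$compound_id, lk$target_id, lk$link_type, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (compound_id, target_id, link_type) link")
  # one name and one class per compound id
  per <- unique(lk[, c("compound_id", "name", "compound_class")])
  if (anyDuplicated(per$compound_id))
    return("conflicting name or class for a compound_id")
  TRUE
})

#' TargetAnnotations: per-protein annotation records
#'
#' One record per target protein: TTD development status, associated disease
#' names, Pfam-style structural domain identifiers (a multiset: repeated
#' domains are kept), biochemical family, subcellular compartments (a set:
#' multi-compartment proteins are counted once per compartment by the
#' location profile) and transcription-factor information. `tf_gene_count`
#' (number of known transcriptional target genes) is independent of `is_tf`:
#' a TF may have zero recorded transcriptional genes.
#'
#' @slot tbl data.frame with columns `target_id`, `name`, `ttd_status`,
#'   `family`, `is_tf`, `tf_gene_count` and list columns `diseases`,
#'   `domain_ids`, `locations`.
#' @seealso [readAnnotationTable()], [annotationTable()]
#' @export
setClass("TargetAnnotations", representation(tbl = "data.frame"))

setValidity("TargetAnnotations", function(object) {
  tb <- object@tbl
  need <- c("target_id", "name", "ttd_status", "diseases", "domain_ids",
            "family", "locations", "is_tf", "tf_gene_count")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0)
    return(paste("missing annotation column(s):", paste(miss, collapse = ", ")))
  if (nrow(tb) == 0) return(TRUE)
  if (anyDuplicated(tb$target_id)) return("duplicate target_id")
  bad <- setdiff(unique(tb$ttd_status), ttdStatuses())
  if (length(bad) > 0)
    return(paste("unknown ttd_status:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(tb$family), proteinFamilies())
  if (length(bad) > 0)
    return(paste("unknown family:", paste(bad, collapse = ", ")))
  locs <- unique(unlist(tb$locations, use.names = FALSE))
  bad <- setdiff(locs, subcellularLocations())
  if (length(bad) > 0)
    return(paste("unknown location:", paste(bad, collapse = ", ")))
  if (!is.logical(tb$is_tf)) return("is_tf must be logical")
  if (any(tb$tf_gene_count < 0)) return("tf_gene_count must be nonnegative")
  TRUE
})

#' PathwayCollection: named gene sets with a basic/disease category
#'
#' A lightweight gene-set collection. Each pathway carries an identifier, a
#' display name, a category (`basic` for ordinary process pathways,
#' `disease` for disease pathways) and a non-empty member set of target ids.
#'
#' @slot info data.frame with columns `pathway_id`, `name`, `category`.
#' @slot members named list of character vectors (member target ids),
#'   parallel to `info`.
#' @seealso [readGmt()], [pathwayMembers()], [splitBasicDisease()]
#' @export
setClass("PathwayCollection",
         representation(info = "data.frame", members = "list"))

setValidity("PathwayCollection", function(object) {
  info <- object@info
  need <- c("pathway_id", "name", "category")
  miss <- setdiff(need, names(info))
  if (length(miss) > 0)
    return(paste("missing pathway column(s):", paste(miss, collapse = ", ")))
  if (nrow(info) != length(object@members))
    return("info and members length mismatch")
  if (nrow(info) == 0) return(TRUE)
  if (anyDuplicated(info$pathway_id)) return("duplicate pathway_id")
  bad <- setdiff(unique(info$category), c("basic", "disease"))
  if (length(bad) > 0)
    return(paste("unknown category:", paste(bad, collapse = ", ")))
  sizes <- lengths(object@members)
  if (any(sizes == 0)) return("pathway with empty member set")
  if (!identical(names(object@members), info$pathway_id))
    return("members must be named by pathway_id in info order")
  TRUE
})

#' CvdDataset: the aggregate analysis input
#'
#' Bundles the three inputs every analysis stage consumes — compounds with
#' their target links, per-target annotations and a pathway collection —
#' plus the size of the annotatable-proteome background used as the default
#' enrichment universe.
#'
#' @slot compounds a [CompoundTable-class].
#' @slot annotations a [TargetAnnotations-class].
#' @slot pathways a [PathwayCollection-class].
#' @slot universeSize positive integer: total annotatable proteins.
#' @seealso [validateDataset()], [paperFixture()], [generateDataset()]
#' @export
setClass("CvdDataset",
         representation(compounds = "CompoundTable",
                        annotations = "TargetAnnotations",
                        pathways = "PathwayCollection",
                        universeSize = "numeric"))

setValidity("CvdDataset", function(object) {
  u <- object@universeSize
  if (length(u) != 1 || is.na(u) || u < 1 || u != floor(u))
    return("universeSize must be a single positive integer")
  TRUE
})

#' BipartiteNetwork: a two-sided node-link structure
#'
#' Represents the target-pathway and compound-pathway networks: left nodes
#' (targets or compounds), right nodes (pathways) and edges between the two
#' sides. Zero-degree nodes are retained. `nodeAttrs` carries per-node kind,
#' degree, and (for pathway nodes with enrichment results) the p-value and
#' significance flag used by downstream styling.
#'
#' @slot leftNodes,rightNodes character vectors of node ids.
#' @slot edges data.frame with columns `left`, `right`.
#' @slot nodeAttrs data.frame with columns `node_id`, `node_kind`, `degree`,
#'   `p_value`, `significant`.
#' @seealso [buildTargetPathwayNetwork()], [degreeDistribution()],
#'   [writeNetwork()]
#' @export
setClass("BipartiteNetwork",
         representation(leftNodes = "character", rightNodes = "character",
                        edges = "data.frame", nodeAttrs = "data.frame"))

setValidity("BipartiteNetwork", function(object) {
  ed <- object@edges
  if (!all(c("left", "right") %in% names(ed)))
    return("edges needs columns left, right")
  if (anyDuplicated(object@leftNodes) || anyDuplicated(object@rightNodes))
    return("duplicate node ids within a side")
  if (length(intersect(object@leftNodes, object@rightNodes)) > 0)
    return("a node id appears on both sides")
  if (nrow(ed) > 0) {
    if (!all(ed$left %in% object@leftNodes))
      return("edge with unknown left endpoint")
    if (!all(ed$right %in% object@rightNodes))
      return("edge with unknown right endpoint")
    if (anyDuplicated(paste(ed$left, ed$right, sep = "\r")))
      return("duplicate edge")
  }
  TRUE
})

#' DiseaseSubnetwork: a curated disease signaling subnetwork
#'
#' A hand-curated local disease network (e.g. an apoptosis- or vascular
#' endothelial cell contraction-centred cardiovascular subnetwork): nodes
#' with a subcellular compartment and an upstream/downstream cascade
#' position, signed edges (activation/inhibition, carried but not
#' interpreted), and, after [annotateRegulators()], the set of compound
#' classes that directly target each node.
#'
#' @slot name subnetwork label.
#' @slot nodes data.frame with columns `node_id`, `compartment`, `position`.
#' @slot edges data.frame with columns `source_id`, `target_id`, `effect`.
#' @slot regulators named list: node_id -> character subset of
#'   `c("herbal", "western")`.
#' @seealso [assembleSubnetwork()], [coverageSummary()],
#'   [positionPreference()]
#' @export
setClass("DiseaseSubnetwork",
         representation(name = "character", nodes = "data.frame",
                        edges = "data.frame", regulators = "list"))

setValidity("DiseaseSubnetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("node_id", "compartment", "position") %in% names(nd)))
    return("nodes needs columns node_id, compartment, position")
  if (!all(c("source_id", "target_id", "effect") %in% names(ed)))
    return("edges needs columns source_id, target_id, effect")
  if (anyDuplicated(nd$node_id)) return("duplicate node_id")
  bad <- setdiff(unique(nd$compartment), subcellularLocations())
  if (length(bad) > 0)
    return(paste("unknown compartment:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(nd$position), c("upstream", "downstream", "unassigned"))
  if (length(bad) > 0)
    return(paste("unknown position:", paste(bad, collapse = ", ")))
  if (nrow(ed) > 0) {
    dangling <- setdiff(unique(c(ed$source_id, ed$target_id)), nd$node_id)
    if (length(dangling) > 0)
      return(paste("edge endpoint(s) not in node table:",
                   paste(dangling, collapse = ", ")))
    bad <- setdiff(unique(ed$effect), c("activation", "inhibition"))
    if (length(bad) > 0)
      return(paste("unknown effect:", paste(bad, collapse = ", ")))
  }
  if (length(object@regulators) > 0) {
    if (is.null(names(object@regulators)) ||
        !all(names(object@regulators) %in% nd$node_id))
      return("regulators keys must be node ids")
    cls <- unique(unlist(object@regulators, use.names = FALSE))
    bad <- setdiff(cls, c("herbal", "western"))
    if (length(bad) > 0)
      return(paste("unknown regulator class:", paste(bad, collapse = ", ")))
  }
  TRUE
})
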