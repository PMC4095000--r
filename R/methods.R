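# Accessor and show methods for the S4 containers.

#' @describeIn accessors distinct compound ids in a CompoundTable.
#' @export
setMethod("compoundIds", "CompoundTable", function(x, ...) {
  sort(unique(x@links$compound_id))
})

#' @describeIn accessors the link table (one row per compound-target link).
#' @export
setMethod("compoundLinks", "CompoundTable", function(x, ...) x@links)

#' @describeIn accessors distinct target ids in a TargetAnnotations.
#' @export
setMethod("targetIds", "TargetAnnotations", function(x, ...) x@tbl$target_id)

#' @describeIn accessors the annotation table with list columns.
#' @export
setMethod("annotationTable", "TargetAnnotations", function(x, ...) x@tbl)

#' @describeIn accessors pathway ids in a PathwayCollection.
#' @export
setMethod("pathwayIds", "PathwayCollection", function(x, ...) {
  x@info$pathway_id
})

#' @describeIn accessors named list of pathway member sets.
#' @export
setMethod("pathwayMembers", "PathwayCollection", function(x, ...) x@members)

#' @describeIn accessors named character vector pathway_id -> category.
#' @export
setMethod("pathwayCategory", "PathwayCollection", function(x, ...) {
  stats::setNames(x@info$category, x@info$pathway_id)
})

#' @export
setMethod("length", "PathwayCollection", function(x) nrow(x@info))

#' @param i index (logical, integer or pathway_id character).
#' @param j,drop unused.
#' @rdname PathwayCollection-class
#' @export
setMethod("[", "PathwayCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$pathway_id)
  new("PathwayCollection",
      info = x@info[i, , drop = FALSE],
      members = x@members[i])
})

#' @rdname directTargets
#' @export
setMethod("directTargets", "CompoundTable",
          function(x, compoundClass = NULL, ...) {
  lk <- x@links
  if (!is.null(compoundClass)) {
    checkTokens(compoundClass, compoundClasses(), "compound_class")
    lk <- lk[lk$compound_class %in% compoundClass, , drop = FALSE]
  }
  sort(unique(lk$target_id[lk$link_type == "direct"]))
})

#' @rdname directTargets
#' @export
setMethod("allTargets", "CompoundTable",
          function(x, compoundClass = NULL, ...) {
  lk <- x@links
  if (!is.null(compoundClass)) {
    checkTokens(compoundClass, compoundClasses(), "compound_class")
    lk <- lk[lk$compound_class %in% compoundClass, , drop = FALSE]
  }
  sort(unique(lk$target_id))
})

#' @rdname directTargets
#' @export
setMethod("directTargets", "CvdDataset",
          function(x, compoundClass = NULL, ...) {
  directTargets(x@compounds, compoundClass = compoundClass)
})

#' @rdname directTargets
#' @export
setMethod("allTargets", "CvdDataset", function(x, compoundClass = NULL, ...) {
  allTargets(x@compounds, compoundClass = compoundClass)
})

#' @describeIn accessors compound table of a CvdDataset.
#' @export
setMethod("compoundLinks", "CvdDataset", function(x, ...) {
  x@compounds@links
})

#' @describeIn accessors annotation table of a CvdDataset.
#' @export
setMethod("annotationTable", "CvdDataset", function(x, ...) {
  x@annotations@tbl
})

#' Dataset component accessors
#'
#' @param x a [CvdDataset-class].
#' @return the corresponding component.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
datasetCompounds <- function(x) {
  stopifnot(is(x, "CvdDataset"))
  x@compounds
}

#' @rdname dataset-accessors
#' @export
datasetAnnotations <- function(x) {
  stopifnot(is(x, "CvdDataset"))
  x@annotations
}

#' @rdname dataset-accessors
#' @export
datasetPathways <- function(x) {
  stopifnot(is(x, "CvdDataset"))
  x@pathways
}

#' @rdname dataset-accessors
#' @export
universeSize <- function(x) {
  stopifnot(is(x, "CvdDataset"))
  x@universeSize
}

#' Network component accessors
#'
#' @param x a [BipartiteNetwork-class].
#' @param side `"left"`, `"right"` or `"both"`.
#' @return `networkEdges()`: the edge data.frame; `networkNodes()`: node ids
#'   on the requested side; `nodeDegrees()`: named integer vector of degrees
#'   on the requested side (zero-degree nodes included);
#'   `networkNodeAttrs()`: the node attribute table.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "BipartiteNetwork"))
  x@edges
}

#' @rdname network-accessors
#' @export
networkNodes <- function(x, side = c("both", "left", "right")) {
  stopifnot(is(x, "BipartiteNetwork"))
  side <- match.arg(side)
  switch(side,
         left = x@leftNodes,
         right = x@rightNodes,
         both = c(x@leftNodes, x@rightNodes))
}

#' @rdname network-accessors
#' @export
networkNodeAttrs <- function(x) {
  stopifnot(is(x, "BipartiteNetwork"))
  x@nodeAttrs
}

#' @rdname network-accessors
#' @export
nodeDegrees <- function(x, side = c("left", "right")) {
  stopifnot(is(x, "BipartiteNetwork"))
  side <- match.arg(side)
  nodes <- if (side == "left") x@leftNodes else x@rightNodes
  ends <- if (side == "left") x@edges$left else x@edges$right
  deg <- table(factor(ends, levels = nodes))
  stats::setNames(as.integer(deg), nodes)
}

#' Subnetwork component accessors
#'
#' @param x a [DiseaseSubnetwork-class].
#' @return node table, edge table or regulator list.
#' @name subnetwork-accessors
NULL

#' @rdname subnetwork-accessors
#' @export
subnetworkNodes <- function(x) {
  stopifnot(is(x, "DiseaseSubnetwork"))
  x@nodes
}

#' @rdname subnetwork-accessors
#' @export
subnetworkEdges <- function(x) {
  stopifnot(is(x, "DiseaseSubnetwork"))
  x@edges
}

#' @rdname subnetwork-accessors
#' @export
subnetworkRegulators <- function(x) {
  stopifnot(is(x, "DiseaseSubnetwork"))
  x@regulators
}

setMethod("show", "CompoundTable", function(object) {
  lk <- object@links
  cat("CompoundTable:", length(unique(lk$compound_id)), "compounds,",
      nrow(lk), "links\n")
  if (nrow(lk) > 0) {
    tb <- table(unique(lk[, c("compound_id", "compound_class")])$compound_class)
    for (cl in names(tb)) cat(" ", cl, ":", tb[[cl]], "\n")
  }
})

setMethod("show", "TargetAnnotations", function(object) {
  cat("TargetAnnotations:", nrow(object@tbl), "targets\n")
})

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection:", nrow(object@info), "pathways (",
      sum(object@info$category == "basic"), "basic /",
      sum(object@info$category == "disease"), "disease )\n")
})

setMethod("show", "CvdDataset", function(object) {
  cat("CvdDataset\n")
  cat("  compounds  :", length(unique(object@compounds@links$compound_id)),
      "\n")
  cat("  annotations:", nrow(object@annotations@tbl), "targets\n")
  cat("  pathways   :", nrow(object@pathways@info), "\n")
  cat("  universe   :", object@universeSize, "proteins\n")
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork:", length(object@leftNodes), "left x",
      length(object@rightNodes), "right,", nrow(object@edges), "edges\n")
})

setMethod("show", "DiseaseSubnetwork", function(object) {
  cat("DiseaseSubnetwork '", object@name, "': ", nrow(object@nodes),
      " nodes, ", nrow(object@edges), " edges, ",
      length(object@regulators), " regulated nodes\n", sep = "")
})
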