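# Bipartite target-pathway / compound-pathway network construction, degree
# distributions and log-log power-law fitting. GraphML serialization is
# delegated to igraph.

makeBipartite <- function(left, right, edges, leftKind, rightKind,
                          rightPvals = NULL, rightSig = NULL) {
  left <- sort(unique(as.character(left)))
  right <- sort(unique(as.character(right)))
  edges <- data.frame(left = as.character(edges$left),
                      right = as.character(edges$right),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$left, edges$right), , drop = FALSE]
  edges <- edges[!duplicated(edges), , drop = FALSE]
  rownames(edges) <- NULL
  degL <- table(factor(edges$left, levels = left))
  degR <- table(factor(edges$right, levels = right))
  attrs <- data.frame(
    node_id = c(left, right),
    node_kind = c(rep(leftKind, length(left)), rep(rightKind, length(right))),
    degree = c(as.integer(degL), as.integer(degR)),
    p_value = rep(NA_real_, length(left) + length(right)),
    significant = rep(NA, length(left) + length(right)),
    stringsAsFactors = FALSE)
  if (!is.null(rightPvals)) {
    idx <- match(right, names(rightPvals))
    attrs$p_value[attrs$node_kind == rightKind] <- as.numeric(rightPvals)[idx]
  }
  if (!is.null(rightSig)) {
    idx <- match(right, names(rightSig))
    attrs$significant[attrs$node_kind == rightKind] <- as.logical(rightSig)[idx]
  }
  new("BipartiteNetwork", leftNodes = left, rightNodes = right,
      edges = edges, nodeAttrs = attrs)
}

#' Build the target-pathway bipartite network
#'
#' Links a target to a pathway whenever the target appears among the
#' pathway's members. Pathway nodes are included when they have at least
#' one edge (or, with `significantOnly`, only when their enrichment is
#' significant); targets with no pathway membership are retained as
#' zero-degree nodes. Enrichment p-values, when supplied, are attached to
#' the pathway nodes for downstream styling.
#'
#' @param targetSet character vector of target ids (left side).
#' @param pathways a [PathwayCollection-class].
#' @param enrichment optional enrichment data.frame from
#'   [enrichPathways()] computed on the same collection.
#' @param significantOnly keep only pathways flagged significant in
#'   `enrichment`.
#' @return a [BipartiteNetwork-class].
#' @export
buildTargetPathwayNetwork <- function(targetSet, pathways,
                                      enrichment = NULL,
                                      significantOnly = FALSE) {
  stopifnot(is(pathways, "PathwayCollection"))
  targetSet <- unique(as.character(targetSet))
  keep <- pathways@info$pathway_id
  if (significantOnly) {
    if (is.null(enrichment)) fail("significantOnly requires enrichment")
    keep <- enrichment$pathway_id[enrichment$significant]
  }
  edges <- list()
  touched <- character(0)
  for (i in seq_len(nrow(pathways@info))) {
    pid <- pathways@info$pathway_id[i]
    if (!pid %in% keep) next
    hit <- intersect(pathways@members[[i]], targetSet)
    if (length(hit) == 0) next
    touched <- c(touched, pid)
    edges[[length(edges) + 1L]] <- data.frame(left = hit, right = pid,
                                              stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(left = character(0), right = character(0))
  pv <- sig <- NULL
  if (!is.null(enrichment)) {
    pv <- stats::setNames(enrichment$p_value, enrichment$pathway_id)
    sig <- stats::setNames(enrichment$significant, enrichment$pathway_id)
  }
  makeBipartite(targetSet, touched, edges, "target", "pathway", pv, sig)
}

#' Build the compound-pathway bipartite network
#'
#' Links a compound to a pathway whenever one of its direct targets is a
#' member of the pathway (indirect herbal links are excluded, mirroring the
#' direct-targets-only comparison). All compounds are retained as left
#' nodes, including those with no pathway hit.
#'
#' @param compounds a [CompoundTable-class] or [CvdDataset-class].
#' @param pathways a [PathwayCollection-class].
#' @param perCompoundEnrichment optional list from [enrichPerCompound()];
#'   pathway node attributes then carry the minimum per-compound p-value.
#' @param compoundClass optional filter to one compound class.
#' @return a [BipartiteNetwork-class].
#' @export
buildCompoundPathwayNetwork <- function(compounds, pathways,
                                        perCompoundEnrichment = NULL,
                                        compoundClass = NULL) {
  if (is(compounds, "CvdDataset")) {
    if (missing(pathways)) pathways <- compounds@pathways
    compounds <- compounds@compounds
  }
  stopifnot(is(compounds, "CompoundTable"), is(pathways, "PathwayCollection"))
  lk <- compounds@links
  if (!is.null(compoundClass)) {
    checkTokens(compoundClass, compoundClasses(), "compound_class")
    lk <- lk[lk$compound_class %in% compoundClass, , drop = FALSE]
  }
  cids <- sort(unique(lk$compound_id))
  direct <- lk[lk$link_type == "direct", , drop = FALSE]
  edges <- list()
  touched <- character(0)
  for (i in seq_len(nrow(pathways@info))) {
    pid <- pathways@info$pathway_id[i]
    mem <- pathways@members[[i]]
    hitC <- unique(direct$compound_id[direct$target_id %in% mem])
    if (length(hitC) == 0) next
    touched <- c(touched, pid)
    edges[[length(edges) + 1L]] <- data.frame(left = hitC, right = pid,
                                              stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(left = character(0), right = character(0))
  pv <- sig <- NULL
  if (!is.null(perCompoundEnrichment) && length(perCompoundEnrichment) > 0) {
    all <- do.call(rbind, perCompoundEnrichment)
    agg <- stats::aggregate(p_value ~ pathway_id, data = all, FUN = min)
    pv <- stats::setNames(agg$p_value, agg$pathway_id)
    sig <- pv < perCompoundEnrichment[[1]]$alpha[1]
  }
  makeBipartite(cids, touched, edges, "compound", "pathway", pv, sig)
}

#' Degree distribution f(x) of one network side
#'
#' The frequency of nodes with degree x: for each observed degree, the
#' fraction of nodes on the chosen side having that degree. Zero-degree
#' nodes appear as the x = 0 point (they are excluded from power-law
#' fitting, where log x is undefined). `side = "both"` pools the two sides.
#'
#' @param network a [BipartiteNetwork-class].
#' @param side `"left"`, `"right"` or `"both"`.
#' @return object of class `DegreeDistribution`: list with `points`
#'   (data.frame `x`, `count`, `f_x`), `n_nodes`, `side`.
#' @export
degreeDistribution <- function(network, side = c("left", "right", "both")) {
  side <- match.arg(side)
  stopifnot(is(network, "BipartiteNetwork"))
  deg <- switch(side,
                left = nodeDegrees(network, "left"),
                right = nodeDegrees(network, "right"),
                both = c(nodeDegrees(network, "left"),
                         nodeDegrees(network, "right")))
  if (length(deg) == 0) fail("empty network side: ", side)
  tb <- table(deg)
  x <- as.integer(names(tb))
  structure(list(
    points = data.frame(x = x, count = as.integer(tb),
                        f_x = as.integer(tb) / length(deg)),
    n_nodes = length(deg),
    side = side
  ), class = "DegreeDistribution")
}

#' @export
print.DegreeDistribution <- function(x, ...) {
  cat("Degree distribution (", x$side, " side, ", x$n_nodes, " nodes)\n",
      sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Fit a power law to a degree distribution
#'
#' Least squares on log f(x) versus log x over degrees `x >= xMin`
#' (zero-degree and zero-frequency points excluded). Points are weighted by
#' their node counts: the sampling variance of an empirical log frequency
#' scales inversely with the number of nodes in the bin, and unweighted
#' log-log regression is otherwise dominated by the noisy one-node tail
#' bins and biased towards shallow slopes. On noiseless input all weights
#' act equally and the fit is exact. The exponent is reported positive,
#' i.e. f(x) proportional to x^(-exponent). Requires at least three
#' distinct positive degrees.
#'
#' @param distribution a `DegreeDistribution` from [degreeDistribution()].
#' @param xMin smallest degree entering the fit (default 1).
#' @return list with `exponent` and `fit_r2`.
#' @export
fitPowerLaw <- function(distribution, xMin = 1) {
  pts <- distribution$points
  pts <- pts[pts$x >= max(1, xMin) & pts$f_x > 0, , drop = FALSE]
  if (nrow(pts) < 3)
    fail("unfittable distribution: fewer than 3 distinct degrees >= xMin")
  fit <- stats::lm(log(f_x) ~ log(x), data = pts, weights = pts$count)
  list(exponent = -unname(stats::coef(fit)[2]),
       fit_r2 = summary(fit)$r.squared)
}

bipartiteToIgraph <- function(network) {
  at <- network@nodeAttrs
  vertices <- data.frame(name = at$node_id, kind = at$node_kind,
                         degree = at$degree,
                         p_value = ifelse(is.na(at$p_value), -1,
                                          at$p_value),
                         significant = ifelse(is.na(at$significant), -1L,
                                              as.integer(at$significant)),
                         stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network@edges, directed = FALSE,
                                vertices = vertices)
}

#' Write a bipartite network to disk
#'
#' GraphML (with node kind, degree, p-value and significance attributes,
#' via igraph) or a 2-column TSV edge list. [readNetwork()] reads either
#' format back to an isomorphic network.
#'
#' @param network a [BipartiteNetwork-class].
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(is(network, "BipartiteNetwork"))
  if (format == "graphml") {
    igraph::write_graph(bipartiteToIgraph(network), path,
                        format = "graphml")
  } else {
    utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a bipartite network written by [writeNetwork()]
#'
#' @param path input path.
#' @param format `"graphml"` or `"edgelist"`.
#' @param leftKind,rightKind node kinds for the edge-list format, where
#'   kinds are not stored in the file.
#' @return a [BipartiteNetwork-class].
#' @export
readNetwork <- function(path, format = c("graphml", "edgelist"),
                        leftKind = "target", rightKind = "pathway") {
  format <- match.arg(format)
  if (!file.exists(path)) fail("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vn <- igraph::vertex_attr(g, "name")
    kind <- igraph::vertex_attr(g, "kind")
    pv <- igraph::vertex_attr(g, "p_value")
    sig <- igraph::vertex_attr(g, "significant")
    el <- igraph::as_edgelist(g, names = TRUE)
    kinds <- unique(kind)
    lk <- if (any(kinds %in% c("target", "compound")))
      intersect(kinds, c("target", "compound"))[1] else kinds[1]
    rk <- setdiff(kinds, lk)
    rk <- if (length(rk) == 0) rightKind else rk[1]
    left <- vn[kind == lk]
    right <- vn[kind != lk]
    if (nrow(el) > 0) {
      swap <- !(el[, 1] %in% left)
      el[swap, ] <- el[swap, c(2, 1)]
    }
    edges <- data.frame(left = el[, 1], right = el[, 2],
                        stringsAsFactors = FALSE)
    pvR <- stats::setNames(ifelse(pv < 0, NA_real_, pv), vn)[right]
    sigR <- stats::setNames(ifelse(sig < 0, NA, sig == 1), vn)[right]
    makeBipartite(left, right, edges, lk, rk, pvR, sigR)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    makeBipartite(df$left, df$right, df, leftKind, rightKind)
  }
}
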