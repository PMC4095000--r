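# One-sided Fisher's exact test (hypergeometric right tail) and the
# pathway over-representation procedure built on it.

#' Right-tail Fisher's exact probability of a 2x2 table
#'
#' Probability of observing at least `a` successes in the top-left cell of
#' a 2x2 contingency table with fixed margins; equivalently the upper tail
#' P(X >= a) of a hypergeometric variable with population `N = a+b+c+d`,
#' `a+c` successes and `a+b` draws. This is the one-sided
#' (over-representation) alternative of Fisher's exact test. Terms are
#' evaluated through `lchoose` and accumulated in log space, so the result
#' is numerically exact (relative error well below 1e-12) for populations
#' up to at least 1e4.
#'
#' @param a in-set and in-pathway count.
#' @param b in-set, not-in-pathway count.
#' @param c not-in-set, in-pathway count.
#' @param d neither count.
#' @return the right-tail probability, in (0, 1].
#' @examples
#' fisherRightTail(3, 1, 1, 3) # 17/70
#' @export
fisherRightTail <- function(a, b, c, d) {
  if (length(a) != 1 || length(b) != 1 || length(c) != 1 || length(d) != 1)
    fail("fisherRightTail expects scalar counts")
  cnt <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    fail("counts must be nonnegative integers")
  N <- a + b + c + d
  if (N == 0) fail("all-zero table")
  k <- a + b   # draws
  m <- a + c   # successes in population
  if (k == 0 || m == 0) fail("degenerate margins: need a+b > 0 and a+c > 0")
  hi <- min(k, m)
  xs <- seq.int(a, hi)
  logTerms <- lchoose(k, xs) + lchoose(N - k, m - xs) - lchoose(N, m)
  mx <- max(logTerms)
  p <- exp(mx) * sum(exp(logTerms - mx))
  min(p, 1)
}

#' Resolve the enrichment background universe
#'
#' The published analysis never states its background population, so the
#' universe is an explicit, configurable choice: the union of all pathway
#' members (default — the background of mappable targets), all annotated
#' targets, or an explicit id vector.
#'
#' @param dataset a [CvdDataset-class].
#' @param mode `"pathway-union"`, `"annotated"`, or a character vector of
#'   target ids used as-is.
#' @return character vector of universe target ids.
#' @export
makeUniverse <- function(dataset, mode = "pathway-union") {
  if (length(mode) > 1 || !mode %in% c("pathway-union", "annotated"))
    return(sort(unique(as.character(mode))))
  switch(mode,
         "pathway-union" = sort(unique(unlist(dataset@pathways@members,
                                              use.names = FALSE))),
         "annotated" = sort(dataset@annotations@tbl$target_id))
}

#' Pathway over-representation for one target set
#'
#' Tests each pathway for over-representation of `targetSet` against the
#' background `universe` with the one-sided Fisher's exact test
#' ([fisherRightTail()]). Pathway member lists are intersected with the
#' universe before tabulation; pathways with no member in the universe are
#' skipped. Significance uses the strict inequality `p < alpha`. Raw
#' p-values are thresholded by default; set `adjust = "BH"` for an optional
#' Benjamini-Hochberg mode (the published procedure thresholds raw p at
#' 0.01).
#'
#' @param targetSet character vector of target ids; must lie inside
#'   `universe`.
#' @param pathways a [PathwayCollection-class].
#' @param universe character vector of background target ids.
#' @param alpha significance level (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per tested pathway, sorted by ascending
#'   p-value (ties broken by pathway id): `pathway_id`, `name`, `category`,
#'   `a`, `b`, `c`, `d`, `p_value`, `significant`, `alpha`.
#' @export
enrichPathways <- function(targetSet, pathways, universe, alpha = 0.01,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is(pathways, "PathwayCollection"))
  universe <- unique(as.character(universe))
  targetSet <- unique(as.character(targetSet))
  if (length(universe) == 0) fail("empty universe")
  if (length(targetSet) == 0) fail("empty target set")
  outside <- setdiff(targetSet, universe)
  if (length(outside) > 0)
    fail("target set contains ids outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  if (!(alpha > 0 && alpha < 1)) fail("alpha must lie in (0, 1)")
  N <- length(universe)
  n <- length(targetSet)
  rows <- lapply(seq_len(nrow(pathways@info)), function(i) {
    mem <- intersect(pathways@members[[i]], universe)
    if (length(mem) == 0) return(NULL)
    a <- length(intersect(targetSet, mem))
    b <- n - a
    cc <- length(mem) - a
    d <- N - a - b - cc
    p <- fisherRightTail(a, b, cc, d)
    data.frame(pathway_id = pathways@info$pathway_id[i],
               name = pathways@info$name[i],
               category = pathways@info$category[i],
               a = a, b = b, c = cc, d = d, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    fail("no pathway has members inside the universe")
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  pv <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else
    res$p_value
  # strict p < alpha; the relative guard keeps ties that equal alpha up to
  # floating-point roundoff (e.g. an exact tail of 1/100 at alpha = 0.01)
  # on the non-significant side
  res$significant <- pv < alpha * (1 - 1e-9)
  res$alpha <- alpha
  res
}

#' Per-compound pathway over-representation
#'
#' Applies [enrichPathways()] to each compound's direct-target set
#' (intersected with the universe). Compounds with no direct target in the
#' universe are skipped with a warning and absent from the result.
#'
#' @param compounds a [CompoundTable-class] or [CvdDataset-class].
#' @param pathways a [PathwayCollection-class].
#' @param universe character vector of background target ids.
#' @param alpha significance level.
#' @param adjust passed to [enrichPathways()].
#' @return named list: compound_id -> enrichment data.frame.
#' @export
enrichPerCompound <- function(compounds, pathways, universe, alpha = 0.01,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is(compounds, "CvdDataset")) compounds <- compounds@compounds
  stopifnot(is(compounds, "CompoundTable"))
  lk <- compounds@links
  lk <- lk[lk$link_type == "direct", , drop = FALSE]
  out <- list()
  skipped <- character(0)
  for (cid in sort(unique(compounds@links$compound_id))) {
    ts <- intersect(unique(lk$target_id[lk$compound_id == cid]), universe)
    if (length(ts) == 0) {
      skipped <- c(skipped, cid)
      next
    }
    out[[cid]] <- enrichPathways(ts, pathways, universe, alpha = alpha,
                                 adjust = adjust)
  }
  if (length(skipped) > 0)
    warning(length(skipped),
            " compound(s) with no direct target in the universe skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "), call. = FALSE)
  out
}

#' Split pathways or enrichment results into basic and disease parts
#'
#' Partitions by the pathway category and reports the disease fraction
#' (|disease| / total).
#'
#' @param x a [PathwayCollection-class], or an enrichment result data.frame
#'   from [enrichPathways()] (its `category` column is used).
#' @param significantOnly for enrichment results: restrict to rows with
#'   `significant == TRUE` before splitting.
#' @return list with elements `basic`, `disease` (same type as `x`) and
#'   `disease_fraction`.
#' @export
splitBasicDisease <- function(x, significantOnly = FALSE) {
  if (is(x, "PathwayCollection")) {
    if (nrow(x@info) == 0) fail("empty pathway collection")
    isDis <- x@info$category == "disease"
    return(list(basic = x[which(!isDis)], disease = x[which(isDis)],
                disease_fraction = sum(isDis) / length(isDis)))
  }
  if (!is.data.frame(x) || !"category" %in% names(x))
    fail("expected a PathwayCollection or an enrichment result data.frame")
  if (significantOnly) x <- x[x$significant, , drop = FALSE]
  if (nrow(x) == 0) fail("empty enrichment result set")
  isDis <- x$category == "disease"
  list(basic = x[!isDis, , drop = FALSE],
       disease = x[isDis, , drop = FALSE],
       disease_fraction = sum(isDis) / length(isDis))
}

#' Write enrichment results to TSV
#'
#' @param results enrichment data.frame from [enrichPathways()].
#' @param path output path.
#' @param entityId label written in the `entity_id` column.
#' @return invisibly, `path`.
#' @export
writeEnrichmentResults <- function(results, path, entityId = "target_set") {
  out <- data.frame(entity_id = entityId,
                    pathway_id = results$pathway_id,
                    a = results$a, b = results$b, c = results$c,
                    d = results$d,
                    p_value = formatC(results$p_value, format = "e",
                                      digits = 5),
                    significant = as.integer(results$significant),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
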