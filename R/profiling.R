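# Target-level comparative statistics: TTD tallies, diseases-per-target
# (d/t), domain/family/location distributions, TF enrichment and the
# multi-target compound classifier.

getAnnotations <- function(annotations, targets, requireAll = TRUE) {
  if (is(annotations, "CvdDataset")) annotations <- annotations@annotations
  stopifnot(is(annotations, "TargetAnnotations"))
  tb <- annotations@tbl
  idx <- match(targets, tb$target_id)
  if (requireAll && anyNA(idx)) {
    fail("unannotated target(s): ",
         paste(utils::head(targets[is.na(idx)], 5), collapse = ", "))
  }
  tb[idx[!is.na(idx)], , drop = FALSE]
}

#' Tally targets by TTD development status
#'
#' Counts a target group by Therapeutic Target Database status (successful,
#' clinical trial, research, discontinued) and reports the in-TTD total;
#' targets with status `"absent"` complete the denominator but are excluded
#' from the in-TTD sum. Percentages follow the package half-up rounding
#' convention at one decimal.
#'
#' @param targets character vector of target ids (the group).
#' @param annotations a [TargetAnnotations-class] or [CvdDataset-class].
#' @param groupLabel label carried in the result.
#' @return object of class `CategoryTally`: a list with `group_label`,
#'   `denominator`, `per_status_count`, `per_status_pct`, `in_ttd_count`,
#'   `in_ttd_pct`.
#' @export
tallyTtd <- function(targets, annotations, groupLabel = "group") {
  targets <- unique(as.character(targets))
  if (length(targets) == 0) fail("empty target set: tally denominator is 0")
  ann <- getAnnotations(annotations, targets)
  statuses <- setdiff(ttdStatuses(), "absent")
  counts <- vapply(statuses, function(s) sum(ann$ttd_status == s),
                   integer(1))
  denom <- length(targets)
  inTtd <- sum(counts)
  structure(list(
    group_label = groupLabel,
    denominator = denom,
    per_status_count = as.list(counts),
    per_status_pct = as.list(pctHalfUp(counts, denom)),
    in_ttd_count = inTtd,
    in_ttd_pct = pctHalfUp(inTtd, denom),
    absent_count = denom - inTtd
  ), class = "CategoryTally")
}

#' @export
print.CategoryTally <- function(x, ...) {
  cat("TTD tally for", x$group_label, "(", x$denominator, "targets )\n")
  for (s in names(x$per_status_count)) {
    cat(sprintf("  %-14s %4d  %5.1f%%\n", s, x$per_status_count[[s]],
                x$per_status_pct[[s]]))
  }
  cat(sprintf("  %-14s %4d  %5.1f%%\n", "in TTD", x$in_ttd_count,
              x$in_ttd_pct))
  invisible(x)
}

#' Diseases-per-target (d/t) statistic
#'
#' For the targets of one group with the given TTD status, the total number
#' of disease associations divided by the number of targets. Associations
#' are summed per target: two targets sharing a disease name contribute two
#' associations, not one — the statistic averages each target's disease
#' count, it does not measure the union of disease names.
#'
#' @param targets character vector of target ids (the group).
#' @param annotations a [TargetAnnotations-class] or [CvdDataset-class].
#' @param status one TTD status (`"successful"`, `"clinical_trial"`,
#'   `"research"`).
#' @param groupLabel label carried in the result.
#' @return object of class `DTStatistic`: list with `group_label`,
#'   `ttd_status`, `n_targets`, `n_disease_associations`, `dt_value`
#'   (exact; round only for display).
#' @export
computeDt <- function(targets, annotations, status, groupLabel = "group") {
  checkTokens(status, ttdStatuses(), "ttd_status")
  targets <- unique(as.character(targets))
  ann <- getAnnotations(annotations, targets)
  sel <- ann[ann$ttd_status == status, , drop = FALSE]
  if (nrow(sel) == 0)
    fail("no target with status '", status, "' in group ", groupLabel)
  nAssoc <- sum(lengths(sel$diseases))
  structure(list(
    group_label = groupLabel,
    ttd_status = status,
    n_targets = nrow(sel),
    n_disease_associations = nAssoc,
    dt_value = nAssoc / nrow(sel)
  ), class = "DTStatistic")
}

#' @export
print.DTStatistic <- function(x, ...) {
  cat(sprintf("d/t [%s, %s]: %d diseases / %d targets = %s\n",
              x$group_label, x$ttd_status, x$n_disease_associations,
              x$n_targets, format(roundHalfUp(x$dt_value, 2))))
  invisible(x)
}

makeProfile <- function(labels, counts, groupLabel, axis, denom) {
  data.frame(group_label = groupLabel, axis = axis,
             bin_label = as.character(labels),
             count = as.integer(counts),
             fraction = as.numeric(counts) / denom,
             stringsAsFactors = FALSE)
}

#' Distribution of structural-domain counts
#'
#' Bins a target group by the number of domain identifiers annotated per
#' target (a multiset count: repeated domains count). Every target falls in
#' exactly one integer bin, so fractions sum to one.
#'
#' @inheritParams tallyTtd
#' @return a `DistributionProfile` data.frame: `group_label`, `axis`,
#'   `bin_label`, `count`, `fraction`.
#' @export
domainCountProfile <- function(targets, annotations, groupLabel = "group") {
  targets <- unique(as.character(targets))
  ann <- getAnnotations(annotations, targets)
  k <- lengths(ann$domain_ids)
  tb <- table(factor(k, levels = 0:max(k, 0)))
  makeProfile(names(tb), as.integer(tb), groupLabel, "domain_count",
              nrow(ann))
}

#' Distribution of protein biochemical families
#'
#' One bin per family category; each target counted once (targets without a
#' stated family are stored as `"other"`). Fractions sum to one.
#'
#' @inheritParams tallyTtd
#' @return a `DistributionProfile` data.frame.
#' @export
familyProfile <- function(targets, annotations, groupLabel = "group") {
  targets <- unique(as.character(targets))
  ann <- getAnnotations(annotations, targets)
  tb <- table(factor(ann$family, levels = proteinFamilies()))
  makeProfile(names(tb), as.integer(tb), groupLabel, "family", nrow(ann))
}

#' Distribution of subcellular locations
#'
#' A target annotated with k compartments contributes one count to each of
#' the k bins, so location fractions may sum to more than one for
#' multi-compartment targets.
#'
#' @inheritParams tallyTtd
#' @return a `DistributionProfile` data.frame.
#' @export
locationProfile <- function(targets, annotations, groupLabel = "group") {
  targets <- unique(as.character(targets))
  ann <- getAnnotations(annotations, targets)
  locs <- unlist(ann$locations, use.names = FALSE)
  tb <- table(factor(locs, levels = subcellularLocations()))
  makeProfile(names(tb), as.integer(tb), groupLabel, "location", nrow(ann))
}

#' Write a distribution profile to TSV
#'
#' @param profile a `DistributionProfile` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeProfile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Transcription-factor enrichment of a target group
#'
#' One-sided Fisher's exact test of whether the group contains more
#' transcription factors than a random draw of the same size from the
#' proteome background. The background is an explicit parameter because the
#' source analysis never states it; the documented defaults are a 20,000
#' protein proteome of which 618 are TFs (the TRANSFAC census).
#'
#' @inheritParams tallyTtd
#' @param universeSize background proteome size (default 20000).
#' @param nTfUniverse TFs in the background (default 618).
#' @return object of class `TFEnrichment`: list with `group_label`,
#'   `n_targets`, `n_tf_targets`, `universe_size`, `n_tf_universe`,
#'   `p_value`.
#' @export
tfEnrichment <- function(targets, annotations, universeSize = 20000,
                         nTfUniverse = 618, groupLabel = "group") {
  targets <- unique(as.character(targets))
  ann <- getAnnotations(annotations, targets)
  n <- nrow(ann)
  if (universeSize < n)
    fail("universeSize (", universeSize, ") smaller than target group (",
         n, ")")
  k <- sum(ann$is_tf)
  if (k > nTfUniverse)
    warning("observed TF count ", k, " exceeds nTfUniverse ", nTfUniverse,
            call. = FALSE)
  p <- fisherRightTail(k, n - k, nTfUniverse - k,
                       universeSize - n - (nTfUniverse - k))
  structure(list(group_label = groupLabel, n_targets = n, n_tf_targets = k,
                 universe_size = universeSize, n_tf_universe = nTfUniverse,
                 p_value = p), class = "TFEnrichment")
}

#' @export
print.TFEnrichment <- function(x, ...) {
  cat(sprintf("TF enrichment [%s]: %d TFs / %d targets vs %d / %d, p = %.4g\n",
              x$group_label, x$n_tf_targets, x$n_targets, x$n_tf_universe,
              x$universe_size, x$p_value))
  invisible(x)
}

#' Classify compounds by the structure of their direct-target set
#'
#' Mirrors the drug-type breakdown used for multi-target western drugs:
#' `single_target` for exactly one distinct direct target;
#' `same_family_multi` for two or more targets all of one biochemical family
#' (different subtypes of one protein type); otherwise `same_process_multi`
#' when all targets co-occur in at least one common pathway (one biological
#' process); `other` otherwise. Precedence is in that order. Compounds with
#' zero direct targets are classified `other` with a warning.
#'
#' @param compounds a [CompoundTable-class] or [CvdDataset-class].
#' @param annotations a [TargetAnnotations-class] or [CvdDataset-class].
#' @param pathways a [PathwayCollection-class].
#' @return named character vector: compound_id -> class.
#' @export
classifyMultiTargetCompounds <- function(compounds, annotations, pathways) {
  if (is(compounds, "CvdDataset")) {
    if (missing(annotations)) annotations <- compounds@annotations
    if (missing(pathways)) pathways <- compounds@pathways
    compounds <- compounds@compounds
  }
  stopifnot(is(compounds, "CompoundTable"), is(pathways, "PathwayCollection"))
  lk <- compounds@links
  direct <- lk[lk$link_type == "direct", , drop = FALSE]
  ids <- sort(unique(lk$compound_id))
  noTargets <- character(0)
  out <- vapply(ids, function(cid) {
    ts <- unique(direct$target_id[direct$compound_id == cid])
    if (length(ts) == 0) {
      noTargets <<- c(noTargets, cid)
      return("other")
    }
    if (length(ts) == 1) return("single_target")
    fam <- getAnnotations(annotations, ts)$family
    if (length(unique(fam)) == 1) return("same_family_multi")
    shared <- vapply(pathways@members, function(m) all(ts %in% m),
                     logical(1))
    if (any(shared)) return("same_process_multi")
    "other"
  }, character(1))
  if (length(noTargets) > 0)
    warning(length(noTargets), " compound(s) with zero direct targets ",
            "classified 'other': ",
            paste(utils::head(noTargets, 5), collapse = ", "),
            call. = FALSE)
  out
}
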