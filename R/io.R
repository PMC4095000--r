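# Readers and writers for the normalized TSV/GMT exchange formats, plus
# dataset-level validation. List-valued cells use ";" as internal delimiter;
# "#"-prefixed lines are comments; comparisons are case-sensitive.

readTsv <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
}

requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    fail("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
}

#' Construct a CompoundTable
#'
#' @param links data.frame with columns `compound_id`, `name`,
#'   `compound_class`, `target_id`, `link_type`.
#' @return a validated [CompoundTable-class].
#' @export
CompoundTable <- function(links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  # canonical row order so equal link sets compare identical
  links <- links[order(links$compound_id, links$target_id,
                       links$link_type), , drop = FALSE]
  rownames(links) <- NULL
  new("CompoundTable", links = links)
}

#' Read a compound-target link table
#'
#' One link per row; links for the same compound are aggregated, so row
#' order never affects the result. Unknown class or link-type tokens, and
#' conflicting names for one compound id, raise errors.
#'
#' @param path TSV file with columns `compound_id`, `name`,
#'   `compound_class`, `target_id`, `link_type`.
#' @return a [CompoundTable-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("compound_id\tname\tcompound_class\ttarget_id\tlink_type",
#'              "c1\tdanshen A\therbal_ingredient\tT1\tdirect",
#'              "c1\tdanshen A\therbal_ingredient\tT2\tdirect"), f)
#' readCompoundTable(f)
#' @export
readCompoundTable <- function(path) {
  df <- readTsv(path)
  requireColumns(df, c("compound_id", "name", "compound_class", "target_id",
                       "link_type"), path)
  if (nrow(df) > 0) {
    bad <- which(!(df$compound_class %in% compoundClasses()))
    if (length(bad) > 0)
      fail("parse error in ", path, " row ", bad[1],
           ": unknown compound_class '", df$compound_class[bad[1]], "'")
    bad <- which(!(df$link_type %in% linkTypes()))
    if (length(bad) > 0)
      fail("parse error in ", path, " row ", bad[1],
           ": unknown link_type '", df$link_type[bad[1]], "'")
    per <- unique(df[, c("compound_id", "name")])
    dup <- per$compound_id[duplicated(per$compound_id)]
    if (length(dup) > 0)
      fail("validation error in ", path, ": conflicting names for compound ",
           dup[1])
  }
  # canonical order: by compound then target then link type
  df <- df[order(df$compound_id, df$target_id, df$link_type), , drop = FALSE]
  df <- df[!duplicated(df[, c("compound_id", "target_id", "link_type")]), ,
           drop = FALSE]
  CompoundTable(df)
}

#' Write a compound-target link table
#'
#' @param x a [CompoundTable-class].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeCompoundTable <- function(x, path) {
  stopifnot(is(x, "CompoundTable"))
  utils::write.table(x@links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a TargetAnnotations object
#'
#' @param tbl data.frame with the annotation columns; `diseases`,
#'   `domain_ids`, `locations` may be character `;`-joined cells or list
#'   columns.
#' @return a validated [TargetAnnotations-class].
#' @export
TargetAnnotations <- function(tbl) {
  tbl <- as.data.frame(tbl, stringsAsFactors = FALSE)
  for (col in c("diseases", "domain_ids", "locations")) {
    v <- tbl[[col]]
    if (!is.list(v)) v <- splitListCell(v)
    tbl[[col]] <- lapply(v, as.character)   # plain list column, no AsIs
  }
  tbl$is_tf <- as.logical(tbl$is_tf)
  tbl$tf_gene_count <- as.integer(tbl$tf_gene_count)
  tbl <- tbl[order(tbl$target_id), , drop = FALSE]
  rownames(tbl) <- NULL
  new("TargetAnnotations", tbl = tbl)
}

#' Read a target annotation table
#'
#' `diseases`, `domain_ids` and `locations` are `;`-separated cells
#' (whitespace around items stripped); empty cells give empty collections.
#' Missing optional columns default to `ttd_status = "absent"`,
#' `family = "other"`, `is_tf = FALSE`, `tf_gene_count = 0`.
#'
#' @param path TSV file with columns `target_id`, `name`, `ttd_status`,
#'   `diseases`, `domain_ids`, `family`, `locations`, `is_tf` (0/1),
#'   `tf_gene_count`.
#' @return a [TargetAnnotations-class].
#' @export
readAnnotationTable <- function(path) {
  df <- readTsv(path)
  requireColumns(df, "target_id", path)
  defaults <- list(name = "", ttd_status = "absent", diseases = "",
                   domain_ids = "", family = "other", locations = "",
                   is_tf = "0", tf_gene_count = "0")
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  if (nrow(df) > 0) {
    if (anyDuplicated(df$target_id)) {
      full <- df[, c("target_id", "name", "ttd_status", "diseases",
                     "domain_ids", "family", "locations", "is_tf",
                     "tf_gene_count")]
      full <- unique(full)
      dup <- full$target_id[duplicated(full$target_id)]
      if (length(dup) > 0)
        fail("validation error in ", path,
             ": duplicate target_id with conflicting fields: ", dup[1])
      df <- df[!duplicated(df$target_id), , drop = FALSE]
    }
    badb <- which(!(df$is_tf %in% c("0", "1", "TRUE", "FALSE")))
    if (length(badb) > 0)
      fail("parse error in ", path, " row ", badb[1],
           ": malformed boolean is_tf '", df$is_tf[badb[1]], "'")
    df$is_tf <- df$is_tf %in% c("1", "TRUE")
    tfg <- suppressWarnings(as.integer(df$tf_gene_count))
    if (anyNA(tfg))
      fail("parse error in ", path, ": malformed tf_gene_count")
    df$tf_gene_count <- tfg
  } else {
    df$is_tf <- logical(0)
    df$tf_gene_count <- integer(0)
  }
  TargetAnnotations(df)
}

#' Write a target annotation table
#'
#' @param x a [TargetAnnotations-class].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeAnnotationTable <- function(x, path) {
  stopifnot(is(x, "TargetAnnotations"))
  tb <- x@tbl
  out <- data.frame(target_id = tb$target_id, name = tb$name,
                    ttd_status = tb$ttd_status,
                    diseases = joinListCell(tb$diseases),
                    domain_ids = joinListCell(tb$domain_ids),
                    family = tb$family,
                    locations = joinListCell(tb$locations),
                    is_tf = as.integer(tb$is_tf),
                    tf_gene_count = tb$tf_gene_count,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a PathwayCollection
#'
#' @param pathway_id,name,category parallel character vectors (category
#'   `"basic"` or `"disease"`).
#' @param members list of character member vectors, parallel to
#'   `pathway_id`.
#' @return a validated [PathwayCollection-class].
#' @export
PathwayCollection <- function(pathway_id, name = pathway_id,
                              category = "basic", members) {
  n <- length(pathway_id)
  info <- data.frame(pathway_id = pathway_id,
                     name = rep_len(name, n),
                     category = rep_len(category, n),
                     stringsAsFactors = FALSE)
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  names(members) <- info$pathway_id
  new("PathwayCollection", info = info, members = members)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `id TAB description TAB member...`. The
#' category is parsed from the description: a description containing the
#' whitespace-separated token `disease` gives category `"disease"`,
#' otherwise `"basic"` (a leading `basic`/`disease` token is stripped from
#' the stored name). Duplicate member ids within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return a [PathwayCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character(0); nms <- character(0); cats <- character(0)
  members <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      fail("parse error in ", path, " line ", i,
           ": GMT line needs >= 3 tab-separated fields")
    desc <- trimws(fields[2])
    toks <- strsplit(desc, "\\s+")[[1]]
    cat_i <- if ("disease" %in% toks) "disease" else "basic"
    if (length(toks) > 0 && toks[1] %in% c("basic", "disease"))
      desc <- trimws(sub("^\\S+\\s*", "", desc))
    ids <- c(ids, fields[1])
    nms <- c(nms, if (nzchar(desc)) desc else fields[1])
    cats <- c(cats, cat_i)
    members[[length(members) + 1L]] <- unique(fields[-(1:2)])
  }
  PathwayCollection(ids, nms, cats, members)
}

#' Write gene sets to a GMT file
#'
#' The category is written as the first token of the description field so
#' that [readGmt()] round-trips it.
#'
#' @param x a [PathwayCollection-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "PathwayCollection"))
  lines <- vapply(seq_len(nrow(x@info)), function(i) {
    paste(c(x@info$pathway_id[i],
            paste(x@info$category[i], x@info$name[i]),
            x@members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a CvdDataset
#'
#' @param compounds a [CompoundTable-class].
#' @param annotations a [TargetAnnotations-class].
#' @param pathways a [PathwayCollection-class] (may be empty).
#' @param universeSize total annotatable proteins; defaults to the number of
#'   annotated targets.
#' @return a [CvdDataset-class].
#' @export
CvdDataset <- function(compounds, annotations,
                       pathways = PathwayCollection(character(0),
                                                    members = list()),
                       universeSize = NULL) {
  if (is.null(universeSize))
    universeSize <- nrow(annotations@tbl)
  new("CvdDataset", compounds = compounds, annotations = annotations,
      pathways = pathways, universeSize = as.numeric(universeSize))
}

#' Validate cross-references in a dataset
#'
#' Reports (never throws) referential problems: target ids referenced by a
#' compound link or a pathway member list without an annotation record,
#' and a `universeSize` smaller than the number of annotated targets.
#'
#' @param dataset a [CvdDataset-class].
#' @return a data.frame with columns `kind`, `id`, `detail`; zero rows when
#'   the dataset is fully consistent.
#' @export
validateDataset <- function(dataset) {
  stopifnot(is(dataset, "CvdDataset"))
  ann <- dataset@annotations@tbl$target_id
  problems <- list()
  dangling <- setdiff(unique(dataset@compounds@links$target_id), ann)
  for (id in dangling) {
    problems[[length(problems) + 1L]] <-
      data.frame(kind = "dangling_compound_target", id = id,
                 detail = "compound link references unannotated target",
                 stringsAsFactors = FALSE)
  }
  pmem <- unique(unlist(dataset@pathways@members, use.names = FALSE))
  for (id in setdiff(pmem, ann)) {
    problems[[length(problems) + 1L]] <-
      data.frame(kind = "dangling_pathway_member", id = id,
                 detail = "pathway member has no annotation record",
                 stringsAsFactors = FALSE)
  }
  if (dataset@universeSize < length(ann)) {
    problems[[length(problems) + 1L]] <-
      data.frame(kind = "universe_too_small", id = "universeSize",
                 detail = sprintf("universeSize %d < %d annotated targets",
                                  as.integer(dataset@universeSize),
                                  length(ann)),
                 stringsAsFactors = FALSE)
  }
  if (length(problems) == 0) {
    return(data.frame(kind = character(0), id = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, problems)
}
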