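# Independent oracles and small fixture builders used across the suite.

# Exhaustive-enumeration oracle for the right-tail Fisher probability:
# enumerate every 2x2 table with the same margins, weight each by its
# number of underlying arrangements, and sum the weights of tables whose
# top-left cell is >= a. Deliberately avoids the hypergeometric closed
# form used by the implementation.
enumRightTail <- function(a, b, c, d) {
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  lo <- max(0, col1 - row2)
  hi <- min(row1, col1)
  ks <- lo:hi
  wt <- choose(row1, ks) * choose(row2, col1 - ks)
  sum(wt[ks >= a]) / sum(wt)
}

# random non-degenerate 2x2 table with N <= nMax
randomTable <- function(nMax = 40) {
  repeat {
    N <- sample(2:nMax, 1)
    cells <- as.vector(stats::rmultinom(1, N, stats::runif(4, 0.05, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (a + b > 0 && a + c > 0) return(c(a = a, b = b, c = c, d = d))
  }
}

# minimal consistent dataset: 2 compounds, 4 targets, 2 pathways
tinyDataset <- function() {
  links <- data.frame(
    compound_id = c("h1", "h1", "h1", "w1", "w1"),
    name = c("ing one", "ing one", "ing one", "drug one", "drug one"),
    compound_class = c(rep("herbal_ingredient", 3), rep("western_drug", 2)),
    target_id = c("T1", "T2", "T3", "T3", "T4"),
    link_type = c("direct", "direct", "indirect", "direct", "direct"),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    target_id = c("T1", "T2", "T3", "T4"),
    name = paste("protein", 1:4),
    ttd_status = c("successful", "research", "absent", "clinical_trial"),
    diseases = I(list(c("d1", "d2"), "d1", character(0), "d3")),
    domain_ids = I(list("PF1", c("PF1", "PF2"), character(0), "PF3")),
    family = c("enzyme", "receptor", "enzyme", "channel_transporter"),
    locations = I(list("cytoplasm", c("plasma_membrane", "cytoplasm"),
                       "nucleus", "plasma_membrane")),
    is_tf = c(TRUE, FALSE, FALSE, FALSE),
    tf_gene_count = c(5L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  CvdDataset(CompoundTable(links), TargetAnnotations(ann),
             PathwayCollection(c("P1", "P2"), c("path one", "path two"),
                               c("basic", "disease"),
                               list(c("T1", "T2"), c("T3", "T4"))),
             universeSize = 4)
}

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
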