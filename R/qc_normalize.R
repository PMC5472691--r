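# Replicate failure detection against water controls, replicate collapsing,
# median-of-totals depth scaling, and rarefaction.

#' Flag failed technical replicates by clustering against water controls
#'
#' Complete-linkage hierarchical clustering of Euclidean distances between
#' `log10(1 + count)` row vectors of the replicate-by-amplicon read-count
#' matrix, cut into two clusters. The cluster holding the majority of water
#' controls is the failure cluster; every non-water replicate in it is
#' flagged. Invariant to row order.
#'
#' @param counts matrix of assigned read counts, replicates in rows, amplicons
#'   in columns.
#' @param is_water logical vector, one per row.
#' @return character vector of flagged replicate ids (rownames).
#' @export
flag_failed_replicates <- function(counts, is_water) {
  if (!any(is_water)) {
    .hb_stop("no water controls present; provide negative controls or apply ",
             "a fixed read-count threshold instead")
  }
  if (nrow(counts) < 2) return(character(0))
  lg <- log10(1 + counts)
  cl <- cutree(hclust(dist(lg, method = "euclidean"), method = "complete"),
               k = 2)
  wat_tab <- table(cl[is_water])
  fail_cl <- as.integer(names(wat_tab)[which.max(wat_tab)])
  if (length(wat_tab) == 2 && wat_tab[1] == wat_tab[2]) {
    # tie: the cluster with the lower mean total is the failure cluster
    tot <- tapply(rowSums(counts), cl, mean)
    fail_cl <- as.integer(names(tot)[which.min(tot)])
  }
  rownames(counts)[cl == fail_cl & !is_water]
}

#' Collapse technical replicates into samples
#'
#' Per sample, counts are the elementwise sum over unflagged, non-water
#' replicates; samples left with no surviving replicate are dropped with a
#' warning.
#'
#' @param rsv_table an `rsv_table` with replicate columns.
#' @param replicate_map data.frame `replicate`, `sample`, `is_water`.
#' @param failed character vector of flagged replicate ids.
#' @return an `rsv_table` with sample columns.
#' @export
collapse_replicates <- function(rsv_table, replicate_map, failed = character(0)) {
  reps <- colnames(rsv_table$counts)
  m <- replicate_map[match(reps, replicate_map$replicate), ]
  if (any(is.na(m$sample))) .hb_stop("replicate without a sample mapping")
  use <- !m$is_water & !reps %in% failed
  samples <- unique(m$sample[!m$is_water])
  out <- matrix(0L, nrow(rsv_table$counts), length(samples),
                dimnames = list(rownames(rsv_table$counts), samples))
  for (s in samples) {
    cols <- which(use & m$sample == s)
    if (length(cols)) {
      out[, s] <- as.integer(rowSums(rsv_table$counts[, cols, drop = FALSE]))
    }
  }
  dead <- vapply(samples, function(s) !any(use & m$sample == s), TRUE)
  if (any(dead)) {
    warning("sample(s) with no surviving replicate dropped: ",
            paste(samples[dead], collapse = ", "))
    out <- out[, !dead, drop = FALSE]
  }
  structure(list(rsv = rsv_table$rsv, counts = out), class = "rsv_table")
}

#' Scale samples to the median total count
#'
#' Each sample's counts are multiplied by `median(totals) / total_j`, so all
#' normalized sample totals equal the median total and within-sample
#' proportions are preserved exactly.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; every
#'   sample total must be positive.
#' @return list `normalized` (real-valued matrix), `factors` (per sample).
#' @export
median_scale <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    .hb_stop("zero-total sample(s): ",
             paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  f <- median(totals) / totals
  list(normalized = sweep(counts, 2, f, `*`), factors = f)
}

#' Rarefy samples to a common depth
#'
#' Draws `depth` reads per sample without replacement (multivariate
#' hypergeometric on the sample's counts). Never introduces a taxon absent
#' from the sample; all output totals equal `depth`.
#'
#' @param counts integer matrix, taxa x samples.
#' @param depth target depth; defaults to the smallest sample total.
#' @param seed integer seed.
#' @return integer matrix of the same shape.
#' @export
rarefy <- function(counts, depth = min(colSums(counts)), seed = 1) {
  totals <- colSums(counts)
  if (any(depth > totals)) {
    .hb_stop("rarefaction depth ", depth, " exceeds total of sample(s): ",
             paste(colnames(counts)[depth > totals], collapse = ", "))
  }
  set.seed(seed)
  out <- counts
  for (j in seq_len(ncol(counts))) {
    if (totals[j] == depth) next
    pool <- rep.int(seq_len(nrow(counts)), counts[, j])
    draw <- pool[sample.int(length(pool), depth)]
    out[, j] <- tabulate(draw, nbins = nrow(counts))
  }
  storage.mode(out) <- "integer"
  out
}
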