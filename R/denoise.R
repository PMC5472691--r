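# Simplified per-amplicon sequence-variant inference, mate concatenation and
# de novo bimera removal, yielding the RSV table.

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Concatenate denoised mates into one RSV sequence
#'
#' Forward sequence, a 10-base N spacer, then the reverse complement of the
#' reverse mate (so both halves read in the forward orientation of the
#' amplified insert). Vectorized.
#'
#' @param fwd,rev character vectors of equal length.
#' @return character vector; `nchar = nchar(fwd) + 10 + nchar(rev)`.
#' @export
concat_pairs <- function(fwd, rev) {
  if (any(nchar(fwd) == 0) || any(nchar(rev) == 0)) .hb_stop("empty mate")
  paste0(fwd, strrep("N", 10), revcomp(rev))
}

#' Infer sequence variants by abundance-skew collapsing
#'
#' A documented, fully specified stand-in for error-model denoising: reads
#' are dereplicated exactly; unique sequences are visited in order of
#' decreasing abundance (ties broken lexicographically) and absorbed into the
#' most abundant already-retained variant within Hamming distance `d_max`
#' whenever their count is at most `skew^d` times that variant's current
#' count. Anything not absorbed becomes a variant itself.
#'
#' @param seqs character vector of (concatenated) reads from one amplicon and
#'   replicate; all must share one length.
#' @param d_max maximum Hamming distance absorbed.
#' @param skew abundance skew: a neighbor at distance d is absorbed when its
#'   count is `<= skew^d * count(center)`.
#' @param min_count unique sequences below this count are dropped before
#'   collapsing.
#' @return data.frame `sequence`, `count`, sorted by decreasing count.
#' @export
infer_rsvs <- function(seqs, d_max = 1, skew = 0.1, min_count = 1) {
  if (length(seqs) == 0) {
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  if (length(unique(nchar(seqs))) > 1) {
    .hb_stop("unequal read lengths within an amplicon")
  }
  tab <- table(seqs)
  uniq <- names(tab); cnt <- as.integer(tab)
  keep <- cnt >= min_count
  uniq <- uniq[keep]; cnt <- cnt[keep]
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]; cnt <- cnt[ord]
  centers <- character(0); ccount <- numeric(0)
  for (i in seq_along(uniq)) {
    absorbed <- FALSE
    if (length(centers) > 0 && d_max > 0) {
      # centers in decreasing current-count order
      for (j in order(-ccount)) {
        d <- hamming(uniq[i], centers[j])
        if (d <= d_max && cnt[i] <= skew^d * ccount[j]) {
          ccount[j] <- ccount[j] + cnt[i]
          absorbed <- TRUE
          break
        }
      }
    }
    if (!absorbed) {
      centers <- c(centers, uniq[i])
      ccount <- c(ccount, cnt[i])
    }
  }
  ord <- order(-ccount, centers)
  data.frame(sequence = centers[ord], count = as.integer(ccount[ord]),
             stringsAsFactors = FALSE)
}

#' Build the RSV-by-replicate count table
#'
#' Runs mate concatenation and [infer_rsvs()] per amplicon and replicate and
#' collates one table of unique (amplicon, sequence) rows by replicate
#' columns.
#'
#' @param stratified named list (by replicate) of named lists (by amplicon)
#'   of trimmed pair data.frames, as produced by [stratify_by_primer()] per
#'   replicate.
#' @param d_max,skew,min_count passed to [infer_rsvs()].
#' @return list of class `rsv_table`: `rsv` (data.frame rsv_id, amplicon,
#'   sequence) and `counts` (matrix rsv x replicate).
#' @export
build_rsv_table <- function(stratified, d_max = 1, skew = 0.1,
                            min_count = 1) {
  rep_ids <- names(stratified)
  per_rep <- lapply(rep_ids, function(rep_id) {
    amps <- stratified[[rep_id]]
    res <- lapply(names(amps), function(a) {
      df <- amps[[a]]
      if (nrow(df) == 0) return(NULL)
      rsv <- infer_rsvs(concat_pairs(df$seq1, df$seq2),
                        d_max = d_max, skew = skew, min_count = min_count)
      if (nrow(rsv) == 0) return(NULL)
      cbind(amplicon = a, rsv, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  names(per_rep) <- rep_ids
  keys <- unique(do.call(rbind, lapply(per_rep, function(x)
    if (is.null(x)) NULL else x[, c("amplicon", "sequence")])))
  if (is.null(keys) || nrow(keys) == 0) {
    return(structure(list(rsv = data.frame(rsv_id = character(0),
                                           amplicon = character(0),
                                           sequence = character(0)),
                          counts = matrix(0L, 0, length(rep_ids),
                                          dimnames = list(NULL, rep_ids))),
                     class = "rsv_table"))
  }
  keys <- keys[order(keys$amplicon, keys$sequence), ]
  key_id <- paste(keys$amplicon, keys$sequence)
  counts <- matrix(0L, nrow(keys), length(rep_ids),
                   dimnames = list(NULL, rep_ids))
  for (r in seq_along(rep_ids)) {
    x <- per_rep[[r]]
    if (is.null(x)) next
    counts[match(paste(x$amplicon, x$sequence), key_id), r] <- x$count
  }
  rsv <- data.frame(rsv_id = sprintf("RSV%05d", seq_len(nrow(keys))),
                    amplicon = keys$amplicon, sequence = keys$sequence,
                    stringsAsFactors = FALSE)
  rownames(counts) <- rsv$rsv_id
  structure(list(rsv = rsv, counts = counts), class = "rsv_table")
}

#' @export
print.rsv_table <- function(x, ...) {
  cat("RSV table:", nrow(x$rsv), "variants x", ncol(x$counts),
      "replicates/samples,", sum(x$counts), "reads\n")
  invisible(x)
}

# longest common prefix / suffix length from pre-computed integer vectors
.lcp_int <- function(ia, ib) {
  d <- which(ia != ib)
  if (length(d) == 0) length(ia) else d[1] - 1L
}

#' Flag and remove two-parent chimeras (bimeras) de novo
#'
#' Within each sample and amplicon, an RSV is flagged when two distinct
#' parents, each at least `parent_fold` times as abundant in that sample, can
#' reconstruct it exactly as prefix-of-A plus suffix-of-B with a split point
#' k >= 1. An RSV flagged in a majority of the samples where it occurs is
#' removed table-wide; the most abundant RSV of each amplicon is never
#' removed.
#'
#' @param rsv_table an `rsv_table`.
#' @param parent_fold required parent/candidate abundance ratio (default 2).
#' @return list: `table` (filtered `rsv_table`), `flagged` (rsv_ids removed).
#' @export
remove_bimeras <- function(rsv_table, parent_fold = 2) {
  rsv <- rsv_table$rsv; counts <- rsv_table$counts
  if (nrow(rsv) == 0) return(list(table = rsv_table, flagged = character(0)))
  flag_votes <- integer(nrow(rsv)); occur <- integer(nrow(rsv))
  for (a in unique(rsv$amplicon)) {
    ai <- which(rsv$amplicon == a)
    if (length(ai) < 3) { occur[ai] <- occur[ai] + rowSums(counts[ai, , drop = FALSE] > 0); next }
    seqs <- rsv$sequence[ai]
    len <- nchar(seqs[1])
    # pairwise prefix/suffix agreement, computed once per amplicon
    m <- length(ai)
    ints <- lapply(seqs, utf8ToInt)
    rints <- lapply(ints, rev)
    lcp <- matrix(0L, m, m); lcs <- matrix(0L, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j && length(ints[[i]]) == length(ints[[j]])) {
        lcp[i, j] <- .lcp_int(ints[[i]], ints[[j]])
        lcs[i, j] <- .lcp_int(rints[[i]], rints[[j]])
      }
    }
    for (s in seq_len(ncol(counts))) {
      cs <- counts[ai, s]
      pres <- which(cs > 0)
      occur[ai[pres]] <- occur[ai[pres]] + 1L
      for (i in pres) {
        parents <- which(cs >= parent_fold * cs[i])
        parents <- setdiff(parents, i)
        if (length(parents) < 2) next
        found <- FALSE
        for (p1 in parents) {
          if (found) break
          for (p2 in setdiff(parents, p1)) {
            lo <- max(1L, len - lcs[i, p2])
            hi <- min(lcp[i, p1], len - 1L)
            if (lo <= hi) { found <- TRUE; break }
          }
        }
        if (found) flag_votes[ai[i]] <- flag_votes[ai[i]] + 1L
      }
    }
    # the most abundant RSV of the amplicon is never flagged
    top <- ai[which.max(rowSums(counts[ai, , drop = FALSE]))]
    flag_votes[top] <- 0L
  }
  flagged <- which(occur > 0 & flag_votes > occur / 2)
  keep <- setdiff(seq_len(nrow(rsv)), flagged)
  out <- structure(list(rsv = rsv[keep, , drop = FALSE],
                        counts = counts[keep, , drop = FALSE]),
                   class = "rsv_table")
  rownames(out$rsv) <- NULL
  list(table = out, flagged = rsv$rsv_id[flagged])
}
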