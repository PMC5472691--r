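# Quality filtering of read pairs and zero-mismatch primer-pair
# stratification into the sample x amplicon matrix.

#' Expected number of sequencing errors from Phred scores
#'
#' `EE = sum(10^(-Q/10))`; additive over concatenation, 0 for an empty read.
#'
#' @param quals numeric vector of Phred quality scores (>= 0).
#' @return expected error count (single number).
#' @examples
#' expected_errors(rep(20, 10)) # 0.1
#' @export
expected_errors <- function(quals) {
  if (length(quals) == 0) return(0)
  if (any(quals < 0)) .hb_stop("negative Phred score")
  sum(10^(-quals / 10))
}

# ASCII (Phred+33) quality string -> integer scores
qual_to_int <- function(qual) utf8ToInt(qual) - 33L

# vectorized single-mate filter; returns list(seq, qual, reason)
.filter_mate <- function(seq, qual, truncLen, maxN, maxEE, truncQ) {
  n <- length(seq)
  reason <- rep(NA_character_, n)
  # truncate at the first base with Q <= truncQ
  stop_char <- intToUtf8(truncQ + 33L)
  cut <- regexpr(sprintf("[\x21-%s]", stop_char), qual)
  has_cut <- cut > 0
  len <- ifelse(has_cut, cut - 1L, nchar(seq))
  reason[len < truncLen] <- "too_short"
  seq <- substr(seq, 1L, pmin(len, truncLen))
  qual <- substr(qual, 1L, pmin(len, truncLen))
  ncount <- nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))
  reason[is.na(reason) & ncount > maxN] <- "maxN"
  todo <- which(is.na(reason))
  if (length(todo)) {
    ee <- vapply(qual[todo], function(q) expected_errors(qual_to_int(q)), 0,
                 USE.NAMES = FALSE)
    reason[todo[ee > maxEE]] <- "maxEE"
  }
  list(seq = seq, qual = qual, reason = reason)
}

#' Quality-filter a single read pair
#'
#' Each mate is truncated at the first base with quality `<= truncQ`, then cut
#' to `truncLen`; the pair is rejected when either mate is shorter than
#' `truncLen` after truncation, still contains an uncalled base (`maxN = 0`),
#' or has more than `maxEE` expected errors. Rejection is a tagged result, not
#' an error, and filtering a kept pair again returns it unchanged.
#'
#' @param pair list or one-row data.frame with `seq1`, `qual1`, `seq2`,
#'   `qual2` (qualities as Phred+33 strings).
#' @param truncLen,maxN,maxEE,truncQ filter parameters (length-2 values are
#'   recycled per mate where applicable).
#' @return list with `kept` (logical), `pair` (trimmed, when kept) and
#'   `reason` (when rejected, one of "too_short", "maxN", "maxEE").
#' @export
quality_filter <- function(pair, truncLen = c(170, 170), maxN = 0,
                           maxEE = c(2, 2), truncQ = 2) {
  truncLen <- rep_len(truncLen, 2); maxEE <- rep_len(maxEE, 2)
  m1 <- .filter_mate(pair$seq1, pair$qual1, truncLen[1], maxN, maxEE[1], truncQ)
  m2 <- .filter_mate(pair$seq2, pair$qual2, truncLen[2], maxN, maxEE[2], truncQ)
  reason <- ifelse(is.na(m1$reason), m2$reason, m1$reason)
  if (!is.na(reason[1])) return(list(kept = FALSE, reason = reason[1]))
  list(kept = TRUE,
       pair = list(id = pair$id, seq1 = m1$seq, qual1 = m1$qual,
                   seq2 = m2$seq, qual2 = m2$qual))
}

#' Quality-filter a table of read pairs
#'
#' Vectorized version of [quality_filter()] for a whole replicate.
#'
#' @param pairs data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @inheritParams quality_filter
#' @return list with `kept` (trimmed data.frame) and `rejected` (data.frame
#'   id, reason).
#' @export
filter_pairs <- function(pairs, truncLen = c(170, 170), maxN = 0,
                         maxEE = c(2, 2), truncQ = 2) {
  truncLen <- rep_len(truncLen, 2); maxEE <- rep_len(maxEE, 2)
  if (nrow(pairs) == 0) {
    return(list(kept = pairs, rejected = data.frame(id = character(0),
                                                    reason = character(0))))
  }
  m1 <- .filter_mate(pairs$seq1, pairs$qual1, truncLen[1], maxN, maxEE[1],
                     truncQ)
  m2 <- .filter_mate(pairs$seq2, pairs$qual2, truncLen[2], maxN, maxEE[2],
                     truncQ)
  reason <- ifelse(is.na(m1$reason), m2$reason, m1$reason)
  keep <- is.na(reason)
  kept <- data.frame(id = pairs$id[keep], seq1 = m1$seq[keep],
                     qual1 = m1$qual[keep], seq2 = m2$seq[keep],
                     qual2 = m2$qual[keep], stringsAsFactors = FALSE)
  list(kept = kept,
       rejected = data.frame(id = pairs$id[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

# IUPAC primer -> anchored regex over ACGT (N in a read never matches:
# character classes never include N)
iupac_regex <- function(primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(primer), "")[[1]]
  if (!all(chars %in% names(map))) {
    .hb_stop("primer contains non-IUPAC character: ", primer)
  }
  paste0("^", paste(vapply(chars, function(ch) {
    bases <- strsplit(map[[ch]], "")[[1]]
    bases <- setdiff(bases, "N")
    if (length(bases) == 1) bases else
      paste0("[", paste(bases, collapse = ""), "]")
  }, ""), collapse = ""))
}

# canonical per-position expansion used to detect duplicate primer pairs
.iupac_canonical <- function(primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(chars, function(ch)
    paste(sort(strsplit(map[[ch]], "")[[1]]), collapse = ""), ""),
    collapse = "|")
}

#' Sort read pairs into amplicons by exact primer-pair match
#'
#' A pair is assigned to an amplicon when the forward primer matches read 1
#' starting at base 1 with zero mismatches (IUPAC degeneracy in the primer
#' counts as a match; an N in the read never matches) and the reverse primer
#' likewise matches read 2. Primers are trimmed from sequence and quality on
#' assignment. A pair matching several panel entries is assigned to the entry
#' with the longest combined primer length; exact ties are left unassigned
#' with a warning. Reads shorter than the primer are unassigned.
#'
#' @param pairs data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param panel data.frame with `amplicon_id`, `fwd_primer`, `rev_primer`.
#' @return list with `assignment` (per input pair: id, amplicon or NA),
#'   `by_amplicon` (named list of trimmed pair data.frames), `unassigned`
#'   (count).
#' @export
stratify_by_primer <- function(pairs, panel) {
  keys <- paste(vapply(panel$fwd_primer, .iupac_canonical, ""),
                vapply(panel$rev_primer, .iupac_canonical, ""))
  if (anyDuplicated(keys)) {
    .hb_stop("panel entries with identical primer pairs under IUPAC expansion: ",
             paste(panel$amplicon_id[duplicated(keys) |
                                       duplicated(keys, fromLast = TRUE)],
                   collapse = ", "))
  }
  n <- nrow(pairs)
  amp <- rep(NA_character_, n)
  if (n > 0) {
    plen <- nchar(panel$fwd_primer) + nchar(panel$rev_primer)
    hit <- matrix(FALSE, n, nrow(panel))
    for (a in seq_len(nrow(panel))) {
      hit[, a] <- grepl(iupac_regex(panel$fwd_primer[a]), pairs$seq1) &
        grepl(iupac_regex(panel$rev_primer[a]), pairs$seq2)
    }
    nhit <- rowSums(hit)
    one <- nhit == 1
    amp[one] <- panel$amplicon_id[max.col(hit[one, , drop = FALSE])]
    multi <- which(nhit > 1)
    tied <- 0L
    for (i in multi) {
      cand <- which(hit[i, ])
      best <- cand[plen[cand] == max(plen[cand])]
      if (length(best) == 1) amp[i] <- panel$amplicon_id[best]
      else tied <- tied + 1L
    }
    if (tied > 0) {
      warning(tied, " read pair(s) matched multiple panel entries with equal ",
              "combined primer length; left unassigned")
    }
  }
  by_amp <- list()
  for (a in seq_len(nrow(panel))) {
    idx <- which(!is.na(amp) & amp == panel$amplicon_id[a])
    f <- nchar(panel$fwd_primer[a]); r <- nchar(panel$rev_primer[a])
    by_amp[[panel$amplicon_id[a]]] <- data.frame(
      id = pairs$id[idx],
      seq1 = substring(pairs$seq1[idx], f + 1L),
      qual1 = substring(pairs$qual1[idx], f + 1L),
      seq2 = substring(pairs$seq2[idx], r + 1L),
      qual2 = substring(pairs$qual2[idx], r + 1L),
      stringsAsFactors = FALSE)
  }
  list(assignment = data.frame(id = pairs$id, amplicon = amp,
                               stringsAsFactors = FALSE),
       by_amplicon = by_amp,
       unassigned = sum(is.na(amp)))
}
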