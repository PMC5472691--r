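test_that("expected errors follow the Phred closed form and are additive", {
  expect_equal(expected_errors(rep(20, 10)), 0.1)
  expect_equal(expected_errors(numeric(0)), 0)
  expect_equal(expected_errors(2), 10^(-0.2), tolerance = 1e-10)
  q1 <- c(30, 20, 10); q2 <- c(15, 25)
  expect_equal(expected_errors(c(q1, q2)),
               expected_errors(q1) + expected_errors(q2))
  expect_error(expected_errors(-1), "negative")
})

test_that("quality filter truncates, screens and is idempotent", {
  p <- mk_pair(rand_seq(200, 1), rand_seq(200, 2), q1 = 30, q2 = 30)
  r <- quality_filter(p)
  expect_true(r$kept)
  expect_equal(nchar(r$pair$seq1), 170)
  expect_equal(nchar(r$pair$seq2), 170)
  again <- quality_filter(r$pair)
  expect_true(again$kept)
  expect_identical(again$pair[c("seq1", "qual1", "seq2", "qual2")],
                   r$pair[c("seq1", "qual1", "seq2", "qual2")])

  # an N inside the first 170 bases is fatal (maxN = 0)
  pn <- p
  substr(pn$seq1, 50, 50) <- "N"
  rn <- quality_filter(pn)
  expect_false(rn$kept)
  expect_equal(rn$reason, "maxN")

  # a 160-base clean mate cannot satisfy truncLen 170
  ps <- mk_pair(rand_seq(160, 3), rand_seq(200, 4))
  rs <- quality_filter(ps)
  expect_false(rs$kept)
  expect_equal(rs$reason, "too_short")

  # a Q<=2 base before position 170 truncates and then fails truncLen
  pq <- p
  substr(pq$qual2, 100, 100) <- "#"
  rq <- quality_filter(pq)
  expect_false(rq$kept)
  expect_equal(rq$reason, "too_short")

  # low-quality mate fails the expected-error bound
  pe <- mk_pair(rand_seq(200, 5), rand_seq(200, 6), q1 = 38, q2 = 12)
  re <- quality_filter(pe)
  expect_false(re$kept)
  expect_equal(re$reason, "maxEE")
})

test_that("vectorized filtering conserves pairs", {
  set.seed(10)
  pairs <- do.call(rbind, lapply(1:30, function(i) {
    mk_pair(rand_seq(200), rand_seq(200), q1 = sample(c(12, 38), 1),
            id = paste0("r", i))
  }))
  res <- filter_pairs(pairs)
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(pairs))
})

test_that("primer stratification demands exact anchored matches", {
  panel <- data.frame(amplicon_id = c("X1", "X2"),
                      fwd_primer = c("ACGTACGTAC", "GGTTGGTTGG"),
                      rev_primer = c("TTGGCCAATT", "CCAATTGGCC"),
                      target = "16S", stringsAsFactors = FALSE)
  tmpl1 <- rand_seq(160, 20); tmpl2 <- rand_seq(160, 21)
  good <- mk_pair(paste0("ACGTACGTAC", tmpl1), paste0("TTGGCCAATT", tmpl2))
  st <- stratify_by_primer(good, panel)
  expect_equal(st$assignment$amplicon, "X1")
  expect_equal(st$by_amplicon$X1$seq1, tmpl1)
  expect_equal(st$by_amplicon$X1$seq2, tmpl2)
  expect_equal(nchar(st$by_amplicon$X1$qual1), nchar(tmpl1))

  # one substitution inside the forward primer
  bad <- good
  substr(bad$seq1, 3, 3) <- "T"  # ACGT -> ACTT...
  expect_equal(stratify_by_primer(bad, panel)$unassigned, 1)

  # primer present but starting at base 2
  off <- mk_pair(paste0("AACGTACGTAC", tmpl1), paste0("TTGGCCAATT", tmpl2))
  expect_equal(stratify_by_primer(off, panel)$unassigned, 1)

  # a read shorter than the primer is unassigned, not an error
  short <- mk_pair("ACGT", "TTGG")
  expect_equal(stratify_by_primer(short, panel)$unassigned, 1)
})

test_that("IUPAC degeneracy matches in primers but N in reads never does", {
  panel <- data.frame(amplicon_id = "D1", fwd_primer = "ACGRACGTAC",
                      rev_primer = "TTGGCCAATT", target = "16S",
                      stringsAsFactors = FALSE)
  tmpl <- rand_seq(160, 22)
  pA <- mk_pair(paste0("ACGAACGTAC", tmpl), paste0("TTGGCCAATT", tmpl))
  pG <- mk_pair(paste0("ACGGACGTAC", tmpl), paste0("TTGGCCAATT", tmpl))
  pN <- mk_pair(paste0("ACGNACGTAC", tmpl), paste0("TTGGCCAATT", tmpl))
  expect_equal(stratify_by_primer(pA, panel)$assignment$amplicon, "D1")
  expect_equal(stratify_by_primer(pG, panel)$assignment$amplicon, "D1")
  expect_true(is.na(stratify_by_primer(pN, panel)$assignment$amplicon))

  dup <- data.frame(amplicon_id = c("E1", "E2"),
                    fwd_primer = c("ACGRACGTAC", "ACGRACGTAC"),
                    rev_primer = c("TTGGCCAATT", "TTGGCCAATT"),
                    target = "16S", stringsAsFactors = FALSE)
  expect_error(stratify_by_primer(pA, dup), "identical")
})

test_that("multi-matching pairs go to the longest primer pair, ties unassigned", {
  panel <- data.frame(amplicon_id = c("L1", "L2"),
                      fwd_primer = c("ACGTACGT", "ACGTACGTAC"),
                      rev_primer = c("TTGGCCAA", "TTGGCCAATT"),
                      target = "16S", stringsAsFactors = FALSE)
  tmpl <- rand_seq(160, 23)
  p <- mk_pair(paste0("ACGTACGTAC", tmpl), paste0("TTGGCCAATT", tmpl))
  st <- stratify_by_primer(p, panel)
  expect_equal(st$assignment$amplicon, "L2")
  tie <- data.frame(amplicon_id = c("T1", "T2"),
                    fwd_primer = c("ACGTACGTAC", "ACGTACGTAY"),
                    rev_primer = c("TTGGCCAATT", "TTGGCCAATT"),
                    target = "16S", stringsAsFactors = FALSE)
  pc <- mk_pair(paste0("ACGTACGTAC", tmpl), paste0("TTGGCCAATT", tmpl))
  expect_warning(sttie <- stratify_by_primer(pc, tie), "unassigned")
  expect_equal(sttie$unassigned, 1)
})

test_that("stratification conserves pairs and recovers generator labels at e = 0", {
  w <- noise_free_world()
  for (rep_id in names(w$reads$reads)[1:3]) {
    kept <- filter_pairs(w$reads$reads[[rep_id]])$kept
    st <- stratify_by_primer(kept, w$panel)
    assigned <- sum(vapply(st$by_amplicon, nrow, 0L))
    expect_equal(assigned + st$unassigned, nrow(kept))
    tt <- w$reads$truth[w$reads$truth$replicate == rep_id, ]
    m <- merge(st$assignment, tt[, c("id", "amplicon")], by = "id")
    expect_equal(sum(m$amplicon.x != m$amplicon.y, na.rm = TRUE), 0)
    expect_equal(sum(is.na(m$amplicon.x)), 0)
  }
})
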