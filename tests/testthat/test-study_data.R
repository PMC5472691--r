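test_that("standardized ranks spread evenly in [-1, 1] with median zero", {
  expect_equal(unname(standardize_ranks(c("a", "b", "c"))), c(1, 0, -1))
  expect_equal(unname(standardize_ranks(letters[1:5])),
               c(1, 0.5, 0, -0.5, -1))
  expect_equal(unname(standardize_ranks(letters[1:4])),
               c(1, 1 / 3, -1 / 3, -1))
  expect_equal(unname(standardize_ranks("solo")), 0)
  expect_error(standardize_ranks(c("a", "a")), "duplicate")
  # symmetry about zero for a range of hierarchy sizes
  for (n in c(2, 3, 7, 10, 21)) {
    r <- unname(standardize_ranks(paste0("h", seq_len(n))))
    expect_equal(r, -rev(r))
    expect_true(all(abs(r) <= 1))
  }
})

test_that("age and rank classification respects the 24-month and zero-rank boundaries", {
  cls <- classify_host(c(23.9, 24, 0, 100), c(0, -0.2, NA, 1))
  expect_equal(as.character(cls$age_class),
               c("juvenile", "adult", "juvenile", "adult"))
  expect_equal(as.character(cls$rank_class), c("high", "low", NA, "high"))
  expect_error(classify_host(-1), "negative")
  expect_error(classify_host(10, 1.5), "std_rank")
})

test_that("synthetic truth is deterministic and encodes the cohort design", {
  t1 <- generate_truth(6, 3, seed = 42)
  t2 <- generate_truth(6, 3, seed = 42)
  expect_identical(t1, t2)
  m <- t1$metadata
  expect_equal(sum(m$age_class == "adult"), 6)
  expect_equal(sum(m$age_class == "juvenile"), 3)
  # juveniles carry no rank; adult ranks cover [-1, 1] symmetrically
  expect_true(all(is.na(m$std_rank[m$age_class == "juvenile"])))
  expect_equal(sort(m$std_rank[m$age_class == "adult"]),
               unname(sort(standardize_ranks(paste0("x", 1:6)))))
  expect_true(all(t1$abundance >= 0))
  expect_error(generate_truth(4, 2, params = truth_params(
    base_richness_16s = 5, age_effect_16s = -10), seed = 1),
    "richness")
})

test_that("adult samples draw richer bacterial communities under an age effect", {
  pw <- truth_params(base_richness_16s = 8, age_effect_16s = 10)
  ok <- vapply(1:200, function(i) {
    tr <- generate_truth(20, 20, params = pw, seed = i)
    rich <- colSums(tr$abundance[tr$lineages$domain == "16S", ] > 0)
    adult <- tr$metadata$age_class == "adult"
    mean(rich[adult]) > mean(rich[!adult])
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("null effect sizes give equal expected richness between groups", {
  p0 <- truth_params(age_effect_16s = 0, rank_effect_18s = 0)
  rich <- vapply(1:60, function(i) {
    tr <- generate_truth(10, 10, params = p0, seed = 300 + i)
    r <- colSums(tr$abundance[tr$lineages$domain == "16S", ] > 0)
    adult <- tr$metadata$age_class == "adult"
    mean(r[adult]) - mean(r[!adult])
  }, 0)
  expect_lt(abs(mean(rich)), 3 * stats::sd(rich) / sqrt(length(rich)) + 0.5)
})

test_that("reference databases separate genera at the k-mer level", {
  lin <- default_lineages()[1:10, ]
  db <- generate_reference_db(lin, seed = 3, n_per_genus = 1)
  db2 <- generate_reference_db(lin, seed = 3, n_per_genus = 1)
  expect_identical(db, db2)
  seqs <- db$sequences
  for (i in seq_along(seqs)) for (j in seq_len(i - 1)) {
    expect_lt(hyenabiome:::shared_kmer_frac(seqs[i], seqs[j]), 0.05)
  }
  expect_error(generate_reference_db(default_lineages()[0, ]), "empty")
  expect_error(generate_reference_db(default_lineages()[1, ]), ">= 2")
})

test_that("read generation conserves depth and honours the no-noise contract", {
  w <- noise_free_world()
  reads <- w$reads
  ordinary <- reads$replicates$replicate[!reads$replicates$is_water &
                                           !reads$replicates$failed]
  for (rep_id in ordinary) {
    expect_equal(nrow(reads$reads[[rep_id]]), 400)
  }
  # with e = 0, every read is its template with the primer prepended
  tt <- reads$truth[!reads$truth$chimera, ]
  rep1 <- ordinary[1]
  df <- reads$reads[[rep1]]
  t1 <- subset(tt, replicate == rep1)
  idx <- match(t1$id, df$id)
  for (k in head(seq_along(idx), 50)) {
    a <- match(t1$amplicon[k], w$panel$amplicon_id)
    fp <- nchar(w$panel$fwd_primer[a])
    ins <- unname(w$refdb$sequences[w$refdb$master[t1$genus[k]]])
    expect_equal(substr(df$seq1[idx[k]], fp + 1, nchar(df$seq1[idx[k]])),
                 substr(ins, 1, nchar(df$seq1[idx[k]]) - fp))
  }
  expect_error(generate_reads(w$truth, w$panel, w$refdb,
                              error = read_error_params(depth = 0),
                              seed = 1),
               "depth")
})

test_that("chimera labelling matches the configured rate", {
  w <- noise_free_world()
  err <- read_error_params(e = 0, c = 0.05, n_rate = 0, bad_q_frac = 0,
                           trunc_q_frac = 0, depth = 2000, fail_rate = 0)
  r <- generate_reads(w$truth, generate_panel(1, 2, seed = 6), w$refdb,
                      error = err, tech_reps = 1, n_water = 0, seed = 9)
  n <- nrow(r$truth)
  frac <- mean(r$truth$chimera)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("coprology generator honours the stated coupling", {
  tr <- generate_truth(50, 30, params = truth_params(abund_meanlog = 5,
                                                     abund_sdlog = 1.5),
                       seed = 13)
  # b = 0 decouples egg counts from abundance
  coup0 <- data.frame(morphotype = "Ancylostoma", taxa = "Ancylostoma",
                      size_classes = "all", class_props = "1",
                      a = 2, b = 0, dispersion = 0.2)
  x <- tr$abundance["Ancylostoma", ]
  cors <- vapply(1:20, function(s) {
    cop0 <- generate_coprology(tr, coup0, seed = 14 + s)
    fec0 <- combine_size_classes(cop0, "Ancylostoma")
    stats::cor(log10(1 + fec0), log10(1 + x[names(fec0)]))
  }, 0)
  expect_lt(abs(mean(cors)),
            3 * stats::sd(cors) / sqrt(length(cors)) + 0.02)
  # zero abundance with a = 0 gives exactly zero chamber counts
  tr0 <- tr
  tr0$abundance["Ancylostoma", ] <- 0
  coupz <- transform(coup0, a = 0, b = 1)
  copz <- generate_coprology(tr0, coupz, seed = 15)
  expect_true(all(copz[, c("c1", "c2", "c3", "c4", "epg")] == 0))
  expect_error(generate_coprology(tr, transform(coup0, dispersion = -1)),
               "dispersion")
})
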