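ref_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lin <- default_lineages()
    lin <- lin[lin$genus %in% c("Clostridium", "Bacteroides", "Ancylostoma",
                                "Diphyllobothrium", "Eimeria", "Aspergillus"), ]
    cache <<- generate_reference_db(lin, seed = 17, n_per_genus = 2)
    cache
  }
})

test_that("training references self-classify with full confidence", {
  db <- ref_fixture()
  model <- train_classifier(db$sequences, db$taxa)
  for (i in seq_along(db$sequences)) {
    cl <- classify(db$sequences[i], model, seed = 3)
    expect_equal(unname(cl$lineage["genus"]),
                 db$taxa$genus[i])
    expect_equal(unname(cl$bootstrap), rep(1, 5))
  }
})

test_that("word probabilities use database-frequency smoothing", {
  db <- ref_fixture()
  model <- train_classifier(db$sequences, db$taxa)
  n_refs <- model$n_refs
  m_g <- table(db$taxa$genus)
  expect_equal(unname(model$log_unseen[names(m_g)]),
               log((0.5 / (n_refs + 1)) / (as.integer(m_g) + 1)))
  # duplicated references leave the model unchanged
  dup_seqs <- c(db$sequences, db$sequences[1])
  dup_taxa <- rbind(db$taxa, db$taxa[1, ])
  m2 <- train_classifier(dup_seqs, dup_taxa)
  expect_equal(m2$logp, model$logp)
  expect_equal(m2$words, model$words)
})

test_that("queries without database support come back UNDEFINED", {
  db <- ref_fixture()
  model <- train_classifier(db$sequences, db$taxa)
  alien <- strrep("AT", 150)  # shares essentially no 8-mers with the refs
  cl <- classify(alien, model, seed = 5)
  expect_true(all(cl$lineage == "UNDEFINED"))
  expect_error(classify("ACGT", model), "no valid word")
})

test_that("an even two-phylum hybrid cannot win genus-level confidence", {
  db <- ref_fixture()
  model <- train_classifier(db$sequences, db$taxa)
  a <- db$sequences[db$taxa$genus == "Clostridium"][1]
  b <- db$sequences[db$taxa$genus == "Ancylostoma"][1]
  hybrid <- paste0(substr(a, 1, 200), substr(b, 201, 400))
  cl <- classify(hybrid, model, seed = 7)
  expect_lt(cl$bootstrap["genus"], 1)
  # the winner is one of the two parents, and deeper levels are less
  # confident than the phylum level
  expect_true(cl$genus_raw %in% c("Clostridium", "Ancylostoma"))
  expect_true(all(diff(cl$bootstrap) <= 1e-12))
})

test_that("classifier agrees with the reference naive-Bayes implementation", {
  skip_if_not_installed("dada2")
  db <- ref_fixture()
  model <- train_classifier(db$sequences, db$taxa)
  fa <- tempfile(fileext = ".fasta")
  lineages <- apply(db$taxa[, c("phylum", "class", "order", "family",
                                "genus")], 1, paste, collapse = ";")
  writeLines(paste0(">", lineages, ";\n", db$sequences), fa)
  set.seed(31)
  queries <- vapply(db$sequences[seq(1, 11, 2)], function(s) {
    pos <- sample(nchar(s), 4)
    for (p in pos) substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    s
  }, "")
  ours <- vapply(queries, function(q)
    classify(q, model, seed = 11)$genus_raw, "")
  theirs <- dada2::assignTaxonomy(
    unname(queries), fa, minBoot = 0,
    taxLevels = c("phylum", "class", "order", "family", "genus"))
  expect_equal(unname(ours), unname(theirs[, "genus"]))
})

test_that("genus agglomeration merges amplicons and applies the exclusion rules", {
  rsv <- data.frame(rsv_id = paste0("r", 1:5),
                    amplicon = c("A01", "A02", "A01", "A01", "A02"),
                    sequence = paste0(c("A", "C", "G", "T", "AA")),
                    stringsAsFactors = FALSE)
  counts <- matrix(c(3, 4, 10, 6, 2,
                     1, 2, 5, 3, 1), 5, 2,
                   dimnames = list(rsv$rsv_id, c("S1", "S2")))
  tab <- structure(list(rsv = rsv, counts = counts), class = "rsv_table")
  asg <- data.frame(
    rsv_id = rsv$rsv_id,
    phylum = c("Firmicutes", "Firmicutes", "Firmicutes", "Nematoda",
               "UNDEFINED"),
    class = "x", order = "x", family = "x",
    genus = c("Clostridium", "Clostridium", "Blautia", "Ancylostoma",
              "UNDEFINED"),
    stringsAsFactors = FALSE)
  panel <- data.frame(amplicon_id = c("A01", "A02"),
                      target = c("16S", "16S"))
  gt <- suppressMessages(agglomerate_genus(tab, asg, panel))
  # r1 + r2 merged across amplicons
  expect_equal(unname(gt$counts["Clostridium", ]), c(7, 3))
  # Ancylostoma is the only genus of its phylum here: excluded
  expect_false("Ancylostoma" %in% gt$taxa$genus)
  # UNDEFINED genus excluded
  expect_false("UNDEFINED" %in% gt$taxa$genus)
  expect_setequal(gt$taxa$genus, c("Clostridium", "Blautia"))
  # conservation over retained RSVs (r1, r2, r3)
  expect_equal(sum(gt$counts), sum(counts[1:3, ]))
  expect_error(suppressMessages(agglomerate_genus(tab, asg[-1, ], panel)),
               "missing")
  # uninformative genus names count as missing
  asg2 <- asg
  asg2$genus[3] <- "uncultured bacterium"
  gt2 <- suppressMessages(agglomerate_genus(tab, asg2, panel))
  expect_false(any(grepl("uncultured", gt2$taxa$genus)))
})

test_that("phylum accounting adds up within and across domains", {
  df <- data.frame(
    genus = paste0("g", 1:7),
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes", "UNDEFINED",
               "Nematoda", "Nematoda", "Ascomycota"),
    domain = c("16S", "16S", "16S", "16S", "18S", "18S", "18S"),
    n_rsvs = c(5, 3, 2, 4, 7, 1, 2),
    reads = c(100, 50, 30, 20, 500, 10, 40),
    stringsAsFactors = FALSE)
  s <- summarize_phyla(df, role_map = default_role_map())
  per <- s$per_phylum
  expect_equal(per$role[per$phylum == "Nematoda"], "eukaryome_parasite")
  tot <- s$domain_totals
  t16 <- tot[tot$domain == "16S", ]
  expect_equal(t16$n_genera, 3)       # named phyla only
  expect_equal(t16$n_genera_full, 4)  # including UNDEFINED
  # named + UNDEFINED = full, per domain
  undef <- per[per$phylum == "UNDEFINED" & per$domain == "16S", ]
  expect_equal(t16$n_genera + undef$n_genera, t16$n_genera_full)
  expect_equal(t16$reads + undef$reads, t16$reads_full)
  # unmapped phylum warns and is undetermined
  expect_warning(s2 <- summarize_phyla(transform(df, phylum = sub(
    "Ascomycota", "Mystery", phylum))), "Mystery")
  expect_equal(s2$per_phylum$role[s2$per_phylum$phylum == "Mystery"],
               "undetermined")
  empty <- summarize_phyla(df[0, ])
  expect_equal(nrow(empty$per_phylum), 0)
})
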