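test_that("McMaster conversion is the 25x multiplier and linear", {
  expect_equal(fec_from_chambers(c(0, 0, 0, 0)), 0)
  expect_equal(fec_from_chambers(c(1, 0, 0, 0)), 25)
  expect_equal(fec_from_chambers(c(2, 3, 1, 2)), 200)
  for (i in 1:5) {
    cc <- sample(0:9, 4, replace = TRUE)
    expect_equal(fec_from_chambers(2 * cc), 2 * fec_from_chambers(cc))
  }
  expect_error(fec_from_chambers(c(-1, 0, 0, 0)), "non-negative")
  expect_error(fec_from_chambers(c(0.5, 0, 0, 0)), "integer")
})

test_that("size classes combine additively per sample", {
  tab <- data.frame(sample = c("s1", "s1", "s2"),
                    morphotype = "Ancylostoma",
                    size_class = c("<80um", ">=80um", "<80um"),
                    epg = c(50, 25, 0))
  tot <- combine_size_classes(tab, "Ancylostoma")
  expect_equal(unname(tot[c("s1", "s2")]), c(75, 0))
  expect_error(combine_size_classes(tab, "Coccidia"), "unknown")
})

test_that("prevalence and intensity summaries follow the positive-sample convention", {
  tab <- data.frame(sample = paste0("s", 1:32), morphotype = "M",
                    size_class = "all",
                    epg = c(rep(0, 6), seq(25, 25 * 26, by = 25)))
  s <- summarize_parasites(tab, n_samples = 32)
  expect_equal(s$prevalence, 81.2)  # 26/32, round half to even
  expect_equal(s$n_positive, 26L)
  expect_equal(s$mean, mean(tab$epg[tab$epg > 0]))
  expect_true(s$mean_ci_low >= 0)
  # zero positives: prevalence 0, intensities NA
  z <- summarize_parasites(transform(tab, epg = 0), 32)
  expect_equal(z$prevalence, 0)
  expect_true(is.na(z$mean))
  # a single positive reports the value with NA intervals
  one <- transform(tab, epg = c(50, rep(0, 31)))
  so <- summarize_parasites(one, 32)
  expect_equal(so$mean, 50)
  expect_equal(so$median, 50)
  expect_true(is.na(so$mean_ci_low) && is.na(so$median_ci_low))
  expect_error(summarize_parasites(tab, 0), "n_samples")
})

test_that("spearman matches ranks, endpoints and the t approximation", {
  expect_equal(spearman(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman(1:8, -(1:8))$rho, -1)
  s <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, 0.8)
  # cross-check against the standard implementation (t approximation)
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30)
  ours <- spearman(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate))
  tstat <- ours$rho * sqrt(28 / (1 - ours$rho^2))
  expect_equal(ours$p, 2 * stats::pt(abs(tstat), 28, lower.tail = FALSE))
  expect_true(is.na(spearman(rep(1, 5), 1:5)$rho))
  expect_error(spearman(1:2, 1:2), "n >= 3")
})

test_that("taxon-node tables sum the hierarchy and declared sets", {
  lin <- default_lineages()
  gt <- structure(list(
    taxa = data.frame(genus = c("Ancylostoma", "Haemonchus", "Eimeria"),
                      phylum = c("Nematoda", "Nematoda", "Apicomplexa"),
                      domain = "18S", stringsAsFactors = FALSE),
    counts = matrix(c(10, 5, 2, 0, 7, 3), 3, 2,
                    dimnames = list(c("Ancylostoma", "Haemonchus", "Eimeria"),
                                    c("s1", "s2")))),
    class = "genus_table")
  nodes <- build_taxon_nodes(gt, lin,
                             taxon_sets = list(pair = c("Ancylostoma",
                                                        "Haemonchus")))
  expect_equal(unname(nodes["order:Rhabditida", ]), c(15, 7))
  expect_equal(unname(nodes["set:pair", ]),
               unname(nodes["genus:Ancylostoma", ] +
                        nodes["genus:Haemonchus", ]))
  expect_equal(unname(nodes["phylum:Apicomplexa", ]), c(2, 3))
})

test_that("constant coprology vectors are excluded from the screen ranking", {
  tr <- generate_truth(10, 5, seed = 31)
  gt <- structure(list(
    taxa = data.frame(genus = rownames(tr$abundance),
                      phylum = tr$lineages$phylum,
                      domain = tr$lineages$domain, stringsAsFactors = FALSE),
    counts = tr$abundance), class = "genus_table")
  nodes <- build_taxon_nodes(gt, tr$lineages)
  cop <- data.frame(sample = colnames(tr$abundance), morphotype = "Flat",
                    size_class = "all", epg = 0)
  expect_error(screen <- correlation_screen(cop, log10p(nodes),
                                            tr$lineages), NA)
  expect_equal(nrow(screen), 0)
})

test_that("log-log models recover exact relations and degenerate inputs", {
  x <- c(10, 100, 1000, 10000)
  y <- 10^(0.5 + 0.9 * log10(1 + x)) - 1
  m <- fit_loglog(y, x)
  expect_equal(m$slope, 0.9, tolerance = 1e-10)
  expect_equal(m$intercept, 0.5, tolerance = 1e-10)
  expect_equal(m$r_squared, 1)
  z <- fit_loglog(rep(0, 4), x)
  expect_equal(z$slope, 0)
  expect_equal(z$r_squared, 0)
  expect_error(fit_loglog(y, rep(5, 4)), "zero variance")
})
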