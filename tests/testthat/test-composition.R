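test_that("Bray-Curtis matches its formula and dissimilarity axioms", {
  m <- rbind(a = c(1, 1), b = c(1, 3), c = c(2, 0), d = c(0, 2))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 2 / 6)
  expect_equal(d["c", "d"], 1)
  expect_equal(d["a", "a"], 0)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # manual-formula oracle on random matrices
  set.seed(5)
  x <- matrix(stats::rpois(30, 4), 5, 6)
  dx <- bray_curtis(x)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(dx[i, j],
                 sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ]))
  }
  z <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  dz <- bray_curtis(z)
  expect_true(is.na(dz["a", "b"]))
  expect_false(is.na(dz["a", "c"]))
})

test_that("NMDS embeds embeddable configurations at near-zero stress", {
  pts <- cbind(seq(0, 10, length.out = 8), 0)
  d <- as.matrix(dist(pts))
  fit <- nmds(d, k = 2, n_restarts = 5, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_lte(fit$stress, min(fit$restart_stress))
  # n = 3 in k = 2 is always embeddable
  d3 <- as.matrix(dist(matrix(rnorm(9), 3, 3)))
  expect_lt(nmds(d3, k = 2, n_restarts = 3, seed = 2)$stress, 1e-3)
  expect_error(nmds(d3, k = 3), "smaller")
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(nmds(dna), "NA")
})

separable_fixture <- function(seed = 7, n = 30, p = 50, delta = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "a", 1:3] <- X[y == "a", 1:3] + delta
  list(X = X, y = y)
}

test_that("PLS-DA separates the seeded clusters and ranks their features first", {
  d <- separable_fixture()
  fit <- pls_da(d$X, d$y)
  expect_equal(fit$accuracy, 1)
  expect_setequal(order(-abs(fit$loadings[, 1]))[1:3], 1:3)
  expect_equal(dim(fit$scores), c(30, fit$A))
  expect_equal(dim(fit$loadings), c(50, fit$A))
  expect_true(all(fit$cv_accuracy >= 0 & fit$cv_accuracy <= 1))
  expect_error(pls_da(d$X, rep("a", 30)), "two classes")
  expect_error(pls_da(matrix(1, 10, 3), rep(c("a", "b"), 5)), "constant")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(1, 1, 1, 1)$p, 1)
  expect_equal(fisher_exact(1, 1, 1, 1)$odds_ratio, 1)
  expect_equal(fisher_exact(2, 0, 0, 2)$p, 2 / 6)
  f <- fisher_exact(3, 1, 1, 3)
  expect_equal(f$odds_ratio, 9)
  expect_equal(f$p, 34 / 70)
  expect_true(is.infinite(fisher_exact(4, 0, 1, 3)$odds_ratio))
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
  # property: equality with enumeration and with the base implementation
  set.seed(12)
  for (i in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    ours <- fisher_exact(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ours$p, brute_fisher_p(cells[1], cells[2], cells[3],
                                        cells[4]))
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("loading enrichment flags a phylum monopolizing the top quartile", {
  set.seed(3)
  n <- 16
  w <- c(stats::runif(4, 10, 20), stats::runif(12, -1, 1))
  phyla <- c(rep("P", 4), sample(c("Q", "R"), 12, replace = TRUE))
  res <- loading_enrichment(matrix(w), phyla, mode = "top")
  rp <- res[res$phylum == "P", ]
  expect_true(is.infinite(rp$odds_ratio))
  expect_lt(rp$p, 0.05)
  # margins always add to the number of genera
  expect_true(all(rowSums(res[, c("a", "b", "c", "d")]) == n))
  # shuffled labels: median odds ratio near 1
  ors <- vapply(1:200, function(i) {
    set.seed(100 + i)
    r <- loading_enrichment(matrix(w), sample(phyla), mode = "top")
    r$odds_ratio[r$phylum == "P"]
  }, 0)
  expect_lt(abs(log(stats::median(pmax(ors, 1 / 16)))), log(3))
  expect_error(loading_enrichment(matrix(w[1:4]), phyla[1:4]), "8 genera")
  # combined-axes product mode
  L2 <- cbind(w, rev(w))
  res2 <- loading_enrichment(L2, phyla, n_axes_combine = 2, mode = "both")
  expect_true(all(rowSums(res2[, c("a", "b", "c", "d")]) == n))
})
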