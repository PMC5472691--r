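# Richness, Chao1, Shannon/Pielou on rarefied counts, and exact tie-aware
# Mann-Whitney group comparisons.

#' Bias-corrected Chao1 richness estimator
#'
#' `S + f1 (f1 - 1) / (2 (f2 + 1))` with f1 singletons and f2 doubletons;
#' defined (and equal to S) when no singletons occur, which is why the
#' bias-corrected form is the default of the standard community-ecology
#' tools.
#'
#' @param counts integer (rarefied) count vector.
#' @return Chao1 estimate, always >= observed richness.
#' @export
chao1 <- function(counts) {
  if (any(counts != round(counts)) || any(counts < 0)) {
    .hb_stop("chao1 expects non-negative integer (rarefied) counts")
  }
  s <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon entropy and Pielou evenness
#'
#' `H = -sum p_i ln p_i` over taxa with positive counts; `J = H / ln S`,
#' `NA` when fewer than two taxa are present.
#'
#' @param counts non-negative count vector with positive total.
#' @return list `H`, `J`.
#' @export
shannon_pielou <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) .hb_stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  h <- -sum(p * log(p))
  s <- length(p)
  list(H = h, J = if (s >= 2) h / log(s) else NA_real_)
}

# exact permutation distribution of the rank-sum of group 1 over all
# C(n1+n2, n1) reassignments, generalized for ties: DP (shift algorithm) over
# doubled midranks, which are integers
.ranksum_tails <- function(scores2, n1, w2_obs) {
  n <- length(scores2)
  smax <- sum(scores2)
  # f[k+1, t+1] = number of k-subsets with doubled-rank sum t
  f <- matrix(0, n1 + 1, smax + 1)
  f[1, 1] <- 1
  for (s in scores2) {
    kmax <- min(n1, n)
    for (k in seq(min(n1, kmax), 1)) {
      idx <- seq_len(smax + 1 - s)
      f[k + 1, idx + s] <- f[k + 1, idx + s] + f[k, idx]
    }
  }
  dist <- f[n1 + 1, ]
  total <- sum(dist)
  sums <- 0:smax
  lower <- sum(dist[sums <= w2_obs]) / total
  upper <- sum(dist[sums >= w2_obs]) / total
  c(lower = lower, upper = upper)
}

#' Exact Mann-Whitney U test with ties
#'
#' U is computed from tie-averaged ranks; the exact two-sided p-value comes
#' from the permutation distribution of the rank-sum over all
#' `choose(n1+n2, n1)` group reassignments, computed by a shift-algorithm
#' dynamic program over doubled midranks (integers even under ties).
#' Two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x,y numeric group vectors (both non-empty).
#' @return list of class `mw_test`: `U`, `n1`, `n2`, `p`.
#' @export
exact_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) .hb_stop("empty group")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  scores2 <- as.integer(round(2 * r))
  tails <- .ranksum_tails(scores2, n1, round(2 * w))
  p <- min(1, 2 * min(tails))
  structure(list(U = u, n1 = n1, n2 = n2, p = p), class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Exact Mann-Whitney: U = %g, n1 = %d, n2 = %d, p = %.4g\n",
              x$U, x$n1, x$n2, x$p))
  invisible(x)
}

#' Per-sample diversity estimates
#'
#' @param counts taxa x samples matrix of rarefied integer counts.
#' @return data.frame per sample: `richness`, `chao1`, `shannon`, `pielou`.
#' @export
diversity_estimates <- function(counts) {
  res <- lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    sp <- if (sum(x) > 0) shannon_pielou(x) else list(H = NA_real_, J = NA_real_)
    data.frame(sample = colnames(counts)[j], richness = sum(x > 0),
               chao1 = chao1(x), shannon = sp$H, pielou = sp$J,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare diversity between host categories
#'
#' Exact Mann-Whitney tests of richness, Chao1 and Pielou evenness between
#' juveniles and adults (factor "age") or high- and low-ranking hosts
#' (factor "rank"; samples without a rank are dropped), overall or
#' separately per phylum (the table is restricted to the phylum's genera
#' before estimating diversity).
#'
#' @param genus_table a `genus_table` of rarefied counts.
#' @param metadata host metadata with `host_id`, `age_class`, `rank_class`.
#' @param factor "age" or "rank".
#' @param scope "all" or "per_phylum".
#' @param measures subset of c("richness", "chao1", "pielou").
#' @return data.frame: measure, scope, U, n1, n2, p.
#' @export
compare_groups <- function(genus_table, metadata,
                           factor = c("age", "rank"),
                           scope = c("all", "per_phylum"),
                           measures = c("richness", "chao1", "pielou")) {
  factor <- match.arg(factor); scope <- match.arg(scope)
  samples <- colnames(genus_table$counts)
  meta <- metadata[match(samples, metadata$host_id), ]
  grp <- if (factor == "age") meta$age_class else meta$rank_class
  use <- !is.na(grp)
  grp <- droplevels(base::factor(grp[use]))
  if (nlevels(grp) < 2 || min(table(grp)) < 2) {
    .hb_stop("each ", factor, " category needs at least two samples")
  }
  scopes <- if (scope == "all") list(all = seq_len(nrow(genus_table$counts)))
  else split(seq_len(nrow(genus_table$counts)), genus_table$taxa$phylum)
  res <- list()
  for (sc in names(scopes)) {
    d <- diversity_estimates(genus_table$counts[scopes[[sc]], use,
                                                drop = FALSE])
    vals <- list(richness = d$richness, chao1 = d$chao1, pielou = d$pielou)
    for (ms in measures) {
      v <- vals[[ms]]
      ok <- !is.na(v)
      if (min(table(grp[ok])) < 2) next
      mw <- exact_mann_whitney(v[ok][grp[ok] == levels(grp)[1]],
                               v[ok][grp[ok] == levels(grp)[2]])
      res[[length(res) + 1]] <- data.frame(
        measure = ms, scope = sc, U = mw$U, n1 = mw$n1, n2 = mw$n2,
        p = mw$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
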