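# Bray-Curtis dissimilarity, non-metric MDS, PLS-DA with LOO axis selection,
# and quartile-loading Fisher enrichment by phylum.

#' log10(1 + x) abundance transform
#'
#' The transform applied before Bray-Curtis, ordination, PLS and the log-log
#' coprology models.
#'
#' @param x numeric matrix or vector of non-negative abundances.
#' @export
log10p <- function(x) log10(1 + x)

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between sample rows
#' (computed through vegan); a pair of all-zero rows has no defined
#' dissimilarity and is returned as NA.
#'
#' @param mat samples x taxa matrix of non-negative (already transformed)
#'   abundances.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\] or NA.
#' @export
bray_curtis <- function(mat) {
  if (any(mat < 0)) .hb_stop("negative entries in abundance matrix")
  d <- as.matrix(suppressWarnings(vegan::vegdist(mat, method = "bray")))
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    d[zero, zero] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 (monotone regression of configuration
#' distances on dissimilarities) via vegan's engine; the first restart
#' starts from the metric (principal-coordinates) configuration, further
#' restarts from random configurations, and the lowest-stress solution is
#' returned. Deterministic given the seed.
#'
#' @param d symmetric dissimilarity matrix (or `dist`), zero diagonal, no NA.
#' @param k target dimension (k < n).
#' @param n_restarts number of starts.
#' @param seed integer seed.
#' @return object of class `nmds_result`: `points` (n x k), `stress`
#'   (stress-1, in \[0, 1\]), `restart_stress`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1) {
  dm <- as.matrix(d)
  if (any(is.na(dm))) .hb_stop("NA dissimilarities")
  n <- nrow(dm)
  if (k >= n) .hb_stop("k must be smaller than the number of samples")
  set.seed(seed)
  dd <- as.dist(dm)
  best <- NULL
  stresses <- numeric(n_restarts)
  for (i in seq_len(n_restarts)) {
    fit <- if (i == 1) {
      vegan::monoMDS(dd, k = k, model = "global")
    } else {
      vegan::monoMDS(dd, y = matrix(rnorm(n * k), n, k), k = k,
                     model = "global")
    }
    stresses[i] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- rownames(dm)
  structure(list(points = pts, stress = best$stress,
                 restart_stress = stresses, n_restarts = n_restarts,
                 seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d samples in %d dimensions, stress-1 = %.4f (%d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_restarts))
  invisible(x)
}

# NIPALS PLS1 fit on centered data; returns weights W, x-loadings P, x-scores
# T, y-loadings q, and regression coefficients for each number of axes
.pls1_fit <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  Wm <- matrix(0, p, A); Pm <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xa <- X; ya <- y
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    pl <- crossprod(Xa, t) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - t %*% t(pl)
    ya <- ya - qa * t
    Wm[, a] <- w; Pm[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  if (A == 0) .hb_stop("constant predictor matrix")
  Wm <- Wm[, seq_len(A), drop = FALSE]; Pm <- Pm[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
  # b(A) = W (P'W)^{-1} q
  beta <- Wm %*% solve(t(Pm) %*% Wm, q)
  list(W = Wm, P = Pm, T = Tm, q = q, beta = beta, A = A)
}

#' PLS discriminant analysis with leave-one-out axis selection
#'
#' PLS1 (NIPALS) regression of a +/-1-coded class on the column-centered
#' predictor matrix. For each candidate number of axes, leave-one-out
#' cross-validation refits on n-1 samples and classifies the held-out sample
#' by the sign of its predicted response; the smallest axis count attaining
#' the maximal LOO accuracy is retained and the full-data fit at that count
#' reported.
#'
#' @param X samples x predictors matrix (transformed genus abundances).
#' @param y two-level factor (or coercible) of length `nrow(X)`.
#' @param max_axes largest axis count considered.
#' @return object of class `pls_da`: `A` (retained axes), `scores` (n x A),
#'   `loadings` (p x A x-loadings), `weights`, `cv_accuracy` (per candidate
#'   A), `accuracy` (at the retained A), `predicted` (LOO classes at the
#'   retained A), `levels`.
#' @export
pls_da <- function(X, y, max_axes = 5) {
  X <- as.matrix(X)
  y <- base::factor(y)
  if (nlevels(y) != 2) .hb_stop("y must have exactly two classes")
  if (nrow(X) < 4) .hb_stop("need n >= 4 samples")
  if (all(apply(X, 2, var) == 0)) .hb_stop("constant predictor matrix")
  yy <- ifelse(y == levels(y)[1], 1, -1)
  n <- nrow(X)
  max_axes <- min(max_axes, n - 2, ncol(X))
  pred <- matrix(NA_real_, n, max_axes)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- yy[-i]
    xc <- colMeans(Xtr); yc <- mean(ytr)
    fit <- .pls1_fit(sweep(Xtr, 2, xc), ytr - yc, max_axes)
    for (a in seq_len(max_axes)) {
      Aa <- min(a, fit$A)
      beta_a <- fit$W[, seq_len(Aa), drop = FALSE] %*%
        solve(t(fit$P[, seq_len(Aa), drop = FALSE]) %*%
                fit$W[, seq_len(Aa), drop = FALSE], fit$q[seq_len(Aa)])
      pred[i, a] <- (X[i, ] - xc) %*% beta_a + yc
    }
  }
  acc <- colMeans(sign(pred) == yy)
  A_star <- which.max(acc == max(acc))
  xc <- colMeans(X)
  full <- .pls1_fit(sweep(X, 2, xc), yy - mean(yy), A_star)
  predicted <- base::factor(ifelse(sign(pred[, A_star]) >= 0,
                                   levels(y)[1], levels(y)[2]),
                            levels = levels(y))
  structure(list(A = full$A, scores = full$T, loadings = full$P,
                 weights = full$W, cv_accuracy = acc,
                 accuracy = acc[A_star], predicted = predicted,
                 levels = levels(y)),
            class = "pls_da")
}

#' @export
print.pls_da <- function(x, ...) {
  cat(sprintf(
    "PLS-DA (%s vs %s): %d axis/axes retained, LOO accuracy %.1f%%\n",
    x$levels[1], x$levels[2], x$A, 100 * x$accuracy))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p sums the hypergeometric probabilities of every table with the
#' observed margins whose probability does not exceed that of the observed
#' table. The odds ratio is the sample odds ratio `ad / bc` (infinite on a
#' zero off-diagonal denominator), not the conditional MLE.
#'
#' @param a,b,c,d non-negative integer cells (row-wise).
#' @return list: `odds_ratio`, `p`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    .hb_stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) .hb_stop("all-zero table")
  m <- a + c; nn <- b + d; kk <- a + b
  lo <- max(0, kk - nn); hi <- min(kk, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, nn, kk)
  p_obs <- dhyper(a, m, nn, kk)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  list(odds_ratio = or, p = min(1, p))
}

#' Phylum enrichment in extreme PLS loadings
#'
#' The working loading per genus is the axis-1 loading, or the elementwise
#' product of the first two axes when `n_axes_combine = 2`. The extreme set
#' is the top quartile, bottom quartile, or their union; quartile boundaries
#' are the 25th/75th percentiles with boundary ties included. Each phylum's
#' 2x2 membership table (extreme x phylum) is tested with [fisher_exact()].
#'
#' @param loadings p x A loading matrix (or vector), rows named or aligned
#'   with `phyla`.
#' @param phyla character vector of phylum labels per genus.
#' @param n_axes_combine 1 or 2.
#' @param mode "top", "bottom" or "both" (union of the two quartiles).
#' @return data.frame per phylum: a, b, c, d, odds_ratio, p.
#' @export
loading_enrichment <- function(loadings, phyla, n_axes_combine = 1,
                               mode = c("both", "top", "bottom")) {
  mode <- match.arg(mode)
  L <- as.matrix(loadings)
  if (nrow(L) < 8) .hb_stop("need at least 8 genera for quartile enrichment")
  if (!n_axes_combine %in% c(1, 2)) .hb_stop("n_axes_combine must be 1 or 2")
  if (n_axes_combine == 2 && ncol(L) < 2) {
    .hb_stop("two axes requested but loadings have fewer")
  }
  w <- if (n_axes_combine == 1) L[, 1] else L[, 1] * L[, 2]
  q <- quantile(w, c(0.25, 0.75), names = FALSE)
  extreme <- switch(mode,
                    top = w >= q[2],
                    bottom = w <= q[1],
                    both = w >= q[2] | w <= q[1])
  res <- lapply(unique(phyla), function(ph) {
    inp <- phyla == ph
    a <- sum(extreme & inp); b <- sum(extreme & !inp)
    c_ <- sum(!extreme & inp); d <- sum(!extreme & !inp)
    ft <- fisher_exact(a, b, c_, d)
    data.frame(phylum = ph, a = a, b = b, c = c_, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
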