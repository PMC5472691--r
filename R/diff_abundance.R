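# Negative-binomial differential abundance with size-factor offsets,
# likelihood-ratio tests and Benjamini-Hochberg correction.

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference taxa of the ratio of its count
#' to the taxon's geometric mean across samples; factors are then rescaled
#' to geometric mean 1. Reference taxa are those with positive counts in
#' every sample; when none exists, the fallback uses taxa positive in at
#' least `fallback_frac` of samples with geometric means and ratios over
#' positive entries only (logged via `message()`).
#'
#' @param counts taxa x samples matrix of non-negative counts.
#' @param fallback_frac positivity fraction for the fallback reference set.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, fallback_frac = 0.9) {
  if (nrow(counts) == 0 || ncol(counts) == 0) .hb_stop("empty count matrix")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    ref <- counts[allpos, , drop = FALSE]
    lgm <- rowMeans(log(ref))
    sf <- apply(ref, 2, function(col) exp(median(log(col) - lgm)))
  } else {
    message("no taxon positive in every sample; size-factor fallback over ",
            "taxa positive in >= ", round(100 * fallback_frac),
            "% of samples")
    qual <- rowMeans(counts > 0) >= fallback_frac
    if (!any(qual)) {
      # matrix too sparse even for the fallback: per-sample depth ratio
      message("no taxon positive in ", round(100 * fallback_frac),
              "% of samples; using total-count ratios")
      tot <- colSums(counts)
      if (any(tot == 0)) .hb_stop("zero-total sample; cannot estimate size factors")
      sf <- tot / exp(mean(log(tot)))
      return(stats::setNames(sf, colnames(counts)))
    }
    ref <- counts[qual, , drop = FALSE]
    lgm <- apply(ref, 1, function(r) mean(log(r[r > 0])))
    sf <- apply(ref, 2, function(col) {
      ok <- col > 0
      if (!any(ok)) return(NA_real_)
      exp(median(log(col[ok]) - lgm[ok]))
    })
    if (anyNA(sf)) {
      # last resort for samples sharing no reference taxon: depth ratio
      tot <- colSums(counts)
      sf[is.na(sf)] <- tot[is.na(sf)] / exp(mean(log(tot[tot > 0])))
    }
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# NB log-likelihood with fixed dispersion theta at fitted means mu
.nb_ll <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# per-taxon NB GLM LRT; returns a one-row data.frame. `theta` can be fixed
# (used by the Poisson-limit checks); by default it is estimated by ML.
.nb_test_one <- function(y, group, sf, theta = NULL) {
  if (sum(y > 0) < 3) {
    return(data.frame(log2fc = NA_real_, lrt = NA_real_, p = NA_real_,
                      theta = NA_real_, base_mean = mean(y / sf)))
  }
  off <- log(sf)
  if (is.null(theta)) {
    theta <- tryCatch(
      suppressWarnings(
        MASS::glm.nb(y ~ group + offset(off))$theta),
      error = function(e) NA_real_)
  }
  if (!is.finite(theta) || theta <= 0) {
    # method-of-moments fallback on offset-corrected counts
    z <- y / sf
    v <- var(z); m <- mean(z)
    theta <- if (is.finite(v) && v > m) m^2 / (v - m) else 1e6
  }
  theta <- min(theta, 1e6)
  fam <- MASS::negative.binomial(theta)
  full <- suppressWarnings(stats::glm(y ~ group + offset(off), family = fam))
  red <- suppressWarnings(stats::glm(y ~ 1 + offset(off), family = fam))
  lrt <- 2 * (.nb_ll(y, stats::fitted(full), theta) -
                .nb_ll(y, stats::fitted(red), theta))
  lrt <- max(0, lrt)
  data.frame(log2fc = unname(coef(full)[2]) / log(2),
             lrt = lrt, p = pchisq(lrt, df = 1, lower.tail = FALSE),
             theta = theta, base_mean = mean(y / sf))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_(j >= i) p_(j) m / j`, capped at 1, returned in input
#' order; NA entries are preserved and excluded from the family size m.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .hb_stop("p-values outside [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  adj <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out[ok[ord]] <- adj
  out
}

#' Per-genus negative-binomial differential abundance
#'
#' Fits, for every taxon, a log-link negative-binomial GLM of counts on the
#' two-level group factor with `log(size factor)` offsets and a taxon-specific
#' maximum-likelihood dispersion (method-of-moments fallback); the
#' likelihood-ratio statistic against the intercept-only model is compared to
#' chi-squared with 1 df, and p-values are Benjamini-Hochberg adjusted over
#' the tested taxa. Taxa with fewer than three positive samples are reported
#' NA and excluded from the family. The log2 fold change is oriented as the
#' second group level over the first.
#'
#' @param counts taxa x samples integer matrix.
#' @param group two-level factor over samples.
#' @param sf size factors; computed from `counts` when NULL.
#' @param taxa optional data.frame (e.g. `genus_table$taxa`) carried through.
#' @return data.frame per taxon: base_mean, log2fc, lrt, p, padj (plus any
#'   `taxa` columns).
#' @export
diff_abundance <- function(counts, group, sf = NULL, taxa = NULL) {
  group <- base::factor(group)
  if (nlevels(group) != 2 || min(table(group)) < 1) {
    .hb_stop("group must have two non-empty levels")
  }
  if (any(counts != round(counts))) .hb_stop("counts must be integers")
  if (is.null(sf)) sf <- size_factors(counts)
  res <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    .nb_test_one(counts[i, ], group, sf)
  }))
  res$padj <- bh_adjust(res$p)
  if (!is.null(taxa)) res <- cbind(taxa, res)
  else res <- cbind(data.frame(taxon = rownames(counts)), res)
  rownames(res) <- NULL
  res
}
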