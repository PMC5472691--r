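# McMaster egg/oocyst quantification, prevalence/intensity summaries, and
# the correlation screen linking coprology to sequence counts.

#' Eggs per gram from four McMaster chamber counts
#'
#' `epg = sum(counts) * dilution / (n_chambers * chamber_volume_ml)`; at the
#' defaults (1:15 dilution, four 0.15 ml chambers) each counted egg
#' represents 25 eggs per gram, consistent with minimum non-zero intensities
#' of 25 in chamber-count data.
#'
#' @param counts vector of non-negative integer chamber counts.
#' @param dilution dilution factor (1:`dilution`).
#' @param chamber_volume_ml volume counted per chamber.
#' @return eggs (or oocysts) per gram of feces.
#' @examples
#' fec_from_chambers(c(1, 0, 0, 0)) # 25
#' @export
fec_from_chambers <- function(counts, dilution = 15, chamber_volume_ml = 0.15) {
  if (any(counts < 0) || any(counts != round(counts))) {
    .hb_stop("chamber counts must be non-negative integers")
  }
  sum(counts) * dilution / (length(counts) * chamber_volume_ml)
}

#' Sum egg counts over the size classes of a morphotype
#'
#' @param table coprology data.frame (`sample`, `morphotype`, `size_class`,
#'   `epg`).
#' @param morphotype morphotype name.
#' @return named numeric vector: per-sample summed epg.
#' @export
combine_size_classes <- function(table, morphotype) {
  d <- table[table$morphotype == morphotype, ]
  if (nrow(d) == 0) .hb_stop("unknown morphotype: ", morphotype)
  tot <- tapply(d$epg, d$sample, sum)
  stats::setNames(as.vector(tot), names(tot))
}

# exact binomial order-statistic CI for the median (NA when m is too small
# for two-sided 95% coverage, i.e. m <= 5)
.median_ci <- function(x, conf = 0.95) {
  m <- length(x)
  alpha <- 1 - conf
  if (m <= 5) return(c(NA_real_, NA_real_))
  xs <- sort(x)
  j <- stats::qbinom(alpha / 2, m, 0.5)
  if (stats::pbinom(j, m, 0.5) > alpha / 2) j <- j - 1
  lo <- j + 1; hi <- m - j
  if (lo < 1 || hi > m || lo > hi) return(c(NA_real_, NA_real_))
  c(xs[lo], xs[hi])
}

#' Prevalence and intensity of infection per parasite taxon
#'
#' Prevalence is the percentage of all samples with epg > 0, reported to one
#' decimal with round-half-to-even. Intensity statistics are computed over
#' positive samples only: mean with a t confidence interval (the lower bound
#' floored at 0, the raw value kept in `mean_ci_low_raw`) and median with an
#' exact binomial order-statistic interval (NA when too few positives).
#' Single-positive taxa report the value as mean/median with NA intervals.
#'
#' @param table coprology data.frame (`sample`, `morphotype`, `size_class`,
#'   `epg`); per-morphotype totals over size classes are added automatically
#'   when a morphotype has several classes.
#' @param n_samples number of examined samples.
#' @param conf confidence level.
#' @return data.frame: taxon, size_class, n_positive, prevalence, mean,
#'   mean_ci_low, mean_ci_low_raw, mean_ci_high, median, median_ci_low,
#'   median_ci_high.
#' @export
summarize_parasites <- function(table, n_samples, conf = 0.95) {
  if (n_samples < 1) .hb_stop("n_samples must be >= 1")
  rows <- list()
  for (m in unique(table$morphotype)) {
    d <- table[table$morphotype == m, ]
    classes <- unique(d$size_class)
    units <- lapply(classes, function(cl)
      tapply(d$epg[d$size_class == cl], d$sample[d$size_class == cl], sum))
    names(units) <- classes
    if (length(classes) > 1) units <- c(list(total = combine_size_classes(table, m)), units)
    for (cl in names(units)) {
      x <- units[[cl]]
      pos <- x[x > 0]
      k <- length(pos)
      prev <- round(100 * k / n_samples, 1)
      if (k == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          taxon = m, size_class = cl, n_positive = 0L, prevalence = prev,
          mean = NA_real_, mean_ci_low = NA_real_,
          mean_ci_low_raw = NA_real_, mean_ci_high = NA_real_,
          median = NA_real_, median_ci_low = NA_real_,
          median_ci_high = NA_real_)
        next
      }
      mu <- mean(pos)
      if (k >= 2 && sd(pos) > 0) {
        se <- sd(pos) / sqrt(k)
        tq <- qt(1 - (1 - conf) / 2, k - 1)
        ci <- c(mu - tq * se, mu + tq * se)
      } else ci <- c(NA_real_, NA_real_)
      med_ci <- .median_ci(pos, conf)
      rows[[length(rows) + 1]] <- data.frame(
        taxon = m, size_class = cl, n_positive = k, prevalence = prev,
        mean = mu, mean_ci_low = max(0, ci[1]), mean_ci_low_raw = ci[1],
        mean_ci_high = ci[2], median = median(pos),
        median_ci_low = med_ci[1], median_ci_high = med_ci[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average (tie-midranked) ranks; the
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom.
#' Zero variance in either vector yields an NA result rather than an error.
#'
#' @param x,y numeric vectors (pairs with NA removed; n >= 3 required).
#' @return list: `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) .hb_stop("spearman needs n >= 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) == 1) return(list(rho = rho, p = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE), n = n)
}

#' Build hierarchical taxon-node count tables
#'
#' Sums genus counts up every level of the lineage (genus, family, order,
#' class, phylum) and appends user-declared taxon sets (summed genus unions),
#' giving the comprehensive node-by-sample matrix the correlation screen
#' scans.
#'
#' @param genus_table a `genus_table`.
#' @param lineages lineage data.frame with `genus`, `family`, `order`,
#'   `class`, `phylum`.
#' @param taxon_sets named list of genus character vectors.
#' @return numeric matrix, nodes x samples; node names are `level:name`.
#' @export
build_taxon_nodes <- function(genus_table, lineages, taxon_sets = list()) {
  counts <- genus_table$counts
  lin <- lineages[match(genus_table$taxa$genus, lineages$genus), ]
  out <- list()
  for (lv in .TAX_LEVELS) {
    grp <- lin[[lv]]
    if (lv == "phylum") grp <- genus_table$taxa$phylum
    ok <- which(!is.na(grp))
    if (length(ok) == 0) next
    s <- rowsum(counts[ok, , drop = FALSE], grp[ok])
    rownames(s) <- paste0(lv, ":", rownames(s))
    out[[lv]] <- s
  }
  if (length(taxon_sets)) {
    s <- do.call(rbind, lapply(names(taxon_sets), function(nm) {
      g <- intersect(taxon_sets[[nm]], rownames(counts))
      colSums(counts[g, , drop = FALSE])
    }))
    rownames(s) <- paste0("set:", names(taxon_sets))
    out$sets <- s
  }
  nodes <- do.call(rbind, out)
  nodes <- nodes[!duplicated(rownames(nodes)), , drop = FALSE]
  attr(nodes, "set_members") <- taxon_sets
  nodes
}

#' Screen coprology totals against all taxonomic nodes
#'
#' Computes the Spearman correlation of each morphotype's per-sample egg
#' counts against every node of the hierarchical count table (plus declared
#' taxon sets), ranks nodes by decreasing rho, and flags taxonomic agreement
#' for the declared target taxa: a node agrees when it is a target genus, an
#' ancestor of one, or a declared set containing one.
#'
#' @param copro coprology data.frame (see [generate_coprology()]).
#' @param nodes node-by-sample matrix from [build_taxon_nodes()].
#' @param lineages lineage data.frame (used to resolve ancestors).
#' @param targets named list morphotype -> character vector of target genera.
#' @param top_k how many top correlations to keep per morphotype.
#' @return data.frame sorted by morphotype and decreasing rho: morphotype,
#'   node, rho, p, n, rank, agreement.
#' @export
correlation_screen <- function(copro, nodes, lineages, targets = list(),
                               top_k = 4) {
  out <- list()
  for (m in unique(copro$morphotype)) {
    fec <- combine_size_classes(copro, m)
    shared <- intersect(names(fec), colnames(nodes))
    if (length(shared) == 0) .hb_stop("no shared samples for ", m)
    fec_s <- fec[shared]
    tg <- targets[[m]]
    agree_nodes <- character(0)
    if (!is.null(tg)) {
      lin <- lineages[lineages$genus %in% tg, ]
      agree_nodes <- c(paste0("genus:", tg),
                       paste0("family:", lin$family),
                       paste0("order:", lin$order),
                       paste0("class:", lin$class),
                       paste0("phylum:", lin$phylum))
      set_rows <- grep("^set:", rownames(nodes), value = TRUE)
      # a declared set agrees when it contains a target genus
      members <- attr(nodes, "set_members")
      agree_nodes <- c(agree_nodes, set_rows[vapply(set_rows, function(sr) {
        any(tg %in% members[[sub("^set:", "", sr)]])
      }, TRUE)])
    }
    res <- lapply(rownames(nodes), function(nd) {
      sp <- spearman(fec_s, nodes[nd, shared])
      data.frame(morphotype = m, node = nd, rho = sp$rho, p = sp$p,
                 n = sp$n, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res <- res[!is.na(res$rho), , drop = FALSE]
    res <- res[order(-res$rho), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    res$agreement <- res$node %in% agree_nodes
    out[[m]] <- head(res, top_k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log-log predictive model of egg counts from sequence counts
#'
#' Ordinary least squares of `log10(1 + epg)` on `log10(1 + count)`, the
#' predictive visualization model of the coprology screen.
#'
#' @param epg,counts aligned numeric vectors (n >= 3).
#' @return object of class `loglog_model`: list `intercept`, `slope`,
#'   `r_squared`, `n`, `fit` (the underlying `lm`).
#' @export
fit_loglog <- function(epg, counts) {
  ok <- stats::complete.cases(epg, counts)
  epg <- epg[ok]; counts <- counts[ok]
  if (length(epg) < 3) .hb_stop("fit_loglog needs n >= 3")
  x <- log10(1 + counts); y <- log10(1 + epg)
  if (var(x) == 0) .hb_stop("zero variance in transformed predictor")
  fit <- lm(y ~ x)
  r2 <- if (var(y) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r_squared = r2,
                 n = length(epg), fit = fit),
            class = "loglog_model")
}

#' @export
print.loglog_model <- function(x, ...) {
  cat(sprintf(
    "log10(1+FEC) = %.3f + %.3f * log10(1+count)   (R^2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}
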