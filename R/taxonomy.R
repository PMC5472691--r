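# Naive-Bayes k-mer classification with bootstrap confidence, genus-level
# agglomeration across amplicons, and phylum accounting with functional roles.

.TAX_LEVELS <- c("phylum", "class", "order", "family", "genus")

# k-mers of a sequence, restricted to plain ACGT words (spacer Ns drop out)
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  w[grepl("^[ACGT]+$", w)]
}

#' Train the naive-Bayes k-mer classifier
#'
#' Word (k-mer) conditional probabilities per genus with the classical
#' database-frequency smoothing: the prior of word w over N reference
#' sequences containing it n(w) times is `Pr(w) = (n(w)+0.5)/(N+1)` and the
#' genus-conditional probability over the M(g) references of genus g is
#' `P(w|g) = (m(w,g)+Pr(w))/(M(g)+1)`. Duplicate reference sequences of the
#' same genus are counted once.
#'
#' @param sequences named character vector of reference sequences.
#' @param taxa data.frame with `seq_id` and lineage columns `phylum`,
#'   `class`, `order`, `family`, `genus` (as in a `hyena_refdb`).
#' @param k word length (default 8).
#' @return object of class `nb_classifier`.
#' @export
train_classifier <- function(sequences, taxa, k = 8) {
  stopifnot(all(names(sequences) %in% taxa$seq_id))
  taxa <- taxa[match(names(sequences), taxa$seq_id), ]
  # deduplicate identical (sequence, genus) references
  dup <- duplicated(paste(sequences, taxa$genus))
  sequences <- sequences[!dup]; taxa <- taxa[!dup, ]
  if (any(nchar(sequences) < k)) .hb_stop("reference sequence shorter than k")
  genera <- unique(taxa$genus)
  if (length(genera) < 2) .hb_stop("need >= 2 genera to train")
  ref_words <- lapply(sequences, function(s) unique(.kmers(s, k)))
  words <- sort(unique(unlist(ref_words)))
  W <- length(words); G <- length(genera); N <- length(sequences)
  n_w <- integer(W)
  m_wg <- matrix(0L, W, G, dimnames = list(NULL, genera))
  for (i in seq_len(N)) {
    idx <- match(ref_words[[i]], words)
    n_w[idx] <- n_w[idx] + 1L
    g <- match(taxa$genus[i], genera)
    m_wg[idx, g] <- m_wg[idx, g] + 1L
  }
  M_g <- as.integer(table(factor(taxa$genus, levels = genera)))
  prior <- (n_w + 0.5) / (N + 1)
  logp <- log(sweep(m_wg + matrix(prior, W, G), 2, M_g + 1, `/`))
  # a word absent from every reference scores the smoothing floor
  log_unseen <- log((0.5 / (N + 1)) / (M_g + 1))
  lineage <- unique(taxa[, .TAX_LEVELS])
  lineage <- lineage[match(genera, lineage$genus), ]
  rownames(lineage) <- NULL
  structure(list(k = k, words = words, logp = logp,
                 log_unseen = stats::setNames(log_unseen, genera),
                 genera = genera, lineage = lineage, n_refs = N),
            class = "nb_classifier")
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat("Naive-Bayes k-mer classifier: k =", x$k, ",", length(x$genera),
      "genera,", x$n_refs, "references,", length(x$words), "words\n")
  invisible(x)
}

#' Classify one sequence with bootstrap confidence
#'
#' The genus score is the summed log word probability over the sequence's
#' k-mers (words containing the N spacer are skipped); `n_bootstrap`
#' resamples of `floor(W/8)` words with replacement yield per-level
#' confidences as the fraction of bootstrap winners agreeing with the
#' full-sequence winner's lineage at that level. Levels with confidence below
#' `min_boot` (and everything below the first such level) are `UNDEFINED`.
#'
#' @param sequence query (concatenated RSV sequences welcome).
#' @param model an `nb_classifier`.
#' @param n_bootstrap bootstrap replicates.
#' @param min_boot minimum per-level confidence retained.
#' @param seed integer seed (bootstrap determinism).
#' @return list: `lineage` (named character over phylum..genus, possibly
#'   `UNDEFINED`), `bootstrap` (named numeric confidences), `genus_raw` (the
#'   unthresholded winner).
#' @export
classify <- function(sequence, model, n_bootstrap = 100, min_boot = 0.5,
                     seed = 1) {
  set.seed(seed)
  res <- .classify_scores(sequence, model)
  winner <- res$winner
  W <- res$n_words
  nboot_words <- max(1L, W %/% 8L)
  boot_win <- integer(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(W, nboot_words, replace = TRUE)
    sc <- colSums(res$contrib[idx, , drop = FALSE])
    # ties (e.g. a query with no database support, where every genus sits on
    # the smoothing floor) are broken at random so confidence splits
    top <- which(sc >= max(sc) - 1e-9)
    boot_win[b] <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
  }
  lin_w <- model$lineage[winner, ]
  conf <- vapply(.TAX_LEVELS, function(lv) {
    mean(model$lineage[[lv]][boot_win] == lin_w[[lv]])
  }, 0)
  lineage <- unlist(lin_w[.TAX_LEVELS])
  bad <- which(conf < min_boot)
  if (length(bad)) lineage[min(bad):length(lineage)] <- "UNDEFINED"
  list(lineage = lineage, bootstrap = conf,
       genus_raw = model$genera[winner])
}

# per-word log-probability contributions of one query against all genera
.classify_scores <- function(sequence, model) {
  words <- .kmers(sequence, model$k)
  if (length(words) == 0) .hb_stop("sequence yields no valid word")
  idx <- match(words, model$words)
  contrib <- matrix(rep(model$log_unseen, each = length(words)),
                    length(words), length(model$genera),
                    dimnames = list(NULL, model$genera))
  known <- !is.na(idx)
  if (any(known)) contrib[known, ] <- model$logp[idx[known], , drop = FALSE]
  score <- colSums(contrib)
  list(contrib = contrib, score = score, winner = which.max(score),
       n_words = length(words))
}

#' Classify every RSV of a table
#'
#' @param rsv_table an `rsv_table`.
#' @inheritParams classify
#' @return data.frame: rsv_id, phylum..genus, boot_phylum..boot_genus.
#' @export
classify_rsvs <- function(rsv_table, model, n_bootstrap = 100, min_boot = 0.5,
                          seed = 1) {
  res <- lapply(seq_len(nrow(rsv_table$rsv)), function(i) {
    cl <- classify(rsv_table$rsv$sequence[i], model,
                   n_bootstrap = n_bootstrap, min_boot = min_boot,
                   seed = seed + i)
    c(as.list(cl$lineage),
      stats::setNames(as.list(cl$bootstrap), paste0("boot_", .TAX_LEVELS)))
  })
  out <- cbind(data.frame(rsv_id = rsv_table$rsv$rsv_id,
                          stringsAsFactors = FALSE),
               do.call(rbind, lapply(res, as.data.frame)))
  rownames(out) <- NULL
  out
}

# uninformative genus annotations, matched case-insensitively
.UNINFORMATIVE <- "undefined|uncultured|unidentified|environmental|metagenome|incertae.?sedis"

.is_informative <- function(x) {
  !is.na(x) & !grepl(.UNINFORMATIVE, x, ignore.case = TRUE)
}

#' Agglomerate RSV counts to genus level across amplicons
#'
#' Counts are summed over all RSVs sharing a genus annotation, across
#' amplicons. RSVs without an informative genus are dropped first (the
#' `NArm` convention, with "undefined"-like terms treated as missing); then
#' genera that are the only genus of their phylum; then genera with an
#' undefined phylum. Drop counts are reported via `message()`.
#'
#' @param rsv_table an `rsv_table` (replicates already collapsed to samples).
#' @param assignments data.frame from [classify_rsvs()].
#' @param panel optional primer panel; when given, each genus is annotated
#'   with the majority target (16S/18S) of its RSVs' amplicons.
#' @return object of class `genus_table`: list `taxa` (genus, phylum,
#'   domain, n_rsvs), `counts` (genus x sample matrix).
#' @export
agglomerate_genus <- function(rsv_table, assignments, panel = NULL) {
  rsv <- rsv_table$rsv
  if (!all(rsv$rsv_id %in% assignments$rsv_id)) {
    .hb_stop("assignment missing for RSV(s): ",
             paste(head(setdiff(rsv$rsv_id, assignments$rsv_id)),
                   collapse = ", "))
  }
  asg <- assignments[match(rsv$rsv_id, assignments$rsv_id), ]
  informative <- .is_informative(asg$genus) & asg$genus != "UNDEFINED"
  message(sum(!informative), " of ", nrow(rsv),
          " RSVs dropped (no informative genus annotation)")
  keep <- which(informative)
  key <- paste(asg$phylum[keep], asg$genus[keep], sep = "|")
  genera <- unique(key)
  counts <- matrix(0, length(genera), ncol(rsv_table$counts),
                   dimnames = list(genera, colnames(rsv_table$counts)))
  for (i in seq_along(keep)) {
    counts[key[i], ] <- counts[key[i], ] + rsv_table$counts[keep[i], ]
  }
  parts <- strsplit(genera, "|", fixed = TRUE)
  taxa <- data.frame(genus = vapply(parts, `[`, "", 2),
                     phylum = vapply(parts, `[`, "", 1),
                     n_rsvs = as.integer(table(factor(key, levels = genera))),
                     stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    amp_target <- stats::setNames(panel$target, panel$amplicon_id)
    taxa$domain <- vapply(genera, function(g) {
      t <- amp_target[rsv$amplicon[keep][key == g]]
      names(sort(table(t), decreasing = TRUE))[1]
    }, "")
  } else {
    taxa$domain <- NA_character_
  }
  # exclusion order: sole-genus-in-phylum, then undefined phylum
  tab <- table(taxa$phylum)
  sole <- taxa$phylum %in% names(tab)[tab == 1] &
    .is_informative(taxa$phylum) & taxa$phylum != "UNDEFINED"
  message(sum(sole), " genera dropped (only genus of their phylum)")
  taxa <- taxa[!sole, , drop = FALSE]; counts <- counts[!sole, , drop = FALSE]
  undef <- !(.is_informative(taxa$phylum) & taxa$phylum != "UNDEFINED")
  message(sum(undef), " genera dropped (undefined phylum)")
  taxa <- taxa[!undef, , drop = FALSE]
  counts <- counts[!undef, , drop = FALSE]
  rownames(taxa) <- NULL
  rownames(counts) <- taxa$genus
  structure(list(taxa = taxa, counts = counts), class = "genus_table")
}

#' @export
print.genus_table <- function(x, ...) {
  cat("Genus table:", nrow(x$taxa), "genera (",
      length(unique(x$taxa$phylum)), "phyla ) x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Phylum-level accounting with functional roles
#'
#' Per phylum: number of genera, number of RSVs and summed reads, with the
#' functional role attached from `role_map`; per domain (16S bacteria / 18S
#' eukaryotes): totals over named phyla and full totals including
#' undefined-phylum rows.
#'
#' @param genus_df data.frame with one row per genus: `phylum`, `domain`,
#'   optionally `n_rsvs` and `reads`. A `genus_table` is also accepted
#'   (reads are its row sums).
#' @param role_map named character vector phylum -> role
#'   (see [default_role_map()]); phyla missing from it get role
#'   "undetermined" with a warning.
#' @return list: `per_phylum` (phylum, domain, role, n_genera, n_rsvs,
#'   reads), `domain_totals` (domain, n_genera/n_rsvs/reads over named phyla,
#'   and `*_full` totals including undefined-phylum rows).
#' @export
summarize_phyla <- function(genus_df, role_map = default_role_map()) {
  if (inherits(genus_df, "genus_table")) {
    df <- genus_df$taxa
    df$reads <- rowSums(genus_df$counts)
    genus_df <- df
  }
  if (nrow(genus_df) == 0) {
    return(list(per_phylum = data.frame(), domain_totals = data.frame(
      domain = character(0), n_genera = integer(0), n_rsvs = integer(0),
      reads = numeric(0), n_genera_full = integer(0),
      n_rsvs_full = integer(0), reads_full = numeric(0))))
  }
  if (is.null(genus_df$n_rsvs)) genus_df$n_rsvs <- NA_integer_
  if (is.null(genus_df$reads)) genus_df$reads <- NA_real_
  named <- .is_informative(genus_df$phylum) & genus_df$phylum != "UNDEFINED"
  genus_df$phylum[!named] <- "UNDEFINED"
  agg <- function(d) {
    data.frame(n_genera = nrow(d), n_rsvs = sum(d$n_rsvs),
               reads = sum(d$reads))
  }
  keys <- unique(genus_df[, c("phylum", "domain")])
  per <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    d <- genus_df[genus_df$phylum == keys$phylum[i] &
                    genus_df$domain %in% keys$domain[i], ]
    cbind(keys[i, ], agg(d))
  }))
  per <- per[order(per$domain, per$phylum), ]
  missing_role <- setdiff(setdiff(per$phylum, "UNDEFINED"), names(role_map))
  if (length(missing_role)) {
    warning("phylum missing from role map, role set to undetermined: ",
            paste(missing_role, collapse = ", "))
  }
  per$role <- ifelse(per$phylum == "UNDEFINED", "undetermined",
                     ifelse(per$phylum %in% names(role_map),
                            role_map[per$phylum], "undetermined"))
  rownames(per) <- NULL
  doms <- unique(per$domain)
  totals <- do.call(rbind, lapply(doms, function(d) {
    full <- per[per$domain %in% d, ]
    nm <- full[full$phylum != "UNDEFINED", ]
    data.frame(domain = d, n_genera = sum(nm$n_genera),
               n_rsvs = sum(nm$n_rsvs), reads = sum(nm$reads),
               n_genera_full = sum(full$n_genera),
               n_rsvs_full = sum(full$n_rsvs), reads_full = sum(full$reads))
  }))
  list(per_phylum = per[, c("phylum", "domain", "role", "n_genera",
                            "n_rsvs", "reads")],
       domain_totals = totals)
}
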