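# Synthetic amplicon world: primer panel, reference database, paired reads
# with PCR failures / water controls / chimeras, and coupled egg counts.

.BASES <- c("A", "C", "G", "T")
# two-fold IUPAC codes usable as degenerate primer positions
.DEGEN <- list(R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
               S = c("C", "G"), K = c("G", "T"), M = c("A", "C"))

rand_dna <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

#' Generate a multi-amplicon primer panel
#'
#' Emulates the study's array of 48 amplicons (4 bacterial 16S, 44 eukaryote
#' 18S targets): unique forward/reverse primer pairs of 18-20 bases, a
#' fraction of which carry one two-fold degenerate IUPAC position.
#'
#' @param n_16s,n_18s number of 16S and 18S amplicons.
#' @param degen_frac fraction of primers given one degenerate position.
#' @param seed integer seed.
#' @return data.frame (`amplicon_id`, `fwd_primer`, `rev_primer`, `target`).
#' @export
generate_panel <- function(n_16s = 4, n_18s = 44, degen_frac = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_16s + n_18s
  mk_primer <- function() {
    p <- rand_dna(sample(18:20, 1))
    if (runif(1) < degen_frac) {
      pos <- sample(nchar(p), 1)
      base <- substr(p, pos, pos)
      codes <- names(.DEGEN)[vapply(.DEGEN, function(s) base %in% s, TRUE)]
      substr(p, pos, pos) <- sample(codes, 1)
    }
    p
  }
  fwd <- character(n); rev <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      f <- mk_primer(); r <- mk_primer()
      key <- paste(f, r)
      if (!key %in% seen && f != r) break
    }
    seen <- c(seen, key)
    fwd[i] <- f; rev[i] <- r
  }
  data.frame(amplicon_id = sprintf("A%02d", seq_len(n)),
             fwd_primer = fwd, rev_primer = rev,
             target = rep(c("16S", "18S"), c(n_16s, n_18s)),
             stringsAsFactors = FALSE)
}

# count of distinct k-mers shared between two sequences
shared_kmer_frac <- function(a, b, k = 8) {
  ka <- unique(substring(a, 1:(nchar(a) - k + 1), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1), k:nchar(b)))
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Generate a synthetic reference database
#'
#' One master sequence per genus (plus optional within-genus variants carrying
#' a few substitutions), with lineage strings. Master sequences are drawn
#' independently per genus, which keeps pairwise shared 8-mer fractions low;
#' when `max_shared` is set, offending pairs are redrawn until genera are
#' k-mer separated at that level.
#'
#' @param lineages data.frame as from [default_lineages()], >= 2 genera in
#'   >= 2 phyla.
#' @param seed integer seed.
#' @param seq_length reference length (also the amplified insert length).
#' @param n_per_genus reference sequences per genus; variants beyond the
#'   first carry ~1% substitutions relative to the master.
#' @param max_shared maximum tolerated pairwise shared 8-mer fraction between
#'   genus masters, or `NULL` to skip the check.
#' @param fasta optional path; when given, references are written as FASTA
#'   and the lineage table as TSV alongside (`<fasta>.lineage.tsv`).
#' @return object of class `hyena_refdb`: list with `sequences` (named
#'   character), `taxa` (data.frame seq_id + lineage columns), `master`
#'   (genus -> master seq id), `seed`.
#' @export
generate_reference_db <- function(lineages, seed = 1, seq_length = 400,
                                  n_per_genus = 2, max_shared = 0.05,
                                  fasta = NULL) {
  if (is.null(lineages) || nrow(lineages) == 0) .hb_stop("empty lineage set")
  if (length(unique(lineages$genus)) < 2 || length(unique(lineages$phylum)) < 2)
    .hb_stop("reference database needs >= 2 genera and >= 2 phyla")
  set.seed(seed)
  genera <- lineages$genus
  masters <- vapply(genera, function(g) rand_dna(seq_length), "")
  if (!is.null(max_shared)) {
    for (tries in 1:20) {
      bad <- FALSE
      for (i in seq_along(masters)) for (j in seq_len(i - 1)) {
        if (shared_kmer_frac(masters[i], masters[j]) > max_shared) {
          masters[i] <- rand_dna(seq_length); bad <- TRUE
        }
      }
      if (!bad) break
    }
  }
  seqs <- character(0); ids <- character(0); rows <- integer(0)
  for (i in seq_along(genera)) {
    for (v in seq_len(n_per_genus)) {
      s <- masters[i]
      if (v > 1) { # within-genus variant: ~1% substitutions
        nmut <- max(1L, round(0.01 * seq_length))
        pos <- sample(seq_length, nmut)
        ch <- charToRaw(s)
        for (p in pos) {
          ch[p] <- charToRaw(sample(setdiff(.BASES, rawToChar(ch[p])), 1))
        }
        s <- rawToChar(ch)
      }
      ids <- c(ids, sprintf("%s_ref%d", genera[i], v))
      seqs <- c(seqs, s); rows <- c(rows, i)
    }
  }
  names(seqs) <- ids
  taxa <- cbind(data.frame(seq_id = ids, stringsAsFactors = FALSE),
                lineages[rows, c("phylum", "class", "order", "family",
                                 "genus", "domain")])
  rownames(taxa) <- NULL
  db <- structure(list(sequences = seqs,
                       taxa = taxa,
                       master = stats::setNames(ids[!duplicated(rows)],
                                                genera),
                       seed = seed),
                  class = "hyena_refdb")
  if (!is.null(fasta)) {
    writeLines(paste0(">", ids, "\n", seqs), fasta)
    lin_str <- apply(taxa[, c("phylum", "class", "order", "family", "genus")],
                     1, paste, collapse = ";")
    write.table(data.frame(seq_id = ids, lineage = lin_str),
                paste0(fasta, ".lineage.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  db
}

#' Read-simulation error parameters
#'
#' @param e per-base substitution rate.
#' @param c chimera (bimera) formation rate per read pair.
#' @param read_len length of each mate as sequenced.
#' @param depth read pairs per ordinary technical replicate (exact).
#' @param fail_rate probability that a replicate's PCR fails (near-zero
#'   depth, Poisson mean `fail_depth`).
#' @param fail_depth,water_mean Poisson means for failed replicates and for
#'   water-control cross-contamination.
#' @param n_rate per-base rate of uncalled (N) bases.
#' @param bad_q_frac fraction of mates with very low quality (rejected by the
#'   expected-error filter); `trunc_q_frac` of mates get one early Q<=2 base.
#' @export
read_error_params <- function(e = 0.002, c = 0.01, read_len = 250,
                              depth = 2000, fail_rate = 0.05, fail_depth = 2,
                              water_mean = 5, n_rate = 5e-4,
                              bad_q_frac = 0.02, trunc_q_frac = 0.02) {
  list(e = e, c = c, read_len = read_len, depth = depth,
       fail_rate = fail_rate, fail_depth = fail_depth,
       water_mean = water_mean, n_rate = n_rate,
       bad_q_frac = bad_q_frac, trunc_q_frac = trunc_q_frac)
}

# inject substitutions (to a random *different* base) at rate `rate`
.inject_subs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nerr > 0)) {
    ch <- charToRaw(seqs[i])
    pos <- sample(length(ch), nerr[i])
    for (p in pos) {
      ch[p] <- charToRaw(sample(setdiff(.BASES, rawToChar(ch[p])), 1))
    }
    seqs[i] <- rawToChar(ch)
  }
  seqs
}

# replace bases by N at rate `rate`
.inject_ns <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  nn <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nn > 0)) {
    ch <- charToRaw(seqs[i])
    ch[sample(length(ch), nn[i])] <- charToRaw("N")
    seqs[i] <- rawToChar(ch)
  }
  seqs
}

# instantiate degenerate IUPAC positions of a primer, one draw per read
.instantiate_primer <- function(primer, n) {
  chars <- strsplit(primer, "")[[1]]
  degen <- which(chars %in% names(.DEGEN))
  if (length(degen) == 0 || n == 0) return(rep(primer, n))
  out <- matrix(rep(chars, n), nrow = length(chars))
  for (d in degen) {
    out[d, ] <- sample(.DEGEN[[chars[d]]], n, replace = TRUE)
  }
  apply(out, 2, paste, collapse = "")
}

#' Simulate primer-prefixed paired reads for every technical replicate
#'
#' Each host sample is sequenced as `tech_reps` technical replicates plus
#' `n_water` water controls. Per ordinary replicate exactly `depth` read
#' pairs are drawn: a (genus, amplicon) template is chosen with probability
#' proportional to true abundance times an amplicon-specific amplification
#' efficiency, read 1 is the instantiated forward primer followed by the
#' insert 5' end, read 2 the reverse primer followed by the reverse
#' complement of the insert 3' end. Chimeric pairs splice the forward region
#' of two templates of the same amplicon. Failed replicates are drawn at
#' `fail_rate` and sequenced at near-zero depth; water controls receive only
#' low-level cross-contamination. Flat per-read quality strings carry the
#' error structure the quality filter screens for (low-quality mates,
#' early Q<=2 truncation points, N bases).
#'
#' @param truth a `hyena_truth` object.
#' @param panel primer panel from [generate_panel()].
#' @param refdb reference database from [generate_reference_db()].
#' @param error list from [read_error_params()].
#' @param tech_reps technical replicates per sample.
#' @param n_water number of water-control replicates.
#' @param p_amp probability that an amplicon amplifies a matching-domain
#'   genus (every genus is guaranteed at least one amplicon).
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @param outdir optional directory: per-replicate FASTQ pairs
#'   (`<rep>_R1.fastq.gz`/`_R2`) and truth tables are written there.
#' @return object of class `hyena_reads`: list with `replicates` (replicate,
#'   sample, is_water, failed), `reads` (per-replicate data.frames id, seq1,
#'   qual1, seq2, qual2), `truth` (per-read: replicate, id, amplicon, genus,
#'   chimera, parent2), `templates` (per genus x amplicon trimmed concatenated
#'   truth sequences), `panel`, `seed`.
#' @export
generate_reads <- function(truth, panel, refdb, error = read_error_params(),
                           tech_reps = 2, n_water = 6, p_amp = 0.35,
                           seed = 1, outdir = NULL) {
  stopifnot(inherits(truth, "hyena_truth"), inherits(refdb, "hyena_refdb"))
  if (nrow(panel) == 0) .hb_stop("empty primer panel")
  if (error$depth <= 0) .hb_stop("depth must be positive for ordinary replicates")
  set.seed(seed)
  lin <- truth$lineages
  abund <- truth$abundance
  genera <- rownames(abund)

  # amplification design: which amplicon amplifies which genus, with bias
  eff <- matrix(0, nrow = length(genera), ncol = nrow(panel),
                dimnames = list(genera, panel$amplicon_id))
  for (g in seq_along(genera)) {
    match_a <- which(panel$target == lin$domain[match(genera[g], lin$genus)])
    on <- match_a[runif(length(match_a)) < p_amp]
    if (length(on) == 0) on <- match_a[sample(length(match_a), 1)]
    eff[g, on] <- rlnorm(length(on), 0, 0.5)
  }

  # per (genus, amplicon) read templates from the genus master reference
  ins <- refdb$sequences[refdb$master[genera]]
  ins_rc <- revcomp(ins)
  t1 <- matrix("", length(genera), nrow(panel),
               dimnames = dimnames(eff))
  t2 <- t1
  for (a in seq_len(nrow(panel))) {
    l1 <- error$read_len - nchar(panel$fwd_primer[a])
    l2 <- error$read_len - nchar(panel$rev_primer[a])
    t1[, a] <- substr(ins, 1, l1)
    t2[, a] <- substr(ins_rc, 1, l2)
  }

  hosts <- truth$metadata$host_id
  reps <- data.frame(
    replicate = c(t(outer(hosts, seq_len(tech_reps),
                          function(h, r) paste0(h, "_R", r))),
                  if (n_water > 0) paste0("W", sprintf("%02d", seq_len(n_water)), "_R1")),
    sample = c(rep(hosts, each = tech_reps),
               if (n_water > 0) paste0("W", sprintf("%02d", seq_len(n_water)))),
    is_water = rep(c(FALSE, TRUE), c(length(hosts) * tech_reps, n_water)),
    stringsAsFactors = FALSE)
  reps$failed <- !reps$is_water & runif(nrow(reps)) < error$fail_rate

  mean_abund <- rowMeans(abund)
  read_list <- list(); truth_list <- list()
  for (i in seq_len(nrow(reps))) {
    rep_id <- reps$replicate[i]
    if (reps$is_water[i]) {
      D <- rpois(1, error$water_mean)
      w <- as.vector(mean_abund * eff)
    } else {
      D <- if (reps$failed[i]) rpois(1, error$fail_depth) else error$depth
      w <- as.vector(abund[, reps$sample[i]] * eff)
    }
    if (D == 0 || sum(w) == 0) {
      read_list[[rep_id]] <- data.frame(id = character(0), seq1 = character(0),
                                        qual1 = character(0),
                                        seq2 = character(0),
                                        qual2 = character(0))
      truth_list[[rep_id]] <- NULL
      next
    }
    pick <- sample.int(length(w), D, replace = TRUE, prob = w)
    gi <- (pick - 1) %% length(genera) + 1
    ai <- (pick - 1) %/% length(genera) + 1
    s1 <- t1[cbind(gi, ai)]
    s2 <- t2[cbind(gi, ai)]
    chim <- runif(D) < error$c
    parent2 <- rep(NA_character_, D)
    for (j in which(chim)) {
      others <- which(eff[, ai[j]] > 0 & w[(ai[j] - 1) * length(genera) +
                                             seq_along(genera)] > 0)
      others <- setdiff(others, gi[j])
      if (length(others) == 0) { chim[j] <- FALSE; next }
      g2 <- if (length(others) == 1) others else
        sample(others, 1, prob = w[(ai[j] - 1) * length(genera) + others])
      len1 <- nchar(s1[j])
      # keep the junction inside the 170-base window retained by the quality
      # filter so the chimeric sequence stays distinguishable after trimming
      k <- sample(20:min(130, len1 - 20), 1)
      s1[j] <- paste0(substr(s1[j], 1, k),
                      substr(t1[g2, ai[j]], k + 1, len1))
      parent2[j] <- genera[g2]
    }
    p1 <- character(D); p2 <- character(D)
    for (a in unique(ai)) {
      idx <- which(ai == a)
      p1[idx] <- .instantiate_primer(panel$fwd_primer[a], length(idx))
      p2[idx] <- .instantiate_primer(panel$rev_primer[a], length(idx))
    }
    seq1 <- .inject_ns(.inject_subs(paste0(p1, s1), error$e), error$n_rate)
    seq2 <- .inject_ns(.inject_subs(paste0(p2, s2), error$e), error$n_rate)

    mk_qual <- function(lens) {
      mu <- ifelse(runif(D) < error$bad_q_frac, 12, 36)
      q <- strrep(vapply(pmin(40, pmax(3, round(rnorm(D, mu, 1)))) + 33L,
                         function(x) intToUtf8(x), ""), lens)
      cut <- which(runif(D) < error$trunc_q_frac)
      for (j in cut) {
        pos <- sample(lens[j], 1)
        substr(q[j], pos, pos) <- "#" # Q2
      }
      q
    }
    qual1 <- mk_qual(nchar(seq1))
    qual2 <- mk_qual(nchar(seq2))
    ids <- sprintf("%s_read%05d", rep_id, seq_len(D))
    read_list[[rep_id]] <- data.frame(id = ids, seq1 = seq1, qual1 = qual1,
                                      seq2 = seq2, qual2 = qual2,
                                      stringsAsFactors = FALSE)
    truth_list[[rep_id]] <- data.frame(
      replicate = rep_id, id = ids,
      amplicon = panel$amplicon_id[ai], genus = genera[gi],
      chimera = chim, parent2 = parent2, stringsAsFactors = FALSE)
  }
  truth_tab <- do.call(rbind, truth_list)
  rownames(truth_tab) <- NULL

  # truth templates in pipeline coordinates: primer-trimmed, truncated to the
  # quality filter's 170 bases, concatenated fwd + 10 N + revcomp(rev)
  templ <- lapply(seq_len(nrow(panel)), function(a) {
    keep <- eff[, a] > 0
    if (!any(keep)) return(NULL)
    f <- substr(t1[keep, a], 1, 170 - nchar(panel$fwd_primer[a]))
    r <- substr(t2[keep, a], 1, 170 - nchar(panel$rev_primer[a]))
    data.frame(amplicon = panel$amplicon_id[a], genus = genera[keep],
               sequence = concat_pairs(f, r), stringsAsFactors = FALSE)
  })
  templates <- do.call(rbind, templ)

  out <- structure(list(replicates = reps, reads = read_list,
                        truth = truth_tab, templates = templates,
                        panel = panel, eff = eff, seed = seed),
                   class = "hyena_reads")
  if (!is.null(outdir)) write_read_bundle(out, outdir)
  out
}

#' @export
print.hyena_reads <- function(x, ...) {
  cat("Synthetic reads:", nrow(x$replicates), "replicates (",
      sum(x$replicates$is_water), "water,", sum(x$replicates$failed),
      "failed ),", sum(vapply(x$reads, nrow, 0L)), "read pairs, seed",
      x$seed, "\n")
  invisible(x)
}

#' Write a simulated read bundle to disk
#'
#' Per-replicate gzipped FASTQ pairs plus replicate and per-read truth tables
#' (TSV) and a small JSON manifest recording the seed.
#'
#' @param reads a `hyena_reads` object.
#' @param outdir output directory, created if needed.
#' @return invisibly, the directory.
#' @export
write_read_bundle <- function(reads, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (rep_id in names(reads$reads)) {
    df <- reads$reads[[rep_id]]
    write_fastq(data.frame(id = df$id, seq = df$seq1, qual = df$qual1),
                file.path(outdir, paste0(rep_id, "_R1.fastq.gz")))
    write_fastq(data.frame(id = df$id, seq = df$seq2, qual = df$qual2),
                file.path(outdir, paste0(rep_id, "_R2.fastq.gz")))
  }
  write.table(reads$replicates, file.path(outdir, "replicates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(reads$truth, file.path(outdir, "read_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = reads$seed,
                            n_replicates = nrow(reads$replicates)),
                       file.path(outdir, "manifest.json"), auto_unbox = TRUE)
  invisible(outdir)
}

#' Default coprology coupling parameters
#'
#' One row per egg/oocyst morphotype, mirroring the morphotypes a McMaster
#' flotation distinguishes in hyena feces: a strongyle-type egg
#' (*Ancylostoma*, two size classes), diphyllobothriid eggs (one class),
#' taeniid eggs (two classes) and coccidian oocysts (two size classes, fed by
#' several genera with indistinguishable oocysts). Expected
#' log10(1 + eggs per gram) is `a + b * log10(1 + true abundance)` with
#' negative-binomial overdispersion on the counted eggs.
#'
#' @return data.frame with columns `morphotype`, `taxa` (";"-joined genera),
#'   `size_classes` (";"), `class_props` (";"), `a`, `b`, `dispersion`.
#' @export
coprology_coupling <- function() {
  data.frame(
    morphotype = c("Ancylostoma", "Diphyllobothriidae", "Taeniidae",
                   "Coccidia"),
    taxa = c("Ancylostoma", "Diphyllobothrium;Spirometra", "Taenia",
             "Eimeria;Isospora;Toxoplasma;Besnoitia"),
    size_classes = c("<80um;>=80um", "all", "<45um;>=45um", "<20um;>=20um"),
    class_props = c("0.95;0.05", "1", "0.5;0.5", "0.7;0.3"),
    a = c(0.2, 0.3, 0, 0.1),
    b = c(0.8, 0.9, 0.7, 0.9),
    dispersion = c(0.5, 0.5, 0.6, 0.4),
    stringsAsFactors = FALSE)
}

#' Simulate McMaster chamber counts coupled to true abundance
#'
#' For each sample and morphotype, the expected fecal egg count follows the
#' log-log coupling `log10(1+FEC) = a + b log10(1+x)` on the summed true
#' abundance `x` of the morphotype's genera; the number of eggs actually
#' counted across the four chambers (FEC / 25 at the default McMaster
#' multiplier) is drawn negative-binomially with the stated overdispersion
#' (Poisson when `dispersion = 0`) and split multinomially over chambers and
#' size classes. Zero abundance with `a = 0` yields exactly zero counts.
#'
#' @param truth a `hyena_truth` object.
#' @param coupling data.frame as [coprology_coupling()].
#' @param seed integer seed.
#' @param multiplier eggs per gram represented by one counted egg (see
#'   [fec_from_chambers()]).
#' @return data.frame: `sample`, `morphotype`, `size_class`, `c1..c4`, `epg`.
#' @export
generate_coprology <- function(truth, coupling = coprology_coupling(),
                               seed = 1, multiplier = 25) {
  stopifnot(inherits(truth, "hyena_truth"))
  if (any(coupling$dispersion < 0)) .hb_stop("negative dispersion")
  set.seed(seed)
  abund <- truth$abundance
  out <- list()
  for (m in seq_len(nrow(coupling))) {
    taxa <- strsplit(coupling$taxa[m], ";")[[1]]
    taxa <- intersect(taxa, rownames(abund))
    classes <- strsplit(coupling$size_classes[m], ";")[[1]]
    props <- as.numeric(strsplit(coupling$class_props[m], ";")[[1]])
    props <- props / sum(props)
    x <- if (length(taxa)) colSums(abund[taxa, , drop = FALSE]) else
      rep(0, ncol(abund))
    mu_fec <- 10^(coupling$a[m] + coupling$b[m] * log10(1 + x)) - 1
    mu_fec[x == 0 & coupling$a[m] == 0] <- 0
    for (s in seq_along(x)) {
      mu_eggs <- mu_fec[s] / multiplier * props
      for (cl in seq_along(classes)) {
        tot <- if (coupling$dispersion[m] > 0) {
          rnbinom(1, mu = mu_eggs[cl], size = 1 / coupling$dispersion[m])
        } else rpois(1, mu_eggs[cl])
        ch <- as.vector(rmultinom(1, tot, rep(1 / 4, 4)))
        out[[length(out) + 1]] <- data.frame(
          sample = colnames(abund)[s], morphotype = coupling$morphotype[m],
          size_class = classes[cl],
          c1 = ch[1], c2 = ch[2], c3 = ch[3], c4 = ch[4],
          epg = fec_from_chambers(ch), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
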