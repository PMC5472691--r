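# Shared fixtures, built in code and cached per test run.

.world_cache <- new.env(parent = emptyenv())

# a small noise-free cohort: 4 adults + 2 juveniles, 2x16S + 3x18S panel
noise_free_world <- function() {
  if (!is.null(.world_cache$nf)) return(.world_cache$nf)
  truth <- generate_truth(4, 2, seed = 5)
  panel <- generate_panel(2, 3, seed = 6)
  refdb <- generate_reference_db(truth$lineages, seed = 7)
  err <- read_error_params(e = 0, c = 0, n_rate = 0, bad_q_frac = 0,
                           trunc_q_frac = 0, depth = 400, fail_rate = 0)
  reads <- generate_reads(truth, panel, refdb, error = err, tech_reps = 1,
                          n_water = 0, seed = 9)
  .world_cache$nf <- list(truth = truth, panel = panel, refdb = refdb,
                          reads = reads)
  .world_cache$nf
}

# read pair constructor with flat qualities
mk_pair <- function(seq1, seq2, q1 = 38, q2 = 38, id = "r1") {
  data.frame(id = id, seq1 = seq1,
             qual1 = strrep(intToUtf8(q1 + 33), nchar(seq1)),
             seq2 = seq2,
             qual2 = strrep(intToUtf8(q2 + 33), nchar(seq2)),
             stringsAsFactors = FALSE)
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force exact two-sided Mann-Whitney p by full enumeration
brute_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  ws <- apply(sets, 2, function(i) sum(r[i]))
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# brute-force two-sided Fisher p by hypergeometric enumeration
brute_fisher_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; kk <- a + b
  xs <- max(0, kk - nn):min(kk, m)
  probs <- stats::dhyper(xs, m, nn, kk)
  sum(probs[probs <= stats::dhyper(a, m, nn, kk) * (1 + 1e-7)])
}
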