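# End-to-end pipeline: simulate -> filter -> stratify -> denoise -> QC ->
# taxonomy -> statistics, with TSV/JSON reports and a run manifest.

#' Demo pipeline configuration
#'
#' A desk-scale version of the emulated study design (fewer hosts, fewer
#' amplicons, shallower replicates) that runs end to end in minutes on one
#' CPU while exercising every stage: PCR failures, water controls, chimeras,
#' coupled egg counts, age and rank effects.
#'
#' @param outdir output directory for reports.
#' @param seed master seed; all stage seeds derive from it.
#' @return a named list understood by [run_pipeline()].
#' @export
demo_config <- function(outdir = tempfile("hyenabiome_demo_"), seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    n_adults = 12, n_juveniles = 6, n_water = 3,
    n_16s = 2, n_18s = 6,
    tech_reps = 2,
    truth = truth_params(),
    error = read_error_params(depth = 1500, e = 0.002, c = 0.02),
    filter = list(truncLen = c(170, 170), maxN = 0, maxEE = c(2, 2),
                  truncQ = 2),
    # singleton unique sequences are not callable as variants at desk scale;
    # min_count = 2 keeps the demo table to genuine templates and chimeras
    denoise = list(d_max = 1, skew = 0.1, min_count = 2),
    taxonomy = list(k = 8, n_bootstrap = 100, min_boot = 0.5),
    stats = list(top_k = 4, max_axes = 5, fdr = 0.05)
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> quality filter -> primer stratification -> variant
#' inference and bimera removal -> replicate QC, collapsing, normalization
#' and rarefaction -> taxonomy and genus agglomeration -> coprology screen,
#' diversity tests, ordination + PLS-DA and differential abundance, writing
#' TSV reports, a JSON summary and a manifest (config hash, seed) to
#' `config$outdir`. Deterministic given the config seeds: rerunning an
#' identical config reproduces identical reports.
#'
#' @param config list from [demo_config()] (or a path to a JSON file with
#'   the same structure).
#' @return object of class `hyena_pipeline` with all intermediate and final
#'   results.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) .hb_stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  required <- c("outdir", "seed", "n_adults", "n_juveniles", "n_water",
                "n_16s", "n_18s", "tech_reps", "error", "filter",
                "denoise", "taxonomy", "stats")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    .hb_stop("config validation failed; missing field(s): ",
             paste(missing, collapse = ", "))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## --- simulate ------------------------------------------------------
  sim <- .stage("simulate", {
    truth <- generate_truth(config$n_adults, config$n_juveniles,
                            params = config$truth, seed = seed)
    panel <- generate_panel(config$n_16s, config$n_18s, seed = seed + 1)
    refdb <- generate_reference_db(truth$lineages, seed = seed + 2)
    reads <- generate_reads(truth, panel, refdb, error = config$error,
                            tech_reps = config$tech_reps,
                            n_water = config$n_water, seed = seed + 3)
    copro <- generate_coprology(truth, seed = seed + 4)
    list(truth = truth, panel = panel, refdb = refdb, reads = reads,
         copro = copro)
  })

  ## --- filter + stratify --------------------------------------------
  strat <- .stage("filter/stratify", {
    lapply(sim$reads$reads, function(df) {
      kept <- do.call(filter_pairs, c(list(df), config$filter))$kept
      stratify_by_primer(kept, sim$panel)
    })
  })
  amp_counts <- t(vapply(strat, function(s)
    vapply(s$by_amplicon, nrow, 0L), integer(nrow(sim$panel))))
  colnames(amp_counts) <- sim$panel$amplicon_id

  ## --- denoise -------------------------------------------------------
  denoised <- .stage("denoise", {
    tab <- build_rsv_table(lapply(strat, `[[`, "by_amplicon"),
                           d_max = config$denoise$d_max,
                           skew = config$denoise$skew,
                           min_count = config$denoise$min_count)
    remove_bimeras(tab)
  })

  ## --- replicate QC + normalization ---------------------------------
  qc <- .stage("qc/normalize", {
    failed <- flag_failed_replicates(amp_counts,
                                     sim$reads$replicates$is_water)
    by_sample <- suppressWarnings(
      collapse_replicates(denoised$table, sim$reads$replicates, failed))
    nonzero <- colSums(by_sample$counts) > 0
    by_sample$counts <- by_sample$counts[, nonzero, drop = FALSE]
    norm <- median_scale(by_sample$counts)
    list(failed = failed, by_sample = by_sample, norm = norm)
  })

  ## --- taxonomy ------------------------------------------------------
  taxo <- .stage("taxonomy", {
    model <- train_classifier(sim$refdb$sequences, sim$refdb$taxa,
                              k = config$taxonomy$k)
    asg <- classify_rsvs(qc$by_sample, model,
                         n_bootstrap = config$taxonomy$n_bootstrap,
                         min_boot = config$taxonomy$min_boot,
                         seed = seed + 5)
    genus <- suppressMessages(
      agglomerate_genus(qc$by_sample, asg, panel = sim$panel))
    list(model = model, assignments = asg, genus = genus)
  })
  genus <- taxo$genus
  genus_norm <- genus
  genus_norm$counts <- median_scale(genus$counts)$normalized
  genus_rare <- genus
  genus_rare$counts <- rarefy(genus$counts, seed = seed + 6)

  meta <- sim$truth$metadata
  dom16 <- genus$taxa$domain == "16S"
  sub_tab <- function(gt, rows) {
    structure(list(taxa = gt$taxa[rows, , drop = FALSE],
                   counts = gt$counts[rows, , drop = FALSE]),
              class = "genus_table")
  }

  ## --- coprology screen ---------------------------------------------
  coprology <- .stage("coprology", {
    coupling <- coprology_coupling()
    targets <- stats::setNames(strsplit(coupling$taxa, ";"),
                               coupling$morphotype)
    nodes <- build_taxon_nodes(genus_norm, sim$truth$lineages,
                               taxon_sets = list(
                                 coccidia_genera = targets$Coccidia))
    nodes_t <- log10p(nodes)
    screen <- correlation_screen(sim$copro, nodes_t, sim$truth$lineages,
                                 targets = targets,
                                 top_k = config$stats$top_k)
    models <- lapply(unique(screen$morphotype), function(m) {
      top <- screen[screen$morphotype == m, ][1, ]
      fec <- combine_size_classes(sim$copro, m)
      shared <- intersect(names(fec), colnames(nodes))
      fit_loglog(fec[shared], nodes[top$node, shared])
    })
    names(models) <- unique(screen$morphotype)
    list(screen = screen, models = models)
  })

  ## --- diversity -----------------------------------------------------
  diversity <- .stage("diversity", {
    rbind(
      cbind(contrast = "age_16S",
            compare_groups(sub_tab(genus_rare, dom16), meta, "age")),
      cbind(contrast = "rank_18S",
            compare_groups(sub_tab(genus_rare, !dom16), meta, "rank")))
  })

  ## --- composition ---------------------------------------------------
  composition <- .stage("composition", {
    enrich <- function(pls, phyla, axes) {
      if (length(phyla) < 8) {
        message("fewer than 8 genera; loading enrichment skipped")
        return(NULL)
      }
      loading_enrichment(pls$loadings, phyla, n_axes_combine = axes)
    }
    x16 <- t(log10p(genus_norm$counts[dom16, , drop = FALSE]))
    x16 <- x16[rowSums(x16) > 0, , drop = FALSE]
    bc <- bray_curtis(x16)
    ord <- nmds(bc, k = 2, n_restarts = 10, seed = seed + 7)
    age <- meta$age_class[match(rownames(x16), meta$host_id)]
    pls_age <- pls_da(x16, age, max_axes = config$stats$max_axes)
    enr_age <- enrich(pls_age, genus_norm$taxa$phylum[dom16],
                      min(2, pls_age$A))
    x18 <- t(log10p(genus_norm$counts[!dom16, , drop = FALSE]))
    rank <- meta$rank_class[match(rownames(x18), meta$host_id)]
    ok <- !is.na(rank) & rowSums(x18) > 0
    pls_rank <- pls_da(x18[ok, , drop = FALSE], rank[ok],
                       max_axes = config$stats$max_axes)
    enr_rank <- enrich(pls_rank, genus_norm$taxa$phylum[!dom16], 1)
    list(nmds = ord, pls_age = pls_age, enrich_age = enr_age,
         pls_rank = pls_rank, enrich_rank = enr_rank)
  })

  ## --- differential abundance ---------------------------------------
  diffab <- .stage("diff_abundance", {
    age <- meta$age_class[match(colnames(genus$counts), meta$host_id)]
    g16 <- sub_tab(genus, dom16)
    diff_abundance(round(g16$counts), age, taxa = g16$taxa)
  })

  ## --- reports -------------------------------------------------------
  .stage("report", {
    out <- config$outdir
    jsonlite::write_json(config, file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_hash <- unname(tools::md5sum(file.path(out, "config.json")))
    write_tsv(cbind(replicate = rownames(amp_counts),
                    as.data.frame(amp_counts)),
              file.path(out, "replicate_amplicon_counts.tsv"))
    write_tsv(data.frame(replicate = qc$failed),
              file.path(out, "failed_replicates.tsv"))
    write_tsv(denoised$table$rsv, file.path(out, "rsv.tsv"))
    write_tsv(cbind(genus$taxa,
                    as.data.frame(genus$counts, check.names = FALSE)),
              file.path(out, "genus_counts.tsv"))
    phyl <- summarize_phyla(genus)
    write_tsv(phyl$per_phylum, file.path(out, "phylum_summary.tsv"))
    write_tsv(coprology$screen, file.path(out, "correlation_screen.tsv"))
    write_tsv(summarize_parasites(sim$copro,
                                  n_samples = ncol(sim$truth$abundance)),
              file.path(out, "parasite_summary.tsv"))
    write_tsv(diversity, file.path(out, "diversity_tests.tsv"))
    write_tsv(cbind(sample = rownames(composition$nmds$points),
                    as.data.frame(composition$nmds$points),
                    stress = composition$nmds$stress),
              file.path(out, "nmds.tsv"))
    write_tsv(diffab, file.path(out, "diff_abundance.tsv"))
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = seed,
           package_version = as.character(utils::packageVersion("hyenabiome")),
           n_replicates = nrow(sim$reads$replicates),
           n_rsvs = nrow(denoised$table$rsv),
           n_genera = nrow(genus$taxa),
           pls_age_accuracy = composition$pls_age$accuracy,
           pls_rank_accuracy = composition$pls_rank$accuracy),
      file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  })

  structure(list(config = config, sim = sim, stratified = strat,
                 amp_counts = amp_counts, rsv = denoised, qc = qc,
                 taxonomy = taxo, genus = genus, genus_norm = genus_norm,
                 genus_rare = genus_rare, coprology = coprology,
                 diversity = diversity, composition = composition,
                 diff_abundance = diffab),
            class = "hyena_pipeline")
}

#' @export
print.hyena_pipeline <- function(x, ...) {
  cat("hyenabiome pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  replicates:", nrow(x$sim$reads$replicates),
      "( failed flagged:", length(x$qc$failed), ")\n")
  cat("  RSVs:", nrow(x$rsv$table$rsv), " genera:", nrow(x$genus$taxa), "\n")
  cat("  PLS-DA LOO accuracy: age", sprintf("%.2f", x$composition$pls_age$accuracy),
      "/ rank", sprintf("%.2f", x$composition$pls_rank$accuracy), "\n")
  cat("  reports in:", x$config$outdir, "\n")
  invisible(x)
}
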