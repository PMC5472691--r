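#' Standardize a dominance hierarchy to the interval [-1, +1]
#'
#' Converts an ordered dominance hierarchy (highest-ranking host first) into
#' standardized ranks distributed evenly between +1 (highest) and -1 (lowest),
#' with the median rank scored exactly 0 for an odd number of hosts. A single
#' host receives rank 0.
#'
#' @param dominance_order character vector of host ids, highest rank first.
#' @return named numeric vector of standardized ranks in \[-1, 1\].
#' @examples
#' standardize_ranks(c("A", "B", "C")) # +1, 0, -1
#' @export
standardize_ranks <- function(dominance_order) {
  hosts <- as.character(dominance_order)
  if (length(hosts) < 1) .hb_stop("dominance_order must contain at least one host")
  if (anyDuplicated(hosts)) {
    .hb_stop("duplicate host id in dominance order: ",
             paste(unique(hosts[duplicated(hosts)]), collapse = ", "))
  }
  n <- length(hosts)
  r <- if (n == 1) 0 else 1 - 2 * (seq_len(n) - 1) / (n - 1)
  stats::setNames(r, hosts)
}

#' Classify hosts into age and rank categories
#'
#' Hosts are juveniles below 24 months of age and adults at or above it.
#' Hosts with a standardized rank of 0 or above are high-ranking, those below
#' 0 low-ranking; hosts without a rank (juveniles) get an `NA` rank class.
#'
#' @param age_months non-negative numeric vector.
#' @param std_rank numeric vector in \[-1, 1\], `NA` allowed; recycled.
#' @return data.frame with columns `age_class` and `rank_class` (factors).
#' @export
classify_host <- function(age_months, std_rank = NA_real_) {
  if (any(age_months < 0, na.rm = TRUE)) .hb_stop("negative age_months")
  if (any(abs(std_rank) > 1, na.rm = TRUE)) .hb_stop("std_rank outside [-1, 1]")
  n <- max(length(age_months), length(std_rank))
  age_months <- rep_len(age_months, n)
  std_rank <- rep_len(std_rank, n)
  age_class <- factor(ifelse(age_months < 24, "juvenile", "adult"),
                      levels = c("juvenile", "adult"))
  rank_class <- factor(ifelse(is.na(std_rank), NA,
                              ifelse(std_rank >= 0, "high", "low")),
                       levels = c("high", "low"))
  data.frame(age_class = age_class, rank_class = rank_class)
}

#' Built-in genus pool with full lineages
#'
#' The default taxon pool used by the synthetic-data generator: bacterial
#' genera across seven phyla typical of carnivore gut microbiomes and
#' eukaryote genera spanning parasites (helminths, coccidia, microsporidia),
#' fungi, algae, and dietary chordates/arthropods. Lineages are
#' phylum;class;order;family;genus. The parasite lineages are real, so the
#' correlation screen can be exercised against genuine higher-level nodes
#' (e.g. order Rhabditida above *Ancylostoma*).
#'
#' @return data.frame with columns `genus`, `family`, `order`, `class`,
#'   `phylum`, `domain` ("16S" or "18S").
#' @export
default_lineages <- function() {
  L <- function(phylum, class, order, family, genus, domain) {
    data.frame(genus = genus, family = family, order = order, class = class,
               phylum = phylum, domain = domain)
  }
  bact <- rbind(
    L("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae",
      c("Clostridium", "Sarcina"), "16S"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae",
      c("Blautia", "Roseburia"), "16S"),
    L("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae",
      c("Ruminococcus", "Faecalibacterium"), "16S"),
    L("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae",
      c("Lactobacillus", "Enterococcus"), "16S"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
      "Bacteroides", "16S"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae",
      "Prevotella", "16S"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae",
      c("Porphyromonas", "Parabacteroides"), "16S"),
    L("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae",
      "Alistipes", "16S"),
    L("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae", "Escherichia", "16S"),
    L("Proteobacteria", "Betaproteobacteria", "Burkholderiales",
      "Sutterellaceae", "Sutterella", "16S"),
    L("Proteobacteria", "Epsilonproteobacteria", "Campylobacterales",
      "Campylobacteraceae", "Campylobacter", "16S"),
    L("Proteobacteria", "Epsilonproteobacteria", "Campylobacterales",
      "Helicobacteraceae", "Helicobacter", "16S"),
    L("Actinobacteria", "Actinobacteria", "Bifidobacteriales",
      "Bifidobacteriaceae", "Bifidobacterium", "16S"),
    L("Actinobacteria", "Coriobacteriia", "Coriobacteriales",
      "Coriobacteriaceae", "Collinsella", "16S"),
    L("Actinobacteria", "Actinobacteria", "Actinomycetales",
      "Actinomycetaceae", "Actinomyces", "16S"),
    L("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae",
      c("Fusobacterium", "Cetobacterium"), "16S"),
    L("Tenericutes", "Mollicutes", "Mycoplasmatales", "Mycoplasmataceae",
      c("Mycoplasma", "Ureaplasma"), "16S"),
    L("Tenericutes", "Mollicutes", "Anaeroplasmatales", "Anaeroplasmataceae",
      "Anaeroplasma", "16S"),
    L("Spirochaetes", "Spirochaetia", "Spirochaetales", "Treponemataceae",
      "Treponema", "16S"),
    L("Spirochaetes", "Spirochaetia", "Brachyspirales", "Brachyspiraceae",
      "Brachyspira", "16S")
  )
  euk <- rbind(
    L("Nematoda", "Chromadorea", "Rhabditida", "Ancylostomatidae",
      "Ancylostoma", "18S"),
    L("Nematoda", "Chromadorea", "Rhabditida", "Trichostrongylidae",
      c("Haemonchus", "Ostertagia"), "18S"),
    L("Nematoda", "Enoplea", "Trichocephalida", "Trichuridae",
      "Trichuris", "18S"),
    L("Nematoda", "Chromadorea", "Ascaridida", "Toxocaridae",
      "Toxocara", "18S"),
    L("Platyhelminthes", "Cestoda", "Diphyllobothriidea", "Diphyllobothriidae",
      c("Diphyllobothrium", "Spirometra"), "18S"),
    L("Platyhelminthes", "Cestoda", "Cyclophyllidea", "Taeniidae",
      "Taenia", "18S"),
    L("Platyhelminthes", "Cestoda", "Cyclophyllidea", "Dipylidiidae",
      "Dipylidium", "18S"),
    L("Apicomplexa", "Conoidasida", "Eucoccidiorida", "Eimeriidae",
      c("Eimeria", "Isospora"), "18S"),
    L("Apicomplexa", "Conoidasida", "Eucoccidiorida", "Sarcocystidae",
      c("Toxoplasma", "Besnoitia"), "18S"),
    L("Microsporidia", "Microsporea", "Microsporida", "Enterocytozoonidae",
      "Enterocytozoon", "18S"),
    L("Microsporidia", "Microsporea", "Microsporida", "Unikaryonidae",
      "Encephalitozoon", "18S"),
    L("Ascomycota", "Eurotiomycetes", "Eurotiales", "Aspergillaceae",
      c("Aspergillus", "Penicillium"), "18S"),
    L("Ascomycota", "Saccharomycetes", "Saccharomycetales",
      "Debaryomycetaceae", "Candida", "18S"),
    L("Ascomycota", "Sordariomycetes", "Hypocreales", "Nectriaceae",
      "Fusarium", "18S"),
    L("Ascomycota", "Dothideomycetes", "Pleosporales", "Pleosporaceae",
      "Alternaria", "18S"),
    L("Ascomycota", "Dothideomycetes", "Capnodiales", "Cladosporiaceae",
      "Cladosporium", "18S"),
    L("Basidiomycota", "Tremellomycetes", "Tremellales", "Cryptococcaceae",
      "Cryptococcus", "18S"),
    L("Basidiomycota", "Malasseziomycetes", "Malasseziales",
      "Malasseziaceae", "Malassezia", "18S"),
    L("Basidiomycota", "Tremellomycetes", "Trichosporonales",
      "Trichosporonaceae", "Trichosporon", "18S"),
    L("Basidiomycota", "Microbotryomycetes", "Sporidiobolales",
      "Sporidiobolaceae", "Rhodotorula", "18S"),
    L("Basidiomycota", "Pucciniomycetes", "Pucciniales", "Pucciniaceae",
      "Puccinia", "18S"),
    L("Chlorophyta", "Trebouxiophyceae", "Chlorellales", "Chlorellaceae",
      "Chlorella", "18S"),
    L("Chlorophyta", "Chlorophyceae", "Chlamydomonadales",
      "Chlamydomonadaceae", c("Chlamydomonas", "Volvox"), "18S"),
    L("Chlorophyta", "Chlorophyceae", "Sphaeropleales", "Scenedesmaceae",
      "Scenedesmus", "18S"),
    L("Chordata", "Mammalia", "Carnivora", "Hyaenidae", "Crocuta", "18S"),
    L("Chordata", "Mammalia", "Artiodactyla", "Bovidae", "Connochaetes", "18S"),
    L("Chordata", "Mammalia", "Perissodactyla", "Equidae", "Equus", "18S"),
    L("Ciliophora", "Litostomatea", "Vestibuliferida", "Balantidiidae",
      "Balantidium", "18S"),
    L("Ciliophora", "Oligohymenophorea", "Hymenostomatida", "Tetrahymenidae",
      "Tetrahymena", "18S"),
    L("Arthropoda", "Insecta", "Diptera", "Muscidae", "Musca", "18S"),
    L("Arthropoda", "Arachnida", "Ixodida", "Ixodidae", "Dermacentor", "18S"),
    L("Arthropoda", "Insecta", "Diptera", "Glossinidae", "Glossina", "18S")
  )
  out <- rbind(bact, euk)
  rownames(out) <- NULL
  out
}

#' Default phylum-to-functional-role map
#'
#' Assigns each phylum in the built-in pool its likely predominant interaction
#' with the host: bacterial phyla form the microbiome; classical parasite
#' phyla (Nematoda, Platyhelminthes, Apicomplexa, Microsporidia) the parasitic
#' eukaryome; fungi and ciliates the wider eukaryome; algae are passing
#' material; chordates and arthropods food items.
#'
#' @return named character vector phylum -> role, roles in
#'   `c("microbiome", "eukaryome", "eukaryome_parasite", "food_item",
#'   "passing_material", "undetermined")`.
#' @export
default_role_map <- function() {
  c(Firmicutes = "microbiome", Bacteroidetes = "microbiome",
    Proteobacteria = "microbiome", Actinobacteria = "microbiome",
    Fusobacteria = "microbiome", Tenericutes = "microbiome",
    Spirochaetes = "microbiome",
    Nematoda = "eukaryome_parasite", Platyhelminthes = "eukaryome_parasite",
    Apicomplexa = "eukaryome_parasite", Microsporidia = "eukaryome_parasite",
    Ascomycota = "eukaryome", Basidiomycota = "eukaryome",
    Ciliophora = "eukaryome",
    Chlorophyta = "passing_material",
    Chordata = "food_item", Arthropoda = "food_item")
}

#' Parameters for the synthetic truth generator
#'
#' Defaults state the emulated world: 35 adult females and 7 juveniles (the
#' study's 42 hosts), a mean of ~22 bacterial genera in juveniles with an age
#' effect of +8 genera in adults (mirroring the reported medians of 41 vs 49
#' genera at a pool roughly one third the size of the real survey), a rank
#' effect of +8 eukaryote genera in high-ranking adults, and log-normal
#' abundances.
#'
#' @param base_richness_16s,base_richness_18s mean number of genera drawn per
#'   sample for the bacterial and eukaryote pools (juvenile / low-rank
#'   baseline).
#' @param age_effect_16s additional bacterial genera in adults.
#' @param rank_effect_18s additional eukaryote genera in high-ranking hosts.
#' @param richness_sd SD of the per-sample richness draw.
#' @param abund_meanlog,abund_sdlog log-normal abundance parameters.
#' @param core_genera genera present in every sample regardless of the
#'   richness draw: host DNA (*Crocuta*) dominates real fecal 18S reads, and
#'   a core of ubiquitous gut bacteria anchors the median-of-ratios size
#'   factors exactly as in real data.
#' @param core_boost added to `abund_meanlog` for the core genera.
#' @param lineages genus pool, see [default_lineages()].
#' @export
truth_params <- function(base_richness_16s = 14, base_richness_18s = 20,
                         age_effect_16s = 5, rank_effect_18s = 8,
                         richness_sd = 2, abund_meanlog = 3, abund_sdlog = 1.2,
                         core_genera = c("Crocuta", "Clostridium",
                                         "Bacteroides", "Blautia"),
                         core_boost = 1.5,
                         lineages = default_lineages()) {
  list(base_richness_16s = base_richness_16s,
       base_richness_18s = base_richness_18s,
       age_effect_16s = age_effect_16s,
       rank_effect_18s = rank_effect_18s,
       richness_sd = richness_sd,
       abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
       core_genera = core_genera, core_boost = core_boost,
       lineages = lineages)
}

#' Generate the synthetic ground truth for one cohort
#'
#' Draws host metadata (ages, a dominance hierarchy over adults, clans) and a
#' true genus-by-sample abundance matrix. Adults draw more bacterial genera
#' and high-ranking hosts more eukaryote genera, by the configured effect
#' sizes; juveniles carry no rank. Everything downstream (reads, coprology,
#' reference database) derives deterministically from this object and a seed.
#'
#' @param n_adults,n_juveniles cohort sizes (defaults: the study's 35 + 7).
#' @param params see [truth_params()].
#' @param seed integer seed; identical seeds give identical truth.
#' @return object of class `hyena_truth`: list with `metadata` (host_id,
#'   age_months, std_rank, age_class, rank_class, clan_id), `abundance`
#'   (genus x sample matrix of true read-scale abundances), `lineages`,
#'   `params`, `seed`.
#' @export
generate_truth <- function(n_adults = 35, n_juveniles = 7,
                           params = truth_params(), seed = 1) {
  set.seed(seed)
  lin <- params$lineages
  pool16 <- lin$genus[lin$domain == "16S"]
  pool18 <- lin$genus[lin$domain == "18S"]
  if (params$base_richness_16s + min(0, params$age_effect_16s) <= 0 ||
      params$base_richness_18s + min(0, params$rank_effect_18s) <= 0) {
    .hb_stop("effect sizes produce non-positive expected richness")
  }
  n <- n_adults + n_juveniles
  host_id <- sprintf("H%02d", seq_len(n))
  age_months <- c(round(runif(n_adults, 24, 180), 1),
                  round(runif(n_juveniles, 2, 23.5), 1))
  adult <- age_months >= 24
  # dominance hierarchy over adults only; juveniles carry no rank
  std_rank <- rep(NA_real_, n)
  if (n_adults > 0) {
    order_adults <- sample(host_id[adult])
    std_rank[match(order_adults, host_id)] <- standardize_ranks(order_adults)
  }
  cls <- classify_host(age_months, std_rank)
  clan_id <- sample(paste0("clan", 1:3), n, replace = TRUE)
  meta <- data.frame(host_id = host_id, age_months = age_months,
                     std_rank = std_rank, age_class = cls$age_class,
                     rank_class = cls$rank_class, clan_id = clan_id,
                     stringsAsFactors = FALSE)

  draw_richness <- function(mu, pool_size) {
    s <- round(rnorm(1, mu, params$richness_sd))
    max(1L, min(pool_size, s))
  }
  abundance <- matrix(0, nrow = nrow(lin), ncol = n,
                      dimnames = list(lin$genus, host_id))
  for (j in seq_len(n)) {
    mu16 <- params$base_richness_16s + params$age_effect_16s * adult[j]
    high <- !is.na(std_rank[j]) && std_rank[j] >= 0
    mu18 <- params$base_richness_18s + params$rank_effect_18s * high
    g16 <- sample(pool16, draw_richness(mu16, length(pool16)))
    g18 <- sample(pool18, draw_richness(mu18, length(pool18)))
    present <- c(g16, g18)
    abundance[present, j] <- rlnorm(length(present), params$abund_meanlog,
                                    params$abund_sdlog)
    core <- intersect(params$core_genera, rownames(abundance))
    core <- core[abundance[core, j] == 0]
    if (length(core)) {
      abundance[core, j] <- rlnorm(length(core),
                                   params$abund_meanlog + params$core_boost,
                                   params$abund_sdlog)
    }
  }
  structure(list(metadata = meta, abundance = abundance, lineages = lin,
                 params = params, seed = seed),
            class = "hyena_truth")
}

#' @export
print.hyena_truth <- function(x, ...) {
  cat("Synthetic cohort truth:", nrow(x$metadata), "hosts (",
      sum(x$metadata$age_class == "adult"), "adults,",
      sum(x$metadata$age_class == "juvenile"), "juveniles ),",
      nrow(x$abundance), "genera in pool, seed", x$seed, "\n")
  invisible(x)
}
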