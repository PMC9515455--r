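# Synthetic communities with known ground truth: genomes with controlled
# divergence (hence controlled ANI), fragmented bins with target
# completeness/contamination, multinomial read counts with planted
# between-group effects, and a mock gene/KO catalog.

DNA_BASES <- c("A", "C", "G", "T")

RANK_PREFIXES <- c(domain = "d__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Specify a synthetic genome
#'
#' A genome is either drawn de novo (i.i.d. bases at a target GC content) or
#' derived from a named parent by i.i.d. substitutions at a fixed per-site
#' rate.  The substitution-only model keeps the average nucleotide identity
#' (ANI) between parent and child analytic: ANI is approximately
#' `100 * (1 - divergence)`, which is what the dereplication stage needs for
#' controlled similarity levels around the 95% species threshold.
#'
#' @param species_id Genome identifier.
#' @param length Genome length in bp (> 0).
#' @param gc_target Target GC fraction in `[0, 1]`; ignored when a parent is
#'   given (the child inherits the parent's composition).
#' @param lineage 7-rank GTDB-style lineage string
#'   `"d__...;p__...;c__...;o__...;f__...;g__...;s__..."`.
#' @param parent_id Optional id of the ancestor genome.
#' @param divergence Per-site substitution rate from the parent (>= 0).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(species_id, length, gc_target = 0.5,
                        lineage = empty_lineage(), parent_id = NULL,
                        divergence = 0) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (length <= 0) stop("genome length must be positive")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0, 1]")
  if (divergence < 0) stop("divergence must be >= 0")
  check_lineage(lineage)
  structure(list(species_id = species_id, length = as.integer(length),
                 gc_target = gc_target, lineage = lineage,
                 parent_id = parent_id, divergence = divergence),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @export
empty_lineage <- function() paste0(RANK_PREFIXES, collapse = ";")

check_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  if (length(parts) != 7L)
    stop("lineage must have exactly 7 rank fields, got ", length(parts))
  invisible(parts)
}

#' Extract one rank from a 7-rank lineage string
#'
#' @param lineage Character vector of lineage strings.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return Character vector of rank names with the `x__` prefix stripped
#'   (possibly `""` for unassigned ranks).
#' @export
lineage_rank <- function(lineage, rank) {
  rank <- match.arg(rank, names(RANK_PREFIXES))
  idx <- match(rank, names(RANK_PREFIXES))
  vapply(strsplit(lineage, ";", fixed = TRUE), function(parts) {
    if (length(parts) != 7L)
      stop("lineage must have exactly 7 rank fields")
    sub(paste0("^", RANK_PREFIXES[[idx]]), "", parts[[idx]])
  }, character(1))
}

#' Generate a synthetic genome sequence
#'
#' De novo genomes are i.i.d. base draws with `P(G) = P(C) = gc_target / 2`;
#' for `length >= 100` kb the realized GC lands within about 0.01 of the
#' target by binomial concentration.  Derived genomes copy the parent and
#' substitute a `Binomial(length, divergence)` number of sites, each to one
#' of the three other bases uniformly, so the realized Hamming distance per
#' site concentrates at `divergence`.
#'
#' @param spec A [genome_spec()].
#' @param rng_seed Integer seed; generation is bit-reproducible.
#' @param genomes Named character vector (or list) of already generated
#'   genomes, used to look up `spec$parent_id`.
#' @return A single character string of A/C/G/T of length `spec$length`.
#' @export
generate_genome <- function(spec, rng_seed, genomes = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(rng_seed)
  if (is.null(spec$parent_id)) {
    gc <- spec$gc_target
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    return(paste0(sample(DNA_BASES, spec$length, replace = TRUE, prob = probs),
                  collapse = ""))
  }
  parent <- genomes[[spec$parent_id]]
  if (is.null(parent)) stop("unknown parent_id: ", spec$parent_id)
  if (nchar(parent) < spec$length)
    stop("parent genome shorter than requested length")
  bases <- strsplit(substr(parent, 1L, spec$length), "", fixed = TRUE)[[1]]
  n_sub <- rbinom(1L, spec$length, spec$divergence)
  if (n_sub > 0) {
    pos <- sample.int(spec$length, n_sub)
    # substitute to one of the 3 other bases, uniformly
    cur <- match(bases[pos], DNA_BASES)
    shift <- sample.int(3L, n_sub, replace = TRUE)
    bases[pos] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste0(bases, collapse = "")
}

#' Simulate species genomes from independent ancestors
#'
#' Convenience generator for dereplication experiments: `n_species`
#' unrelated ancestor genomes, each expanded into one or more MAG genomes
#' at a small within-species divergence.  Between-species similarity is that
#' of unrelated random sequences (ANI far below any species threshold),
#' within-species ANI is approximately `100 * (1 - divergence)`.
#'
#' @param n_species Number of ancestors.
#' @param mags_per_species Integer (recycled) number of MAGs per species.
#' @param genome_length Length of every genome in bp.
#' @param within_divergence Upper bound of the per-MAG substitution rate;
#'   each MAG draws its divergence uniformly from
#'   `[within_divergence / 4, within_divergence]`.
#' @param gc_target GC fraction of the ancestors.
#' @param seed Integer seed.
#' @return A list with `genomes` (named character vector, MAG id ->
#'   sequence), `truth` (data.frame `mag_id`, `species_id`, `divergence`)
#'   and `lineages` (named character vector, species id -> lineage).
#' @export
simulate_species_genomes <- function(n_species = 8, mags_per_species = 3,
                                     genome_length = 20000,
                                     within_divergence = 0.02,
                                     gc_target = 0.45, seed = 1) {
  set.seed(seed)
  mags_per_species <- rep_len(mags_per_species, n_species)
  lineages <- synthetic_lineages(n_species, seed = seed)
  species_ids <- names(lineages)
  genomes <- list()
  truth <- list()
  for (i in seq_len(n_species)) {
    sp <- species_ids[[i]]
    anc_seed <- sample.int(.Machine$integer.max, 1L)
    ancestor <- generate_genome(
      genome_spec(sp, genome_length, gc_target, lineages[[sp]]), anc_seed)
    genomes[[sp]] <- ancestor
    for (j in seq_len(mags_per_species[[i]])) {
      d <- runif(1, within_divergence / 4, within_divergence)
      mag_id <- sprintf("%s_MAG%02d", sp, j)
      child_seed <- sample.int(.Machine$integer.max, 1L)
      genomes[[mag_id]] <- generate_genome(
        genome_spec(mag_id, genome_length, gc_target, lineages[[sp]],
                    parent_id = sp, divergence = d),
        child_seed, genomes = genomes)
      truth[[mag_id]] <- data.frame(mag_id = mag_id, species_id = sp,
                                    divergence = d)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  mag_seqs <- unlist(genomes[truth$mag_id])
  list(genomes = mag_seqs, ancestors = unlist(genomes[species_ids]),
       truth = truth, lineages = lineages)
}

#' Generate hierarchical 7-rank lineages for synthetic species
#'
#' Species are spread over a small number of genera, families, orders,
#' classes and phyla so that taxonomic roll-ups have non-trivial structure.
#'
#' @param n_species Number of species lineages.
#' @param n_phyla,n_families,n_genera Approximate numbers of higher taxa.
#' @param seed Integer seed.
#' @return Named character vector, species id -> lineage string.
#' @export
synthetic_lineages <- function(n_species, n_phyla = 3, n_families = 5,
                               n_genera = 8, seed = 1) {
  set.seed(seed)
  species <- sprintf("SP%03d", seq_len(n_species))
  genus <- sprintf("Genus%02d", sample.int(min(n_genera, n_species),
                                           n_species, replace = TRUE))
  # nest deterministically: genus -> family -> order/class/phylum
  g_ids <- sort(unique(genus))
  fam_of_g <- setNames(sprintf("Family%02d",
                               ((seq_along(g_ids) - 1L) %% n_families) + 1L),
                       g_ids)
  f_ids <- sort(unique(fam_of_g))
  phy_of_f <- setNames(sprintf("Phylum%02d",
                               ((seq_along(f_ids) - 1L) %% n_phyla) + 1L),
                       f_ids)
  fam <- fam_of_g[genus]
  phy <- phy_of_f[fam]
  lin <- sprintf("d__Bacteria;p__%s;c__Class_%s;o__Order_%s;f__%s;g__%s;s__%s",
                 phy, phy, fam, fam, genus, species)
  setNames(lin, species)
}

#' Fragment a genome into a bin with target completeness and contamination
#'
#' Emulates the output of contig binning: the genome is tiled into contigs
#' of random length (all at least `min_contig` bp), a random subset of
#' contigs totalling approximately `target_completeness` percent of the
#' genome is retained, and contaminant contigs cut from a pool of foreign
#' sequences are added until contaminant bases reach approximately
#' `target_contamination` percent of the retained native bases.  Targets are
#' met within about 2 percentage points whenever the genome is much longer
#' than a single contig; for very short genomes the closest achievable
#' subset is used.
#'
#' @param genome Character string, the source genome.
#' @param target_completeness Percent of the genome to retain, in (0, 100].
#' @param contaminant_pool Character vector of foreign contigs/genomes.
#' @param target_contamination Contaminant bases as a percent of native
#'   bases (>= 0).
#' @param min_contig Minimum emitted contig length in bp.
#' @param rng_seed Integer seed.
#' @return A list with `contigs` (named character vector), `source`
#'   (character, `"native"`/`"contaminant"` per contig),
#'   `realized_completeness` and `realized_contamination` (percent).
#' @export
fragment_to_bin <- function(genome, target_completeness = 100,
                            contaminant_pool = character(),
                            target_contamination = 0,
                            min_contig = 2000, rng_seed = 1) {
  if (target_completeness <= 0 || target_completeness > 100)
    stop("target_completeness must be in (0, 100]")
  if (target_contamination < 0) stop("target_contamination must be >= 0")
  glen <- nchar(genome)
  if (glen < min_contig) stop("genome shorter than min_contig")
  set.seed(rng_seed)
  pieces <- tile_contigs(genome, min_contig)
  if (target_completeness >= 100) {
    keep <- seq_along(pieces)
  } else {
    ord <- sample(seq_along(pieces))
    cum <- cumsum(nchar(pieces[ord]))
    target <- target_completeness / 100 * glen
    n_keep <- which.min(abs(cum - target))
    keep <- ord[seq_len(n_keep)]
  }
  native <- pieces[sort(keep)]
  native_bases <- sum(nchar(native))

  contam <- character()
  if (target_contamination > 0 && length(contaminant_pool) > 0) {
    pool_pieces <- unlist(lapply(sample(contaminant_pool),
                                 tile_contigs, min_contig = min_contig))
    target_bases <- target_contamination / 100 * native_bases
    cum <- cumsum(nchar(pool_pieces))
    n_take <- which.min(abs(c(0, cum) - target_bases)) - 1L
    if (n_take > 0) contam <- pool_pieces[seq_len(n_take)]
  }
  contigs <- c(native, contam)
  names(contigs) <- sprintf("contig_%03d", seq_along(contigs))
  list(contigs = contigs,
       source = rep(c("native", "contaminant"),
                    c(length(native), length(contam))),
       realized_completeness = 100 * native_bases / glen,
       realized_contamination = 100 * sum(nchar(contam)) / native_bases)
}

# Tile a sequence into contigs of random length in [min_contig, 5*min_contig];
# a short terminal remainder is absorbed into the previous contig.
tile_contigs <- function(genome, min_contig) {
  glen <- nchar(genome)
  if (glen < 2L * min_contig) return(genome)
  lens <- integer()
  total <- 0L
  while (total < glen) {
    l <- sample(min_contig:(5L * min_contig), 1L)
    lens <- c(lens, l)
    total <- total + l
  }
  lens[length(lens)] <- lens[length(lens)] - (total - glen)
  if (length(lens) > 1L && lens[length(lens)] < min_contig) {
    lens[length(lens) - 1L] <- lens[length(lens) - 1L] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  substring(genome, starts, ends)
}

#' Design a two-group synthetic community
#'
#' Captures the study conditions of a case-control cohort: per-group sample
#' sizes, baseline species abundances, planted per-species log2 fold changes
#' (case vs control), and the spread of per-sample log-normal noise.
#'
#' @param n_pe,n_hc Samples in the case (PE) and control (HC) group.
#' @param species_ids Character vector of species identifiers.
#' @param base_abundances Positive baseline abundance per species (recycled).
#' @param planted_log2fc Per-species log2 fold change PE vs HC (recycled);
#'   0 means no planted effect.
#' @param noise_sigma Standard deviation of the per-sample perturbation on
#'   the log2-abundance scale.
#' @param seed Integer seed.
#' @return An object of class `community_design`.
#' @export
community_design <- function(n_pe, n_hc, species_ids,
                             base_abundances = 1, planted_log2fc = 0,
                             noise_sigma = 1, seed = 1) {
  stopifnot(n_pe >= 1, n_hc >= 1, length(species_ids) >= 1)
  base_abundances <- rep_len(base_abundances, length(species_ids))
  planted_log2fc <- rep_len(planted_log2fc, length(species_ids))
  if (any(base_abundances <= 0)) stop("base_abundances must all be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_pe = as.integer(n_pe), n_hc = as.integer(n_hc),
                 species_ids = species_ids,
                 base_abundances = setNames(base_abundances, species_ids),
                 planted_log2fc = setNames(planted_log2fc, species_ids),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "community_design")
}

#' Simulate per-sample mapped-read counts
#'
#' For each sample the species cell proportions are the design's baseline
#' abundances, multiplied by `2^planted_log2fc` for PE samples and by
#' per-sample log-normal noise (`2^N(0, noise_sigma)` per species), then
#' normalized.  Read counts are multinomial with probability proportional
#' to proportion times genome length, emulating mapping of a fixed number
#' of reads against a genome catalog: longer genomes soak up more reads,
#' which the depth normalization downstream must undo.
#'
#' @param design A [community_design()].
#' @param genome_lengths Named numeric vector of genome lengths in bp
#'   (names = species ids).
#' @param read_length Read length in bp.
#' @param reads_per_sample Total mapped reads per sample.
#' @return A list with `counts` (samples x species integer matrix), `truth`
#'   (samples x species matrix of true cell proportions), `labels` (factor
#'   PE/HC per sample), `genome_lengths` and `read_length`.
#' @export
simulate_counts <- function(design, genome_lengths, read_length = 150,
                            reads_per_sample = 1e5) {
  stopifnot(inherits(design, "community_design"))
  if (reads_per_sample <= 0) stop("reads_per_sample must be > 0")
  sp <- design$species_ids
  if (!all(sp %in% names(genome_lengths)))
    stop("genome_lengths missing species: ",
         paste(setdiff(sp, names(genome_lengths)), collapse = ", "))
  glen <- genome_lengths[sp]
  n <- design$n_pe + design$n_hc
  labels <- factor(rep(c("PE", "HC"), c(design$n_pe, design$n_hc)),
                   levels = c("HC", "PE"))
  sample_ids <- sprintf("%s%02d", as.character(labels),
                        c(seq_len(design$n_pe), seq_len(design$n_hc)))
  set.seed(design$seed)
  counts <- matrix(0L, n, length(sp), dimnames = list(sample_ids, sp))
  truth <- matrix(0, n, length(sp), dimnames = list(sample_ids, sp))
  log2_base <- log2(design$base_abundances)
  for (i in seq_len(n)) {
    l2 <- log2_base + rnorm(length(sp), 0, design$noise_sigma)
    if (labels[[i]] == "PE") l2 <- l2 + design$planted_log2fc
    a <- 2^l2
    truth[i, ] <- a / sum(a)
    p <- a * glen
    counts[i, ] <- as.integer(rmultinom(1L, reads_per_sample, p / sum(p)))
  }
  list(counts = counts, truth = truth, labels = labels,
       genome_lengths = glen, read_length = read_length)
}

#' Generate a mock gene catalog with KO hits and category map
#'
#' Emulates gene calling plus KEGG annotation: every gene belongs to exactly
#' one genome and carries a true KO; the hit table contains, per gene, the
#' true-KO hit plus optional decoys, with a configurable fraction of genes
#' whose hits all fail the downstream best-hit filter (e-value < 1e-10 and
#' coverage > 50%), so that the filter is genuinely exercised.  KOs are
#' grouped into (possibly overlapping) modules and pathways.
#'
#' @param species_ids Character vector of genome/species ids.
#' @param n_kos Size of the KO universe (> 0).
#' @param genes_per_genome Genes per genome (0 yields empty tables).
#' @param planted_kos Optional named list, KO id -> character vector of
#'   species that exclusively carry that KO (one gene per listed species).
#' @param frac_subthreshold Fraction of genes whose hits all fail the
#'   e-value/coverage filter.
#' @param frac_two_copy Fraction of genes present in two copies.
#' @param n_modules,kos_per_module,n_pathways,kos_per_pathway Category map
#'   shape; categories may overlap (a KO can sit in several).
#' @param seed Integer seed.
#' @return A list with `genes` (gene_id, species_id, ko_true, copy),
#'   `hits` (gene_id, ko, e_value, coverage) and `categories`
#'   (category_id, type, ko).
#' @export
generate_gene_catalog <- function(species_ids, n_kos = 50,
                                  genes_per_genome = 20,
                                  planted_kos = NULL,
                                  frac_subthreshold = 0.1,
                                  frac_two_copy = 0.05,
                                  n_modules = 6, kos_per_module = 4,
                                  n_pathways = 4, kos_per_pathway = 10,
                                  seed = 1) {
  if (n_kos <= 0) stop("n_kos must be > 0")
  set.seed(seed)
  kos <- sprintf("K%05d", seq_len(n_kos))
  planted_ids <- names(planted_kos)
  if (!all(planted_ids %in% kos))
    stop("planted KOs must be drawn from the KO universe")
  free_kos <- setdiff(kos, planted_ids)

  genes <- list()
  gi <- 0L
  for (sp in species_ids) {
    if (genes_per_genome > 0) {
      for (j in seq_len(genes_per_genome)) {
        gi <- gi + 1L
        genes[[gi]] <- data.frame(
          gene_id = sprintf("%s_g%04d", sp, j), species_id = sp,
          ko_true = sample(free_kos, 1L),
          copy = if (runif(1) < frac_two_copy) 2L else 1L)
      }
    }
  }
  for (ko in planted_ids) {
    for (sp in planted_kos[[ko]]) {
      gi <- gi + 1L
      genes[[gi]] <- data.frame(
        gene_id = sprintf("%s_planted_%s", sp, ko), species_id = sp,
        ko_true = ko, copy = 1L)
    }
  }
  genes <- if (gi > 0) do.call(rbind, genes) else
    data.frame(gene_id = character(), species_id = character(),
               ko_true = character(), copy = integer())

  hits <- list()
  if (nrow(genes) > 0) {
    fail <- runif(nrow(genes)) < frac_subthreshold
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (fail[[i]]) {
        # all hits below threshold: weak e-value or short coverage
        hits[[i]] <- data.frame(
          gene_id = g$gene_id, ko = g$ko_true,
          e_value = if (runif(1) < 0.5) 10^-runif(1, 2, 9) else
            10^-runif(1, 12, 40),
          coverage = if (runif(1) < 0.5) runif(1, 0.55, 0.95) else
            runif(1, 0.1, 0.5))
        # make sure at least one criterion fails
        if (hits[[i]]$e_value < 1e-10 && hits[[i]]$coverage > 0.5)
          hits[[i]]$coverage <- runif(1, 0.1, 0.5)
      } else {
        h <- data.frame(gene_id = g$gene_id, ko = g$ko_true,
                        e_value = 10^-runif(1, 12, 40),
                        coverage = runif(1, 0.55, 0.95))
        if (runif(1) < 0.3) {  # a worse decoy hit
          h <- rbind(h, data.frame(gene_id = g$gene_id,
                                   ko = sample(kos, 1L),
                                   e_value = h$e_value * 10^runif(1, 1, 5),
                                   coverage = runif(1, 0.5, 0.9)))
        }
        hits[[i]] <- h
      }
    }
  }
  hits <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(gene_id = character(), ko = character(),
               e_value = numeric(), coverage = numeric())
  rownames(hits) <- NULL

  categories <- list()
  if (nrow(genes) > 0) {
    for (m in seq_len(n_modules)) {
      member <- sample(kos, min(kos_per_module, n_kos))
      categories[[length(categories) + 1L]] <- data.frame(
        category_id = sprintf("M%05d", m), type = "module", ko = member)
    }
    for (p in seq_len(n_pathways)) {
      member <- sample(kos, min(kos_per_pathway, n_kos))
      categories[[length(categories) + 1L]] <- data.frame(
        category_id = sprintf("map%05d", p), type = "pathway", ko = member)
    }
  }
  categories <- if (length(categories) > 0) do.call(rbind, categories) else
    data.frame(category_id = character(), type = character(),
               ko = character())
  rownames(categories) <- NULL
  list(genes = genes, hits = hits, categories = categories)
}
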