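# Pipeline orchestration: one validated configuration drives the chain
# fixtures -> refine -> derep -> profile -> functions -> stats -> classify,
# with mtime+hash stage caching and a run manifest.

CONFIG_DEFAULTS <- list(
  out_dir = NULL, seed = 1L,
  # synthetic community shape
  n_pe = 40L, n_hc = 37L, n_species = 10L, mags_per_species = 3L,
  genome_length = 300000L, within_divergence = 0.01, gc_target = 0.45,
  n_planted = 4L, planted_log2fc = 1.5, noise_sigma = 1,
  reads_per_sample = 100000L, read_length = 150L,
  genes_per_genome = 20L, n_kos = 50L,
  # thresholds (the audited parameter record)
  depth_tol = 0.10, gc_tol = 0.02, qs_min = 60, min_total_size = 200000,
  min_contig = 2000L, ani_threshold = 95, k = 21L, sketch_size = 5000L,
  ko_evalue = 1e-10, ko_coverage = 0.5,
  n_perm = 1000L, n_trees = 1000L, alpha = 0.05)

#' Build and validate a pipeline configuration
#'
#' All tunable thresholds of the chain live in one audited record; unknown
#' keys are rejected and every threshold is range-checked.  Defaults follow
#' the analysis conventions the package implements: depth tolerance 10%,
#' GC tolerance 0.02, QS minimum 60, 95% ANI, KO filter e-value 1e-10 and
#' coverage 0.5, 1000 permutations, 1000 trees, alpha 0.05.
#'
#' @param out_dir Output directory for all stage outputs.
#' @param ... Overrides for any default (see `magprof:::CONFIG_DEFAULTS`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, ...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, overrides)
  cfg$out_dir <- out_dir
  with(cfg, {
    stopifnot(depth_tol > 0, depth_tol < 1, gc_tol > 0, gc_tol < 1,
              qs_min >= 0, qs_min <= 100, min_total_size > 0,
              ani_threshold > 0, ani_threshold <= 100,
              ko_evalue > 0, ko_coverage >= 0, ko_coverage < 1,
              n_perm >= 1, n_trees >= 1, alpha > 0, alpha < 1,
              n_pe >= 1, n_hc >= 1, n_species >= 2, noise_sigma >= 0,
              genome_length > min_contig)
  })
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults;
#'   must contain `out_dir`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  if (is.null(vals$out_dir)) stop("configuration must set out_dir")
  do.call(pipeline_config, vals)
}

#' Hash of a configuration (for output provenance headers)
#'
#' @param config A [pipeline_config()].
#' @return Character md5 hash of the deparsed configuration.
#' @export
config_hash <- function(config) {
  cfg <- config[setdiff(sort(names(config)), "out_dir")]  # location-free
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

pipe_path <- function(config, ...) file.path(config$out_dir, ...)

stage_fresh <- function(config, outputs, deps) {
  out <- pipe_path(config, outputs)
  if (!all(file.exists(out))) return(FALSE)
  if (length(deps) == 0) return(TRUE)
  dep <- pipe_path(config, deps)
  all(file.exists(dep)) &&
    max(file.mtime(dep)) <= min(file.mtime(out))
}

#' Run the full analysis chain
#'
#' Executes the stages `fixtures`, `refine`, `derep`, `profile`,
#' `functions`, `stats`, `classify` in dependency order; a stage is skipped
#' when all of its outputs exist and are newer than its inputs, unless
#' `force`.  Every output TSV carries a header comment naming its stage and
#' the configuration hash; the run manifest records which stages ran.
#'
#' @param config A [pipeline_config()].
#' @param force Recompute all stages regardless of caching.
#' @param stages Optional subset of stage names to run (dependencies are
#'   not auto-added; upstream outputs must already exist).
#' @return Invisibly, the manifest data.frame (also written to
#'   `manifest.tsv`).
#' @export
run_pipeline <- function(config, force = FALSE, stages = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(pipe_path(config, "bins"), showWarnings = FALSE)
  dir.create(pipe_path(config, "refined_bins"), showWarnings = FALSE)
  hash <- config_hash(config)

  registry <- list(
    fixtures = list(fn = stage_fixtures, deps = character(),
                    outputs = c("quality.tsv", "taxonomy.tsv", "counts.tsv",
                                "truth_proportions.tsv", "labels.tsv",
                                "genome_lengths.tsv", "genes.tsv",
                                "hits.tsv", "categories.tsv")),
    refine = list(fn = stage_refine, deps = c("quality.tsv", "taxonomy.tsv",
                                              "counts.tsv"),
                  outputs = "refined_bins.tsv"),
    derep = list(fn = stage_derep, deps = "refined_bins.tsv",
                 outputs = c("clusters.tsv", "membership.tsv")),
    profile = list(fn = stage_profile,
                   deps = c("clusters.tsv", "counts.tsv",
                            "genome_lengths.tsv"),
                   outputs = c("abundance_species.tsv",
                               "abundance_family.tsv",
                               "abundance_phylum.tsv", "diversity.tsv",
                               "rarefaction.tsv")),
    functions = list(fn = stage_functions,
                     deps = c("abundance_species.tsv", "genes.tsv",
                              "hits.tsv", "categories.tsv"),
                     outputs = c("ko_assignments.tsv", "abundance_ko.tsv",
                                 "abundance_module.tsv",
                                 "abundance_pathway.tsv")),
    stats = list(fn = stage_stats,
                 deps = c("abundance_species.tsv", "abundance_ko.tsv",
                          "labels.tsv"),
                 outputs = c("bray_curtis.tsv", "pcoa.tsv", "permanova.tsv",
                             "differential_species.tsv",
                             "differential_ko.tsv")),
    classify = list(fn = stage_classify,
                    deps = c("abundance_species.tsv", "labels.tsv"),
                    outputs = c("classifier_report.tsv", "roc_points.tsv",
                                "top_features.tsv")))
  if (is.null(stages)) stages <- names(registry)
  unknown <- setdiff(stages, names(registry))
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))

  manifest <- list()
  for (nm in intersect(names(registry), stages)) {
    st <- registry[[nm]]
    missing_deps <- st$deps[!file.exists(pipe_path(config, st$deps))]
    fresh <- !force && stage_fresh(config, st$outputs, st$deps)
    if (!fresh && length(missing_deps) > 0)
      stop("stage '", nm, "' is missing upstream output(s): ",
           paste(missing_deps, collapse = ", "))
    if (!fresh) st$fn(config, hash)
    dep_hash <- if (length(st$deps) > 0)
      paste(substr(tools::md5sum(pipe_path(config, st$deps)), 1, 8),
            collapse = ",") else ""
    manifest[[nm]] <- data.frame(
      stage = nm, ran = !fresh, seed = config$seed, params_hash = hash,
      input_hashes = dep_hash,
      outputs = paste(st$outputs, collapse = ","))
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  write_stage_tsv(manifest, pipe_path(config, "manifest.tsv"),
                  stage = "manifest", params_hash = hash)
  invisible(manifest)
}

# -- stage implementations ---------------------------------------------------

# ground-truth community + bins + counts + gene catalog, all written to disk
stage_fixtures <- function(config, hash) {
  set.seed(config$seed)
  sim <- simulate_species_genomes(
    n_species = config$n_species,
    mags_per_species = config$mags_per_species,
    genome_length = config$genome_length,
    within_divergence = config$within_divergence,
    gc_target = config$gc_target,
    seed = config$seed)
  species <- names(sim$lineages)

  # planted between-group effects: half up in PE, half up in HC
  n_pl <- min(config$n_planted, config$n_species)
  planted <- setNames(numeric(length(species)), species)
  up <- species[seq_len(ceiling(n_pl / 2))]
  down <- if (n_pl > length(up))
    species[seq.int(length(up) + 1L, n_pl)] else character()
  planted[up] <- config$planted_log2fc
  planted[down] <- -config$planted_log2fc

  base <- rlnorm(length(species), meanlog = 0, sdlog = 1)
  design <- community_design(config$n_pe, config$n_hc, species,
                             base_abundances = base,
                             planted_log2fc = planted,
                             noise_sigma = config$noise_sigma,
                             seed = config$seed)
  glens <- setNames(rep(config$genome_length, length(species)), species)
  cnt <- simulate_counts(design, glens, config$read_length,
                         config$reads_per_sample)

  # bins: each MAG lands in one sample; the first MAG of each species is
  # split into two compatible raw bins so the merge stage has work to do
  set.seed(config$seed + 1L)
  samples <- rownames(cnt$counts)
  qrows <- list()
  trows <- list()
  for (i in seq_len(nrow(sim$truth))) {
    mag <- sim$truth$mag_id[i]
    sp <- sim$truth$species_id[i]
    smp <- sample(samples, 1L)
    first <- grepl("_MAG01$", mag)
    comp <- if (first) runif(1, 90, 99) else runif(1, 55, 99)
    contam <- if (first) runif(1, 0, 2) else min(rexp(1, 2 / 3), 10)
    bin <- fragment_to_bin(sim$genomes[[mag]], comp,
                           contaminant_pool = sim$genomes[
                             sim$truth$mag_id[sim$truth$species_id != sp]],
                           target_contamination = contam,
                           min_contig = config$min_contig,
                           rng_seed = sample.int(2^31 - 1, 1))
    depth <- compute_depth(cnt$counts[smp, sp], config$read_length,
                           sum(nchar(bin$contigs)))
    parts <- if (first && length(bin$contigs) >= 4) {
      half <- seq_len(floor(length(bin$contigs) / 2))
      list(a = bin$contigs[half], b = bin$contigs[-half])
    } else list(a = bin$contigs)
    for (pn in names(parts)) {
      bid <- if (length(parts) > 1) paste0(mag, "_", pn) else mag
      write_fasta(parts[[pn]], pipe_path(config, "bins",
                                         paste0(bid, ".fasta")))
      # split parts carry the parent bin's quality estimates so that the
      # length-weighted recombination of the re-merged bin reproduces the
      # parent's quality (stands in for an external re-estimate)
      qrows[[bid]] <- data.frame(
        bin_id = bid, sample_id = smp,
        completeness = bin$realized_completeness,
        contamination = bin$realized_contamination,
        depth = depth)
      trows[[bid]] <- data.frame(bin_id = bid,
                                 lineage = sim$lineages[[sp]])
    }
  }
  write_stage_tsv(do.call(rbind, qrows), pipe_path(config, "quality.tsv"),
                  "fixtures", hash)
  write_stage_tsv(do.call(rbind, trows), pipe_path(config, "taxonomy.tsv"),
                  "fixtures", hash)
  write_matrix_tsv(cnt$counts, pipe_path(config, "counts.tsv"),
                   "fixtures", hash)
  write_matrix_tsv(cnt$truth, pipe_path(config, "truth_proportions.tsv"),
                   "fixtures", hash)
  write_stage_tsv(data.frame(sample_id = samples,
                             group = as.character(cnt$labels)),
                  pipe_path(config, "labels.tsv"), "fixtures", hash)
  write_stage_tsv(data.frame(species_id = species, length = glens,
                             lineage = unname(sim$lineages),
                             planted_log2fc = unname(planted)),
                  pipe_path(config, "genome_lengths.tsv"), "fixtures", hash)

  cat <- generate_gene_catalog(
    species, n_kos = config$n_kos,
    genes_per_genome = config$genes_per_genome,
    planted_kos = planted_ko_map(up, down, config$n_kos),
    seed = config$seed)
  write_stage_tsv(cat$genes, pipe_path(config, "genes.tsv"),
                  "fixtures", hash)
  write_stage_tsv(cat$hits, pipe_path(config, "hits.tsv"), "fixtures", hash)
  write_stage_tsv(cat$categories, pipe_path(config, "categories.tsv"),
                  "fixtures", hash)
}

# the last KOs of the universe are reserved as planted, group-exclusive KOs
planted_ko_map <- function(up, down, n_kos) {
  ids <- sprintf("K%05d", seq.int(n_kos - 3L, n_kos))
  out <- list(up, up, down, down)
  names(out) <- ids
  out[vapply(out, length, integer(1)) > 0]
}

stage_refine <- function(config, hash) {
  quality <- read_stage_tsv(pipe_path(config, "quality.tsv"))
  taxonomy <- read_stage_tsv(pipe_path(config, "taxonomy.tsv"))
  bins <- lapply(seq_len(nrow(quality)), function(i) {
    q <- quality[i, ]
    new_bin(q$bin_id, q$sample_id,
            read_fasta(pipe_path(config, "bins",
                                 paste0(q$bin_id, ".fasta"))),
            depth = q$depth,
            lineage = taxonomy$lineage[match(q$bin_id, taxonomy$bin_id)],
            completeness = q$completeness, contamination = q$contamination,
            qs_min = config$qs_min)
  })
  refined <- unlist(lapply(split(bins, quality$sample_id), merge_bins,
                           depth_tol = config$depth_tol,
                           gc_tol = config$gc_tol,
                           qs_min = config$qs_min),
                    recursive = FALSE)
  manifest <- filter_bins(bin_manifest(refined),
                          min_total_size = config$min_total_size,
                          qs_min = config$qs_min)
  for (b in refined) {
    if (manifest$derep_eligible[match(b$bin_id, manifest$bin_id)])
      write_fasta(b$contigs, pipe_path(config, "refined_bins",
                                       paste0(gsub("[^A-Za-z0-9_+.-]", "_",
                                                   b$bin_id), ".fasta")))
  }
  write_stage_tsv(manifest, pipe_path(config, "refined_bins.tsv"),
                  "refine", hash)
}

stage_derep <- function(config, hash) {
  manifest <- read_stage_tsv(pipe_path(config, "refined_bins.tsv"))
  eligible <- manifest[manifest$derep_eligible, ]
  if (nrow(eligible) == 0) stop("no dereplication-eligible bins")
  seqs <- lapply(eligible$bin_id, function(id) {
    read_fasta(pipe_path(config, "refined_bins",
                         paste0(gsub("[^A-Za-z0-9_+.-]", "_", id),
                                ".fasta")))
  })
  sketches <- setNames(lapply(seqs, function(s)
    sketch_genome(paste0(s, collapse = ""), k = config$k,
                  sketch_size = config$sketch_size)), eligible$bin_id)
  quality <- data.frame(mag_id = eligible$bin_id, qs = eligible$qs,
                        total_length = eligible$total_length,
                        lineage = eligible$lineage)
  cl <- cluster_species(sketches, quality,
                        ani_threshold = config$ani_threshold)
  write_stage_tsv(cl$clusters, pipe_path(config, "clusters.tsv"),
                  "derep", hash)
  write_stage_tsv(data.frame(mag_id = names(cl$membership),
                             species_id = unname(cl$membership)),
                  pipe_path(config, "membership.tsv"), "derep", hash)
}

# collapse true-species counts onto recovered clusters (labelled by the
# representative's species-rank name for interpretability downstream)
cluster_counts <- function(config) {
  clusters <- read_stage_tsv(pipe_path(config, "clusters.tsv"))
  counts <- read_matrix_tsv(pipe_path(config, "counts.tsv"))
  glen_tab <- read_stage_tsv(pipe_path(config, "genome_lengths.tsv"))
  label <- lineage_rank(clusters$lineage, "species")
  label[!nzchar(label)] <- clusters$species_id[!nzchar(label)]
  present <- unique(intersect(label, colnames(counts)))
  dropped <- setdiff(colnames(counts), present)
  if (length(dropped) > 0)
    message("species without a recovered cluster dropped from profiling: ",
            paste(dropped, collapse = ", "))
  list(counts = counts[, present, drop = FALSE],
       genome_lengths = setNames(glen_tab$length,
                                 glen_tab$species_id)[present],
       lineages = setNames(glen_tab$lineage, glen_tab$species_id)[present])
}

stage_profile <- function(config, hash) {
  cc <- cluster_counts(config)
  labels <- read_stage_tsv(pipe_path(config, "labels.tsv"))
  depths <- depth_from_counts(cc$counts, cc$genome_lengths,
                              config$read_length)
  ab <- relative_abundance(depths)
  write_matrix_tsv(ab, pipe_path(config, "abundance_species.tsv"),
                   "profile", hash)
  for (rank in c("family", "phylum"))
    write_matrix_tsv(rollup_taxa(ab, cc$lineages, rank),
                     pipe_path(config, paste0("abundance_", rank, ".tsv")),
                     "profile", hash)
  div <- data.frame(sample_id = rownames(ab),
                    shannon = diversity_index(ab, "shannon"),
                    simpson = diversity_index(ab, "simpson"))
  write_stage_tsv(div, pipe_path(config, "diversity.tsv"), "profile", hash)
  rc <- rarefaction_curve(ab, labels$group[match(rownames(ab),
                                                 labels$sample_id)],
                          n_reps = 30, rng_seed = config$seed)
  write_stage_tsv(rc, pipe_path(config, "rarefaction.tsv"), "profile", hash)
}

stage_functions <- function(config, hash) {
  ab <- read_matrix_tsv(pipe_path(config, "abundance_species.tsv"))
  genes <- read_stage_tsv(pipe_path(config, "genes.tsv"))
  hits <- read_stage_tsv(pipe_path(config, "hits.tsv"))
  categories <- read_stage_tsv(pipe_path(config, "categories.tsv"))
  genes <- genes[genes$species_id %in% colnames(ab), , drop = FALSE]
  assignments <- assign_ko(hits, evalue_max = config$ko_evalue,
                           coverage_min = config$ko_coverage)
  assignments <- assignments[assignments$gene_id %in% genes$gene_id, ,
                             drop = FALSE]
  write_stage_tsv(assignments, pipe_path(config, "ko_assignments.tsv"),
                  "functions", hash)
  ga <- gene_abundance(ab, genes)
  write_matrix_tsv(category_abundance(ga, assignments),
                   pipe_path(config, "abundance_ko.tsv"), "functions", hash)
  for (ty in c("module", "pathway")) {
    cats <- categories[categories$type == ty, , drop = FALSE]
    m <- suppressWarnings(
      category_abundance(ga, assignments, cats, level_tag = ty))
    write_matrix_tsv(m, pipe_path(config,
                                  paste0("abundance_", ty, ".tsv")),
                     "functions", hash)
  }
}

stage_stats <- function(config, hash) {
  ab <- read_matrix_tsv(pipe_path(config, "abundance_species.tsv"))
  ko <- read_matrix_tsv(pipe_path(config, "abundance_ko.tsv"))
  labels <- read_stage_tsv(pipe_path(config, "labels.tsv"))
  grp <- labels$group[match(rownames(ab), labels$sample_id)]
  d <- bray_curtis(ab)
  dm <- as.matrix(d)
  write_stage_tsv(data.frame(sample_id = rownames(dm), dm,
                             check.names = FALSE),
                  pipe_path(config, "bray_curtis.tsv"), "stats", hash)
  pc <- pcoa(d, n_axes = 2)
  write_stage_tsv(data.frame(sample_id = rownames(pc$coordinates),
                             pc$coordinates,
                             group = grp, check.names = FALSE),
                  pipe_path(config, "pcoa.tsv"), "stats", hash)
  pm <- permanova(d, grp, n_perm = config$n_perm, rng_seed = config$seed)
  write_stage_tsv(data.frame(pseudo_F = pm$pseudo_F, r2 = pm$r2,
                             p_perm = pm$p_perm, n_perm = pm$n_perm),
                  pipe_path(config, "permanova.tsv"), "stats", hash)
  write_stage_tsv(differential_features(ab, grp, alpha = config$alpha,
                                        use_q = FALSE),
                  pipe_path(config, "differential_species.tsv"),
                  "stats", hash)
  write_stage_tsv(differential_features(ko, grp, alpha = config$alpha,
                                        use_q = TRUE),
                  pipe_path(config, "differential_ko.tsv"), "stats", hash)
}

stage_classify <- function(config, hash) {
  ab <- read_matrix_tsv(pipe_path(config, "abundance_species.tsv"))
  labels <- read_stage_tsv(pipe_path(config, "labels.tsv"))
  grp <- labels$group[match(rownames(ab), labels$sample_id)]
  rep <- classifier_report(ab, grp, n_trees = config$n_trees,
                           rng_seed = config$seed)
  write_stage_tsv(data.frame(sample_id = names(rep$scores),
                             score = unname(rep$scores), group = grp,
                             auc = rep$auc, ci_low = rep$ci_low,
                             ci_high = rep$ci_high),
                  pipe_path(config, "classifier_report.tsv"),
                  "classify", hash)
  write_stage_tsv(rep$roc_points, pipe_path(config, "roc_points.tsv"),
                  "classify", hash)
  write_stage_tsv(rep$top_features, pipe_path(config, "top_features.tsv"),
                  "classify", hash)
}
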