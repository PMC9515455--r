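test_that("de novo genomes hit the requested length and GC", {
  spec <- genome_spec("g1", 200000, gc_target = 0.5)
  g <- generate_genome(spec, 42)
  expect_equal(nchar(g), 200000)
  gc <- compute_gc(g)
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
  # bit-reproducible under the same seed
  expect_identical(g, generate_genome(spec, 42))
})

test_that("derived genomes realize the requested divergence", {
  parent <- generate_genome(genome_spec("p", 100000, 0.45), 1)
  child0 <- generate_genome(genome_spec("c0", 100000, 0.45, parent_id = "p",
                                        divergence = 0),
                            2, genomes = list(p = parent))
  expect_identical(child0, parent)
  child <- generate_genome(genome_spec("c", 100000, 0.45, parent_id = "p",
                                       divergence = 0.05),
                           3, genomes = list(p = parent))
  h <- 1 - exact_identity(parent, child) / 100
  expect_gt(h, 0.045)
  expect_lt(h, 0.055)
  expect_error(generate_genome(genome_spec("x", 100, 0.5, parent_id = "nope",
                                           divergence = 0.1),
                               1, genomes = list(p = parent)),
               "unknown parent_id")
})

test_that("genome_spec validates its invariants", {
  expect_error(genome_spec("a", 0), "positive")
  expect_error(genome_spec("a", 10, gc_target = 1.2), "gc_target")
  expect_error(genome_spec("a", 10, divergence = -1), "divergence")
  expect_error(genome_spec("a", 10, lineage = "d__;p__"), "7 rank")
})

test_that("fragment_to_bin respects completeness, contamination and contig floor", {
  genome <- generate_genome(genome_spec("g", 1000000, 0.45), 5)
  full <- fragment_to_bin(genome, 100, min_contig = 2000, rng_seed = 1)
  expect_identical(paste0(full$contigs, collapse = ""), genome)
  expect_true(all(full$source == "native"))

  half <- fragment_to_bin(genome, 50, min_contig = 2000, rng_seed = 2)
  retained <- sum(nchar(half$contigs))
  expect_gte(retained, 480000)
  expect_lte(retained, 520000)
  expect_true(all(nchar(half$contigs) >= 2000))

  pool <- generate_genome(genome_spec("f", 200000, 0.45), 6)
  dirty <- fragment_to_bin(genome, 80, contaminant_pool = pool,
                           target_contamination = 5, min_contig = 2000,
                           rng_seed = 3)
  expect_gt(dirty$realized_contamination, 3)
  expect_lt(dirty$realized_contamination, 7)
  expect_true(all(nchar(dirty$contigs) >= 2000))
  expect_error(fragment_to_bin("ACGT", 100, min_contig = 2000),
               "shorter than min_contig")
})

test_that("simulate_counts follows abundance x length and plants effects", {
  sp <- c("A", "B")
  # single species: all reads land on it
  d1 <- community_design(2, 2, "A", seed = 1)
  c1 <- simulate_counts(d1, c(A = 1e6), reads_per_sample = 1000)
  expect_true(all(c1$counts[, "A"] == 1000))

  # equal abundance, equal length: 50:50 within a generous binomial CI
  d2 <- community_design(5, 5, sp, base_abundances = 1, noise_sigma = 0,
                         seed = 2)
  c2 <- simulate_counts(d2, c(A = 1e6, B = 1e6), reads_per_sample = 1e5)
  frac <- c2$counts[, "A"] / rowSums(c2$counts)
  expect_true(all(abs(frac - 0.5) < 0.01))

  # planted +2 log2 effect recovered in the group mean ratio
  cnt <- planted_community(20, 20, 30, planted = c(2, numeric(29)),
                           noise_sigma = 1, seed = 3)
  ab <- relative_abundance(depth_from_counts(cnt$counts,
                                             cnt$genome_lengths, 150))
  ratio <- log2(mean(ab[cnt$labels == "PE", "SP001"]) /
                  mean(ab[cnt$labels == "HC", "SP001"]))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
  # per-sample counts always sum to the read budget
  expect_true(all(rowSums(cnt$counts) == 1e5))
})

test_that("gene catalog exercises the KO filter and plants exclusive KOs", {
  sp <- sprintf("SP%03d", 1:6)
  empty <- generate_gene_catalog(sp, n_kos = 10, genes_per_genome = 0,
                                 seed = 1)
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$hits), 0)

  cat <- generate_gene_catalog(sp, n_kos = 40, genes_per_genome = 50,
                               frac_subthreshold = 0.1,
                               planted_kos = list(K00040 = c("SP001",
                                                             "SP002")),
                               seed = 7)
  expect_true(all(table(cat$genes$gene_id) == 1))
  asg <- assign_ko(cat$hits)
  frac_fail <- mean(is.na(asg$ko))
  expect_gt(frac_fail, 0.05)
  expect_lt(frac_fail, 0.15)
  # planted KO is carried only by the named species
  carriers <- cat$genes$species_id[cat$genes$ko_true == "K00040"]
  expect_setequal(unique(carriers), c("SP001", "SP002"))
  # no unplanted gene received the reserved KO
  expect_false(any(cat$genes$ko_true[!grepl("planted", cat$genes$gene_id)] ==
                     "K00040"))
})

test_that("synthetic lineages are well-formed and hierarchical", {
  lin <- synthetic_lineages(20, seed = 3)
  expect_length(lin, 20)
  for (l in lin) expect_length(strsplit(l, ";")[[1]], 7)
  # one genus never spans two families
  g <- lineage_rank(lin, "genus")
  f <- lineage_rank(lin, "family")
  expect_true(all(tapply(f, g, function(x) length(unique(x))) == 1))
})
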