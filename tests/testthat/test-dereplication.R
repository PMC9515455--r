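test_that("sketches are deterministic, canonical and bounded", {
  g <- generate_genome(genome_spec("g", 5000, 0.5), 1)
  s1 <- sketch_genome(g, k = 21, sketch_size = 1000)
  s2 <- sketch_genome(g, k = 21, sketch_size = 1000)
  expect_identical(s1$hashes, s2$hashes)
  expect_lte(length(s1$hashes), 1000)
  # reverse complement yields the identical sketch (canonical k-mers)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  expect_identical(sketch_genome(rc, 21, 1000)$hashes, s1$hashes)
  expect_error(sketch_genome("ACGT", k = 21), "shorter than k")
})

test_that("sketch covers the full k-mer set when sketch_size is large", {
  g <- generate_genome(genome_spec("g", 2000, 0.5), 2)
  s <- sketch_genome(g, k = 15, sketch_size = 1e6)
  # brute-force canonical k-mer set
  kmers <- substring(g, 1:(2000 - 14), 15:2000)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- unique(pmin(kmers, rc))
  expect_equal(s$n_kmers, length(canon))
  expect_equal(length(s$hashes), length(canon))
})

test_that("sketch ANI tracks exact identity on substitution-only pairs", {
  parent <- generate_genome(genome_spec("p", 500000, 0.45), 3)
  child <- generate_genome(genome_spec("c", 500000, 0.45, parent_id = "p",
                                       divergence = 0.03),
                           4, genomes = list(p = parent))
  ani <- estimate_ani(sketch_genome(parent), sketch_genome(child))
  expect_gt(ani, 96.3)
  expect_lt(ani, 97.7)
  expect_equal(estimate_ani(sketch_genome(parent), sketch_genome(parent)),
               100)
  # unrelated genomes score far below the clustering threshold
  other <- generate_genome(genome_spec("o", 500000, 0.45), 5)
  expect_lt(estimate_ani(sketch_genome(parent), sketch_genome(other)), 80)
})

test_that("sketch ANI agrees with exact global-alignment identity", {
  # substitution-only pairs: the optimal global alignment is ungapped, so
  # exact identity is positional; confirm that equivalence with an actual
  # Needleman-Wunsch alignment on a few pairs, then use it as the oracle
  set.seed(6)
  parent <- generate_genome(genome_spec("p", 10000, 0.45), 6)
  for (i in 1:5) {
    d <- runif(1, 0.005, 0.05)
    child <- generate_genome(genome_spec("c", 10000, 0.45, parent_id = "p",
                                         divergence = d),
                             sample.int(1e6, 1), genomes = list(p = parent))
    oracle <- exact_identity(parent, child)
    if (i == 1) {
      aln <- Biostrings::pairwiseAlignment(parent, child, type = "global")
      expect_equal(Biostrings::pid(aln), oracle, tolerance = 1e-6)
    }
    ani <- estimate_ani(sketch_genome(parent), sketch_genome(child))
    expect_lt(abs(ani - oracle), 1.0)
  }
})

test_that("greedy clustering follows the QS order and ANI threshold", {
  # hand-traceable greedy rule on stubbed ANI values via tiny genomes:
  # build three genomes where AB ANI > 95 but AC, BC < 95
  anc <- generate_genome(genome_spec("A", 50000, 0.45), 7)
  b <- generate_genome(genome_spec("B", 50000, 0.45, parent_id = "A",
                                   divergence = 0.01),
                       8, genomes = list(A = anc))
  c_ <- generate_genome(genome_spec("C", 50000, 0.45, parent_id = "A",
                                    divergence = 0.12),
                        9, genomes = list(A = anc))
  sk <- list(A = sketch_genome(anc), B = sketch_genome(b),
             C = sketch_genome(c_))
  qual <- data.frame(mag_id = c("A", "B", "C"), qs = c(90, 80, 70),
                     total_length = 50000)
  cl <- cluster_species(sk, qual, ani_threshold = 95)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(unname(cl$membership[["A"]]), unname(cl$membership[["B"]]))
  expect_false(cl$membership[["C"]] == cl$membership[["A"]])
  # every MAG in exactly one cluster
  expect_setequal(names(cl$membership), c("A", "B", "C"))

  # all mutually similar -> one cluster
  b2 <- generate_genome(genome_spec("B2", 50000, 0.45, parent_id = "A",
                                    divergence = 0.015),
                        10, genomes = list(A = anc))
  sk3 <- list(A = sk$A, B = sk$B, B2 = sketch_genome(b2))
  qual3 <- data.frame(mag_id = c("A", "B", "B2"), qs = c(90, 80, 70),
                      total_length = 50000)
  expect_equal(nrow(cluster_species(sk3, qual3)$clusters), 1)
})

test_that("cluster count is monotone in the ANI threshold", {
  sim <- simulate_species_genomes(n_species = 4, mags_per_species = 3,
                                  genome_length = 15000,
                                  within_divergence = 0.03, seed = 11)
  sk <- lapply(sim$genomes, sketch_genome)
  qual <- data.frame(mag_id = sim$truth$mag_id,
                     qs = 90 - seq_len(nrow(sim$truth)),
                     total_length = 15000)
  counts <- vapply(c(90, 95, 99), function(th)
    nrow(cluster_species(sk, qual, ani_threshold = th)$clusters),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("representative selection maximizes QS with documented tie-breaks", {
  qual <- data.frame(mag_id = c("A", "B", "C"), qs = c(80, 90, 90),
                     total_length = c(2e6, 2e6, 3e6))
  expect_equal(select_representative("A", qual), "A")
  expect_equal(select_representative(c("A", "B"), qual), "B")
  expect_equal(select_representative(c("B", "C"), qual), "C")  # longer wins
  qual2 <- data.frame(mag_id = c("B", "A"), qs = 90, total_length = 2e6)
  expect_equal(select_representative(c("B", "A"), qual2), "A")  # lexicographic
  expect_error(select_representative(character(), qual), "empty cluster")
})
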