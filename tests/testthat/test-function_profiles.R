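test_that("KO assignment enforces the best-hit filter", {
  one <- data.frame(gene_id = "g1", ko = "K1", e_value = 1e-12,
                    coverage = 0.6)
  expect_equal(assign_ko(one)$ko, "K1")
  weak <- data.frame(gene_id = "g1", ko = "K1", e_value = 1e-9,
                     coverage = 0.9)
  expect_true(is.na(assign_ko(weak)$ko))
  short <- data.frame(gene_id = "g1", ko = "K1", e_value = 1e-30,
                      coverage = 0.5)  # coverage must strictly exceed 0.5
  expect_true(is.na(assign_ko(short)$ko))
  # minimal e-value wins among survivors
  hits <- data.frame(gene_id = "g1", ko = c("K1", "K2"),
                     e_value = c(1e-20, 1e-30), coverage = c(0.6, 0.55))
  expect_equal(assign_ko(hits)$ko, "K2")
  # e-value tie: higher coverage, then lexicographic KO
  tie <- data.frame(gene_id = "g1", ko = c("K2", "K1"),
                    e_value = 1e-20, coverage = c(0.8, 0.6))
  expect_equal(assign_ko(tie)$ko, "K2")
  tie2 <- data.frame(gene_id = "g1", ko = c("K2", "K1"),
                     e_value = 1e-20, coverage = 0.8)
  expect_equal(assign_ko(tie2)$ko, "K1")
  # boundary: e-value exactly 1e-10 fails the strict rule
  edge <- data.frame(gene_id = "g1", ko = "K1", e_value = 1e-10,
                     coverage = 0.9)
  expect_true(is.na(assign_ko(edge)$ko))
})

test_that("gene abundance propagates species abundance times copy number", {
  fx <- tiny_function_fixture()
  ga <- gene_abundance(fx$ab, fx$genes)
  expect_equal(ga[, "gA1"], c(s1 = 0.5, s2 = 0.2))
  expect_equal(ga[, "gA2"], c(s1 = 1.0, s2 = 0.4))  # two-copy gene
  # absent species -> zero gene abundance
  ab0 <- abundance_matrix(matrix(c(0, 1), 1, 2,
                                 dimnames = list("s", c("A", "B"))),
                          "species")
  ga0 <- gene_abundance(ab0, data.frame(gene_id = "gA1", species_id = "A"))
  expect_equal(unname(ga0[, "gA1"]), 0)
  orphan <- data.frame(gene_id = "gX", species_id = "NOPE")
  expect_error(gene_abundance(fx$ab, orphan), "gX")
})

test_that("category abundance sums member genes; overlaps double-count", {
  fx <- tiny_function_fixture()
  ga <- gene_abundance(fx$ab, fx$genes)
  ko <- category_abundance(ga, fx$assignments)
  # K1 <- gA1 + gB1; K2 <- gA2 (x2 copies); K3 <- gC1
  expect_equal(ko[, "K1"], ga[, "gA1"] + ga[, "gB1"])
  expect_equal(ko[, "K2"], ga[, "gA2"])
  cats <- category_abundance(ga, fx$assignments, fx$categories)
  expect_equal(cats[, "M1"], ko[, "K1"] + ko[, "K2"])
  expect_equal(cats[, "M2"], ko[, "K2"] + ko[, "K3"])
  # K2 is counted in both M1 and M2 by design
  expect_equal(sum(cats[1, ]), sum(ko[1, ]) + ko[1, "K2"])
  expect_false(attr(cats, "relative"))
  # linearity: doubling gene abundances doubles every category row
  expect_equal(unclass(category_abundance(ga * 2, fx$assignments,
                                          fx$categories)),
               unclass(cats) * 2)
  # unassigned genes are skipped; empty categories warn with zero rows
  cats2 <- rbind(fx$categories,
                 data.frame(category_id = "M9", ko = "K9"))
  expect_warning(out <- category_abundance(ga, fx$assignments, cats2),
                 "M9")
  expect_true(all(out[, "M9"] == 0))
})

test_that("species contributions sum to one and restrict to subsets", {
  fx <- tiny_function_fixture()
  ga <- gene_abundance(fx$ab, fx$genes)
  sc <- species_contribution("M1", ga, fx$genes, fx$assignments,
                             fx$categories)
  expect_equal(unname(colSums(sc$contribution)), c(1, 1), tolerance = 1e-12)
  # sample s1: A contributes gA1 + gA2 = 1.5, B contributes 0.3 -> 5/6, 1/6
  expect_equal(sc$contribution["A", "s1"], 1.5 / 1.8)
  expect_equal(sc$contribution["B", "s1"], 0.3 / 1.8)
  # single-species category
  sc3 <- species_contribution("K3", ga, fx$genes, fx$assignments)
  expect_true(all(sc3$contribution["C", ] == 1))
  # subset columns sum to less than 1 by the excluded contribution
  sub <- species_contribution("M1", ga, fx$genes, fx$assignments,
                              fx$categories, species_subset = "A")
  expect_equal(unname(colSums(sub$contribution)),
               1 - unname(sc$contribution["B", ]))
})

test_that("zero-abundance samples are flagged, not divided by", {
  ab <- abundance_matrix(matrix(c(1, 0,
                                  0, 1), 2, 2, byrow = TRUE,
                                dimnames = list(c("s1", "s2"),
                                                c("A", "B"))),
                         "species")
  genes <- data.frame(gene_id = "gA", species_id = "A")
  asg <- data.frame(gene_id = "gA", ko = "K1")
  ga <- gene_abundance(ab, genes)
  sc <- species_contribution("K1", ga, genes, asg)
  expect_equal(sc$zero_samples, "s2")
  expect_equal(unname(sc$contribution["A", "s2"]), 0)
})

test_that("planted group-exclusive KOs track their species' abundances", {
  cnt <- planted_community(15, 15, 20, planted = c(1.5, numeric(19)),
                           seed = 9)
  ab <- relative_abundance(depth_from_counts(cnt$counts,
                                             cnt$genome_lengths, 150))
  cat <- generate_gene_catalog(colnames(ab), n_kos = 30,
                               genes_per_genome = 10,
                               planted_kos = list(K00030 = "SP001"),
                               frac_subthreshold = 0, seed = 10)
  ga <- gene_abundance(ab, cat$genes)
  asg <- assign_ko(cat$hits)
  ko <- category_abundance(ga, asg)
  expect_gt(cor(ko[, "K00030"], ab[, "SP001"]), 0.99)
  ratio <- log2(mean(ko[cnt$labels == "PE", "K00030"]) /
                  mean(ko[cnt$labels == "HC", "K00030"]))
  expect_gt(ratio, 0.5)  # inherits the planted positive effect
})
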