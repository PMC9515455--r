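Package: magprof
Title: Metagenome-Assembled Genome Refinement, Dereplication, Profiling
    and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully seeded implementation of a
    shotgun-metagenomics analysis chain for case-control gut microbiome
    cohorts: bin refinement (depth and GC computation, same-sample bin
    merging, quality scoring and MIMAG tier assignment, size and quality
    filtering), species-level dereplication of metagenome-assembled
    genomes (MAGs) at 95% average nucleotide identity using MinHash
    sketches, taxonomic and functional (KEGG orthologue, module and
    pathway) relative-abundance profiling with per-species contribution
    decomposition, community statistics (Bray-Curtis, PCoA, PERMANOVA,
    Mantel, Wilcoxon rank-sum with Benjamini-Hochberg correction), and a
    random-forest disease-status classifier with out-of-bag ROC/AUC.
    Ships a synthetic-community generator with known ground truth so the
    whole chain is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    pROC,
    randomForest,
    stats,
    tools,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
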