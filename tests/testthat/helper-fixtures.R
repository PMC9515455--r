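# Shared fixture builders; everything is generated in code under fixed seeds.

# n x p log-normal null community (no group effect), rows normalized
null_community <- function(n = 40, p = 50, seed = 1, sdlog = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n * p, sdlog = sdlog), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  m / rowSums(m)
}

# two-group community via the package generator; planted_log2fc recycled
planted_community <- function(n_pe = 20, n_hc = 20, n_species = 50,
                              planted = c(1.5, numeric(49)),
                              noise_sigma = 1, seed = 1,
                              reads = 1e5) {
  sp <- sprintf("SP%03d", seq_len(n_species))
  design <- community_design(n_pe, n_hc, sp, base_abundances = 1,
                             planted_log2fc = planted,
                             noise_sigma = noise_sigma, seed = seed)
  glens <- setNames(rep(2.5e6, n_species), sp)
  simulate_counts(design, glens, read_length = 150, reads_per_sample = reads)
}

# independent brute-force Benjamini-Hochberg, straight from the definition:
# q_i = min over thresholds t >= p_i of min(1, m * t / #{p <= t})
brute_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min((m / vapply(ts, function(t) sum(p <= t), numeric(1))) * ts))
  }, numeric(1))
}

# exact identity (percent) between two equal-length substitution-only
# sequences: the optimal global alignment is ungapped, so identity is
# positional
exact_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  100 * mean(av == bv)
}

# small 3-species gene/function fixture with hand-computable sums
tiny_function_fixture <- function() {
  ab <- abundance_matrix(
    matrix(c(0.5, 0.3, 0.2,
             0.2, 0.2, 0.6), 2, 3, byrow = TRUE,
           dimnames = list(c("s1", "s2"), c("A", "B", "C"))),
    level_tag = "species")
  genes <- data.frame(gene_id = c("gA1", "gA2", "gB1", "gC1"),
                      species_id = c("A", "A", "B", "C"),
                      copy = c(1, 2, 1, 1))
  assignments <- data.frame(gene_id = c("gA1", "gA2", "gB1", "gC1"),
                            ko = c("K1", "K2", "K1", "K3"))
  categories <- data.frame(category_id = c("M1", "M1", "M2", "M2"),
                           ko = c("K1", "K2", "K2", "K3"))
  list(ab = ab, genes = genes, assignments = assignments,
       categories = categories)
}
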