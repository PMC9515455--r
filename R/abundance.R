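# Abundance profiling: depth-normalized relative abundance, taxonomic
# roll-ups that conserve mass, Shannon/Simpson diversity, and sample-based
# rarefaction with median/quartile summaries.

#' Tag a samples x features matrix as an abundance matrix
#'
#' A thin wrapper around a numeric matrix carrying the aggregation level
#' (`species`, `phylum`, ..., `ko`, `module`, `pathway`) and whether rows
#' are relative (sum to 1).
#'
#' @param values Numeric samples x features matrix with dimnames.
#' @param level_tag Character level label.
#' @param relative Logical; when `TRUE`, every row must sum to 1 within
#'   1e-9.
#' @return The matrix with class `abundance_matrix` and attributes
#'   `level_tag`, `relative`.
#' @export
abundance_matrix <- function(values, level_tag, relative = TRUE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0)) stop("abundances must be non-negative")
  if (anyDuplicated(colnames(values)))
    stop("feature ids must be unique")
  if (relative && any(abs(rowSums(values) - 1) > 1e-9))
    stop("rows of a relative abundance matrix must sum to 1")
  structure(values, class = c("abundance_matrix", class(values)),
            level_tag = level_tag, relative = relative)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d samples x %d features, level=%s, %s\n",
              nrow(x), ncol(x), attr(x, "level_tag"),
              if (isTRUE(attr(x, "relative"))) "relative" else "unnormalized"))
  invisible(x)
}

#' Depth matrix from mapped-read counts
#'
#' Applies [compute_depth()] per (sample, species) cell: depth = counts *
#' read length / genome length, removing genome-length bias from raw counts.
#'
#' @param counts Samples x species integer matrix of mapped reads.
#' @param genome_lengths Named vector of genome lengths in bp (names cover
#'   the count columns).
#' @param read_length Mean read length in bp.
#' @return Numeric samples x species depth matrix.
#' @export
depth_from_counts <- function(counts, genome_lengths, read_length = 150) {
  missing <- setdiff(colnames(counts), names(genome_lengths))
  if (length(missing) > 0)
    stop("genome_lengths missing: ", paste(missing, collapse = ", "))
  sweep(counts * read_length, 2, genome_lengths[colnames(counts)], "/")
}

#' Species-level relative abundance from depths
#'
#' Per sample, `abundance_i = depth_i / sum(depth)`; rows sum to 1.
#'
#' @param depths Samples x species numeric matrix of depths (>= 0).
#' @return An [abundance_matrix()] tagged `species`, relative.
#' @export
relative_abundance <- function(depths) {
  stopifnot(is.matrix(depths))
  if (any(depths < 0)) stop("depths must be non-negative")
  totals <- rowSums(depths)
  bad <- rownames(depths)[totals == 0]
  if (length(bad) > 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  abundance_matrix(depths / totals, level_tag = "species", relative = TRUE)
}

#' Roll species abundances up to a higher taxonomic rank
#'
#' Taxon abundance is the sum of the relative abundances of its member
#' species; row sums are preserved exactly, so mass is conserved at every
#' rank.  Species with an empty name at the requested rank are pooled under
#' `"unassigned"`.
#'
#' @param species_matrix An [abundance_matrix()] at species level (columns
#'   named by species id).
#' @param lineages Named character vector of 7-rank lineages covering all
#'   columns.
#' @param rank Target rank (`"domain"` ... `"genus"`).
#' @return An [abundance_matrix()] tagged with `rank`.
#' @export
rollup_taxa <- function(species_matrix, lineages, rank) {
  rank <- match.arg(rank, names(RANK_PREFIXES))
  sp <- colnames(species_matrix)
  missing <- setdiff(sp, names(lineages))
  if (length(missing) > 0)
    stop("lineages missing for: ", paste(missing, collapse = ", "))
  taxa <- lineage_rank(lineages[sp], rank)
  taxa[!nzchar(taxa)] <- "unassigned"
  rolled <- t(rowsum(t(unclass(species_matrix)), group = taxa))
  abundance_matrix(rolled[, order(colnames(rolled)), drop = FALSE],
                   level_tag = rank,
                   relative = isTRUE(attr(species_matrix, "relative")))
}

#' Shannon or Simpson diversity of relative-abundance rows
#'
#' Shannon: `-sum(p * log(p))` over positive entries (natural log);
#' Simpson: `1 - sum(p^2)`, both computed with [vegan::diversity()].
#'
#' @param x A relative-abundance row (numeric vector) or samples x features
#'   matrix.
#' @param index `"shannon"` or `"simpson"`.
#' @return Numeric value per sample.
#' @export
diversity_index <- function(x, index = c("shannon", "simpson")) {
  index <- match.arg(index)
  unname(vegan::diversity(x, index = index))
}

#' Sample-based rarefaction curve per group
#'
#' For each group and each subsample size `m` from 1 to the group size,
#' draws `n_reps` random subsets of `m` samples (without replacement within
#' a draw) and counts the features with abundance above `floor` in at least
#' one drawn sample; reports the median and quartiles across draws.
#'
#' @param species_matrix Samples x features abundance matrix.
#' @param group_labels Factor/character group label per sample (row).
#' @param n_reps Random subsets per size (default 30).
#' @param rng_seed Integer seed.
#' @param floor Detection floor; a feature is present iff abundance >
#'   `floor` (default 0).
#' @return data.frame with columns `group`, `n_samples`, `median`, `q1`,
#'   `q3`.
#' @export
rarefaction_curve <- function(species_matrix, group_labels, n_reps = 30,
                              rng_seed = 1, floor = 0) {
  stopifnot(nrow(species_matrix) == length(group_labels))
  set.seed(rng_seed)
  present <- unclass(species_matrix) > floor
  out <- list()
  for (g in unique(as.character(group_labels))) {
    rows <- which(as.character(group_labels) == g)
    for (m in seq_along(rows)) {
      richness <- vapply(seq_len(n_reps), function(r) {
        drawn <- sample(rows, m)
        sum(colSums(present[drawn, , drop = FALSE]) > 0)
      }, numeric(1))
      qs <- quantile(richness, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, n_samples = m, median = qs[2], q1 = qs[1], q3 = qs[3])
    }
  }
  do.call(rbind, out)
}
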