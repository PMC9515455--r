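# Bin refinement: depth and GC computation, the same-sample merge heuristic,
# quality scoring (QS = completeness - 5 * contamination), MIMAG tier
# assignment, and size/quality filtering with an audit trail.

#' Sequencing depth of a bin
#'
#' `depth = total_mapped_reads * average_read_length / total_bin_length`,
#' i.e. the mean number of read bases covering each position of the bin.
#'
#' @param total_mapped_reads Number of reads mapped to the bin (>= 0).
#' @param average_read_length Mean read length in bp (> 0).
#' @param total_bin_length Total bin length in bp (> 0).
#' @return Numeric depth (x coverage); vectorized over its arguments.
#' @export
compute_depth <- function(total_mapped_reads, average_read_length,
                          total_bin_length) {
  if (any(total_bin_length <= 0)) stop("total_bin_length must be > 0")
  if (any(average_read_length <= 0)) stop("average_read_length must be > 0")
  total_mapped_reads * average_read_length / total_bin_length
}

#' GC content of a set of contigs
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases (N etc.) are excluded from
#' the denominator.
#'
#' @param contigs Character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return GC fraction in `[0, 1]`.
#' @export
compute_gc <- function(contigs) {
  if (!inherits(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (length(contigs) == 0L || sum(Biostrings::width(contigs)) == 0L)
    stop("compute_gc needs at least one base")
  freq <- colSums(Biostrings::letterFrequency(contigs, c("A", "C", "G", "T")))
  denom <- sum(freq)
  if (denom == 0) stop("no unambiguous A/C/G/T bases in input")
  unname((freq[["G"]] + freq[["C"]]) / denom)
}

#' Genome quality score
#'
#' `QS = completeness - 5 * contamination` (both in percent).
#'
#' @param completeness Completeness percent in `[0, 100]`.
#' @param contamination Contamination percent (>= 0).
#' @return Numeric QS; vectorized.
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100))
    stop("completeness must be in [0, 100]")
  if (any(contamination < 0)) stop("contamination must be >= 0")
  completeness - 5 * contamination
}

#' MIMAG quality tier
#'
#' Draft-genome tiers: `high` for completeness >= 90% and contamination
#' < 5%; `medium` for completeness >= 70%, contamination < 5% and quality
#' score >= `qs_min`; `low` for completeness >= 50% not reaching a higher
#' tier; `fail` otherwise.
#'
#' @inheritParams quality_score
#' @param qs_min QS threshold entering the medium tier (default 60).
#' @return Factor with levels `high`, `medium`, `low`, `fail`; vectorized.
#' @export
mimag_tier <- function(completeness, contamination, qs_min = 60) {
  qs <- quality_score(completeness, contamination)
  tier <- rep("fail", length(qs))
  tier[completeness >= 50] <- "low"
  tier[completeness >= 70 & contamination < 5 & qs >= qs_min] <- "medium"
  tier[completeness >= 90 & contamination < 5] <- "high"
  factor(tier, levels = c("high", "medium", "low", "fail"))
}

#' Construct a bin
#'
#' A bin bundles contigs with per-sample metadata: mapping-derived depth,
#' GC content, a 7-rank lineage and a quality record.  Total length and GC
#' are computed from the contigs.
#'
#' @param bin_id,sample_id Identifiers.
#' @param contigs Character vector (or DNAStringSet) of contig sequences.
#' @param depth Mean coverage (x); see [compute_depth()].
#' @param lineage 7-rank lineage string.
#' @param completeness,contamination Quality estimates in percent.
#' @param qs_min QS threshold used for tier assignment.
#' @return An object of class `mag_bin`.
#' @export
new_bin <- function(bin_id, sample_id, contigs, depth = NA_real_,
                    lineage = empty_lineage(), completeness = NA_real_,
                    contamination = NA_real_, qs_min = 60) {
  check_lineage(lineage)
  contigs <- as.character(contigs)
  total_length <- sum(nchar(contigs))
  qs <- if (is.na(completeness)) NA_real_ else
    quality_score(completeness, contamination)
  tier <- if (is.na(completeness)) factor("fail", c("high", "medium", "low", "fail")) else
    mimag_tier(completeness, contamination, qs_min)
  structure(list(bin_id = bin_id, sample_id = sample_id, contigs = contigs,
                 total_length = total_length, gc = compute_gc(contigs),
                 depth = depth, lineage = lineage,
                 completeness = completeness, contamination = contamination,
                 qs = qs, tier = tier, merged = FALSE,
                 merged_from = bin_id),
            class = "mag_bin")
}

#' @export
print.mag_bin <- function(x, ...) {
  cat(sprintf("<mag_bin %s> sample=%s contigs=%d length=%d gc=%.3f depth=%.2f qs=%.1f tier=%s\n",
              x$bin_id, x$sample_id, length(x$contigs), x$total_length,
              x$gc, x$depth, x$qs, as.character(x$tier)))
  invisible(x)
}

#' Manifest table for a list of bins
#'
#' @param bins List of [new_bin()] objects.
#' @return data.frame with one row per bin (bin_id, sample_id, total_length,
#'   gc, depth, completeness, contamination, qs, tier, merged, merged_from).
#' @export
bin_manifest <- function(bins) {
  do.call(rbind, lapply(bins, function(b) data.frame(
    bin_id = b$bin_id, sample_id = b$sample_id, n_contigs = length(b$contigs),
    total_length = b$total_length, gc = b$gc, depth = b$depth,
    lineage = b$lineage, completeness = b$completeness,
    contamination = b$contamination, qs = b$qs, tier = as.character(b$tier),
    merged = b$merged, merged_from = paste(b$merged_from, collapse = "+"))))
}

#' Merge same-sample bins with matching depth, GC and species assignment
#'
#' Two bins of one sample are merge-compatible iff their depths agree within
#' `depth_tol` relative to the pair mean, their GC contents differ by at
#' most `gc_tol`, and their species-rank lineage entries are identical and
#' non-empty.  Compatibility is closed transitively (single linkage), which
#' makes the result independent of input order.  A merged bin unions the
#' contigs, recomputes GC from sequence, takes the length-weighted mean
#' depth, combines completeness/contamination length-weighted, and is
#' flagged `merged` with its constituent ids recorded.
#'
#' @param bins List of [new_bin()] objects sharing one `sample_id`.
#' @param depth_tol Relative depth gap tolerance (default 0.10, i.e. +/-10%).
#' @param gc_tol Absolute GC tolerance (default 0.02).
#' @param qs_min QS threshold used when re-tiering merged bins.
#' @return List of `mag_bin` objects (merged bins plus untouched singletons).
#' @export
merge_bins <- function(bins, depth_tol = 0.10, gc_tol = 0.02, qs_min = 60) {
  if (length(bins) == 0L) return(bins)
  samples <- vapply(bins, `[[`, character(1), "sample_id")
  if (length(unique(samples)) != 1L)
    stop("merge_bins requires bins from a single sample; got: ",
         paste(unique(samples), collapse = ", "))
  n <- length(bins)
  depth <- vapply(bins, `[[`, numeric(1), "depth")
  gc <- vapply(bins, `[[`, numeric(1), "gc")
  species <- lineage_rank(vapply(bins, `[[`, character(1), "lineage"),
                          "species")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (!nzchar(species[i]) || species[i] != species[j]) next
      if (abs(gc[i] - gc[j]) > gc_tol) next
      m <- mean(c(depth[i], depth[j]))
      if (m == 0) { if (depth[i] != depth[j]) next }
      else if (abs(depth[i] - depth[j]) / m > depth_tol) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), comp), function(idx) {
    if (length(idx) == 1L) return(bins[[idx]])
    members <- bins[idx]
    ids <- sort(vapply(members, `[[`, character(1), "bin_id"))
    w <- vapply(members, `[[`, numeric(1), "total_length")
    merged <- new_bin(
      bin_id = paste(ids, collapse = "+"),
      sample_id = members[[1]]$sample_id,
      contigs = unlist(lapply(members, `[[`, "contigs")),
      depth = sum(w * vapply(members, `[[`, numeric(1), "depth")) / sum(w),
      lineage = members[[1]]$lineage,
      completeness = sum(w * vapply(members, `[[`, numeric(1),
                                    "completeness")) / sum(w),
      contamination = sum(w * vapply(members, `[[`, numeric(1),
                                     "contamination")) / sum(w),
      qs_min = qs_min)
    merged$merged <- TRUE
    merged$merged_from <- ids
    merged
  })
  names(out) <- NULL
  out
}

#' Filter bins by total size and dereplication eligibility
#'
#' Bins are retained in the catalog when their total length exceeds
#' `min_total_size`; among retained bins, only those in the high or medium
#' MIMAG tier with QS >= `qs_min` are eligible for species-level
#' dereplication.  Every rejection is recorded with its reason.
#'
#' @param manifest A [bin_manifest()] data.frame (columns `bin_id`,
#'   `total_length`, `qs`, `tier` are required).
#' @param min_total_size Minimum bin size in bp (retained iff strictly
#'   larger; default 200,000).
#' @param qs_min Minimum QS for dereplication eligibility (default 60).
#' @return The manifest with logical columns `retained`, `derep_eligible`
#'   and a character column `reject_reason` (`""` when retained and
#'   eligible).
#' @export
filter_bins <- function(manifest, min_total_size = 200000, qs_min = 60) {
  stopifnot(all(c("bin_id", "total_length", "qs", "tier") %in%
                  colnames(manifest)))
  manifest$retained <- manifest$total_length > min_total_size
  manifest$derep_eligible <- manifest$retained &
    manifest$tier %in% c("high", "medium") & manifest$qs >= qs_min
  reason <- character(nrow(manifest))
  reason[!manifest$retained] <- "size"
  small_q <- manifest$retained & !manifest$derep_eligible
  reason[small_q & !(manifest$tier %in% c("high", "medium"))] <- "tier"
  reason[small_q & manifest$tier %in% c("high", "medium") &
           manifest$qs < qs_min] <- "qs"
  manifest$reject_reason <- reason
  manifest
}
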