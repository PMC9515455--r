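# Species-level dereplication: bottom-s MinHash sketches over canonical
# k-mers, Mash-formula ANI estimation from sketch Jaccard, greedy QS-ordered
# clustering at an ANI threshold, and representative selection.
#
# k-mers are 2-bit packed into doubles (k <= 26 keeps values < 2^52, exact
# in IEEE doubles); the hash is a two-round modular linear mix whose
# intermediate products stay below 2^53, so sketches are bit-reproducible
# across platforms.

HASH_MOD <- 2147483647          # 2^31 - 1
HASH_A <- 1597334677            # < 2^31
HASH_B <- 1291169091            # < 2^31
HASH_C <- 1876917763            # < 2^31
HASH_SPLIT <- 2097152           # 2^21

# integer codes A=0 C=1 G=2 T=3; ambiguous bases -> NA
seq_codes <- function(genome) {
  match(strsplit(toupper(genome), "", fixed = TRUE)[[1]], DNA_BASES) - 1L
}

# packed values of all k-mers and their reverse complements; k-mers touching
# an ambiguous base are dropped
canonical_kmer_values <- function(genome, k) {
  codes <- seq_codes(genome)
  n <- length(codes) - k + 1L
  if (n < 1L) stop("genome shorter than k")
  fwd <- numeric(n)
  rev <- numeric(n)
  for (j in seq_len(k)) {
    cj <- codes[seq.int(j, j + n - 1L)]
    fwd <- fwd + cj * 4^(k - j)
    rev <- rev + (3 - cj) * 4^(j - 1)
  }
  v <- pmin(fwd, rev)
  v[!is.na(v)]
}

# three 21-bit limbs keep every product below 2^53 (exact in doubles)
hash_values <- function(v) {
  lo <- v %% HASH_SPLIT
  mid <- (v %/% HASH_SPLIT) %% HASH_SPLIT
  hi <- v %/% (HASH_SPLIT * HASH_SPLIT)
  h <- ((lo * HASH_B) %% HASH_MOD + (mid * HASH_A) %% HASH_MOD +
          (hi * HASH_C) %% HASH_MOD) %% HASH_MOD
  (h * 2971 + 1013904223) %% HASH_MOD
}

#' Bottom-s MinHash sketch of a genome
#'
#' Canonical k-mers (the lexicographically smaller 2-bit packing of a k-mer
#' and its reverse complement) are hashed with a fixed deterministic hash;
#' the sketch is the sorted set of the `sketch_size` smallest distinct hash
#' values.  If the genome has fewer distinct k-mers than `sketch_size` the
#' sketch is the full hashed k-mer set.
#'
#' @param genome Character string of A/C/G/T (ambiguous bases are skipped).
#' @param k k-mer size (default 21; must not exceed 26).
#' @param sketch_size Number of retained hash values (default 5000).
#' @return An object of class `mag_sketch` with fields `hashes`, `k`,
#'   `sketch_size`, `n_kmers` (distinct canonical k-mers).
#' @export
sketch_genome <- function(genome, k = 21, sketch_size = 5000) {
  stopifnot(k >= 3, k <= 26, sketch_size >= 1)
  if (nchar(genome) < k) stop("genome shorter than k")
  h <- unique(hash_values(canonical_kmer_values(genome, k)))
  h <- sort(h)
  structure(list(hashes = head(h, sketch_size), k = as.integer(k),
                 sketch_size = as.integer(sketch_size),
                 n_kmers = length(h)),
            class = "mag_sketch")
}

#' Estimate average nucleotide identity from two sketches
#'
#' The Jaccard index `j` is estimated on the bottom-`s` sketch of the union
#' of the two hash sets (the Mash estimator); ANI follows the Mash distance
#' formula `ANI = 100 * (1 + log(2j / (1 + j)) / k)`, clamped to
#' `[0, 100]`.  Identical sketches give exactly 100.
#'
#' @param sketch_a,sketch_b Objects from [sketch_genome()] built with the
#'   same `k` and `sketch_size`.
#' @return ANI in percent.
#' @export
estimate_ani <- function(sketch_a, sketch_b) {
  stopifnot(inherits(sketch_a, "mag_sketch"), inherits(sketch_b, "mag_sketch"))
  if (sketch_a$k != sketch_b$k || sketch_a$sketch_size != sketch_b$sketch_size)
    stop("sketches must share k and sketch_size")
  if (length(sketch_a$hashes) == 0L || length(sketch_b$hashes) == 0L)
    stop("empty sketch")
  k <- sketch_a$k
  s <- sketch_a$sketch_size
  merged <- sort(unique(c(sketch_a$hashes, sketch_b$hashes)))
  su <- head(merged, s)
  shared <- sum(su %in% sketch_a$hashes & su %in% sketch_b$hashes)
  j <- shared / length(su)
  if (j <= 0) return(0)
  ani <- 100 * (1 + log(2 * j / (1 + j)) / k)
  min(max(ani, 0), 100)
}

#' Greedy species-level clustering of MAGs at an ANI threshold
#'
#' MAGs are visited in decreasing quality-score order (ties: larger total
#' length, then lexicographic id).  Each MAG joins the first existing
#' cluster whose representative (founder) exceeds the ANI threshold with
#' it, otherwise it founds a new cluster.  Every MAG ends up in exactly one
#' cluster; the representative is re-derived with
#' [select_representative()] (the founder, by construction of the visiting
#' order).  The cluster lineage is the representative's; members whose
#' lineage disagrees are reported with a warning.
#'
#' @param sketches Named list of [sketch_genome()] objects (names = MAG ids).
#' @param quality data.frame with columns `mag_id`, `qs`, `total_length`
#'   and optionally `lineage`.
#' @param ani_threshold Clustering threshold in ANI percent (default 95;
#'   membership requires ANI strictly greater).
#' @return A list with `clusters` (data.frame: species_id,
#'   representative_mag_id, n_members, members, lineage) and `membership`
#'   (named character vector MAG id -> species_id).
#' @export
cluster_species <- function(sketches, quality, ani_threshold = 95) {
  stopifnot(all(c("mag_id", "qs", "total_length") %in% colnames(quality)))
  ids <- quality$mag_id
  if (!all(ids %in% names(sketches)))
    stop("missing sketches for: ",
         paste(setdiff(ids, names(sketches)), collapse = ", "))
  ord <- order(-quality$qs, -quality$total_length, quality$mag_id)
  ids <- ids[ord]
  reps <- character()
  members <- list()
  for (id in ids) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (estimate_ani(sketches[[id]], sketches[[reps[ci]]]) > ani_threshold) {
        members[[ci]] <- c(members[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  qs <- setNames(quality$qs, quality$mag_id)
  lin <- if ("lineage" %in% colnames(quality))
    setNames(quality$lineage, quality$mag_id) else
    setNames(rep(empty_lineage(), nrow(quality)), quality$mag_id)
  clusters <- do.call(rbind, lapply(seq_along(reps), function(ci) {
    rep_id <- select_representative(members[[ci]], quality)
    mem_lin <- unique(lin[members[[ci]]])
    if (length(mem_lin) > 1L)
      warning("cluster ", ci, " members disagree on lineage; using the ",
              "representative's", call. = FALSE)
    data.frame(species_id = sprintf("S%04d", ci),
               representative_mag_id = rep_id,
               n_members = length(members[[ci]]),
               members = paste(sort(members[[ci]]), collapse = ","),
               lineage = unname(lin[rep_id]))
  }))
  membership <- setNames(rep(clusters$species_id, clusters$n_members),
                         unlist(members))
  list(clusters = clusters, membership = membership)
}

#' Select a cluster's representative MAG
#'
#' The member with maximal QS; ties broken by larger total length, then by
#' lexicographically smaller id.
#'
#' @param member_ids Character vector of MAG ids (non-empty).
#' @param quality data.frame with columns `mag_id`, `qs`, `total_length`.
#' @return The representative MAG id.
#' @export
select_representative <- function(member_ids, quality) {
  if (length(member_ids) == 0L) stop("empty cluster")
  q <- quality[match(member_ids, quality$mag_id), ]
  if (anyNA(q$mag_id)) stop("quality records missing for some members")
  q <- q[order(-q$qs, -q$total_length, q$mag_id), ]
  q$mag_id[[1]]
}
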