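# Functional profiling: KO assignment by best-hit filtering, gene and
# category (KO/module/pathway) abundance aggregation, and per-species
# contribution decomposition of each functional category.

KO_EVALUE_MAX <- 1e-10
KO_COVERAGE_MIN <- 0.5

#' Assign KOs to genes by best-hit filtering
#'
#' Hits with `e_value >= evalue_max` or `coverage <= coverage_min` are
#' discarded; among the survivors of each gene the KO of the minimal
#' e-value wins, ties broken by higher coverage then lexicographically
#' smaller KO.  Genes with no surviving hit are unassigned (`NA`).
#'
#' @param hits data.frame with columns `gene_id`, `ko`, `e_value`,
#'   `coverage` (one or many genes).
#' @param evalue_max Strict e-value cutoff (default 1e-10; a hit must be
#'   strictly below it).
#' @param coverage_min Strict coverage cutoff as a fraction of the protein
#'   length (default 0.5; a hit must strictly exceed it).
#' @return data.frame with columns `gene_id`, `ko` (`NA` = unassigned),
#'   one row per input gene.
#' @export
assign_ko <- function(hits, evalue_max = KO_EVALUE_MAX,
                      coverage_min = KO_COVERAGE_MIN) {
  stopifnot(all(c("gene_id", "ko", "e_value", "coverage") %in% colnames(hits)))
  if (any(hits$e_value < 0)) stop("e_value must be >= 0")
  if (any(hits$coverage < 0 | hits$coverage > 1))
    stop("coverage must be in [0, 1]")
  genes <- unique(hits$gene_id)
  ok <- hits$e_value < evalue_max & hits$coverage > coverage_min
  surv <- hits[ok, , drop = FALSE]
  best <- surv[order(surv$gene_id, surv$e_value, -surv$coverage, surv$ko), ]
  best <- best[!duplicated(best$gene_id), c("gene_id", "ko")]
  out <- data.frame(gene_id = genes,
                    ko = best$ko[match(genes, best$gene_id)])
  rownames(out) <- NULL
  out
}

#' Gene-level abundance propagated from species abundance
#'
#' The abundance of a gene in a sample is the relative abundance of its
#' species times the gene's copy number in the species representative; the
#' simplest model consistent with summing gene abundances into category
#' abundances when genes are single-copy.
#'
#' @param species_matrix Samples x species [abundance_matrix()].
#' @param genes data.frame with columns `gene_id`, `species_id` and
#'   optionally `copy` (default 1).
#' @return Samples x genes numeric matrix (columns named by `gene_id`).
#' @export
gene_abundance <- function(species_matrix, genes) {
  stopifnot(all(c("gene_id", "species_id") %in% colnames(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id must be unique")
  orphans <- setdiff(genes$species_id, colnames(species_matrix))
  if (length(orphans) > 0)
    stop("genes reference species absent from the matrix: ",
         paste(genes$gene_id[genes$species_id %in% orphans], collapse = ", "))
  copy <- if ("copy" %in% colnames(genes)) genes$copy else
    rep(1, nrow(genes))
  out <- unclass(species_matrix)[, genes$species_id, drop = FALSE]
  out <- sweep(out, 2, copy, "*")
  colnames(out) <- genes$gene_id
  out
}

#' Functional-category abundance
#'
#' The abundance of a category (a single KO, a module or a pathway) in a
#' sample is the sum of the abundances of the genes whose assigned KO
#' belongs to the category.  Categories are summed independently, so
#' overlapping categories double-count shared KOs by design.  The result is
#' not renormalized: rows need not sum to 1.
#'
#' @param gene_abund Samples x genes matrix from [gene_abundance()].
#' @param assignments data.frame from [assign_ko()] (`gene_id`, `ko`;
#'   unassigned genes are skipped).
#' @param categories Optional data.frame with columns `category_id`, `ko`
#'   (and optionally `type`); when `NULL`, each assigned KO is its own
#'   category (KO-level profile).
#' @param level_tag Level label for the result (defaults to `"ko"` when
#'   `categories` is `NULL`, else `"category"`).
#' @return Samples x categories [abundance_matrix()] with
#'   `relative = FALSE`.  Categories with no assigned gene get an all-zero
#'   column and a warning.
#' @export
category_abundance <- function(gene_abund, assignments, categories = NULL,
                               level_tag = NULL) {
  stopifnot(all(c("gene_id", "ko") %in% colnames(assignments)))
  assignments <- assignments[!is.na(assignments$ko), , drop = FALSE]
  gk <- assignments[assignments$gene_id %in% colnames(gene_abund), ,
                    drop = FALSE]
  if (is.null(categories)) {
    kos <- sort(unique(gk$ko))
    out <- matrix(0, nrow(gene_abund), length(kos),
                  dimnames = list(rownames(gene_abund), kos))
    if (nrow(gk) > 0) {
      summed <- t(rowsum(t(gene_abund[, gk$gene_id, drop = FALSE]),
                         group = gk$ko))
      out[, colnames(summed)] <- summed
    }
    return(abundance_matrix(out, level_tag %||% "ko", relative = FALSE))
  }
  stopifnot(all(c("category_id", "ko") %in% colnames(categories)))
  cat_ids <- unique(categories$category_id)
  out <- matrix(0, nrow(gene_abund), length(cat_ids),
                dimnames = list(rownames(gene_abund), cat_ids))
  empty <- character()
  for (cid in cat_ids) {
    member <- categories$ko[categories$category_id == cid]
    gidx <- gk$gene_id[gk$ko %in% member]
    if (length(gidx) == 0) { empty <- c(empty, cid); next }
    out[, cid] <- rowSums(gene_abund[, gidx, drop = FALSE])
  }
  if (length(empty) > 0)
    warning("categories with no assigned genes (all-zero rows): ",
            paste(empty, collapse = ", "), call. = FALSE)
  abundance_matrix(out, level_tag %||% "category", relative = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-species contribution to a functional category
#'
#' For each sample, a species' contribution is the summed abundance of the
#' species' genes in the category divided by the category's total
#' abundance; over all species the contributions sum to exactly 1 in every
#' sample with positive category abundance.  Samples where the category is
#' absent get contribution 0 and are flagged.  When `species_subset` is
#' given, only those rows are reported (columns may then sum to less
#' than 1).
#'
#' @param category_id The category to decompose.
#' @param gene_abund Samples x genes matrix from [gene_abundance()].
#' @param genes data.frame mapping `gene_id` to `species_id`.
#' @param assignments data.frame from [assign_ko()].
#' @param categories data.frame `category_id`, `ko`; `NULL` treats
#'   `category_id` as a single KO.
#' @param species_subset Optional character vector of species to report.
#' @return A list with `contribution` (species x samples matrix),
#'   `mean_contribution` (named vector, mean across samples) and
#'   `zero_samples` (samples with zero category abundance).
#' @export
species_contribution <- function(category_id, gene_abund, genes,
                                 assignments, categories = NULL,
                                 species_subset = NULL) {
  member <- if (is.null(categories)) category_id else
    categories$ko[categories$category_id == category_id]
  assignments <- assignments[!is.na(assignments$ko), , drop = FALSE]
  gidx <- assignments$gene_id[assignments$ko %in% member]
  gidx <- intersect(gidx, colnames(gene_abund))
  if (length(gidx) == 0)
    stop("category ", category_id, " has no assigned genes")
  sub <- gene_abund[, gidx, drop = FALSE]
  sp <- genes$species_id[match(gidx, genes$gene_id)]
  by_species <- t(rowsum(t(sub), group = sp))      # samples x species
  total <- rowSums(by_species)
  if (all(total == 0))
    stop("category ", category_id, " has zero abundance in every sample")
  contrib <- by_species
  pos <- total > 0
  contrib[pos, ] <- by_species[pos, , drop = FALSE] / total[pos]
  contrib[!pos, ] <- 0
  contrib <- t(contrib)                            # species x samples
  if (!is.null(species_subset))
    contrib <- contrib[intersect(species_subset, rownames(contrib)), ,
                       drop = FALSE]
  list(contribution = contrib,
       mean_contribution = rowMeans(contrib),
       zero_samples = rownames(by_species)[!pos])
}
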