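#' Link peaks to genes by TSS proximity and classify annotation categories
#'
#' A TSS is linked to a peak when the distance between the TSS point and the
#' peak interval is strictly less than `gene_link_dist` bp (distance 0 inside
#' the peak). Each peak is then assigned exactly one category:
#' `protein_coding` if any linked transcript is protein coding, `noncoding`
#' if it is linked only to non-coding transcripts, and `unannotated` if no
#' TSS lies within range. Protein-coding dominance keeps the three
#' categories a partition of the catalog.
#'
#' @param peaks Peak catalog `GRanges` with ids as names.
#' @param tss TSS table from [read_tss_table()].
#' @param gene_link_dist Linkage distance in bp, exclusive (default 2000).
#' @return `data.frame` with `peak_id`, `category`, `n_linked`,
#'   `linked_genes` and `linked_coding_genes` (comma-separated gene ids).
#' @export
annotate_peaks <- function(peaks, tss, gene_link_dist = 2000) {
  if (is.null(tss) || nrow(tss) == 0L) stop("empty TSS table")
  ids <- names(peaks)
  tss_gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(as.integer(tss$tss_pos_1based), width = 1L))
  # expanding by (dist - 1) turns "point within < dist of the interval" into
  # plain overlap, since genomic distances are integral
  ext <- suppressWarnings(peaks + (as.integer(gene_link_dist) - 1L))
  hits <- GenomicRanges::findOverlaps(ext, tss_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  coding <- tss$biotype[sh] == "protein_coding"
  genes_all <- split(tss$gene_id[sh], factor(qh, levels = seq_along(peaks)))
  genes_cod <- split(tss$gene_id[sh][coding],
                     factor(qh[coding], levels = seq_along(peaks)))
  n_linked <- lengths(lapply(genes_all, unique))
  has_coding <- lengths(genes_cod) > 0L
  category <- ifelse(n_linked == 0L, "unannotated",
                     ifelse(has_coding, "protein_coding", "noncoding"))
  data.frame(
    peak_id = ids,
    category = category,
    n_linked = as.integer(n_linked),
    linked_genes = vapply(genes_all, function(g)
      paste(unique(g), collapse = ","), character(1L)),
    linked_coding_genes = vapply(genes_cod, function(g)
      paste(unique(g), collapse = ","), character(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' One-tailed Fisher's exact test for enrichment
#'
#' Tests enrichment of a category in a foreground set against a background
#' using the hypergeometric upper tail `P(X >= a)` given the table margins.
#' The table layout is `a` = foreground in category, `b` = foreground outside
#' it, `c` = rest of background in category, `d` = remainder. The odds ratio
#' is the cross-product `(a d)/(b c)`; `NA` when 0/0.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return One-row `data.frame`: `a`, `b`, `c`, `d`, `odds_ratio`, `p`.
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("cell counts must be non-negative integers")
  }
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  num <- a * d
  den <- b * c
  or <- if (num == 0 && den == 0) NA_real_ else num / den
  data.frame(a = a, b = b, c = c, d = d, odds_ratio = or, p = p)
}

#' Annotation-category enrichment of altered loci
#'
#' Tests whether the altered loci are enriched in each annotation category
#' against the full peak catalog, one one-tailed Fisher test per category
#' row, Bonferroni-adjusted over the number of rows tested. The `annotated`
#' row is the union of `protein_coding` and `noncoding`.
#'
#' @param annotation Peak annotation from [annotate_peaks()] covering the
#'   whole catalog.
#' @param altered_ids Character vector of altered peak ids (non-empty,
#'   subset of the catalog).
#' @param categories Category rows to test (default the four standard rows).
#' @return `data.frame` with one row per category: counts, odds ratio, `p`,
#'   `p_adjusted` (= min(1, m p)), `method`.
#' @export
category_enrichment <- function(annotation, altered_ids,
                                categories = c("annotated", "protein_coding",
                                               "noncoding", "unannotated")) {
  altered_ids <- unique(altered_ids)
  if (length(altered_ids) == 0L) stop("altered peak set is empty")
  if (!all(altered_ids %in% annotation$peak_id)) {
    stop("altered_ids must be a subset of the annotated peak catalog")
  }
  fg <- annotation$peak_id %in% altered_ids
  rows <- lapply(categories, function(cat) {
    in_cat <- if (cat == "annotated") {
      annotation$category != "unannotated"
    } else {
      annotation$category == cat
    }
    a <- sum(fg & in_cat)
    b <- sum(fg & !in_cat)
    cc <- sum(!fg & in_cat)
    d <- sum(!fg & !in_cat)
    cbind(data.frame(test_name = cat, stringsAsFactors = FALSE),
          fisher_one_tailed(a, b, cc, d))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out$method <- "bonferroni"
  rownames(out) <- NULL
  out
}

#' Build a merged region set from GWAS variants
#'
#' Selects variants passing the p-value threshold and extends each by a
#' symmetric flank (100 kb each side by default, i.e. a ~200-kb total span
#' per variant), merging the results. Regions are clipped at position 1.
#'
#' @param variants Variant `data.frame` from [read_gwas_table()].
#' @param p_threshold Keep variants with `pvalue` strictly below this
#'   (default genome-wide significance, 5e-8).
#' @param flank Flank size in bp on each side (default 1e5).
#' @return Merged `GRanges` region set (empty if no variant passes).
#' @export
build_region_set <- function(variants, p_threshold = 5e-8, flank = 1e5) {
  stopifnot(flank >= 0)
  pass <- variants$pvalue < p_threshold
  if (!any(pass)) {
    return(GenomicRanges::GRanges())
  }
  pos <- as.integer(variants$pos_1based[pass])
  gr <- GenomicRanges::GRanges(
    variants$chrom[pass],
    IRanges::IRanges(pmax(1L, pos - as.integer(flank)),
                     pos + as.integer(flank)))
  merge_intervals(gr)
}

#' Overlap test between altered loci and a GWAS-derived region set
#'
#' The peak universe is restricted to catalog peaks overlapping (by at least
#' one base) the background regions built from *all* tested variants with
#' the same flank; within that universe a one-tailed Fisher test asks
#' whether altered peaks overlap the significant regions more often than the
#' rest.
#'
#' @param peaks Peak catalog `GRanges` with ids as names.
#' @param altered_ids Altered peak ids.
#' @param significant_regions `GRanges` from [build_region_set()] at the
#'   significance threshold.
#' @param background_regions `GRanges` built from all tested variants (or
#'   whole chromosomes via [read_chrom_sizes()] for genome-wide backgrounds).
#' @return One-row `data.frame` as from [fisher_one_tailed()].
#' @export
region_overlap_test <- function(peaks, altered_ids, significant_regions,
                                background_regions) {
  in_bg <- suppressWarnings(
    GenomicRanges::countOverlaps(peaks, background_regions,
                                 ignore.strand = TRUE)) > 0L
  universe <- peaks[in_bg]
  if (length(universe) == 0L) {
    stop("empty peak universe: no catalog peak overlaps the background regions")
  }
  alt <- names(universe) %in% altered_ids
  sig <- GenomicRanges::countOverlaps(universe, significant_regions,
                                      ignore.strand = TRUE) > 0L
  fisher_one_tailed(sum(alt & sig), sum(alt & !sig),
                    sum(!alt & sig), sum(!alt & !sig))
}

#' Overlap test between altered genes and a reported gene list
#'
#' One-tailed Fisher test of the overlap between the genes linked to altered
#' loci and a list of genes reported by an independent study, against a
#' common gene background (all protein-coding genes, typically). Reported
#' genes absent from the background are dropped with a warning.
#'
#' @param altered_genes Genes linked to altered loci (subset of background).
#' @param reported_genes Genes reported by the external study.
#' @param background_genes The gene universe.
#' @return One-row `data.frame` as from [fisher_one_tailed()].
#' @export
gene_overlap_test <- function(altered_genes, reported_genes,
                              background_genes) {
  background_genes <- unique(background_genes)
  altered_genes <- unique(altered_genes)
  reported_genes <- unique(reported_genes)
  if (!all(altered_genes %in% background_genes)) {
    stop("altered_genes must be a subset of background_genes")
  }
  dropped <- setdiff(reported_genes, background_genes)
  if (length(dropped)) {
    warning(sprintf("dropped %d reported gene(s) absent from background",
                    length(dropped)))
    reported_genes <- intersect(reported_genes, background_genes)
  }
  a <- length(intersect(altered_genes, reported_genes))
  b <- length(setdiff(altered_genes, reported_genes))
  cc <- length(setdiff(reported_genes, altered_genes))
  d <- length(background_genes) - a - b - cc
  fisher_one_tailed(a, b, cc, d)
}

#' Apply BH-FDR across a battery of overlap tests
#'
#' Used to correct the tests run per external dataset (e.g. up-, down- and
#' all-peak sets for each case group: six tests). Adds `p_adjusted`
#' (Benjamini-Hochberg q-value), `method` and `significant` (q < `alpha`).
#'
#' @param results `data.frame` with at least `test_name` and `p` columns.
#' @param alpha FDR threshold (default 0.05).
#' @return The input with adjustment columns appended.
#' @export
run_test_battery <- function(results, alpha = 0.05) {
  stopifnot(all(c("test_name", "p") %in% names(results)))
  results$p_adjusted <- stats::p.adjust(results$p, method = "BH")
  results$method <- "bh"
  results$significant <- results$p_adjusted < alpha
  results
}

#' Over-representation analysis of a gene list against GMT gene sets
#'
#' Local stand-in for web-based pathway tools: one one-tailed Fisher test per
#' gene set (genes outside the background are dropped, with a warning giving
#' the total), BH-FDR across all sets, sorted by q-value.
#'
#' @param gene_list Non-empty character vector of genes of interest (subset
#'   of the background).
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param background_genes The gene universe.
#' @param alpha FDR threshold (default 0.05).
#' @return `data.frame`, one row per set, sorted by `p_adjusted` then `p`.
#' @export
run_ora <- function(gene_list, gene_sets, background_genes, alpha = 0.05) {
  gene_list <- unique(gene_list)
  background_genes <- unique(background_genes)
  if (length(gene_list) == 0L) stop("empty gene list")
  if (!all(gene_list %in% background_genes)) {
    stop("gene_list must be a subset of background_genes")
  }
  n_dropped <- sum(vapply(gene_sets, function(s)
    length(setdiff(s, background_genes)), integer(1L)))
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d gene-set member(s) absent from background",
                    n_dropped))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background_genes)
    a <- length(intersect(gene_list, set))
    b <- length(setdiff(gene_list, set))
    cc <- length(setdiff(set, gene_list))
    d <- length(background_genes) - a - b - cc
    cbind(data.frame(test_name = nm, stringsAsFactors = FALSE),
          fisher_one_tailed(a, b, cc, d))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$method <- "bh"
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
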