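#' Build merged promoter regions around TSSs
#'
#' Each TSS contributes a window of `half_window` bases on each side (4 kbp
#' total by default); windows are clipped at the chromosome start and merged
#' into maximal disjoint regions. The merged set defines the denominator of
#' the promoter-anchored library normalization.
#'
#' @param tss TSS table as returned by [read_tss_table()] (needs `chrom` and
#'   `tss_pos_1based`).
#' @param half_window Window half-width in bp (default 2000).
#' @return Sorted, disjoint `GRanges` of promoter regions.
#' @export
build_promoter_set <- function(tss, half_window = 2000) {
  if (is.null(tss) || nrow(tss) == 0L) {
    stop("empty TSS table: promoter normalization is undefined")
  }
  stopifnot(half_window > 0)
  pos <- as.integer(tss$tss_pos_1based)
  # 1-based window [pos - hw, pos + hw - 1] covers the same 2*hw bases as the
  # 0-based half-open [pos0 - hw, pos0 + hw); clipped at the chromosome start.
  gr <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(pmax(1L, pos - as.integer(half_window)),
                     pos + as.integer(half_window) - 1L)
  )
  merge_intervals(gr)
}

#' Count reads whose mapped 5' position falls in the promoter set
#'
#' A read is counted if its 5'-most mapped coordinate lies inside the merged
#' promoter regions; fractional overlap of the read body is deliberately not
#' considered so the tally is order-independent and reproducible from a
#' position list alone. Users with their own counting convention can supply a
#' precomputed tally to [normalization_factor()] directly.
#'
#' @param chrom Character vector of read chromosomes.
#' @param pos_1based Integer vector of 5' mapped positions (1-based).
#' @param promoter_set `GRanges` from [build_promoter_set()].
#' @return Integer tally of reads inside the promoter set.
#' @export
promoter_read_tally <- function(chrom, pos_1based, promoter_set) {
  stopifnot(length(chrom) == length(pos_1based))
  if (length(chrom) == 0L) {
    return(0L)
  }
  reads <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos_1based, width = 1L))
  sum(GenomicRanges::countOverlaps(reads, promoter_set, ignore.strand = TRUE) > 0L)
}

#' Promoter-anchored normalization factor
#'
#' The per-sample scale factor is the promoter read tally divided by 1e7, so
#' a library with ten million promoter reads has factor 1 and normalized
#' coverages are comparable across sequencing depths.
#'
#' @param tally Total number of reads mapped to the promoter regions.
#' @return List with `tally` and the scale `factor` (= tally / 1e7).
#' @export
normalization_factor <- function(tally) {
  if (length(tally) != 1L || is.na(tally) || tally < 0) {
    stop("tally must be a single non-negative number")
  }
  if (tally == 0) {
    stop("empty promoter tally: normalization factor undefined")
  }
  list(tally = as.numeric(tally), factor = as.numeric(tally) / 1e7)
}

#' Quantify normalized peak coverage for one sample
#'
#' The normalized coverage of a peak is the sum over its bases of the raw
#' per-base coverage, divided by the sample's normalization factor. Peaks on
#' chromosomes absent from the track get coverage 0 with a warning.
#'
#' @param track Coverage `GRanges` with `score` (see [read_bedgraph()]).
#' @param peaks Peak catalog `GRanges` with ids as names.
#' @param factor Positive scale factor (see [normalization_factor()]).
#' @return Named numeric vector of normalized coverages, in peak order.
#' @export
quantify_peaks <- function(track, peaks, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("normalization factor must be a single positive number")
  }
  missing_chrom <- setdiff(
    unique(as.character(GenomicRanges::seqnames(peaks))),
    unique(as.character(GenomicRanges::seqnames(track)))
  )
  if (length(missing_chrom)) {
    warning(sprintf("peaks on chromosome(s) absent from track (coverage 0): %s",
                    paste(missing_chrom, collapse = ", ")))
  }
  q <- track_sum(track, peaks) / factor
  names(q) <- names(peaks)
  q
}

#' Assemble the peaks-by-samples normalized coverage matrix
#'
#' @param tracks Named list of coverage `GRanges`, one per sample.
#' @param peaks Peak catalog `GRanges`.
#' @param tallies Named numeric vector of promoter read tallies, same names
#'   as `tracks`.
#' @return Numeric matrix, peaks as rows (ids as rownames), samples as
#'   columns in `tracks` order.
#' @export
build_peak_matrix <- function(tracks, peaks, tallies) {
  stopifnot(!is.null(names(tracks)), all(names(tracks) %in% names(tallies)))
  cols <- vapply(names(tracks), function(s) {
    quantify_peaks(tracks[[s]], peaks, normalization_factor(tallies[[s]])$factor)
  }, numeric(length(peaks)))
  mat <- matrix(cols, nrow = length(peaks),
                dimnames = list(names(peaks), names(tracks)))
  mat
}

#' Per-peak fraction of low-MAPQ reads
#'
#' Computes, for each peak, the fraction of overlapping reads (pooled across
#' all cohort samples) with MAPQ below `mapq_min`. Peaks with no reads get an
#' `NA` fraction: absent evidence of poor mappability does not exclude a
#' peak.
#'
#' @param mapqs_by_peak Named list; each element is the integer vector of
#'   MAPQ values of reads overlapping that peak.
#' @param mapq_min Reads with MAPQ strictly below this count as low quality
#'   (default 10).
#' @return `data.frame` with `peak_id`, `n_reads`, `low_mapq_fraction`.
#' @export
mapq_fraction <- function(mapqs_by_peak, mapq_min = 10) {
  if (any(vapply(mapqs_by_peak, function(m) any(m < 0), logical(1L)))) {
    stop("negative MAPQ value")
  }
  n <- lengths(mapqs_by_peak)
  frac <- vapply(mapqs_by_peak, function(m) {
    if (length(m) == 0L) NA_real_ else mean(m < mapq_min)
  }, numeric(1L))
  data.frame(peak_id = names(mapqs_by_peak), n_reads = as.integer(n),
             low_mapq_fraction = unname(frac), stringsAsFactors = FALSE)
}
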