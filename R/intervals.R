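#' Read a BED file of genomic intervals
#'
#' Reads a 3+ column BED file into a [GenomicRanges::GRanges]. BED coordinates
#' are 0-based half-open on disk; the returned object uses the 1-based
#' inclusive convention native to R/Bioconductor, so a BED record
#' `chr2 862856 865643` becomes `chr2:862857-865643`, which is also how loci
#' are printed in reports (see [format_region()]).
#'
#' Interval identifiers are taken from BED column 4 when present and
#' non-empty; records without a usable name receive a synthesized
#' `peak_<n>` id (`<n>` is the record's position in the file). Columns
#' beyond the fourth are ignored, as are `track`, `browser` and `#` lines.
#'
#' @param path Path to a BED file (3 or more tab-separated columns).
#' @return A `GRanges` in file order, with interval ids as `names()`.
#'   Malformed coordinates or empty intervals (`end <= start`) raise an
#'   error naming the offending line.
#' @export
read_bed <- function(path) {
  raw <- readLines(path)
  keep <- which(nzchar(trimws(raw)) & !grepl("^(track|browser|#)", raw))
  if (length(keep) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 columns",
                 keep[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
  bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: non-integer coordinates", keep[bad[1L]]))
  }
  bad <- which(start0 < 0)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d: start < 0", keep[bad[1L]]))
  }
  bad <- which(end0 <= start0)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d: end <= start", keep[bad[1L]]))
  }
  ids <- rep(NA_character_, length(keep))
  has4 <- nf >= 4L
  ids[has4] <- vapply(fields[has4], `[[`, character(1L), 4L)
  synth <- is.na(ids) | !nzchar(ids) | ids == "."
  ids[synth] <- paste0("peak_", seq_along(ids))[synth]
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  names(gr) <- ids
  gr
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: converts back to 0-based half-open coordinates.
#'
#' @param gr A `GRanges`; `names(gr)` become BED column 4.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(names(gr))) paste0("peak_", seq_along(gr)) else names(gr),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Reads a 4-column bedGraph into a `GRanges` with a numeric `score` column.
#' Records are sorted; gaps between records are implicitly zero coverage.
#' Overlapping records are rejected, since a step function must assign a
#' single value per base.
#'
#' @param path Path to a bedGraph file.
#' @return Sorted `GRanges` with a `score` metadata column.
#' @seealso [track_sum()] for interval queries against the track.
#' @export
read_bedgraph <- function(path) {
  raw <- readLines(path)
  keep <- which(nzchar(trimws(raw)) & !grepl("^(track|browser|#)", raw))
  if (length(keep) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(raw[keep], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("malformed bedGraph line %d: fewer than 4 columns",
                 keep[which(nf < 4L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 4L)))
  bad <- which(is.na(start0) | is.na(end0) | is.na(value) |
                 start0 != floor(start0) | end0 != floor(end0) | start0 < 0)
  if (length(bad)) {
    stop(sprintf("malformed bedGraph line %d", keep[bad[1L]]))
  }
  bad <- which(end0 <= start0)
  if (length(bad)) {
    stop(sprintf("invalid bedGraph interval at line %d: end <= start", keep[bad[1L]]))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               score = value)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (any(GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1L)) {
    stop("overlapping bedGraph records: coverage value per base is ambiguous")
  }
  gr
}

#' Write a coverage track as bedGraph
#'
#' @param track `GRanges` with a `score` column (as from [read_bedgraph()]).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    value = format(track$score, digits = 15, scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-base sum of a coverage track over query intervals
#'
#' For each query interval, returns the sum over its bases of the track value
#' at that base (zero where the track has no record). This is the primitive
#' behind peak quantification: the "coverage" of a region is the sum of
#' per-base coverages.
#'
#' @param track Coverage `GRanges` with `score`, non-overlapping records.
#' @param query `GRanges` of intervals to evaluate.
#' @return Numeric vector, one sum per query interval.
#' @export
track_sum <- function(track, query) {
  out <- numeric(length(query))
  if (length(track) == 0L || length(query) == 0L) {
    return(out)
  }
  # disjoint chromosome sets between track and query are legitimate here
  # (they simply contribute zero coverage), so the seqlevel warning is noise
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, track, ignore.strand = TRUE))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- pmin(GenomicRanges::end(query)[qh], GenomicRanges::end(track)[sh]) -
      pmax(GenomicRanges::start(query)[qh], GenomicRanges::start(track)[sh]) + 1L
    agg <- rowsum(w * track$score[sh], qh)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Merge intervals into a sorted, disjoint union
#'
#' Union semantics: overlapping and touching intervals are merged into
#' maximal runs, matching how merged promoter regions are constructed.
#' Strand is ignored.
#'
#' @param x A `GRanges`.
#' @return Sorted, disjoint `GRanges` covering exactly the same bases.
#' @export
merge_intervals <- function(x) {
  GenomicRanges::reduce(x, ignore.strand = TRUE)
}

#' Format intervals as 1-based inclusive region strings
#'
#' Publication-style `chrom:start-end` labels (1-based, inclusive), e.g. the
#' BED record `chr2 862856 865643` prints as `chr2:862857-865643`.
#'
#' @param gr A `GRanges`.
#' @return Character vector of region labels.
#' @export
format_region <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr))
}
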