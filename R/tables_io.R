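# Tab-separated table readers/writers shared by the pipeline. All readers
# validate schemas up front and fail loudly rather than coerce silently.

read_tsv_checked <- function(path, required) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects tab-separated columns `gene_id`, `transcript_id`, `biotype`,
#' `chrom`, `tss_pos_1based`, `strand`. One row per transcript; the TSS
#' position is the transcription start of that transcript (strand has already
#' been resolved by whatever produced the table).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with the columns above.
#' @export
read_tss_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "transcript_id", "biotype",
                                 "chrom", "tss_pos_1based", "strand"))
  df$tss_pos_1based <- as.integer(df$tss_pos_1based)
  if (any(is.na(df$tss_pos_1based)) || any(df$tss_pos_1based < 1L)) {
    stop("tss_pos_1based must be a positive integer")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(is.na(df$biotype) | !nzchar(df$biotype))) {
    stop("biotype must be nonempty")
  }
  df
}

#' Read a case/control sample sheet
#'
#' Tab-separated with columns `sample_id` and `group` (values `case` or
#' `control`); optional covariate columns (e.g. `age`, `sex`) are carried
#' through untouched.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`. Duplicate sample ids or unknown group labels are
#'   errors.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "group"))
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample_id in sample sheet: %s",
                 df$sample_id[duplicated(df$sample_id)][1L]))
  }
  if (!all(df$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  df
}

#' Read GWAS summary statistics
#'
#' Tab-separated with columns `rsid`, `chrom`, `pos_1based`, `pvalue`.
#' P-values must lie in (0, 1].
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of variants.
#' @export
read_gwas_table <- function(path) {
  df <- read_tsv_checked(path, c("rsid", "chrom", "pos_1based", "pvalue"))
  df$pos_1based <- as.integer(df$pos_1based)
  df$pvalue <- as.numeric(df$pvalue)
  if (any(is.na(df$pos_1based)) || any(df$pos_1based < 1L)) {
    stop("pos_1based must be a positive integer")
  }
  if (any(is.na(df$pvalue)) || any(df$pvalue <= 0 | df$pvalue > 1)) {
    stop("pvalue must lie in (0, 1]")
  }
  df
}

#' Read gene sets in GMT format
#'
#' Each line is `set_name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Genes are de-duplicated within a set.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) {
    stop("empty GMT file")
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: need name, description and >= 1 gene",
                 bad[1L]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in GMT file")
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Tab-separated, columns `chrom` and `length`; used to build whole-genome
#' background region sets.
#'
#' @param path Path to the TSV file.
#' @return `GRanges` spanning each chromosome.
#' @export
read_chrom_sizes <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "length"))
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(1L, as.integer(df$length)))
}

#' Write outlier calls to TSV
#'
#' Writes one row per call with the locus coordinates (1-based inclusive)
#' pulled from the peak catalog. Round-trips through [read_calls_tsv()].
#'
#' @param calls Calls `data.frame` from [detect_outliers()].
#' @param peaks Peak catalog `GRanges` (names are peak ids).
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, peaks, path) {
  idx <- match(calls$peak_id, names(peaks))
  if (anyNA(idx)) {
    stop("calls reference peak ids absent from the catalog")
  }
  out <- data.frame(
    peak_id = calls$peak_id,
    chrom = as.character(GenomicRanges::seqnames(peaks))[idx],
    start_1based = GenomicRanges::start(peaks)[idx],
    end_1based = GenomicRanges::end(peaks)[idx],
    sample_id = calls$sample_id,
    direction = calls$direction,
    extreme_fold = calls$extreme_fold,
    nominal_p = calls$nominal_p,
    control_mean = calls$control_mean,
    control_sd = calls$control_sd,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Read an outlier-calls TSV written by [write_calls_tsv()]
#' @param path Path to the TSV file.
#' @return A `data.frame` of calls with coordinates.
#' @export
read_calls_tsv <- function(path) {
  read_tsv_checked(path, c("peak_id", "chrom", "start_1based", "end_1based",
                           "sample_id", "direction", "extreme_fold",
                           "nominal_p", "control_mean", "control_sd"))
}

#' Write an enrichment-results table to TSV
#' @param df Results `data.frame` (e.g. from [category_enrichment()]).
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(df, path) {
  write_tsv(df, path)
}

#' Write / read a peaks-by-samples coverage matrix
#'
#' The on-disk form is a TSV with a leading `peak_id` column followed by one
#' column per sample.
#'
#' @param mat Numeric matrix with peak ids as rownames, sample ids as
#'   colnames.
#' @param path File path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(peak_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_checked(path, "peak_id")
  m <- as.matrix(df[, setdiff(names(df), "peak_id"), drop = FALSE])
  rownames(m) <- df$peak_id
  storage.mode(m) <- "double"
  m
}

#' Read per-peak low-MAPQ fractions
#'
#' TSV with columns `peak_id` and `low_mapq_fraction` (fraction of reads in
#' the peak with MAPQ < 10, pooled over samples; `NA` when no reads were
#' observed).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of fractions.
#' @export
read_mapq_tsv <- function(path) {
  df <- read_tsv_checked(path, c("peak_id", "low_mapq_fraction"))
  frac <- as.numeric(df$low_mapq_fraction)
  if (any(frac < 0 | frac > 1, na.rm = TRUE)) {
    stop("low_mapq_fraction must lie in [0, 1]")
  }
  stats::setNames(frac, df$peak_id)
}

#' Read per-sample promoter read tallies
#'
#' TSV with columns `sample_id` and `promoter_tally` (total reads mapped to
#' the merged promoter regions of that sample's library).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of tallies.
#' @export
read_tally_tsv <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "promoter_tally"))
  stats::setNames(as.numeric(df$promoter_tally), df$sample_id)
}
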