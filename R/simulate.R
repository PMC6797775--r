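#' Configuration for a synthetic case-control cohort
#'
#' Describes the statistical model of the simulated cohort: per-peak
#' log-normal baseline coverage shared by all samples, multiplicative
#' log-normal sample noise with a given coefficient of variation, per-sample
#' library-size factors (which cancel under promoter-anchored
#' normalization), a list of case-specific spiked alterations, and a small
#' fraction of mappability-artifact peaks with high low-MAPQ read fractions.
#' Defaults mirror the cohort the detection rules were designed for:
#' 16 cases and 16 controls with thousands of promoter-scale peaks.
#'
#' @param n_cases,n_controls Number of case/control samples (default 16 each).
#' @param n_peaks Number of catalog peaks (default 5000).
#' @param peak_width Peak width in bp (default 1500).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-peak baseline normalized coverage (defaults `log(20)` and 1).
#' @param sample_noise_cv Coefficient of variation of the multiplicative
#'   per-sample noise (default 0.15); 0 gives a noiseless cohort.
#' @param library_factor_range Range of the uniform per-sample library
#'   factor (default `c(0.5, 2)`); affects raw coverage and promoter
#'   tallies jointly, leaving normalized coverage untouched.
#' @param spikes Optional `data.frame` with columns `peak` (row index),
#'   `case` (case index), `direction` (`up`/`down`) and `fold` (above 1 for
#'   up, in (0, 1) for down) describing the ground-truth alterations.
#' @param mapq_artifact_fraction Fraction of (non-spiked) peaks simulated as
#'   mappability artifacts, with low-MAPQ fraction >= 0.75 (default 0.01).
#' @param down_ctrl_floor Down-spiked peaks are rescaled so every control
#'   stays at least this high (default 5.5), keeping the every-control-at-
#'   least-5 clause of the down rule exercisable by construction.
#' @param seed Integer RNG seed for the bundle.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 16, n_controls = 16, n_peaks = 5000,
                              peak_width = 1500,
                              baseline_meanlog = log(20), baseline_sdlog = 1,
                              sample_noise_cv = 0.15,
                              library_factor_range = c(0.5, 2),
                              spikes = NULL,
                              mapq_artifact_fraction = 0.01,
                              down_ctrl_floor = 5.5,
                              seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_peaks >= 1, peak_width >= 1,
            sample_noise_cv >= 0, length(library_factor_range) == 2L,
            library_factor_range[1] > 0,
            library_factor_range[2] >= library_factor_range[1],
            mapq_artifact_fraction >= 0, mapq_artifact_fraction < 1)
  if (!is.null(spikes)) {
    stopifnot(is.data.frame(spikes),
              all(c("peak", "case", "direction", "fold") %in% names(spikes)))
    if (any(spikes$peak < 1 | spikes$peak > n_peaks)) {
      stop("spike peak index out of range")
    }
    if (any(spikes$case < 1 | spikes$case > n_cases)) {
      stop("spike case index out of range")
    }
    if (!all(spikes$direction %in% c("up", "down"))) {
      stop("spike direction must be 'up' or 'down'")
    }
    up <- spikes$direction == "up"
    if (any(spikes$fold[up] <= 1) ||
        any(spikes$fold[!up] <= 0 | spikes$fold[!up] >= 1)) {
      stop("spike fold must be > 1 for up and in (0, 1) for down")
    }
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_peaks = as.integer(n_peaks),
                 peak_width = as.integer(peak_width),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 sample_noise_cv = sample_noise_cv,
                 library_factor_range = library_factor_range,
                 spikes = spikes,
                 mapq_artifact_fraction = mapq_artifact_fraction,
                 down_ctrl_floor = down_ctrl_floor,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw a random ground-truth spike table
#'
#' Picks distinct peaks and random case samples for the requested numbers of
#' up- and down-spiked alterations. Uses the current RNG state.
#'
#' @param config A [simulation_config()] (for the index ranges).
#' @param n_up,n_down Number of up/down spikes.
#' @param up_fold,down_fold Spike folds (defaults 4 and 0.2).
#' @return Spike `data.frame` suitable for `simulation_config(spikes = )`.
#' @export
random_spikes <- function(config, n_up = 50, n_down = 50,
                          up_fold = 4, down_fold = 0.2) {
  n <- n_up + n_down
  stopifnot(n <= config$n_peaks)
  peaks <- sample.int(config$n_peaks, n)
  data.frame(
    peak = peaks,
    case = sample.int(config$n_cases, n, replace = TRUE),
    direction = rep(c("up", "down"), c(n_up, n_down)),
    fold = rep(c(up_fold, down_fold), c(n_up, n_down)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete case-control cohort bundle
#'
#' Generates, deterministically for a given seed, a peak catalog on a
#' synthetic chromosome, the peaks-by-samples normalized coverage matrix
#' under the model `q_ij = baseline_i * noise_ij * spike_ij`, a sample
#' sheet, pooled low-MAPQ fractions (with artifact peaks chosen among
#' non-spiked peaks), per-sample library factors and promoter tallies, and
#' the ground-truth spike table. Down-spiked rows are rescaled upward when
#' needed so that every control keeps coverage above `down_ctrl_floor`,
#' guaranteeing the down rule can fire on them. Library factors are drawn
#' last so that changing their range perturbs nothing else.
#'
#' @param config A [simulation_config()].
#' @return A `cohort_bundle` list: `peaks` (`GRanges`), `matrix`,
#'   `sample_sheet`, `mapq`, `truth` (spikes with ids), `artifacts`
#'   (logical per peak), `library` (sample_id, promoter_tally, factor) and
#'   the echoed `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_peaks <- config$n_peaks
  cases <- paste0("S", seq_len(config$n_cases))
  controls <- paste0("C", seq_len(config$n_controls))
  samples <- c(cases, controls)
  n_samples <- length(samples)

  gap <- 10000L
  starts <- (seq_len(n_peaks) - 1L) * (config$peak_width + gap) + 1L
  peak_ids <- sprintf("peak_%05d", seq_len(n_peaks))
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, width = config$peak_width))
  names(peaks) <- peak_ids

  baseline <- stats::rlnorm(n_peaks, config$baseline_meanlog,
                            config$baseline_sdlog)
  sdlog <- sqrt(log(1 + config$sample_noise_cv^2))
  noise <- matrix(
    stats::rlnorm(n_peaks * n_samples, meanlog = -sdlog^2 / 2, sdlog = sdlog),
    nrow = n_peaks)
  q <- baseline * noise
  dimnames(q) <- list(peak_ids, samples)

  spikes <- config$spikes
  if (!is.null(spikes) && nrow(spikes)) {
    ctrl_cols <- (config$n_cases + 1L):n_samples
    down_peaks <- unique(spikes$peak[spikes$direction == "down"])
    for (i in down_peaks) {
      mc <- min(q[i, ctrl_cols])
      if (mc < config$down_ctrl_floor) {
        q[i, ] <- q[i, ] * (config$down_ctrl_floor / mc)
      }
    }
    for (k in seq_len(nrow(spikes))) {
      q[spikes$peak[k], spikes$case[k]] <-
        q[spikes$peak[k], spikes$case[k]] * spikes$fold[k]
    }
  }

  spiked_peaks <- if (is.null(spikes)) integer(0) else unique(spikes$peak)
  n_art <- round(config$mapq_artifact_fraction * n_peaks)
  candidates <- setdiff(seq_len(n_peaks), spiked_peaks)
  if (n_art > length(candidates)) {
    stop("not enough non-spiked peaks to host the requested artifact fraction")
  }
  artifact <- rep(FALSE, n_peaks)
  low_frac <- stats::runif(n_peaks, 0, 0.5)
  if (n_art > 0L) {
    art_idx <- sample(candidates, n_art)
    artifact[art_idx] <- TRUE
    low_frac[art_idx] <- stats::runif(n_art, 0.75, 0.98)
  }

  # library factors drawn last: changing their range leaves q and mapq
  # draws untouched
  lf <- stats::runif(n_samples, config$library_factor_range[1],
                     config$library_factor_range[2])
  tallies <- round(lf * 1e7)

  truth <- if (is.null(spikes) || nrow(spikes) == 0L) {
    data.frame(peak_id = character(0), sample_id = character(0),
               direction = character(0), fold = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = peak_ids[spikes$peak],
               sample_id = cases[spikes$case],
               direction = spikes$direction, fold = spikes$fold,
               stringsAsFactors = FALSE)
  }

  structure(list(
    peaks = peaks,
    matrix = q,
    sample_sheet = data.frame(
      sample_id = samples,
      group = rep(c("case", "control"),
                  c(config$n_cases, config$n_controls)),
      stringsAsFactors = FALSE),
    mapq = stats::setNames(low_frac, peak_ids),
    truth = truth,
    artifacts = stats::setNames(artifact, peak_ids),
    library = data.frame(sample_id = samples, promoter_tally = tallies,
                         factor = tallies / 1e7, stringsAsFactors = FALSE),
    config = config
  ), class = "cohort_bundle")
}

#' Write a cohort bundle to disk
#'
#' Emits the bundle in the plain-text formats the pipeline readers accept:
#' `peaks.bed`, `matrix.tsv`, `samples.tsv`, `mapq.tsv`, `tallies.tsv`,
#' `truth_spikes.tsv`, `truth_artifacts.tsv` and a `manifest.yaml` recording
#' the seed, the configuration and per-file MD5 checksums. With
#' `tracks = TRUE` it additionally writes one bedGraph per sample with
#' rectangular per-peak profiles (uniform per-base value
#' `q * factor / width`), which quantify back to the matrix exactly up to
#' floating-point formatting.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param tracks Also write per-sample bedGraph tracks? (default `FALSE`)
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir, tracks = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    peaks = file.path(dir, "peaks.bed"),
    matrix = file.path(dir, "matrix.tsv"),
    samples = file.path(dir, "samples.tsv"),
    mapq = file.path(dir, "mapq.tsv"),
    tallies = file.path(dir, "tallies.tsv"),
    truth_spikes = file.path(dir, "truth_spikes.tsv"),
    truth_artifacts = file.path(dir, "truth_artifacts.tsv")
  )
  write_bed(bundle$peaks, paths[["peaks"]])
  write_matrix_tsv(bundle$matrix, paths[["matrix"]])
  write_tsv(bundle$sample_sheet, paths[["samples"]])
  write_tsv(data.frame(peak_id = names(bundle$mapq),
                       low_mapq_fraction = unname(bundle$mapq),
                       stringsAsFactors = FALSE), paths[["mapq"]])
  write_tsv(bundle$library[, c("sample_id", "promoter_tally")],
            paths[["tallies"]])
  write_tsv(bundle$truth, paths[["truth_spikes"]])
  write_tsv(data.frame(peak_id = names(bundle$artifacts),
                       artifact = unname(bundle$artifacts),
                       stringsAsFactors = FALSE), paths[["truth_artifacts"]])
  if (tracks) {
    for (j in seq_len(ncol(bundle$matrix))) {
      s <- bundle$sample_sheet$sample_id[j]
      fac <- bundle$library$factor[j]
      track <- bundle$peaks
      track$score <- bundle$matrix[, j] * fac / GenomicRanges::width(track)
      names(track) <- NULL
      p <- file.path(dir, paste0("coverage_", s, ".bedgraph"))
      write_bedgraph(track, p)
      paths <- c(paths, stats::setNames(p, paste0("coverage_", s)))
    }
  }
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  cfg_list$spikes <- if (is.null(cfg$spikes)) NULL else
    lapply(seq_len(nrow(cfg$spikes)), function(k) as.list(cfg$spikes[k, ]))
  manifest <- list(
    seed = cfg$seed,
    config = cfg_list,
    files = lapply(stats::setNames(as.list(unname(paths)), names(paths)),
                   function(p) list(path = basename(p),
                                    md5 = unname(tools::md5sum(p))))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Simulate a TSS annotation for a peak catalog
#'
#' Assigns each peak to `protein_coding`, `noncoding` or `unannotated` in
#' the requested proportions (realized exactly up to rounding, assignment
#' randomized with the current RNG). Annotated peaks get one TSS at their
#' midpoint with a matching biotype.
#'
#' @param peaks Peak catalog `GRanges`.
#' @param proportions Named numeric vector summing to 1 with entries
#'   `protein_coding`, `noncoding`, `unannotated`.
#' @return TSS `data.frame` in the [read_tss_table()] schema.
#' @export
simulate_annotation <- function(peaks,
                                proportions = c(protein_coding = 0.565,
                                                noncoding = 0.130,
                                                unannotated = 0.305)) {
  stopifnot(all(c("protein_coding", "noncoding", "unannotated") %in%
                  names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-6) stop("proportions must sum to 1")
  n <- length(peaks)
  # largest-remainder apportionment: counts match proportions up to rounding
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  cat_assign <- sample(rep(names(proportions), counts))
  keep <- cat_assign != "unannotated"
  idx <- which(keep)
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) %/% 2L
  data.frame(
    gene_id = sprintf("GENE%05d", idx),
    transcript_id = sprintf("TX%05d", idx),
    biotype = ifelse(cat_assign[idx] == "protein_coding",
                     "protein_coding", "lincRNA"),
    chrom = as.character(GenomicRanges::seqnames(peaks))[idx],
    tss_pos_1based = mid[idx],
    strand = "+",
    stringsAsFactors = FALSE
  )
}

#' Simulate GWAS summary statistics around a peak catalog
#'
#' Places one genome-wide-significant variant at the center of each peak in
#' `sig_peak_ids` and `n_noise` non-significant variants at random positions
#' across the catalog's span.
#'
#' @param peaks Peak catalog `GRanges`.
#' @param sig_peak_ids Peak ids that should carry a significant variant.
#' @param n_noise Number of background variants (default 1000).
#' @param sig_p P-value assigned to significant variants (default 1e-9).
#' @return Variant `data.frame` in the [read_gwas_table()] schema.
#' @export
simulate_gwas <- function(peaks, sig_peak_ids = character(0), n_noise = 1000,
                          sig_p = 1e-9) {
  idx <- match(sig_peak_ids, names(peaks))
  if (anyNA(idx)) stop("sig_peak_ids must be peak ids from the catalog")
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) %/% 2L
  span <- max(GenomicRanges::end(peaks))
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  sig <- data.frame(
    rsid = sprintf("rs_sig_%04d", seq_along(idx)),
    chrom = chrom[idx], pos_1based = mid[idx], pvalue = sig_p,
    stringsAsFactors = FALSE)
  noise <- data.frame(
    rsid = sprintf("rs_bg_%05d", seq_len(n_noise)),
    chrom = chrom[1L],
    pos_1based = sample.int(span, n_noise, replace = TRUE),
    pvalue = stats::runif(n_noise, 1e-5, 1),
    stringsAsFactors = FALSE)
  rbind(sig, noise)
}

#' Simulate gene sets in GMT form
#'
#' Samples gene sets from a gene universe with the current RNG; useful as a
#' fixture for over-representation analysis.
#'
#' @param genes Gene universe (character vector).
#' @param n_sets Number of sets (default 10).
#' @param set_size Genes per set (default 20).
#' @return Named list of gene sets.
#' @export
simulate_gene_sets <- function(genes, n_sets = 10, set_size = 20) {
  stopifnot(set_size <= length(genes))
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  sets
}
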