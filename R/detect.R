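#' Detection thresholds for outlier calling
#'
#' Bundles the tunable thresholds of the outlier-calling rules. Defaults
#' reproduce the published analysis: an up call needs at least a 1.5-fold
#' excess over every control and case coverage of at least 5; a down call
#' needs at most a 0.5-fold ratio against every control with every control
#' at least 5; both need a one-tailed normal-model p below 0.01. Loci are
#' only testable when their pooled low-MAPQ read fraction is below 0.75 and
#' their cohort-mean normalized coverage is at least 2.5. All threshold
#' comparisons are exact ("at least"/"at most" read inclusively); no epsilon
#' is applied.
#'
#' @param up_fold Minimum case/control fold for an up call (> 1).
#' @param down_fold Maximum case/control fold for a down call (in (0, 1)).
#' @param min_case_cov_up Minimum case normalized coverage for an up call.
#' @param min_ctrl_cov_down Minimum normalized coverage required of every
#'   control for a down call.
#' @param nominal_p_max Upper bound (exclusive) on the nominal p.
#' @param low_cov_exclude Loci with cohort-mean normalized coverage below
#'   this are excluded from testing.
#' @param mapq_frac_exclude Loci whose low-MAPQ read fraction is at least
#'   this are excluded as mappability artifacts.
#' @param gene_link_dist Peak-to-TSS linkage distance in bp (strictly less
#'   than) used downstream by [annotate_peaks()].
#' @return A `detection_thresholds` list.
#' @export
detection_thresholds <- function(up_fold = 1.5, down_fold = 0.5,
                                 min_case_cov_up = 5, min_ctrl_cov_down = 5,
                                 nominal_p_max = 0.01, low_cov_exclude = 2.5,
                                 mapq_frac_exclude = 0.75,
                                 gene_link_dist = 2000) {
  if (!(up_fold > 1)) stop("up_fold must exceed 1")
  if (!(down_fold > 0 && down_fold < 1)) stop("down_fold must lie in (0, 1)")
  if (!(nominal_p_max > 0 && nominal_p_max < 1)) {
    stop("nominal_p_max must lie in (0, 1)")
  }
  structure(list(up_fold = up_fold, down_fold = down_fold,
                 min_case_cov_up = min_case_cov_up,
                 min_ctrl_cov_down = min_ctrl_cov_down,
                 nominal_p_max = nominal_p_max,
                 low_cov_exclude = low_cov_exclude,
                 mapq_frac_exclude = mapq_frac_exclude,
                 gene_link_dist = gene_link_dist),
            class = "detection_thresholds")
}

mapq_vector <- function(mapq, peak_ids) {
  if (is.null(mapq)) {
    return(rep(NA_real_, length(peak_ids)))
  }
  if (is.data.frame(mapq)) {
    mapq <- stats::setNames(mapq$low_mapq_fraction, mapq$peak_id)
  }
  out <- unname(mapq[peak_ids])
  as.numeric(out)
}

#' Which peaks are testable?
#'
#' A peak is excluded when its pooled low-MAPQ read fraction is known and at
#' least `mapq_frac_exclude`, or when its mean normalized coverage over all
#' cohort samples falls below `low_cov_exclude`. Peaks with no MAPQ
#' information are never excluded by the MAPQ rule.
#'
#' @param mat Peaks-by-samples normalized coverage matrix.
#' @param mapq Optional named numeric vector (or `data.frame` with
#'   `peak_id`, `low_mapq_fraction`) of pooled low-MAPQ fractions.
#' @param thresholds A [detection_thresholds()] object.
#' @return Named logical vector, `TRUE` for testable peaks.
#' @export
eligible_peaks <- function(mat, mapq = NULL,
                           thresholds = detection_thresholds()) {
  frac <- mapq_vector(mapq, rownames(mat))
  bad_mapq <- !is.na(frac) & frac >= thresholds$mapq_frac_exclude
  low_cov <- rowMeans(mat) < thresholds$low_cov_exclude
  stats::setNames(!(bad_mapq | low_cov), rownames(mat))
}

#' Human-readable exclusion reasons per peak
#'
#' @inheritParams eligible_peaks
#' @return Character vector ("" for testable peaks, otherwise
#'   `low_mapq`, `low_coverage`, or both separated by `;`).
#' @export
exclusion_reasons <- function(mat, mapq = NULL,
                              thresholds = detection_thresholds()) {
  frac <- mapq_vector(mapq, rownames(mat))
  bad_mapq <- !is.na(frac) & frac >= thresholds$mapq_frac_exclude
  low_cov <- rowMeans(mat) < thresholds$low_cov_exclude
  reason <- character(nrow(mat))
  reason[bad_mapq] <- "low_mapq"
  reason[low_cov] <- ifelse(nzchar(reason[low_cov]), "low_mapq;low_coverage",
                            "low_coverage")
  stats::setNames(reason, rownames(mat))
}

#' One-tailed nominal p under a normal control model
#'
#' Fits a normal distribution to the control coverages (sample mean and
#' unbiased n-1 standard deviation) and returns the one-tailed probability of
#' drawing a value at least as extreme as the case value in the tested
#' direction: the upper tail `P(X >= q)` for `up`, the lower tail
#' `P(X <= q)` for `down`. When the controls are identical (sd 0) the model
#' degenerates to a point mass: the p is 0 if the case value differs from
#' the control value in the tested direction and 1 otherwise.
#'
#' @param q_case Case normalized coverage (vectorized).
#' @param controls Numeric vector of control coverages (length >= 2).
#' @param direction `"up"` or `"down"`.
#' @return Probability in `[0, 1]`, same length as `q_case`.
#' @export
nominal_p <- function(q_case, controls, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(controls) < 2L) {
    stop("need at least 2 control values to fit the normal model")
  }
  mu <- mean(controls)
  sdv <- stats::sd(controls)
  if (sdv == 0) {
    extreme <- if (direction == "up") q_case > mu else q_case < mu
    return(ifelse(extreme, 0, 1))
  }
  if (direction == "up") {
    stats::pnorm(q_case, mu, sdv, lower.tail = FALSE)
  } else {
    stats::pnorm(q_case, mu, sdv)
  }
}

# Vectorized tail probabilities over peaks; handles per-peak sd = 0.
tail_p <- function(q, mu, sdv, upper) {
  p <- numeric(length(q))
  deg <- sdv == 0
  if (any(!deg)) {
    p[!deg] <- stats::pnorm(q[!deg], mu[!deg], sdv[!deg], lower.tail = !upper)
  }
  if (any(deg)) {
    extreme <- if (upper) q[deg] > mu[deg] else q[deg] < mu[deg]
    p[deg] <- ifelse(extreme, 0, 1)
  }
  p
}

#' Call per-case up/down outlier loci against all controls
#'
#' For every testable peak and every case sample, an **up** call is made when
#' the case coverage is at least `min_case_cov_up`, is at least
#' `up_fold` times the coverage of *every* control, and the one-tailed
#' nominal p is below `nominal_p_max`. A **down** call is made when every
#' control has coverage at least `min_ctrl_cov_down`, the case coverage is at
#' most `down_fold` times that of every control, and the lower-tail nominal p
#' is below `nominal_p_max`. A locus may be called up in one case sample and
#' down in another.
#'
#' `extreme_fold` records the worst-case ratio against the control panel:
#' the minimum of `q_case / q_control` for up calls and the maximum for down
#' calls.
#'
#' @param mat Peaks-by-samples normalized coverage matrix (sample ids as
#'   colnames).
#' @param sample_sheet `data.frame` with `sample_id` and `group`
#'   (`case`/`control`); every matrix column must appear in the sheet.
#' @param mapq Optional low-MAPQ fractions (see [eligible_peaks()]).
#' @param thresholds A [detection_thresholds()] object.
#' @param case_ids Optional subset of case samples to analyze (e.g. a
#'   correlation-flagged subgroup); each is still compared against the full
#'   control panel. Default: all cases in the sheet.
#' @return `data.frame` of calls ordered by (peak, sample): `peak_id`,
#'   `sample_id`, `direction`, `extreme_fold`, `nominal_p`, `control_mean`,
#'   `control_sd`.
#' @export
detect_outliers <- function(mat, sample_sheet, mapq = NULL,
                            thresholds = detection_thresholds(),
                            case_ids = NULL) {
  if (is.null(colnames(mat)) || is.null(rownames(mat))) {
    stop("matrix must have peak rownames and sample colnames")
  }
  unknown <- setdiff(colnames(mat), sample_sheet$sample_id)
  if (length(unknown)) {
    stop(sprintf("sample(s) in matrix missing from sample sheet: %s",
                 paste(unknown, collapse = ", ")))
  }
  controls <- intersect(sample_sheet$sample_id[sample_sheet$group == "control"],
                        colnames(mat))
  cases <- intersect(sample_sheet$sample_id[sample_sheet$group == "case"],
                     colnames(mat))
  if (!is.null(case_ids)) {
    missing <- setdiff(case_ids, cases)
    if (length(missing)) {
      stop(sprintf("case_ids not present as cases in the matrix: %s",
                   paste(missing, collapse = ", ")))
    }
    cases <- intersect(cases, case_ids)
  }
  if (length(cases) < 1L) stop("need at least 1 case sample")
  if (length(controls) < 2L) stop("need at least 2 control samples")

  elig <- eligible_peaks(mat, mapq, thresholds)
  ctrl <- mat[, controls, drop = FALSE]
  ctrl_mean <- rowMeans(ctrl)
  ctrl_sd <- apply(ctrl, 1L, stats::sd)
  ctrl_max <- apply(ctrl, 1L, max)
  ctrl_min <- apply(ctrl, 1L, min)
  down_possible <- ctrl_min >= thresholds$min_ctrl_cov_down

  pieces <- vector("list", length(cases))
  for (j in seq_along(cases)) {
    q <- mat[, cases[j]]
    p_up <- tail_p(q, ctrl_mean, ctrl_sd, upper = TRUE)
    p_dn <- tail_p(q, ctrl_mean, ctrl_sd, upper = FALSE)
    up <- elig & q >= thresholds$min_case_cov_up &
      q >= thresholds$up_fold * ctrl_max &
      p_up < thresholds$nominal_p_max
    dn <- elig & down_possible &
      q <= thresholds$down_fold * ctrl_min &
      p_dn < thresholds$nominal_p_max
    rows <- list()
    if (any(up)) {
      i <- which(up)
      rows$up <- data.frame(
        peak_idx = i, peak_id = rownames(mat)[i], sample_id = cases[j],
        direction = "up", extreme_fold = q[i] / ctrl_max[i],
        nominal_p = p_up[i], control_mean = ctrl_mean[i],
        control_sd = ctrl_sd[i], stringsAsFactors = FALSE
      )
    }
    if (any(dn)) {
      i <- which(dn)
      rows$down <- data.frame(
        peak_idx = i, peak_id = rownames(mat)[i], sample_id = cases[j],
        direction = "down", extreme_fold = q[i] / ctrl_min[i],
        nominal_p = p_dn[i], control_mean = ctrl_mean[i],
        control_sd = ctrl_sd[i], stringsAsFactors = FALSE
      )
    }
    if (length(rows)) {
      pieces[[j]] <- do.call(rbind, rows)
    }
  }
  calls <- do.call(rbind, c(pieces, list(empty_calls())))
  ord <- order(calls$peak_idx, match(calls$sample_id, cases),
               match(calls$direction, c("up", "down")))
  calls <- calls[ord, setdiff(names(calls), "peak_idx"), drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(peak_idx = integer(0), peak_id = character(0),
             sample_id = character(0), direction = character(0),
             extreme_fold = numeric(0), nominal_p = numeric(0),
             control_mean = numeric(0), control_sd = numeric(0),
             stringsAsFactors = FALSE)
}

#' Summarize recurrence of outlier calls across case samples
#'
#' Groups calls by (locus, direction) and, as a secondary view, by locus
#' regardless of direction. The singleton fraction is the share of groups
#' contributed by exactly one case sample -- the signature of
#' individual-specific ("epi-mutation"-like) alterations.
#'
#' @param calls Calls `data.frame` from [detect_outliers()].
#' @return List with `by_locus_direction` (peak_id, direction, n_samples),
#'   `singleton_fraction`, `multi` (groups with >= 2 samples), `by_locus`
#'   (distinct samples per peak, any direction) and
#'   `singleton_fraction_by_locus`. Fractions are `NA` when there are no
#'   calls.
#' @export
summarize_recurrence <- function(calls) {
  if (nrow(calls) == 0L) {
    empty <- data.frame(peak_id = character(0), direction = character(0),
                        n_samples = integer(0), stringsAsFactors = FALSE)
    return(structure(list(
      by_locus_direction = empty, singleton_fraction = NA_real_,
      multi = empty,
      by_locus = empty[, c("peak_id", "n_samples")],
      singleton_fraction_by_locus = NA_real_
    ), class = "recurrence_summary"))
  }
  bld <- stats::aggregate(list(n_samples = calls$sample_id),
                          by = list(peak_id = calls$peak_id,
                                    direction = calls$direction),
                          FUN = function(x) length(unique(x)))
  bld <- bld[order(bld$peak_id, bld$direction), , drop = FALSE]
  rownames(bld) <- NULL
  bl <- stats::aggregate(list(n_samples = calls$sample_id),
                         by = list(peak_id = calls$peak_id),
                         FUN = function(x) length(unique(x)))
  bl <- bl[order(bl$peak_id), , drop = FALSE]
  rownames(bl) <- NULL
  structure(list(
    by_locus_direction = bld,
    singleton_fraction = mean(bld$n_samples == 1L),
    multi = bld[bld$n_samples >= 2L, , drop = FALSE],
    by_locus = bl,
    singleton_fraction_by_locus = mean(bl$n_samples == 1L)
  ), class = "recurrence_summary")
}

#' @export
print.recurrence_summary <- function(x, ...) {
  cat(sprintf("recurrence over %d (locus, direction) groups\n",
              nrow(x$by_locus_direction)))
  cat(sprintf("  singleton fraction: %s\n",
              format(x$singleton_fraction, digits = 3)))
  cat(sprintf("  groups altered in >= 2 samples: %d\n", nrow(x$multi)))
  invisible(x)
}

#' Genome-wide Pearson correlation between samples
#'
#' Pearson correlation between the per-peak normalized coverage vectors of
#' every pair of samples. Zero-variance columns get `NA` against all
#' partners; the diagonal is 1 by convention.
#'
#' @param mat Peaks-by-samples normalized coverage matrix (>= 2 peaks).
#' @return Symmetric correlation matrix with sample ids as dimnames.
#' @export
sample_correlation <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 peaks to correlate samples")
  sds <- apply(mat, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(mat))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Flag globally divergent but mutually correlated case subgroups
#'
#' Operationalizes the cohort-splitting step: a cluster of case samples is
#' flagged when every within-cluster correlation exceeds each member's mean
#' correlation to all samples outside the cluster by at least `delta`. Such
#' samples resemble each other far more than they resemble the rest of the
#' cohort and are analyzed as a separate group. The procedure is
#' deterministic: qualifying pairs define a graph, connected components of
#' size >= 2 are candidate clusters, and a candidate is flagged only if all
#' its internal pairs qualify against the outside-cluster means.
#'
#' @param pcc Correlation matrix from [sample_correlation()] (all samples).
#' @param case_ids Case sample ids to consider for flagging; defaults to all
#'   row names.
#' @param delta Minimum correlation gap (default 0.05).
#' @return List with `flagged` (list of character vectors, possibly empty)
#'   and `main` (unflagged case ids).
#' @export
flag_subgroups <- function(pcc, case_ids = NULL, delta = 0.05) {
  all_ids <- rownames(pcc)
  if (is.null(case_ids)) case_ids <- all_ids
  stopifnot(all(case_ids %in% all_ids))
  n <- length(case_ids)
  qualifies <- function(i, j, exclude) {
    rest_i <- setdiff(all_ids, c(i, exclude))
    rest_j <- setdiff(all_ids, c(j, exclude))
    m_i <- mean(pcc[i, rest_i], na.rm = TRUE)
    m_j <- mean(pcc[j, rest_j], na.rm = TRUE)
    v <- pcc[i, j]
    !is.na(v) && v >= m_i + delta && v >= m_j + delta
  }
  adj <- matrix(FALSE, n, n, dimnames = list(case_ids, case_ids))
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        adj[a, b] <- adj[b, a] <-
          qualifies(case_ids[a], case_ids[b], case_ids[c(a, b)])
      }
    }
  }
  # connected components of the qualifying-pair graph
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (a in seq_len(n)) {
    if (is.na(comp[a])) {
      k <- k + 1L
      frontier <- a
      comp[a] <- k
      while (length(frontier)) {
        nb <- which(adj[frontier[1L], ] & is.na(comp))
        comp[nb] <- k
        frontier <- c(frontier[-1L], nb)
      }
    }
  }
  flagged <- list()
  for (g in unique(comp)) {
    members <- case_ids[comp == g]
    if (length(members) < 2L) next
    pairs_ok <- TRUE
    for (a in seq_len(length(members) - 1L)) {
      for (b in seq((a + 1L), length(members))) {
        if (!qualifies(members[a], members[b], members)) {
          pairs_ok <- FALSE
        }
      }
    }
    if (pairs_ok) {
      flagged[[length(flagged) + 1L]] <- members
    }
  }
  list(flagged = flagged,
       main = setdiff(case_ids, unlist(flagged)))
}
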