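# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (per-base masks, literal clause loops, log-binomial enumeration) and
# never call the code paths they check.

gr1 <- function(chrom, start, end, ids = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(ids)) names(g) <- ids
  g
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# per-base union oracle for interval merging (single chromosome)
merge_oracle_bases <- function(starts, ends) {
  mask <- logical(max(ends))
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  which(mask)
}

# sample sheet for n cases (S1..) and m controls (C1..)
make_sheet <- function(n_cases, n_controls) {
  data.frame(
    sample_id = c(paste0("S", seq_len(n_cases)), paste0("C", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    stringsAsFactors = FALSE
  )
}

# literal four-clause brute-force outlier caller, independent of the package
# implementation (manual mean/sd, explicit per-control loops)
brute_detect <- function(mat, sheet, mapq = NULL,
                         up_fold = 1.5, down_fold = 0.5,
                         min_case = 5, min_ctrl = 5, p_max = 0.01,
                         low_cov = 2.5, mapq_excl = 0.75) {
  cases <- sheet$sample_id[sheet$group == "case"]
  controls <- sheet$sample_id[sheet$group == "control"]
  out <- list()
  for (i in seq_len(nrow(mat))) {
    f <- if (is.null(mapq)) NA_real_ else unname(mapq[rownames(mat)[i]])
    if (!is.na(f) && f >= mapq_excl) next
    if (mean(mat[i, ]) < low_cov) next
    ctrl <- mat[i, controls]
    mu <- sum(ctrl) / length(ctrl)
    sdv <- sqrt(sum((ctrl - mu)^2) / (length(ctrl) - 1))
    for (s in cases) {
      q <- mat[i, s]
      # up: case >= min_case, >= up_fold * every control, upper-tail p < p_max
      if (q >= min_case && all(q >= up_fold * ctrl)) {
        p <- if (sdv > 0) stats::pnorm(q, mu, sdv, lower.tail = FALSE)
             else if (q > mu) 0 else 1
        if (p < p_max) {
          out[[length(out) + 1L]] <- c(rownames(mat)[i], s, "up")
        }
      }
      # down: every control >= min_ctrl, case <= down_fold * every control
      if (all(ctrl >= min_ctrl) && all(q <= down_fold * ctrl)) {
        p <- if (sdv > 0) stats::pnorm(q, mu, sdv)
             else if (q < mu) 0 else 1
        if (p < p_max) {
          out[[length(out) + 1L]] <- c(rownames(mat)[i], s, "down")
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(peak_id = character(0), sample_id = character(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("peak_id", "sample_id", "direction")
  df[order(df$peak_id, df$sample_id, df$direction), , drop = FALSE]
}

call_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$peak_id, df$sample_id, df$direction, sep = "|"))
}

# hypergeometric upper-tail oracle by direct enumeration over the support,
# via log-binomial coefficients (independent of phyper)
hyper_tail_enum <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  if (a > hi) return(0)
  xs <- max(a, lo):hi
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Benjamini-Hochberg q-values from the textbook formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# random coverage track (step function) on one chromosome, plus a per-base
# expansion for brute-force quantification oracles
random_track <- function(n_steps, max_pos = 500) {
  bounds <- sort(sample.int(max_pos, n_steps + 1L))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L] - 1L
  keep <- ends >= starts
  gr <- gr1("chr1", starts[keep], ends[keep])
  gr$score <- round(stats::runif(sum(keep), 0, 10), 3)
  gr
}

track_per_base <- function(track, max_pos) {
  v <- numeric(max_pos)
  for (i in seq_along(track)) {
    v[GenomicRanges::start(track)[i]:GenomicRanges::end(track)[i]] <-
      track$score[i]
  }
  v
}
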