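make_mat <- function(values, peak_ids, sample_ids) {
  matrix(values, nrow = length(peak_ids), byrow = TRUE,
         dimnames = list(peak_ids, sample_ids))
}

test_that("locus eligibility applies the MAPQ and low-coverage filters at exact boundaries", {
  sheet <- make_sheet(1, 2)
  mat <- make_mat(c(100, 100, 100,
                    1, 1, 1,
                    100, 100, 100,
                    100, 100, 100), paste0("p", 1:4), sheet$sample_id)
  mapq <- c(p1 = 0.1, p2 = 0.1, p3 = 0.75, p4 = NA)
  elig <- eligible_peaks(mat, mapq)
  expect_true(elig[["p1"]])                 # clean peak
  expect_false(elig[["p2"]])                # cohort mean 1 < 2.5
  expect_false(elig[["p3"]])                # mapq fraction 0.75 is inclusive
  expect_true(elig[["p4"]])                 # missing mapq never excludes
  reasons <- exclusion_reasons(mat, mapq)
  expect_equal(unname(reasons[c("p1", "p2", "p3")]),
               c("", "low_coverage", "low_mapq"))
})

test_that("nominal p is one-tailed with a degenerate point-mass rule at sd 0", {
  # identical controls, case above: certainty in the up direction
  expect_equal(nominal_p(20, rep(10, 16), "up"), 0)
  expect_equal(nominal_p(10, rep(10, 16), "up"), 1)
  expect_equal(nominal_p(5, rep(10, 16), "down"), 0)
  # mean 10, sd 2 controls; case at the 99th percentile
  controls <- 10 + c(-1, 1) * sqrt(2)
  expect_equal(mean(controls), 10)
  expect_equal(sd(controls), 2)
  p_up <- nominal_p(10 + 2.3263 * 2, controls, "up")
  expect_equal(p_up, 0.01, tolerance = 1e-3)
  # symmetric down case gives the same tail probability
  p_dn <- nominal_p(10 - 2.3263 * 2, controls, "down")
  expect_equal(p_dn, p_up, tolerance = 1e-12)
  expect_error(nominal_p(5, 10, "up"), "at least 2 control")
})

test_that("detect_outliers applies the four clauses literally", {
  sheet <- make_sheet(2, 16)
  ids <- sheet$sample_id
  # p1: S1 at 30 vs all controls 10 -> up call, fold 3, p 0
  # p2: S1 at 12 vs controls 10 -> fails the 1.5-fold clause
  # p3: S2 at 4 vs controls 10 (all >= 5) -> down call, fold 0.4
  mat <- make_mat(c(30, 10, rep(10, 16),
                    12, 10, rep(10, 16),
                    10, 4, rep(10, 16)), paste0("p", 1:3), ids)
  calls <- detect_outliers(mat, sheet)
  expect_equal(nrow(calls), 2L)
  up <- calls[calls$direction == "up", ]
  expect_equal(up$peak_id, "p1")
  expect_equal(up$sample_id, "S1")
  expect_equal(up$extreme_fold, 3)
  expect_equal(up$nominal_p, 0)
  expect_equal(up$control_mean, 10)
  dn <- calls[calls$direction == "down", ]
  expect_equal(dn$peak_id, "p3")
  expect_equal(dn$sample_id, "S2")
  expect_equal(dn$extreme_fold, 0.4)
})

test_that("a locus can be up in one case and down in another", {
  sheet <- make_sheet(2, 16)
  mat <- make_mat(c(30, 4, rep(10, 16)), "p1", sheet$sample_id)
  calls <- detect_outliers(mat, sheet)
  expect_equal(call_key(calls), c("p1|S1|up", "p1|S2|down"))
})

test_that("detection validates the sample sheet against the matrix", {
  sheet <- make_sheet(1, 2)
  mat <- make_mat(c(1, 2, 3, 4), "p1", c(sheet$sample_id, "ghost"))
  expect_error(detect_outliers(mat, sheet), "ghost")
  small <- make_mat(c(1, 2), "p1", c("S1", "C1"))
  expect_error(detect_outliers(small, make_sheet(1, 1)), "2 control")
})

test_that("calls match the literal brute-force oracle on random matrices", {
  set.seed(202)
  sheet <- make_sheet(4, 8)
  for (trial in 1:50) {
    mat <- matrix(rlnorm(60 * 12, log(8), 1.2), 60,
                  dimnames = list(sprintf("p%02d", 1:60), sheet$sample_id))
    mapq <- setNames(runif(60), rownames(mat))
    calls <- detect_outliers(mat, sheet, mapq)
    expect_equal(call_key(calls), call_key(brute_detect(mat, sheet, mapq)))
  }
})

test_that("tightening thresholds never enlarges the call set", {
  set.seed(77)
  sheet <- make_sheet(4, 8)
  mat <- matrix(rlnorm(300 * 12, log(10), 1), 300,
                dimnames = list(sprintf("p%03d", 1:300), sheet$sample_id))
  base <- call_key(detect_outliers(mat, sheet))
  tighter_fold <- call_key(detect_outliers(
    mat, sheet, thresholds = detection_thresholds(up_fold = 2, down_fold = 0.4)))
  tighter_p <- call_key(detect_outliers(
    mat, sheet, thresholds = detection_thresholds(nominal_p_max = 0.001)))
  expect_true(all(tighter_fold %in% base))
  expect_true(all(tighter_p %in% base))
})

test_that("recurrence summaries group by locus and direction", {
  calls <- data.frame(
    peak_id = c("p1", "p1", "p2"),
    sample_id = c("S1", "S2", "S3"),
    direction = c("up", "up", "down"),
    stringsAsFactors = FALSE
  )
  rec <- summarize_recurrence(calls)
  expect_equal(rec$by_locus_direction$n_samples, c(2L, 1L))
  expect_equal(rec$singleton_fraction, 0.5)
  expect_equal(rec$multi$peak_id, "p1")
  # empty input: fractions reported missing
  rec0 <- summarize_recurrence(calls[0, ])
  expect_true(is.na(rec0$singleton_fraction))
  expect_equal(nrow(rec0$by_locus_direction), 0L)
})

test_that("recurrence matches a brute-force grouping oracle on random call sets", {
  set.seed(15)
  for (trial in 1:20) {
    calls <- data.frame(
      peak_id = sample(sprintf("p%02d", 1:12), 40, replace = TRUE),
      sample_id = sample(paste0("S", 1:6), 40, replace = TRUE),
      direction = sample(c("up", "down"), 40, replace = TRUE),
      stringsAsFactors = FALSE
    )
    calls <- unique(calls)
    rec <- summarize_recurrence(calls)
    key <- paste(calls$peak_id, calls$direction)
    oracle <- vapply(split(calls$sample_id, key),
                     function(x) length(unique(x)), integer(1L))
    got <- setNames(rec$by_locus_direction$n_samples,
                    paste(rec$by_locus_direction$peak_id,
                          rec$by_locus_direction$direction))
    expect_equal(got[names(oracle)], oracle)
    expect_equal(rec$singleton_fraction, mean(oracle == 1))
  }
})

test_that("sample correlation is Pearson on columns with NA for flat samples", {
  set.seed(21)
  mat <- matrix(rnorm(5 * 4, 10), 5,
                dimnames = list(paste0("p", 1:5), paste0("X", 1:4)))
  mat[, 2] <- mat[, 1]            # identical
  mat[, 3] <- 30 - mat[, 1]       # negation plus constant
  cc <- sample_correlation(mat)
  expect_equal(cc["X1", "X2"], 1)
  expect_equal(cc["X1", "X3"], -1)
  expect_equal(cc, t(cc))
  # direct covariance-formula oracle
  manual <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc["X1", "X4"], manual(mat[, 1], mat[, 4]), tolerance = 1e-12)
  # zero-variance column
  mat[, 4] <- 7
  cc2 <- sample_correlation(mat)
  expect_true(all(is.na(cc2["X4", c("X1", "X2", "X3")])))
  expect_equal(cc2["X4", "X4"], 1)
})

test_that("subgroup flagging isolates mutually correlated, globally divergent pairs", {
  ids <- c(paste0("S", 1:4), paste0("C", 1:4))
  pcc <- matrix(0.89, 8, 8, dimnames = list(ids, ids))
  diag(pcc) <- 1
  pcc["S1", "S2"] <- pcc["S2", "S1"] <- 0.97   # gap 0.08 >= 0.05
  fl <- flag_subgroups(pcc, case_ids = paste0("S", 1:4))
  expect_equal(fl$flagged, list(c("S1", "S2")))
  expect_equal(fl$main, c("S3", "S4"))
  # homogeneous cohort: nothing flagged
  hom <- matrix(0.9, 8, 8, dimnames = list(ids, ids)); diag(hom) <- 1
  expect_equal(flag_subgroups(hom, paste0("S", 1:4))$flagged, list())
  # vacuous threshold
  expect_equal(flag_subgroups(pcc, paste0("S", 1:4), delta = 1)$flagged,
               list())
})
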