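mk_tss <- function(gene, biotype, pos, chrom = "chr1") {
  data.frame(gene_id = gene, transcript_id = paste0(gene, ".t1"),
             biotype = biotype, chrom = chrom, tss_pos_1based = pos,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("peak-to-gene linkage uses strict <2 kb distance with coding dominance", {
  peaks <- gr1("chr1", c(1000, 1000, 1000, 1000), c(2000, 2000, 2000, 2000),
               paste0("p", 1:4))
  # p1: TSS inside (distance 0); p2: coding TSS 1501 bp away (linked);
  # p3: only a noncoding TSS in range; p4: nearest TSS exactly 2000 bp away
  tss <- rbind(
    mk_tss("G1", "protein_coding", 1500),
    mk_tss("G2", "protein_coding", 3501),
    mk_tss("G3", "lincRNA", 1200),
    mk_tss("G4", "protein_coding", 4000)
  )
  ann <- annotate_peaks(peaks[1], tss[1, ])
  expect_equal(ann$category, "protein_coding")
  ann2 <- annotate_peaks(peaks[2], tss[2, ])
  expect_equal(ann2$category, "protein_coding")  # distance 1501 < 2000
  ann3 <- annotate_peaks(peaks[3], tss[3, ])
  expect_equal(ann3$category, "noncoding")
  ann4 <- annotate_peaks(peaks[4], tss[4, ])
  expect_equal(ann4$category, "unannotated")     # distance 2000 not < 2000
  # dominance: coding + noncoding links -> protein_coding
  ann5 <- annotate_peaks(peaks[1], rbind(tss[1, ], tss[3, ]))
  expect_equal(ann5$category, "protein_coding")
  expect_equal(ann5$linked_genes, "G1,G3")
  expect_equal(ann5$linked_coding_genes, "G1")
})

test_that("annotation categories partition the catalog", {
  set.seed(31)
  n <- 400
  peaks <- gr1("chr1", seq(1, by = 5000, length.out = n) ,
               seq(1, by = 5000, length.out = n) + 999,
               sprintf("p%03d", 1:n))
  tss <- simulate_annotation(peaks)
  ann <- annotate_peaks(peaks, tss)
  expect_equal(nrow(ann), n)
  expect_equal(sum(table(ann$category)), n)
  expect_true(all(ann$category %in%
                    c("protein_coding", "noncoding", "unannotated")))
})

test_that("one-tailed Fisher matches closed-form small tables", {
  r <- fisher_one_tailed(4, 0, 1, 5)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)  # C(5,4)C(5,0)/C(10,4)
  expect_equal(fisher_one_tailed(0, 5, 3, 2)$p, 1)  # P(X >= 0) = 1
  expect_error(fisher_one_tailed(-1, 1, 1, 1), "non-negative")
  expect_true(is.na(fisher_one_tailed(0, 3, 0, 5)$odds_ratio))  # 0/0
  expect_equal(fisher_one_tailed(2, 1, 1, 2)$odds_ratio, 4)
})

test_that("category enrichment reproduces fixture counts and composes fisher tests", {
  # catalog with the published margins: 16689 coding, 3857 noncoding,
  # 9000 unannotated peaks; 561 altered loci hitting 157/112/292 of them
  categories <- rep(c("protein_coding", "noncoding", "unannotated"),
                    c(16689, 3857, 9001))
  ann <- data.frame(peak_id = sprintf("pk%05d", seq_along(categories)),
                    category = categories, stringsAsFactors = FALSE)
  altered <- c(ann$peak_id[ann$category == "protein_coding"][1:157],
               ann$peak_id[ann$category == "noncoding"][1:112],
               ann$peak_id[ann$category == "unannotated"][1:292])
  res <- category_enrichment(ann, altered)
  expect_equal(res$test_name,
               c("annotated", "protein_coding", "noncoding", "unannotated"))
  expect_equal(res$a, c(269L, 157L, 112L, 292L))
  expect_equal(res$a + res$b + res$c + res$d, rep(nrow(ann), 4L))
  # compositional oracle: each row equals a direct fisher_one_tailed call
  for (i in seq_len(nrow(res))) {
    direct <- fisher_one_tailed(res$a[i], res$b[i], res$c[i], res$d[i])
    expect_equal(res$p[i], direct$p, tolerance = 1e-14)
  }
  # Bonferroni is min(1, m p) exactly
  expect_equal(res$p_adjusted, pmin(1, 4 * res$p))
  # degenerate foreground: altered = all peaks -> no enrichment possible
  res_all <- category_enrichment(ann, ann$peak_id)
  expect_true(all(res_all$p == 1))
  expect_error(category_enrichment(ann, character(0)), "empty")
})

test_that("GWAS region sets merge flanked significant variants", {
  variants <- data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    chrom = "chr1",
    pos_1based = c(1000000L, 1150000L, 5000000L),
    pvalue = c(1e-9, 4e-8, 0.2),
    stringsAsFactors = FALSE
  )
  rs <- build_region_set(variants)
  expect_equal(length(rs), 1L)
  expect_equal(GenomicRanges::start(rs), 900000L)
  expect_equal(GenomicRanges::end(rs), 1250000L)
  expect_equal(GenomicRanges::width(rs), 350001L)
  # no passing variants
  expect_equal(length(build_region_set(variants, p_threshold = 1e-12)), 0L)
  # suggestive threshold yields a covering superset of the significant set
  strict <- build_region_set(variants, 5e-8)
  loose <- build_region_set(variants, 1e-6)
  ov <- GenomicRanges::intersect(loose, strict)
  expect_equal(sum(GenomicRanges::width(ov)), sum(GenomicRanges::width(strict)))
})

test_that("region overlap test restricts the universe to background-overlapping peaks", {
  set.seed(42)
  n <- 120
  starts <- seq(1, by = 10000, length.out = n)
  peaks <- gr1("chr1", starts, starts + 999, sprintf("p%03d", 1:n))
  bg <- gr1("chr1", 1, starts[80] + 999)        # first 80 peaks in universe
  sig <- gr1("chr1", 1, starts[20] + 999)       # first 20 overlap significant
  altered <- sprintf("p%03d", c(1:10, 41:50, 100:110))  # 100:110 outside bg
  r <- region_overlap_test(peaks, altered, sig, bg)
  # brute-force recount over the universe
  expect_equal(unlist(r[c("a", "b", "c", "d")], use.names = FALSE),
               c(10, 10, 10, 50))
  expect_equal(r$p, fisher_one_tailed(10, 10, 10, 50)$p)
  # significant set equal to the background: the category is the universe
  expect_equal(region_overlap_test(peaks, altered, bg, bg)$p, 1)
  # no altered peak overlaps significant regions -> a = 0 -> p = 1
  none <- region_overlap_test(peaks, sprintf("p%03d", 41:50), sig, bg)
  expect_equal(none$a, 0)
  expect_equal(none$p, 1)
  expect_error(region_overlap_test(peaks, altered, sig,
                                   gr1("chr9", 1, 10)), "empty peak universe")
})

test_that("region overlap is invariant to splitting regions into touching pieces", {
  n <- 60
  starts <- seq(1, by = 10000, length.out = n)
  peaks <- gr1("chr1", starts, starts + 999, sprintf("p%03d", 1:n))
  bg <- gr1("chr1", 1, max(starts) + 999)
  sig <- gr1("chr1", 1, 250000)
  split_sig <- gr1("chr1", c(1, 100001, 200001), c(100000, 200000, 250000))
  altered <- sprintf("p%03d", seq(2, 40, by = 3))
  expect_equal(region_overlap_test(peaks, altered, sig, bg),
               region_overlap_test(peaks, altered, split_sig, bg))
})

test_that("gene overlap tests and the BH battery behave on known tables", {
  bg <- sprintf("G%03d", 1:100)
  r <- gene_overlap_test("G001", "G001", bg)
  expect_equal(unlist(r[c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 0, 0, 99))
  expect_equal(r$p, 1 / 100, tolerance = 1e-12)
  # disjoint lists: a = 0 -> p = 1
  expect_equal(gene_overlap_test("G001", "G002", bg)$p, 1)
  # reported genes outside the background are dropped with a warning
  expect_warning(gene_overlap_test("G001", c("G001", "ZZZ"), bg), "dropped 1")
  expect_error(gene_overlap_test("ZZZ", "G001", bg), "subset")
  # BH with six tied p-values: all q equal the common p
  battery <- data.frame(test_name = paste0("t", 1:6), p = rep(0.01, 6),
                        stringsAsFactors = FALSE)
  adj <- run_test_battery(battery)
  expect_equal(adj$p_adjusted, rep(0.01, 6))
  expect_true(all(adj$significant))
})

test_that("ORA matches per-set fisher + BH oracles on random gene sets", {
  set.seed(66)
  bg <- sprintf("G%04d", 1:500)
  gene_list <- sample(bg, 60)
  sets <- lapply(1:20, function(i) sample(bg, sample(10:60, 1)))
  names(sets) <- sprintf("set%02d", 1:20)
  res <- run_ora(gene_list, sets, bg)
  expect_equal(nrow(res), 20L)
  for (i in seq_len(nrow(res))) {
    set <- sets[[res$test_name[i]]]
    a <- length(intersect(gene_list, set))
    direct <- fisher_one_tailed(a, 60 - a, length(set) - a,
                                500 - 60 - length(set) + a)
    expect_equal(res$p[i], direct$p, tolerance = 1e-14)
  }
  p_by_set <- res$p[match(names(sets), res$test_name)]
  expect_equal(res$p_adjusted[match(names(sets), res$test_name)],
               bh_oracle(p_by_set))
  expect_true(!is.unsorted(res$p_adjusted))
  # degenerate cases
  tight_bg <- sprintf("G%04d", 1:30)
  one <- run_ora(tight_bg[1:10], list(hit = tight_bg[1:10]), tight_bg)
  expect_lt(one$p, 1e-6)
  expect_equal(one$p_adjusted, one$p)
  disj <- run_ora(tight_bg[1:10], list(miss = tight_bg[11:20]), tight_bg)
  expect_equal(disj$p, 1)
  expect_error(run_ora(character(0), list(s = bg[1:5]), bg), "empty gene list")
})
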