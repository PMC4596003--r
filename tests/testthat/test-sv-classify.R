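test_that("high-confidence filter follows the evidence rule examples", {
  sv <- function(dp = 0, sr = 0, sc = 0, nrm = 0, cov = 60) {
    data.frame(discordant_pairs = dp, split_reads = sr, soft_clip = sc,
               normal_evidence = nrm, region_coverage = cov)
  }
  expect_true(filter_high_confidence(sv(dp = 4, sr = 3))$pass)
  expect_true(filter_high_confidence(sv(sr = 10))$pass)
  expect_false(filter_high_confidence(sv(sr = 9))$pass)
  r <- filter_high_confidence(sv(dp = 8, sr = 8, nrm = 1))
  expect_false(r$pass); expect_equal(r$reason, "normal_evidence")
  r <- filter_high_confidence(sv(dp = 8, sr = 8, cov = 1500))
  expect_false(r$pass); expect_equal(r$reason, "repeat_coverage")
  r <- filter_high_confidence(sv())
  expect_false(r$pass); expect_equal(r$reason, "evidence")
})

test_that("high-confidence filter is monotone in support and normal evidence", {
  set.seed(11)
  for (i in 1:200) {
    dp <- sample(0:12, 1); sr <- sample(0:12, 1); sc <- sample(0:12, 1)
    nrm <- sample(0:2, 1); cov <- sample(c(60, 900, 1100), 1)
    base <- data.frame(discordant_pairs = dp, split_reads = sr, soft_clip = sc,
                       normal_evidence = nrm, region_coverage = cov)
    more <- base; more$split_reads <- more$split_reads + sample(1:10, 1)
    if (filter_high_confidence(base)$pass) {
      expect_true(filter_high_confidence(more)$pass)
    }
    worse <- base; worse$normal_evidence <- worse$normal_evidence + 1
    if (!filter_high_confidence(base)$pass) {
      expect_false(filter_high_confidence(worse)$pass)
    }
  }
})

test_that("eight-way SV typing matches a hand-built decision-table oracle", {
  # one loss segment [2,3) Mb, one gain [5,6) Mb, two amplified [8,8.4), [8.6,9) Mb
  segments <- segs_df("chr1",
                      c(0, 2e6, 3e6, 5e6, 6e6, 8e6, 8.4e6, 8.6e6, 9e6, 1e7),
                      cn = c(2, 1, 2, 4, 2, 7, 2, 8, 2),
                      maf = c(0.5, 1, 0.5, 0.75, 0.5, 6 / 7, 0.5, 7 / 8, 0.5))
  mk <- function(pos1, o1, pos2, o2, chrom2 = "chr1") {
    list(chrom1 = "chr1", pos1 = pos1, orient1 = o1,
         chrom2 = chrom2, pos2 = pos2, orient2 = o2)
  }
  cases <- list(
    # 1: interchromosomal is always a translocation
    list(mk(1e6, "head", 5e5, "tail", chrom2 = "chr2"), "translocation"),
    # 2: deletion-type join boundary-matched to the loss segment (+-30 kb)
    list(mk(2e6 + 25e3, "head", 3e6 - 25e3, "tail"), "deletion"),
    list(mk(2e6 + 40e3, "head", 3e6, "tail"), "intrachromosomal"),  # 40 kb off
    # 3: duplication-type join boundary-matched to the gain segment
    list(mk(5e6, "tail", 6e6, "head"), "tandem_duplication"),
    #    overlapping the gain without boundary match
    list(mk(5.2e6, "tail", 5.5e6, "head"), "duplication"),
    #    no gain overlap at all
    list(mk(1e5, "tail", 2e5, "head"), "intrachromosomal"),
    # 4: same-orientation short join with a CN step nearby -> fold-back
    list(mk(8e6 - 5e3, "head", 8e6 + 4e3, "head"), "foldback_inversion"),
    #    both breakends inside amplified segments, far from any step
    list(mk(8.1e6, "head", 8.7e6, "head"), "amplified_inversion"),
    #    plain inversion otherwise
    list(mk(1e6, "tail", 1.5e6, "tail"), "inversion"),
    # deletion-type join matching a *gain* boundary is not a deletion
    list(mk(5e6, "head", 6e6, "tail"), "intrachromosomal"))
  for (cs in cases) {
    expect_equal(classify_sv(cs[[1]], segments), cs[[2]],
                 info = paste(unlist(cs[[1]]), collapse = " "))
  }
  # empty segment list: CN-refined labels unreachable
  empty <- cn_set()
  expect_equal(classify_sv(mk(1e6, "head", 2e6, "tail"), empty), "intrachromosomal")
  expect_equal(classify_sv(mk(1e6, "head", 2e6, "head"), empty), "inversion")
  expect_equal(classify_sv(mk(1e6, "tail", 2e6, "head"), empty), "intrachromosomal")
})

test_that("typing is total and deterministic over all orientation pairs", {
  segments <- segs_df("chr1", c(0, 2e6, 3e6, 1e7), cn = c(2, 1, 2),
                      maf = c(0.5, 1, 0.5))
  for (o1 in c("head", "tail")) for (o2 in c("head", "tail")) {
    for (pos in list(c(2e6, 3e6), c(1e5, 2e5), c(4e6, 4.005e6))) {
      sv <- list(chrom1 = "chr1", pos1 = pos[1], orient1 = o1,
                 chrom2 = "chr1", pos2 = pos[2], orient2 = o2)
      t1 <- classify_sv(sv, segments)
      expect_true(t1 %in% c("deletion", "duplication", "tandem_duplication",
                            "foldback_inversion", "amplified_inversion",
                            "inversion", "intrachromosomal"))
      expect_identical(t1, classify_sv(sv, segments))
    }
  }
})

test_that("centromere/telomere annotation respects the 100 kb window", {
  gb <- toy_genome(n = 2, len = 1e7)   # centromeres at 4.5-4.6 Mb
  svs <- sv_set(chrom1 = rep("chr1", 3),
                pos1 = c(50e3, 100001, 4.45e6), orient1 = "head",
                chrom2 = rep("chr1", 3),
                pos2 = c(3e6, 3e6, 7e6), orient2 = "tail", genome = gb)
  ann <- annotate_special_regions(svs, gb)
  expect_equal(ann$near_telomere, c(TRUE, FALSE, FALSE))
  expect_equal(ann$near_centromere, c(FALSE, FALSE, TRUE))
  gb2 <- genome_build("chr1", 1e7)
  expect_message(ann2 <- annotate_special_regions(svs, gb2), "no centromere")
  expect_false(any(ann2$near_centromere))
})

test_that("microhomology equals the brute-force oracle", {
  expect_equal(compute_microhomology("GGACGT", "ACGTTT", 6), 4L)
  expect_equal(compute_microhomology("AAAA", "CCCC", 4), 0L)
  expect_equal(compute_microhomology("ACGTACGTAC", "ACGTACGTAC", 10), 10L)
  expect_error(compute_microhomology("ACGN", "ACGT", 4),
               class = "shatterscan_sequence_error")
  set.seed(5)
  for (i in 1:100) {
    l <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1), TRUE), collapse = "")
    r <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1), TRUE), collapse = "")
    expect_equal(compute_microhomology(l, r, 15), microhomology_oracle(l, r, 15))
  }
})

test_that("SV-type prevalence comparison matches the Welch formula", {
  a <- data.frame(inversion = c(0.4, 0.5, 0.45), deletion = c(0.2, 0.25, 0.22))
  b <- data.frame(inversion = c(0.1, 0.12, 0.08), deletion = c(0.21, 0.24, 0.23))
  res <- sv_type_prevalence_test(a, b)
  inv <- res[res$sv_type == "inversion", ]
  orc <- welch_oracle(a$inversion, b$inversion)
  expect_equal(inv$t, orc$t, tolerance = 1e-12)
  expect_equal(inv$p, orc$p, tolerance = 1e-12)
  expect_lt(inv$p, 0.05)

  same <- data.frame(inversion = c(0.3, 0.3))
  res2 <- sv_type_prevalence_test(same, same)
  expect_equal(res2$t, 0); expect_equal(res2$p, 1)
  expect_true(res2$zero_variance)
  expect_error(sv_type_prevalence_test(a[1, , drop = FALSE], b),
               class = "shatterscan_statistics_error")
})
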