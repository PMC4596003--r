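test_that("copy-number states map onto the five-state scheme", {
  expect_equal(classify_cn_state(7, 0.6), "amplified")
  expect_equal(classify_cn_state(2, 1.0), "cn_loh")
  expect_equal(classify_cn_state(2, 0.5), "neutral")
  expect_equal(classify_cn_state(0, NA), "loss")
  expect_equal(classify_cn_state(1, 1.0), "loss")
  expect_equal(classify_cn_state(c(3, 5, 6), c(0.67, 0.6, 0.99)),
               c("gain", "gain", "amplified"))
  expect_error(classify_cn_state(2, 0.3), class = "shatterscan_validation_error")
})

test_that("switch counting equals the brute-force adjacent-pair count", {
  cn <- c(2, 3, 2, 3, 2, 3, 2, 3, 2, 3, 2)
  seg <- segs_df("chr1", seq(0, by = 1e6, length.out = length(cn) + 1), cn,
                 maf = ifelse(cn == 3, 2 / 3, 0.5))
  sw <- count_state_switches(seg)
  expect_equal(sw$n_switches, 10L)
  expect_equal(sw$distinct_cn_levels, 2L)
  expect_equal(count_state_switches(seg[1, ])$n_switches, 0L)
  expect_equal(count_state_switches(cn_set()), list(n_switches = 0L,
                                                    distinct_cn_levels = 0L))
  set.seed(2)
  for (i in 1:50) {
    cn <- sample(1:4, sample(2:15, 1), replace = TRUE)
    seg <- segs_df("chr1", seq(0, by = 1e5, length.out = length(cn) + 1), cn,
                   maf = 1)
    brute <- sum(vapply(seq_len(length(cn) - 1),
                        function(k) cn[k] != cn[k + 1], logical(1)))
    expect_equal(count_state_switches(seg)$n_switches, brute)
  }
})

test_that("heterozygosity retention inspects the modal retained level", {
  seg <- segs_df("chr1", c(0, 1e6, 2e6, 3e6, 4e6), cn = c(3, 2, 3, 2),
                 maf = c(2 / 3, 1, 2 / 3, 1))
  expect_true(heterozygosity_retained(seg))
  seg$major_allele_fraction[3] <- 1.0
  seg$state <- NA_character_
  expect_false(heterozygosity_retained(seg))
  seg$major_allele_fraction <- NA_real_
  expect_true(is.na(heterozygosity_retained(seg)))
})

test_that("breaks/Mb counts each breakend toward its own chromosome", {
  gb <- default_genome(2, 1e8)
  svs <- sv_set(chrom1 = c("chr1", "chr1"), pos1 = c(1e6, 2e6),
                orient1 = "head",
                chrom2 = c("chr1", "chr2"), pos2 = c(5e6, 9e6),
                orient2 = "tail", genome = gb)
  r <- breaks_per_mb(svs, gb)
  expect_equal(r$per_chrom$n_breakends, c(3, 1))   # intra: 2, translocation: 1+1
  expect_equal(r$per_chrom$rate, c(3, 1) / 100)
  expect_equal(r$genome_rate, 4 / 200)
  r0 <- breaks_per_mb(sv_set(), gb)
  expect_true(all(r0$per_chrom$rate == 0))
})

test_that("KS clustering detects concentration and stays calibrated on uniform draws", {
  set.seed(21)
  clustered <- runif(100, 0, 0.01) * 1e8
  r <- ks_clustering_test(clustered, 1e8)
  expect_gt(r$D, 0.95)
  expect_lt(r$p, 1e-3)

  quantiles <- ((1:50) - 0.5) / 50 * 1e8
  expect_gt(ks_clustering_test(quantiles, 1e8)$p, 0.99)

  few <- ks_clustering_test(c(1, 2), 1e8)
  expect_equal(few$p, 1); expect_true(few$small_n)
  expect_error(ks_clustering_test(c(-5, 100), 1e8),
               class = "shatterscan_coordinate_error")

  ps <- replicate(400, ks_clustering_test(runif(50) * 1e8, 1e8)$p)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("join-orientation randomness test matches the chi-square reference", {
  mk <- function(counts) {
    data.frame(orient1 = rep(c("head", "tail", "head", "tail"), counts),
               orient2 = rep(c("tail", "head", "head", "tail"), counts))
  }
  r <- random_joins_test(mk(c(10, 10, 10, 10)))
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)
  r2 <- random_joins_test(mk(c(40, 0, 0, 0)))
  expect_lt(r2$p, 1e-3)
  expect_equal(r2$statistic, unname(suppressWarnings(
    chisq.test(c(40, 0, 0, 0), p = rep(0.25, 4))$statistic)))
  r3 <- random_joins_test(mk(c(2, 1, 1, 1)))
  expect_true(r3$indeterminate)
  set.seed(9)
  for (i in 1:20) {
    counts <- as.vector(rmultinom(1, 40, rep(0.25, 4)))
    r4 <- random_joins_test(mk(counts))
    expect_equal(r4$p, suppressWarnings(
      chisq.test(counts, p = rep(0.25, 4))$p.value))
  }
})

test_that("chromothripsis detection recovers planted events and rejects lookalikes", {
  gb <- default_genome(4, 1e8)
  set.seed(1)
  ct <- simulate_chromothripsis_chrom("chr1", 1e8,
                                      list(n_fragments = 30, cn_states = c(2, 3),
                                           p_retain = 0.5, span_fraction = 0.15))
  seg <- validate_cn_set(ct$segments, gb)
  svs <- validate_sv_set(canonicalize_svs(ct$svs, gb), gb)
  v <- detect_chromothripsis(seg, svs, "chr1", gb)
  expect_true(v$chromothripsis)
  expect_true(all(unlist(v[paste0("flag_", c("clustering", "switches", "states",
                                             "het", "random_joins"))])))
  # composite equals the conjunction of its flags
  expect_identical(v$chromothripsis,
                   v$flag_clustering && v$flag_switches && v$flag_states &&
                     v$flag_het && v$flag_random_joins)

  bfb <- simulate_bfb_chrom("chr2", 1e8,
                            list(lost_telomeric_bp = 5e6, amplicon_bp = 4e6,
                                 amplicon_cn = 8, n_foldbacks = 20))
  vb <- detect_chromothripsis(validate_cn_set(bfb$segments, gb),
                              validate_sv_set(canonicalize_svs(bfb$svs, gb), gb),
                              "chr2", gb)
  expect_false(vb$chromothripsis)
  expect_false(vb$flag_switches)

  # 12 switches across 4 distinct CN levels fails the state-count criterion
  cn <- rep(c(1, 2, 3, 4), length.out = 13)
  seg4 <- segs_df("chr3", seq(0, by = 1e6, length.out = 14), cn,
                  maf = ifelse(cn == 1, 1, ifelse(cn == 2, 0.5, 2 / 3)))
  v4 <- detect_chromothripsis(seg4, svs, "chr3", gb)
  expect_false(v4$chromothripsis)
  expect_false(v4$flag_states)
  expect_gte(v4$n_switches, 12)
})

test_that("array-only chromothripsis screen uses switches, states and heterozygosity", {
  cn <- rep(c(2, 3), length.out = 11)
  maf_het <- ifelse(cn == 3, 2 / 3, 1)
  seg <- segs_df("chr1", seq(0, by = 1e6, length.out = 12), cn, maf_het)
  expect_true(detect_chromothripsis_array_only(seg))
  expect_false(detect_chromothripsis_array_only(seg[1:10, ]))   # 9 switches
  seg_loh <- segs_df("chr1", seq(0, by = 1e6, length.out = 12), cn,
                     maf = 1)                                    # retained LOH
  expect_false(detect_chromothripsis_array_only(seg_loh))
})

test_that("BFB detection needs telomeric loss, amplified neighbor and inversions", {
  gb <- default_genome(1, 1e8)
  set.seed(4)
  run_bfb <- function(p) {
    r <- simulate_bfb_chrom("chr1", 1e8, p)
    seg <- validate_cn_set(r$segments, gb)
    svs <- validate_sv_set(canonicalize_svs(r$svs, gb), gb)
    svs <- classify_svs(svs, seg)
    detect_bfb(seg, svs, "chr1")
  }
  base <- list(lost_telomeric_bp = 5e6, amplicon_bp = 4e6, amplicon_cn = 8,
               n_foldbacks = 20)
  v <- run_bfb(base)
  expect_true(v$bfb)
  expect_identical(v$bfb, v$flag_telomeric_loss && v$flag_amplified_neighbor &&
                     v$flag_inversions)
  expect_false(run_bfb(modifyList(base, list(n_foldbacks = 0)))$bfb)
  expect_false(run_bfb(modifyList(base, list(lost_telomeric_bp = 0)))$bfb)
  expect_false(suppressWarnings(
    run_bfb(modifyList(base, list(amplicon_cn = 3))))$bfb)
})

test_that("catastrophe detectors are invariant under chromosome mirror reflection", {
  gb <- default_genome(1, 1e8)
  set.seed(17)
  ct <- simulate_chromothripsis_chrom("chr1", 1e8,
                                      list(n_fragments = 30, cn_states = c(2, 3),
                                           p_retain = 0.5, span_fraction = 0.15))
  mirror_seg <- function(seg, len) {
    out <- seg
    out$start <- len - seg$end
    out$end <- len - seg$start
    validate_cn_set(out[order(out$start), ])
  }
  mirror_svs <- function(svs, len) {
    out <- svs
    out$pos1 <- len - svs$pos1; out$pos2 <- len - svs$pos2
    flip <- c(head = "tail", tail = "head")
    out$orient1 <- unname(flip[svs$orient1])
    out$orient2 <- unname(flip[svs$orient2])
    validate_sv_set(canonicalize_svs(out))
  }
  seg <- validate_cn_set(ct$segments); svs <- validate_sv_set(canonicalize_svs(ct$svs))
  v1 <- detect_chromothripsis(seg, svs, "chr1", gb)
  v2 <- detect_chromothripsis(mirror_seg(seg, 1e8), mirror_svs(svs, 1e8),
                              "chr1", gb)
  expect_equal(v1$chromothripsis, v2$chromothripsis)
  expect_equal(v1$n_switches, v2$n_switches)
  expect_equal(v1$clustering_p, v2$clustering_p, tolerance = 1e-9)

  bfb <- simulate_bfb_chrom("chr1", 1e8,
                            list(lost_telomeric_bp = 5e6, amplicon_bp = 4e6,
                                 amplicon_cn = 8, n_foldbacks = 20))
  segb <- validate_cn_set(bfb$segments)
  svb <- classify_svs(validate_sv_set(canonicalize_svs(bfb$svs)), segb)
  b1 <- detect_bfb(segb, svb, "chr1")
  segm <- mirror_seg(segb, 1e8)
  svm <- classify_svs(mirror_svs(svb, 1e8), segm)
  b2 <- detect_bfb(segm, svm, "chr1")
  expect_true(b1$bfb && b2$bfb)
  expect_equal(b1$side, "start"); expect_equal(b2$side, "end")
})

test_that("genome subtyping follows the SV-count and 3x localization rules", {
  gb <- default_genome(10, 1e8)
  rates_flat <- list(per_chrom = data.frame(chrom = gb$chrom_names,
                                            n_breakends = 30, rate = 0.3),
                     genome_rate = 0.3)
  expect_equal(subtype_genome(776, rates_flat), "unstable")
  expect_equal(subtype_genome(300, rates_flat), "scattered")
  rates_hot <- rates_flat
  rates_hot$per_chrom$rate[3] <- 1.2   # 4x the genome rate
  expect_equal(subtype_genome(300, rates_hot), "complex_localized")
  rates_cold <- rates_flat
  rates_cold$per_chrom$rate[3] <- 0.36  # 1.2x only
  expect_equal(subtype_genome(300, rates_cold), "scattered")
})
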