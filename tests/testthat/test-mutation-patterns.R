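test_that("trinucleotide classification closes onto exactly 96 classes", {
  # definitional example and its reverse complement
  idx_ct_aca <- trinucleotide_class("C", "T", "A", "A")
  expect_equal(idx_ct_aca, 16L * 2L + 0L + 0L)      # C>T at A_A
  expect_equal(trinucleotide_class("G", "A", "T", "T"), idx_ct_aca)

  # enumerate all 192 raw (ref, alt, 5', 3') combinations
  bases <- c("A", "C", "G", "T")
  raw <- expand.grid(ref = bases, alt = bases, b5 = bases, b3 = bases,
                     stringsAsFactors = FALSE)
  raw <- raw[raw$ref != raw$alt, ]
  idx <- trinucleotide_class(raw$ref, raw$alt, raw$b5, raw$b3)
  expect_true(all(idx >= 0 & idx <= 95))
  expect_equal(length(unique(idx)), 96L)
  expect_equal(as.vector(table(idx)), rep(2L, 96))  # each class from 2 strands

  # reverse-complement invariance, checked pair by pair
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- trinucleotide_class(comp[raw$ref], comp[raw$alt], comp[raw$b3], comp[raw$b5])
  expect_equal(unname(rc), unname(idx))
  expect_error(trinucleotide_class("N", "A", "C", "C"),
               class = "shatterscan_sequence_error")
})

test_that("intermutation distances follow the definition and its contracts", {
  expect_equal(intermutation_distances(c(100, 250, 1250)), c(150, 1000))
  expect_equal(intermutation_distances(500), numeric(0))
  expect_error(intermutation_distances(c(250, 100)),
               class = "shatterscan_ordering_error")
  expect_message(d <- intermutation_distances(c(100, 100, 300)), "duplicate")
  expect_equal(d, 200)
})

test_that("piecewise constant fitting is exact against exhaustive enumeration", {
  fit <- pcf_segment(rep(3.2, 17), gamma = 25, kmin = 2)
  expect_equal(fit$n_segments, 1L)

  fit2 <- pcf_segment(c(0, 0, 0, 100, 100, 100), gamma = 25, kmin = 2)
  expect_equal(fit2$n_segments, 2L)
  expect_equal(fit2$ends, c(3L, 6L))
  expect_equal(fit2$cost, pcf_oracle_cost(c(0, 0, 0, 100, 100, 100), 25, 2))

  set.seed(41)
  for (i in 1:60) {
    n <- sample(2:20, 1)
    x <- round(stats::rnorm(n, sd = sample(c(0.5, 3, 10), 1)), 3)
    gamma <- sample(c(1, 5, 25), 1)
    kmin <- sample(1:2, 1)
    fit <- pcf_segment(x, gamma, kmin)
    expect_equal(fit$cost, pcf_oracle_cost(x, gamma, kmin), tolerance = 1e-8,
                 info = sprintf("n=%d gamma=%g kmin=%d", n, gamma, kmin))
    expect_true(all(diff(c(0, fit$ends)) >= min(kmin, n)))
  }
  # kmin larger than the series: single flagged segment
  f <- pcf_segment(c(1, 2), gamma = 25, kmin = 5)
  expect_true(f$single_flag)
  expect_equal(f$n_segments, 1L)
})

test_that("kataegis calling applies the six-mutation / 1 kb segment rule", {
  gb <- default_genome(4, 1e8)
  mk_snvs <- function(pos, chrom = "chr1") {
    snv_set(chrom = chrom, pos = pos, ref = "C",
            alt = rep(c("T", "G"), length.out = length(pos)),
            context5 = "T", context3 = "C")
  }
  # 6 mutations at 1,000-bp steps on a sparse background
  bg <- seq(5e6, 9.5e7, by = 5e6)
  foc <- 2.05e7 + (0:5) * 1000
  snvs <- mk_snvs(sort(c(bg, foc)))
  foci <- call_kataegis(snvs, gb)
  expect_equal(nrow(foci), 1L)
  expect_equal(foci$n_mutations, 6L)
  expect_lte(foci$mean_imd, 1000)
  expect_equal(foci$start, 2.05e7)
  expect_equal(foci$end, 2.05e7 + 5000)
  expect_equal(foci$n_c_to_t + foci$n_c_to_g, 6L)

  # 5 clustered mutations stay below the minimum
  snvs5 <- mk_snvs(sort(c(bg, 2e7 + (0:4) * 800)))
  expect_equal(nrow(call_kataegis(snvs5, gb)), 0L)

  # truth recovery from the generator
  set.seed(11)
  kat <- simulate_kataegis_snvs(list(n_foci = 3, mutations_per_focus = 8,
                                     focus_span_bp = 4000,
                                     background_rate_per_mb = 1), gb)
  called <- call_kataegis(kat$snvs, gb)
  expect_equal(nrow(called), 3L)
  for (k in seq_len(3)) {
    tr <- kat$foci[k, ]
    hit <- called[called$chrom == tr$chrom & called$start <= tr$start &
                    called$end >= tr$end, ]
    expect_equal(nrow(hit), 1L)
  }
})

test_that("kataegis calls are invariant to coordinate translation and distant mutations", {
  gb <- default_genome(1, 1e8)
  set.seed(13)
  pos <- sort(c(sample.int(9e7, 40), 3e7 + cumsum(sample(200:900, 7))))
  snvs <- snv_set(chrom = "chr1", pos = pos, ref = "C", alt = "T",
                  context5 = "T", context3 = "A")
  base <- call_kataegis(snvs, gb)
  shifted <- snvs; shifted$pos <- shifted$pos + 1e6
  shift_call <- call_kataegis(shifted, gb)
  expect_equal(shift_call$start, base$start + 1e6)
  expect_equal(shift_call$n_mutations, base$n_mutations)
  expect_equal(shift_call$mean_imd, base$mean_imd)

  # adding one mutation >= 1 Mb from every focus never removes a focus
  far <- rbind(as.data.frame(snvs),
               data.frame(chrom = "chr1", pos = 9.9e7, ref = "C", alt = "T",
                          context5 = "T", context3 = "A", class96 = NA_integer_))
  far_call <- call_kataegis(validate_snv_set(far), gb)
  for (k in seq_len(nrow(base))) {
    expect_true(any(far_call$start == base$start[k] &
                      far_call$n_mutations >= base$n_mutations[k]))
  }
})

test_that("kataegis burden labels follow the focus-count thresholds", {
  expect_equal(kataegis_burden(0), "none")
  expect_equal(kataegis_burden(9), "occasional")
  expect_equal(kataegis_burden(10), "numerous")
  expect_equal(kataegis_burden(17), "numerous")
})

test_that("spectrum matrix conserves counts and is deterministic", {
  one <- annotate_snv_classes(snv_set(chrom = "chr1", pos = 10, ref = "C",
                                      alt = "T", context5 = "A", context3 = "A"))
  m <- spectrum_matrix(list(s1 = one))
  expect_equal(sum(m), 1L)
  expect_equal(m["A[C>T]A", "s1"], 1L)

  set.seed(3)
  gb <- default_genome(2, 5e7)
  kat <- simulate_kataegis_snvs(list(n_foci = 1, mutations_per_focus = 8,
                                     focus_span_bp = 4000,
                                     background_rate_per_mb = 3), gb)
  m2 <- spectrum_matrix(list(a = kat$snvs, b = kat$snvs))
  expect_equal(unname(colSums(m2)), rep(nrow(kat$snvs), 2))
  expect_identical(m2[, "a"], m2[, "b"])
  expect_error(spectrum_matrix(list(x = snv_set(chrom = "chr1", pos = 1,
                                                ref = "C", alt = "T"))),
               class = "shatterscan_annotation_error")
})
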