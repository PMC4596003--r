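test_that("genome build validates lengths and centromeres", {
  expect_s3_class(genome_build(c("chr1", "chr2"), c(1e8, 5e7)), "genome_build")
  expect_error(genome_build("chr1", 0), class = "shatterscan_validation_error")
  expect_error(genome_build(c("chr1", "chr1"), c(1, 2)),
               class = "shatterscan_validation_error")
  expect_error(
    genome_build("chr1", 1e6,
                 centromeres = data.frame(chrom = "chr1", start = 5e5, end = 2e6)),
    class = "shatterscan_validation_error")
})

test_that("VCF reading converts coordinates, splits multiallelics, skips non-SNVs", {
  gb <- toy_genome()
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t128000\t.\tC\tT\t.\tPASS\t.",
    "chr1\t200000\t.\tAT\tA\t.\tPASS\t.",        # indel: skipped
    "chr2\t500\t.\tG\tA,C\t.\tPASS\t."), vcf)    # multiallelic: split
  expect_message(snvs <- read_snv_vcf(vcf, gb), "skipped 1 non-SNV")
  expect_equal(nrow(snvs), 3L)
  expect_equal(snvs$pos[1], 127999)              # 1-based -> 0-based
  expect_equal(snvs$alt[snvs$chrom == "chr2"], c("A", "C"))

  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrUn\t100\t.\tC\tT\t.\tPASS\t."), vcf)
  expect_error(read_snv_vcf(vcf, gb), class = "shatterscan_coordinate_error")
})

test_that("BEDPE reading maps strands to orientations and canonicalizes", {
  gb <- toy_genome()
  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c(
    paste0("#", paste(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                        "name", "score", "strand1", "strand2",
                        "discordant_pairs", "split_reads", "soft_clip",
                        "normal_evidence", "region_coverage"), collapse = "\t")),
    "chr2\t999\t1000\tchr1\t49\t50\tsv1\t.\t+\t-\t4\t3\t0\t0\t60"), bedpe)
  svs <- read_sv_bedpe(bedpe, gb)
  expect_equal(nrow(svs), 1L)
  # canonicalized: chr1 breakend first, orientation travelled with it
  expect_equal(svs$chrom1, "chr1")
  expect_equal(svs$orient1, "tail")   # '-' on the chr1 breakend
  expect_equal(svs$orient2, "head")
  expect_equal(svs$discordant_pairs, 4)
  expect_equal(svs$split_reads, 3)
  expect_equal(svs$normal_evidence, 0)

  writeLines(c("chr1\t10\t11\tchr2\t20\t21\tsv1\t.\t*\t-"), bedpe)
  expect_error(suppressWarnings(read_sv_bedpe(bedpe, gb)),
               class = "shatterscan_format_error")

  # missing evidence columns default to zero with a warning
  writeLines(c("chr1\t10\t11\tchr2\t20\t21\tsv1\t.\t+\t-"), bedpe)
  expect_warning(svs2 <- read_sv_bedpe(bedpe, gb), "defaulting to 0")
  expect_equal(svs2$discordant_pairs, 0)
})

test_that("CN TSV reading enforces coordinates, order and overlap checks", {
  gb <- toy_genome()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\ttotal_cn\tmajor_allele_fraction",
               "chr1\t1\t5000000\t2\t0.5",
               "chr1\t5000001\t9000000\t3\t0.67"), tsv)
  cn <- read_cn_segments(tsv, gb)
  expect_equal(nrow(cn), 2L)
  expect_equal(cn$start, c(0, 5e6))   # 1-based inclusive -> half-open
  expect_equal(cn$end, c(5e6, 9e6))

  writeLines(c("chrom\tstart\tend\ttotal_cn\tmajor_allele_fraction",
               "chr1\t1\t5000000\t2\t0.5",
               "chr1\t5000000\t9000000\t3\t0.67"), tsv)   # 1 bp overlap
  expect_error(read_cn_segments(tsv, gb), class = "shatterscan_validation_error")

  # cn 0 with undefined maf is legal
  writeLines(c("chrom\tstart\tend\ttotal_cn\tmajor_allele_fraction",
               "chr1\t1\t1000\t0\tNA"), tsv)
  cn0 <- read_cn_segments(tsv, gb)
  expect_true(is.na(cn0$major_allele_fraction))
})

test_that("writers round-trip every field bit-exactly", {
  gb <- toy_genome()
  set.seed(7)
  snvs <- snv_set(chrom = c("chr1", "chr2", "chr2"),
                  pos = c(100, 5000, 123456),
                  ref = c("C", "G", "T"), alt = c("T", "A", "G"),
                  context5 = c("A", "T", "C"), context3 = c("A", "G", "T"))
  snvs <- annotate_snv_classes(snvs)
  f <- tempfile(fileext = ".vcf")
  write_snv_vcf(snvs, f, gb)
  expect_equal(as.data.frame(read_snv_vcf(f, gb)), as.data.frame(snvs))

  svs <- one_sv(pos1 = 1000, orient1 = "head", pos2 = 99000, orient2 = "tail")
  svs$sv_type <- "deletion"; svs$microhomology_len <- 4
  svs$near_centromere <- FALSE; svs$near_telomere <- TRUE
  f2 <- tempfile(fileext = ".bedpe")
  write_sv_bedpe(svs, f2)
  expect_equal(as.data.frame(read_sv_bedpe(f2, gb)), as.data.frame(svs))

  cn <- segs_df("chr1", c(0, 1e6, 3e6), cn = c(2, 3), maf = c(0.5, 2 / 3))
  f3 <- tempfile(fileext = ".tsv")
  write_cn_segments(cn, f3)
  expect_equal(as.data.frame(read_cn_segments(f3, gb)), as.data.frame(cn))

  reads <- c(r1 = "ACGTACGTACGTACGTAAAA", r2 = strrep("TTAGGG", 4))
  f4 <- tempfile(fileext = ".fastq")
  write_fastq(reads, f4)
  expect_identical(read_fastq(f4), reads)
})

test_that("SV canonicalization orders breakends and keeps orientations attached", {
  gb <- toy_genome()
  sv <- sv_set(chrom1 = "chr1", pos1 = 9000, orient1 = "tail",
               chrom2 = "chr1", pos2 = 100, orient2 = "head", genome = gb)
  expect_equal(sv$pos1, 100)
  expect_equal(sv$orient1, "head")
  expect_equal(sv$orient2, "tail")
  expect_error(
    sv_set(chrom1 = "chr1", pos1 = 10, orient1 = "head",
           chrom2 = "chr1", pos2 = 20, orient2 = "tail",
           sv_type = "translocation"),
    class = "shatterscan_validation_error")
})

test_that("bundle assembly validates all coordinates against the build", {
  gb <- toy_genome()
  expect_error(
    sample_bundle("s1", snv_set(chrom = "chr9", pos = 1, ref = "C", alt = "T"),
                  sv_set(), cn_set(), genome = gb),
    class = "shatterscan_coordinate_error")
  b <- sample_bundle("s1", snv_set(), sv_set(), cn_set(), genome = gb)
  expect_s3_class(b, "sample_bundle")
})
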