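# Readers and writers for the pipeline's carrier formats.
# VCF 4.2 for SNVs (1-based at I/O), BEDPE (0-based half-open) with named extra
# columns for SVs, TSV (1-based inclusive) for CN segments, FASTQ for reads.
# Internal coordinates are 0-based half-open throughout.

#' Read somatic SNVs from a VCF file
#'
#' Biallelic SNV records become one row each; multiallelic records are split
#' into one row per alternate allele; non-SNV records (indels, symbolic
#' alleles) are skipped with a logged count. VCF 1-based positions are
#' converted to the 0-based internal convention. Trinucleotide context and
#' 96-class annotation, when previously written by [write_snv_vcf()], are
#' recovered from the INFO fields `CTX5`, `CTX3` and `CLS96`.
#'
#' @param path VCF file (plain or gzipped), version >= 4.1.
#' @param genome a `genome_build`; records on chromosomes absent from the
#'   build raise a coordinate error naming the record.
#' @return An `snv_set`.
#' @export
read_snv_vcf <- function(path, genome) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    ss_error("shatterscan_format_error",
                             "malformed VCF '%s': %s", path, conditionMessage(e))
                  })
  fmt <- grep("^##fileformat=VCF", vcf@meta, value = TRUE)
  if (!length(fmt)) {
    ss_error("shatterscan_format_error", "VCF '%s' lacks a ##fileformat header", path)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(snv_set(genome = genome))
  }
  out <- list(); skipped <- 0L
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  for (r in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[r])
    alts <- strsplit(toupper(fix$ALT[r] %||% ""), ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (nchar(ref) == 1L && nchar(alt) == 1L &&
          ref %in% BASES && alt %in% BASES && ref != alt) {
        info <- fix$INFO[r] %||% "."
        out[[length(out) + 1L]] <- data.frame(
          chrom = fix$CHROM[r], pos = as.numeric(fix$POS[r]) - 1,
          ref = ref, alt = alt,
          context5 = info_field(info, "CTX5"),
          context3 = info_field(info, "CTX3"),
          class96 = suppressWarnings(as.integer(info_field(info, "CLS96"))),
          stringsAsFactors = FALSE)
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  if (skipped > 0L) {
    message(sprintf("read_snv_vcf: skipped %d non-SNV allele(s)", skipped))
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), context5 = character(), context3 = character(),
               class96 = integer(), stringsAsFactors = FALSE)
  validate_snv_set(df, genome)
}

#' Write somatic SNVs as VCF 4.2
#'
#' @param snvs an `snv_set` (internal 0-based positions; written 1-based).
#' @param path output file.
#' @param genome optional `genome_build` used to emit contig header lines.
#' @export
write_snv_vcf <- function(snvs, path, genome = NULL) {
  snvs <- validate_snv_set(as.data.frame(snvs), genome)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=CTX5,Number=1,Type=String,Description=\"5' flanking base\">",
           "##INFO=<ID=CTX3,Number=1,Type=String,Description=\"3' flanking base\">",
           "##INFO=<ID=CLS96,Number=1,Type=Integer,Description=\"96-class index\">")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", genome$chrom_names,
                          as.integer(genome$chrom_lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(snvs)), function(i) {
    parts <- character()
    if (!is.na(snvs$context5[i])) parts <- c(parts, paste0("CTX5=", snvs$context5[i]))
    if (!is.na(snvs$context3[i])) parts <- c(parts, paste0("CTX3=", snvs$context3[i]))
    if (!is.na(snvs$class96[i])) parts <- c(parts, paste0("CLS96=", snvs$class96[i]))
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  snvs$chrom, as.integer(snvs$pos) + 1L, snvs$ref, snvs$alt, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

BEDPE_EXTRA <- c("discordant_pairs", "split_reads", "soft_clip",
                 "normal_evidence", "region_coverage")

#' Read structural variants from BEDPE
#'
#' Expects 0-based half-open BEDPE with the 10 standard columns plus named
#' extra columns `discordant_pairs`, `split_reads`, `soft_clip`,
#' `normal_evidence`, `region_coverage` (this package's dialect, announced by a
#' `#`-prefixed header line). Strands are mapped to breakend orientations
#' (`+` -> head, `-` -> tail) and breakends canonicalized to genome order.
#' Missing evidence columns default to 0 with a warning.
#'
#' @param path BEDPE file.
#' @param genome a `genome_build`.
#' @return An `sv_set`.
#' @export
read_sv_bedpe <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  std <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "name", "score", "strand1", "strand2")
  if (length(lines) && startsWith(lines[1], "#")) {
    cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
  } else {
    cols <- std
  }
  if (!length(lines)) return(sv_set(genome = genome))
  df <- utils::read.table(text = lines, sep = "\t", col.names = cols,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(std %in% names(df))) {
    ss_error("shatterscan_format_error",
             "BEDPE '%s' lacks the 10 standard columns", path)
  }
  missing_extra <- setdiff(BEDPE_EXTRA, names(df))
  if (length(missing_extra)) {
    warning(sprintf("read_sv_bedpe: evidence column(s) %s missing; defaulting to 0",
                    paste(missing_extra, collapse = ", ")), call. = FALSE)
    for (m in missing_extra) df[[m]] <- "0"
  }
  to_orient <- function(s) {
    s <- gsub("−", "-", s)  # tolerate unicode minus
    if (any(!(s %in% c("+", "-")))) {
      ss_error("shatterscan_format_error",
               "BEDPE strand '%s' not in {+,-}", s[!(s %in% c("+", "-"))][1])
    }
    ifelse(s == "+", "head", "tail")
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  sv_set(chrom1 = df$chrom1, pos1 = as.numeric(df$start1),
         orient1 = to_orient(df$strand1),
         chrom2 = df$chrom2, pos2 = as.numeric(df$start2),
         orient2 = to_orient(df$strand2),
         discordant_pairs = as.numeric(df$discordant_pairs),
         split_reads = as.numeric(df$split_reads),
         soft_clip = as.numeric(df$soft_clip),
         normal_evidence = as.numeric(df$normal_evidence),
         region_coverage = as.numeric(df$region_coverage),
         sv_type = if ("sv_type" %in% names(df))
           ifelse(df$sv_type == ".", NA_character_, df$sv_type) else NA_character_,
         microhomology_len = if ("microhomology_len" %in% names(df))
           num_or_na(df$microhomology_len) else NA_real_,
         near_centromere = if ("near_centromere" %in% names(df))
           num_or_na(df$near_centromere) > 0 else NA,
         near_telomere = if ("near_telomere" %in% names(df))
           num_or_na(df$near_telomere) > 0 else NA,
         genome = genome)
}

#' Write structural variants as BEDPE
#'
#' Emits the dialect read by [read_sv_bedpe()]: 10 standard columns (each
#' breakend as a 1-bp interval), the five evidence columns, and the annotation
#' columns when present.
#'
#' @param svs an `sv_set`.
#' @param path output file.
#' @export
write_sv_bedpe <- function(svs, path) {
  svs <- validate_sv_set(as.data.frame(svs))
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", BEDPE_EXTRA,
            "sv_type", "microhomology_len", "near_centromere", "near_telomere")
  n <- nrow(svs)
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  body <- if (n) {
    data.frame(
      chrom1 = svs$chrom1, start1 = fmt_num(svs$pos1), end1 = fmt_num(svs$pos1 + 1),
      chrom2 = svs$chrom2, start2 = fmt_num(svs$pos2), end2 = fmt_num(svs$pos2 + 1),
      name = sprintf("sv%d", seq_len(n)), score = ".",
      strand1 = ifelse(svs$orient1 == "head", "+", "-"),
      strand2 = ifelse(svs$orient2 == "head", "+", "-"),
      discordant_pairs = fmt_num(svs$discordant_pairs),
      split_reads = fmt_num(svs$split_reads),
      soft_clip = fmt_num(svs$soft_clip),
      normal_evidence = fmt_num(svs$normal_evidence),
      region_coverage = fmt_num(svs$region_coverage),
      sv_type = ifelse(is.na(svs$sv_type), ".", svs$sv_type),
      microhomology_len = fmt_num(svs$microhomology_len),
      near_centromere = ifelse(is.na(svs$near_centromere), ".",
                               as.integer(svs$near_centromere)),
      near_telomere = ifelse(is.na(svs$near_telomere), ".",
                             as.integer(svs$near_telomere)),
      stringsAsFactors = FALSE)
  } else NULL
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (!is.null(body)) {
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read allele-specific copy-number segments from TSV
#'
#' Expects a header with columns `chrom`, `start`, `end` (1-based inclusive),
#' `total_cn`, `major_allele_fraction` and optional `mean_baf`, `mean_logr`,
#' `state`. Converted to half-open internal coordinates; per-chromosome sort is
#' enforced and overlapping segments raise a validation error.
#'
#' @param path TSV file.
#' @param genome a `genome_build`.
#' @return A `cn_set`.
#' @export
read_cn_segments <- function(path, genome) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end", "total_cn", "major_allele_fraction")
  if (!all(need %in% names(df))) {
    ss_error("shatterscan_format_error",
             "CN TSV '%s' lacks column(s): %s", path,
             paste(setdiff(need, names(df)), collapse = ", "))
  }
  cn_set(chrom = df$chrom,
         start = as.numeric(df$start) - 1,   # 1-based inclusive -> half-open
         end = as.numeric(df$end),
         total_cn = df$total_cn,
         major_allele_fraction = df$major_allele_fraction,
         mean_baf = if ("mean_baf" %in% names(df)) df$mean_baf else NA_real_,
         mean_logr = if ("mean_logr" %in% names(df)) df$mean_logr else NA_real_,
         state = if ("state" %in% names(df)) df$state else NA_character_,
         genome = genome)
}

#' Write copy-number segments as TSV (1-based inclusive)
#'
#' @param cn a `cn_set`.
#' @param path output file.
#' @export
write_cn_segments <- function(cn, path) {
  cn <- validate_cn_set(as.data.frame(cn))
  out <- data.frame(chrom = cn$chrom,
                    start = format(cn$start + 1, scientific = FALSE, trim = TRUE),
                    end = format(cn$end, scientific = FALSE, trim = TRUE),
                    total_cn = cn$total_cn,
                    major_allele_fraction = cn$major_allele_fraction,
                    mean_baf = cn$mean_baf, mean_logr = cn$mean_logr,
                    state = cn$state, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' Gzip-transparent; qualities are ignored (the telomere counter only needs
#' base strings).
#'
#' @param path FASTQ file.
#' @return Character vector of read sequences (named by read id).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write reads as FASTQ
#'
#' @param reads character vector of sequences; names become read ids
#'   (default `read1..readN`).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% sprintf("read%d", seq_along(reads))
  if (is.null(names(reads))) names(reads) <- ids
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}
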