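# Domain containers: SNV sets, SV call sets, CN segment sets, sample bundles.
# All are plain data.frames with fixed columns, validated by constructors.
# Coordinates are 0-based half-open internally; 1-based only at I/O boundaries.

SNV_COLS <- c("chrom", "pos", "ref", "alt", "context5", "context3", "class96")
SV_COLS <- c("chrom1", "pos1", "orient1", "chrom2", "pos2", "orient2",
             "discordant_pairs", "split_reads", "soft_clip",
             "normal_evidence", "region_coverage",
             "sv_type", "microhomology_len", "near_centromere", "near_telomere")
CN_COLS <- c("chrom", "start", "end", "total_cn", "major_allele_fraction",
             "mean_baf", "mean_logr", "state")

SV_TYPES <- c("deletion", "duplication", "tandem_duplication",
              "foldback_inversion", "amplified_inversion", "inversion",
              "intrachromosomal", "translocation")

#' Construct a somatic SNV set
#'
#' @param chrom,pos,ref,alt parallel vectors; `pos` is 0-based internal.
#' @param context5,context3 optional flanking bases (5' and 3' of the mutated
#'   base on the reference strand); `NA` until annotated.
#' @param class96 optional integer 0-95; must be consistent with
#'   (ref, alt, context) under pyrimidine normalization when set.
#' @param genome optional `genome_build` used to bounds-check coordinates.
#' @return data.frame of class `snv_set`.
#' @export
snv_set <- function(chrom = character(), pos = numeric(),
                    ref = character(), alt = character(),
                    context5 = NA_character_, context3 = NA_character_,
                    class96 = NA_integer_, genome = NULL) {
  n <- max(length(chrom), length(pos))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = as.numeric(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   context5 = rep_len(as.character(context5), n),
                   context3 = rep_len(as.character(context3), n),
                   class96 = rep_len(as.integer(class96), n),
                   stringsAsFactors = FALSE)
  validate_snv_set(df, genome)
}

validate_snv_set <- function(df, genome = NULL) {
  stopifnot(all(SNV_COLS %in% names(df)))
  df <- df[SNV_COLS]
  if (nrow(df)) {
    if (any(!(df$ref %in% BASES)) || any(!(df$alt %in% BASES))) {
      ss_error("shatterscan_validation_error", "ref/alt bases must be one of A,C,G,T")
    }
    if (any(df$ref == df$alt)) {
      ss_error("shatterscan_validation_error", "ref and alt must differ")
    }
    ctx <- !is.na(df$class96)
    if (any(ctx)) {
      if (any(is.na(df$context5[ctx])) || any(is.na(df$context3[ctx]))) {
        ss_error("shatterscan_validation_error", "class96 set without context bases")
      }
      expect <- trinucleotide_class(df$ref[ctx], df$alt[ctx],
                                    df$context5[ctx], df$context3[ctx])
      if (any(expect != df$class96[ctx])) {
        ss_error("shatterscan_validation_error",
                 "class96 inconsistent with (ref, alt, context)")
      }
    }
    if (!is.null(genome)) check_positions(genome, df$chrom, df$pos, "SNV")
  }
  class(df) <- c("snv_set", "data.frame")
  df
}

#' Construct a structural-variant call set
#'
#' Each row is one somatic rearrangement: two oriented breakends plus evidence
#' counts. Orientation `"head"` means the retained sequence continues toward
#' higher coordinates from the breakend, `"tail"` toward lower coordinates.
#' Breakends are canonicalized to genome order (bnd1 <= bnd2).
#'
#' @param chrom1,pos1,orient1,chrom2,pos2,orient2 breakend fields.
#' @param discordant_pairs,split_reads,soft_clip per-class evidence read counts.
#' @param normal_evidence supporting-read count in the matched normal.
#' @param region_coverage fold coverage at the breakends.
#' @param sv_type optional type label (one of the eight classes) or `NA`.
#' @param microhomology_len optional junction microhomology length (bp).
#' @param near_centromere,near_telomere optional annotation booleans.
#' @param genome optional `genome_build` for bounds checks and canonical order.
#' @return data.frame of class `sv_set`.
#' @export
sv_set <- function(chrom1 = character(), pos1 = numeric(), orient1 = character(),
                   chrom2 = character(), pos2 = numeric(), orient2 = character(),
                   discordant_pairs = 0, split_reads = 0, soft_clip = 0,
                   normal_evidence = 0, region_coverage = 0,
                   sv_type = NA_character_, microhomology_len = NA_real_,
                   near_centromere = NA, near_telomere = NA, genome = NULL) {
  n <- max(length(chrom1), length(pos1))
  df <- data.frame(chrom1 = rep_len(as.character(chrom1), n),
                   pos1 = as.numeric(pos1),
                   orient1 = rep_len(as.character(orient1), n),
                   chrom2 = rep_len(as.character(chrom2), n),
                   pos2 = as.numeric(pos2),
                   orient2 = rep_len(as.character(orient2), n),
                   discordant_pairs = rep_len(as.numeric(discordant_pairs), n),
                   split_reads = rep_len(as.numeric(split_reads), n),
                   soft_clip = rep_len(as.numeric(soft_clip), n),
                   normal_evidence = rep_len(as.numeric(normal_evidence), n),
                   region_coverage = rep_len(as.numeric(region_coverage), n),
                   sv_type = rep_len(as.character(sv_type), n),
                   microhomology_len = rep_len(as.numeric(microhomology_len), n),
                   near_centromere = rep_len(as.logical(near_centromere), n),
                   near_telomere = rep_len(as.logical(near_telomere), n),
                   stringsAsFactors = FALSE)
  df <- canonicalize_svs(df, genome)
  validate_sv_set(df, genome)
}

# enforce bnd1 <= bnd2 in genome order; orientations travel with breakends
canonicalize_svs <- function(df, genome = NULL) {
  if (!nrow(df)) return(df)
  if (!is.null(genome)) {
    i1 <- chrom_index(genome, df$chrom1, "SV breakend 1")
    i2 <- chrom_index(genome, df$chrom2, "SV breakend 2")
  } else {
    lev <- unique(c(df$chrom1, df$chrom2))
    i1 <- match(df$chrom1, lev); i2 <- match(df$chrom2, lev)
  }
  swap <- i2 < i1 | (i1 == i2 & df$pos2 < df$pos1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "orient1")]
    df[swap, c("chrom1", "pos1", "orient1")] <-
      df[swap, c("chrom2", "pos2", "orient2")]
    df[swap, c("chrom2", "pos2", "orient2")] <- tmp
  }
  df
}

validate_sv_set <- function(df, genome = NULL) {
  stopifnot(all(SV_COLS %in% names(df)))
  df <- df[SV_COLS]
  if (nrow(df)) {
    if (any(!(df$orient1 %in% c("head", "tail"))) ||
        any(!(df$orient2 %in% c("head", "tail")))) {
      ss_error("shatterscan_validation_error", "orientations must be 'head' or 'tail'")
    }
    cnt <- c(df$discordant_pairs, df$split_reads, df$soft_clip,
             df$normal_evidence, df$region_coverage)
    if (any(cnt < 0)) {
      ss_error("shatterscan_validation_error", "evidence counts must be >= 0")
    }
    typed <- !is.na(df$sv_type)
    if (any(typed & !(df$sv_type %in% SV_TYPES))) {
      ss_error("shatterscan_validation_error", "unknown sv_type label")
    }
    inter <- df$chrom1 != df$chrom2
    if (any(typed & ((df$sv_type == "translocation") != inter))) {
      ss_error("shatterscan_validation_error",
               "sv_type is 'translocation' iff chrom1 != chrom2")
    }
    if (!is.null(genome)) {
      check_positions(genome, df$chrom1, df$pos1, "SV breakend 1")
      check_positions(genome, df$chrom2, df$pos2, "SV breakend 2")
    }
  }
  class(df) <- c("sv_set", "data.frame")
  df
}

#' Construct an allele-specific copy-number segment set
#'
#' Segments are half-open `[start, end)` internally, sorted and non-overlapping
#' per chromosome. `major_allele_fraction` lies in [0.5, 1] and is undefined
#' (`NA`) when `total_cn` is 0.
#'
#' @param chrom,start,end segment interval (0-based half-open internal).
#' @param total_cn non-negative integer total copy number.
#' @param major_allele_fraction fraction of the major allele, in [0.5, 1].
#' @param mean_baf,mean_logr optional SNP-array summaries.
#' @param state optional CN state label; must equal
#'   `classify_cn_state(total_cn, major_allele_fraction)` when set.
#' @param genome optional `genome_build` for bounds checks and sorting order.
#' @return data.frame of class `cn_set`.
#' @export
cn_set <- function(chrom = character(), start = numeric(), end = numeric(),
                   total_cn = integer(), major_allele_fraction = NA_real_,
                   mean_baf = NA_real_, mean_logr = NA_real_,
                   state = NA_character_, genome = NULL) {
  n <- max(length(chrom), length(start))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   total_cn = rep_len(as.numeric(total_cn), n),
                   major_allele_fraction = rep_len(as.numeric(major_allele_fraction), n),
                   mean_baf = rep_len(as.numeric(mean_baf), n),
                   mean_logr = rep_len(as.numeric(mean_logr), n),
                   state = rep_len(as.character(state), n),
                   stringsAsFactors = FALSE)
  validate_cn_set(df, genome)
}

validate_cn_set <- function(df, genome = NULL) {
  stopifnot(all(CN_COLS %in% names(df)))
  df <- df[CN_COLS]
  if (nrow(df)) {
    if (any(df$start >= df$end)) {
      ss_error("shatterscan_validation_error", "CN segment with start >= end")
    }
    if (any(df$total_cn < 0) || any(df$total_cn != floor(df$total_cn))) {
      ss_error("shatterscan_validation_error",
               "total_cn must be a non-negative integer")
    }
    maf <- df$major_allele_fraction
    bad_maf <- !is.na(maf) & (maf < 0.5 | maf > 1)
    if (any(bad_maf)) {
      ss_error("shatterscan_validation_error",
               "major_allele_fraction outside [0.5, 1] in row %d", which(bad_maf)[1])
    }
    if (!is.null(genome)) {
      check_positions(genome, df$chrom, df$start, "CN segment start")
      ord <- order(chrom_index(genome, df$chrom), df$start)
    } else {
      ord <- order(match(df$chrom, unique(df$chrom)), df$start)
    }
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (nrow(df) > 1) {
      ovl <- same & df$start[-1] < df$end[-nrow(df)]
      if (any(ovl)) {
        k <- which(ovl)[1]
        ss_error("shatterscan_validation_error",
                 "overlapping CN segments on %s (rows %d and %d after sorting)",
                 df$chrom[k], k, k + 1L)
      }
    }
    st <- !is.na(df$state)
    if (any(st)) {
      expect <- classify_cn_state(df$total_cn[st], df$major_allele_fraction[st])
      if (any(expect != df$state[st])) {
        ss_error("shatterscan_validation_error",
                 "state label inconsistent with classify_cn_state")
      }
    }
  }
  class(df) <- c("cn_set", "data.frame")
  df
}

#' Assemble a per-sample bundle
#'
#' @param sample_id sample identifier string.
#' @param snvs an `snv_set`.
#' @param svs an `sv_set`.
#' @param cn_segments a `cn_set`.
#' @param telomere_stats list with `tumor_count`, `tumor_mean_coverage`,
#'   `normal_count`, `normal_mean_coverage`.
#' @param genome a `genome_build`; all coordinates are checked against it.
#' @return list of class `sample_bundle`.
#' @export
sample_bundle <- function(sample_id, snvs, svs, cn_segments,
                          telomere_stats = NULL, genome) {
  stopifnot(inherits(genome, "genome_build"))
  snvs <- validate_snv_set(as.data.frame(snvs), genome)
  svs <- validate_sv_set(canonicalize_svs(as.data.frame(svs), genome), genome)
  cn_segments <- validate_cn_set(as.data.frame(cn_segments), genome)
  if (!is.null(telomere_stats)) {
    need <- c("tumor_count", "tumor_mean_coverage",
              "normal_count", "normal_mean_coverage")
    if (!all(need %in% names(telomere_stats))) {
      ss_error("shatterscan_validation_error",
               "telomere_stats must carry %s", paste(need, collapse = ", "))
    }
  }
  structure(list(sample_id = as.character(sample_id), snvs = snvs, svs = svs,
                 cn_segments = cn_segments, telomere_stats = telomere_stats,
                 genome = genome),
            class = "sample_bundle")
}

#' @export
print.sample_bundle <- function(x, ...) {
  cat(sprintf("<sample_bundle> %s: %d SNVs, %d SVs, %d CN segments\n",
              x$sample_id, nrow(x$snvs), nrow(x$svs), nrow(x$cn_segments)))
  invisible(x)
}
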