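# High-confidence evidence filtering, eight-way SV typing with copy-number
# integration, breakpoint annotation, junction microhomology, and subtype-wise
# SV-type prevalence comparison.

#' Evidence rule for high-confidence SV calls
#'
#' A call is high confidence when it has at least two evidence classes
#' (discordant pairs, split reads, soft clipping) with any support, or a single
#' class with at least `min_reads_single_class` supporting reads; no evidence
#' in the matched normal; and breakend region coverage at most
#' `max_repeat_coverage` (excluding high-coverage repeat regions).
#'
#' @param min_evidence_classes minimum number of evidence classes (default 2).
#' @param min_reads_single_class minimum reads when only one class supports
#'   the call (default 10).
#' @param max_normal_evidence maximum supporting reads allowed in the matched
#'   normal (default 0).
#' @param max_repeat_coverage maximum breakend fold-coverage (default 1000).
#' @return list of class `evidence_rule`.
#' @export
evidence_rule <- function(min_evidence_classes = 2L, min_reads_single_class = 10L,
                          max_normal_evidence = 0L, max_repeat_coverage = 1000) {
  structure(list(min_evidence_classes = min_evidence_classes,
                 min_reads_single_class = min_reads_single_class,
                 max_normal_evidence = max_normal_evidence,
                 max_repeat_coverage = max_repeat_coverage),
            class = "evidence_rule")
}

#' Matching windows for CN-integrated SV typing
#'
#' @param cn_boundary_window_bp window for matching breakends to copy-number
#'   segment boundaries (+-30 kb).
#' @param special_region_window_bp window for centromere/telomere proximity
#'   annotation (100 kb).
#' @param foldback_max_span_bp maximum breakend separation for a fold-back
#'   inversion (default 30 kb).
#' @return list of class `match_params`.
#' @export
match_params <- function(cn_boundary_window_bp = 30000,
                         special_region_window_bp = 1e5,
                         foldback_max_span_bp = 30000) {
  stopifnot(cn_boundary_window_bp > 0, special_region_window_bp > 0,
            foldback_max_span_bp > 0)
  structure(list(cn_boundary_window_bp = cn_boundary_window_bp,
                 special_region_window_bp = special_region_window_bp,
                 foldback_max_span_bp = foldback_max_span_bp),
            class = "match_params")
}

#' Filter SV calls by the high-confidence evidence rule
#'
#' Total, vectorized function. The reject reason names the first failed clause
#' in rule order: `evidence` (fewer than two classes and no single class with
#' enough reads), `normal_evidence`, `repeat_coverage`.
#'
#' @param svs an `sv_set` (or data.frame with the evidence columns).
#' @param rule an [evidence_rule()].
#' @return data.frame with logical `pass` and character `reason` (`NA` when
#'   passing), one row per SV.
#' @export
filter_high_confidence <- function(svs, rule = evidence_rule()) {
  dp <- svs$discordant_pairs; sr <- svs$split_reads; sc <- svs$soft_clip
  n_classes <- (dp >= 1) + (sr >= 1) + (sc >= 1)
  max_single <- pmax(dp, sr, sc)
  evidence_ok <- n_classes >= rule$min_evidence_classes |
    (n_classes == 1L & max_single >= rule$min_reads_single_class)
  normal_ok <- svs$normal_evidence <= rule$max_normal_evidence
  coverage_ok <- svs$region_coverage <= rule$max_repeat_coverage
  pass <- evidence_ok & normal_ok & coverage_ok
  reason <- rep(NA_character_, length(pass))
  reason[!coverage_ok] <- "repeat_coverage"
  reason[!normal_ok] <- "normal_evidence"
  reason[!evidence_ok] <- "evidence"   # first clause wins
  reason[pass] <- NA_character_
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

# segment state, computing it from (cn, maf) when the column is absent
segment_states <- function(segments) {
  st <- segments$state
  miss <- is.na(st)
  if (any(miss)) {
    st[miss] <- classify_cn_state(segments$total_cn[miss],
                                  segments$major_allele_fraction[miss])
  }
  st
}

#' Classify one SV into the eight-way type scheme
#'
#' Deterministic first-match-wins decision table integrating breakend
#' orientations with copy-number segment context:
#' interchromosomal events are translocations; a (head, tail) deletion-type
#' join whose breakends both match (within the CN window) the two boundaries
#' of a loss segment is a deletion; a (tail, head) duplication-type join
#' boundary-matched to a gained/amplified segment is a tandem duplication, or
#' a duplication when it overlaps a gained segment without boundary match;
#' same-orientation joins are fold-back inversions (short span with a CN state
#' step near the join), amplified inversions (both breakends inside amplified
#' segments) or plain inversions; everything else is intrachromosomal.
#'
#' @param sv single-row `sv_set` (or list with the breakend fields).
#' @param segments `cn_set` for the SV's chromosome (other chromosomes are
#'   ignored); may be empty, in which case CN-refined labels are unreachable.
#' @param params a [match_params()].
#' @return one of the eight `sv_type` labels.
#' @export
classify_sv <- function(sv, segments, params = match_params()) {
  if (sv$chrom1 != sv$chrom2) return("translocation")
  w <- params$cn_boundary_window_bp
  seg <- segments[segments$chrom == sv$chrom1, , drop = FALSE]
  st <- if (nrow(seg)) segment_states(seg) else character()
  p1 <- sv$pos1; p2 <- sv$pos2
  o <- paste(sv$orient1, sv$orient2)

  boundary_matched <- function(keep) {
    any(keep & abs(seg$start - p1) <= w & abs(seg$end - p2) <= w)
  }
  if (o == "head tail") {
    if (nrow(seg) && boundary_matched(st == "loss")) return("deletion")
  } else if (o == "tail head") {
    gainlike <- st %in% c("gain", "amplified")
    if (nrow(seg)) {
      if (boundary_matched(gainlike)) return("tandem_duplication")
      overlaps <- gainlike & seg$start < p2 & seg$end > p1
      if (any(overlaps)) return("duplication")
    }
  } else {  # head head / tail tail: inversion family
    if (nrow(seg)) {
      sep <- p2 - p1
      if (sep <= params$foldback_max_span_bp && nrow(seg) > 1) {
        # CN step: internal boundary where the state changes
        bnd <- seg$end[-nrow(seg)]
        step <- st[-1] != st[-nrow(seg)]
        near <- abs(bnd - p1) <= w | abs(bnd - p2) <= w
        if (any(step & near)) return("foldback_inversion")
      }
      inside_amp <- function(p) any(st == "amplified" & seg$start <= p & p < seg$end)
      if (inside_amp(p1) && inside_amp(p2)) return("amplified_inversion")
    }
    return("inversion")
  }
  "intrachromosomal"
}

#' Classify every SV in a set
#'
#' @param svs an `sv_set`.
#' @param segments a `cn_set` covering the genome (filtered per chromosome
#'   internally).
#' @param params a [match_params()].
#' @return the `sv_set` with `sv_type` filled in.
#' @export
classify_svs <- function(svs, segments, params = match_params()) {
  if (!nrow(svs)) return(svs)
  svs$sv_type <- vapply(seq_len(nrow(svs)), function(i) {
    classify_sv(svs[i, ], segments, params)
  }, character(1))
  svs
}

#' Annotate SVs near centromeres and telomeres
#'
#' `near_telomere` is TRUE when either breakend lies within the window of
#' position 0 or the chromosome end; `near_centromere` when within the window
#' of the centromere interval (FALSE, with a single log message, when the
#' build carries no centromere table).
#'
#' @param svs an `sv_set`.
#' @param genome a `genome_build`.
#' @param params a [match_params()] (uses `special_region_window_bp`).
#' @return the `sv_set` with annotation columns filled.
#' @export
annotate_special_regions <- function(svs, genome, params = match_params()) {
  if (!nrow(svs)) return(svs)
  w <- params$special_region_window_bp
  near_tel <- function(chrom, pos) {
    len <- genome$chrom_lengths[chrom_index(genome, chrom)]
    pos <= w | pos >= len - w
  }
  svs$near_telomere <- near_tel(svs$chrom1, svs$pos1) | near_tel(svs$chrom2, svs$pos2)
  if (is.null(genome$centromeres)) {
    message("annotate_special_regions: no centromere intervals in build; near_centromere set FALSE")
    svs$near_centromere <- FALSE
  } else {
    cen <- genome$centromeres
    near_cen <- function(chrom, pos) {
      i <- match(chrom, cen$chrom)
      !is.na(i) & pos >= cen$start[i] - w & pos < cen$end[i] + w
    }
    svs$near_centromere <- near_cen(svs$chrom1, svs$pos1) | near_cen(svs$chrom2, svs$pos2)
  }
  svs
}

#' Junction microhomology length
#'
#' Longest `L <= max_check` such that the last `L` bases of `left_flank`
#' (reference sequence ending at breakend 1, joined side) equal the first `L`
#' bases of `right_flank` (starting at breakend 2, joined side), both
#' orientation-adjusted to the junction strand.
#'
#' @param left_flank,right_flank nucleotide strings (A/C/G/T,
#'   case-insensitive).
#' @param max_check maximum homology length to test.
#' @return integer length, 0 when none.
#' @export
compute_microhomology <- function(left_flank, right_flank, max_check = 25L) {
  left <- toupper(left_flank); right <- toupper(right_flank)
  if (grepl("[^ACGT]", left) || grepl("[^ACGT]", right)) {
    ss_error("shatterscan_sequence_error", "flank contains non-ACGT characters")
  }
  lmax <- min(max_check, nchar(left), nchar(right))
  nl <- nchar(left)
  for (L in seq(lmax, 1L, by = -1L)) {
    if (substr(left, nl - L + 1L, nl) == substr(right, 1L, L)) return(L)
  }
  0L
}

#' Compare SV-type prevalence between two sample groups
#'
#' Welch two-sample t test, per SV type, of per-sample type fractions.
#' When a type's data are constant in both groups: equal means give t = 0 and
#' p = 1; unequal means give p = 0 — both flagged `zero_variance`.
#'
#' @param group_a,group_b data.frames or matrices of per-sample SV-type
#'   fractions (samples in rows, one column per type); at least 2 samples per
#'   group.
#' @return data.frame with `sv_type`, `t`, `p`, `zero_variance`.
#' @export
sv_type_prevalence_test <- function(group_a, group_b) {
  group_a <- as.data.frame(group_a); group_b <- as.data.frame(group_b)
  if (nrow(group_a) < 2L || nrow(group_b) < 2L) {
    ss_error("shatterscan_statistics_error",
             "each group needs at least 2 samples (got %d and %d)",
             nrow(group_a), nrow(group_b))
  }
  types <- intersect(names(group_a), names(group_b))
  res <- lapply(types, function(ty) {
    a <- group_a[[ty]]; b <- group_b[[ty]]
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        data.frame(sv_type = ty, t = 0, p = 1, zero_variance = TRUE)
      } else {
        data.frame(sv_type = ty, t = sign(mean(a) - mean(b)) * Inf, p = 0,
                   zero_variance = TRUE)
      }
    } else {
      data.frame(sv_type = ty, t = unname(tt$statistic), p = tt$p.value,
                 zero_variance = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Tabulate SV types per sample
#'
#' @param svs a typed `sv_set`.
#' @return named integer vector over the eight type labels.
#' @export
sv_type_counts <- function(svs) {
  tab <- table(factor(svs$sv_type, levels = SV_TYPES))
  out <- as.integer(tab); names(out) <- SV_TYPES
  out
}
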