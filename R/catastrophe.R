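# Copy-number state logic, breakpoint clustering statistics, chromothripsis
# (WGS and array-only) and BFB detection, and genome subtyping.

#' Chromothripsis detection criteria
#'
#' A chromosome is chromothriptic when its breakpoints cluster (one-sample KS
#' p below `clustering_alpha`), its copy number oscillates with at least
#' `min_switches` transitions between 2 or 3 distinct states, heterozygosity
#' is retained in the retained (higher-CN) segments, and the orientations of
#' its rearrangement joins are consistent with random joining (chi-square
#' goodness-of-fit p at least `random_join_alpha`).
#'
#' @param min_switches minimum adjacent copy-number transitions (default 10).
#' @param max_distinct_states maximum number of distinct total-CN levels
#'   (default 3; at least 2 are required).
#' @param clustering_alpha KS clustering significance level (default 0.001).
#' @param random_join_alpha level below which join orientations are considered
#'   non-random (default 0.001).
#' @param het_maf major-allele fraction below which a segment is called
#'   heterozygous (default 0.9, tolerant of BAF noise at realistic tumor
#'   cellularity).
#' @return list of class `chromothripsis_criteria`.
#' @export
chromothripsis_criteria <- function(min_switches = 10L, max_distinct_states = 3L,
                                    clustering_alpha = 0.001,
                                    random_join_alpha = 0.001, het_maf = 0.9) {
  stopifnot(min_switches >= 1, max_distinct_states >= 2)
  structure(list(min_switches = as.integer(min_switches),
                 max_distinct_states = as.integer(max_distinct_states),
                 clustering_alpha = clustering_alpha,
                 random_join_alpha = random_join_alpha, het_maf = het_maf),
            class = "chromothripsis_criteria")
}

#' Breakage-fusion-bridge detection criteria
#'
#' @param min_telomeric_loss_bp minimum span of the terminal loss-state run
#'   (default 1 Mb).
#' @param amplified_min_cn copy number at which a segment counts as amplified
#'   (default 6).
#' @param min_inversions minimum inversion-family SVs inside the amplified
#'   region (default 2).
#' @param adjacency_window_bp maximum gap between the telomeric loss run and
#'   the amplified region (default 1 Mb).
#' @return list of class `bfb_criteria`.
#' @export
bfb_criteria <- function(min_telomeric_loss_bp = 1e6, amplified_min_cn = 6L,
                         min_inversions = 2L, adjacency_window_bp = 1e6) {
  stopifnot(min_telomeric_loss_bp > 0, amplified_min_cn > 0,
            min_inversions > 0, adjacency_window_bp > 0)
  structure(list(min_telomeric_loss_bp = min_telomeric_loss_bp,
                 amplified_min_cn = as.integer(amplified_min_cn),
                 min_inversions = as.integer(min_inversions),
                 adjacency_window_bp = adjacency_window_bp),
            class = "bfb_criteria")
}

#' Classify a copy-number state
#'
#' Integer total copy number and major-allele fraction are mapped to the
#' five-state scheme: loss (CN 0-1), copy-neutral LOH (CN 2 with a single
#' parental allele, maf >= 0.9), neutral (CN 2 heterozygous), gain (CN 3-5),
#' amplified (CN >= 6).
#'
#' @param total_cn non-negative integer copy number (vectorized).
#' @param major_allele_fraction fraction in [0.5, 1]; may be `NA` (undefined
#'   for CN 0; CN-2 segments without allele data default to neutral).
#' @param het_maf threshold separating heterozygous from LOH (default 0.9).
#' @return character vector of state labels.
#' @export
classify_cn_state <- function(total_cn, major_allele_fraction = NA_real_,
                              het_maf = 0.9) {
  n <- max(length(total_cn), length(major_allele_fraction))
  cn <- rep_len(total_cn, n)
  maf <- rep_len(major_allele_fraction, n)
  if (any(cn < 0) || any(cn != floor(cn))) {
    ss_error("shatterscan_validation_error", "total_cn must be a non-negative integer")
  }
  bad <- !is.na(maf) & (maf < 0.5 | maf > 1)
  if (any(bad)) {
    ss_error("shatterscan_validation_error",
             "major_allele_fraction outside [0.5, 1]")
  }
  out <- character(n)
  out[cn <= 1] <- "loss"
  out[cn == 2] <- ifelse(!is.na(maf[cn == 2]) & maf[cn == 2] >= het_maf,
                         "cn_loh", "neutral")
  out[cn >= 3 & cn <= 5] <- "gain"
  out[cn >= 6] <- "amplified"
  out
}

#' Count copy-number state switches along a chromosome
#'
#' @param segments `cn_set` rows of one chromosome, sorted.
#' @return list with `n_switches` (adjacent segment pairs with unequal
#'   total_cn) and `distinct_cn_levels`; `(0, 0)` for an empty set.
#' @export
count_state_switches <- function(segments) {
  if (!nrow(segments)) return(list(n_switches = 0L, distinct_cn_levels = 0L))
  cn <- segments$total_cn
  list(n_switches = sum(diff(cn) != 0),
       distinct_cn_levels = length(unique(cn)))
}

#' Is heterozygosity retained in the retained segments?
#'
#' TRUE when every segment at the modal higher copy-number level (the most
#' frequent level above the chromosome's minimum — the "retained" state of an
#' oscillating profile) is heterozygous (maf below `het_maf`). Segments at the
#' minimum level ("lost") are exempt. Returns `NA` (indeterminate) when the
#' relevant segments carry no allele data.
#'
#' @param segments `cn_set` rows of one chromosome.
#' @param het_maf heterozygosity threshold on major-allele fraction.
#' @return TRUE / FALSE / NA.
#' @export
heterozygosity_retained <- function(segments, het_maf = 0.9) {
  if (!nrow(segments)) return(NA)
  cn <- segments$total_cn
  if (length(unique(cn)) == 1L) {
    cand <- segments
  } else {
    cand <- segments[cn > min(cn), , drop = FALSE]
    tab <- table(cand$total_cn)
    modal <- as.numeric(names(tab)[which.max(tab)])
    cand <- cand[cand$total_cn == modal, , drop = FALSE]
  }
  maf <- cand$major_allele_fraction
  if (all(is.na(maf))) return(NA)
  all(maf < het_maf, na.rm = FALSE) && !anyNA(maf)
}

#' Double-strand breaks per Mb
#'
#' Each breakend counts once toward its own chromosome (a translocation
#' contributes one breakend to each of two chromosomes).
#'
#' @param svs an `sv_set` (high-confidence filtered).
#' @param genome a `genome_build`.
#' @return list with `per_chrom` (data.frame `chrom`, `n_breakends`, `rate`)
#'   and `genome_rate`.
#' @export
breaks_per_mb <- function(svs, genome) {
  chroms <- genome$chrom_names
  counts <- table(factor(c(svs$chrom1, svs$chrom2), levels = chroms))
  n <- as.numeric(counts)
  rate <- n / (genome$chrom_lengths / 1e6)
  list(per_chrom = data.frame(chrom = chroms, n_breakends = n,
                              rate = unname(rate), stringsAsFactors = FALSE),
       genome_rate = sum(n) / (sum(genome$chrom_lengths) / 1e6))
}

#' Kolmogorov-Smirnov breakpoint clustering test
#'
#' One-sample KS goodness-of-fit test of breakend positions (scaled by
#' chromosome length) against Uniform(0,1); the asymptotic two-sided p-value
#' is reported. A small p indicates clustering. Fewer than `min_n` positions
#' return p = 1 with `small_n = TRUE`.
#'
#' @param positions breakend positions on one chromosome (0-based bp).
#' @param chrom_length chromosome length in bp.
#' @param min_n minimum positions for a meaningful test (default 5).
#' @return list with `p`, `D` (KS statistic, NA when small-n), `n`, `small_n`.
#' @export
ks_clustering_test <- function(positions, chrom_length, min_n = 5L) {
  if (length(positions) && (any(positions < 0) || any(positions >= chrom_length))) {
    ss_error("shatterscan_coordinate_error",
             "breakend position outside [0, chrom_length)")
  }
  n <- length(positions)
  if (n < min_n) {
    return(list(p = 1, D = NA_real_, n = n, small_n = TRUE))
  }
  kt <- suppressWarnings(stats::ks.test(positions / chrom_length, "punif",
                                        exact = FALSE))
  list(p = kt$p.value, D = unname(kt$statistic), n = n, small_n = FALSE)
}

#' Join-orientation randomness test
#'
#' Chi-square goodness-of-fit (df = 3) of the four breakend orientation-pair
#' counts (head-tail, tail-head, head-head, tail-tail) against equal
#' proportions. A high p is consistent with the random joining expected of
#' chromothripsis. Fewer than `min_n` joins are indeterminate.
#'
#' @param svs `sv_set` rows of one chromosome region (intrachromosomal joins).
#' @param min_n minimum joins (default 8).
#' @return list with `p`, `statistic`, `counts` (named length-4),
#'   `indeterminate`.
#' @export
random_joins_test <- function(svs, min_n = 8L) {
  o <- paste(svs$orient1, svs$orient2)
  counts <- c(head_tail = sum(o == "head tail"), tail_head = sum(o == "tail head"),
              head_head = sum(o == "head head"), tail_tail = sum(o == "tail tail"))
  n <- sum(counts)
  if (n < min_n) {
    return(list(p = NA_real_, statistic = NA_real_, counts = counts,
                indeterminate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, p = rep(0.25, 4)))
  list(p = ct$p.value, statistic = unname(ct$statistic), counts = counts,
       indeterminate = FALSE)
}

# breakend positions of a chromosome (translocations contribute one end)
chrom_breakends <- function(svs, chrom) {
  c(svs$pos1[svs$chrom1 == chrom], svs$pos2[svs$chrom2 == chrom])
}

#' Detect chromothripsis on one chromosome
#'
#' Positive iff all five criteria hold: breakpoint clustering
#' (p < `clustering_alpha`), >= `min_switches` copy-number switches, 2 or 3
#' distinct CN levels, heterozygosity retained in retained segments, and join
#' orientations consistent with randomness (p >= `random_join_alpha`). The
#' verdict is `NA` (indeterminate) when heterozygosity cannot be assessed and
#' every other criterion passes.
#'
#' @param segments `cn_set` rows of the chromosome.
#' @param svs full `sv_set` of the sample (filtered internally).
#' @param chrom chromosome identifier.
#' @param genome a `genome_build`.
#' @param criteria a [chromothripsis_criteria()].
#' @return one-row data.frame: statistics, per-criterion flags and the
#'   composite `chromothripsis` verdict.
#' @export
detect_chromothripsis <- function(segments, svs, chrom, genome,
                                  criteria = chromothripsis_criteria()) {
  len <- genome$chrom_lengths[chrom_index(genome, chrom)]
  pos <- chrom_breakends(svs, chrom)
  ks <- ks_clustering_test(pos, len)
  sw <- count_state_switches(segments[segments$chrom == chrom, , drop = FALSE])
  het <- heterozygosity_retained(segments[segments$chrom == chrom, , drop = FALSE],
                                 criteria$het_maf)
  joins <- svs[svs$chrom1 == chrom & svs$chrom2 == chrom, , drop = FALSE]
  rj <- random_joins_test(joins)
  flags <- c(
    clustering = ks$p < criteria$clustering_alpha,
    switches = sw$n_switches >= criteria$min_switches,
    states = sw$distinct_cn_levels >= 2 &&
      sw$distinct_cn_levels <= criteria$max_distinct_states,
    het_retained = het,
    random_joins = !rj$indeterminate && rj$p >= criteria$random_join_alpha)
  verdict <- if (is.na(flags[["het_retained"]])) {
    if (all(flags[-4])) NA else FALSE
  } else {
    all(flags)
  }
  # invariant: composite equals the conjunction of its flags
  if (!is.na(verdict)) stopifnot(identical(verdict, all(flags) && TRUE))
  data.frame(chrom = chrom, n_breakends = ks$n, clustering_p = ks$p,
             n_switches = sw$n_switches, distinct_states = sw$distinct_cn_levels,
             het_retained = het, random_join_p = rj$p,
             flag_clustering = flags[["clustering"]],
             flag_switches = flags[["switches"]],
             flag_states = flags[["states"]],
             flag_het = flags[["het_retained"]],
             flag_random_joins = flags[["random_joins"]],
             chromothripsis = verdict,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Array-only chromothripsis screen for one chromosome
#'
#' Copy-number-only inference: positive iff >= `min_switches` switches between
#' 2 or 3 distinct CN levels with heterozygosity retained; no SV input is
#' used.
#'
#' @param segments `cn_set` rows of one chromosome.
#' @param criteria a [chromothripsis_criteria()].
#' @return TRUE / FALSE / NA (indeterminate heterozygosity).
#' @export
detect_chromothripsis_array_only <- function(segments,
                                             criteria = chromothripsis_criteria()) {
  sw <- count_state_switches(segments)
  het <- heterozygosity_retained(segments, criteria$het_maf)
  ok <- sw$n_switches >= criteria$min_switches &&
    sw$distinct_cn_levels >= 2 &&
    sw$distinct_cn_levels <= criteria$max_distinct_states
  if (!ok) return(FALSE)
  het
}

# terminal loss run and adjacent amplified region on one side of a chromosome
bfb_side <- function(seg, st, side, criteria) {
  n <- nrow(seg)
  idx <- if (side == "start") seq_len(n) else rev(seq_len(n))
  run <- integer(0)
  for (i in idx) {
    if (st[i] == "loss") run <- c(run, i) else break
  }
  if (!length(run)) {
    return(list(loss = FALSE, amp = FALSE, amp_start = NA, amp_end = NA))
  }
  span <- max(seg$end[run]) - min(seg$start[run])
  loss_ok <- span >= criteria$min_telomeric_loss_bp
  inner_edge <- if (side == "start") max(seg$end[run]) else min(seg$start[run])
  amp <- which(st == "amplified" & seg$total_cn >= criteria$amplified_min_cn)
  if (!length(amp)) {
    return(list(loss = loss_ok, amp = FALSE, amp_start = NA, amp_end = NA))
  }
  gap <- if (side == "start") seg$start[amp] - inner_edge else inner_edge - seg$end[amp]
  near <- amp[gap >= -1 & gap <= criteria$adjacency_window_bp]
  if (!length(near)) {
    return(list(loss = loss_ok, amp = FALSE, amp_start = NA, amp_end = NA))
  }
  # contiguous run of amplified segments containing the matched one
  a <- near[1]
  lo <- a; while (lo > 1 && st[lo - 1] == "amplified") lo <- lo - 1
  hi <- a; while (hi < n && st[hi + 1] == "amplified") hi <- hi + 1
  list(loss = loss_ok, amp = TRUE, amp_start = seg$start[lo], amp_end = seg$end[hi])
}

#' Detect breakage-fusion-bridge on one chromosome
#'
#' Positive iff a terminal (chromosome-start or -end) run of loss-state
#' segments spans at least `min_telomeric_loss_bp`, an amplified segment
#' (CN >= `amplified_min_cn`) begins within `adjacency_window_bp` of that run,
#' and at least `min_inversions` inversion-family SVs (inversion, fold-back
#' inversion, amplified inversion) have both breakends inside the amplified
#' region. Untyped SVs fall back to same-orientation joins as the
#' inversion-family proxy.
#'
#' @param segments `cn_set` rows of the chromosome.
#' @param svs full `sv_set` of the sample.
#' @param chrom chromosome identifier.
#' @param criteria a [bfb_criteria()].
#' @return one-row data.frame: per-criterion flags, amplified-region interval,
#'   inversion count and the composite `bfb` verdict.
#' @export
detect_bfb <- function(segments, svs, chrom, criteria = bfb_criteria()) {
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  res <- list(loss = FALSE, amp = FALSE, amp_start = NA, amp_end = NA)
  side_used <- NA_character_
  if (nrow(seg)) {
    st <- segment_states(seg)
    for (side in c("start", "end")) {
      cand <- bfb_side(seg, st, side, criteria)
      if (cand$loss && cand$amp) { res <- cand; side_used <- side; break }
      if (cand$loss && !res$loss) { res <- cand; side_used <- side }
    }
  }
  n_inv <- 0L
  if (res$amp) {
    intra <- svs[svs$chrom1 == chrom & svs$chrom2 == chrom, , drop = FALSE]
    inv_family <- ifelse(is.na(intra$sv_type),
                         intra$orient1 == intra$orient2,
                         intra$sv_type %in% c("inversion", "foldback_inversion",
                                              "amplified_inversion"))
    inside <- intra$pos1 >= res$amp_start & intra$pos1 < res$amp_end &
      intra$pos2 >= res$amp_start & intra$pos2 < res$amp_end
    n_inv <- sum(inv_family & inside)
  }
  flags <- c(telomeric_loss = res$loss, amplified_neighbor = res$amp,
             inversions = n_inv >= criteria$min_inversions)
  verdict <- all(flags)
  stopifnot(identical(verdict, all(flags)))
  data.frame(chrom = chrom, side = side_used,
             flag_telomeric_loss = flags[["telomeric_loss"]],
             flag_amplified_neighbor = flags[["amplified_neighbor"]],
             flag_inversions = flags[["inversions"]],
             amp_start = res$amp_start, amp_end = res$amp_end,
             n_inversions_in_amplicon = n_inv, bfb = verdict,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome subtype from SV burden and distribution
#'
#' `unstable` at >= `min_sv_unstable` high-confidence SVs; otherwise
#' `complex_localized` when any chromosome carries at least `min_breakends`
#' breakends at >= `fold` times the genome-wide breaks/Mb rate; otherwise
#' `scattered`.
#'
#' @param n_svs total high-confidence SV count.
#' @param rates output of [breaks_per_mb()].
#' @param min_sv_unstable SV-count threshold (default 450).
#' @param fold per-chromosome enrichment factor (default 3).
#' @param min_breakends minimum breakends for a chromosome to count
#'   (default 5).
#' @return one of `"unstable"`, `"scattered"`, `"complex_localized"`.
#' @export
subtype_genome <- function(n_svs, rates, min_sv_unstable = 450L, fold = 3,
                           min_breakends = 5L) {
  if (n_svs >= min_sv_unstable) return("unstable")
  pc <- rates$per_chrom
  hot <- pc$n_breakends >= min_breakends &
    rates$genome_rate > 0 & pc$rate >= fold * rates$genome_rate
  if (any(hot)) "complex_localized" else "scattered"
}
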