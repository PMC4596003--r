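# Synthetic tumor-cohort generator: chromosomes with implanted catastrophes
# (chromothripsis, BFB, circular double-minute amplicons), kataegis foci,
# scattered background SVs and telomeric/non-telomeric read mixtures, with
# truth labels for every planted event. All draws use R's global RNG, so a
# single set.seed() (done by simulate_sample) makes a whole sample
# reproducible.

#' Simulation parameters
#'
#' Defaults define the package's reference study conditions: 22 chromosomes of
#' 100 Mb; chromothriptic chromosomes shattered into 30 fragments oscillating
#' between CN states {2,3} with retention probability 0.5, confined to 15% of
#' the chromosome; BFB chromosomes with 5 Mb telomeric loss, a 4 Mb CN-8
#' amplicon and 20 fold-back inversions; kataegis foci of 8 mutations over
#' 4 kb on a 1/Mb background; a 2.5 Mb six-fragment CN-8 double minute spread
#' over 3 chromosomes; scattered background SVs at 0.03/Mb; and tumor/normal
#' read mixtures at 74x/39x coverage.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param chromothripsis list: `n_chromosomes`, `n_fragments` (>= 12),
#'   `cn_states` (2-3 distinct non-negative integers), `p_retain` in (0,1),
#'   `span_fraction` of the chromosome that is shattered.
#' @param bfb list: `n_chromosomes`, `lost_telomeric_bp`, `amplicon_bp`,
#'   `amplicon_cn`, `n_foldbacks`.
#' @param kataegis list: `n_foci`, `mutations_per_focus`, `focus_span_bp`,
#'   `background_rate_per_mb`, `min_focus_separation_bp` (distinct foci are
#'   spread over distinct chromosomes when possible and otherwise kept at
#'   least this far apart, default 10 Mb).
#' @param dm list: `k_fragments` (0 disables), `fragment_cn`, `total_bp`,
#'   `n_chromosomes` the fragments are spread over.
#' @param background_sv_rate_per_mb scattered SV rate.
#' @param telomere list: `read_length` (>= 18), `n_reads`, `tumor_fraction`,
#'   `normal_fraction`, `tumor_coverage`, `normal_coverage`.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_chromosomes = 22L, chrom_length_bp = 1e8,
                       chromothripsis = list(), bfb = list(), kataegis = list(),
                       dm = list(), background_sv_rate_per_mb = 0.03,
                       telomere = list()) {
  ct <- utils::modifyList(list(n_chromosomes = 1L, n_fragments = 30L,
                               cn_states = c(2L, 3L), p_retain = 0.5,
                               span_fraction = 0.15), chromothripsis)
  bf <- utils::modifyList(list(n_chromosomes = 1L, lost_telomeric_bp = 5e6,
                               amplicon_bp = 4e6, amplicon_cn = 8L,
                               n_foldbacks = 20L), bfb)
  ka <- utils::modifyList(list(n_foci = 3L, mutations_per_focus = 8L,
                               focus_span_bp = 4000,
                               background_rate_per_mb = 1,
                               min_focus_separation_bp = 1e7), kataegis)
  dmp <- utils::modifyList(list(k_fragments = 6L, fragment_cn = 8L,
                                total_bp = 2.5e6, n_chromosomes = 3L), dm)
  tel <- utils::modifyList(list(read_length = 100L, n_reads = 10000L,
                                tumor_fraction = 0.01, normal_fraction = 0.02,
                                tumor_coverage = 74, normal_coverage = 39),
                           telomere)
  states <- unique(as.integer(ct$cn_states))
  if (length(states) < 2 || length(states) > 3 || any(states < 0)) {
    ss_error("shatterscan_parameter_error",
             "cn_states must hold 2 or 3 distinct non-negative integers")
  }
  if (!(ct$p_retain > 0 && ct$p_retain < 1)) {
    ss_error("shatterscan_parameter_error", "p_retain must lie strictly in (0,1)")
  }
  counts <- c(ct$n_chromosomes, ct$n_fragments, bf$n_chromosomes, bf$n_foldbacks,
              ka$n_foci, ka$mutations_per_focus, dmp$k_fragments, tel$n_reads)
  if (any(counts < 0)) {
    ss_error("shatterscan_parameter_error", "all counts must be >= 0")
  }
  ct$cn_states <- states
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp, chromothripsis = ct,
                 bfb = bf, kataegis = ka, dm = dmp,
                 background_sv_rate_per_mb = background_sv_rate_per_mb,
                 telomere = tel),
            class = "sim_params")
}

# evidence counts: a fraction p_pass of simulated SVs pass the
# high-confidence filter, the rest exercise the reject paths
draw_sv_evidence <- function(n, p_pass = 0.95) {
  pass <- stats::runif(n) < p_pass
  dp <- ifelse(pass, sample(3:20, n, replace = TRUE), 0)
  sr <- ifelse(pass, sample(1:15, n, replace = TRUE), 0)
  sc <- sample(0:5, n, replace = TRUE) * pass
  nrm <- numeric(n); cov <- sample(30:90, n, replace = TRUE)
  if (any(!pass)) {
    mode <- sample(c("single9", "normal", "coverage"), sum(!pass), replace = TRUE)
    i <- which(!pass)
    dp[i] <- ifelse(mode == "single9", 9, 8)
    sr[i] <- ifelse(mode == "single9", 0, 8)
    nrm[i] <- ifelse(mode == "normal", 1, 0)
    cov[i] <- ifelse(mode == "coverage", 1500, cov[i])
    # the "single9" and "normal"/"coverage" rows fail evidence, normal or
    # coverage clauses respectively
  }
  data.frame(discordant_pairs = dp, split_reads = sr, soft_clip = sc,
             normal_evidence = nrm, region_coverage = cov)
}

neutral_segment <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, total_cn = 2,
             major_allele_fraction = 0.5, mean_baf = 0.5, mean_logr = 0,
             state = "neutral", stringsAsFactors = FALSE)
}

# merge adjacent segments with identical (cn, maf)
merge_equal_segments <- function(df) {
  if (nrow(df) < 2) return(df)
  keep <- logical(nrow(df)); keep[1] <- TRUE
  for (i in 2:nrow(df)) {
    same <- df$chrom[i] == df$chrom[i - 1] &&
      df$total_cn[i] == df$total_cn[i - 1] &&
      isTRUE(all.equal(df$major_allele_fraction[i],
                       df$major_allele_fraction[i - 1])) &&
      df$start[i] == df$end[i - 1]
    keep[i] <- !same
  }
  grp <- cumsum(keep)
  out <- df[keep, , drop = FALSE]
  out$end <- as.numeric(tapply(df$end, factor(grp, levels = unique(grp)), max))
  rownames(out) <- NULL
  out
}

#' Simulate a chromothriptic chromosome
#'
#' A sub-region of the chromosome (`span_fraction` of its length) is shattered
#' into `n_fragments` intervals. Each fragment is independently retained
#' (higher CN state, heterozygous) or lost (lowest state, major allele
#' fraction 1) with probability `p_retain`; the retained/lost assignment is
#' redrawn (budget `max_retries`) until the profile shows at least
#' `min_switches` copy-number switches and enough retained fragments to
#' produce at least 8 joins. Consecutive retained fragments are joined by SVs
#' whose breakend orientations are drawn uniformly from the four head/tail
#' combinations, redrawn until a chi-square goodness-of-fit test against
#' uniformity gives p >= 0.01 (clear-margin random joins). The shattering is
#' confined to a sub-region because the event is a localized catastrophe:
#' detection requires significant breakpoint clustering on the chromosome.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length (bp).
#' @param p chromothripsis parameter list (see [sim_params()]).
#' @param min_switches required CN switches (default 10).
#' @param max_retries redraw budget (default 100) before a parameter error.
#' @return list with `segments` (data.frame rows for [cn_set()]) and `svs`.
#' @export
simulate_chromothripsis_chrom <- function(chrom, chrom_length, p,
                                          min_switches = 10L,
                                          max_retries = 100L) {
  if (p$n_fragments < 12) {
    ss_error("shatterscan_parameter_error",
             "n_fragments = %d too small to admit %d switches",
             p$n_fragments, min_switches)
  }
  if (!(p$p_retain > 0 && p$p_retain < 1)) {
    ss_error("shatterscan_parameter_error", "p_retain must lie strictly in (0,1)")
  }
  states <- sort(unique(as.integer(p$cn_states)))
  lo <- states[1]; hi <- states[-1]
  if (p$span_fraction > 0.3) {
    ss_error("shatterscan_parameter_error",
             "span_fraction must be <= 0.3 (localized catastrophe)")
  }
  span <- round(p$span_fraction * chrom_length)
  # distal q arm, clear of the centromere: arm-confined shattering keeps the
  # breakpoint cluster far from the chromosome-wide uniform expectation
  region_start <- round(stats::runif(1, 0.6, 0.92 - p$span_fraction) * chrom_length)
  cuts <- region_start + sort(sample.int(span - 1L, p$n_fragments - 1L))
  starts <- c(region_start, cuts)
  ends <- c(cuts, region_start + span)

  n <- p$n_fragments
  ok <- FALSE
  for (try in seq_len(max_retries)) {
    retained <- stats::runif(n) < p$p_retain
    hi_draw <- if (length(hi) == 1L) rep(hi, n) else sample(hi, n, replace = TRUE)
    cn <- ifelse(retained, hi_draw, lo)
    if (sum(diff(cn) != 0) >= min_switches && sum(retained) >= 9 &&
        any(!retained)) { ok <- TRUE; break }
  }
  if (!ok) {
    ss_error("shatterscan_parameter_error",
             "could not reach %d switches in %d redraws", min_switches, max_retries)
  }
  maf <- ifelse(retained, ceiling(cn / 2) / cn, ifelse(cn == 0, NA_real_, 1.0))
  frag <- data.frame(chrom = chrom, start = starts, end = ends, total_cn = cn,
                     major_allele_fraction = maf, mean_baf = NA_real_,
                     mean_logr = NA_real_, state = NA_character_,
                     stringsAsFactors = FALSE)
  segs <- rbind(neutral_segment(chrom, 0, region_start), frag,
                neutral_segment(chrom, region_start + span, chrom_length))
  segs <- merge_equal_segments(segs)
  segs$state <- classify_cn_state(segs$total_cn, segs$major_allele_fraction)

  ridx <- which(retained)
  n_join <- length(ridx) - 1L
  pos1 <- ends[ridx[-length(ridx)]]
  pos2 <- starts[ridx[-1L]]
  for (try in seq_len(max_retries)) {
    o1 <- sample(c("head", "tail"), n_join, replace = TRUE)
    o2 <- sample(c("head", "tail"), n_join, replace = TRUE)
    rj <- random_joins_test(data.frame(orient1 = o1, orient2 = o2))
    if (!rj$indeterminate && rj$p >= 0.01) break
  }
  ev <- draw_sv_evidence(n_join)
  svs <- data.frame(chrom1 = chrom, pos1 = pos1, orient1 = o1,
                    chrom2 = chrom, pos2 = pos2, orient2 = o2,
                    ev, sv_type = NA_character_, microhomology_len = NA_real_,
                    near_centromere = NA, near_telomere = NA,
                    stringsAsFactors = FALSE)
  list(segments = segs, svs = svs)
}

#' Simulate a breakage-fusion-bridge chromosome
#'
#' Terminal telomeric loss (`[0, lost_telomeric_bp)` at CN 1), an adjacent
#' amplicon at `amplicon_cn`, `n_foldbacks` same-orientation (fold-back)
#' inversions with both breakends inside the amplicon and separation below
#' 30 kb, and a CN-neutral remainder.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length (bp).
#' @param p bfb parameter list (see [sim_params()]).
#' @return list with `segments` and `svs` (possibly 0 rows).
#' @export
simulate_bfb_chrom <- function(chrom, chrom_length, p) {
  if (p$lost_telomeric_bp + p$amplicon_bp >= chrom_length) {
    ss_error("shatterscan_parameter_error",
             "lost_telomeric_bp + amplicon_bp must be < chrom_length")
  }
  if (p$amplicon_cn < 6) {
    warning("simulate_bfb_chrom: amplicon_cn < 6 generates a negative control",
            call. = FALSE)
  }
  amp_start <- p$lost_telomeric_bp
  amp_end <- amp_start + p$amplicon_bp
  segs <- list()
  if (p$lost_telomeric_bp > 0) {
    segs[[1]] <- data.frame(chrom = chrom, start = 0, end = amp_start,
                            total_cn = 1, major_allele_fraction = 1.0,
                            mean_baf = NA_real_, mean_logr = NA_real_,
                            state = NA_character_, stringsAsFactors = FALSE)
  }
  segs[[length(segs) + 1L]] <- data.frame(
    chrom = chrom, start = amp_start, end = amp_end, total_cn = p$amplicon_cn,
    major_allele_fraction = (p$amplicon_cn - 1) / p$amplicon_cn,
    mean_baf = NA_real_, mean_logr = NA_real_, state = NA_character_,
    stringsAsFactors = FALSE)
  segs[[length(segs) + 1L]] <- neutral_segment(chrom, amp_end, chrom_length)
  segs <- do.call(rbind, segs)
  segs$state <- classify_cn_state(segs$total_cn, segs$major_allele_fraction)

  nf <- p$n_foldbacks
  if (nf > 0) {
    span <- round(stats::runif(nf, 200, 29000))
    pos1 <- round(stats::runif(nf, amp_start, amp_end - 1 - span))
    pos2 <- pos1 + span
    orient <- sample(c("head", "tail"), nf, replace = TRUE)
    ev <- draw_sv_evidence(nf)
    svs <- data.frame(chrom1 = chrom, pos1 = pos1, orient1 = orient,
                      chrom2 = chrom, pos2 = pos2, orient2 = orient,
                      ev, sv_type = NA_character_, microhomology_len = NA_real_,
                      near_centromere = NA, near_telomere = NA,
                      stringsAsFactors = FALSE)
  } else {
    svs <- as.data.frame(sv_set())
  }
  list(segments = segs, svs = svs)
}

#' Simulate somatic SNVs with planted kataegis foci
#'
#' Background SNVs are placed uniformly across the genome at
#' `background_rate_per_mb`; each focus places `mutations_per_focus` C>T or
#' C>G mutations uniformly within `focus_span_bp`. Overlapping focus
#' placements are redrawn (budget 100).
#'
#' @param p kataegis parameter list (see [sim_params()]).
#' @param genome a `genome_build`.
#' @return list with `snvs` (annotated `snv_set`) and `foci` (truth
#'   data.frame `chrom`, `start`, `end`).
#' @export
simulate_kataegis_snvs <- function(p, genome) {
  m <- p$mutations_per_focus
  if (p$n_foci > 0 && m > 1 && p$focus_span_bp / (m - 1) > 1000) {
    ss_error("shatterscan_parameter_error",
             "focus_span_bp / (mutations_per_focus - 1) must be <= 1000 bp")
  }
  total_mb <- sum(genome$chrom_lengths) / 1e6
  n_bg <- stats::rpois(1, p$background_rate_per_mb * total_mb)
  bg <- NULL
  if (n_bg > 0) {
    chrom <- sample(genome$chrom_names, n_bg, replace = TRUE,
                    prob = genome$chrom_lengths / sum(genome$chrom_lengths))
    pos <- floor(stats::runif(n_bg) * genome$chrom_lengths[chrom])
    ref <- sample(BASES, n_bg, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
                  USE.NAMES = FALSE)
    bg <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     context5 = sample(BASES, n_bg, replace = TRUE),
                     context3 = sample(BASES, n_bg, replace = TRUE),
                     class96 = NA_integer_, stringsAsFactors = FALSE)
  }
  foci <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     stringsAsFactors = FALSE)
  fmut <- NULL
  if (p$n_foci > 0) {
    # distinct kataegis events: spread over distinct chromosomes when
    # possible, and otherwise keep a wide separation so each focus sits in
    # its own background context for the segmentation
    sep <- p$min_focus_separation_bp %||% 1e7
    host <- rep(sample(genome$chrom_names), length.out = p$n_foci)
    for (f in seq_len(p$n_foci)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        chrom <- host[f]
        len <- genome$chrom_lengths[chrom]
        # interior placement: a focus needs background mutations on both
        # sides to anchor its segment boundaries in the IMD series
        start <- floor(stats::runif(1, 0.2 * len, 0.8 * len - p$focus_span_bp))
        clash <- any(foci$chrom == chrom &
                       foci$start < start + p$focus_span_bp + sep &
                       foci$end > start - sep)
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) {
        ss_error("shatterscan_parameter_error",
                 "could not place non-overlapping kataegis foci in 100 redraws")
      }
      pos <- start + sort(sample.int(p$focus_span_bp, m)) - 1L
      fmut <- rbind(fmut, data.frame(
        chrom = chrom, pos = pos, ref = "C",
        alt = sample(c("T", "G"), m, replace = TRUE, prob = c(0.6, 0.4)),
        context5 = "T", context3 = sample(BASES, m, replace = TRUE),
        class96 = NA_integer_, stringsAsFactors = FALSE))
      foci <- rbind(foci, data.frame(chrom = chrom, start = min(pos),
                                     end = max(pos), stringsAsFactors = FALSE))
    }
  }
  if (!is.null(bg) && nrow(foci)) {
    # guard zone: background must not intrude on a planted focus, so the
    # truth label's mutation count stays exact
    guard <- 1e4
    keep <- rep(TRUE, nrow(bg))
    for (f in seq_len(nrow(foci))) {
      keep <- keep & !(bg$chrom == foci$chrom[f] &
                         bg$pos > foci$start[f] - guard &
                         bg$pos < foci$end[f] + guard)
    }
    bg <- bg[keep, , drop = FALSE]
  }
  snvs <- rbind(bg, fmut)
  if (is.null(snvs)) snvs <- as.data.frame(snv_set())
  snvs <- snvs[!duplicated(snvs[c("chrom", "pos")]), , drop = FALSE]
  snvs <- annotate_snv_classes(validate_snv_set(snvs, genome))
  list(snvs = snvs, foci = foci)
}

#' Simulate a telomeric/non-telomeric read mixture
#'
#' A `telomere_read_fraction` share of reads are tandem TTAGGG (or CCCTAA)
#' repeats spanning the full read (random phase); the rest are i.i.d. uniform
#' nucleotides.
#'
#' @param read_length read length in bp (>= 18, so the x3 motif can fit).
#' @param n_reads number of reads.
#' @param telomere_read_fraction expected telomeric fraction.
#' @return list with `reads` (character vector), `truth_fraction` and
#'   `n_telomeric_truth` (realized count).
#' @export
simulate_telomere_reads <- function(read_length, n_reads,
                                    telomere_read_fraction) {
  if (read_length < 18) {
    ss_error("shatterscan_parameter_error",
             "read_length must be >= 18 to contain the x3 telomeric motif")
  }
  n_tel <- stats::rbinom(1, n_reads, telomere_read_fraction)
  reads <- character(n_reads)
  if (n_reads > n_tel) {
    n_bg <- n_reads - n_tel
    mat <- matrix(sample(BASES, n_bg * read_length, replace = TRUE),
                  nrow = n_bg)
    reads[seq_len(n_bg)] <- apply(mat, 1, paste, collapse = "")
  }
  if (n_tel > 0) {
    motif <- sample(c("TTAGGG", "CCCTAA"), n_tel, replace = TRUE)
    offset <- sample(0:5, n_tel, replace = TRUE)
    tandem <- strrep(motif, ceiling((read_length + 5) / 6) + 1)
    reads[n_reads - n_tel + seq_len(n_tel)] <-
      substr(tandem, offset + 1, offset + read_length)
  }
  reads <- reads[sample.int(n_reads)]
  list(reads = reads, truth_fraction = telomere_read_fraction,
       n_telomeric_truth = n_tel)
}

# plant a circular double minute: k amplified fragments spread over
# dm$n_chromosomes of `chroms`, joined in a randomly oriented cycle
simulate_dm <- function(dmp, chroms, chrom_lengths) {
  k <- dmp$k_fragments
  frag_len <- round(dmp$total_bp / k)
  host <- rep(chroms, length.out = k)
  frags <- NULL
  for (chrom in unique(host)) {
    kk <- sum(host == chrom)
    len <- chrom_lengths[chrom]
    # sequential placement with >= 2 Mb gaps, inside [0.1, 0.9] of the chromosome
    lo <- 0.1 * len
    starts <- numeric(kk)
    for (j in seq_len(kk)) {
      starts[j] <- round(stats::runif(1, lo, lo + 5e6))
      lo <- starts[j] + frag_len + 2e6
    }
    frags <- rbind(frags, data.frame(chrom = chrom, start = starts,
                                     end = starts + frag_len,
                                     stringsAsFactors = FALSE))
  }
  frags <- frags[sample.int(k), , drop = FALSE]  # random cycle order
  rownames(frags) <- NULL
  frags$total_cn <- dmp$fragment_cn
  orient <- sample(c("+", "-"), k, replace = TRUE)
  port_bnd <- function(i, port) {
    if (port == "L") list(pos = frags$start[i], orient = "head")
    else list(pos = frags$end[i], orient = "tail")
  }
  svs <- NULL
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    b1 <- port_bnd(i, if (orient[i] == "+") "R" else "L")
    b2 <- port_bnd(j, if (orient[j] == "+") "L" else "R")
    svs <- rbind(svs, data.frame(
      chrom1 = frags$chrom[i], pos1 = b1$pos, orient1 = b1$orient,
      chrom2 = frags$chrom[j], pos2 = b2$pos, orient2 = b2$orient,
      stringsAsFactors = FALSE))
  }
  # junction-grade evidence: every joining SV passes the confidence filter
  ev <- draw_sv_evidence(k, p_pass = 1)
  svs <- cbind(svs, ev, sv_type = NA_character_, microhomology_len = NA_real_,
               near_centromere = NA, near_telomere = NA)
  list(fragments = frags, orientations = orient, svs = svs)
}

# scattered background SVs, uniform per bp, orientations uniform over the
# four head/tail pairs
simulate_background_svs <- function(rate_per_mb, genome) {
  n <- stats::rpois(1, rate_per_mb * sum(genome$chrom_lengths) / 1e6)
  if (n == 0) return(as.data.frame(sv_set()))
  chrom1 <- sample(genome$chrom_names, n, replace = TRUE,
                   prob = genome$chrom_lengths / sum(genome$chrom_lengths))
  pos1 <- floor(stats::runif(n) * (genome$chrom_lengths[chrom1] - 6e6))
  intra <- stats::runif(n) < 0.7
  chrom2 <- ifelse(intra, chrom1,
                   vapply(chrom1, function(c1)
                     sample(setdiff(genome$chrom_names, c1), 1), character(1),
                     USE.NAMES = FALSE))
  pos2 <- ifelse(intra, pos1 + round(stats::runif(n, 1e4, 5e6)),
                 floor(stats::runif(n) * genome$chrom_lengths[chrom2]))
  ev <- draw_sv_evidence(n)
  df <- data.frame(chrom1 = chrom1, pos1 = pos1,
                   orient1 = sample(c("head", "tail"), n, replace = TRUE),
                   chrom2 = chrom2, pos2 = pos2,
                   orient2 = sample(c("head", "tail"), n, replace = TRUE),
                   ev, sv_type = NA_character_, microhomology_len = NA_real_,
                   near_centromere = NA, near_telomere = NA,
                   stringsAsFactors = FALSE)
  canonicalize_svs(df, genome)
}

# split the neutral cover of a chromosome around planted amplified fragments
insert_fragments_into_neutral <- function(chrom, chrom_length, frags) {
  frags <- frags[order(frags$start), , drop = FALSE]
  segs <- NULL
  cursor <- 0
  for (i in seq_len(nrow(frags))) {
    if (frags$start[i] > cursor) {
      segs <- rbind(segs, neutral_segment(chrom, cursor, frags$start[i]))
    }
    segs <- rbind(segs, data.frame(
      chrom = chrom, start = frags$start[i], end = frags$end[i],
      total_cn = frags$total_cn[i],
      major_allele_fraction = (frags$total_cn[i] - 1) / frags$total_cn[i],
      mean_baf = NA_real_, mean_logr = NA_real_,
      state = classify_cn_state(frags$total_cn[i],
                                (frags$total_cn[i] - 1) / frags$total_cn[i]),
      stringsAsFactors = FALSE))
    cursor <- frags$end[i]
  }
  rbind(segs, neutral_segment(chrom, cursor, chrom_length))
}

#' Simulate a whole tumor sample with truth labels
#'
#' Deterministic given `params$seed`. Chromosomes are assigned at most one
#' catastrophe each (chromothripsis or BFB); double-minute fragments are
#' spread over otherwise event-free chromosomes; scattered background SVs,
#' kataegis SNVs and tumor/normal telomere read mixtures complete the bundle.
#'
#' @param params a [sim_params()].
#' @return list with `bundle` (a validated `sample_bundle`) and `truth`
#'   (per-chromosome event labels, kataegis focus intervals, planted DM
#'   fragments and cycle, telomere truth).
#' @export
simulate_sample <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  genome <- default_genome(params$n_chromosomes, params$chrom_length_bp)
  chroms <- genome$chrom_names
  n_ct <- params$chromothripsis$n_chromosomes
  n_bfb <- params$bfb$n_chromosomes
  dm_on <- params$dm$k_fragments > 0
  n_dm_chrom <- if (dm_on) min(params$dm$n_chromosomes, params$dm$k_fragments) else 0L
  need <- n_ct + n_bfb + n_dm_chrom
  if (need > length(chroms)) {
    ss_error("shatterscan_parameter_error",
             "%d event chromosomes requested but only %d available",
             need, length(chroms))
  }
  picked <- sample(chroms, need)
  ct_chroms <- utils::head(picked, n_ct)
  bfb_chroms <- picked[seq_len(n_bfb) + n_ct]
  dm_chroms <- utils::tail(picked, n_dm_chrom)

  events <- stats::setNames(rep("none", length(chroms)), chroms)
  events[ct_chroms] <- "chromothripsis"
  events[bfb_chroms] <- "bfb"

  bg_svs <- simulate_background_svs(params$background_sv_rate_per_mb, genome)

  seg_list <- list(); sv_list <- list()
  for (chrom in ct_chroms) {
    len <- genome$chrom_lengths[chrom]
    # margin-verified planting: the emitted event must exhibit its defining
    # features at detection conditions with clear margin (breakpoint
    # clustering and join randomness evaluated on the chromosome's full
    # high-confidence SV complement, background included); a draw that fails
    # to exhibit the phenomenon is redrawn, per the retry-until-criterion
    # design of this generator
    ok <- FALSE
    for (try in seq_len(100L)) {
      r <- simulate_chromothripsis_chrom(chrom, len, params$chromothripsis)
      all_svs <- rbind(r$svs, as.data.frame(bg_svs))
      hc <- all_svs[filter_high_confidence(all_svs)$pass, , drop = FALSE]
      pos <- c(hc$pos1[hc$chrom1 == chrom], hc$pos2[hc$chrom2 == chrom])
      ks <- ks_clustering_test(pos, len)
      rj <- random_joins_test(hc[hc$chrom1 == chrom & hc$chrom2 == chrom, ,
                                 drop = FALSE])
      if (ks$p <= 1e-4 && !rj$indeterminate && rj$p >= 0.01) { ok <- TRUE; break }
    }
    if (!ok) {
      ss_error("shatterscan_parameter_error",
               "could not plant a clear-margin chromothripsis on %s in 100 redraws",
               chrom)
    }
    seg_list[[chrom]] <- r$segments; sv_list[[length(sv_list) + 1L]] <- r$svs
  }
  for (chrom in bfb_chroms) {
    r <- simulate_bfb_chrom(chrom, genome$chrom_lengths[chrom], params$bfb)
    seg_list[[chrom]] <- r$segments; sv_list[[length(sv_list) + 1L]] <- r$svs
  }
  dm <- NULL
  if (dm_on) {
    dm <- simulate_dm(params$dm, dm_chroms, genome$chrom_lengths)
    for (chrom in dm_chroms) {
      f <- dm$fragments[dm$fragments$chrom == chrom, , drop = FALSE]
      seg_list[[chrom]] <- insert_fragments_into_neutral(
        chrom, genome$chrom_lengths[chrom], f)
    }
    sv_list[[length(sv_list) + 1L]] <- dm$svs
  }
  for (chrom in setdiff(chroms, names(seg_list))) {
    seg_list[[chrom]] <- neutral_segment(chrom, 0, genome$chrom_lengths[chrom])
  }
  sv_list[[length(sv_list) + 1L]] <- as.data.frame(bg_svs)
  svs <- do.call(rbind, lapply(sv_list, as.data.frame))
  segments <- do.call(rbind, seg_list[chroms])

  kat <- simulate_kataegis_snvs(params$kataegis, genome)

  tel <- params$telomere
  telomere_stats <- NULL
  tel_truth <- NULL
  if (tel$n_reads > 0) {
    tum <- simulate_telomere_reads(tel$read_length, tel$n_reads, tel$tumor_fraction)
    nrm <- simulate_telomere_reads(tel$read_length, tel$n_reads, tel$normal_fraction)
    telomere_stats <- list(
      tumor_count = count_telomeric_reads(tum$reads)$n_telomeric,
      tumor_mean_coverage = tel$tumor_coverage,
      normal_count = count_telomeric_reads(nrm$reads)$n_telomeric,
      normal_mean_coverage = tel$normal_coverage)
    tel_truth <- list(tumor_fraction = tel$tumor_fraction,
                      normal_fraction = tel$normal_fraction,
                      tumor_n_telomeric = tum$n_telomeric_truth,
                      normal_n_telomeric = nrm$n_telomeric_truth)
  }

  bundle <- sample_bundle(sample_id = sprintf("SIM_%06d", params$seed),
                          snvs = kat$snvs, svs = svs, cn_segments = segments,
                          telomere_stats = telomere_stats, genome = genome)
  truth <- list(chrom_events = events, kataegis_foci = kat$foci,
                dm = if (dm_on) list(fragments = dm$fragments,
                                     orientations = dm$orientations,
                                     n_fragments = params$dm$k_fragments,
                                     total_bp = round(params$dm$total_bp /
                                                        params$dm$k_fragments) *
                                       params$dm$k_fragments) else NULL,
                telomere = tel_truth)
  list(bundle = bundle, truth = truth)
}

#' Write truth labels as JSON
#'
#' @param truth the `truth` component of [simulate_sample()].
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
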