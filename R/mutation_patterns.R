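# 96-trinucleotide-context spectra, intermutation distances, exact piecewise
# constant fitting, and kataegis focus calling.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Kataegis calling parameters
#'
#' Defaults follow the published procedure: piecewise constant fitting of
#' intermutation distances with penalty c = 25 and minimum segment length
#' kmin = 2, a focus being a segment of six or more consecutive mutations with
#' mean intermutation distance at most 1,000 bp; ten or more foci per genome
#' are labelled "numerous".
#'
#' @param pcf_penalty segmentation penalty per changepoint (c).
#' @param pcf_kmin minimum PCF segment length.
#' @param min_focus_mutations minimum consecutive mutations per focus.
#' @param max_mean_imd_bp maximum mean intermutation distance (bp).
#' @param numerous_threshold focus count at which the burden is "numerous".
#' @return list of class `kataegis_params`.
#' @export
kataegis_params <- function(pcf_penalty = 25, pcf_kmin = 2L,
                            min_focus_mutations = 6L, max_mean_imd_bp = 1000,
                            numerous_threshold = 10L) {
  stopifnot(pcf_penalty > 0, pcf_kmin >= 1, min_focus_mutations > 0,
            max_mean_imd_bp > 0, numerous_threshold > 0)
  structure(list(pcf_penalty = pcf_penalty, pcf_kmin = as.integer(pcf_kmin),
                 min_focus_mutations = as.integer(min_focus_mutations),
                 max_mean_imd_bp = max_mean_imd_bp,
                 numerous_threshold = as.integer(numerous_threshold)),
            class = "kataegis_params")
}

#' 96-class index of a substitution in trinucleotide context
#'
#' Substitutions are pyrimidine-normalized: purine-reference mutations are
#' reverse-complemented (ref, alt and flanks swapped and complemented) before
#' indexing. The index is `16 * sub + 4 * idx(5') + idx(3')` with substitution
#' order C>A, C>G, C>T, T>A, T>C, T>G and base order A, C, G, T; values run
#' 0-95.
#'
#' @param ref,alt reference and alternate base (single characters, vectorized).
#' @param base5,base3 bases immediately 5' and 3' of the mutated base on the
#'   reference strand.
#' @return integer vector of class indices in 0..95.
#' @export
trinucleotide_class <- function(ref, alt, base5, base3) {
  ref <- toupper(ref); alt <- toupper(alt)
  base5 <- toupper(base5); base3 <- toupper(base3)
  ok <- ref %in% BASES & alt %in% BASES & base5 %in% BASES & base3 %in% BASES
  if (any(!ok)) {
    ss_error("shatterscan_sequence_error", "invalid base in (ref, alt, context)")
  }
  if (any(ref == alt)) {
    ss_error("shatterscan_sequence_error", "ref and alt must differ")
  }
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, complement_base(ref), ref)
  a <- ifelse(flip, complement_base(alt), alt)
  b5 <- ifelse(flip, complement_base(base3), base5)
  b3 <- ifelse(flip, complement_base(base5), base3)
  sub <- match(paste0(r, ">", a), SUB_CLASSES) - 1L
  as.integer(16L * sub + 4L * (match(b5, BASES) - 1L) + (match(b3, BASES) - 1L))
}

#' Labels of the 96 classes in index order
#'
#' @return character vector like `"A[C>A]A"`, `"A[C>A]C"`, ... of length 96.
#' @export
class96_labels <- function() {
  out <- character(96)
  for (s in 0:5) for (b5 in 0:3) for (b3 in 0:3) {
    out[16 * s + 4 * b5 + b3 + 1] <-
      sprintf("%s[%s]%s", BASES[b5 + 1], SUB_CLASSES[s + 1], BASES[b3 + 1])
  }
  out
}

#' Annotate SNVs with their 96-class index
#'
#' @param snvs an `snv_set` with `context5`/`context3` filled.
#' @return the set with `class96` filled.
#' @export
annotate_snv_classes <- function(snvs) {
  if (!nrow(snvs)) return(snvs)
  if (any(is.na(snvs$context5)) || any(is.na(snvs$context3))) {
    ss_error("shatterscan_annotation_error",
             "SNVs lack trinucleotide context; annotate context5/context3 first")
  }
  snvs$class96 <- trinucleotide_class(snvs$ref, snvs$alt,
                                      snvs$context5, snvs$context3)
  snvs
}

#' Intermutation distances of sorted positions
#'
#' @param positions numeric vector of per-chromosome mutation positions;
#'   must be sorted ascending (an ordering error otherwise). Duplicate
#'   positions are collapsed to one with a log message.
#' @return numeric vector `positions[i+1] - positions[i]`; empty when fewer
#'   than 2 distinct positions.
#' @export
intermutation_distances <- function(positions) {
  if (is.unsorted(positions)) {
    ss_error("shatterscan_ordering_error",
             "positions must be sorted ascending; sort explicitly before calling")
  }
  dup <- duplicated(positions)
  if (any(dup)) {
    message(sprintf("intermutation_distances: collapsed %d duplicate position(s)",
                    sum(dup)))
    positions <- positions[!dup]
  }
  if (length(positions) < 2L) return(numeric(0))
  diff(positions)
}

#' Exact piecewise constant fitting
#'
#' Minimizes the sum of within-segment squared deviations from segment means
#' plus `gamma * (number of segments - 1)`, subject to every segment having at
#' least `kmin` points; the exact optimum is found by an O(n^2) dynamic
#' program. Ties are broken toward fewer segments, then toward earlier
#' boundaries.
#'
#' @param values numeric series (length >= 1).
#' @param gamma penalty per changepoint (> 0).
#' @param kmin minimum segment length (>= 1). When `kmin > length(values)` a
#'   single segment is returned with `single_flag = TRUE`.
#' @return list with `ends` (1-based inclusive end index of each segment),
#'   `starts`, `means`, `cost` (penalized objective), `n_segments`,
#'   `single_flag`.
#' @export
pcf_segment <- function(values, gamma = 25, kmin = 2L) {
  n <- length(values)
  stopifnot(n >= 1, gamma > 0, kmin >= 1)
  sse_all <- function(x) sum((x - mean(x))^2)
  if (kmin > n) {
    return(list(ends = n, starts = 1L, means = mean(values),
                cost = sse_all(values), n_segments = 1L, single_flag = TRUE))
  }
  s1 <- c(0, cumsum(values)); s2 <- c(0, cumsum(values^2))
  segcost <- function(i, j) {  # inclusive 1-based
    len <- j - i + 1
    s2[j + 1] - s2[i] - (s1[j + 1] - s1[i])^2 / len
  }
  INF <- Inf
  best <- rep(INF, n + 1L); best[1] <- 0
  nseg <- rep(0L, n + 1L)
  back <- rep(NA_integer_, n + 1L)
  eps <- 1e-9
  for (j in seq_len(n)) {
    if (j < kmin) next
    # previous cut i (0-based count of points already segmented)
    cand <- c(0L, seq_len(max(0L, j - kmin)))
    cand <- cand[cand == 0L | cand >= kmin]      # every segment >= kmin
    cand <- cand[j - cand >= kmin]               # current segment >= kmin
    for (i in cand) {
      if (!is.finite(best[i + 1L])) next
      cost <- best[i + 1L] + segcost(i + 1L, j) + if (i > 0L) gamma else 0
      k <- nseg[i + 1L] + 1L
      better <- cost < best[j + 1L] - eps ||
        (cost < best[j + 1L] + eps &&
           (k < nseg[j + 1L] ||
              (k == nseg[j + 1L] && !is.na(back[j + 1L]) && i < back[j + 1L])))
      if (better) {
        best[j + 1L] <- cost; nseg[j + 1L] <- k; back[j + 1L] <- i
      }
    }
  }
  if (!is.finite(best[n + 1L])) {
    # n < 2*kmin admits only the single segment (caught above for kmin > n)
    return(list(ends = n, starts = 1L, means = mean(values),
                cost = sse_all(values), n_segments = 1L, single_flag = FALSE))
  }
  ends <- integer(0); j <- n
  while (j > 0L) { ends <- c(j, ends); j <- back[j + 1L] }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  means <- vapply(seq_along(ends), function(k) {
    mean(values[starts[k]:ends[k]])
  }, numeric(1))
  list(ends = ends, starts = starts, means = means, cost = best[n + 1L],
       n_segments = length(ends), single_flag = FALSE)
}

#' Call kataegis foci from somatic SNVs
#'
#' Per chromosome: positions are sorted (duplicates collapsed), intermutation
#' distances (IMDs) computed, and the log10(IMD) series segmented by exact PCF
#' with (`pcf_penalty`, `pcf_kmin`). A focus is a run of
#' `min_focus_mutations` or more consecutive mutations, contained in one
#' segment, whose arithmetic mean raw IMD is at most `max_mean_imd_bp`; the
#' longest such run is taken (a segment boundary that absorbed a flanking
#' background mutation does not disqualify the cluster inside it), and
#' disjoint qualifying runs are reported separately. The focus interval spans
#' the first to last qualifying mutation.
#'
#' @param snvs an `snv_set`.
#' @param genome a `genome_build` (chromosome iteration order).
#' @param params a [kataegis_params()].
#' @return data.frame with one row per focus: `chrom`, `start`, `end`,
#'   `n_mutations`, `mean_imd`, `n_c_to_t`, `n_c_to_g`, `n_other`.
#' @export
call_kataegis <- function(snvs, genome, params = kataegis_params()) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_mutations = integer(), mean_imd = numeric(),
                      n_c_to_t = integer(), n_c_to_g = integer(),
                      n_other = integer(), stringsAsFactors = FALSE)
  if (!nrow(snvs)) return(empty)
  out <- list()
  for (chrom in genome$chrom_names) {
    sub <- snvs[snvs$chrom == chrom, , drop = FALSE]
    if (nrow(sub) < params$min_focus_mutations) next
    sub <- sub[order(sub$pos), , drop = FALSE]
    sub <- sub[!duplicated(sub$pos), , drop = FALSE]
    pos <- sub$pos
    if (length(pos) < 2L) next
    imd <- diff(pos)
    fit <- pcf_segment(log10(pmax(imd, 1)), params$pcf_penalty, params$pcf_kmin)
    w_min <- params$min_focus_mutations - 1L   # IMDs per qualifying run
    s1 <- c(0, cumsum(imd))
    # longest run of >= w_min consecutive IMDs with mean <= threshold inside
    # [lo, hi]; recurse on the flanks so disjoint runs are reported apart
    runs <- list()
    find_runs <- function(lo, hi) {
      if (hi - lo + 1L < w_min) return(invisible(NULL))
      for (w in seq(hi - lo + 1L, w_min)) {
        i <- lo:(hi - w + 1L)
        means <- (s1[i + w] - s1[i]) / w
        ok <- which(means <= params$max_mean_imd_bp)
        if (length(ok)) {
          a <- i[ok[which.min(means[ok])]]
          runs[[length(runs) + 1L]] <<- c(a, a + w - 1L)
          find_runs(lo, a - 1L)
          find_runs(a + w, hi)
          return(invisible(NULL))
        }
      }
    }
    for (k in seq_along(fit$ends)) find_runs(fit$starts[k], fit$ends[k])
    for (run in runs) {
      a <- run[1]; b <- run[2]
      m <- b - a + 1L
      raw_mean <- mean(imd[a:b])
      {
        mut <- sub[a:(b + 1L), , drop = FALSE]
        # pyrimidine-normalized substitution classes within the focus
        norm_sub <- ifelse(mut$ref %in% c("A", "G"),
                           paste0(complement_base(mut$ref), ">",
                                  complement_base(mut$alt)),
                           paste0(mut$ref, ">", mut$alt))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = pos[a], end = pos[b + 1L],
          n_mutations = m + 1L, mean_imd = raw_mean,
          n_c_to_t = sum(norm_sub == "C>T"),
          n_c_to_g = sum(norm_sub == "C>G"),
          n_other = sum(!(norm_sub %in% c("C>T", "C>G"))),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, genome$chrom_names), res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Kataegis burden label
#'
#' @param n_foci number of kataegic foci in a genome.
#' @param params a [kataegis_params()] (uses `numerous_threshold`).
#' @return `"none"` (0 foci), `"occasional"` (1 to threshold-1) or
#'   `"numerous"` (>= threshold).
#' @export
kataegis_burden <- function(n_foci, params = kataegis_params()) {
  stopifnot(is_count(n_foci))
  if (n_foci == 0) "none"
  else if (n_foci < params$numerous_threshold) "occasional"
  else "numerous"
}

#' 96 x n_samples mutation spectrum matrix
#'
#' @param samples named list of annotated `snv_set`s (one per sample).
#' @return integer matrix, 96 rows in fixed [class96_labels()] order, one
#'   column per sample; column sums equal per-sample SNV counts.
#' @export
spectrum_matrix <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1)
  ids <- names(samples) %||% sprintf("sample%d", seq_along(samples))
  mat <- matrix(0L, nrow = 96L, ncol = length(samples),
                dimnames = list(class96_labels(), ids))
  for (j in seq_along(samples)) {
    cls <- samples[[j]]$class96
    if (anyNA(cls)) {
      ss_error("shatterscan_annotation_error",
               "sample '%s' has unannotated SNVs (class96 missing)", ids[j])
    }
    if (length(cls)) {
      tab <- tabulate(cls + 1L, nbins = 96L)
      mat[, j] <- tab
    }
  }
  mat
}

#' Write a spectrum matrix as TSV
#'
#' @param mat output of [spectrum_matrix()].
#' @param path output file (96 rows x samples, with a `context` column).
#' @export
write_spectrum_tsv <- function(mat, path) {
  df <- data.frame(context = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-mutation rainfall table
#'
#' Position and distance-to-previous-mutation per chromosome, the standard
#' input for rainfall plots.
#'
#' @param snvs an `snv_set`.
#' @param genome a `genome_build`.
#' @return data.frame with `chrom`, `pos`, `imd` (NA for the first mutation of
#'   a chromosome), `class96`.
#' @export
rainfall_table <- function(snvs, genome) {
  out <- list()
  for (chrom in genome$chrom_names) {
    sub <- snvs[snvs$chrom == chrom, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$pos), , drop = FALSE]
    sub <- sub[!duplicated(sub$pos), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom, pos = sub$pos,
      imd = c(NA_real_, diff(sub$pos)), class96 = sub$class96,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = numeric(), imd = numeric(),
               class96 = integer(), stringsAsFactors = FALSE)
}
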