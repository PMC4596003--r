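# Per-sample orchestration and cohort aggregation.

#' Default analysis configuration
#'
#' One auditable object pinning every threshold of the analysis to its
#' reference value: the high-confidence evidence rule (2 evidence classes /
#' 10 reads single-class / no normal evidence / coverage <= 1000), the
#' +-30 kb CN-boundary and 100 kb centromere/telomere windows, the kataegis
#' parameters (c = 25, kmin = 2, >= 6 mutations at <= 1,000 bp), the
#' chromothripsis criteria (>= 10 switches, 2-3 states, p < 0.001 clustering),
#' the BFB criteria, the subtype thresholds (>= 450 SVs unstable; 3x
#' breaks/Mb localized) and the amplicon search cap.
#'
#' @return list of class `shatterscan_config`.
#' @export
default_config <- function() {
  structure(list(evidence_rule = evidence_rule(),
                 match = match_params(),
                 kataegis = kataegis_params(),
                 chromothripsis = chromothripsis_criteria(),
                 bfb = bfb_criteria(),
                 subtype = list(min_sv_unstable = 450L, fold = 3,
                                min_breakends = 5L),
                 amplicon = list(max_cycle_fragments = 12L,
                                 amplified_min_cn = 6L)),
            class = "shatterscan_config")
}

#' Run the full analysis on one sample
#'
#' Stages in order: evidence filter, SV typing, CN state annotation,
#' breaks/Mb and breakpoint clustering, per-chromosome chromothripsis and BFB
#' detection, genome subtyping, kataegis calling, telomere ratio, amplicon
#' cycle search. Log lines record record counts in and out of each stage.
#'
#' @param bundle a `sample_bundle`.
#' @param config a [default_config()]-style configuration.
#' @return list of class `sample_report`.
#' @export
run_sample <- function(bundle, config = default_config()) {
  stopifnot(inherits(bundle, "sample_bundle"))
  genome <- bundle$genome
  log_stage <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s: %s", bundle$sample_id, stage, sprintf(fmt, ...)))
  }

  hc <- filter_high_confidence(bundle$svs, config$evidence_rule)
  svs <- bundle$svs[hc$pass, , drop = FALSE]
  rej <- table(hc$reason[!hc$pass])
  log_stage("evidence_filter", "%d/%d SVs high-confidence%s",
            nrow(svs), nrow(bundle$svs),
            if (length(rej)) paste0(" (rejected: ",
                                    paste(names(rej), rej, sep = "=",
                                          collapse = ", "), ")") else "")

  segments <- bundle$cn_segments
  if (nrow(segments)) {
    segments$state <- segment_states(segments)
  }
  svs <- classify_svs(svs, segments, config$match)
  svs <- annotate_special_regions(svs, genome, config$match)
  log_stage("sv_typing", "%d SVs typed", nrow(svs))

  rates <- breaks_per_mb(svs, genome)
  verdicts <- do.call(rbind, lapply(genome$chrom_names, function(chrom) {
    ct <- detect_chromothripsis(segments, svs, chrom, genome,
                                config$chromothripsis)
    bf <- detect_bfb(segments, svs, chrom, config$bfb)
    cbind(ct, bf[setdiff(names(bf), "chrom")],
          breaks_per_mb = rates$per_chrom$rate[rates$per_chrom$chrom == chrom])
  }))
  log_stage("catastrophes", "%d chromothripsis-positive, %d BFB-positive chromosome(s)",
            sum(verdicts$chromothripsis, na.rm = TRUE),
            sum(verdicts$bfb, na.rm = TRUE))

  subtype <- subtype_genome(nrow(svs), rates,
                            config$subtype$min_sv_unstable,
                            config$subtype$fold, config$subtype$min_breakends)

  foci <- call_kataegis(bundle$snvs, genome, config$kataegis)
  burden <- kataegis_burden(nrow(foci), config$kataegis)
  log_stage("kataegis", "%d focus/foci (%s)", nrow(foci), burden)

  tel <- NULL
  if (!is.null(bundle$telomere_stats)) {
    ts <- bundle$telomere_stats
    ratio <- suppressWarnings(telomere_ratio(
      telomere_count(ts$tumor_count, ts$tumor_mean_coverage),
      telomere_count(ts$normal_count, ts$normal_mean_coverage)))
    tel <- list(tumor_count = ts$tumor_count,
                tumor_mean_coverage = ts$tumor_mean_coverage,
                normal_count = ts$normal_count,
                normal_mean_coverage = ts$normal_mean_coverage,
                ratio = ratio)
  }

  graph <- withCallingHandlers(
    build_breakpoint_graph(segments, svs, config$match,
                           config$amplicon$amplified_min_cn),
    message = function(m) invokeRestart("muffleMessage"))
  cycles <- find_circular_amplicons(graph, config$amplicon$max_cycle_fragments)
  log_stage("amplicons", "%d candidate circular amplicon(s)", length(cycles))

  report <- structure(list(
    schema_version = "1.0",
    sample_id = bundle$sample_id,
    subtype = subtype,
    verdicts = verdicts,
    kataegis = list(foci = foci, burden = burden),
    telomere = tel,
    amplicons = lapply(cycles, function(cy) {
      c(score_amplicon(cy),
        list(fragment_chrom = cy$fragments$chrom,
             fragment_start = cy$fragments$start,
             fragment_end = cy$fragments$end,
             orientations = cy$orientations))
    }),
    counts = list(n_svs_total = nrow(bundle$svs),
                  n_svs_high_confidence = nrow(svs),
                  n_snvs = nrow(bundle$snvs),
                  sv_type_counts = as.list(sv_type_counts(svs)))),
    class = "sample_report")
  report
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s: subtype %s; %d chromothripsis+, %d BFB+ chromosome(s); %d kataegis focus/foci (%s); %d amplicon(s)\n",
              x$sample_id, x$subtype,
              sum(x$verdicts$chromothripsis, na.rm = TRUE),
              sum(x$verdicts$bfb, na.rm = TRUE),
              nrow(x$kataegis$foci), x$kataegis$burden, length(x$amplicons)))
  invisible(x)
}

#' Write a sample report as JSON
#'
#' Deterministic serialization: identical reports yield byte-identical files.
#'
#' @param report a `sample_report`.
#' @param path output file.
#' @export
write_sample_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Aggregate sample reports into a cohort summary
#'
#' @param reports list of `sample_report`s with unique sample ids.
#' @return list of class `cohort_summary`: sample count, chromothripsis and
#'   BFB positive counts and fractions, subtype and kataegis-burden
#'   tabulations.
#' @export
aggregate_cohort <- function(reports) {
  stopifnot(length(reports) >= 1)
  ids <- vapply(reports, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    ss_error("shatterscan_aggregation_error",
             "duplicate sample id '%s'", ids[duplicated(ids)][1])
  }
  ct_pos <- vapply(reports, function(r) {
    any(r$verdicts$chromothripsis, na.rm = TRUE)
  }, logical(1))
  bfb_pos <- vapply(reports, function(r) {
    any(r$verdicts$bfb, na.rm = TRUE)
  }, logical(1))
  subtypes <- vapply(reports, `[[`, character(1), "subtype")
  burdens <- vapply(reports, function(r) r$kataegis$burden, character(1))
  n <- length(reports)
  structure(list(
    n_samples = n,
    n_chromothripsis = sum(ct_pos),
    fraction_chromothripsis = sum(ct_pos) / n,
    n_bfb = sum(bfb_pos),
    fraction_bfb = sum(bfb_pos) / n,
    subtype_counts = as.list(table(factor(subtypes, levels = c(
      "unstable", "scattered", "complex_localized")))),
    kataegis_burden_counts = as.list(table(factor(burdens, levels = c(
      "none", "occasional", "numerous"))))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d samples: %d (%.1f%%) chromothripsis+, %d (%.1f%%) BFB+\n",
              x$n_samples, x$n_chromothripsis, 100 * x$fraction_chromothripsis,
              x$n_bfb, 100 * x$fraction_bfb))
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary a `cohort_summary`.
#' @param path output file.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
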