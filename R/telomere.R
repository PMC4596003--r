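# Telomeric read counting and tumor/normal telomere-content ratio.

TEL_MOTIF_F <- strrep("TTAGGG", 3)  # 5'-TTAGGG-3' x 3
TEL_MOTIF_R <- strrep("CCCTAA", 3)  # reverse complement motif x 3

#' Count telomeric reads
#'
#' A read counts once iff it contains the telomeric repeat
#' `TTAGGG` x 3 or `CCCTAA` x 3 as a contiguous substring (case-insensitive;
#' `N` bases break matches).
#'
#' @param reads character vector of read sequences (e.g. from
#'   [read_fastq()]).
#' @return list of class `telomere_count` with `n_telomeric` and `n_total`.
#' @export
count_telomeric_reads <- function(reads) {
  if (!length(reads)) {
    return(structure(list(n_telomeric = 0L, n_total = 0L),
                     class = "telomere_count"))
  }
  up <- toupper(reads)
  hit <- grepl(TEL_MOTIF_F, up, fixed = TRUE) | grepl(TEL_MOTIF_R, up, fixed = TRUE)
  structure(list(n_telomeric = sum(hit), n_total = length(reads)),
            class = "telomere_count")
}

#' Coverage-normalized telomere count
#'
#' @param n_telomeric telomeric read count.
#' @param mean_coverage average genomic base coverage (fold, > 0).
#' @param n_total optional total read count.
#' @return list of class `telomere_count` with `normalized = n_telomeric /
#'   mean_coverage`.
#' @export
telomere_count <- function(n_telomeric, mean_coverage, n_total = NA_integer_) {
  if (!is.numeric(mean_coverage) || mean_coverage <= 0) {
    ss_error("shatterscan_validation_error", "mean_coverage must be > 0")
  }
  if (n_telomeric < 0) {
    ss_error("shatterscan_validation_error", "counts must be >= 0")
  }
  structure(list(n_telomeric = n_telomeric, n_total = n_total,
                 mean_coverage = mean_coverage,
                 normalized = n_telomeric / mean_coverage),
            class = "telomere_count")
}

#' Tumor/normal telomere-content ratio
#'
#' `ratio = (tumor count / tumor coverage) / (normal count / normal
#' coverage)`; a ratio below 1 indicates somatic telomere shortening. A
#' normal count of 0 yields `NaN` (undefined-ratio flag).
#'
#' @param tumor,normal [telomere_count()] objects (with `mean_coverage` set).
#' @return numeric ratio (`NaN` when undefined).
#' @export
telomere_ratio <- function(tumor, normal) {
  for (x in list(tumor, normal)) {
    if (is.null(x$mean_coverage) || x$mean_coverage <= 0) {
      ss_error("shatterscan_validation_error",
               "telomere_ratio needs mean_coverage > 0 on both sides")
    }
  }
  if (normal$n_telomeric == 0) {
    warning("telomere_ratio: normal telomeric count is 0; ratio undefined",
            call. = FALSE)
    return(NaN)
  }
  (tumor$n_telomeric / tumor$mean_coverage) /
    (normal$n_telomeric / normal$mean_coverage)
}
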