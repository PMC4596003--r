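#' Genome build table
#'
#' A minimal genome description: ordered chromosome names, their lengths in bp,
#' and optional centromere intervals. Only the coordinate table is needed by the
#' pipeline, never sequence. All internal coordinates are 0-based half-open.
#'
#' @param chrom_names character vector of unique chromosome identifiers, in
#'   genome order.
#' @param chrom_lengths numeric vector of chromosome lengths (bp), same length
#'   and order as `chrom_names`; all must be > 0.
#' @param centromeres optional `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based half-open) giving one centromere interval per chromosome;
#'   each interval must lie within `[0, length)` of its chromosome.
#' @return An object of class `genome_build`.
#' @examples
#' gb <- genome_build(c("chr1", "chr2"), c(2e8, 1.5e8))
#' @export
genome_build <- function(chrom_names, chrom_lengths, centromeres = NULL) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    ss_error("shatterscan_validation_error",
             "chrom_names and chrom_lengths differ in length (%d vs %d)",
             length(chrom_names), length(chrom_lengths))
  }
  if (anyDuplicated(chrom_names)) {
    ss_error("shatterscan_validation_error", "duplicated chromosome names")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    ss_error("shatterscan_validation_error", "all chromosome lengths must be > 0")
  }
  names(chrom_lengths) <- chrom_names
  if (!is.null(centromeres)) {
    stopifnot(is.data.frame(centromeres),
              all(c("chrom", "start", "end") %in% names(centromeres)))
    bad <- !(centromeres$chrom %in% chrom_names)
    if (any(bad)) {
      ss_error("shatterscan_coordinate_error",
               "centromere chromosome '%s' not in build", centromeres$chrom[bad][1])
    }
    len <- chrom_lengths[centromeres$chrom]
    if (any(centromeres$start < 0 | centromeres$end > len |
            centromeres$start >= centromeres$end)) {
      ss_error("shatterscan_validation_error",
               "centromere interval outside [0, length) or empty")
    }
  }
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = chrom_lengths,
                 centromeres = centromeres),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %d chromosomes, %.1f Mb total%s\n",
              length(x$chrom_names), sum(x$chrom_lengths) / 1e6,
              if (is.null(x$centromeres)) "" else ", centromeres annotated"))
  invisible(x)
}

# index of a chromosome in the build order; classed error when absent
chrom_index <- function(genome, chrom, context = NULL) {
  i <- match(chrom, genome$chrom_names)
  if (anyNA(i)) {
    bad <- chrom[is.na(i)][1]
    where <- if (is.null(context)) "" else sprintf(" (%s)", context)
    ss_error("shatterscan_coordinate_error",
             "chromosome '%s' absent from genome build%s", bad, where)
  }
  i
}

check_positions <- function(genome, chrom, pos, context = "record") {
  i <- chrom_index(genome, chrom, context)
  len <- genome$chrom_lengths[i]
  bad <- pos < 0 | pos >= len
  if (any(bad)) {
    k <- which(bad)[1]
    ss_error("shatterscan_coordinate_error",
             "position %s on %s outside [0, %s) (%s)",
             format(pos[k], scientific = FALSE), chrom[k],
             format(len[k], scientific = FALSE), context)
  }
  invisible(TRUE)
}

#' Default synthetic genome
#'
#' Convenience genome used by the simulators: `n` equally sized chromosomes
#' named `chr1..chrn`, each with a 1 Mb centromere interval placed at 45% of
#' its length.
#'
#' @param n_chromosomes number of chromosomes (default 22, emulating autosomes).
#' @param chrom_length_bp length of each chromosome in bp (default 1e8).
#' @return A `genome_build`.
#' @export
default_genome <- function(n_chromosomes = 22L, chrom_length_bp = 1e8) {
  nm <- paste0("chr", seq_len(n_chromosomes))
  cen <- data.frame(chrom = nm,
                    start = rep(round(0.45 * chrom_length_bp), n_chromosomes),
                    end = rep(round(0.45 * chrom_length_bp) + 1e6, n_chromosomes))
  genome_build(nm, rep(chrom_length_bp, n_chromosomes), cen)
}
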