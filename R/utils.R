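# internal helpers shared across modules

# classed conditions so callers/tests can distinguish failure modes
ss_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "shatterscan_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
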