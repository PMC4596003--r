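# Double-minute reconstruction: amplified fragments become nodes with two
# ports (left/right end); SVs whose breakends match fragment ends become
# edges; candidate circular amplicons are port-consistent simple cycles.

#' Build a breakpoint graph over amplified fragments
#'
#' Nodes are amplified copy-number segments (CN >= `amplified_min_cn`), each
#' with a left and right port. An SV becomes an edge when both breakends match
#' a fragment end within the CN boundary window, the port being determined by
#' breakend orientation: a head breakend (retained sequence running to higher
#' coordinates) matches a fragment's left end, a tail breakend its right end.
#' SVs matching no fragment end are ignored with a logged count.
#'
#' @param segments a `cn_set`.
#' @param svs an `sv_set` (high-confidence).
#' @param params a [match_params()] (uses `cn_boundary_window_bp`).
#' @param amplified_min_cn copy number defining an amplified fragment
#'   (default 6).
#' @return list of class `breakpoint_graph` with `fragments` (data.frame
#'   `id`, `chrom`, `start`, `end`, `total_cn`) and `edges` (data.frame
#'   `edge_id`, `frag1`, `port1`, `frag2`, `port2`, `sv_row`).
#' @export
build_breakpoint_graph <- function(segments, svs, params = match_params(),
                                   amplified_min_cn = 6L) {
  amp <- segments[segments$total_cn >= amplified_min_cn, , drop = FALSE]
  frags <- if (nrow(amp)) {
    data.frame(id = seq_len(nrow(amp)), chrom = amp$chrom, start = amp$start,
               end = amp$end, total_cn = amp$total_cn, stringsAsFactors = FALSE)
  } else {
    data.frame(id = integer(), chrom = character(), start = numeric(),
               end = numeric(), total_cn = numeric(), stringsAsFactors = FALSE)
  }
  w <- params$cn_boundary_window_bp
  match_port <- function(chrom, pos, orient) {
    if (!nrow(frags)) return(NULL)
    if (orient == "head") {
      hit <- which(frags$chrom == chrom & abs(frags$start - pos) <= w)
      port <- "L"
    } else {
      hit <- which(frags$chrom == chrom & abs(frags$end - pos) <= w)
      port <- "R"
    }
    if (!length(hit)) return(NULL)
    list(frag = hit[1], port = port)
  }
  edges <- list(); dropped <- 0L
  for (i in seq_len(nrow(svs))) {
    m1 <- match_port(svs$chrom1[i], svs$pos1[i], svs$orient1[i])
    m2 <- match_port(svs$chrom2[i], svs$pos2[i], svs$orient2[i])
    if (is.null(m1) || is.null(m2)) { dropped <- dropped + 1L; next }
    edges[[length(edges) + 1L]] <- data.frame(
      edge_id = length(edges) + 1L, frag1 = m1$frag, port1 = m1$port,
      frag2 = m2$frag, port2 = m2$port, sv_row = i, stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    message(sprintf("build_breakpoint_graph: %d SV(s) matched no fragment end",
                    dropped))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(edge_id = integer(), frag1 = integer(), port1 = character(),
               frag2 = integer(), port2 = character(), sv_row = integer(),
               stringsAsFactors = FALSE)
  structure(list(fragments = frags, edges = edges), class = "breakpoint_graph")
}

# edges incident to a (fragment, port), as (edge_id, other_frag, other_port)
incident_edges <- function(graph, frag, port) {
  e <- graph$edges
  a <- e$frag1 == frag & e$port1 == port
  b <- e$frag2 == frag & e$port2 == port
  rbind(
    data.frame(edge_id = e$edge_id[a], frag = e$frag2[a], port = e$port2[a],
               stringsAsFactors = FALSE),
    data.frame(edge_id = e$edge_id[b & !a], frag = e$frag1[b & !a],
               port = e$port1[b & !a], stringsAsFactors = FALSE))
}

#' Find circular amplicons (candidate double minutes)
#'
#' Exhaustively enumerates simple cycles in which every fragment is traversed
#' through opposite ports (entering one end, leaving the other) and
#' consecutive fragments are linked by an SV edge whose ports agree with the
#' traversal orientations. Each cycle is reported once, in canonical form
#' (rotated to start at its lowest fragment id, traversed with that fragment
#' in forward orientation), sorted by total length descending.
#'
#' @param graph a [build_breakpoint_graph()] result.
#' @param max_cycle_fragments cap on fragments per cycle (default 12,
#'   the exhaustive regime).
#' @return list of `amplicon_cycle` objects, each with `fragment_ids`,
#'   `orientations` (`+`/`-`), `edge_ids`, `total_length_bp`, `mean_cn`,
#'   `chromosomes` and a `fragments` data.frame in traversal order.
#' @export
find_circular_amplicons <- function(graph, max_cycle_fragments = 12L) {
  stopifnot(max_cycle_fragments >= 1, max_cycle_fragments <= 12L)
  frags <- graph$fragments
  cycles <- list()
  if (!nrow(frags) || !nrow(graph$edges)) return(cycles)
  for (s in frags$id) {
    # DFS; only fragments with id >= s so each cycle starts at its minimum id
    path_frags <- s; path_orients <- "+"; path_edges <- integer(0)
    recurse <- function(cur, exit_port) {
      inc <- incident_edges(graph, cur, exit_port)
      for (k in seq_len(nrow(inc))) {
        e <- inc$edge_id[k]; g <- inc$frag[k]; r <- inc$port[k]
        if (e %in% path_edges) next
        if (g == s && r == "L" && length(path_frags) >= 1L) {
          cycles[[length(cycles) + 1L]] <<- list(
            fragment_ids = path_frags, orientations = path_orients,
            edge_ids = c(path_edges, e))
          next
        }
        if (g <= s || g %in% path_frags) next
        if (length(path_frags) >= max_cycle_fragments) next
        orient <- if (r == "L") "+" else "-"
        path_frags <<- c(path_frags, g)
        path_orients <<- c(path_orients, orient)
        path_edges <<- c(path_edges, e)
        recurse(g, if (r == "L") "R" else "L")
        path_frags <<- utils::head(path_frags, -1L)
        path_orients <<- utils::head(path_orients, -1L)
        path_edges <<- utils::head(path_edges, -1L)
      }
    }
    recurse(s, "R")
  }
  cycles <- lapply(cycles, function(cy) {
    stopifnot(validate_cycle(graph, cy))   # port-consistency invariant
    f <- frags[match(cy$fragment_ids, frags$id), , drop = FALSE]
    structure(list(fragment_ids = cy$fragment_ids,
                   orientations = cy$orientations,
                   edge_ids = cy$edge_ids,
                   fragments = f,
                   total_length_bp = sum(f$end - f$start),
                   mean_cn = sum((f$end - f$start) * f$total_cn) /
                     sum(f$end - f$start),
                   chromosomes = unique(f$chrom)),
              class = "amplicon_cycle")
  })
  ord <- order(vapply(cycles, `[[`, numeric(1), "total_length_bp"),
               decreasing = TRUE)
  cycles[ord]
}

# independent re-validation that consecutive traversal orientations agree
# with the SV edge ports (used as an internal invariant and by tests)
validate_cycle <- function(graph, cycle) {
  ids <- cycle$fragment_ids; ors <- cycle$orientations; eds <- cycle$edge_ids
  n <- length(ids)
  if (length(ors) != n || length(eds) != n || anyDuplicated(ids)) return(FALSE)
  exit_port <- ifelse(ors == "+", "R", "L")
  entry_port <- ifelse(ors == "+", "L", "R")
  for (k in seq_len(n)) {
    nxt <- if (k == n) 1L else k + 1L
    e <- graph$edges[graph$edges$edge_id == eds[k], , drop = FALSE]
    if (nrow(e) != 1L) return(FALSE)
    want <- c(paste(ids[k], exit_port[k]), paste(ids[nxt], entry_port[nxt]))
    have <- c(paste(e$frag1, e$port1), paste(e$frag2, e$port2))
    if (!setequal(want, have)) return(FALSE)
    # a self-matching edge must actually join the two required port slots
    if (want[1] == want[2] && have[1] != have[2]) return(FALSE)
  }
  TRUE
}

#' Summarize an amplicon cycle
#'
#' @param cycle an `amplicon_cycle`.
#' @return list with `mean_cn` (length-weighted), `min_cn`,
#'   `n_chromosomes`, `total_length_bp`, `n_fragments`.
#' @export
score_amplicon <- function(cycle) {
  f <- cycle$fragments
  len <- f$end - f$start
  list(mean_cn = sum(len * f$total_cn) / sum(len),
       min_cn = min(f$total_cn),
       n_chromosomes = length(unique(f$chrom)),
       total_length_bp = sum(len),
       n_fragments = nrow(f))
}

#' @export
print.amplicon_cycle <- function(x, ...) {
  cat(sprintf("<amplicon_cycle> %d fragments, %.2f Mb, mean CN %.1f (%s)\n",
              length(x$fragment_ids), x$total_length_bp / 1e6, x$mean_cn,
              paste(x$chromosomes, collapse = ",")))
  invisible(x)
}
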