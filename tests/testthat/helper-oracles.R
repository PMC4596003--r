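# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation (enumeration, brute
# force, closed form) kept separate from the implementation it checks.

toy_genome <- function(n = 3, len = 1e7) default_genome(n, len)

# --- exhaustive piecewise-constant-fit optimum over all compositions -------
pcf_oracle_cost <- function(values, gamma, kmin) {
  n <- length(values)
  sse <- function(x) sum((x - mean(x))^2)
  best <- Inf
  recurse <- function(start, cost, nseg) {
    if (start > n) {
      best <<- min(best, cost + gamma * (nseg - 1))
      return(invisible(NULL))
    }
    remain <- n - start + 1
    for (len in seq_len(remain)) {
      if (len < kmin) next
      if (remain - len != 0 && remain - len < kmin) next
      recurse(start + len, cost + sse(values[start:(start + len - 1)]), nseg + 1)
    }
  }
  recurse(1L, 0, 0L)
  best
}

# --- O(L^2) microhomology brute force --------------------------------------
microhomology_oracle <- function(left, right, max_check) {
  left <- toupper(left); right <- toupper(right)
  best <- 0L
  for (L in seq_len(min(max_check, nchar(left), nchar(right)))) {
    if (substr(left, nchar(left) - L + 1, nchar(left)) == substr(right, 1, L)) {
      best <- L
    }
  }
  best
}

# --- Welch t statistic from the textbook formula ---------------------------
welch_oracle <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((stats::var(a) / length(a))^2 / (length(a) - 1) +
                   (stats::var(b) / length(b))^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# --- port-graph constructor + edge-subset cycle enumeration ----------------
# A breakpoint_graph built directly from fragment/edge tables (same field
# layout as build_breakpoint_graph output).
make_port_graph <- function(n_frag, edges, chrom = "chr1",
                            frag_len = 4e5, cn = 8) {
  frags <- data.frame(id = seq_len(n_frag), chrom = chrom,
                      start = (seq_len(n_frag) - 1) * 1e6,
                      end = (seq_len(n_frag) - 1) * 1e6 + frag_len,
                      total_cn = cn, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges$edge_id <- seq_len(nrow(edges))
  edges$sv_row <- seq_len(nrow(edges))
  structure(list(fragments = frags,
                 edges = edges[c("edge_id", "frag1", "port1", "frag2", "port2",
                                 "sv_row")]),
            class = "breakpoint_graph")
}

# all port-consistent simple cycles, by enumerating every SV-edge subset:
# a k-fragment cycle uses exactly k edges, each involved fragment has both
# ports at degree exactly 1, and the alternating walk closes in one component
cycles_oracle <- function(graph, max_frag = 12) {
  e <- graph$edges
  m <- nrow(e)
  out <- list()
  if (m == 0) return(out)
  ep1 <- paste(e$frag1, e$port1); ep2 <- paste(e$frag2, e$port2)
  for (mask in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0L)
    frs <- unique(c(e$frag1[idx], e$frag2[idx]))
    if (length(idx) != length(frs) || length(frs) > max_frag) next
    ports <- c(ep1[idx], ep2[idx])
    deg <- table(ports)
    if (!(all(deg == 1) && length(deg) == 2 * length(frs))) next
    # walk: enter fragment at one port, leave via the other, follow the edge
    lookup <- stats::setNames(seq_along(idx), ep1[idx])
    lookup2 <- stats::setNames(seq_along(idx), ep2[idx])
    start <- frs[1]; cur <- start; port <- "R"; visited <- 0L; closed <- FALSE
    repeat {
      key <- paste(cur, port)
      k <- if (!is.na(lookup[key])) idx[lookup[key]] else idx[lookup2[key]]
      nxt <- if (ep1[k] == key) c(e$frag2[k], e$port2[k]) else c(e$frag1[k], e$port1[k])
      visited <- visited + 1L
      cur <- as.integer(nxt[1])
      port <- if (nxt[2] == "L") "R" else "L"   # traverse fragment internally
      if (cur == start && nxt[2] == "L") { closed <- TRUE; break }
      if (visited > length(idx)) break
    }
    if (closed && visited == length(idx)) {
      out[[length(out) + 1L]] <- sort(e$edge_id[idx])
    }
  }
  unique(out)
}

canonical_edge_sets <- function(cycles) {
  unique(lapply(cycles, function(cy) sort(cy$edge_ids)))
}

setequal_edge_sets <- function(a, b) {
  fa <- sort(vapply(a, paste, character(1), collapse = ","))
  fb <- sort(vapply(b, paste, character(1), collapse = ","))
  identical(fa, fb)
}

# --- planted-cycle builder: segments + SVs that wire k amplified fragments
# into one circle with the given orientations ------------------------------
plant_cycle <- function(chroms, starts, frag_len, orient, cn = 8,
                        genome = NULL) {
  k <- length(chroms)
  seg <- data.frame(chrom = chroms, start = starts, end = starts + frag_len,
                    total_cn = cn,
                    major_allele_fraction = (cn - 1) / cn,
                    mean_baf = NA_real_, mean_logr = NA_real_,
                    state = "amplified", stringsAsFactors = FALSE)
  bnd <- function(i, port) {
    if (port == "L") list(chrom = chroms[i], pos = starts[i], orient = "head")
    else list(chrom = chroms[i], pos = starts[i] + frag_len[i], orient = "tail")
  }
  rows <- lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    b1 <- bnd(i, if (orient[i] == "+") "R" else "L")
    b2 <- bnd(j, if (orient[j] == "+") "L" else "R")
    data.frame(chrom1 = b1$chrom, pos1 = b1$pos, orient1 = b1$orient,
               chrom2 = b2$chrom, pos2 = b2$pos, orient2 = b2$orient,
               discordant_pairs = 10, split_reads = 5, soft_clip = 1,
               normal_evidence = 0, region_coverage = 60,
               sv_type = NA_character_, microhomology_len = NA_real_,
               near_centromere = NA, near_telomere = NA,
               stringsAsFactors = FALSE)
  })
  list(segments = seg, svs = do.call(rbind, rows))
}

# --- small SV/CN builders --------------------------------------------------
one_sv <- function(chrom1 = "chr1", pos1, orient1, chrom2 = chrom1, pos2,
                   orient2, dp = 10, sr = 5, sc = 0, nrm = 0, cov = 60) {
  sv_set(chrom1 = chrom1, pos1 = pos1, orient1 = orient1,
         chrom2 = chrom2, pos2 = pos2, orient2 = orient2,
         discordant_pairs = dp, split_reads = sr, soft_clip = sc,
         normal_evidence = nrm, region_coverage = cov)
}

segs_df <- function(chrom, bounds, cn, maf) {
  cn_set(chrom = chrom, start = utils::head(bounds, -1), end = bounds[-1],
         total_cn = cn, major_allele_fraction = maf)
}
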