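#' Extract rearrangement junctions from split/gapped alignments
#'
#' A junction `(exit, reentry)` is the pair (last reference base before
#' the join, first reference base after the join), 1-based on the
#' circular reference. Junctions come from two sources: (i) reference
#' gaps (`D`/`N` CIGAR runs) of at least `min_gap` bases inside one
#' record, and (ii) consecutive split segments of one read on the same
#' strand, ordered by position in the read. In both cases the emission
#' rule is circular: a candidate is kept iff its circular gap
#' `(reentry - exit - 1) mod L >= min_gap`, which suppresses both small
#' alignment indels and the zero-gap join of a read crossing the
#' reference origin, while keeping back-jump (duplication) junctions
#' whose gap measured around the circle is large.
#'
#' When flanking sequence identity (microhomology) makes the breakpoint
#' placement ambiguous, junctions are left-aligned: shifted as far 5' as
#' `base(exit) == base(reentry - 1)` holds. Identical junctions are
#' aggregated and junctions within `merge_tol` of each other (circular
#' Chebyshev distance on the coordinate pair) are merged by single
#' linkage, support summed, with the best-supported member pair (ties:
#' smallest coordinates) as the representative.
#'
#' @param aln An [mt_alignments()] table on the circular reference.
#' @param genome The [circular_genome()].
#' @param min_gap Minimum circular gap distinguishing a junction from an
#'   alignment indel (default 30).
#' @param min_segment Minimum aligned length (bases) of each segment or
#'   block flanking a junction (default 20).
#' @param min_mapq Records below this mapping quality are ignored
#'   (default 20).
#' @param merge_tol Merge radius in bases (default 5).
#' @return `data.frame` of class `junction_table`: columns `exit`,
#'   `reentry`, `support`, sorted by decreasing support then coordinates.
#' @export
extract_junctions <- function(aln, genome, min_gap = 30L, min_segment = 20L,
                              min_mapq = 20L, merge_tol = 5L) {
  L <- genome$length
  keep <- aln$mapq >= min_mapq
  aln <- aln[keep, , drop = FALSE]
  empty <- data.frame(exit = integer(), reentry = integer(), support = integer())
  if (nrow(aln) == 0L) return(junction_table(empty))
  blocks <- alignment_blocks(aln)
  recs <- record_summaries(aln, blocks)

  exits <- integer(0)
  reentries <- integer(0)
  circ_gap <- function(a, b) (b - a - 1L) %% L

  # (i) within-record gaps
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (nrow(b) < 2L) next
    for (j in 2L:nrow(b)) {
      if (b$gap_before[j] < min_gap) next
      lft <- b$ref_end[j - 1L] - b$ref_start[j - 1L] + 1L
      rgt <- b$ref_end[j] - b$ref_start[j] + 1L
      if (lft < min_segment || rgt < min_segment) next
      a <- wrap_position(b$ref_end[j - 1L], L)
      r <- wrap_position(b$ref_start[j], L)
      if (circ_gap(a, r) >= min_gap) {
        exits <- c(exits, a)
        reentries <- c(reentries, r)
      }
    }
  }

  # (ii) split segments: consecutive records of one read, same strand,
  # ordered by read offset
  ord <- order(recs$read_id, recs$strand, recs$first_read)
  recs <- recs[ord, , drop = FALSE]
  same <- which(recs$read_id[-1L] == recs$read_id[-nrow(recs)] &
                recs$strand[-1L] == recs$strand[-nrow(recs)])
  for (i in same) {
    if (recs$aligned_len[i] < min_segment ||
        recs$aligned_len[i + 1L] < min_segment) next
    a <- wrap_position(recs$ref_end[i], L)
    r <- wrap_position(recs$ref_start[i + 1L], L)
    if (circ_gap(a, r) >= min_gap) {
      exits <- c(exits, a)
      reentries <- c(reentries, r)
    }
  }

  if (length(exits) == 0L) return(junction_table(empty))

  # left-align each observation under flanking microhomology
  for (i in seq_along(exits)) {
    la <- left_align_junction(exits[i], reentries[i], genome)
    exits[i] <- la[1L]
    reentries[i] <- la[2L]
  }

  tab <- stats::aggregate(list(support = rep(1L, length(exits))),
                          by = list(exit = exits, reentry = reentries), sum)
  tab <- merge_junctions(tab, L, merge_tol)
  junction_table(tab)
}

junction_table <- function(df) {
  df <- df[order(-df$support, df$exit, df$reentry), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("junction_table", "data.frame"))
}

# Shift (exit, reentry) as far 5' as flanking identity allows; capped at
# L - 1 shifts so a fully periodic genome cannot loop forever.
left_align_junction <- function(exit, reentry, genome) {
  L <- genome$length
  ch <- genome$chars
  shifts <- 0L
  while (shifts < L - 1L &&
         ch[exit] == ch[wrap_position(reentry - 1L, L)]) {
    exit <- wrap_position(exit - 1L, L)
    reentry <- wrap_position(reentry - 1L, L)
    shifts <- shifts + 1L
  }
  c(exit, reentry)
}

# Single-linkage merge of junction observations within tol (circular
# Chebyshev metric on the (exit, reentry) pair).
merge_junctions <- function(tab, L, tol) {
  k <- nrow(tab)
  if (k <= 1L || tol <= 0L) return(tab)
  cdist <- function(x, y) pmin((x - y) %% L, (y - x) %% L)
  # union-find
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- max(cdist(tab$exit[i], tab$exit[j]),
               cdist(tab$reentry[i], tab$reentry[j]))
      if (d <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(k), find, 1L)
  out <- lapply(split(seq_len(k), root), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    best <- sub[order(-sub$support, sub$exit, sub$reentry), ][1L, ]
    data.frame(exit = best$exit, reentry = best$reentry,
               support = sum(sub$support))
  })
  do.call(rbind, out)
}

#' Classify junctions as deletions or duplications
#'
#' The rule: build the putative recombinant molecule retained by the
#' junction - the arc running (increasing coordinates, wrapping) from the
#' reentry position to the exit position. If that arc is missing the
#' heavy-strand replication origin O_H (i.e. contains no O_H base), the
#' molecule could not replicate as a circle on its own and the junction
#' is flagged as a duplication of the arc; if the arc retains any O_H
#' base it is called a deletion, the deleted segment being the
#' complementary arc. The call size is the arc length `reentry -> exit`.
#'
#' Degenerate junctions (`exit == reentry`) are dropped with a warning.
#'
#' @param junctions A `junction_table` (or data.frame with `exit`,
#'   `reentry`, `support`).
#' @param genome The [circular_genome()].
#' @param annotations An [annotation_set()] that includes a region
#'   labelled `oh_label`, used both for the classification rule and for
#'   naming the regions the breakpoints fall in.
#' @param oh_label Label of the O_H region (default `"O_H"`).
#' @return `data.frame` of class `call_table`: `exit, reentry, class,
#'   size, support, start_label, end_label` (the duplicated/retained
#'   arc's start, i.e. reentry, is the paper-style "start" breakpoint).
#' @export
classify_calls <- function(junctions, genome, annotations, oh_label = "O_H") {
  L <- genome$length
  oh <- annotations[annotations$label == oh_label, , drop = FALSE]
  if (nrow(oh) != 1L) stop("annotations must contain exactly one '", oh_label, "' region")
  deg <- junctions$exit == junctions$reentry
  if (any(deg)) {
    warning(sum(deg), " degenerate junction(s) with exit == reentry suppressed")
    junctions <- junctions[!deg, , drop = FALSE]
  }
  n <- nrow(junctions)
  cls <- character(n)
  for (i in seq_len(n)) {
    has_oh <- arcs_intersect(junctions$reentry[i], junctions$exit[i],
                             oh$start, oh$end, L)
    cls[i] <- if (has_oh) "deletion" else "duplication"
  }
  out <- data.frame(
    exit = junctions$exit, reentry = junctions$reentry, class = cls,
    size = if (n) arc_length(junctions$reentry, junctions$exit, L) else integer(),
    support = junctions$support,
    start_label = vapply(junctions$reentry, function(p) feature_at(annotations, p),
                         character(1L)),
    end_label = vapply(junctions$exit, function(p) feature_at(annotations, p),
                       character(1L)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("call_table", "data.frame"), genome_length = L)
}

#' Heteroplasmy of a junction
#'
#' Fraction of molecules carrying the rearrangement: junction-supporting
#' reads over (supporting + reads spanning the exit position without the
#' junction).
#'
#' @param support Junction-supporting read count (`>= 1`).
#' @param spanning_depth Reads whose gapless aligned block covers the
#'   exit position and the next reference base (`>= 0`).
#' @return Fraction in `[0, 1]`.
#' @export
heteroplasmy <- function(support, spanning_depth) {
  stopifnot(spanning_depth >= 0)
  if (support == 0) stop("no supporting reads: heteroplasmy undefined")
  support / (support + spanning_depth)
}

#' Spanning depth at a position
#'
#' Number of alignment records with a gapless aligned block covering the
#' reference-contiguous alternative to a junction at `pos`: at least
#' `min_flank` bases on each side of the `pos`/`pos + 1` adjacency.
#' Matching `min_flank` to the extractor's `min_segment` keeps the
#' junction and spanning read acceptance windows the same width, so the
#' heteroplasmy ratio is not biased against the junction allele. Reads
#' crossing the circular origin are split by convention, so a junction
#' at exactly `pos == L` sees spanning depth 0 from this counter.
#'
#' @param aln An [mt_alignments()] table.
#' @param pos Reference position(s) (the junction exit).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param min_flank Required bases on each side of the adjacency
#'   (default 20, the extractor's `min_segment` default).
#' @return Integer count, vectorised over `pos`.
#' @export
spanning_depth <- function(aln, pos, min_mapq = 20L, min_flank = 20L) {
  b <- block_ranges(aln, min_mapq)
  vapply(pos, function(p) {
    sum(b$ref_start <= p - min_flank + 1L & b$ref_end >= p + min_flank)
  }, 1L)
}

# all gapless aligned blocks of a record set as one two-column table
block_ranges <- function(aln, min_mapq) {
  aln <- aln[aln$mapq >= min_mapq, , drop = FALSE]
  blocks <- alignment_blocks(aln)
  data.frame(ref_start = unlist(lapply(blocks, `[[`, "ref_start")),
             ref_end = unlist(lapply(blocks, `[[`, "ref_end")))
}

#' Annotate a call table with heteroplasmy
#'
#' @param calls A `call_table`.
#' @param aln The [mt_alignments()] the calls came from.
#' @param min_mapq Minimum mapping quality for the spanning counter.
#' @param min_flank Spanning-read flank requirement; keep equal to the
#'   extractor's `min_segment` for an unbiased ratio.
#' @return The call table with a `heteroplasmy` column appended.
#' @export
add_heteroplasmy <- function(calls, aln, min_mapq = 20L, min_flank = 20L) {
  span <- spanning_depth(aln, calls$exit, min_mapq, min_flank)
  calls$heteroplasmy <- vapply(seq_len(nrow(calls)), function(i) {
    heteroplasmy(calls$support[i], span[i])
  }, numeric(1L))
  calls
}

#' Cluster breakpoint positions into hotspots
#'
#' Single-linkage clustering of exit (or reentry) positions at circular
#' distance `<= tol`; each cluster is labelled with the annotation region
#' containing its modal (highest-support; ties: smallest) position.
#'
#' @param calls A `call_table` (non-empty).
#' @param annotations An [annotation_set()].
#' @param tol Linkage distance in bases (default 10).
#' @param side `"exit"` or `"reentry"`.
#' @return `data.frame`: `modal_position, count, n_sites, feature_label`,
#'   plus a list column `positions`; sorted by decreasing count.
#' @export
cluster_hotspots <- function(calls, annotations, tol = 10L,
                             side = c("exit", "reentry")) {
  side <- match.arg(side)
  if (nrow(calls) == 0L) stop("no calls to cluster")
  L <- attr(calls, "genome_length")
  if (is.null(L)) L <- attr(annotations, "genome_length")
  pos <- calls[[side]]
  sup <- calls$support
  agg <- stats::aggregate(list(support = sup), by = list(pos = pos), sum)
  agg <- agg[order(agg$pos), , drop = FALSE]
  k <- nrow(agg)
  # breaks where the gap to the previous site exceeds tol (linear scan),
  # then mend the circular seam between the last and first cluster
  cl <- cumsum(c(1L, diff(agg$pos) > tol))
  if (k > 1L && max(cl) > 1L && (agg$pos[1L] + L - agg$pos[k]) <= tol) {
    cl[cl == max(cl)] <- 1L
  }
  out <- lapply(split(seq_len(k), cl), function(idx) {
    sub <- agg[idx, , drop = FALSE]
    modal <- sub$pos[order(-sub$support, sub$pos)][1L]
    data.frame(modal_position = modal, count = sum(sub$support),
               n_sites = nrow(sub),
               feature_label = feature_at(annotations, modal),
               positions = I(list(sub$pos)))
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$count, out$modal_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Size/position table for duplication-size analysis
#'
#' One row per call with the columns needed for size histograms and the
#' size-versus-breakpoint-position scatter (size grows linearly with the
#' exit position in a fixed-reentry duplication family).
#'
#' @param calls A `call_table`.
#' @return `data.frame`: `exit, reentry, size, class, support`.
#' @export
size_position_table <- function(calls) {
  out <- as.data.frame(calls)[, intersect(c("exit", "reentry", "size",
                                            "class", "support"),
                                          names(calls)), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a call table to TSV
#' @param calls A `call_table`.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Affected arcs as BED
#'
#' Writes one BED line per call covering the retained/duplicated arc
#' (reentry to exit); arcs wrapping the origin use the `end = end + L`
#' convention of [write_annotations_bed()].
#'
#' @param calls A `call_table`.
#' @param genome The [circular_genome()].
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, genome, path) {
  L <- genome$length
  end <- ifelse(calls$exit < calls$reentry, calls$exit + L, calls$exit)
  out <- data.frame(chrom = genome$name, start0 = calls$reentry - 1L,
                    end = end,
                    name = paste0(calls$class, "_", seq_len(nrow(calls))),
                    score = calls$support, strand = ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Full breakpoint-calling pipeline
#'
#' Convenience wrapper: [extract_junctions()] then [classify_calls()],
#' [add_heteroplasmy()] and [annotate_microhomology()].
#'
#' @param aln An [mt_alignments()] table.
#' @param genome The [circular_genome()].
#' @param annotations An [annotation_set()] containing an O_H region.
#' @param ... Passed to [extract_junctions()].
#' @param flank_len Microhomology flank half-width.
#' @return A `call_table` with `heteroplasmy` and `microhomology_len`.
#' @export
call_structural_alterations <- function(aln, genome, annotations, ...,
                                        flank_len = 20L) {
  j <- extract_junctions(aln, genome, ...)
  if (nrow(j) == 0L) {
    return(structure(data.frame(exit = integer(), reentry = integer(),
                                class = character(), size = integer(),
                                support = integer(),
                                start_label = character(),
                                end_label = character(),
                                heteroplasmy = numeric(),
                                microhomology_len = integer()),
                     class = c("call_table", "data.frame"),
                     genome_length = genome$length))
  }
  calls <- classify_calls(j, genome, annotations)
  calls <- add_heteroplasmy(calls, aln)
  annotate_microhomology(calls, genome, flank_len = flank_len)
}
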