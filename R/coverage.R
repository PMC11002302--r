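#' Per-base depth profile on the circular reference
#'
#' Counts, for every reference position, the aligned blocks covering it
#' (CIGAR `M` runs only, so split reads contribute each aligned segment
#' once and reference gaps contribute nothing). Reads crossing the
#' origin arrive as split records and are counted on both arcs.
#'
#' @param aln An [mt_alignments()] table.
#' @param genome The [circular_genome()].
#' @return Object of class `depth_profile`: `depth` (integer vector over
#'   `[1, L]`), `total_reads`, `mean_depth`.
#' @export
depth_profile <- function(aln, genome) {
  L <- genome$length
  depth <- integer(L)
  if (nrow(aln) == 0L) {
    warning("no alignments: all-zero depth profile")
  } else {
    blocks <- alignment_blocks(aln)
    for (b in blocks) {
      for (i in seq_len(nrow(b))) {
        idx <- wrap_position(seq.int(b$ref_start[i], b$ref_end[i]), L)
        depth[idx] <- depth[idx] + 1L
      }
    }
  }
  structure(list(depth = depth, total_reads = length(unique(aln$read_id)),
                 mean_depth = mean(depth)),
            class = "depth_profile")
}

#' Coverage as a function of distance downstream of O_H
#'
#' Bins per-base depth by circular distance downstream of the
#' heavy-strand origin and normalises to the first bin, the framing in
#' which replication-linked fragment gradients appear as a decline away
#' from O_H. A Kendall-type trend score (mean pairwise sign of
#' later-minus-earlier bin differences, in `[-1, 1]`) is attached as
#' attribute `trend`.
#'
#' @param profile A [depth_profile()].
#' @param oh_pos Reference position of O_H (e.g. the region midpoint).
#' @param bin Bin width in bases (default 100).
#' @param direction `+1` to walk downstream in increasing coordinates
#'   (the package's heavy-strand convention), `-1` for the reverse.
#' @return `data.frame`: `distance` (bin start, bases downstream of
#'   `oh_pos`), `mean_depth`, `norm_depth`; attribute `trend`.
#' @export
coverage_vs_oh <- function(profile, oh_pos, bin = 100L, direction = 1L) {
  stopifnot(bin >= 1L, direction %in% c(-1L, 1L))
  depth <- profile$depth
  L <- length(depth)
  check_pos(oh_pos, L)
  d <- seq.int(0L, L - 1L)
  pos <- wrap_position(oh_pos + direction * d, L)
  bin_id <- d %/% bin
  mean_depth <- as.numeric(tapply(depth[pos], bin_id, mean))
  if (mean_depth[1L] == 0) stop("zero depth in the first bin: cannot normalise")
  out <- data.frame(distance = unique(bin_id) * bin,
                    mean_depth = mean_depth,
                    norm_depth = mean_depth / mean_depth[1L])
  m <- nrow(out)
  trend <- 0
  if (m > 1L) {
    s <- 0L
    for (i in seq_len(m - 1L)) {
      s <- s + sum(sign(out$norm_depth[(i + 1L):m] - out$norm_depth[i]))
    }
    trend <- s / choose(m, 2L)
  }
  attr(out, "trend") <- trend
  out
}

#' Fit an exponential decay length to a coverage gradient
#'
#' Log-linear regression of binned mean depth on distance, returning the
#' decay length `tau` (bases) of `depth ~ exp(-distance / tau)`. Because
#' coverage is the fragment-extent convolution of the fragment-midpoint
#' law, the exponential rate is only clean away from the origin-proximal
#' boundary and the circular wrap-around tail; restrict the fit window
#' accordingly (defaults trim nothing).
#'
#' @param gradient A [coverage_vs_oh()] table.
#' @param d_min,d_max Distance window for the fit.
#' @return List: `tau` (bases), `fit` (the `lm` object).
#' @export
fit_decay_tau <- function(gradient, d_min = 0, d_max = Inf) {
  sub <- gradient[gradient$distance >= d_min & gradient$distance <= d_max &
                    gradient$mean_depth > 0, , drop = FALSE]
  if (nrow(sub) < 3L) stop("too few informative bins for a decay fit")
  fit <- stats::lm(log(mean_depth) ~ distance, data = sub)
  slope <- stats::coef(fit)[["distance"]]
  if (slope >= 0) warning("non-decaying profile: tau is negative or infinite")
  list(tau = -1 / slope, fit = fit)
}

#' Per-site SNV fractions from a simple pileup
#'
#' For every reference position, the fraction of covering read bases
#' that differ from the reference (substitutions only; a pileup mismatch
#' fraction, not haplotype calling). Positions below `min_depth` are
#' flagged absent (`NA`).
#'
#' @param aln An [mt_alignments()] table with base calls in `seq`.
#' @param genome The [circular_genome()].
#' @param min_depth Minimum depth for a defined fraction (default 10).
#' @return `data.frame` of class `snv_profile`: `pos, depth,
#'   snv_fraction`.
#' @export
snv_fractions <- function(aln, genome, min_depth = 10L) {
  L <- genome$length
  ref <- charToRaw(genome$sequence)
  depth <- integer(L)
  mism <- integer(L)
  if (nrow(aln) > 0L) {
    blocks <- alignment_blocks(aln)
    for (r in seq_len(nrow(aln))) {
      b <- blocks[[r]]
      if (nrow(b) == 0L) next
      rd <- charToRaw(aln$seq[r])
      for (i in seq_len(nrow(b))) {
        rpos <- wrap_position(seq.int(b$ref_start[i], b$ref_end[i]), L)
        qpos <- seq.int(b$read_start[i], b$read_end[i])
        depth[rpos] <- depth[rpos] + 1L
        ne <- rpos[rd[qpos] != ref[rpos]]
        if (length(ne)) mism[ne] <- mism[ne] + 1L
      }
    }
  }
  frac <- ifelse(depth >= min_depth, mism / pmax(depth, 1L), NA_real_)
  structure(data.frame(pos = seq_len(L), depth = depth, snv_fraction = frac),
            class = c("snv_profile", "data.frame"))
}
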