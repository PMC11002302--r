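#' Circular genome with 1-based wrapped coordinates
#'
#' Container for a circular reference sequence (mtDNA-like). All coordinates
#' in the package are 1-based inclusive; position `L + 1` is position 1.
#'
#' @param sequence Character scalar over `{A,C,G,T,N}` (case-insensitive).
#' @param name Sequence name used in SAM/BED output.
#' @return An object of class `circular_genome` with elements `name`,
#'   `sequence`, `length`, and `chars` (cached per-base character vector).
#' @export
circular_genome <- function(sequence, name = "chrM") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("invalid genome: empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("invalid genome: disallowed residues ", paste(unique(chars[bad]), collapse = ","))
  }
  structure(
    list(name = name, sequence = sequence, length = L, chars = chars),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, GC %.3f\n", x$name, x$length,
              mean(x$chars %in% c("G", "C"))))
  invisible(x)
}

#' Read a circular reference genome from FASTA
#'
#' The file must contain exactly one record; multi-record input is an error
#' (the pipeline models a single circular molecule).
#'
#' @param path Path to a FASTA file.
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop("expected a single-record FASTA, found ", length(ss), " records")
  }
  nm <- sub("\\s.*$", "", names(ss)[1L])
  circular_genome(as.character(ss[[1L]]), name = nm)
}

#' Write a circular genome to FASTA
#' @param g A [circular_genome()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(g, path) {
  ss <- Biostrings::DNAStringSet(g$sequence)
  names(ss) <- g$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Generate a random circular genome
#'
#' Seeded uniform-composition stand-in for a real mitochondrial reference;
#' used by the synthetic-data module and tests.
#'
#' @param length Genome length in bases (default the mouse mtDNA length).
#' @param seed Integer seed.
#' @param gc Target GC fraction.
#' @param name Sequence name.
#' @return A [circular_genome()].
#' @export
random_genome <- function(length = 16299L, seed = 1L, gc = 0.4, name = "chrM_synthetic") {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  circular_genome(paste(sample(names(p), length, replace = TRUE, prob = p),
                        collapse = ""), name = name)
}

#' Wrap a position onto the circle
#'
#' @param p Integer position(s), any value.
#' @param L Genome length (bases), `>= 1`.
#' @return `((p - 1) mod L) + 1`, always in `[1, L]`. Vectorised over `p`.
#' @export
wrap_position <- function(p, L) {
  if (length(L) != 1L || is.na(L) || L < 1) stop("invalid genome length")
  ((as.integer(p) - 1L) %% as.integer(L)) + 1L
}

#' Arc length on the circle
#'
#' Number of bases on the increasing-coordinate arc from `a` to `b`
#' inclusive, wrapping through the origin when `b < a`.
#'
#' @param a,b Positions in `[1, L]`.
#' @param L Genome length.
#' @return `((b - a) mod L) + 1`. Vectorised.
#' @export
arc_length <- function(a, b, L) {
  check_pos(c(a, b), L)
  ((as.integer(b) - as.integer(a)) %% as.integer(L)) + 1L
}

check_pos <- function(p, L) {
  if (any(is.na(p)) || any(p < 1) || any(p > L)) {
    stop("position out of bounds [1, ", L, "]")
  }
  invisible(TRUE)
}

#' Construct a genomic region (possibly wrapping the origin)
#'
#' `end < start` denotes a region that wraps through the origin, e.g. a
#' control region spanning the sequence start.
#'
#' @param label Region name (unique within an annotation set).
#' @param start,end 1-based inclusive bounds.
#' @param strand One of `"+", "-", "."`.
#' @return A one-row `data.frame` with columns `label,start,end,strand`.
#' @export
region <- function(label, start, end, strand = ".") {
  stopifnot(strand %in% c("+", "-", "."))
  data.frame(label = as.character(label), start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Test whether positions lie on a region's arc
#'
#' Membership on the increasing-coordinate arc `start -> end`; wrapped
#' regions (`end < start`) are handled.
#'
#' @param r A region (one-row data.frame or list with `start`, `end`).
#' @param p Position(s) in `[1, L]`.
#' @param L Genome length.
#' @return Logical vector along `p`.
#' @export
region_contains <- function(r, p, L) {
  check_pos(p, L)
  check_pos(c(r$start, r$end), L)
  if (r$start <= r$end) p >= r$start & p <= r$end else p >= r$start | p <= r$end
}

#' Arc length of a region
#' @inheritParams region_contains
#' @return Bases on the arc `start -> end` inclusive.
#' @export
region_length <- function(r, L) arc_length(r$start, r$end, L)

# TRUE iff the arc [rs..re] lies entirely on the arc [as..ae] (both wrapped).
arc_contains_arc <- function(as, ae, rs, re, L) {
  alen <- arc_length(as, ae, L)
  off <- (as.integer(rs) - as.integer(as)) %% as.integer(L)
  rlen <- arc_length(rs, re, L)
  off + rlen <= alen
}

# TRUE iff arcs [as..ae] and [bs..be] share at least one base.
arcs_intersect <- function(as, ae, bs, be, L) {
  a <- list(start = as, end = ae)
  b <- list(start = bs, end = be)
  region_contains(a, bs, L) || region_contains(b, as, L)
}

#' Build an annotation set
#'
#' @param regions A `data.frame` with columns `label,start,end,strand`
#'   (rows as produced by [region()]).
#' @param genome The [circular_genome()] the coordinates refer to.
#' @return Object of class `annotation_set`: the region table with the
#'   genome length attached.
#' @export
annotation_set <- function(regions, genome) {
  stopifnot(all(c("label", "start", "end", "strand") %in% names(regions)))
  if (anyDuplicated(regions$label)) stop("region labels must be unique")
  check_pos(c(regions$start, regions$end), genome$length)
  structure(regions, class = c("annotation_set", "data.frame"),
            genome_length = genome$length, genome_name = genome$name)
}

#' Look up the annotation region containing a position
#'
#' @param ann An [annotation_set()].
#' @param p A single position.
#' @return The label of the first (smallest-arc) region containing `p`,
#'   or `"other"`. Overlapping annotations are resolved in favour of the
#'   shortest region so nested features (e.g. CSBs inside the D-loop) win.
#' @export
feature_at <- function(ann, p) {
  L <- attr(ann, "genome_length")
  hit <- vapply(seq_len(nrow(ann)), function(i) {
    region_contains(ann[i, ], p, L)
  }, logical(1L))
  if (!any(hit)) return("other")
  cand <- ann[hit, , drop = FALSE]
  cand$label[which.min(arc_length(cand$start, cand$end, L))]
}

#' Read annotations from BED
#'
#' Standard 6-column BED (0-based half-open on disk, converted to 1-based
#' inclusive on load). A region wrapping the circular origin cannot be
#' expressed in legal BED, so the convention here is: an on-disk `end`
#' beyond the genome length wraps (`end > L` means the region runs through
#' the origin and re-enters at the start).
#'
#' @param path BED file path.
#' @param genome The [circular_genome()] the file annotates.
#' @return An [annotation_set()].
#' @export
read_annotations_bed <- function(path, genome) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start0", "end", "label",
                                         "score", "strand")[1:6])
  L <- genome$length
  start1 <- raw$start0 + 1L
  end1 <- raw$end
  wrapped <- end1 > L
  end1[wrapped] <- end1[wrapped] - L
  regions <- data.frame(label = raw$label, start = as.integer(start1),
                        end = as.integer(end1), strand = raw$strand,
                        stringsAsFactors = FALSE)
  annotation_set(regions, genome)
}

#' Write annotations to BED
#'
#' Inverse of [read_annotations_bed()]; wrapped regions are written with
#' `end = end + L`.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @export
write_annotations_bed <- function(ann, path) {
  L <- attr(ann, "genome_length")
  end <- ifelse(ann$end < ann$start, ann$end + L, ann$end)
  out <- data.frame(chrom = attr(ann, "genome_name"), start0 = ann$start - 1L,
                    end = end, label = ann$label, score = 0L,
                    strand = ann$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default mouse-mtDNA-like feature annotations
#'
#' Editable default coordinates for the features used in hotspot reporting
#' (D-loop, TAS, ISR, CSB1-3, O_H, O_L, trnP, and the four gene targets).
#' The control-region sub-feature boundaries are configuration values, not
#' constants: primary literature does not pin exact O_H/ISR/CSB bounds, so
#' these defaults are chosen for internal consistency (O_H within the
#' CSB2-3 region) and should be overridden when a curated annotation is
#' available. Shipped as plain BED in `inst/extdata/`.
#'
#' @param genome A [circular_genome()] of length 16,299 (default: the
#'   packaged seeded synthetic stand-in reference).
#' @return An [annotation_set()].
#' @export
mouse_mtdna_features <- function(genome = mouse_mtdna_genome()) {
  path <- system.file("extdata", "mouse_mtdna_features.bed",
                      package = "mitofrag", mustWork = TRUE)
  read_annotations_bed(path, genome)
}

#' Packaged synthetic stand-in for the mouse mitochondrial reference
#'
#' A seeded random 16,299 bp circular sequence at mouse-mtDNA-like GC
#' content. It is synthetic: coordinates match the packaged feature table,
#' but the residues are not NC_005089.1.
#'
#' @return A [circular_genome()] named `chrM_synthetic`.
#' @export
mouse_mtdna_genome <- function() {
  random_genome(length = 16299L, seed = 16299L, gc = 0.38,
                name = "chrM_synthetic")
}

#' Windowed GC content on the circle
#'
#' Sliding-window GC fraction; windows wrap across the origin. `N` counts
#' as non-GC and stays in the denominator, so fractions are deterministic
#' on ambiguous bases.
#'
#' @param g A [circular_genome()].
#' @param window Window size in bases (`1 <= window <= L`).
#' @param step Step between window starts (`>= 1`); the number of windows
#'   is `ceiling(L / step)`.
#' @return `data.frame` with columns `start` (window start position) and
#'   `gc` (fraction in `[0, 1]`).
#' @export
gc_windows <- function(g, window, step = window) {
  L <- g$length
  if (window > L) stop("window larger than genome")
  stopifnot(window >= 1L, step >= 1L)
  is_gc <- as.integer(g$chars %in% c("G", "C"))
  ext <- c(is_gc, is_gc[seq_len(min(window, L))])
  cs <- c(0L, cumsum(ext))
  starts <- seq.int(1L, L, by = step)
  gc <- (cs[starts + window] - cs[starts]) / window
  data.frame(start = starts, gc = gc)
}
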