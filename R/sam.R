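#' Alignment tables
#'
#' The package exchanges alignments as a plain `data.frame` of class
#' `mt_alignments` with one row per SAM record and columns
#' `read_id, flag, pos, mapq, cigar, seq` plus attributes `genome_name`
#' and `genome_length`. Split reads appear as several records sharing a
#' `read_id` (supplementary segments carry flag bit 2048); the aligned
#' part of each record is marked by `M` runs in the CIGAR, with soft
#' clips covering the rest of the read.
#'
#' @param records `data.frame` with the columns above.
#' @param genome The [circular_genome()] the records are mapped to.
#' @return An `mt_alignments` object.
#' @export
mt_alignments <- function(records, genome) {
  need <- c("read_id", "flag", "pos", "mapq", "cigar", "seq")
  stopifnot(all(need %in% names(records)))
  structure(as.data.frame(records)[need],
            class = c("mt_alignments", "data.frame"),
            genome_name = genome$name, genome_length = genome$length)
}

#' Read alignments from a SAM file
#'
#' Minimal plain-text SAM reader (header skipped, unmapped records
#' dropped). Records mapped to a reference other than `genome$name` are
#' an input error: the pipeline assumes mtDNA-only alignments.
#'
#' @param path SAM file path.
#' @param genome The [circular_genome()] the file was aligned to.
#' @return An [mt_alignments()] table.
#' @export
read_sam <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(mt_alignments(data.frame(read_id = character(), flag = integer(),
                                    pos = integer(), mapq = integer(),
                                    cigar = character(), seq = character(),
                                    stringsAsFactors = FALSE), genome))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1L), i)
  flag <- as.integer(get(2L))
  rname <- get(3L)
  mapped <- bitwAnd(flag, 4L) == 0L
  if (any(mapped & rname != genome$name)) {
    stop("alignments mapped to reference '",
         unique(rname[mapped & rname != genome$name])[1L],
         "' but genome is '", genome$name, "'")
  }
  rec <- data.frame(read_id = get(1L), flag = flag,
                    pos = as.integer(get(4L)), mapq = as.integer(get(5L)),
                    cigar = get(6L), seq = get(10L),
                    stringsAsFactors = FALSE)
  mt_alignments(rec[mapped, , drop = FALSE], genome)
}

#' Write alignments to a SAM file
#' @param aln An [mt_alignments()] table.
#' @param path Output path.
#' @export
write_sam <- function(aln, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", attr(aln, "genome_name"),
                   attr(aln, "genome_length")))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  aln$read_id, aln$flag, attr(aln, "genome_name"),
                  aln$pos, aln$mapq, aln$cigar, aln$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Parse one CIGAR string into aligned blocks.
# Returns a data.frame with one row per M/=/X run: ref_start, ref_end,
# read_start, read_end, and gap_before (reference bases skipped by D/N
# immediately before the block; 0 for the first block and after I runs).
cigar_blocks <- function(pos, cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  ops <- regmatches(cigar, list(m))[[1L]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  ref <- pos
  rd <- 1L
  gap <- 0L
  out <- vector("list", length(op))
  k <- 0L
  for (i in seq_along(op)) {
    len <- n[i]
    if (op[i] %in% c("M", "=", "X")) {
      k <- k + 1L
      out[[k]] <- c(ref, ref + len - 1L, rd, rd + len - 1L, gap)
      ref <- ref + len
      rd <- rd + len
      gap <- 0L
    } else if (op[i] %in% c("D", "N")) {
      ref <- ref + len
      gap <- gap + len
    } else if (op[i] %in% c("I", "S")) {
      rd <- rd + len
    } # H, P consume nothing we track
  }
  if (k == 0L) {
    return(data.frame(ref_start = integer(), ref_end = integer(),
                      read_start = integer(), read_end = integer(),
                      gap_before = integer()))
  }
  b <- do.call(rbind, out[seq_len(k)])
  data.frame(ref_start = b[, 1L], ref_end = b[, 2L], read_start = b[, 3L],
             read_end = b[, 4L], gap_before = b[, 5L])
}

# Aligned blocks for every record: list parallel to rows of aln.
alignment_blocks <- function(aln) {
  Map(cigar_blocks, aln$pos, aln$cigar)
}

# Per-record summary used by the junction extractor.
# strand from flag bit 16; aligned_len = total M bases.
record_summaries <- function(aln, blocks) {
  data.frame(
    read_id = aln$read_id,
    strand = ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+"),
    mapq = aln$mapq,
    first_read = vapply(blocks, function(b) if (nrow(b)) b$read_start[1L] else NA_integer_, 1L),
    ref_start = vapply(blocks, function(b) if (nrow(b)) b$ref_start[1L] else NA_integer_, 1L),
    ref_end = vapply(blocks, function(b) if (nrow(b)) b$ref_end[nrow(b)] else NA_integer_, 1L),
    aligned_len = vapply(blocks, function(b) sum(b$ref_end - b$ref_start + 1L), 1L),
    stringsAsFactors = FALSE
  )
}
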