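#' Sequence flanks around a junction
#'
#' Extracts, with circular wrapping, a window of `2 * flank_len` bases
#' centred on each side of the junction: positions
#' `exit - flank_len + 1 .. exit + flank_len` and likewise for the
#' reentry position.
#'
#' @param genome A [circular_genome()].
#' @param exit,reentry Junction coordinates.
#' @param flank_len Bases per side (`2 * flank_len <= L`).
#' @return List of class `flank_pair`: `exit_flank`, `reentry_flank`
#'   (character strings), `flank_len`.
#' @export
junction_flanks <- function(genome, exit, reentry, flank_len = 20L) {
  L <- genome$length
  if (flank_len < 1L || 2L * flank_len > L) {
    stop("flank_len must satisfy 1 <= 2*flank_len <= genome length")
  }
  check_pos(c(exit, reentry), L)
  slice <- function(centre) {
    idx <- wrap_position(seq.int(centre - flank_len + 1L, centre + flank_len), L)
    paste(genome$chars[idx], collapse = "")
  }
  structure(list(exit_flank = slice(exit), reentry_flank = slice(reentry),
                 flank_len = flank_len),
            class = "flank_pair")
}

#' Longest (im)perfect direct repeat shared by two flanks
#'
#' Scans all same-orientation, equal-length, gapless substring pairs (one
#' from each flank) and reports the longest with at most the allowed
#' number of substitution mismatches; ties break by fewer mismatches,
#' then smallest exit offset, then smallest reentry offset.
#'
#' "Imperfect" means substitutions only, no indels. By default the
#' mismatch allowance grows with repeat length: 1 mismatch per 8 bases,
#' rounded down (so repeats under 8 bp must be perfect). Pass a number to
#' fix the allowance instead.
#'
#' @param pair A [junction_flanks()] result, or any list with
#'   `exit_flank` and `reentry_flank` strings.
#' @param max_mismatches `NULL` for the per-8-bases rule, or a fixed
#'   non-negative integer.
#' @param min_len Minimum reportable repeat length (default 2, the lower
#'   end of the junction-microhomology range seen in rearranged mtDNA).
#' @return `NULL` if no qualifying repeat, else a list of class
#'   `repeat_hit`: `length, mismatches, offset_exit, offset_reentry,
#'   perfect`.
#' @export
longest_direct_repeat <- function(pair, max_mismatches = NULL, min_len = 2L) {
  stopifnot(min_len >= 1L)
  x <- strsplit(pair$exit_flank, "", fixed = TRUE)[[1L]]
  y <- strsplit(pair$reentry_flank, "", fixed = TRUE)[[1L]]
  allowed <- if (is.null(max_mismatches)) {
    function(len) len %/% 8L
  } else {
    stopifnot(max_mismatches >= 0L)
    function(len) max_mismatches
  }
  n1 <- length(x)
  n2 <- length(y)
  best <- NULL
  better <- function(len, mm, i, j) {
    if (is.null(best)) return(TRUE)
    if (len != best$length) return(len > best$length)
    if (mm != best$mismatches) return(mm < best$mismatches)
    if (i != best$offset_exit) return(i < best$offset_exit)
    j < best$offset_reentry
  }
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      kmax <- min(n1 - i, n2 - j) + 1L
      if (kmax < min_len) next
      mm <- cumsum(x[i:(i + kmax - 1L)] != y[j:(j + kmax - 1L)])
      for (len in kmax:min_len) {
        if (mm[len] <= allowed(len)) {
          if (better(len, mm[len], i, j)) {
            best <- list(length = len, mismatches = mm[[len]],
                         offset_exit = i, offset_reentry = j,
                         perfect = mm[[len]] == 0L)
          }
          break # shorter lengths at this (i,j) cannot beat this hit
        }
      }
    }
  }
  if (!is.null(best)) class(best) <- "repeat_hit"
  best
}

#' Annotate a call table with microhomology lengths
#'
#' Adds a `microhomology_len` column: the [longest_direct_repeat()]
#' length for each call's junction flanks (0 when no repeat of at least
#' `min_len` is found).
#'
#' @param calls A `call_table`.
#' @param genome The [circular_genome()].
#' @param flank_len Flank half-width (default 20, covering the observed
#'   2-14 bp microhomology range with margin).
#' @param max_mismatches,min_len Passed to [longest_direct_repeat()].
#' @return The call table with `microhomology_len` appended.
#' @export
annotate_microhomology <- function(calls, genome, flank_len = 20L,
                                   max_mismatches = NULL, min_len = 2L) {
  calls$microhomology_len <- vapply(seq_len(nrow(calls)), function(i) {
    pair <- junction_flanks(genome, calls$exit[i], calls$reentry[i], flank_len)
    hit <- longest_direct_repeat(pair, max_mismatches, min_len)
    if (is.null(hit)) 0L else hit$length
  }, integer(1L))
  calls
}
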