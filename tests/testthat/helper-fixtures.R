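# Shared fixtures, all built in code.

# deterministic toy circular genome of length L
toy_genome <- function(L = 100L, seed = 42L, name = "toy") {
  random_genome(length = L, seed = seed, gc = 0.5, name = name)
}

# annotation set with a single O_H region on a toy genome
toy_annotations <- function(genome, oh_start, oh_end, extra = NULL) {
  regs <- rbind(region("O_H", oh_start, oh_end), extra)
  annotation_set(regs, genome)
}

# a molecule_population data.frame built by hand (bypasses sampling)
manual_population <- function(form, junction_exit = NA_integer_,
                              junction_reentry = NA_integer_,
                              frag_start = NA_integer_,
                              frag_end = NA_integer_, L) {
  n <- length(form)
  je <- rep_len(as.integer(junction_exit), n)
  jr <- rep_len(as.integer(junction_reentry), n)
  fs <- rep_len(as.integer(frag_start), n)
  fe <- rep_len(as.integer(frag_end), n)
  mol_len <- integer(n)
  for (i in seq_len(n)) {
    mol_len[i] <- switch(form[i],
      circle = L,
      circle_with_duplication = L + arc_length(jr[i], je[i], L),
      linear_fragment = arc_length(fs[i], fe[i], L),
      seven_s = arc_length(fs[i], fe[i], L))
  }
  structure(data.frame(form = form, junction_exit = je, junction_reentry = jr,
                       frag_start = fs, frag_end = fe, mol_len = mol_len,
                       stringsAsFactors = FALSE),
            class = c("molecule_population", "data.frame"))
}

# brute-force membership of position p on the arc a..b (wrapping)
arc_positions <- function(a, b, L) {
  if (a <= b) a:b else c(a:L, 1:b)
}

# exhaustive longest-direct-repeat scan over all substring pairs
brute_force_repeat <- function(x, y, max_mismatches, min_len) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  best <- NULL
  for (i in seq_along(cx)) for (j in seq_along(cy)) {
    maxlen <- min(length(cx) - i, length(cy) - j) + 1
    if (maxlen < min_len) next
    for (len in min_len:maxlen) {
      mm <- sum(cx[i:(i + len - 1)] != cy[j:(j + len - 1)])
      if (mm > max_mismatches) next
      if (is.null(best) || len > best$length ||
          (len == best$length && (mm < best$mismatches ||
            (mm == best$mismatches && (i < best$offset_exit ||
              (i == best$offset_exit && j < best$offset_reentry)))))) {
        best <- list(length = len, mismatches = mm,
                     offset_exit = i, offset_reentry = j)
      }
    }
  }
  best
}
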