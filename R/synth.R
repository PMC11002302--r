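#' Duplication class for the population generator
#'
#' One generative family of tandem-duplication junctions. The reentry
#' (paper-style "start") breakpoint is drawn from point masses
#' (`reentry_sites`), a grid (`reentry_grid`), or uniformly over a
#' region; the exit ("end") breakpoint either places the duplicated-arc
#' size at `round(rnorm(size_mean, size_sd))` bases or is drawn from
#' `exit_sites` / uniformly over `exit_region`.
#'
#' @param weight Relative abundance (`>= 0`).
#' @param reentry_sites,reentry_grid Integer vectors of positions.
#' @param reentry_region A [region()].
#' @param size_mean,size_sd Duplicated-arc size law (bases).
#' @param exit_sites Integer vector of exit positions.
#' @param exit_region A [region()].
#' @return Object of class `duplication_class`.
#' @export
duplication_class <- function(weight = 1,
                              reentry_sites = NULL, reentry_grid = NULL,
                              reentry_region = NULL,
                              size_mean = NULL, size_sd = 0,
                              exit_sites = NULL, exit_region = NULL) {
  stopifnot(weight >= 0)
  if (is.null(reentry_sites) && is.null(reentry_grid) && is.null(reentry_region)) {
    stop("one of reentry_sites / reentry_grid / reentry_region is required")
  }
  if (is.null(size_mean) && is.null(exit_sites) && is.null(exit_region)) {
    stop("one of size_mean / exit_sites / exit_region is required")
  }
  structure(list(weight = weight, reentry_sites = reentry_sites,
                 reentry_grid = reentry_grid, reentry_region = reentry_region,
                 size_mean = size_mean, size_sd = size_sd,
                 exit_sites = exit_sites, exit_region = exit_region),
            class = "duplication_class")
}

#' Genotype specification for the population generator
#'
#' Encodes, as named parameters, the qualitative mtDNA spectrum of a
#' genotype: the fraction of intact circles, tandem-duplication classes,
#' a linear-fragment abundance gradient decaying with distance
#' downstream of O_H (midpoint weight `exp(-d / tau)`, or a linear ramp
#' behind `gradient_form = "linear"`), a D-loop-only short species
#' standing in for 7S DNA (abundance scaled by `seven_s_excess`), an
#' O_L-to-O_H "major arc" linear fragment, and a per-base SNV load
#' realised as read substitutions.
#'
#' @param label Free-text genotype label.
#' @param intact_fraction Fraction of plain circles, in `[0, 1]`.
#' @param duplication_classes List of [duplication_class()].
#' @param fragment_weight,major_arc_weight Relative abundances among
#'   non-intact molecules.
#' @param fragment_tau Gradient decay length in bases (`> 0`).
#' @param fragment_len_mean,fragment_len_sd Fragment length law (bases).
#' @param seven_s_excess Multiplier on the base 7S-species weight (0.2).
#' @param snv_rate Substitutions per base, in `[0, 0.05]`.
#' @param gradient_form `"exp"` or `"linear"`.
#' @return Object of class `genotype_spec`.
#' @export
genotype_spec <- function(label = "custom", intact_fraction = 0.9,
                          duplication_classes = list(),
                          fragment_weight = 1, fragment_tau = 5000,
                          fragment_len_mean = 2000, fragment_len_sd = 500,
                          major_arc_weight = 0, seven_s_excess = 1,
                          snv_rate = 0, gradient_form = c("exp", "linear")) {
  stopifnot(intact_fraction >= 0, intact_fraction <= 1, fragment_tau > 0,
            snv_rate >= 0, snv_rate <= 0.05,
            fragment_weight >= 0, major_arc_weight >= 0, seven_s_excess >= 0)
  structure(list(label = label, intact_fraction = intact_fraction,
                 duplication_classes = duplication_classes,
                 fragment_weight = fragment_weight,
                 fragment_tau = fragment_tau,
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd,
                 major_arc_weight = major_arc_weight,
                 seven_s_excess = seven_s_excess, snv_rate = snv_rate,
                 gradient_form = match.arg(gradient_form)),
            class = "genotype_spec")
}

#' Built-in genotype presets
#'
#' Illustrative defaults encoding each genotype's qualitative spectrum;
#' the relative weights are generator choices, not literature-asserted
#' constants.
#'
#' * `"wt"` - mostly intact circles, mild fragment gradient, no
#'   duplications, baseline 7S, low SNV load.
#' * `"mgme1"` - 5'-3' exonuclease-null-like: an evenly spaced grid of
#'   ~100 bp duplications along the molecule, control-region-anchored
#'   ~690 bp duplications re-entering at three tRNA-Pro sites, a strong
#'   fragment gradient from O_H, a major-arc linear fragment, strong 7S
#'   excess, low SNV load.
#' * `"polg"` - proofreading-deficient-polymerase-like: duplications
#'   from a single tRNA-Pro site to four discrete ISR exit sites, mild
#'   gradient, modest major-arc and 7S levels, high SNV load.
#'
#' @param preset One of `"wt"`, `"mgme1"`, `"polg"`.
#' @return A [genotype_spec()].
#' @export
genotype_preset <- function(preset = c("wt", "mgme1", "polg")) {
  switch(match.arg(preset),
    wt = genotype_spec(label = "WT-like", intact_fraction = 0.95,
                       fragment_weight = 1, fragment_tau = 8000,
                       seven_s_excess = 1, snv_rate = 5e-4),
    mgme1 = genotype_spec(
      label = "Mgme1-like", intact_fraction = 0.15,
      duplication_classes = list(
        duplication_class(weight = 1, reentry_grid = seq(500L, 16000L, by = 500L),
                          size_mean = 100, size_sd = 10),
        duplication_class(weight = 2, reentry_sites = c(15368L, 15388L, 15403L),
                          size_mean = 690, size_sd = 15)),
      fragment_weight = 6, fragment_tau = 3000, major_arc_weight = 2,
      seven_s_excess = 5, snv_rate = 5e-4),
    polg = genotype_spec(
      label = "Polg-like", intact_fraction = 0.6,
      duplication_classes = list(
        duplication_class(weight = 1, reentry_sites = 15373L,
                          exit_sites = c(15746L, 15763L, 15808L, 15931L))),
      fragment_weight = 0.8, fragment_tau = 8000, major_arc_weight = 0.3,
      seven_s_excess = 2, snv_rate = 2e-3)
  )
}

draw_from <- function(class, field_sites, field_grid, field_region, n, L) {
  if (!is.null(class[[field_sites]])) {
    s <- class[[field_sites]]
    s[sample.int(length(s), n, replace = TRUE)]
  } else if (!is.null(class[[field_grid]])) {
    g <- class[[field_grid]]
    g[sample.int(length(g), n, replace = TRUE)]
  } else {
    r <- class[[field_region]]
    span <- arc_length(r$start, r$end, L)
    wrap_position(r$start + sample.int(span, n, replace = TRUE) - 1L, L)
  }
}

#' Sample a synthetic mtDNA molecule population
#'
#' Draws `n` molecules according to the genotype's class weights:
#' intact circles, tandem-duplication circles (one junction each),
#' gradient linear fragments (midpoint weight decaying with circular
#' distance downstream of O_H), a fixed major-arc fragment (O_L end to
#' O_H start), and a 7S-like D-loop-only species (TAS to just past O_H).
#'
#' @param spec A [genotype_spec()].
#' @param n Number of molecules (`> 0`).
#' @param genome The [circular_genome()].
#' @param annotations An [annotation_set()] with `O_H`, `O_L`, `TAS`
#'   regions.
#' @param seed Integer seed.
#' @return `data.frame` of class `molecule_population`: `form`
#'   (`circle`, `circle_with_duplication`, `linear_fragment`,
#'   `seven_s`), `junction_exit`, `junction_reentry`, `frag_start`,
#'   `frag_end`, `mol_len`; attribute `spec`.
#' @export
sample_population <- function(spec, n, genome, annotations, seed = 1L) {
  stopifnot(n > 0L)
  L <- genome$length
  oh <- annotations[annotations$label == "O_H", ]
  ol <- annotations[annotations$label == "O_L", ]
  tas <- annotations[annotations$label == "TAS", ]
  set.seed(seed)

  dup_w <- vapply(spec$duplication_classes, function(d) d$weight, numeric(1L))
  w <- c(dup_w, fragment = spec$fragment_weight,
         major_arc = spec$major_arc_weight,
         seven_s = 0.2 * spec$seven_s_excess)
  if (spec$intact_fraction < 1 && sum(w) == 0) {
    stop("all non-intact class weights are zero")
  }
  cats <- c(if (length(dup_w)) paste0("dup", seq_along(dup_w)),
            "fragment", "major_arc", "seven_s")
  prob <- c(spec$intact_fraction,
            if (sum(w) > 0) (1 - spec$intact_fraction) * w / sum(w) else rep(0, length(w)))
  draw <- sample(c("circle", cats), n, replace = TRUE, prob = prob)

  form <- character(n)
  je <- jr <- fs <- fe <- rep(NA_integer_, n)
  mol_len <- integer(n)

  is_circle <- draw == "circle"
  form[is_circle] <- "circle"
  mol_len[is_circle] <- L

  for (ci in seq_along(spec$duplication_classes)) {
    idx <- which(draw == paste0("dup", ci))
    if (!length(idx)) next
    d <- spec$duplication_classes[[ci]]
    r <- draw_from(d, "reentry_sites", "reentry_grid", "reentry_region",
                   length(idx), L)
    if (!is.null(d$size_mean)) {
      size <- pmax(10L, as.integer(round(stats::rnorm(length(idx), d$size_mean,
                                                      d$size_sd))))
      e <- wrap_position(r + size - 1L, L)
    } else {
      e <- draw_from(d, "exit_sites", NULL, "exit_region", length(idx), L)
    }
    form[idx] <- "circle_with_duplication"
    jr[idx] <- r
    je[idx] <- e
    mol_len[idx] <- L + arc_length(r, e, L)
  }

  idx <- which(draw == "fragment")
  if (length(idx)) {
    d <- (seq_len(L) - oh$start) %% L
    wt <- if (spec$gradient_form == "exp") exp(-d / spec$fragment_tau)
          else pmax(1 - d / (2 * spec$fragment_tau), 0)
    mid <- sample.int(L, length(idx), replace = TRUE, prob = wt)
    len <- pmin(pmax(as.integer(round(stats::rnorm(length(idx),
                                                   spec$fragment_len_mean,
                                                   spec$fragment_len_sd))),
                     200L), L - 1L)
    form[idx] <- "linear_fragment"
    fs[idx] <- wrap_position(mid - len %/% 2L, L)
    fe[idx] <- wrap_position(fs[idx] + len - 1L, L)
    mol_len[idx] <- len
  }

  idx <- which(draw == "major_arc")
  if (length(idx)) {
    form[idx] <- "linear_fragment"
    fs[idx] <- wrap_position(ol$end + 1L, L)
    fe[idx] <- wrap_position(oh$start - 1L, L)
    mol_len[idx] <- arc_length(fs[idx], fe[idx], L)
  }

  idx <- which(draw == "seven_s")
  if (length(idx)) {
    form[idx] <- "seven_s"
    fs[idx] <- tas$start
    fe[idx] <- wrap_position(oh$end + 1L, L)
    mol_len[idx] <- arc_length(fs[idx], fe[idx], L)
  }

  structure(data.frame(form = form, junction_exit = je, junction_reentry = jr,
                       frag_start = fs, frag_end = fe, mol_len = mol_len,
                       stringsAsFactors = FALSE),
            class = c("molecule_population", "data.frame"), spec = spec)
}

#' Plant a direct repeat across a junction's flanks
#'
#' Edits a genome so the `len` bases ending at the junction exit equal
#' the `len` bases ending just upstream of the reentry position, giving
#' the junction a perfect direct-repeat microhomology of at least `len`
#' bases (chance extension can lengthen it). Junction-bearing molecules
#' simulated on the edited genome then carry the repeat at their
#' breakpoint, the pattern seen at rearrangement junctions in vivo.
#'
#' @param genome A [circular_genome()].
#' @param exit,reentry Junction coordinates on the edited genome.
#' @param len Repeat length to plant (`>= 1`).
#' @return A new [circular_genome()] differing only at the `len` bases
#'   ending at `exit`.
#' @export
plant_junction_microhomology <- function(genome, exit, reentry, len) {
  L <- genome$length
  stopifnot(len >= 1L, len < L)
  check_pos(c(exit, reentry), L)
  src <- wrap_position(seq.int(reentry - len, reentry - 1L), L)
  dst <- wrap_position(seq.int(exit - len + 1L, exit), L)
  chars <- genome$chars
  chars[dst] <- chars[src]
  circular_genome(paste(chars, collapse = ""), name = genome$name)
}

#' Canonical (left-aligned) form of a junction
#'
#' Shifts a junction as far 5' as flanking sequence identity allows, the
#' same normalisation [extract_junctions()] applies; use it to compare
#' planted truth junctions with called ones.
#'
#' @param genome A [circular_genome()].
#' @param exit,reentry Junction coordinates.
#' @return Named integer vector `c(exit =, reentry =)`.
#' @export
canonical_junction <- function(genome, exit, reentry) {
  la <- left_align_junction(exit, reentry, genome)
  c(exit = la[1L], reentry = la[2L])
}

# molecule-coordinate -> reference-position map for one molecule row
mol_ref_map <- function(mol, m, L) {
  if (mol$form == "circle") {
    wrap_position(m, L)
  } else if (mol$form == "circle_with_duplication") {
    e <- mol$junction_exit
    r <- mol$junction_reentry
    ifelse(m <= L, wrap_position(e + m, L), wrap_position(r + (m - L) - 1L, L))
  } else {
    wrap_position(mol$frag_start + m - 1L, L)
  }
}

#' Emit sequencing reads with truth alignments
#'
#' Samples reads uniformly along each molecule (allocation across
#' molecules proportional to molecule length; total reads
#' `round(depth * L / read_len)`), applies i.i.d. substitution errors,
#' and returns truth alignments as an [mt_alignments()] table: one SAM
#' record per reference-contiguous run, so reads crossing a junction or
#' the circular origin yield split records (soft-clipped, supplementary
#' flag on the non-first segments).
#'
#' @param molecules A [sample_population()] table.
#' @param genome The [circular_genome()].
#' @param read_len Read length in bases; must not exceed the shortest
#'   molecule (configuration error otherwise).
#' @param depth Target fold-coverage of the reference.
#' @param error_rate Per-base substitution probability (sequencing error
#'   plus any biological SNV load).
#' @param seed Integer seed.
#' @param mapq Reported mapping quality (constant).
#' @return An [mt_alignments()] table; attribute `truth` holds the input
#'   molecule table.
#' @export
emit_reads <- function(molecules, genome, read_len = 120L, depth = 50,
                       error_rate = 0, seed = 1L, mapq = 60L) {
  L <- genome$length
  if (any(molecules$mol_len < read_len)) {
    stop("read_len exceeds the shortest molecule (", min(molecules$mol_len), " bases)")
  }
  set.seed(seed)
  total_reads <- max(1L, as.integer(round(depth * L / read_len)))
  alloc <- sample.int(nrow(molecules), total_reads, replace = TRUE,
                      prob = molecules$mol_len)
  bases <- c("A", "C", "G", "T")

  cap <- as.integer(total_reads * 2.2) + 8L
  o_id <- character(cap); o_flag <- integer(cap); o_pos <- integer(cap)
  o_cig <- character(cap); o_seq <- character(cap)
  k <- 0L
  for (i in seq_len(total_reads)) {
    mol <- molecules[alloc[i], ]
    circ <- mol$form %in% c("circle", "circle_with_duplication")
    s <- if (circ) sample.int(mol$mol_len, 1L)
         else sample.int(mol$mol_len - read_len + 1L, 1L)
    m <- s + seq_len(read_len) - 1L
    if (circ) m <- ((m - 1L) %% mol$mol_len) + 1L
    refpos <- mol_ref_map(mol, m, L)
    chars <- genome$chars[refpos]
    if (error_rate > 0) {
      err <- which(stats::runif(read_len) < error_rate)
      for (e in err) {
        chars[e] <- sample(setdiff(bases, chars[e]), 1L)
      }
    }
    seq_str <- paste(chars, collapse = "")
    breaks <- c(0L, which(diff(refpos) != 1L), read_len)
    rid <- sprintf("m%d_r%06d", alloc[i], i)
    for (seg in seq_len(length(breaks) - 1L)) {
      from <- breaks[seg] + 1L
      to <- breaks[seg + 1L]
      pre <- from - 1L
      post <- read_len - to
      cig <- paste0(if (pre) paste0(pre, "S"), to - from + 1L, "M",
                    if (post) paste0(post, "S"))
      k <- k + 1L
      o_id[k] <- rid
      o_flag[k] <- if (seg == 1L) 0L else 2048L
      o_pos[k] <- refpos[from]
      o_cig[k] <- cig
      o_seq[k] <- seq_str
    }
  }
  rec <- data.frame(read_id = o_id[seq_len(k)], flag = o_flag[seq_len(k)],
                    pos = o_pos[seq_len(k)], mapq = mapq,
                    cigar = o_cig[seq_len(k)], seq = o_seq[seq_len(k)],
                    stringsAsFactors = FALSE)
  out <- mt_alignments(rec, genome)
  attr(out, "truth") <- molecules
  out
}

#' Load a molecule population onto a digital-PCR plate
#'
#' A molecule carries a channel's target iff the amplicon region lies
#' entirely within one of the molecule's retained arcs (circles and
#' duplication circles retain the whole genome; fragments their arc).
#' Molecules are grouped by carried-target signature into species whose
#' Poisson means preserve the population proportions and sum to
#' `mean_molecules`, then loaded via [simulate_plate()]. Channels with
#' no target region (nuclear/tag channels) are never carried by mtDNA
#' molecules; attach them via `extra_species`.
#'
#' @param molecules A [sample_population()] table.
#' @param channels List of [assay_channel()].
#' @param genome The [circular_genome()].
#' @param n_partitions Partitions per plate (default 8,500).
#' @param seed Integer seed.
#' @param mean_molecules Expected total mtDNA molecules per reaction
#'   (default `0.6 * n_partitions`, inside the 20-80\% positivity QC
#'   window for whole-molecule channels).
#' @param extra_species List of [molecule_species()] to co-load (e.g. a
#'   nuclear reference target).
#' @return A [dpcr_plate()].
#' @export
emit_plate <- function(molecules, channels, genome, n_partitions = 8500L,
                       seed = 1L, mean_molecules = 0.6 * n_partitions,
                       extra_species = list()) {
  L <- genome$length
  ch_regions <- lapply(channels, function(c) c$target_region)
  ch_names <- channel_names(channels)
  sig <- vapply(seq_len(nrow(molecules)), function(i) {
    mol <- molecules[i, ]
    carried <- vapply(seq_along(channels), function(j) {
      r <- ch_regions[[j]]
      if (is.null(r)) return(FALSE)
      if (mol$form %in% c("circle", "circle_with_duplication")) return(TRUE)
      arc_contains_arc(mol$frag_start, mol$frag_end, r$start, r$end, L)
    }, logical(1L))
    paste(ch_names[carried], collapse = "+")
  }, character(1L))
  grp <- table(sig)
  species <- lapply(seq_along(grp), function(gi) {
    s <- names(grp)[gi]
    molecule_species(label = if (nzchar(s)) s else "untargeted",
                     targets = if (nzchar(s)) strsplit(s, "+", fixed = TRUE)[[1L]]
                               else character(),
                     mean_molecules = mean_molecules * as.integer(grp[gi]) / nrow(molecules))
  })
  all_names <- unique(c(ch_names,
                        unlist(lapply(extra_species, function(s) s$targets))))
  simulate_plate(c(species, extra_species), all_names, n_partitions, seed)
}

#' Default mtDNA assay channels
#'
#' Amplicon stand-ins (100 bp) inside the four gene targets and the
#' D-loop of the packaged feature table, plus an untargeted nuclear
#' `18s` channel.
#'
#' @return Named list of [assay_channel()].
#' @export
default_channels <- function() {
  list(
    Nd1 = assay_channel("Nd1", region("Nd1_amp", 3000L, 3099L)),
    Nd4 = assay_channel("Nd4", region("Nd4_amp", 10500L, 10599L)),
    CoxI = assay_channel("CoxI", region("CoxI_amp", 6000L, 6099L)),
    Cytb = assay_channel("Cytb", region("Cytb_amp", 14500L, 14599L)),
    Dloop = assay_channel("Dloop", region("Dloop_amp", 15500L, 15599L)),
    `18s` = assay_channel("18s", NULL)
  )
}

#' Double-strand-break degradation time-course
#'
#' Exponential decay to a residual floor:
#' `level(t) = 100 * (floor + (1 - floor) * exp(-k t))` percent of
#' baseline. The floor models genotypes that retain a residual mtDNA
#' pool (~30\% of baseline in degradation-deficient settings);
#' post-nadir repopulation is out of scope.
#'
#' @param days Numeric vector of time points (days, `>= 0`).
#' @param k Decay rate per day (`>= 0`).
#' @param floor Residual fraction in `[0, 1]`.
#' @return `data.frame`: `day`, `pct_baseline` (monotone
#'   non-increasing).
#' @export
dsb_timecourse <- function(days, k, floor = 0) {
  stopifnot(all(days >= 0), k >= 0, floor >= 0, floor <= 1)
  data.frame(day = days,
             pct_baseline = 100 * (floor + (1 - floor) * exp(-k * days)))
}

#' Expected Mendelian offspring frequencies for a multi-locus cross
#'
#' Parents are written as `/`-separated two-allele locus genotypes, e.g.
#' `"MW/KW"` for a double heterozygote over an M/W locus and a K/W
#' locus. Loci are treated as unlinked: offspring frequencies are the
#' product of per-locus Punnett-square frequencies. Genotypes are
#' reported with each locus' alleles in alphabetical order.
#'
#' @param parent_a,parent_b Genotype strings with the same locus count.
#' @return `data.frame`: `genotype`, `freq` (sums to 1), sorted by
#'   genotype.
#' @export
mendelian_expectation <- function(parent_a, parent_b) {
  pa <- parse_genotype(parent_a)
  pb <- parse_genotype(parent_b)
  if (length(pa) != length(pb)) stop("parents must have the same number of loci")
  per_locus <- Map(function(a, b) {
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    geno <- vapply(seq_len(nrow(g)), function(i) {
      paste(sort(c(g$a[i], g$b[i])), collapse = "")
    }, character(1L))
    tab <- table(geno) / length(geno)
    data.frame(geno = names(tab), freq = as.numeric(tab))
  }, pa, pb)
  combo <- Reduce(function(x, y) {
    g <- expand.grid(i = seq_len(nrow(x)), j = seq_len(nrow(y)))
    data.frame(geno = paste(x$geno[g$i], y$geno[g$j], sep = "/"),
               freq = x$freq[g$i] * y$freq[g$j])
  }, per_locus)
  combo <- combo[order(combo$geno), , drop = FALSE]
  rownames(combo) <- NULL
  names(combo) <- c("genotype", "freq")
  combo
}

parse_genotype <- function(s) {
  loci <- strsplit(s, "/", fixed = TRUE)[[1L]]
  if (!length(loci) || any(nchar(loci) != 2L)) {
    stop("malformed genotype '", s, "': expected /-separated two-allele loci")
  }
  lapply(loci, function(l) strsplit(l, "", fixed = TRUE)[[1L]])
}
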