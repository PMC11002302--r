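---
title: "Quantifying mitochondrial DNA integrity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial DNA integrity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofrag)
```

# Scope

Mammalian mitochondrial DNA (mtDNA) is a circular, multi-copy genome
(~16.3 kb in mouse). Genotypes that impair mtDNA turnover — loss of the
MGME1 5'→3' exonuclease, or a proofreading-deficient POLG — accumulate
broken and rearranged molecules: linear fragments whose abundance decays
with distance from the heavy-strand replication origin O~H~, excess 7S DNA
over the displacement loop, and tandem duplications anchored in the control
region. `mitofrag` implements two complementary ways of measuring this:

1. **Partition statistics of multiplex digital PCR (dPCR)**: Poisson
   copy-number estimation per channel (1D) and double/single-positive
   partition analysis of channel pairs (2D), including a model-based
   linked-fraction estimator.
2. **Split-read structural analysis** of alignments to the circular
   reference: junction extraction, duplication-versus-deletion
   classification by O~H~ containment, hotspot clustering, junction
   microhomology, and coverage/SNV gradients relative to O~H~.

A genotype-parameterised synthetic-data generator produces molecule
populations, truth-aligned SAM reads and dPCR plates, so the full pipeline
is exercised without external data.

# Circular coordinates

All coordinates are 1-based inclusive; position $L + 1$ is position 1.
The two primitives everything rests on are `wrap_position(p, L)`
$= ((p-1) \bmod L) + 1$ and the inclusive arc length
$\mathrm{arc}(a,b) = ((b - a) \bmod L) + 1$, the number of bases on the
increasing-coordinate arc from $a$ to $b$. Regions may wrap (`end <
start`); on-disk BED cannot express this, so the reader/writer uses the
convention that an `end` beyond $L$ wraps through the origin. Conversion
to 0-based half-open happens only at the BED and SAM boundaries. `N`
residues count as non-GC and stay in GC-window denominators, so windowed
GC is deterministic on ambiguous bases.

# Digital PCR model

A reaction is partitioned into $n$ compartments (default $n = 8{,}500$,
the nanoplate geometry used for mtDNA work). Under Poisson loading with
mean $\lambda$ molecules per partition, the negative proportion is
$e^{-\lambda}$, so from an observed positive proportion $p$:

$$\hat\lambda = -\ln(1-p), \qquad \widehat{\text{copies}} = n\,\hat\lambda.$$

The 95 % interval propagates the binomial error of $p$ through the log
(delta method); ratios of two estimates get a delta-method interval from
the two $\lambda$ standard errors. Saturated plates ($p = 1$) are an
error, not a clamp. The 20–80 % positivity quality window is applied with
inclusive bounds (the source protocols state a range without boundary
semantics).

For a channel pair, partitions split into double positives (DPP), two
single-positive classes (SPP) and negatives; each category as percent of
all partitions is the raw "2D %PP" report, the default descriptive
output. Linked molecules (two targets on one molecule) generate DPPs
directly; free molecules generate DPPs only by chance co-localisation.
The model-based correction uses the three negative-probability
identities: with $P(A^-)$, $P(B^-)$, $P(AB^-)$,

$$\lambda_{\text{linked}} = \ln\frac{P(AB^-)}{P(A^-)P(B^-)}, \qquad
\lambda_{\text{free},A} = -\ln P(A^-) - \lambda_{\text{linked}},$$

clamped at zero (a clamp triggers a warning: at the boundary, sampling
noise can push a free rate slightly negative). The linked fraction per
channel is $\lambda_{\text{linked}} / (\lambda_{\text{linked}} +
\lambda_{\text{free}})$. Both raw and corrected values are exposed
because published 2D %PP figures do not state whether chance
co-localisation was removed (it is usually controlled by dilution
instead); we report both and default to raw.

Relative qPCR quantification uses the comparative Ct closed form
$RQ = 2^{-\Delta\Delta C_t}$.

# Structural-alteration calling

A junction is the ordered pair (exit, reentry): the last reference base
before the join and the first after it. Junctions are collected from (i)
reference gaps (`D`/`N` CIGAR runs) of at least `min_gap` bases within
one record and (ii) consecutive same-strand split segments of one read
ordered by read offset. A single circular emission rule covers both
sources and the origin: a candidate is kept iff its circular gap
$((\text{reentry} - \text{exit} - 1) \bmod L) \ge \texttt{min\_gap}$.
This suppresses small indels and the zero-gap join of an origin-crossing
read while keeping back-jump junctions, whose gap measured around the
circle is large.

**Classification.** The retained arc of a junction is the arc from
reentry to exit. If that arc contains no O~H~ base, the putative
recombinant could not replicate independently and the junction is
flagged as a duplication of the arc; otherwise it is a deletion (the
deleted segment is the complement arc). Call size is the retained-arc
length, so for a fixed reentry, size grows linearly with exit position.
A junction with exit = reentry is degenerate and suppressed with a
warning. Where the arc-choice ambiguity could flip a class (both arcs
lacking O~H~ is impossible — the two arcs partition the circle, and O~H~
lies on exactly one of them unless it straddles a breakpoint), the rule
is applied literally to the retained arc.

**Left alignment.** When sequence identity flanks the junction, its
placement is ambiguous; junctions are shifted as far 5' as
`base(exit) == base(reentry - 1)` holds (capped at $L - 1$ shifts so a
periodic toy genome cannot loop). This makes call tables byte-identical
across runs. `canonical_junction()` applies the same normalisation to
planted truth for comparisons.

**Heteroplasmy.** The fraction of molecules carrying a junction is
estimated as junction reads over (junction + spanning reads), where a
spanning read must have a gapless block with at least `min_flank` bases
on each side of the exit adjacency. Matching `min_flank` to the
extractor's `min_segment` equalises the two acceptance windows;
otherwise spanning reads are accepted over a wider window than junction
reads and the ratio is biased low. Note that a tandem-duplication
molecule contains the reference adjacency too (in its second arc copy),
so the read-level fraction sits slightly below the molecule-level
fraction by construction. The spanning denominator is evaluated at the
exit position only — one consistent choice.

**Hotspots.** Exit and reentry positions are clustered separately by
single linkage at distance `tol` (circular, seam-mended), and each
cluster is labelled with the annotation region containing its modal
position; overlapping annotations resolve to the shortest region so
nested control-region features win over the D-loop.

**Microhomology.** For each call, windows of $2 \times$`flank_len`
(default 20) bases centred on the exit and reentry are searched for the
longest gapless, same-orientation substring pair with at most the
allowed substitutions. "Imperfect" means substitutions only. The default
allowance is 1 mismatch per 8 bases of repeat length rounded down — the
literature reports a 2–14 bp range without defining a tolerance, so this
is a named configuration value, not an assertion. Ties break by fewer
mismatches, then smallest exit offset, then smallest reentry offset.

# Coverage and SNV profiles

Depth is the per-position count of aligned (`M`) blocks, circular-aware;
split reads contribute each segment once, so total depth equals total
aligned bases. `coverage_vs_oh()` bins depth by circular distance
downstream of O~H~ (package convention: increasing coordinates;
`direction = -1` reverses), normalises to the first bin to match the
"decline downstream of O~H~" framing, and attaches a Kendall-type sign
score over bins in $[-1, 1]$. The SNV profile is a pileup mismatch
fraction with positions under `min_depth` (default 10) flagged absent —
deliberately not haplotype calling, which is no part of the contribution
being packaged.

Exponential decay lengths are recovered by log-linear regression of
binned depth on distance (`fit_decay_tau`). Coverage is the
fragment-extent convolution of the fragment-midpoint law, so the
exponential rate is clean only away from the origin-proximal boundary
(within about one fragment length of O~H~) and away from the circular
wrap, where origin-proximal fragments leak coverage into the largest
distances. The fit window is therefore an explicit argument; analyses in
the test-suite use 1–10 kb on the 16.3 kb genome, chosen from those two
geometric considerations, not from observed recovery error.

# The synthetic world

`sample_population()` draws molecules from a `genotype_spec()`:

| parameter | default | meaning |
|---|---|---|
| `intact_fraction` | genotype preset | fraction of plain circles |
| `duplication_classes` | preset | tandem-duplication families: reentry law (sites / grid / region), exit law (size $\mathcal N(\mu,\sigma)$ or sites/region) |
| `fragment_tau` | 3,000–8,000 bases | fragment-midpoint weight $\propto e^{-d/\tau}$, $d$ = circular distance downstream of O~H~ (linear ramp behind `gradient_form = "linear"`; the direction, not the functional form, is established biology) |
| `fragment_len_mean/sd` | 2,000/500 bases | fragment length law, truncated at 200 bases |
| `major_arc_weight` | preset | the fixed O~L~→O~H~ (~11 kb) linear species |
| `seven_s_excess` | 1–5 | multiplier on the D-loop-only short species (TAS to just past O~H~) standing in for 7S DNA |
| `snv_rate` | ≤ 0.05 | biological substitution load, realised as i.i.d. per-read substitutions at emission (no site linkage) |

Duplicated molecules carry a single tandem junction (no nested events) —
the evidence unit split-read callers consume. `emit_reads()` samples
reads uniformly along each molecule (allocation proportional to molecule
length, total `depth * L / read_len` reads) and writes truth alignments:
one SAM record per reference-contiguous run, split and soft-clipped at
junctions and at the origin. `emit_plate()` marks a molecule as carrying
a channel iff the amplicon lies entirely within a retained arc, groups
molecules into species and delegates to the Poisson plate simulator.
`plant_junction_microhomology()` edits the reference so a junction's two
flanks share a direct repeat of a chosen length.

**Presets.** `wt`, `mgme1` and `polg` encode qualitative spectra: the
Mgme1-like preset combines an evenly spaced grid of ~100 bp duplications,
~690 bp duplications re-entering at three tRNA-Pro sites (15368, 15388,
15403), a strong fragment gradient ($\tau = 3{,}000$), a major-arc
species and a 5× 7S excess; the Polg-like preset uses a single tRNA-Pro
reentry site (15373) with four discrete ISR exit sites, a mild gradient
and a high SNV load. The class *weights* are generator choices tuned
once so that the genotype's stated qualitative directions all hold
simultaneously — in particular, enough fragment mass that coverage
declines downstream of O~H~ despite the flat background from intact
circles, and enough major-arc mass that Nd4-side single positives exceed
Nd1-side ones even though gradient fragments (which sit near O~H~)
preferentially cover Nd1. No preset number is asserted against external
data, and tests never treat preset weights as measurements.

**What a green test does not establish.** The generator emulates
composition, not chemistry: no amplification or GC bias, no quality
scores, no chimeric artefacts, no alignment — reads carry truth
coordinates, so junction recall measures the extractor's bookkeeping,
not aligner sensitivity. Substitution errors cannot displace a truth
breakpoint; real aligners can. The packaged 16.3 kb reference is a
seeded synthetic sequence with mouse-like GC content, and the feature
coordinates (O~H~, ISR, CSB bounds in particular) are editable defaults
chosen for internal consistency, not curated annotation.

# Numerical and design choices

- `min_gap = 30` separates junctions from alignment indels; `min_mapq =
  20`; `merge_tol = 5` (single-linkage, circular Chebyshev metric on the
  coordinate pair; the best-supported member represents a merged
  cluster, ties to smallest coordinates). All configurable.
- Only same-strand split segments join: inversions are out of scope.
- Degenerate inputs fail loudly: saturated plates, zero first coverage
  bin, zero-support heteroplasmy and empty hotspot input are errors, not
  silent values.
- Seeds are explicit arguments everywhere; no global RNG state is
  relied on, and equal seeds give bit-identical output.
- The O~H~ containment test uses arc intersection (either arc endpoint
  inside the other arc), exact on wrapped arcs.

# Known limitations

- A junction at exactly exit $= L$ sees spanning depth 0 (origin-crossing
  reads are split by convention), overstating heteroplasmy there.
- The linked-fraction estimator assumes exactly three Poisson species
  (linked, free A, free B); populations with molecules carrying neither
  target dilute nothing but add no information, and heavy multi-way
  linkage beyond a pair is not modelled.
- Fragment ends are sampled uniformly in the interior, slightly
  under-representing coverage at fragment termini relative to real
  sonication/degradation chemistry.
- Hotspot clustering is single linkage: dense breakpoint fields can
  chain into one cluster at large `tol`.
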