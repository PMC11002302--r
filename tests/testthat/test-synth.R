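test_that("intact_fraction 1 gives only plain circles", {
  g <- mouse_mtdna_genome()
  ann <- mouse_mtdna_features(g)
  spec <- genotype_spec(intact_fraction = 1)
  pop <- sample_population(spec, 500, g, ann, seed = 2)
  expect_true(all(pop$form == "circle"))
  expect_true(all(pop$mol_len == g$length))
})

test_that("generators are reproducible under a fixed seed", {
  g <- mouse_mtdna_genome()
  ann <- mouse_mtdna_features(g)
  spec <- genotype_preset("mgme1")
  p1 <- sample_population(spec, 300, g, ann, seed = 77)
  p2 <- sample_population(spec, 300, g, ann, seed = 77)
  expect_identical(p1, p2)
  a1 <- emit_reads(p1, g, read_len = 100, depth = 5, error_rate = 0.01, seed = 5)
  a2 <- emit_reads(p2, g, read_len = 100, depth = 5, error_rate = 0.01, seed = 5)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  pl1 <- emit_plate(p1, default_channels(), g, seed = 6)
  pl2 <- emit_plate(p2, default_channels(), g, seed = 6)
  expect_identical(pl1$positivity, pl2$positivity)
  p3 <- sample_population(spec, 300, g, ann, seed = 78)
  expect_false(identical(p1, p3))
})

test_that("grid duplication class plants junctions on the grid with ~100 bp sizes", {
  g <- mouse_mtdna_genome()
  ann <- mouse_mtdna_features(g)
  grid <- seq(500L, 16000L, by = 500L)
  spec <- genotype_spec(intact_fraction = 0,
                        duplication_classes = list(
                          duplication_class(reentry_grid = grid,
                                            size_mean = 100, size_sd = 10)),
                        fragment_weight = 0, major_arc_weight = 0,
                        seven_s_excess = 0)
  pop <- sample_population(spec, 10000, g, ann, seed = 13)
  expect_true(all(pop$form == "circle_with_duplication"))
  expect_true(all(pop$junction_reentry %in% grid))
  sizes <- arc_length(pop$junction_reentry, pop$junction_exit, g$length)
  expect_lt(abs(mean(sizes) - 100), 5)
})

test_that("fragment gradient concentrates mass near O_H", {
  g <- mouse_mtdna_genome()
  ann <- mouse_mtdna_features(g)
  oh <- ann[ann$label == "O_H", ]
  spec <- genotype_spec(intact_fraction = 0, fragment_weight = 1,
                        fragment_tau = 2000, seven_s_excess = 0)
  pop <- sample_population(spec, 4000, g, ann, seed = 21)
  expect_true(all(pop$form == "linear_fragment"))
  mid <- wrap_position(pop$frag_start + pop$mol_len %/% 2L, g$length)
  d <- (mid - oh$start) %% g$length
  # empirical mean distance of an exp(tau) law truncated to the circle
  dd <- 0:(g$length - 1)
  expect_lt(abs(mean(d) - sum(dd * exp(-dd / 2000)) / sum(exp(-dd / 2000))) / 2000,
            0.1)
})

test_that("emit_reads hits the depth target and propagates planted truth", {
  g <- mouse_mtdna_genome()
  ann <- mouse_mtdna_features(g)
  pop <- manual_population("circle", L = g$length)
  aln <- emit_reads(pop, g, read_len = 120, depth = 50, seed = 31)
  emitted <- sum(vapply(aln$cigar, function(c) {
    sum(as.integer(regmatches(c, gregexpr("\\d+(?=M)", c, perl = TRUE))[[1]]))
  }, numeric(1)))
  expect_lt(abs(emitted - 50 * g$length) / (50 * g$length), 0.02)

  # a single duplicated molecule at 50x: its junction is recovered exactly
  pop2 <- manual_population("circle_with_duplication",
                            junction_exit = 9000, junction_reentry = 8001,
                            L = g$length)
  aln2 <- emit_reads(pop2, g, read_len = 120, depth = 50, seed = 32)
  j <- extract_junctions(aln2, g)
  expect_identical(nrow(j), 1L)
  truth <- canonical_junction(g, 9000L, 8001L)
  expect_identical(c(j$exit, j$reentry), unname(truth))

  expect_error(emit_reads(manual_population("linear_fragment",
                                            frag_start = 100, frag_end = 300,
                                            L = g$length),
                          g, read_len = 500, depth = 1),
               "read_len exceeds")
})

test_that("trnP-to-ISR duplication families classify as duplications end to end", {
  g <- mouse_mtdna_genome()
  ann <- mouse_mtdna_features(g)
  spec <- genotype_preset("polg")
  spec$intact_fraction <- 0
  spec$fragment_weight <- 0
  spec$major_arc_weight <- 0
  spec$seven_s_excess <- 0
  pop <- sample_population(spec, 40, g, ann, seed = 41)
  aln <- emit_reads(pop, g, read_len = 120, depth = 60, seed = 41)
  calls <- call_structural_alterations(aln, g, ann)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$class == "duplication"))
  expect_true(all(calls$start_label == "trnP"))
  expect_true(all(calls$end_label == "ISR"))
})

test_that("emit_plate links whole-molecule targets and frees fragment targets", {
  g <- mouse_mtdna_genome()
  ann <- mouse_mtdna_features(g)
  ch <- default_channels()

  # all-intact population: no SPPs beyond chance
  intact <- sample_population(genotype_spec(intact_fraction = 1), 2000, g, ann,
                              seed = 51)
  pl <- emit_plate(intact, ch, g, seed = 51)
  s <- pair_summary(pl, "Nd1", "Nd4")
  expect_identical(s$n_spp_a + s$n_spp_b, 0L)

  # major-arc fragments span Nd4 but not Nd1 -> Nd4+ SPP excess
  mixed <- manual_population(c(rep("circle", 50), rep("linear_fragment", 50)),
                             frag_start = 5192, frag_end = 16149, L = g$length)
  pl2 <- emit_plate(mixed, ch, g, seed = 52)
  s2 <- pair_summary(pl2, "Nd1", "Nd4")
  expect_gt(s2$n_spp_b, s2$n_spp_a + 50)

  # 7S excess pushes D-loop copies above Nd1 copies
  seven <- sample_population(genotype_spec(intact_fraction = 0.5,
                                           fragment_weight = 0,
                                           major_arc_weight = 0,
                                           seven_s_excess = 10),
                             3000, g, ann, seed = 53)
  pl3 <- emit_plate(seven, ch, g, seed = 53)
  est <- estimate_copies_plate(pl3)
  expect_gt(est$copies[est$channel == "Dloop"],
            est$copies[est$channel == "Nd1"])
})

test_that("dsb_timecourse decays monotonically to its floor", {
  expect_equal(dsb_timecourse(0, k = 1.5)$pct_baseline, 100)
  expect_true(all(dsb_timecourse(0:10, k = 0)$pct_baseline == 100))
  tc <- dsb_timecourse(seq(0, 30, by = 0.5), k = 2, floor = 0.3)
  expect_true(all(diff(tc$pct_baseline) <= 0))
  expect_equal(tc$pct_baseline[nrow(tc)], 30, tolerance = 1e-6)
})

test_that("mendelian_expectation reproduces Punnett products and is symmetric", {
  one <- mendelian_expectation("MW", "MW")
  expect_equal(one$freq[one$genotype == "MM"], 0.25)
  expect_equal(sum(one$freq), 1)

  two <- mendelian_expectation("MW/KW", "MW/KW")
  expect_equal(two$freq[two$genotype == "MM/KK"], 1 / 16)
  expect_equal(sum(two$freq), 1)

  # MM/KW x MW/KW -> MM/KK expected 1/2 * 1/4 = 1/8
  cross <- mendelian_expectation("MM/KW", "MW/KW")
  expect_equal(cross$freq[cross$genotype == "MM/KK"], 1 / 8)

  # symmetry in parents, for random crosses
  set.seed(5)
  for (i in 1:10) {
    mk <- function() paste(c(sample(c("M", "W"), 2, TRUE),
                             "/",
                             sample(c("K", "W"), 2, TRUE)), collapse = "")
    a <- mk(); b <- mk()
    ab <- mendelian_expectation(a, b)
    ba <- mendelian_expectation(b, a)
    expect_equal(ab, ba)
    expect_equal(sum(ab$freq), 1)
  }
  expect_error(mendelian_expectation("MWX", "MW"), "malformed")
})

test_that("emit_plate plus linkage inference recovers the planted intact fraction", {
  g <- mouse_mtdna_genome()
  ch <- default_channels()
  n_mol <- 400L
  for (f in c(0.25, 0.5, 0.75)) {
    rec <- vapply(1:20, function(seed) {
      n_int <- round(f * n_mol)
      pop <- manual_population(c(rep("circle", n_int),
                                 rep("linear_fragment", n_mol - n_int)),
                               frag_start = 5192, frag_end = 16149,
                               L = g$length)
      pl <- emit_plate(pop, ch, g, seed = 90L + seed)
      # major-arc fragments carry Nd4 but not Nd1: the Nd4-side linked
      # fraction is the intact molecule fraction
      suppressWarnings(
        estimate_linkage(pair_summary(pl, "Nd1", "Nd4"))$linked_fraction_b)
    }, numeric(1))
    expect_lt(abs(mean(rec) - f), 0.05)
  }
})
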