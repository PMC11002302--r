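test_that("estimate_copies matches the Poisson closed form with sane CIs", {
  e0 <- estimate_copies(0, 8500)
  expect_equal(e0$lambda, 0)
  expect_equal(e0$copies, 0)
  e <- estimate_copies(4250, 8500)
  expect_equal(e$lambda, log(2))
  expect_equal(e$copies, log(2) * 8500)      # ~5892 copies per reaction
  expect_true(e$ci_low <= e$copies && e$copies <= e$ci_high)
  expect_error(estimate_copies(8500, 8500), "saturated")
})

test_that("copy_ratio has the right point value and degenerate behaviour", {
  a <- estimate_copies(3000, 8500)
  expect_equal(copy_ratio(a, a)$ratio, 1)
  z <- estimate_copies(0, 8500)
  expect_equal(copy_ratio(z, a)$ratio, 0)
  expect_error(copy_ratio(a, z), "zero copies")
})

test_that("pair_summary counts partition the plate and match a manual tally", {
  # hand-built 10-partition plate
  pos <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                  TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                ncol = 2, dimnames = list(NULL, c("A", "B")))
  plate <- dpcr_plate(pos)
  s <- pair_summary(plate, "A", "B")
  expect_identical(c(s$n_dpp, s$n_spp_a, s$n_spp_b, s$n_neg), c(3L, 2L, 1L, 4L))
  expect_equal(s$pct_dpp + s$pct_spp_a + s$pct_spp_b + 100 * s$n_neg / 10, 100)
  expect_error(pair_summary(plate, "A", "C"), "not on plate")

  # all-negative plate
  neg <- dpcr_plate(matrix(FALSE, 10, 2, dimnames = list(NULL, c("A", "B"))))
  sn <- pair_summary(neg, "A", "B")
  expect_identical(sn$n_neg, 10L)
  expect_equal(c(sn$pct_dpp, sn$pct_spp_a, sn$pct_spp_b), c(0, 0, 0))
})

test_that("simulate_plate honours linkage identities and conservation", {
  # zero-abundance species -> all-negative plate
  p0 <- simulate_plate(list(molecule_species("none", c("A", "B"), 0)),
                       c("A", "B"), 500, seed = 1)
  expect_false(any(p0$positivity))
  # fully linked species: every A-positive partition is B-positive
  p1 <- simulate_plate(list(molecule_species("link", c("Nd1", "Nd4"), 300)),
                       c("Nd1", "Nd4"), 2000, seed = 2)
  s1 <- pair_summary(p1, "Nd1", "Nd4")
  expect_identical(s1$n_spp_a, 0L)
  expect_identical(s1$n_spp_b, 0L)
  expect_true(s1$n_dpp > 0L)
  # conservation across random mixtures
  set.seed(9)
  for (rep in 1:20) {
    sp <- list(molecule_species("ab", c("A", "B"), runif(1, 0, 800)),
               molecule_species("a", "A", runif(1, 0, 800)),
               molecule_species("b", "B", runif(1, 0, 800)))
    pl <- simulate_plate(sp, c("A", "B"), 1000, seed = rep)
    s <- pair_summary(pl, "A", "B")
    expect_identical(s$n_dpp + s$n_spp_a + s$n_spp_b + s$n_neg, 1000L)
  }
  expect_error(molecule_species("bad", "A", -1), "finite and >= 0")
})

test_that("independent species give DPP counts at the chance level", {
  # closed-form independence product as oracle over replicate plates
  n <- 2000L
  reps <- 400L
  dpp <- pa <- pb <- numeric(reps)
  for (r in seq_len(reps)) {
    pl <- simulate_plate(list(molecule_species("a", "A", 600),
                              molecule_species("b", "B", 600)),
                         c("A", "B"), n, seed = r)
    s <- pair_summary(pl, "A", "B")
    dpp[r] <- s$n_dpp
    pa[r] <- (s$n_dpp + s$n_spp_a) / n
    pb[r] <- (s$n_dpp + s$n_spp_b) / n
  }
  expected <- mean(n * pa * pb)
  se <- sd(dpp) / sqrt(reps)
  expect_lt(abs(mean(dpp) - expected), 4 * se + 1)
})

test_that("small plates match exhaustive enumeration of placements", {
  # exact oracle: distribution of (dpp, spp_a, spp_b, neg) for k molecules
  # in m partitions from all m^k equally likely placements
  targets <- list(c("A", "B"), "A", "B")
  m <- 5L
  k <- length(targets)
  states <- expand.grid(rep(list(seq_len(m)), k))
  key <- function(cnt) paste(cnt, collapse = "/")
  exact <- new.env()
  for (i in seq_len(nrow(states))) {
    pos <- matrix(FALSE, m, 2, dimnames = list(NULL, c("A", "B")))
    for (j in seq_len(k)) pos[states[i, j], targets[[j]]] <- TRUE
    cnt <- c(sum(pos[, 1] & pos[, 2]), sum(pos[, 1] & !pos[, 2]),
             sum(!pos[, 1] & pos[, 2]), sum(!pos[, 1] & !pos[, 2]))
    kk <- key(cnt)
    exact[[kk]] <- (if (is.null(exact[[kk]])) 0 else exact[[kk]]) + 1 / nrow(states)
  }
  reps <- 4000L
  obs <- table(vapply(seq_len(reps), function(r) {
    set.seed(r)
    pl <- place_molecules(targets, c("A", "B"), m)
    s <- pair_summary(pl, "A", "B")
    key(c(s$n_dpp, s$n_spp_a, s$n_spp_b, s$n_neg))
  }, character(1)))
  cats <- ls(exact)
  expect_true(all(names(obs) %in% cats))
  p_exp <- vapply(cats, function(c) exact[[c]], numeric(1))
  o <- vapply(cats, function(c) if (c %in% names(obs)) obs[[c]] else 0L, numeric(1))
  chi <- sum((o - reps * p_exp)^2 / (reps * p_exp))
  # df = categories - 1; reject only at p < 0.001
  expect_lt(chi, qchisq(0.999, length(cats) - 1))
})

test_that("estimate_linkage solves the duplex algebra", {
  # analytic independence: P(AB-) = P(A-) P(B-) exactly -> lambda_linked = 0
  n <- 10000L
  p_a <- 0.6; p_b <- 0.5  # negative proportions
  n_neg <- round(n * p_a * p_b)
  s <- data.frame(n_dpp = n - round(n * p_a) - round(n * p_b) + n_neg,
                  n_spp_a = round(n * (1 - p_a)) - (n - round(n * p_a) - round(n * p_b) + n_neg),
                  n_spp_b = round(n * (1 - p_b)) - (n - round(n * p_a) - round(n * p_b) + n_neg),
                  n_neg = n_neg)
  est <- estimate_linkage(s)
  expect_equal(est$lambda_linked, 0)
  expect_equal(est$linked_fraction_a, 0)

  # single fully linked species at per-partition mean lambda:
  # P(A-) = P(B-) = P(AB-) = exp(-lambda) -> lambda_linked = lambda
  lambda <- 0.8
  neg <- round(n * exp(-lambda))
  s2 <- data.frame(n_dpp = n - neg, n_spp_a = 0L, n_spp_b = 0L, n_neg = neg)
  est2 <- estimate_linkage(s2)
  expect_equal(est2$lambda_linked, -log(neg / n), tolerance = 1e-12)
  expect_equal(est2$lambda_free_a, 0)
  expect_equal(est2$linked_fraction_a, 1)

  s3 <- data.frame(n_dpp = 10L, n_spp_a = 0L, n_spp_b = 0L, n_neg = 0L)
  expect_error(estimate_linkage(s3), "saturated")
})

test_that("qc_positivity applies the inclusive 20-80% window", {
  mk <- function(npos, n = 1000L) {
    dpcr_plate(matrix(seq_len(n) <= npos, ncol = 1, dimnames = list(NULL, "A")))
  }
  expect_true(qc_positivity(mk(500), "A")$pass)
  expect_false(qc_positivity(mk(199), "A")$pass)  # 19.9% is below the window
  expect_true(qc_positivity(mk(200), "A")$pass)
  expect_true(qc_positivity(mk(800), "A")$pass)   # inclusive upper bound
  expect_false(qc_positivity(mk(801), "A")$pass)
})

test_that("relative_quant_ddct computes 2^-ddCt", {
  expect_equal(relative_quant_ddct(20, 18, 22, 20), 1)
  expect_equal(relative_quant_ddct(25, 20, 24, 20), 0.5)
  expect_equal(relative_quant_ddct(25, 20, 24, 20, percent = TRUE), 50)
  expect_error(relative_quant_ddct(NA, 20, 24, 20), "finite")
})

test_that("plate CSV round-trips and rejects non-binary input", {
  pl <- simulate_plate(list(molecule_species("a", "A", 50),
                            molecule_species("b", "B", 80)),
                       c("A", "B"), 200, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_plate_csv(pl, f)
  back <- read_plate_csv(f)
  expect_identical(back$positivity, pl$positivity)
  writeLines(c("A,B", "1,0", "2,0"), f)
  expect_error(read_plate_csv(f), "0/1")
})

test_that("expected DPPs rise and SPPs fall as the linked fraction grows", {
  n <- 4000L
  lambda_tot <- 0.5
  mean_pcts <- t(vapply(c(0, 0.5, 1), function(f) {
    pct <- vapply(1:12, function(seed) {
      sp <- list(molecule_species("ab", c("A", "B"), f * lambda_tot * n),
                 molecule_species("a", "A", (1 - f) * lambda_tot * n),
                 molecule_species("b", "B", (1 - f) * lambda_tot * n))
      s <- pair_summary(simulate_plate(sp, c("A", "B"), n, seed = 70 + seed),
                        "A", "B")
      c(s$pct_dpp, s$pct_spp_a + s$pct_spp_b)
    }, numeric(2))
    rowMeans(pct)
  }, numeric(2)))
  expect_true(all(diff(mean_pcts[, 1]) > 0))  # DPP% strictly increasing
  expect_true(all(diff(mean_pcts[, 2]) < 0))  # SPP% strictly decreasing
})

test_that("estimated copies scale linearly with input below saturation", {
  n <- 8500L
  conc <- c(0.25, 0.5, 1, 2, 4) * 1500  # true molecules per reaction
  est <- vapply(seq_along(conc), function(i) {
    mean(vapply(1:10, function(seed) {
      pl <- simulate_plate(list(molecule_species("m", "A", conc[i])),
                           "A", n, seed = 80L + 10L * i + seed)
      estimate_copies(sum(pl$positivity[, "A"]), n)$copies
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(est ~ conc))[["conc"]]
  expect_lt(abs(slope - 1), 0.05)
})
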