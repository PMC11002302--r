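#' Assay channel
#'
#' A fluorescence channel of a multiplex digital-PCR assay. Mitochondrial
#' channels carry the amplicon location on the reference; nuclear or tag
#' channels have no target region.
#'
#' @param name Channel name (e.g. `"Nd1"`, `"Nd4"`, `"18s"`).
#' @param target_region A [region()] for the amplicon, or `NULL`.
#' @return Object of class `assay_channel`.
#' @export
assay_channel <- function(name, target_region = NULL) {
  structure(list(name = name, target_region = target_region),
            class = "assay_channel")
}

#' Molecule species for plate simulation
#'
#' @param label Species label (e.g. `"circular"`, `"major_arc_fragment"`).
#' @param targets Character vector of channel names the species carries.
#' @param mean_molecules Expected molecules of this species per reaction
#'   (Poisson mean); must be finite and `>= 0`.
#' @return Object of class `molecule_species`.
#' @export
molecule_species <- function(label, targets, mean_molecules) {
  if (!is.finite(mean_molecules) || mean_molecules < 0) {
    stop("mean_molecules must be finite and >= 0")
  }
  structure(list(label = label, targets = as.character(targets),
                 mean_molecules = mean_molecules),
            class = "molecule_species")
}

#' Digital-PCR plate
#'
#' @param positivity Logical matrix, `n_partitions` rows by one column per
#'   channel (named).
#' @return Object of class `dpcr_plate`.
#' @export
dpcr_plate <- function(positivity) {
  stopifnot(is.matrix(positivity), is.logical(positivity),
            !is.null(colnames(positivity)), nrow(positivity) > 0L)
  if (anyDuplicated(colnames(positivity))) stop("channel names must be unique")
  structure(list(n_partitions = nrow(positivity), positivity = positivity),
            class = "dpcr_plate")
}

#' @export
print.dpcr_plate <- function(x, ...) {
  pct <- round(100 * colMeans(x$positivity), 1)
  cat(sprintf("<dpcr_plate> %d partitions; %% positivity: %s\n",
              x$n_partitions,
              paste(sprintf("%s=%.1f", names(pct), pct), collapse = " ")))
  invisible(x)
}

#' Place a fixed set of molecules into partitions
#'
#' Deterministic-count core of [simulate_plate()]: each molecule (a
#' vector of carried channel names) lands in one uniformly random
#' partition; a partition is positive for a channel iff at least one
#' resident molecule carries it. Exposed so small plates can be checked
#' against exhaustive enumeration of placements.
#'
#' @param target_sets List of character vectors (targets per molecule).
#' @param channel_names Channel names defining the plate columns.
#' @param n_partitions Partitions on the plate.
#' @return A [dpcr_plate()].
#' @export
place_molecules <- function(target_sets, channel_names, n_partitions) {
  pos <- matrix(FALSE, nrow = n_partitions, ncol = length(channel_names),
                dimnames = list(NULL, channel_names))
  if (length(target_sets)) {
    part <- sample.int(n_partitions, length(target_sets), replace = TRUE)
    for (i in seq_along(target_sets)) {
      tg <- intersect(target_sets[[i]], channel_names)
      if (length(tg)) pos[part[i], tg] <- TRUE
    }
  }
  dpcr_plate(pos)
}

#' Simulate loading a molecule mixture into a partition plate
#'
#' Poisson loading: the number of molecules of each species is drawn from
#' a Poisson law with the species' mean, and every molecule lands in one
#' uniformly random partition independently. A partition reads positive
#' for a channel iff at least one resident molecule carries that
#' channel's target.
#'
#' @param species List of [molecule_species()].
#' @param channels Character vector of channel names, or list of
#'   [assay_channel()].
#' @param n_partitions Partitions per plate (default 8,500, the nanoplate
#'   geometry used for mtDNA work).
#' @param seed Integer seed; randomness is local to this call.
#' @return A [dpcr_plate()].
#' @export
simulate_plate <- function(species, channels, n_partitions = 8500L, seed = 1L) {
  stopifnot(n_partitions > 0L)
  ch <- channel_names(channels)
  set.seed(seed)
  pos <- matrix(FALSE, nrow = n_partitions, ncol = length(ch),
                dimnames = list(NULL, ch))
  for (s in species) {
    n <- stats::rpois(1L, s$mean_molecules)
    tg <- intersect(s$targets, ch)
    if (n == 0L || length(tg) == 0L) next
    part <- sample.int(n_partitions, n, replace = TRUE)
    pos[unique(part), tg] <- TRUE
  }
  dpcr_plate(pos)
}

channel_names <- function(channels) {
  nm <- if (is.character(channels)) channels
        else vapply(channels, function(c) c$name, character(1L))
  if (anyDuplicated(nm)) stop("channel names must be unique")
  nm
}

#' Read a plate from CSV
#'
#' Dialect: one row per partition, one 0/1 column per channel, header row
#' with channel names. The reader validates rectangularity and 0/1 coding.
#'
#' @param path CSV path.
#' @return A [dpcr_plate()].
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(m %in% c(0L, 1L))) stop("plate CSV must be 0/1 coded")
  dpcr_plate(matrix(m == 1L, nrow = nrow(m),
                    dimnames = list(NULL, colnames(df))))
}

#' Write a plate to CSV
#' @param plate A [dpcr_plate()].
#' @param path Output path.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(as.data.frame(plate$positivity * 1L), path,
                   row.names = FALSE)
  invisible(path)
}

#' Poisson copy-number estimate from partition positivity
#'
#' With observed positive proportion `p`, the mean molecules per partition
#' is `lambda = -ln(1 - p)` and copies per reaction `lambda * n`. The
#' 95\% (by default) confidence interval propagates the binomial error on
#' `p` through the log transform (delta method).
#'
#' @param n_positive Positive partitions (`0 <= n_positive <= n_partitions`).
#' @param n_partitions Total partitions.
#' @param conf Confidence level.
#' @return Object of class `copy_estimate`: list with `lambda`, `copies`,
#'   `ci_low`, `ci_high`, `n_positive`, `n_partitions`.
#' @export
estimate_copies <- function(n_positive, n_partitions, conf = 0.95) {
  stopifnot(n_positive >= 0, n_positive <= n_partitions, n_partitions > 0)
  if (n_positive == n_partitions) {
    stop("saturated plate: all partitions positive, lambda undefined")
  }
  p <- n_positive / n_partitions
  lambda <- -log1p(-p)
  se_lambda <- sqrt(p * (1 - p) / n_partitions) / (1 - p)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(lambda = lambda, copies = lambda * n_partitions,
                 ci_low = max(0, (lambda - z * se_lambda)) * n_partitions,
                 ci_high = (lambda + z * se_lambda) * n_partitions,
                 se_lambda = se_lambda,
                 n_positive = n_positive, n_partitions = n_partitions),
            class = "copy_estimate")
}

#' Per-channel copy estimates for a plate
#' @param plate A [dpcr_plate()].
#' @param conf Confidence level.
#' @return `data.frame` with one row per channel: `channel, n_positive,
#'   positivity_pct, lambda, copies, ci_low, ci_high`.
#' @export
estimate_copies_plate <- function(plate, conf = 0.95) {
  rows <- lapply(colnames(plate$positivity), function(ch) {
    npos <- sum(plate$positivity[, ch])
    e <- estimate_copies(npos, plate$n_partitions, conf)
    data.frame(channel = ch, n_positive = npos,
               positivity_pct = 100 * npos / plate$n_partitions,
               lambda = e$lambda, copies = e$copies,
               ci_low = e$ci_low, ci_high = e$ci_high)
  })
  do.call(rbind, rows)
}

#' Ratio of two copy estimates
#'
#' Point ratio `a/b` with a delta-method confidence interval from the two
#' lambda standard errors (independent plates/channels assumed).
#'
#' @param a,b [estimate_copies()] results; `b` must have positive copies.
#' @param conf Confidence level.
#' @return List with `ratio`, `ci_low`, `ci_high`.
#' @export
copy_ratio <- function(a, b, conf = 0.95) {
  if (b$copies <= 0) stop("reference estimate has zero copies")
  ratio <- a$copies / b$copies
  if (a$copies == 0) return(list(ratio = 0, ci_low = 0, ci_high = 0))
  cv2 <- (a$se_lambda / a$lambda)^2 + (b$se_lambda / b$lambda)^2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- ratio * sqrt(cv2)
  list(ratio = ratio, ci_low = max(0, ratio - z * se), ci_high = ratio + z * se)
}

#' Two-channel partition summary (2D analysis)
#'
#' Counts of double-positive (DPP), single-positive (SPP) and
#' all-negative partitions for a channel pair, with each category also as
#' percent of total partitions (the "2D \%PP" metric).
#'
#' @param plate A [dpcr_plate()].
#' @param a,b Channel names present on the plate.
#' @return Object of class `pair_summary` (also a one-row `data.frame`):
#'   `channel_a, channel_b, n_dpp, n_spp_a, n_spp_b, n_neg, pct_dpp,
#'   pct_spp_a, pct_spp_b`.
#' @export
pair_summary <- function(plate, a, b) {
  pos <- plate$positivity
  if (!all(c(a, b) %in% colnames(pos))) {
    stop("channel not on plate: ", paste(setdiff(c(a, b), colnames(pos)), collapse = ","))
  }
  pa <- pos[, a]
  pb <- pos[, b]
  n <- plate$n_partitions
  out <- data.frame(channel_a = a, channel_b = b,
                    n_dpp = sum(pa & pb), n_spp_a = sum(pa & !pb),
                    n_spp_b = sum(!pa & pb), n_neg = sum(!pa & !pb))
  out$pct_dpp <- 100 * out$n_dpp / n
  out$pct_spp_a <- 100 * out$n_spp_a / n
  out$pct_spp_b <- 100 * out$n_spp_b / n
  structure(out, class = c("pair_summary", "data.frame"), n_partitions = n)
}

#' Linked-fraction inference from a pair summary
#'
#' Duplex-dPCR algebra on the three negative proportions. With
#' `P(A-) = (n_neg + n_spp_b)/n`, `P(B-) = (n_neg + n_spp_a)/n` and
#' `P(AB-) = n_neg/n`, independent Poisson loading of linked and free
#' molecules gives `lambda_linked = ln(P(AB-) / (P(A-) P(B-)))` (clamped
#' at 0) and `lambda_free_a = -ln P(A-) - lambda_linked` (and analogously
#' for B; clamped at 0 with a warning on degenerate input). The linked
#' fraction per channel is `lambda_linked / (lambda_linked +
#' lambda_free)`.
#'
#' Raw 2D \%PP values (in the input summary) are the primary descriptive
#' report; this model-based estimate corrects the DPP count for chance
#' co-localisation of two free molecules in one partition.
#'
#' @param s A [pair_summary()].
#' @return List of class `linkage_estimate`: `lambda_linked,
#'   lambda_free_a, lambda_free_b, linked_fraction_a, linked_fraction_b`.
#' @export
estimate_linkage <- function(s) {
  n <- s$n_dpp + s$n_spp_a + s$n_spp_b + s$n_neg
  if (s$n_neg == 0L) stop("saturated plate: no negative partitions")
  p_a_neg <- (s$n_neg + s$n_spp_b) / n
  p_b_neg <- (s$n_neg + s$n_spp_a) / n
  p_ab_neg <- s$n_neg / n
  lambda_linked <- max(0, log(p_ab_neg / (p_a_neg * p_b_neg)))
  free_a <- -log(p_a_neg) - lambda_linked
  free_b <- -log(p_b_neg) - lambda_linked
  if (free_a < 0 || free_b < 0) {
    warning("degenerate input: negative free lambda clamped at 0")
  }
  free_a <- max(0, free_a)
  free_b <- max(0, free_b)
  lf <- function(free) {
    if (lambda_linked + free > 0) lambda_linked / (lambda_linked + free) else NA_real_
  }
  structure(list(lambda_linked = lambda_linked, lambda_free_a = free_a,
                 lambda_free_b = free_b, linked_fraction_a = lf(free_a),
                 linked_fraction_b = lf(free_b)),
            class = "linkage_estimate")
}

#' Positivity quality-control verdict
#'
#' Samples are diluted so that per-channel positivity falls in the 20-80\%
#' window where both 1D copy estimation and 2D linkage analysis are
#' informative; bounds are inclusive.
#'
#' @param plate A [dpcr_plate()].
#' @param channel Channel name.
#' @param bounds Length-2 numeric, percent positivity window.
#' @return List: `channel`, `positivity_pct`, `pass`.
#' @export
qc_positivity <- function(plate, channel, bounds = c(20, 80)) {
  if (!channel %in% colnames(plate$positivity)) stop("channel not on plate: ", channel)
  pct <- 100 * mean(plate$positivity[, channel])
  list(channel = channel, positivity_pct = pct,
       pass = pct >= bounds[1L] && pct <= bounds[2L])
}

#' Comparative Ct relative quantification
#'
#' `RQ = 2^-ddCt` with `ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,baseline - Ct_ref,baseline)`.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_baseline,ct_ref_baseline
#'   Cycle-threshold values.
#' @param percent If `TRUE`, return percent of baseline (RQ x 100).
#' @return Relative quantity (or percent baseline).
#' @export
relative_quant_ddct <- function(ct_target_sample, ct_ref_sample,
                                ct_target_baseline, ct_ref_baseline,
                                percent = FALSE) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_baseline, ct_ref_baseline)
  if (!all(is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_baseline - ct_ref_baseline)
  rq <- 2^(-ddct)
  if (percent) 100 * rq else rq
}
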