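# Synthetic RH panel generator.
#
# The generative model implements the chromatin-openness working hypothesis
# directly: each bin carries an openness score omega > 0 that drives both
# somatic break/repair and meiotic crossing-over.  Per informative line and
# bin, the number of radiation-induced deletions is Poisson with rate
# lambda * omega * size_mb.  A deletion starts uniformly within its bin and
# extends in a random direction with a position-dependent hazard
# omega(x) / mu per Mb - equivalently, its extent is Exponential(mean mu)
# in the cumulative-openness coordinate Omega(x) - truncated at the arm
# boundaries (deletions never cross the centromere).  Within a homogeneous
# bin this reduces to an Exponential physical length of mean mu / omega_b;
# across bins it keeps the stationary per-marker deletion probability at
# exactly 1 - exp(-lambda * mu) irrespective of omega (number ~ omega, size
# ~ 1/omega cancel), reproducing the evenly-distributed deletion frequency
# of the real panel, while open bins accumulate many small deletions and
# compact bins few large ones.  Genetic spans are cM_b = rho * omega_b *
# size_mb with Poisson counting noise over a notional F2.

#' Simulation configuration for a synthetic RH panel
#'
#' @param seed integer seed; the whole panel is reproducible from it.
#' @param n_lines panel size (default 92).
#' @param bins data frame with `bin_name`, `arm` (S/L), `frac_start`,
#'   `frac_end`, `size_mb`, `omega` (openness, > 0); optional `cm_override`.
#' @param markers_per_bin integer vector (one per bin) of marker counts, or
#'   `NULL` to place `markers_per_mb * size_mb` markers per bin.
#' @param markers_per_mb marker density used when `markers_per_bin` is
#'   `NULL`.
#' @param marker_placement `"uniform"` scatters marker positions uniformly
#'   within each bin; `"even"` spaces them regularly (useful for designs
#'   that must guarantee a minimum inter-locus distance).
#' @param anchor_fraction fraction of each bin's markers flagged as anchors
#'   (at least one per bin).
#' @param class_mix named proportions for INTACT / WHOLE_LOSS /
#'   SUPRA_ARM_LOSS / INFORMATIVE lines; must sum to 1.
#' @param lambda deletion-initiation rate per Mb per unit openness.
#' @param mu mean deletion extent in openness-weighted Mb; within a bin of
#'   openness `omega` the mean physical deletion length is `mu / omega`.
#' @param rho crossing-over rate (cM per Mb per unit openness).
#' @param epsilon per-call assay error (flip) probability.
#' @param missing_rate per-call missing probability (applied after flips).
#' @param f2_size notional F2 population behind the genetic map.
#' @return validated config list of class `rh_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_lines = 92L, bins,
                       markers_per_bin = NULL, markers_per_mb = 0.6,
                       marker_placement = c("uniform", "even"),
                       anchor_fraction = 0.24,
                       class_mix = c(INTACT = 13, WHOLE_LOSS = 9,
                                     SUPRA_ARM_LOSS = 8,
                                     INFORMATIVE = 62) / 92,
                       lambda = 0.003, mu = 26.4, rho = 0.2,
                       epsilon = 0, missing_rate = 0.01,
                       f2_size = 300L) {
  bins <- validate_bin_table(bins)
  stopifnot(!is.null(bins$omega), all(bins$omega > 0))
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) == c("INTACT", "WHOLE_LOSS",
                                      "SUPRA_ARM_LOSS", "INFORMATIVE")))
  stopifnot(lambda >= 0, mu > 0, rho >= 0, epsilon >= 0, epsilon <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(markers_per_bin))
    stopifnot(length(markers_per_bin) == nrow(bins), all(markers_per_bin >= 1))
  else if (any(round(markers_per_mb * bins$size_mb) < 1))
    stop("bin(s) too small to hold a marker at this density: ",
         paste(bins$bin_name[round(markers_per_mb * bins$size_mb) < 1],
               collapse = ", "))
  marker_placement <- match.arg(marker_placement)
  structure(list(seed = as.integer(seed), n_lines = as.integer(n_lines),
                 bins = bins, markers_per_bin = markers_per_bin,
                 markers_per_mb = markers_per_mb,
                 marker_placement = marker_placement,
                 anchor_fraction = anchor_fraction, class_mix = class_mix,
                 lambda = lambda, mu = mu, rho = rho, epsilon = epsilon,
                 missing_rate = missing_rate, f2_size = as.integer(f2_size)),
            class = "rh_sim_config")
}

#' Wheat-3B-like simulation preset
#'
#' A configuration emulating the published 92-line chromosome 3B panel: the
#' 11 tabulated deletion bins with their physical sizes and marker counts,
#' openness proportional to the per-bin BR frequency (normalised to a
#' size-weighted mean of 1), and rates calibrated so that an informative
#' line carries on average 2.8 deletions of mean length 26.4 Mb, giving a
#' panel-wide retention near 0.8 and per-line informative retention near
#' 0.92.  Assay flips are off by default (the real panel was genotyped in
#' duplicate with PCR failure controls); 1% of calls are missing.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return an `rh_sim_config`.
#' @export
wheat3b_preset <- function(seed = 1L, ...) {
  ref <- load_wheat3b_tables()$bins
  b <- ref[ref$bin_name != "Chr",
           c("bin_name", "arm", "frac_start", "frac_end", "size_mb")]
  br <- ref$print_br[ref$bin_name != "Chr"]
  b$omega <- br * sum(b$size_mb) / sum(br * b$size_mb)
  total_mb <- sum(b$size_mb)           # 891 Mb over the 11 tabulated bins
  # lambda is calibrated above the nominal 2.8 / total_mb because a fraction
  # of generated deletions covers no marker at the panel's marker density;
  # the factor makes the *observed* deletions per informative line match 2.8
  defaults <- list(seed = seed, bins = b,
                   markers_per_bin = ref$n_markers[ref$bin_name != "Chr"],
                   anchor_fraction = 128 / 541,
                   lambda = 1.15 * 2.8 / total_mb, mu = 26.4,
                   rho = 179 / total_mb,
                   epsilon = 0, missing_rate = 0.01)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Simulate a radiation hybrid panel
#'
#' Draws a full panel under the configuration's generative model (see the
#' package overview): marker placement, line classes, deletions, assay
#' noise and a bin-level genetic map.  Bit-reproducible for a fixed seed.
#'
#' @param config an `rh_sim_config` from [sim_config()] or
#'   [wheat3b_preset()].
#' @return list of class `rh_sim` with elements `genotypes`
#'   ([rh_genotypes]), `marker_info` (as [read_marker_info()]), `bins` (bin
#'   table with simulated `map_cM` and `n_markers`) and `truth` (marker
#'   positions and order, per-line classes, planted deletion intervals,
#'   per-bin openness and expected centiRay positions).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "rh_sim_config"))
  set.seed(config$seed)
  bins <- config$bins[match(bin_chrom_order(config$bins),
                            config$bins$bin_name), ]
  bins$chrom_end <- cumsum(bins$size_mb)
  bins$chrom_start <- bins$chrom_end - bins$size_mb
  arm_break <- max(bins$chrom_end[bins$arm == "S"])
  total_mb <- max(bins$chrom_end)
  arm_range <- function(arm)
    if (arm == "S") c(0, arm_break) else c(arm_break, total_mb)
  # cumulative openness coordinate (piecewise linear, strictly increasing)
  knots <- c(bins$chrom_start, total_mb)
  omknots <- cumsum(c(0, bins$omega * bins$size_mb))
  Omega <- function(x) {
    j <- pmin(findInterval(x, knots, rightmost.closed = TRUE), nrow(bins))
    omknots[j] + (x - knots[j]) * bins$omega[j]
  }
  Omega_inv <- function(u) {
    j <- pmin(findInterval(u, omknots, rightmost.closed = TRUE), nrow(bins))
    knots[j] + (u - omknots[j]) / bins$omega[j]
  }

  # --- markers ---------------------------------------------------------------
  n_b <- if (!is.null(config$markers_per_bin))
    config$markers_per_bin[match(bins$bin_name, config$bins$bin_name)]
  else round(config$markers_per_mb * bins$size_mb)
  n_mk <- sum(n_b)
  pos <- unlist(lapply(seq_len(nrow(bins)), function(j) {
    if (identical(config$marker_placement, "even"))
      bins$chrom_start[j] + (seq_len(n_b[j]) - 0.5) / n_b[j] * bins$size_mb[j]
    else sort(stats::runif(n_b[j], bins$chrom_start[j], bins$chrom_end[j]))
  }))
  mk_bin <- rep(bins$bin_name, n_b)
  mk_arm <- rep(bins$arm, n_b)
  cls_prob <- c(ISBP = 96, SSR = 19, DArT = 426) / 541
  mk_class <- sample(names(cls_prob), n_mk, replace = TRUE, prob = cls_prob)
  prefix <- c(ISBP = "cfp", SSR = "barc", DArT = "wPt-")
  ids <- sprintf("%s%04d", prefix[mk_class], sample.int(9999L, n_mk))
  is_anchor <- unlist(lapply(seq_len(nrow(bins)), function(j) {
    k <- max(1L, round(config$anchor_fraction * n_b[j]))
    ix <- rep(FALSE, n_b[j]); ix[sample.int(n_b[j], k)] <- TRUE; ix
  }))

  # --- line classes ----------------------------------------------------------
  counts <- round(config$class_mix * config$n_lines)
  while (sum(counts) > config$n_lines) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  while (sum(counts) < config$n_lines) counts[which.max(counts)] <-
      counts[which.max(counts)] + 1L
  classes <- sample(rep(names(counts), counts))
  line_ids <- sprintf("RH%03d", seq_len(config$n_lines))

  # --- deletions -------------------------------------------------------------
  calls <- matrix(1L, config$n_lines, n_mk,
                  dimnames = list(line_ids, ids))
  deletions <- list()
  for (i in seq_len(config$n_lines)) {
    cl <- classes[i]
    if (cl == "INTACT") next
    if (cl == "WHOLE_LOSS") {
      calls[i, ] <- 0L
      deletions[[length(deletions) + 1L]] <-
        data.frame(line_id = line_ids[i], start_mb = 0, end_mb = total_mb)
      next
    }
    if (cl == "SUPRA_ARM_LOSS") {
      lost <- sample(c("S", "L"), 1L)
      other <- arm_range(setdiff(c("S", "L"), lost))
      ext <- stats::runif(1L, 0, diff(other))
      iv <- if (lost == "S") c(0, arm_break + ext) else
        c(arm_break - ext, total_mb)
    } else {
      iv <- NULL
      for (j in seq_len(nrow(bins))) {
        k <- stats::rpois(1L, config$lambda * bins$omega[j] * bins$size_mb[j])
        if (k == 0L) next
        s <- stats::runif(k, bins$chrom_start[j], bins$chrom_end[j])
        ext <- stats::rexp(k, 1 / config$mu)      # extent in openness units
        dir <- sample(c(-1, 1), k, replace = TRUE)
        arm <- arm_range(bins$arm[j])
        e <- Omega_inv(pmin(pmax(Omega(s) + dir * ext, Omega(arm[1L])),
                            Omega(arm[2L])))
        iv <- rbind(iv, cbind(pmin(s, e), pmax(s, e)))
      }
      if (is.null(iv)) next
    }
    iv <- matrix(iv, ncol = 2L)
    for (r in seq_len(nrow(iv))) {
      calls[i, pos >= iv[r, 1L] & pos <= iv[r, 2L]] <- 0L
      deletions[[length(deletions) + 1L]] <-
        data.frame(line_id = line_ids[i], start_mb = iv[r, 1L],
                   end_mb = iv[r, 2L])
    }
  }

  # --- assay noise -----------------------------------------------------------
  if (config$epsilon > 0) {
    flip <- matrix(stats::runif(length(calls)) < config$epsilon, nrow(calls))
    calls[flip] <- 1L - calls[flip]
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow(calls))
    calls[miss] <- NA_integer_
  }

  # --- genetic map -----------------------------------------------------------
  exp_cm <- if (!is.null(bins$cm_override)) bins$cm_override else
    config$rho * bins$omega * bins$size_mb
  co_counts <- stats::rpois(nrow(bins), config$f2_size * exp_cm / 100)
  bins$map_cM <- 100 * co_counts / config$f2_size
  bins$n_markers <- n_b

  # --- truth & expected centiRay positions -----------------------------------
  dOm <- diff(Omega(pos))          # adjacent gaps in openness units
  same_arm <- mk_arm[-1L] == mk_arm[-n_mk]
  exp_disc <- expected_discordance(ifelse(same_arm, dOm, Inf), 1,
                                   config$lambda, config$mu)
  truth <- list(
    markers = data.frame(marker_id = ids, pos_mb = pos, bin_name = mk_bin,
                         arm = mk_arm, order = seq_len(n_mk),
                         pos_cr_expected = cumsum(c(0, 100 * exp_disc)),
                         stringsAsFactors = FALSE),
    lines = data.frame(line_id = line_ids, class = classes,
                       stringsAsFactors = FALSE),
    deletions = if (length(deletions)) do.call(rbind, deletions) else
      data.frame(line_id = character(0), start_mb = numeric(0),
                 end_mb = numeric(0)),
    bins = bins)
  marker_info <- data.frame(
    marker_id = ids, marker_class = mk_class, is_anchor = is_anchor,
    bin_name = ifelse(is_anchor, mk_bin, NA_character_),
    contig_id = NA_character_, physical_bp = NA_real_,
    stringsAsFactors = FALSE)
  structure(list(genotypes = rh_genotypes(calls),
                 marker_info = marker_info,
                 bins = bins[, c("bin_name", "arm", "frac_start", "frac_end",
                                 "size_mb", "map_cM", "n_markers")],
                 truth = truth),
            class = "rh_sim")
}

#' True-order map of a simulated panel
#'
#' Builds an [rh_map] directly from the simulator's ground truth: one locus
#' per marker in true chromosome order, with positions either the physical
#' Mb coordinates (`scale = "mb"`; deletion sizes from [call_deletions()]
#' then come out in Mb with a unit resolution) or the expected cumulative
#' centiRay positions of the deletion model (`scale = "expected_cr"`).
#' Useful for validating the inference pipeline against the generating
#' truth.
#'
#' @param sim an `rh_sim` from [simulate_panel()].
#' @param scale position scale, see above.
#' @return an [rh_map] with `bin_spans` attached (resolution 1 on the Mb
#'   scale).
#' @export
true_marker_map <- function(sim, scale = c("mb", "expected_cr")) {
  scale <- match.arg(scale)
  tmk <- sim$truth$markers[order(sim$truth$markers$order), ]
  pos <- if (scale == "mb") tmk$pos_mb else tmk$pos_cr_expected
  members <- stats::setNames(as.list(tmk$marker_id), tmk$marker_id)
  map <- new_rh_map(tmk$marker_id, pos, rep(TRUE, nrow(tmk)), members,
                    bin_name = tmk$bin_name)
  if (scale == "mb") {
    bins <- sim$truth$bins
    attr(map, "bin_spans") <- data.frame(
      bin_name = bins$bin_name, cr_start = bins$chrom_start,
      cr_end = bins$chrom_end, map_cR = bins$size_mb,
      resolution = 1, stringsAsFactors = FALSE)
  }
  map
}

#' Expected discordance between two loci under the deletion model
#'
#' Closed form for the stationary Poisson/Exponential deletion field of the
#' simulator: with initiation rate `lambda * omega` per Mb, mean length
#' `m = mu / omega` and `q = exp(-lambda * mu)` the probability that exactly
#' one of two loci `d` Mb apart (same arm) is deleted is
#' `2 * (q - q^(2 - exp(-d / m)))`.  `d = Inf` (e.g. across the centromere)
#' gives the independence limit `2 q (1 - q)`.  The first-order
#' approximation `2 * lambda * mu * (1 - exp(-d * omega / mu))` is available
#' for reference.
#'
#' @param d_mb distance(s) in Mb (may be `Inf`).
#' @param omega openness of the surrounding bin.
#' @param lambda,mu simulator rates, see [sim_config()].
#' @param approx use the first-order approximation.
#' @return expected discordance probability (multiply by 100 for cR).
#' @export
expected_discordance <- function(d_mb, omega, lambda, mu, approx = FALSE) {
  if (approx) return(2 * lambda * mu * (1 - exp(-d_mb * omega / mu)))
  q <- exp(-lambda * mu)
  2 * (q - q^(2 - exp(-d_mb * omega / mu)))
}
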