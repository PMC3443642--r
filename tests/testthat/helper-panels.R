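# shared fixtures and utilities, all built in code

# genotype matrix from compact strings ("1", "0", "N" per call)
g_from_strings <- function(rows, line_ids = NULL, marker_ids = NULL) {
  cells <- do.call(rbind, strsplit(rows, ""))
  m <- matrix(NA_integer_, nrow(cells), ncol(cells))
  m[cells == "1"] <- 1L
  m[cells == "0"] <- 0L
  rownames(m) <- line_ids %||% sprintf("L%02d", seq_len(nrow(m)))
  colnames(m) <- marker_ids %||% sprintf("m%02d", seq_len(ncol(m)))
  rh_genotypes(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of a vector (for exhaustive-order oracles)
perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms(v[-i]), function(p) c(v[i], p))))
}

# single-arm panel with well-separated, evenly spaced loci; strong breakage
# so that adjacent linkage dominates sampling noise
oracle_config <- function(seed, n_loci = 7, n_lines = 200) {
  bins <- data.frame(bin_name = "B1", arm = "S", frac_start = 0,
                     frac_end = 1, size_mb = 100, omega = 1)
  sim_config(seed = seed, n_lines = n_lines, bins = bins,
             markers_per_bin = n_loci, marker_placement = "even",
             class_mix = c(INTACT = 0.1, WHOLE_LOSS = 0.05,
                           SUPRA_ARM_LOSS = 0, INFORMATIVE = 0.85),
             lambda = 0.012, mu = 15, missing_rate = 0.02, epsilon = 0)
}

# two arms x two bins, spacing 0.4 deletion lengths: the well-powered
# parameter-recovery design (adjacent expected discordance ~ 18% among
# informative lines, far above the 5% floor)
recovery_config <- function(seed, per_bin = 6, n_lines = 92) {
  bins <- data.frame(bin_name = c("S2", "S1", "L1", "L2"),
                     arm = c("S", "S", "L", "L"),
                     frac_start = c(0.5, 0, 0, 0.5),
                     frac_end = c(1, 0.5, 0.5, 1),
                     size_mb = 4.8 * per_bin, omega = 1)
  sim_config(seed = seed, n_lines = n_lines, bins = bins,
             markers_per_bin = rep(per_bin, 4), marker_placement = "even",
             class_mix = c(INTACT = 0.1, WHOLE_LOSS = 0.05,
                           SUPRA_ARM_LOSS = 0.05, INFORMATIVE = 0.8),
             lambda = 0.5 / 12, mu = 12, anchor_fraction = 0.5,
             missing_rate = 0.02)
}

# ten bins whose openness spans a 10-fold range (or is constant, for the
# null), shared driver of break/repair and crossing over
openness_config <- function(seed, tenfold = TRUE) {
  nb <- 10
  om <- if (tenfold) exp(seq(log(0.316), log(3.16), length.out = nb)) else
    rep(1, nb)
  sz <- rep(40, nb)
  om <- om * sum(sz) / sum(om * sz)
  bins <- data.frame(bin_name = sprintf("B%02d", 1:nb),
                     arm = rep(c("S", "L"), each = 5),
                     frac_start = c(rev(seq(0, 0.8, by = 0.2)),
                                    seq(0, 0.8, by = 0.2)),
                     frac_end = c(rev(seq(0.2, 1, by = 0.2)),
                                  seq(0.2, 1, by = 0.2)),
                     size_mb = sz, omega = om)
  sim_config(seed = seed, n_lines = 92, bins = bins,
             markers_per_bin = rep(12, nb), marker_placement = "even",
             anchor_fraction = 0.5, lambda = 0.012, mu = 20, rho = 0.2,
             missing_rate = 0.01, f2_size = 600)
}

# per-bin BR frequency recovered by the full pipeline vs the simulated CO
# frequency, as one Pearson test
br_co_test <- function(cfg) {
  sim <- simulate_panel(cfg)
  map <- suppressWarnings(build_framework_map(sim$genotypes,
                                              sim$marker_info,
                                              bins = sim$bins))
  map <- suppressWarnings(assign_bins(map, sim$marker_info))
  spans <- attr(map, "bin_spans")
  b <- merge(spans, sim$bins[, c("bin_name", "size_mb", "map_cM")],
             by = "bin_name")
  pearson_cor((b$map_cR / 2) / b$size_mb, b$map_cM / b$size_mb)
}

# markers thinned so consecutive kept markers are >= min_cr apart in
# panel-scale expected centiRays (expected discordance scaled by the
# informative-line fraction, the only class that witnesses breakage)
thin_markers <- function(sim, min_cr = 5) {
  tmk <- sim$truth$markers
  f_inf <- mean(sim$truth$lines$class == "INFORMATIVE")
  ecr <- tmk$pos_cr_expected * f_inf
  sel <- integer(0)
  last <- -Inf
  for (i in seq_len(nrow(tmk)))
    if (ecr[i] - last >= min_cr) { sel <- c(sel, i); last <- ecr[i] }
  list(idx = sel, marker_id = tmk$marker_id[sel], expected_cr = ecr[sel])
}

# Kendall tau between the true marker order and mapped positions
map_truth_tau <- function(sim, map, markers = NULL) {
  tmk <- sim$truth$markers[order(sim$truth$markers$order), ]
  ids <- markers %||% tmk$marker_id
  ids <- ids[order(match(ids, tmk$marker_id))]
  col <- collapse_cosegregating(sim$genotypes)
  pos <- stats::setNames(map$position_cR, map$locus_id)[col$locus_of[ids]]
  suppressWarnings(stats::cor(seq_along(ids), unname(pos),
                              method = "kendall"))
}

# printed-cell consistency: a printed table cell agrees with the formula if
# it lies within one unit in its last printed digit of the formula evaluated
# at some inputs consistent with their own printed rounding
print_consistent <- function(printed, f, inputs, input_ulps) {
  if (is.na(printed)) return(TRUE)
  ulp <- 10^(-decimals(printed))
  corners <- expand.grid(lapply(seq_along(inputs), function(i)
    c(inputs[[i]] - input_ulps[[i]] / 2, inputs[[i]] + input_ulps[[i]] / 2)))
  vals <- apply(corners, 1L, function(ro) do.call(f, unname(as.list(ro))))
  printed >= min(vals) - ulp && printed <= max(vals) + ulp
}
decimals <- function(x) {
  s <- format(x, trim = TRUE)
  if (!grepl("\\.", s)) 0L else nchar(sub(".*\\.", "", s))
}
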