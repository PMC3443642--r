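tabs <- load_wheat3b_tables()
bins_ref <- tabs$bins[tabs$bins$bin_name != "Chr", ]
chr_ref <- tabs$bins[tabs$bins$bin_name == "Chr", ]

test_that("per-bin metrics reproduce the published derived cells", {
  m <- compute_bin_metrics(rbind(bins_ref, chr_ref)[, c("bin_name",
                                                        "n_markers",
                                                        "size_mb", "map_cR",
                                                        "map_cM")])
  # spot values quoted in the text
  expect_equal(m$br_freq[m$bin_name == "3BS2"], 36.7 / 2 / 4,
               tolerance = 1e-12)
  expect_equal(round(m$br_freq[m$bin_name == "3BS2"], 1), 4.6)
  expect_equal(round(m$resolution_gen[m$bin_name == "3BS3"], 1), 10.8)
  expect_equal(compute_bin_metrics(data.frame(bin_name = "x", size_mb = 10,
                                              map_cR = 10))$resolution_rh, 1)

  # every printed cell is consistent with the formula applied to inputs
  # within their own print rounding (several genetic cells were printed from
  # unrounded cM spans, so the inputs are interval-valued)
  printed <- rbind(bins_ref, chr_ref)
  for (i in seq_len(nrow(printed))) {
    row <- printed[i, ]
    expect_true(print_consistent(row$print_saturation,
                                 function(s, n) s / n,
                                 list(row$size_mb, row$n_markers),
                                 list(1, 0)),
                info = paste(row$bin_name, "saturation"))
    expect_true(print_consistent(row$print_br,
                                 function(cr, s) (cr / 2) / s,
                                 list(row$map_cR, row$size_mb),
                                 list(0.1, 1)),
                info = paste(row$bin_name, "BR"))
    expect_true(print_consistent(row$print_res_rh,
                                 function(s, cr) s / cr,
                                 list(row$size_mb, row$map_cR),
                                 list(1, 0.1)),
                info = paste(row$bin_name, "resolution Mb/cR"))
    expect_true(print_consistent(row$print_co,
                                 function(cm, s) cm / s,
                                 list(row$map_cM, row$size_mb),
                                 list(0.1, 1)),
                info = paste(row$bin_name, "CO"))
    expect_true(print_consistent(row$print_res_gen,
                                 function(s, cm) s / cm,
                                 list(row$size_mb, row$map_cM),
                                 list(1, 0.1)),
                info = paste(row$bin_name, "resolution Mb/cM"))
    expect_true(print_consistent(row$print_ratio,
                                 function(cr, cm) cr / cm,
                                 list(row$map_cR, row$map_cM),
                                 list(0.1, 0.1)),
                info = paste(row$bin_name, "cR/cM"))
  }
})

test_that("metric identities hold on arbitrary inputs", {
  set.seed(4)
  b <- data.frame(bin_name = letters[1:6],
                  size_mb = runif(6, 5, 200), map_cR = runif(6, 10, 500),
                  map_cM = runif(6, 0.5, 100), n_markers = sample(3:50, 6))
  m <- compute_bin_metrics(b)
  expect_equal(m$resolution_rh * m$map_cR, m$size_mb, tolerance = 1e-12)
  expect_equal(m$br_freq, m$map_cR / (2 * m$size_mb), tolerance = 1e-12)
  expect_equal(m$ratio_cr_per_cm, m$resolution_gen / m$resolution_rh,
               tolerance = 1e-12)
  # chromosome totals are totals-based, not means of bin values
  tot <- chromosome_metrics(b)
  expect_equal(tot$resolution_rh, sum(b$size_mb) / sum(b$map_cR))
  # absent genetic spans give NA genetic metrics
  m2 <- compute_bin_metrics(data.frame(bin_name = "3BS2", size_mb = 4,
                                       map_cR = 36.7))
  expect_true(is.na(m2$resolution_gen) && is.na(m2$co_freq))
})

test_that("uniformity folds match the published comparison", {
  # genetic: extremes 1.2 and 167.1 around the 5.5 average -> ~30-fold
  expect_equal(uniformity_fold(c(1.2, 167.1), 992 / 179), 30.15,
               tolerance = 0.01)
  # RH: extremes 0.1 and 1.8 around 0.53 -> ~5-fold
  rh <- uniformity_fold(c(0.1, 1.8), 992 / 1871.9)
  expect_equal(rh, 5.3, tolerance = 0.01)
  expect_equal(uniformity_fold(c(2, 2, 2), 2), 1)
  expect_error(uniformity_fold(c(1, 2), 0), "zero")

  ref <- wheat3b_reference_analysis()
  expect_equal(ref$uniformity$rh_fold, 5.3, tolerance = 0.01)
  expect_gt(ref$uniformity$uniformity_gain, 5)   # "six fold more uniform"
  expect_lt(ref$uniformity$uniformity_gain, 7)
})

test_that("contig spans and orientability follow the published table", {
  cm <- contig_metrics(tabs$contigs)
  expect_equal(sum(cm$orientable), 9L)
  expect_equal(cm$resolution[cm$contig_id == "Ctg0954"], 2.6 / 311.5,
               tolerance = 1e-9)
  expect_equal(round(cm$resolution[cm$contig_id == "Ctg0954"], 2), 0.01)
  # every printed within-contig resolution is consistent with its printed
  # size and span (some cells were printed from unrounded spans)
  for (i in which(!is.na(tabs$contigs$print_resolution))) {
    row <- tabs$contigs[i, ]
    expect_true(print_consistent(row$print_resolution,
                                 function(s, cr) s / cr,
                                 list(row$size_mb, row$span_cR),
                                 list(0.1, 0.1)),
                info = row$contig_id)
  }

  # two markers at identical positions cannot orient a contig
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tlocus_id\tposition_cR\tframework\tbin_name",
               "A\tA\t0\tTRUE\tb", "B\tA\t0\tTRUE\tb", "C\tC\t9\tTRUE\tb"),
             path)
  map <- read_rh_map(path)
  info <- data.frame(marker_id = c("A", "B", "C"), marker_class = "ISBP",
                     is_anchor = FALSE, bin_name = NA,
                     contig_id = c("ctg1", "ctg1", "ctg2"))
  cm2 <- contig_metrics(data.frame(contig_id = c("ctg1", "ctg2"),
                                   size_mb = c(1, 1),
                                   n_markers = c(2, 1), bin_name = "b"),
                        map, info)
  expect_false(cm2$orientable[cm2$contig_id == "ctg1"])
  expect_false(cm2$orientable[cm2$contig_id == "ctg2"])
})

test_that("marker density and placement error reproduce the worked examples", {
  d <- marker_density(1871.9, 541, 993)
  expect_equal(d$cr_per_marker, 3.46, tolerance = 0.005)
  expect_equal(d$mb_per_marker, 1.84, tolerance = 0.005)
  expect_equal(marker_density(100, 10, 50)$cr_per_marker, 10)

  expect_equal(placement_error(c(1103689, 1640531), 2170833, 993e6),
               100 * (2170833 - 1640531) / 993e6, tolerance = 1e-12)
  expect_equal(round(placement_error(c(1103689, 1640531), 2170833, 993e6),
                     2), 0.05)
  expect_equal(placement_error(c(10, 20), 15, 100), 0)
  expect_equal(placement_error(c(0, 0), 993e6, 993e6), 100)
})
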