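#' Per-bin map statistics
#'
#' From each bin's physical size (Mb), RH map span (cR), genetic map span
#' (cM, optional) and marker count, derives:
#' saturation (Mb per marker), RH resolution (Mb per cR), genetic resolution
#' (Mb per cM), breakage/repair frequency `BR = (cR / 2) / Mb` (one deletion
#' between two loci reflects two breaks, so half the cR span counts
#' break/repair events), crossing-over frequency `CO = cM / Mb`, and the
#' cR-per-cM ratio.  A chromosome-total row is treated like any other row
#' (totals-based averages: total Mb over total span).  Genetic statistics
#' are `NA` where `map_cM` is missing.
#'
#' Raw values are returned; `display` columns round to the conventional
#' print precision (one decimal, two for cR/cM ratios of 10 or more,
#' half-up).
#'
#' @param bins data frame with `bin_name`, `size_mb`, `map_cR` and
#'   optionally `map_cM`, `n_markers`.
#' @param display add display-rounded columns.
#' @return data frame of per-bin metrics.
#' @examples
#' compute_bin_metrics(data.frame(bin_name = "3BS2", size_mb = 4,
#'                                map_cR = 36.7, n_markers = 3))$br_freq
#' @export
compute_bin_metrics <- function(bins, display = TRUE) {
  stopifnot(all(bins$size_mb > 0), all(bins$map_cR >= 0))
  cm <- if (is.null(bins$map_cM)) rep(NA_real_, nrow(bins)) else bins$map_cM
  nm <- if (is.null(bins$n_markers)) rep(NA_real_, nrow(bins)) else
    bins$n_markers
  out <- data.frame(
    bin_name = bins$bin_name,
    n_markers = nm, size_mb = bins$size_mb,
    map_cR = bins$map_cR, map_cM = cm,
    saturation = bins$size_mb / nm,
    resolution_rh = bins$size_mb / bins$map_cR,
    br_freq = (bins$map_cR / 2) / bins$size_mb,
    resolution_gen = bins$size_mb / cm,
    co_freq = cm / bins$size_mb,
    ratio_cr_per_cm = bins$map_cR / cm,
    stringsAsFactors = FALSE)
  if (display) {
    rnd <- function(x, ratio = FALSE)
      ifelse(ratio & !is.na(x) & x >= 10, round_half_up(x, 2L),
             round_half_up(x, 1L))
    out$display_saturation <- rnd(out$saturation)
    out$display_resolution_rh <- rnd(out$resolution_rh)
    out$display_br_freq <- rnd(out$br_freq)
    out$display_resolution_gen <- rnd(out$resolution_gen)
    out$display_co_freq <- rnd(out$co_freq)
    out$display_ratio <- rnd(out$ratio_cr_per_cm, ratio = TRUE)
  }
  out
}

round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Chromosome totals from a bin table
#'
#' Sums size, spans and marker counts over bins and applies the per-bin
#' formulas to the totals (totals-based averages, not means of bin values).
#'
#' @param bins as in [compute_bin_metrics()].
#' @param bin_metrics passed through to [compute_bin_metrics()].
#' @return one-row metrics data frame with `bin_name = "total"`.
#' @export
chromosome_metrics <- function(bins, bin_metrics = TRUE) {
  tot <- data.frame(bin_name = "total",
                    size_mb = sum(bins$size_mb),
                    map_cR = sum(bins$map_cR),
                    map_cM = if (is.null(bins$map_cM)) NA_real_ else
                      sum(bins$map_cM, na.rm = TRUE),
                    n_markers = if (is.null(bins$n_markers)) NA_real_ else
                      sum(bins$n_markers))
  compute_bin_metrics(tot, display = bin_metrics)
}

#' Fold-deviation of a resolution metric from its chromosome average
#'
#' For bin values `m` and chromosome average `m_bar` the fold-deviation is
#' the maximum over bins of `max(m / m_bar, m_bar / m)`; the uniformity gain
#' of the RH map is the genetic fold divided by the RH fold.
#'
#' @param values per-bin metric values (`NA` dropped).
#' @param average the chromosome (totals-based) average of the metric.
#' @return largest fold-deviation.
#' @examples
#' uniformity_fold(c(1.2, 167.1), 5.5)   # ~30-fold
#' @export
uniformity_fold <- function(values, average) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need >= 2 bins with the metric defined")
  if (!is.finite(average) || average == 0) stop("zero chromosome average")
  max(pmax(values / average, average / values))
}

#' @rdname uniformity_fold
#' @param metrics data frame from [compute_bin_metrics()] (bins only).
#' @param chromosome one-row data frame from [chromosome_metrics()] (or the
#'   chromosome row of the input table).
#' @return `uniformity_report()`: list with `rh_fold`, `gen_fold`,
#'   `uniformity_gain`.
#' @export
uniformity_report <- function(metrics, chromosome) {
  rh <- uniformity_fold(metrics$resolution_rh, chromosome$resolution_rh)
  gen <- uniformity_fold(metrics$resolution_gen, chromosome$resolution_gen)
  list(rh_fold = rh, gen_fold = gen, uniformity_gain = gen / rh)
}

#' Per-contig span and resolution on the RH map
#'
#' A contig's span is the cR distance between its outermost mapped markers.
#' Contigs are orientable when they have at least two mapped markers at
#' distinct positions (span > 0); only then is a within-contig resolution
#' (Mb per cR) defined.
#'
#' @param contigs contig table (see [read_contig_table()]); used for sizes,
#'   marker counts and - when `map` is `NULL` - a precomputed `span_cR`
#'   column.
#' @param map optional [rh_map]; spans are then measured from the mapped
#'   positions of each contig's markers (`marker_info` links markers to
#'   contigs via `contig_id`).
#' @param marker_info marker metadata, required with `map`.
#' @return data frame `contig_id`, `size_mb`, `n_markers`, `span_cR`,
#'   `orientable`, `resolution` (Mb per cR, `NA` if not orientable).
#' @export
contig_metrics <- function(contigs, map = NULL, marker_info = NULL) {
  if (is.null(map)) {
    if (is.null(contigs$span_cR)) stop("need a map or a span_cR column")
    span <- contigs$span_cR
    nmapped <- contigs$n_markers
  } else {
    stopifnot(!is.null(marker_info$contig_id))
    members <- attr(map, "markers")
    pos_of <- stats::setNames(
      rep(map$position_cR, lengths(members[map$locus_id])),
      unlist(members[map$locus_id]))
    span <- nmapped <- numeric(nrow(contigs))
    for (j in seq_len(nrow(contigs))) {
      mk <- marker_info$marker_id[marker_info$contig_id %in%
                                    contigs$contig_id[j]]
      p <- pos_of[intersect(mk, names(pos_of))]
      nmapped[j] <- length(p)
      span[j] <- if (length(p)) max(p) - min(p) else NA_real_
    }
    none <- nmapped == 0L
    if (any(none)) {
      warning("contig(s) with no mapped marker skipped: ",
              paste(contigs$contig_id[none], collapse = ", "))
      contigs <- contigs[!none, ]; span <- span[!none]
      nmapped <- nmapped[!none]
    }
  }
  orientable <- span > 0 & nmapped >= 2L
  data.frame(contig_id = contigs$contig_id, size_mb = contigs$size_mb,
             n_markers = nmapped, span_cR = span, orientable = orientable,
             resolution = ifelse(orientable, contigs$size_mb / span,
                                 NA_real_),
             stringsAsFactors = FALSE)
}

#' Average marker density of a map
#'
#' @param total_cR total map length in cR.
#' @param n_markers number of mapped markers.
#' @param chromosome_mb physical chromosome size in Mb.
#' @return list with `cr_per_marker` and `mb_per_marker`.
#' @examples
#' marker_density(1871.9, 541, 993)   # one marker / 3.5 cR / 1.8 Mb
#' @export
marker_density <- function(total_cR, n_markers, chromosome_mb) {
  stopifnot(n_markers >= 1)
  list(cr_per_marker = total_cR / n_markers,
       mb_per_marker = chromosome_mb / n_markers)
}

#' Relative error of a physical locus placement
#'
#' Distance from the true position to the nearest edge of the predicted
#' interval (0 when inside), normalised so that an error of one whole
#' chromosome length is 100%.
#'
#' @param interval_bp length-2 numeric, predicted interval (bp).
#' @param true_bp true position (bp).
#' @param chromosome_bp chromosome length (bp).
#' @return percent error.
#' @examples
#' placement_error(c(1103689, 1640531), 2170833, 993e6)   # ~0.05%
#' @export
placement_error <- function(interval_bp, true_bp, chromosome_bp) {
  stopifnot(length(interval_bp) == 2L)
  lo <- min(interval_bp); hi <- max(interval_bp)
  d <- if (true_bp >= lo && true_bp <= hi) 0 else
    min(abs(true_bp - lo), abs(true_bp - hi))
  100 * d / chromosome_bp
}
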