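#' Convert a centiRay span to megabases
#'
#' One bin's physical-to-map conversion: span (cR) times the bin's
#' resolution (Mb per cR).
#'
#' @param span_cR centiRay span(s).
#' @param resolution_mb_per_cr bin resolution(s) in Mb per cR.
#' @return size in Mb.
#' @examples
#' cr_to_mb(120.2, 1.2)   # 144.24 Mb
#' cr_to_mb(13.1, 0.1)    # 1.31 Mb
#' @export
cr_to_mb <- function(span_cR, resolution_mb_per_cr) {
  stopifnot(all(span_cR >= 0))
  span_cR * resolution_mb_per_cr
}

#' Convert an interval on the cR axis to Mb across bin boundaries
#'
#' The interval is partitioned by the per-bin cR spans of a mapped
#' chromosome; each segment is multiplied by its bin's resolution and the
#' pieces are summed.
#'
#' @param lo,hi interval bounds on the map's cR axis (`lo <= hi`).
#' @param bin_spans data frame with `bin_name`, `cr_start`, `cr_end` (e.g.
#'   `attr(assign_bins(...), "bin_spans")`) and a `resolution` column in Mb
#'   per cR.
#' @return size in Mb.
#' @export
cr_interval_to_mb <- function(lo, hi, bin_spans) {
  stopifnot(lo <= hi, all(c("cr_start", "cr_end", "resolution") %in%
                            names(bin_spans)))
  seg <- pmax(0, pmin(hi, bin_spans$cr_end) - pmax(lo, bin_spans$cr_start))
  touched <- seg > 0
  if (hi == lo) {                      # zero span still needs a defined bin
    touched <- bin_spans$cr_start <= lo & bin_spans$cr_end >= lo
    if (!any(touched)) stop("interval outside the mapped bins")
    return(0)
  }
  if (any(touched & is.na(bin_spans$resolution)))
    stop("interval overlaps bin(s) without a defined resolution: ",
         paste(bin_spans$bin_name[touched & is.na(bin_spans$resolution)],
               collapse = ", "))
  sum(seg[touched] * bin_spans$resolution[touched])
}

#' Call radiation-induced deletions along the map
#'
#' For each requested line, maximal runs of consecutive deleted loci in map
#' order are reported as deletions.  Runs are bounded by retained loci or by
#' the map ends; missing locus calls bridge a run without extending it.  The
#' inner span is the cR distance between the first and last deleted locus,
#' the outer span the distance between the flanking retained loci (map ends
#' if terminal), and the reported deletion size is the midpoint convention
#' `(inner + outer) / 2` - the unbiased choice when the true breakpoint is
#' uniform within the flanking interval.  If `bin_spans` (with a
#' `resolution` column) is supplied, sizes are also converted to Mb by
#' [cr_interval_to_mb()] on the midpoint interval (`NA` when the interval
#' overlaps a bin without resolution).
#'
#' @param g an [rh_genotypes] matrix.
#' @param map an [rh_map] object built from `g`.
#' @param lines line ids to call; defaults to all lines classified
#'   `INFORMATIVE` when `classes` is given, otherwise all lines.
#' @param classes optional factor from [classify_lines()]; lines of any
#'   other class are refused.
#' @param bin_spans optional bin span/resolution table, see above.
#' @return data frame with one row per deletion: `line_id`,
#'   `first_deleted_locus`, `last_deleted_locus`, `n_loci`,
#'   `inner_span_cR`, `outer_span_cR`, `size_cR`, `size_mb`, `bins_touched`
#'   (comma-separated), `bin_mid` (bin containing the midpoint-interval
#'   centre).
#' @export
call_deletions <- function(g, map, lines = NULL, classes = NULL,
                           bin_spans = NULL) {
  if (is.null(bin_spans) && !is.null(attr(map, "bin_spans")))
    bin_spans <- attr(map, "bin_spans")
  if (is.null(lines))
    lines <- if (!is.null(classes))
      names(classes)[classes == "INFORMATIVE"] else rownames(g)
  if (!is.null(classes)) {
    bad <- lines[classes[lines] != "INFORMATIVE"]
    if (length(bad))
      stop("deletions are called on INFORMATIVE lines only; run ",
           "classify_lines() first. Offending: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  states <- locus_states(g, map)
  pos <- map$position_cR
  map_lo <- min(pos); map_hi <- max(pos)
  out <- list()
  for (ln in lines) {
    s <- states[ln, ]
    runs <- deleted_runs(s)
    for (r in runs) {
      inner <- pos[r$to] - pos[r$from]
      prev_ret <- rev(which(s[seq_len(r$from)] == 1L))[1L]
      next_ret <- which(s == 1L & seq_along(s) > r$to)[1L]
      out_lo <- if (is.na(prev_ret)) map_lo else pos[prev_ret]
      out_hi <- if (is.na(next_ret)) map_hi else pos[next_ret]
      outer <- out_hi - out_lo
      mid_lo <- (out_lo + pos[r$from]) / 2
      mid_hi <- (pos[r$to] + out_hi) / 2
      size_mb <- NA_real_
      bin_mid <- NA_character_
      if (!is.null(bin_spans)) {
        if (!is.null(bin_spans$resolution))
          size_mb <- tryCatch(cr_interval_to_mb(mid_lo, mid_hi, bin_spans),
                              error = function(e) NA_real_)
        centre <- (mid_lo + mid_hi) / 2
        j <- findInterval(centre, bin_spans$cr_start, rightmost.closed = TRUE)
        if (j >= 1L && j <= nrow(bin_spans)) bin_mid <- bin_spans$bin_name[j]
      }
      bins_touched <- unique(map$bin_name[r$from:r$to])
      out[[length(out) + 1L]] <- data.frame(
        line_id = ln,
        first_deleted_locus = map$locus_id[r$from],
        last_deleted_locus = map$locus_id[r$to],
        n_loci = sum(s[r$from:r$to] == 0L, na.rm = TRUE),
        inner_span_cR = inner, outer_span_cR = outer,
        size_cR = (inner + outer) / 2, size_mb = size_mb,
        bins_touched = paste(bins_touched[!is.na(bins_touched)],
                             collapse = ","),
        bin_mid = bin_mid, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(line_id = character(0),
                      first_deleted_locus = character(0),
                      last_deleted_locus = character(0),
                      n_loci = integer(0), inner_span_cR = numeric(0),
                      outer_span_cR = numeric(0), size_cR = numeric(0),
                      size_mb = numeric(0), bins_touched = character(0),
                      bin_mid = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# per-line locus states along the map: majority call of the member markers
# (ties and all-missing loci give NA)
locus_states <- function(g, map) {
  x <- unclass(g)
  members <- attr(map, "markers")
  st <- vapply(map$locus_id, function(lc) {
    mk <- members[[lc]]
    sub <- x[, mk, drop = FALSE]
    n1 <- rowSums(sub == 1L, na.rm = TRUE)
    n0 <- rowSums(sub == 0L, na.rm = TRUE)
    ifelse(n1 > n0, 1L, ifelse(n0 > n1, 0L, NA_integer_))
  }, integer(nrow(x)))
  rownames(st) <- rownames(x)
  st
}

#' Summarise deletions per bin and per line
#'
#' Each deletion is attributed to the bin containing its midpoint; per-bin
#' count, mean and sd of the Mb size are reported together with per-line
#' deletion counts and the chromosome-wide mean size.
#'
#' @param calls data frame from [call_deletions()].
#' @return list with `bins` (`bin_name`, `n_deletions`, `mean_size_mb`,
#'   `sd_size_mb`), `lines` (`line_id`, `n_deletions`) and `mean_size_mb`.
#' @export
summarize_deletions <- function(calls) {
  if (!nrow(calls)) stop("no deletion calls to summarise")
  by_bin <- split(calls$size_mb, calls$bin_mid)
  bins <- data.frame(
    bin_name = names(by_bin),
    n_deletions = lengths(by_bin),
    mean_size_mb = vapply(by_bin, function(v) mean(v, na.rm = TRUE), 0),
    sd_size_mb = vapply(by_bin, function(v) stats::sd(v[!is.na(v)]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  lines <- as.data.frame(table(calls$line_id), stringsAsFactors = FALSE)
  names(lines) <- c("line_id", "n_deletions")
  list(bins = bins, lines = lines,
       mean_size_mb = mean(calls$size_mb, na.rm = TRUE))
}

#' Mean marker deletion frequency per bin
#'
#' The per-bin deletion frequency is the average over the bin's markers of
#' each marker's deletion frequency (deleted calls over genotyped calls).
#'
#' @param g an [rh_genotypes] matrix.
#' @param marker_bin named character vector mapping marker id -> bin name
#'   (e.g. from marker metadata or mapped loci).
#' @param lines optional subset of lines (e.g. informative lines only).
#' @return data frame `bin_name`, `n_markers`, `mean_deletion_frequency`,
#'   `sd_deletion_frequency`.
#' @export
bin_deletion_frequency <- function(g, marker_bin, lines = NULL) {
  x <- if (is.null(lines)) g else
    rh_genotypes(unclass(g)[lines, , drop = FALSE])
  df <- deletion_frequency(x)
  mk <- intersect(names(df), names(marker_bin))
  by_bin <- split(df[mk], marker_bin[mk])
  data.frame(bin_name = names(by_bin),
             n_markers = lengths(by_bin),
             mean_deletion_frequency = vapply(by_bin, mean, 0),
             sd_deletion_frequency = vapply(by_bin, stats::sd, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-square test of deletion-frequency uniformity across bins
#'
#' Probes one marker per bin - the one nearest the bin's physical centre, so
#' that probes are farther apart than typical deletion lengths and their
#' deleted-line counts are approximately independent - and tests the counts
#' against expectations proportional to the number of genotyped lines per
#' probe.
#'
#' @param g an [rh_genotypes] matrix.
#' @param marker_info marker metadata including a chromosome-scale `pos_mb`
#'   column and `bin_name` per marker.
#' @param bins bin table with `bin_name` and physical extent (`chrom_start`,
#'   `chrom_end` in Mb, or `size_mb` in chromosome order).
#' @param lines optional subset of lines (e.g. informative lines).
#' @return list with `p_value`, `statistic`, `probes` (marker per bin) and
#'   `counts`.
#' @export
deletion_uniformity_test <- function(g, marker_info, bins, lines = NULL) {
  stopifnot(!is.null(marker_info$pos_mb))
  if (is.null(bins$chrom_start)) {
    ord <- if (!is.null(bins$arm)) match(bin_chrom_order(bins), bins$bin_name)
           else seq_len(nrow(bins))
    bins <- bins[ord, ]
    bins$chrom_end <- cumsum(bins$size_mb)
    bins$chrom_start <- bins$chrom_end - bins$size_mb
  }
  centre <- (bins$chrom_start + bins$chrom_end) / 2
  probes <- vapply(seq_len(nrow(bins)), function(j) {
    in_bin <- marker_info$bin_name %in% bins$bin_name[j] |
      (marker_info$pos_mb >= bins$chrom_start[j] &
         marker_info$pos_mb < bins$chrom_end[j])
    if (!any(in_bin)) return(NA_character_)
    cand <- marker_info[in_bin, ]
    cand$marker_id[order(abs(cand$pos_mb - centre[j]), cand$marker_id)][1L]
  }, "")
  probes <- probes[!is.na(probes)]
  x <- unclass(g)[if (is.null(lines)) TRUE else lines, probes, drop = FALSE]
  deleted <- colSums(x == 0L, na.rm = TRUE)
  genotyped <- colSums(!is.na(x))
  ct <- suppressWarnings(
    stats::chisq.test(deleted, p = genotyped / sum(genotyped)))
  list(p_value = ct$p.value, statistic = unname(ct$statistic),
       probes = probes, counts = deleted)
}
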