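#' Pearson correlation with two-tailed t significance
#'
#' Product-moment correlation with the significance of the two-tail test on
#' `t = r * sqrt((n - 2) / (1 - r^2))` at `n - 2` degrees of freedom, `n`
#' being the number of complete pairs (pairs with any missing value are
#' dropped).
#'
#' @param x,y numeric vectors of equal length.
#' @param alpha optional significance level to flag.
#' @return list of class `rh_correlation`: `r`, `n`, `df`, `t_stat`,
#'   `p_two_tailed`, `alpha`, `significant`.
#' @export
pearson_cor <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  df <- n - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(r = r, n = n, df = df, t_stat = t_stat, p_two_tailed = p,
                 alpha = alpha, significant = p < alpha),
            class = "rh_correlation")
}

#' @export
print.rh_correlation <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, df = %d, t = %.2f, two-tailed p = %.4g)%s\n",
              x$r, x$n, x$df, x$t_stat, x$p_two_tailed,
              if (isTRUE(x$significant))
                sprintf("  * significant at %g", x$alpha) else ""))
  invisible(x)
}

#' Distance of a deletion bin from the centromere
#'
#' The convention used is the midpoint of the bin's fractional arm interval,
#' scaled by the arm's physical size (or returned as a bare arm fraction).
#' Centromere-spanning bins (fractions starting at 0) are treated
#' identically: distance of the outer-fraction midpoint from the centromere.
#'
#' @param bins bin table with `arm`, `frac_start`, `frac_end`.
#' @param arm_mb named vector of arm sizes in Mb (`c(S = ..., L = ...)`).
#' @param units `"mb"` or `"fraction"`.
#' @return numeric vector of distances, one per bin.
#' @examples
#' centromere_distance(data.frame(arm = "S", frac_start = 0.87,
#'                                frac_end = 1), c(S = 414, L = 578))
#' @export
centromere_distance <- function(bins, arm_mb = wheat3b_arm_sizes(),
                                units = c("mb", "fraction")) {
  units <- match.arg(units)
  mid <- (bins$frac_start + bins$frac_end) / 2
  if (units == "fraction") return(mid)
  unname(arm_mb[bins$arm] * mid)
}

#' The BR / CO / deletion correlation suite
#'
#' One Pearson test per relationship examined in the 3B analysis: BR vs CO
#' frequency, each frequency vs centromere distance, deletion count vs mean
#' deletion size across bins, BR and CO vs per-bin deletion count, mean
#' size, and mean marker deletion frequency.  Bins missing either variable
#' of a pair are dropped from that pair (e.g. a bin without a genetic span
#' contributes no CO value); pairs with fewer than 3 usable bins are
#' reported as `NA` with a reason.
#'
#' @param metrics per-bin data frame from [compute_bin_metrics()] (bins
#'   only, no chromosome row).
#' @param deletion_bins optional per-bin deletion summary
#'   (`summarize_deletions()$bins`), matched by `bin_name`.
#' @param deletion_freq optional per-bin marker deletion frequency
#'   ([bin_deletion_frequency()]), matched by `bin_name`.
#' @param centromere optional named numeric: distance from the centromere
#'   per bin ([centromere_distance()]), matched by `bin_name`.
#' @param alpha significance level flagged in the output.
#' @return data frame: `pair`, `r`, `n`, `df`, `t`, `p`, `significant`,
#'   `note`.  Row order is fixed; values are invariant to bin ordering.
#' @export
correlation_suite <- function(metrics, deletion_bins = NULL,
                              deletion_freq = NULL, centromere = NULL,
                              alpha = 0.05) {
  metrics <- metrics[order(metrics$bin_name), ]
  v <- list(br = stats::setNames(metrics$br_freq, metrics$bin_name),
            co = stats::setNames(metrics$co_freq, metrics$bin_name))
  if (!is.null(centromere)) v$cen <- centromere
  if (!is.null(deletion_bins)) {
    v$ndel <- stats::setNames(deletion_bins$n_deletions,
                              deletion_bins$bin_name)
    v$msize <- stats::setNames(deletion_bins$mean_size_mb,
                               deletion_bins$bin_name)
  }
  if (!is.null(deletion_freq))
    v$dfreq <- stats::setNames(deletion_freq$mean_deletion_frequency,
                               deletion_freq$bin_name)
  pairs <- list(
    br_vs_co = c("br", "co"),
    co_vs_centromere_distance = c("co", "cen"),
    br_vs_centromere_distance = c("br", "cen"),
    n_deletions_vs_mean_size = c("ndel", "msize"),
    co_vs_n_deletions = c("co", "ndel"),
    br_vs_n_deletions = c("br", "ndel"),
    co_vs_mean_size = c("co", "msize"),
    br_vs_mean_size = c("br", "msize"),
    co_vs_deletion_frequency = c("co", "dfreq"),
    br_vs_deletion_frequency = c("br", "dfreq"))
  rows <- lapply(names(pairs), function(nm) {
    ab <- pairs[[nm]]
    if (!all(ab %in% names(v)))
      return(data.frame(pair = nm, r = NA_real_, n = NA_integer_,
                        df = NA_integer_, t = NA_real_, p = NA_real_,
                        significant = NA,
                        note = "variable not supplied",
                        stringsAsFactors = FALSE))
    bn <- intersect(names(v[[ab[1L]]]), names(v[[ab[2L]]]))
    x <- v[[ab[1L]]][bn]; y <- v[[ab[2L]]][bn]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      return(data.frame(pair = nm, r = NA_real_, n = sum(ok),
                        df = NA_integer_, t = NA_real_, p = NA_real_,
                        significant = NA, note = "fewer than 3 usable bins",
                        stringsAsFactors = FALSE))
    ct <- pearson_cor(x[ok], y[ok], alpha = alpha)
    note <- if (all(ok)) "" else
      paste("excluded:", paste(sort(bn[!ok]), collapse = ","))
    data.frame(pair = nm, r = ct$r, n = ct$n, df = ct$df, t = ct$t_stat,
               p = ct$p_two_tailed, significant = ct$significant,
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
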