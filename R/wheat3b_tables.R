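# Packaged reference tables for wheat chromosome 3B: the published per-bin
# map/physical summary (11 deletion bins plus a chromosome-total row) and the
# 17 multi-marker BAC contigs of known physical size.  The *_print columns
# hold the values exactly as printed in the source tables (one decimal; two
# for cR/cM ratios >= 10); the remaining columns are the raw inputs from
# which the derived statistics can be recomputed.

.wheat3b_md5 <- c(
  wheat3b_bins.tsv    = "6d1c3821b40567adcbe14405dd6188e0",
  wheat3b_contigs.tsv = "f6f7bffb04c03cf857b01e9ee1eb4d0f"
)

wheat3b_file <- function(name) {
  path <- system.file("extdata", name, package = "rhmapper", mustWork = TRUE)
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(.wheat3b_md5[[name]])))
    stop("checksum mismatch for packaged table ", name,
         " - the installed file is corrupted")
  path
}

#' Packaged wheat chromosome 3B reference tables
#'
#' `load_wheat3b_tables()` returns the transcribed per-bin comparison of the
#' 3B radiation hybrid and genetic maps (`$bins`: 11 deletion bins plus the
#' chromosome-total row `Chr`) and the multi-marker BAC contig table
#' (`$contigs`: 17 contigs, of which 9 have a non-zero cR span).  Columns
#' prefixed `print_` are the published display-rounded cells; `n_markers`,
#' `size_mb`, `map_cR` and `map_cM` are the raw inputs.  Files are verified
#' against embedded checksums before parsing.
#'
#' Note that the `Chr` row is the published chromosome total (992 Mb over the
#' whole map), not the sum of the 11 tabulated bins (891 Mb): two anchor-less
#' bins (3BL8-0.28-0.31, 3BL9-0.38-0.50) are absent from the per-bin rows.
#'
#' @return list with data frames `bins` and `contigs`.
#' @examples
#' tabs <- load_wheat3b_tables()
#' subset(tabs$bins, bin_name == "3BS8")[, c("size_mb", "map_cR", "map_cM")]
#' @export
load_wheat3b_tables <- function() {
  bins <- utils::read.delim(wheat3b_file("wheat3b_bins.tsv"),
                            stringsAsFactors = FALSE)
  contigs <- utils::read.delim(wheat3b_file("wheat3b_contigs.tsv"),
                               stringsAsFactors = FALSE)
  validate_bin_table(bins[bins$bin_name != "Chr", ])
  list(bins = bins, contigs = contigs)
}

#' Arm sizes of wheat chromosome 3B
#'
#' Physical sizes in Mb of the short and long arm implied by the 992 Mb
#' chromosome and the tabulated short-arm bins (which tile the S arm
#' completely: 414 Mb).
#'
#' @return named numeric vector `c(S = 414, L = 578)`.
#' @export
wheat3b_arm_sizes <- function() c(S = 414, L = 578)
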