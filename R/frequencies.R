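#' Retention and deletion frequencies
#'
#' `retention_frequency()` gives, per RH line, the fraction of non-missing
#' marker calls that are retained; `deletion_frequency()` gives, per marker,
#' the fraction of non-missing line calls that are deleted.  The two are
#' complements on the same vector of calls: deletion frequency is the number
#' of deleted calls over the number genotyped, and retention frequency is one
#' minus that.
#'
#' @param g an [rh_genotypes] matrix, or a single 0/1/NA call vector.
#' @return named numeric vector (per line, resp. per marker), in `[0, 1]`.
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("mA", "mB")))
#' retention_frequency(rh_genotypes(m))
#' @export
retention_frequency <- function(g) {
  x <- as_call_matrix(g, by = "line")
  n <- rowSums(!is.na(x))
  if (any(n == 0L))
    stop("line(s) with no genotyped marker: ",
         paste(rownames(x)[n == 0L], collapse = ", "))
  rowSums(x == 1L, na.rm = TRUE) / n
}

#' @rdname retention_frequency
#' @export
deletion_frequency <- function(g) {
  x <- as_call_matrix(g, by = "marker")
  n <- colSums(!is.na(x))
  if (any(n == 0L))
    stop("marker(s) with no genotyped line: ",
         paste(colnames(x)[n == 0L], collapse = ", "))
  colSums(x == 0L, na.rm = TRUE) / n
}

as_call_matrix <- function(g, by) {
  if (is.matrix(g)) return(unclass(g))
  x <- as.integer(g)
  if (by == "line") matrix(x, nrow = 1L, dimnames = list("line", names(g)))
  else matrix(x, ncol = 1L, dimnames = list(names(g), "marker"))
}

#' Classify RH lines by chromosome-scale loss
#'
#' Lines retaining every genotyped marker are `INTACT`; lines with retention
#' below `whole_loss_below` lost the whole chromosome (`WHOLE_LOSS`); lines
#' whose single uninterrupted deleted run covers all loci of one arm plus at
#' least one locus of the other are `SUPRA_ARM_LOSS` (in the source panel
#' these are interpreted as translocation survivors); everything else is
#' `INFORMATIVE` and enters deletion calling.
#'
#' @param g an [rh_genotypes] matrix whose columns are in (true or mapped)
#'   chromosome order.
#' @param marker_arm character vector, `"S"`/`"L"` per marker (matrix column).
#' @param whole_loss_below retention threshold for whole-chromosome loss.
#' @return factor of classes, one per line.
#' @export
classify_lines <- function(g, marker_arm,
                           whole_loss_below = 0.020) {
  stopifnot(length(marker_arm) == ncol(g), all(marker_arm %in% c("S", "L")))
  rf <- retention_frequency(g)
  cls <- rep("INFORMATIVE", nrow(g))
  cls[rf < whole_loss_below] <- "WHOLE_LOSS"
  cls[rf == 1] <- "INTACT"
  maybe <- which(cls == "INFORMATIVE")
  for (i in maybe) {
    runs <- deleted_runs(unclass(g)[i, ])
    for (r in runs) {
      arms <- marker_arm[r$from:r$to]
      covered <- unique(arms)
      if (length(covered) == 2L &&
          (all(which(marker_arm == "S") >= r$from & which(marker_arm == "S") <= r$to) ||
           all(which(marker_arm == "L") >= r$from & which(marker_arm == "L") <= r$to))) {
        cls[i] <- "SUPRA_ARM_LOSS"
        break
      }
    }
  }
  factor(stats::setNames(cls, rownames(g)),
         levels = c("INTACT", "WHOLE_LOSS", "SUPRA_ARM_LOSS", "INFORMATIVE"))
}

# maximal runs of 0 calls along a call vector; NA bridges a run but neither
# starts nor ends one.  Returns list of (from, to) indices of deleted calls.
deleted_runs <- function(calls) {
  del <- which(calls == 0L)
  if (!length(del)) return(list())
  ret <- which(calls == 1L)
  # run breaks where a retained call falls between consecutive deleted calls
  breaks <- vapply(seq_len(length(del) - 1L), function(k) {
    any(ret > del[k] & ret < del[k + 1L])
  }, TRUE)
  grp <- cumsum(c(0L, breaks))
  lapply(split(del, grp), function(ix) list(from = min(ix), to = max(ix)))
}
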