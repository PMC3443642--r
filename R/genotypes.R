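#' Genotype matrix of a radiation hybrid panel
#'
#' An `rh_genotypes` object is an integer matrix with one row per RH line and
#' one column per marker.  Cells are `1L` (marker retained), `0L` (marker
#' deleted) or `NA` (assay failed / no call).  Row and column names carry the
#' line and marker identifiers and must be unique.
#'
#' @param calls integer (or coercible) matrix with values in `{0, 1, NA}`,
#'   with unique rownames (line ids) and colnames (marker ids).
#' @return an `rh_genotypes` object.
#' @examples
#' m <- matrix(c(1, 0, 1, NA, 1, 1), nrow = 2,
#'             dimnames = list(c("L1", "L2"), c("mA", "mB", "mC")))
#' g <- rh_genotypes(m)
#' @export
rh_genotypes <- function(calls) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1L], dim(calls))
    stop(sprintf("invalid genotype call at line %s, marker %s",
                 rownames(calls)[idx[1L]] %||% idx[1L],
                 colnames(calls)[idx[2L]] %||% idx[2L]))
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("genotype matrix needs line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate line ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  structure(calls, class = c("rh_genotypes", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.rh_genotypes <- function(x, ...) {
  cat(sprintf("RH genotype matrix: %d lines x %d markers (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a genotype matrix from delimited text
#'
#' The file layout is one header row of marker ids, then one row per line with
#' the line id in the first column.  State tokens are configurable; the
#' defaults are `"1"` (retained), `"0"` (deleted) and `"NA"` (missing).
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param tokens named character vector with entries `retained`, `deleted`,
#'   `missing`.
#' @param sep field separator; `NULL` chooses from the file extension.
#' @return an [rh_genotypes] matrix.
#' @export
read_genotype_matrix <- function(path,
                                 tokens = c(retained = "1", deleted = "0",
                                            missing = "NA"),
                                 sep = NULL) {
  stopifnot(all(c("retained", "deleted", "missing") %in% names(tokens)))
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genotype file needs a header and >= 1 line row")
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncol_expect <- length(cells[[1L]])
  ragged <- which(lengths(cells) != ncol_expect)
  if (length(ragged))
    stop("ragged row(s) in genotype file: row ", paste(ragged, collapse = ", "))
  marker_ids <- cells[[1L]][-1L]
  line_ids <- vapply(cells[-1L], `[[`, "", 1L)
  raw <- do.call(rbind, lapply(cells[-1L], function(r) r[-1L]))
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw),
                  dimnames = list(line_ids, marker_ids))
  calls[raw == tokens[["retained"]]] <- 1L
  calls[raw == tokens[["deleted"]]]  <- 0L
  known <- raw %in% c(tokens[["retained"]], tokens[["deleted"]],
                      tokens[["missing"]])
  if (!all(known)) {
    idx <- which(matrix(!known, nrow(raw)), arr.ind = TRUE)[1L, ]
    stop(sprintf("unrecognised genotype token '%s' at line %s, marker %s",
                 raw[idx[1L], idx[2L]], line_ids[idx[1L]], marker_ids[idx[2L]]))
  }
  rh_genotypes(calls)
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [read_genotype_matrix()]: `read(write(g))` is the identity.
#'
#' @param g an [rh_genotypes] matrix.
#' @inheritParams read_genotype_matrix
#' @export
write_genotype_matrix <- function(g, path,
                                  tokens = c(retained = "1", deleted = "0",
                                             missing = "NA"),
                                  sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- matrix(tokens[["missing"]], nrow(g), ncol(g))
  out[which(g == 1L)] <- tokens[["retained"]]
  out[which(g == 0L)] <- tokens[["deleted"]]
  con <- file(path, "wb")   # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(c(paste(c("line_id", colnames(g)), collapse = sep),
               paste(rownames(g), apply(out, 1L, paste, collapse = sep),
                     sep = sep)),
             con)
  invisible(path)
}

# ---- tabular metadata -------------------------------------------------------

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(basename(path), " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read marker metadata
#'
#' Expected columns: `marker_id`, `marker_class` (ISBP/SSR/DArT/OTHER),
#' `is_anchor` (logical or 0/1); optional `bin_name`, `contig_id`,
#' `physical_bp` (0-based position within the contig) and `pos_mb`
#' (chromosome-scale position, emitted by the simulator).
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_marker_info <- function(path) {
  df <- read_tsv_checked(path, c("marker_id", "marker_class", "is_anchor"))
  validate_marker_info(df)
}

#' @rdname read_marker_info
#' @param info marker metadata data frame to validate in place.
#' @export
validate_marker_info <- function(info) {
  if (anyDuplicated(info$marker_id))
    stop("duplicate marker ids in marker metadata")
  info$is_anchor <- as.logical(info$is_anchor)
  if (is.null(info$bin_name)) info$bin_name <- NA_character_
  bad <- info$is_anchor & (is.na(info$bin_name) | info$bin_name == "")
  if (any(bad))
    stop("anchor markers without a bin assignment: ",
         paste(utils::head(info$marker_id[bad], 5L), collapse = ", "))
  info
}

#' Read a deletion-bin table
#'
#' Expected columns: `bin_name`, `arm` (S/L), `frac_start`, `frac_end`
#' (arm fractions in `[0, 1]`), `size_mb`; optional `map_cR`, `map_cM`,
#' `n_markers`.
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_bin_table <- function(path) {
  df <- read_tsv_checked(path, c("bin_name", "arm", "frac_start", "frac_end",
                                 "size_mb"))
  validate_bin_table(df)
}

#' @rdname read_bin_table
#' @param bins bin table data frame to validate in place.
#' @export
validate_bin_table <- function(bins) {
  if (anyDuplicated(bins$bin_name)) stop("duplicate bin names")
  if (!all(bins$arm %in% c("S", "L"))) stop("bin arm must be 'S' or 'L'")
  if (any(bins$frac_start >= bins$frac_end))
    stop("bin frac_start must be < frac_end")
  if (any(bins$size_mb <= 0)) stop("bin size_mb must be > 0")
  if (!is.null(bins$map_cR) && any(bins$map_cR < 0, na.rm = TRUE))
    stop("bin map_cR must be >= 0")
  bins
}

#' Read a BAC-contig table
#'
#' Expected columns: `contig_id`, `size_mb`, `n_markers`, `bin_name`;
#' optional `span_cR` (span of the contig's markers on an existing map).
#' A physical size of 0.0 means "below fingerprinting resolution", not empty.
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_contig_table <- function(path) {
  df <- read_tsv_checked(path, c("contig_id", "size_mb", "n_markers",
                                 "bin_name"))
  if (anyDuplicated(df$contig_id)) stop("duplicate contig ids")
  if (any(df$size_mb < 0)) stop("contig size_mb must be >= 0")
  if (any(df$n_markers < 1)) stop("contigs need >= 1 marker")
  df
}

#' Write an RH map as TSV
#'
#' Columns: `locus_id`, `group_id`, `position_cR`, `framework`, `bin_name`,
#' plus one row per member marker (`marker_id`).
#'
#' @param map an [rh_map] object.
#' @param path output TSV path.
#' @export
write_rh_map <- function(map, path) {
  loci <- as.data.frame(map)
  members <- attr(map, "markers")
  out <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    data.frame(marker_id = members[[loci$locus_id[i]]],
               locus_id = loci$locus_id[i],
               position_cR = loci$position_cR[i],
               framework = loci$framework[i],
               bin_name = loci$bin_name[i],
               stringsAsFactors = FALSE)
  }))
  write_tsv_plain(out, path)
  invisible(path)
}

# fixed-format writer so that identical inputs give byte-identical files
write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(df, sep = "\t"))), con)
  invisible(path)
}

#' Read back an RH map written by [write_rh_map()]
#'
#' @param path TSV produced by [write_rh_map()].
#' @return an [rh_map] object.
#' @export
read_rh_map <- function(path) {
  df <- read_tsv_checked(path, c("marker_id", "locus_id", "position_cR",
                                 "framework", "bin_name"))
  loci <- df[!duplicated(df$locus_id),
             c("locus_id", "position_cR", "framework", "bin_name")]
  members <- split(df$marker_id, df$locus_id)[loci$locus_id]
  new_rh_map(loci$locus_id, loci$position_cR, as.logical(loci$framework),
             members, bin_name = loci$bin_name)
}
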