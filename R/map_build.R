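# Framework RH map construction.
#
# Orders are scored by a composite multipoint objective: the sum over
# adjacent locus pairs of the two-point linkage LOD (base-10 likelihood
# ratio against independence), with missing calls excluded pairwise.  The
# LOD is the order-comparable part of the Markov-chain likelihood across
# adjacent loci: the chain decomposes into per-edge joint likelihoods, and
# subtracting each edge's independence likelihood removes the marginal
# entropy terms, which depend on the pair's pooled retention and would
# otherwise dominate the comparison between edges.  Pairs beyond the
# breakage saturation distance contribute LOD ~ 0, so the objective is
# honest about what the data cannot order.

new_rh_map <- function(locus_id, position_cR, framework, markers,
                       bin_name = NA_character_, objective = NA_real_) {
  df <- data.frame(locus_id = locus_id, position_cR = position_cR,
                   framework = framework, bin_name = bin_name,
                   n_markers = lengths(markers[locus_id]),
                   stringsAsFactors = FALSE)
  structure(df, markers = markers, objective = objective,
            class = c("rh_map", "data.frame"))
}

#' @export
print.rh_map <- function(x, ...) {
  cat(sprintf("RH map: %d loci (%d framework), %d markers, %.1f cR\n",
              nrow(x), sum(x$framework), sum(x$n_markers),
              max(x$position_cR)))
  NextMethod()
}

#' Collapse markers with identical segregation patterns into loci
#'
#' Markers whose call vectors are identical across all lines cannot be
#' separated by the panel and are mapped as one locus.  By default the
#' missing-call pattern is part of the identity test; with
#' `missing_wildcard = TRUE` a missing call is compatible with either state
#' and markers are greedily merged (in lexicographic marker order) into the
#' first group whose consensus pattern they do not contradict.
#'
#' @param g an [rh_genotypes] matrix.
#' @param missing_wildcard logical, see above.
#' @return list with `groups` (named list: locus id, the lexicographically
#'   smallest member marker, to member marker ids), `pattern` (matrix of one
#'   representative/consensus call column per locus, lines x loci) and
#'   `locus_of` (named map marker id -> locus id).
#' @export
collapse_cosegregating <- function(g, missing_wildcard = FALSE) {
  x <- unclass(g)
  ord <- order(colnames(x))
  if (!missing_wildcard) {
    key <- apply(x[, ord, drop = FALSE], 2L, function(cl)
      paste(ifelse(is.na(cl), "N", cl), collapse = ""))
    grp <- split(colnames(x)[ord], factor(key, levels = unique(key)))
    names(grp) <- vapply(grp, `[[`, "", 1L)
    pattern <- x[, names(grp), drop = FALSE]
  } else {
    grp <- list(); cons <- list()
    for (mk in colnames(x)[ord]) {
      v <- x[, mk]
      hit <- NULL
      for (gname in names(grp)) {
        cv <- cons[[gname]]
        if (!any(!is.na(v) & !is.na(cv) & v != cv)) { hit <- gname; break }
      }
      if (is.null(hit)) {
        grp[[mk]] <- mk; cons[[mk]] <- v
      } else {
        grp[[hit]] <- c(grp[[hit]], mk)
        cv <- cons[[hit]]; cv[is.na(cv)] <- v[is.na(cv)]
        cons[[hit]] <- cv
      }
    }
    pattern <- do.call(cbind, cons)
    colnames(pattern) <- names(grp)
  }
  locus_of <- stats::setNames(rep(names(grp), lengths(grp)), unlist(grp))
  list(groups = grp, pattern = pattern, locus_of = locus_of)
}

#' Composite multipoint objective of a locus order
#'
#' Sum over adjacent pairs of the two-point linkage LOD (element `lod` of
#' [two_point_all()]); the objective maximised by [build_framework_map()]
#' and usable for exhaustive-enumeration checks.
#'
#' @param order character vector of locus ids (or indices).
#' @param loglik_matrix symmetric pairwise linkage matrix (adjacent-pair
#'   LODs).
#' @return scalar composite score (base-10 log-likelihood-ratio units).
#' @export
multipoint_loglik <- function(order, loglik_matrix) {
  k <- length(order)
  if (k < 2L) return(0)
  sum(loglik_matrix[cbind(order[-k], order[-1L])])
}

#' Build the framework RH map by iterative LOD-gated insertion
#'
#' Stage 1 seeds the order with the anchor-locus pair of maximal two-point
#' LOD.  Then, repeatedly, every unplaced locus is scored at every insertion
#' slot of the current order under the composite multipoint objective; the
#' placement LOD of a locus is the base-10 likelihood gap between its best
#' and second-best slot.  The locus with the largest placement LOD is
#' inserted while that LOD meets the current threshold; when no locus
#' qualifies the next (lower) threshold of `lod_schedule` is used.  Loci
#' never reaching the final threshold are attached at their best slot and
#' flagged non-framework.  A ripple pass (all permutations of every sliding
#' window of three loci, accepting strict improvements, iterated to a
#' fixpoint) polishes the order.  Positions are cumulative adjacent
#' two-point centiRay distances, and the map is oriented so that anchor bins
#' run from the distal short arm to the distal long arm (`bin_order`).
#'
#' All ties are broken lexicographically, so the result is deterministic.
#'
#' @param g an [rh_genotypes] matrix.
#' @param marker_info marker metadata (see [read_marker_info()]); used for
#'   anchor flags and bin names.  May be `NULL` (no anchors: the seed falls
#'   back to the globally best pair, with a warning).
#' @param lod_schedule decreasing numeric vector of placement-LOD thresholds.
#' @param bin_order character vector of bin names in chromosome order
#'   (distal S first); `NULL` derives it from `bins`.
#' @param bins optional bin table (arm + arm fractions) used to derive
#'   `bin_order`.
#' @param missing_wildcard passed to [collapse_cosegregating()].
#' @param likelihood_lines line ids used for the ordering likelihood.  The
#'   default keeps lines with retention frequency in `[0.5, 1)` - the
#'   classical definition of an informative RH line.  Lines retaining or
#'   lacking the whole chromosome witness no breakage, and lines that lost
#'   more than an arm create apparent linkage between loci hundreds of Mb
#'   apart; both distort the haploid two-point model.  Positions (cR
#'   distances) always use all lines screened.
#' @param verbose log each insertion (locus, slot, placement LOD).
#' @return an [rh_map] object (positions in cR, `framework` flags, locus
#'   membership in `attr(, "markers")`, objective in `attr(, "objective")`).
#' @export
build_framework_map <- function(g, marker_info = NULL,
                                lod_schedule = c(10, 8, 6, 3),
                                bin_order = NULL, bins = NULL,
                                missing_wildcard = FALSE,
                                likelihood_lines = NULL,
                                verbose = FALSE) {
  stopifnot(!is.unsorted(rev(lod_schedule)))
  col <- collapse_cosegregating(g, missing_wildcard)
  loci <- colnames(col$pattern)
  if (length(loci) < 3L) stop("need at least 3 distinct loci to build a map")
  tp <- two_point_all(col$pattern)
  if (is.null(likelihood_lines)) {
    rf <- retention_frequency(rh_genotypes(col$pattern))
    likelihood_lines <- names(rf)[rf >= 0.5 & rf < 1]
    if (length(likelihood_lines) < 2L) {  # fall back: any line showing both
      p <- col$pattern                    # states carries breakage signal
      likelihood_lines <- rownames(p)[rowSums(p == 0L, na.rm = TRUE) > 0L &
                                        rowSums(p == 1L, na.rm = TRUE) > 0L]
    }
  }
  if (length(likelihood_lines) < 2L)
    stop("no informative line; the panel carries no ordering signal")
  tpl <- if (length(likelihood_lines) == nrow(col$pattern)) tp else
    two_point_all(col$pattern[likelihood_lines, , drop = FALSE])
  M <- tpl$lod

  anchors <- character(0)
  anchor_bin <- NULL
  if (!is.null(marker_info)) {
    marker_info <- validate_marker_info(marker_info)
    amk <- marker_info[marker_info$is_anchor, ]
    hit <- amk$marker_id %in% names(col$locus_of)
    anchors <- unique(col$locus_of[amk$marker_id[hit]])
    anchor_bin <- stats::setNames(amk$bin_name[hit],
                                  col$locus_of[amk$marker_id[hit]])
    anchor_bin <- anchor_bin[!duplicated(names(anchor_bin))]
  }
  if (is.null(bin_order) && !is.null(bins)) bin_order <- bin_chrom_order(bins)

  # Arms are separate linkage groups in an RH panel (interstitial deletions
  # do not cross the centromere), so each arm is ordered on its own and the
  # arms are concatenated short-distal -> long-distal.  Without arm
  # information the chromosome is ordered as a single chain.
  arm_of <- NULL
  if (length(anchors) >= 2L && !is.null(bins) && all(!is.na(bins$arm))) {
    arm_of_bin <- stats::setNames(bins$arm, bins$bin_name)
    aarm <- arm_of_bin[anchor_bin]
    names(aarm) <- names(anchor_bin)
    aarm <- aarm[!is.na(aarm)]
    if (length(unique(aarm)) == 2L) {
      # linkage groups at the lowest framework threshold; each group takes
      # the majority arm of its anchors, anchorless groups join the arm of
      # their best-linked assigned locus
      comp <- linkage_components(tpl$lod, min(lod_schedule))
      arm_of <- stats::setNames(rep(NA_character_, length(loci)), loci)
      arm_of[names(aarm)] <- aarm
      for (cid in unique(comp)) {
        members <- loci[comp == cid]
        seen <- arm_of[members]
        if (all(is.na(seen))) next
        tab <- sort(table(seen), decreasing = TRUE)
        arm_of[members] <- names(tab)[1L]
        arm_of[names(aarm)] <- aarm    # anchors keep their known arm
      }
      while (anyNA(arm_of)) {
        todo <- names(arm_of)[is.na(arm_of)]
        done <- names(arm_of)[!is.na(arm_of)]
        if (!length(done)) { arm_of[todo] <- "S"; break }
        sub <- tpl$lod[todo, done, drop = FALSE]
        best <- apply(sub, 1L, max)
        pick <- todo[order(-best, todo)[1L]]
        arm_of[pick] <- if (max(sub[pick, ]) > 0)
          arm_of[done[which.max(sub[pick, ])]] else "S"
      }
    }
  }

  framework <- stats::setNames(rep(FALSE, length(loci)), loci)
  build_chain <- function(chain_loci) {
    if (length(chain_loci) <= 2L) {
      framework[chain_loci] <<- TRUE
      return(sort(chain_loci))
    }
    pool <- intersect(anchors, chain_loci)
    if (length(pool) < 2L) {
      if (!is.null(marker_info))
        warning("fewer than 2 anchor loci; seeding from the best overall pair")
      pool <- chain_loci
    }
    lodp <- tpl$lod[pool, pool, drop = FALSE]
    diag(lodp) <- -Inf
    best <- which(lodp == max(lodp), arr.ind = TRUE)
    pairs <- unique(t(apply(best, 1L, function(ix)
      sort(c(rownames(lodp)[ix[1L]], colnames(lodp)[ix[2L]])))))
    ord <- pairs[order(pairs[, 1L], pairs[, 2L])[1L], ]
    framework[ord] <<- TRUE
    unplaced <- setdiff(chain_loci, ord)
    stage <- 1L
    while (length(unplaced)) {
      sc <- placement_scores(ord, unplaced, M)
      qual <- which(sc$lod >= lod_schedule[stage])
      if (!length(qual)) {
        if (stage < length(lod_schedule)) { stage <- stage + 1L; next }
        while (length(unplaced)) {     # attach leftovers, non-framework
          sc <- placement_scores(ord, unplaced, M)
          pick <- order(-sc$lod, unplaced)[1L]
          ord <- append(ord, unplaced[pick], after = sc$slot[pick] - 1L)
          if (verbose)
            message(sprintf("attach %s at slot %d (LOD %.2f)",
                            unplaced[pick], sc$slot[pick], sc$lod[pick]))
          unplaced <- unplaced[-pick]
        }
        break
      }
      pick <- qual[order(-sc$lod[qual], unplaced[qual])[1L]]
      ord <- append(ord, unplaced[pick], after = sc$slot[pick] - 1L)
      framework[unplaced[pick]] <<- TRUE
      if (verbose)
        message(sprintf("insert %s at slot %d (LOD %.2f, threshold %g)",
                        unplaced[pick], sc$slot[pick], sc$lod[pick],
                        lod_schedule[stage]))
      unplaced <- unplaced[-pick]
    }
    polish_order(ord, M)
  }

  if (!is.null(arm_of)) {
    ords <- lapply(c("S", "L"), function(a) {
      o <- build_chain(names(arm_of)[arm_of == a])
      orient_order(o, col$locus_of, marker_info, bin_order)
    })
    ord <- c(ords[[1L]], ords[[2L]])
  } else {
    ord <- build_chain(loci)
    ord <- orient_order(ord, col$locus_of, marker_info, bin_order)
  }

  pos <- cumsum(c(0, tp$distance_cR[cbind(ord[-length(ord)], ord[-1L])]))
  new_rh_map(ord, pos, unname(framework[ord]), col$groups,
             objective = multipoint_loglik(ord, M))
}

# best and second-best insertion gain for each unplaced locus.
# Slot s means "insert before position s" (1 .. k+1).
placement_scores <- function(ord, unplaced, M) {
  k <- length(ord)
  Mou <- M[ord, unplaced, drop = FALSE]           # k x u
  adj <- M[cbind(ord[-k], ord[-1L])]              # k-1 adjacent terms
  gains <- rbind(Mou[1L, , drop = FALSE],         # prepend
                 if (k > 1L) Mou[-k, , drop = FALSE] +
                   Mou[-1L, , drop = FALSE] - adj,
                 Mou[k, , drop = FALSE])          # append
  best <- apply(gains, 2L, max)
  slot <- apply(gains, 2L, which.max)
  second <- apply(gains, 2L, function(v) sort(v, decreasing = TRUE)[2L])
  list(lod = best - second, slot = slot, gain = best)
}

# Polishing: alternate segment-reversal (2-opt), single-locus relocation and
# the window-3 ripple until none of them improves the composite objective.
# Greedy insertion can leave a terminal segment attached in reverse
# orientation ("fold-back"); a window of 3 cannot unfold a long reversed
# block, whereas one 2-opt reversal can, at the cost of re-scoring only the
# two boundary edges.
polish_order <- function(ord, M, max_rounds = 20L) {
  for (round in seq_len(max_rounds)) {
    r1 <- two_opt_pass(ord, M)
    r2 <- relocate_pass(r1$ord, M)
    r3 <- ripple_order(r2$ord, M)
    changed <- r1$changed || r2$changed || !identical(r3, r2$ord)
    ord <- r3
    if (!changed) break
  }
  ord
}

# reverse ord[i..j] wherever it strictly improves the objective; only the
# boundary edges (i-1, i) and (j, j+1) change.
two_opt_pass <- function(ord, M, tol = 1e-9) {
  k <- length(ord)
  changed <- FALSE
  repeat {
    e <- c(0, M[cbind(ord[-k], ord[-1L])], 0)   # e[i+1] = edge (i, i+1)
    best <- c(0, NA, NA)
    for (i in seq_len(k - 1L)) {
      j <- i:(k - 1L) + 1L                      # candidate block ends
      left <- if (i > 1L) M[ord[i - 1L], ord[j]] else 0
      right <- ifelse(j < k, M[ord[i], ord[pmin(j + 1L, k)]], 0)
      delta <- left + right - e[i] - e[j + 1L]
      m <- which.max(delta)
      if (delta[m] > best[1L] + tol) best <- c(delta[m], i, j[m])
    }
    if (is.na(best[2L])) break
    ord[best[2L]:best[3L]] <- rev(ord[best[2L]:best[3L]])
    changed <- TRUE
  }
  list(ord = ord, changed = changed)
}

# move contiguous segments (length 1..max_len, either orientation) to their
# best slot wherever it strictly improves the objective
relocate_pass <- function(ord, M, tol = 1e-9, max_len = 3L) {
  changed <- FALSE
  repeat {
    k <- length(ord)
    moved <- FALSE
    for (len in seq_len(min(max_len, k - 1L))) {
      for (i in seq_len(k - len + 1L)) {
        j <- i + len - 1L
        seg <- ord[i:j]
        rest <- ord[-(i:j)]
        lose <- (if (i > 1L) M[ord[i - 1L], seg[1L]] else 0) +
          (if (j < k) M[seg[len], ord[j + 1L]] else 0) -
          (if (i > 1L && j < k) M[ord[i - 1L], ord[j + 1L]] else 0)
        kr <- length(rest)
        adj <- M[cbind(rest[-kr], rest[-1L])]
        best_gain <- -Inf
        for (orient in if (len > 1L) list(seg, rev(seg)) else list(seg)) {
          Ma <- M[rest, orient[1L]]     # entry edge
          Mb <- M[rest, orient[len]]    # exit edge
          gains <- c(Mb[1L], Ma[-kr] + Mb[-1L] - adj, Ma[kr])
          s <- which.max(gains)
          if (gains[s] > best_gain) {
            best_gain <- gains[s]
            best <- list(orient = orient, slot = s)
          }
        }
        if (best_gain > lose + tol) {
          ord <- append(rest, best$orient, after = best$slot - 1L)
          moved <- TRUE
          changed <- TRUE
          break
        }
      }
      if (moved) break
    }
    if (!moved) break
  }
  list(ord = ord, changed = changed)
}

# all 6 permutations of a window of 3
.perm3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

ripple_order <- function(ord, M, max_passes = 30L) {
  k <- length(ord)
  if (k < 3L) return(ord)
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (i in seq_len(k - 2L)) {
      w <- ord[i:(i + 2L)]
      left <- if (i > 1L) ord[i - 1L] else NA
      right <- if (i + 3L <= k) ord[i + 3L] else NA
      score <- function(p) {
        s <- M[w[p[1L]], w[p[2L]]] + M[w[p[2L]], w[p[3L]]]
        if (!is.na(left)) s <- s + M[left, w[p[1L]]]
        if (!is.na(right)) s <- s + M[w[p[3L]], right]
        s
      }
      sc <- apply(.perm3, 1L, score)
      if (max(sc) > sc[1L] + 1e-9) {
        best <- which.max(sc)
        ord[i:(i + 2L)] <- w[.perm3[best, ]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ord
}

# connected components of the locus linkage graph (edges: lod >= threshold)
linkage_components <- function(lod, threshold) {
  n <- nrow(lod)
  comp <- integer(n)
  cur <- 0L
  adj <- lod >= threshold
  diag(adj) <- FALSE
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# chromosome order of bins: short arm distal -> centromere, then long arm
# centromere -> distal
bin_chrom_order <- function(bins) {
  s <- bins[bins$arm == "S", ]
  l <- bins[bins$arm == "L", ]
  c(s$bin_name[order(-s$frac_start)], l$bin_name[order(l$frac_start)])
}

orient_order <- function(ord, locus_of, marker_info, bin_order) {
  flip <- NA
  if (!is.null(bin_order) && !is.null(marker_info)) {
    amk <- marker_info[marker_info$is_anchor &
                         marker_info$bin_name %in% bin_order, ]
    if (nrow(amk)) {
      locus <- locus_of[amk$marker_id]
      rank_bin <- match(amk$bin_name, bin_order)
      rank_pos <- match(locus, ord)
      keep <- !is.na(rank_pos)
      if (sum(keep) >= 2L && stats::sd(rank_bin[keep]) > 0) {
        ct <- suppressWarnings(stats::cor(rank_pos[keep], rank_bin[keep],
                                          method = "kendall"))
        if (!is.na(ct) && ct != 0) flip <- ct < 0
      }
    }
  }
  if (is.na(flip)) flip <- ord[1L] > ord[length(ord)]  # lexicographic tie-break
  if (flip) rev(ord) else ord
}

#' Assign deletion bins to all mapped loci
#'
#' Anchor loci carry known bins; bin boundaries on the cR axis are placed at
#' the midpoint between adjacent anchor loci of different bins, terminal bins
#' extending to the map ends, and every locus inherits the bin of its cR
#' interval.  If one bin's anchors are interleaved with another's, a warning
#' is issued, bins are ordered by their median anchor position, and
#' boundaries are clipped to be non-decreasing.
#'
#' @param map an [rh_map] object.
#' @param marker_info marker metadata with anchor flags and bin names.
#' @return the map with `bin_name` filled; per-bin cR spans in
#'   `attr(, "bin_spans")` (data frame `bin_name`, `cr_start`, `cr_end`,
#'   `map_cR`).
#' @export
assign_bins <- function(map, marker_info) {
  marker_info <- validate_marker_info(marker_info)
  members <- attr(map, "markers")
  anchor_bin <- vapply(map$locus_id, function(lc) {
    mk <- intersect(members[[lc]],
                    marker_info$marker_id[marker_info$is_anchor])
    if (!length(mk)) return(NA_character_)
    b <- marker_info$bin_name[match(mk, marker_info$marker_id)]
    tab <- sort(table(b), decreasing = TRUE)
    names(tab)[tab == tab[1L]][1L]           # majority, tie lexicographic
  }, "")
  ai <- which(!is.na(anchor_bin))
  if (!length(ai)) stop("no anchor locus on the map; cannot assign bins")
  apos <- map$position_cR[ai]
  abin <- anchor_bin[ai]
  blocks <- rle(abin)
  if (anyDuplicated(blocks$values)) {
    warning("anchors of different bins are interleaved on the map; ",
            "assigning bins by median anchor position")
    med <- vapply(split(apos, abin), stats::median, 0)
    ubin <- names(sort(med))
  } else ubin <- blocks$values
  lo <- hi <- numeric(length(ubin))
  for (j in seq_along(ubin)) {
    p <- apos[abin == ubin[j]]
    lo[j] <- if (j == 1L) min(map$position_cR) else
      (max(apos[abin == ubin[j - 1L]]) + min(p)) / 2
    hi[j] <- if (j == length(ubin)) max(map$position_cR) else
      (max(p) + min(apos[abin == ubin[j + 1L]])) / 2
  }
  lo <- cummax(lo); hi <- pmax(lo, cummax(hi))
  idx <- findInterval(map$position_cR, lo, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  map$bin_name <- ubin[idx]
  attr(map, "bin_spans") <- data.frame(bin_name = ubin, cr_start = lo,
                                       cr_end = hi, map_cR = hi - lo,
                                       stringsAsFactors = FALSE)
  map
}

#' Order concordance between two maps
#'
#' Kendall rank correlation of two marker orders on their shared markers,
#' reported as a magnitude plus an orientation flag (a perfectly reversed
#' order is concordance 1 with `reversed = TRUE`).
#'
#' @param order_a,order_b character vectors of marker ids in map order.
#' @return list with `tau` (in `[0, 1]`), `reversed`, `n_shared`.
#' @export
order_concordance <- function(order_a, order_b) {
  shared <- intersect(order_a, order_b)
  if (length(shared) < 2L) stop("need at least 2 shared markers")
  ra <- match(shared, order_a)
  rb <- match(shared, order_b)
  tau <- stats::cor(ra, rb, method = "kendall")
  list(tau = abs(tau), reversed = tau < 0, n_shared = length(shared))
}
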