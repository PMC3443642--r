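#' Two-point breakage statistics for a marker pair
#'
#' For two markers the centiRay distance is defined directly from the data:
#' 100 times the number of lines in which the two loci are in different
#' states (one retained, one deleted) divided by the number of lines
#' genotyped at both.  On top of this the haploid equal-retention model gives
#' a breakage-probability estimate and a linkage LOD.  Writing `r` for the
#' pooled retention of the pair and `theta` for the probability of at least
#' one effective break between the loci, cell probabilities are
#' `P(1,1) = (1-theta) r + theta r^2`, `P(1,0) = P(0,1) = theta r (1-r)`,
#' `P(0,0) = (1-theta)(1-r) + theta (1-r)^2`; independence is the `theta = 1`
#' boundary of the same family.  The moment estimate
#' `theta_hat = min(1, D / (2 r (1-r)))`, with `D` the discordance fraction,
#' is also the maximiser of this likelihood, and the LOD is the base-10
#' log-likelihood ratio of `theta_hat` against independence.
#'
#' @param g an [rh_genotypes] matrix.
#' @param marker_a,marker_b marker ids (or column indices).
#' @return list with elements `marker_a`, `marker_b`, `n_informative`,
#'   `n_discordant`, `distance_cR`, `r_hat`, `theta_hat`, `lod`,
#'   `degenerate` (`TRUE` when `r_hat` is 0 or 1 and `theta_hat` is
#'   undefined; then `lod` is 0).
#' @examples
#' g <- rh_genotypes(matrix(c(1, 1, 0, 1, 1, 0, 0, 1), 4, 2,
#'                   dimnames = list(paste0("L", 1:4), c("mA", "mB"))))
#' two_point(g, "mA", "mB")$distance_cR
#' @export
two_point <- function(g, marker_a, marker_b) {
  x <- unclass(g)[, marker_a]
  y <- unclass(g)[, marker_b]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 1L) stop("no line genotyped at both markers")
  a <- sum(x[ok] == 1L & y[ok] == 1L)
  b <- sum(x[ok] != y[ok])
  cc <- n - a - b
  est <- tp_estimate(a, b, cc)
  c(list(marker_a = if (is.character(marker_a)) marker_a else colnames(g)[marker_a],
         marker_b = if (is.character(marker_b)) marker_b else colnames(g)[marker_b]),
    est)
}

# scalar two-point estimate from the 2x2 concordance counts
tp_estimate <- function(n11, ndisc, n00) {
  n <- n11 + ndisc + n00
  D <- ndisc / n
  r <- (2 * n11 + ndisc) / (2 * n)
  if (r <= 0 || r >= 1) {
    return(list(n_informative = n, n_discordant = ndisc,
                distance_cR = 100 * D, r_hat = r, theta_hat = NA_real_,
                lod = 0, degenerate = TRUE))
  }
  theta <- min(1, D / (2 * r * (1 - r)))
  lod <- (tp_loglik(theta, n11, ndisc, n00, r) -
          tp_loglik(1, n11, ndisc, n00, r)) / log(10)
  list(n_informative = n, n_discordant = ndisc, distance_cR = 100 * D,
       r_hat = r, theta_hat = theta, lod = max(0, lod), degenerate = FALSE)
}

# natural-log likelihood of the haploid two-point model (0*log(0) = 0)
tp_loglik <- function(theta, n11, ndisc, n00, r) {
  term <- function(k, p) if (k == 0) 0 else k * log(p)
  term(n11, r * (1 - theta * (1 - r))) +
    term(ndisc, theta * r * (1 - r)) +
    term(n00, (1 - r) * (1 - theta * r))
}

#' All-pairs two-point statistics
#'
#' Vectorised computation of the two-point quantities for every marker (or
#' locus) pair of a genotype matrix, with missing calls excluded pairwise.
#'
#' @param g an [rh_genotypes] matrix (or plain 0/1/NA matrix).
#' @return list of symmetric matrices: `n_informative`, `n_discordant`,
#'   `distance_cR`, `r_hat`, `theta_hat`, `lod` (base 10) and `loglik`
#'   (natural-log maximised pair likelihood, the building block of the
#'   composite map objective); `degenerate` is a logical matrix.
#' @export
two_point_all <- function(g) {
  x <- unclass(g)
  R1 <- (x == 1L); R1[is.na(R1)] <- FALSE
  R0 <- (x == 0L); R0[is.na(R0)] <- FALSE
  m1 <- matrix(as.numeric(R1), nrow(x))
  m0 <- matrix(as.numeric(R0), nrow(x))
  n11 <- crossprod(m1)
  n00 <- crossprod(m0)
  ndisc <- crossprod(m1, m0); ndisc <- ndisc + t(ndisc)
  n <- n11 + n00 + ndisc
  D <- ndisc / n
  r <- (2 * n11 + ndisc) / (2 * n)
  degen <- !(r > 0 & r < 1) | n == 0
  rs <- ifelse(degen, 0.5, r)   # placeholder to keep arithmetic finite
  theta <- pmin(D / (2 * rs * (1 - rs)), 1)
  lterm <- function(k, p) ifelse(k == 0, 0, k * log(p))
  ll <- function(th) lterm(n11, rs * (1 - th * (1 - rs))) +
    lterm(ndisc, th * rs * (1 - rs)) +
    lterm(n00, (1 - rs) * (1 - th * rs))
  llmax <- ll(theta)
  lod <- pmax((llmax - ll(matrix(1, nrow(n11), ncol(n11)))) / log(10), 0)
  theta[degen] <- NA_real_
  lod[degen] <- 0
  llmax[degen] <- 0   # degenerate pairs carry no ordering information
  dn <- list(colnames(x), colnames(x))
  out <- list(n_informative = n, n_discordant = ndisc, distance_cR = 100 * D,
              r_hat = r, theta_hat = theta, lod = lod, loglik = llmax,
              degenerate = degen)
  lapply(out, function(m) { dimnames(m) <- dn; m })
}
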