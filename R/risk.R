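#' At-risk status of a couple
#'
#' A pair is "at risk" of an autosomal-recessive condition in their
#' offspring when both members carry a P/LP variant in the same gene.
#'
#' @param i,j individual ids.
#' @param carriers a [carrier_table()].
#' @return 1 or 0.
#' @export
at_risk <- function(i, j, carriers) {
  gi <- carriers$genes[[i]]; gj <- carriers$genes[[j]]
  if (is.null(gi) || is.null(gj)) stop("unknown individual")
  as.integer(length(intersect(gi, gj)) > 0)
}

# n x n 0/1 at-risk matrix over the given ids (diagonal 0)
.risk_matrix <- function(carriers, ids) {
  sets <- carriers$genes[ids]
  genes <- sort(unique(unlist(sets)))
  n <- length(ids)
  if (!length(genes)) return(matrix(0L, n, n))
  M <- vapply(sets, function(g) as.integer(genes %in% g),
              integer(length(genes)))
  M <- matrix(M, nrow = length(genes))
  S <- (crossprod(M) > 0) * 1L
  diag(S) <- 0L
  S
}

# variance of the mean at-risk fraction, intra-group form:
# [ P Var(s) + n(n-1)(n-2) Cov(s_ij, s_ik) ] / P^2 with P = n(n-1)/2 pairs,
# assuming zero covariance between disjoint couples
.var_intra <- function(S) {
  n <- nrow(S)
  s <- S[upper.tri(S)]
  v <- stats::var(s)
  cv <- .cov_shared_index(S)
  P <- n * (n - 1) / 2
  (P * v + n * (n - 1) * (n - 2) * cv) / P^2
}

# sample covariance of (s_ij, s_ik) over all index-sharing couple pairs
.cov_shared_index <- function(S, two_sided = FALSE) {
  if (!two_sided) {
    # within one set: ordered triples (i, j, k) with j != k, both paired to i
    n <- nrow(S)
    if (n < 3) return(0)
    rs <- rowSums(S)
    num_pairs <- n * (n - 1) * (n - 2)
    m1 <- sum(rs * (rs - 1)) / num_pairs       # mean of s_ij * s_ik
    mu <- mean(S[upper.tri(S)])
    m1 - mu^2
  } else {
    # between two sets: s_ij with i in rows, j in cols of S (n1 x n2);
    # index-sharing pairs share either the row or the column individual
    n1 <- nrow(S); n2 <- ncol(S)
    if (n1 * n2 * (n1 + n2 - 2) == 0) return(0)
    rs <- rowSums(S); cs <- colSums(S)
    prod_sum <- sum(rs * (rs - 1)) + sum(cs * (cs - 1))
    m1 <- prod_sum / (n1 * n2 * (n1 + n2 - 2))
    mu <- mean(S)
    m1 - mu^2
  }
}

#' Fraction of at-risk couples within or between groups
#'
#' `mode = "intra"`: all n(n-1)/2 couples formed from two individuals of
#' the index group. `mode = "inter"`: all n1 x n2 couples formed from one
#' index-group member and one individual from any other group. The
#' variance of the mean follows the moment formula with the empirical
#' variance of the s values and the empirical covariance over
#' index-sharing couples, assuming zero covariance between disjoint
#' couples.
#'
#' @param carriers a [carrier_table()].
#' @param index_group group label.
#' @param mode `"intra"` or `"inter"`.
#' @return object of class `risk_estimate`: list with `mean`, `variance`,
#'   `sd`, `mode`, `group`, and the couple count `n_pairs`.
#' @export
group_risk <- function(carriers, index_group, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  grp <- carriers$individuals$group
  ids_in <- carriers$individuals$id[grp == index_group]
  if (mode == "intra") {
    n <- length(ids_in)
    if (n < 2) stop("intra-group risk needs group size >= 2")
    S <- .risk_matrix(carriers, ids_in)
    mu <- mean(S[upper.tri(S)])
    v <- .var_intra(S)
    np <- n * (n - 1) / 2
  } else {
    ids_out <- carriers$individuals$id[grp != index_group]
    if (!length(ids_in) || !length(ids_out)) stop("both sides must be non-empty")
    sets <- carriers$genes
    genes <- sort(unique(unlist(sets[c(ids_in, ids_out)])))
    enc <- function(ids) {
      M <- vapply(sets[ids], function(g) as.integer(genes %in% g),
                  integer(length(genes)))
      matrix(M, nrow = length(genes))
    }
    if (!length(genes)) {
      S <- matrix(0L, length(ids_in), length(ids_out))
    } else {
      S <- (crossprod(enc(ids_in), enc(ids_out)) > 0) * 1L
    }
    mu <- mean(S)
    n1 <- nrow(S); n2 <- ncol(S)
    v <- (n1 * n2 * stats::var(as.vector(S)) +
            n1 * n2 * (n1 + n2 - 2) * .cov_shared_index(S, two_sided = TRUE)) /
      (n1 * n2)^2
    np <- n1 * n2
  }
  structure(list(mean = mu, variance = max(v, 0), sd = sqrt(max(v, 0)),
                 mode = mode, group = index_group, n_pairs = np),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("<risk_estimate> %s %s: mean %.4g (sd %.3g) over %d couples\n",
              x$mode, x$group, x$mean, x$sd, x$n_pairs))
  invisible(x)
}

#' Permutation test for excess intra-group couple risk
#'
#' Tests whether the intra-group at-risk fraction of `index_group` exceeds
#' its inter-group fraction by permuting the group labels `B` times and
#' reporting the fraction of permutations in which the permuted difference
#' is at least the observed one. p = 0 is reported as 1/(B+1) so the
#' result can be quoted as "< 1/B".
#'
#' @param carriers a [carrier_table()].
#' @param index_group group label.
#' @param B number of permutations (default 10,000).
#' @param seed integer seed.
#' @return list with `p`, `delta_obs`, `B`.
#' @export
permutation_test <- function(carriers, index_group, B = 10000, seed = 1) {
  set.seed(seed)
  ids <- carriers$individuals$id
  in_grp <- carriers$individuals$group == index_group
  n_in <- sum(in_grp)
  S <- .risk_matrix(carriers, ids)
  stat <- function(sel) {
    Sii <- S[sel, sel, drop = FALSE]
    Sio <- S[sel, !sel, drop = FALSE]
    mean(Sii[upper.tri(Sii)]) - mean(Sio)
  }
  delta_obs <- stat(in_grp)
  n <- length(ids)
  exceed <- 0L
  for (b in seq_len(B)) {
    sel <- logical(n); sel[sample.int(n, n_in)] <- TRUE
    if (stat(sel) >= delta_obs) exceed <- exceed + 1L
  }
  p <- exceed / B
  list(p = if (p == 0) 1 / (B + 1) else p, delta_obs = delta_obs, B = B,
       p_is_upper_bound = p == 0)
}

#' Kinship-matched simulated first-cousin couple risk
#'
#' Repeatedly samples `n_pairs` couples whose kinship distribution matches
#' a reference histogram (eight bins of width 0.05 on `[0, 0.4)`, e.g. the
#' observed kinship of self-declared first-cousin spouse pairs), and
#' reports the mean and SD of the at-risk fraction over replicates.
#' Per-bin couple counts use the largest-remainder rounding so they sum to
#' `n_pairs` exactly; an individual enters at most one couple per
#' replicate (rejection with a retry cap).
#'
#' @param carriers a [carrier_table()].
#' @param pair_kinship data.frame with columns `i`, `j` (ids) and
#'   `kinship` for the candidate pairs.
#' @param reference_bins numeric vector of 8 proportions (bins
#'   `[0,0.05), ..., [0.35,0.4)`), normalised internally.
#' @param n_pairs couples per replicate (default 150).
#' @param n_reps replicates (default 1000).
#' @param seed integer seed.
#' @return a `risk_estimate` (mode `matched_fc`) with the per-replicate
#'   fractions in `$replicates` and the per-bin couple counts in
#'   `$bin_counts`.
#' @export
matched_fc_risk <- function(carriers, pair_kinship, reference_bins,
                            n_pairs = 150, n_reps = 1000, seed = 1) {
  if (length(reference_bins) != 8) stop("reference_bins must have 8 bins")
  set.seed(seed)
  counts <- largest_remainder(reference_bins / sum(reference_bins), n_pairs)
  bin <- findInterval(pair_kinship$kinship, seq(0, 0.4, by = 0.05),
                      rightmost.closed = FALSE, left.open = FALSE)
  # findInterval gives 1..9 with 9 = >= 0.4; restrict to the 8 bins
  by_bin <- lapply(seq_len(8), function(b) which(bin == b))
  short <- which(counts > 0 & vapply(by_bin, length, 1L) < counts)
  if (length(short))
    stop("insufficient candidate pairs in kinship bin(s) ",
         paste(short, collapse = ", "))
  frac <- numeric(n_reps)
  for (rep_i in seq_len(n_reps)) {
    chosen <- integer(0)
    for (b in which(counts > 0)) {
      cand <- by_bin[[b]]
      got <- integer(0); tries <- 0L
      used <- c(pair_kinship$i[chosen], pair_kinship$j[chosen])
      while (length(got) < counts[b] && tries < 200L) {
        tries <- tries + 1L
        pick <- cand[sample.int(length(cand), 1L)]
        ii <- pair_kinship$i[pick]; jj <- pair_kinship$j[pick]
        if (!(ii %in% used) && !(jj %in% used)) {
          got <- c(got, pick); used <- c(used, ii, jj)
        }
      }
      if (length(got) < counts[b])
        stop("could not fill kinship bin ", b, " without reusing individuals")
      chosen <- c(chosen, got)
    }
    frac[rep_i] <- mean(vapply(chosen, function(pk)
      at_risk(pair_kinship$i[pk], pair_kinship$j[pk], carriers), 1L))
  }
  structure(list(mean = mean(frac), variance = stats::var(frac),
                 sd = stats::sd(frac), mode = "matched_fc", group = NA,
                 n_pairs = n_pairs, replicates = frac, bin_counts = counts),
            class = "risk_estimate")
}

#' Largest-remainder apportionment
#'
#' Rounds `total * proportions` to integers summing to `total`, assigning
#' leftover units to the largest fractional remainders. Reproduces the
#' worked matching example: a bin holding 20/75 = 26.67% of the reference
#' mass receives exactly 40 of 150 couples.
#'
#' @param proportions non-negative weights (normalised internally).
#' @param total integer total to apportion.
#' @return integer vector summing to `total`.
#' @export
largest_remainder <- function(proportions, total) {
  p <- proportions / sum(proportions)
  raw <- p * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  as.integer(base)
}
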