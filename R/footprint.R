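#' @name footprint_model
#' @title Expected ROH/IBD footprints under endogamy and consanguinity
#'
#' @description
#' The model: a population of Ne(t) reproducing pairs in which, each
#' generation, a couple is a degree-i relative pair (connected by a single
#' path) with probability r_i. The average parental kinship is
#' k = sum_i r_i/4^i (valid while k < 1/4). The time to the most recent
#' common ancestor (TMRCA) of two chromosomes in *unrelated* individuals
#' (t_between) follows a discrete coalescent with an effective
#' chromosome-pair scale S(t) = 4 Ne(t) (1 - 3k); the TMRCA of the two
#' homologues of one individual (t_within) additionally has probability
#' k/(1-3k) of a rapid within-family coalescence. Given these
#' distributions, classical segment-length theory yields the expected
#' genome fraction in IBD (resp. ROH) segments of each length class.
NULL

#' Effective chromosome-pair coalescence scale
#'
#' Builds the per-generation scale S(t) that drives both TMRCA
#' distributions, extended as a constant beyond the observed horizon.
#'
#' `effective_trajectory()` takes model parameters directly: `ne_pairs`
#' reproducing pairs per generation (scalar or vector) and kinship `k`,
#' giving S(t) = 4 ne_pairs(t) (1 - 3k).
#'
#' `rescale_ne()` takes an estimator-output trajectory ([ne_trajectory()],
#' in diploid individuals). IBD-based estimators infer Ne(t)(1-3k) rather
#' than Ne(t), so after halving (individuals to pairs) the estimate *is*
#' the effective scale: S(t) = Ne_hat(t)/2, with no further k correction.
#'
#' @param ne_pairs numeric scalar/vector of reproducing pairs per generation.
#' @param k parental kinship (must be < 1/4).
#' @param horizon minimum number of generations to materialise.
#' @return object of class `effective_trajectory`: list with `S` (numeric
#'   vector, constant-extended) and `k`.
#' @export
effective_trajectory <- function(ne_pairs, k = 0, horizon = 50) {
  if (k >= 0.25) stop("k must be < 1/4")
  S <- 4 * ne_pairs * (1 - 3 * k)
  if (any(S <= 1)) stop("effective scale must exceed 1 chromosome pair")
  if (length(S) < horizon) S <- c(S, rep(S[length(S)], horizon - length(S)))
  structure(list(S = S, k = k), class = "effective_trajectory")
}

#' @rdname effective_trajectory
#' @param traj an [ne_trajectory()] as printed by the upstream estimator
#'   (diploid individuals).
#' @export
rescale_ne <- function(traj, k = 0, horizon = 50) {
  stopifnot(inherits(traj, "ne_trajectory"))
  if (k >= 0.25) stop("k must be < 1/4")
  S <- traj$ne / 2
  if (any(S <= 1)) stop("effective scale must exceed 1 chromosome pair")
  if (length(S) < horizon) S <- c(S, rep(S[length(S)], horizon - length(S)))
  structure(list(S = S, k = k), class = "effective_trajectory")
}

# S(t) with constant extension
.S_at <- function(eff, t) {
  S <- eff$S
  ifelse(t <= length(S), S[pmin(t, length(S))], S[length(S)])
}

.S_vec <- function(eff, T_max) {
  S <- eff$S
  if (T_max <= length(S)) S[seq_len(T_max)]
  else c(S, rep(S[length(S)], T_max - length(S)))
}

# default horizon: survival below tail_tol under the constant-extended tail
.default_T_max <- function(eff, tail_tol = 1e-9, cap = 5e6) {
  S_inf <- eff$S[length(eff$S)]
  T_est <- length(eff$S) + ceiling(log(tail_tol) / log(1 - 1 / S_inf))
  min(max(T_est, length(eff$S) + 10L), cap)
}

#' TMRCA distribution for chromosomes in unrelated individuals
#'
#' Discrete-time coalescent: P(t) = (1/S(t)) prod_{tau<t} (1 - 1/S(tau)).
#' The horizon is chosen automatically so that the truncated tail mass is
#' below `tail_tol`; the distribution is renormalised (with a warning if
#' the truncated mass exceeds 1e-6).
#'
#' @param eff an [effective_trajectory()].
#' @param T_max optional explicit horizon.
#' @param tail_tol target truncated tail mass for the automatic horizon.
#' @return object of class `tmrca_distribution`: list with `p` (P(t) for
#'   t = 1..T_max) and `flavor = "between"`.
#' @export
tmrca_between <- function(eff, T_max = NULL, tail_tol = 1e-9) {
  if (is.null(T_max)) T_max <- .default_T_max(eff, tail_tol)
  q <- 1 / .S_vec(eff, T_max)
  surv <- cumprod(1 - q)
  p <- q * c(1, surv[-length(surv)])
  mass <- sum(p)
  if (1 - mass > 1e-6)
    warning(sprintf("truncated tail mass %.3g at T_max = %d; renormalising",
                    1 - mass, T_max))
  structure(list(p = p / mass, flavor = "between", eff = eff),
            class = "tmrca_distribution")
}

#' @export
print.tmrca_distribution <- function(x, ...) {
  cat(sprintf("<tmrca_distribution> flavor %s, horizon %d, mean %.1f generations\n",
              x$flavor, length(x$p), sum(x$p * seq_along(x$p))))
  invisible(x)
}

#' TMRCA distribution for the two homologues of one individual
#'
#' Composite distribution: for t <= `T_switch` the within-family Markov
#' chain is run as a Monte-Carlo lineage simulation (`mc_iterations`
#' replicates). Two lineages start in the focal individual's parents; each
#' generation, the couple currently carrying them is a degree-i relative
#' pair with probability `r[i]`. On a connecting path both lineages stay
#' on-path with probability 1/4 per generation (each picks the connecting
#' parent with probability 1/2); a degree-1 (sibling) pair ascends into
#' the shared parental couple, where landing in the same individual gives
#' coalescence with probability 1/2; any lineage leaving the path makes
#' the pair "unrelated", coalescing with probability 1/S(t) per
#' generation. This realisation reproduces the rapid-coalescence mass
#' k/(1-3k) predicted by the separation-of-timescales analysis.
#'
#' For t > `T_switch` the distribution is proportional to the unrelated
#' (between) form, the proportionality constant being fixed by overall
#' normalisation. Results are insensitive to `T_switch` in 10..50.
#'
#' @param eff an [effective_trajectory()].
#' @param r numeric consanguinity rates (r1..r5, padded with zeros).
#' @param T_switch generation at which the chain hands over to the scaled
#'   coalescent form (default 50).
#' @param mc_iterations Monte-Carlo replicates (default 100,000; < 1000
#'   warns).
#' @param seed integer seed.
#' @param eff_tail optional alternative [effective_trajectory()] used for
#'   the t > T_switch tail, e.g. to model a sudden historic change in
#'   consanguinity (kinship set near zero in the past).
#' @return a `tmrca_distribution` with `flavor = "within"`.
#' @export
tmrca_within <- function(eff, r, T_switch = 50, mc_iterations = 1e5,
                         seed = NULL, eff_tail = eff) {
  if (length(r) > 5) stop("at most five rate components")
  r <- c(r, numeric(5 - length(r)))
  k <- kinship_from_r(r)  # errors if k >= 1/4
  if (mc_iterations < 1000) warning("mc_iterations < 1000: within-family mass will be noisy")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(mc_iterations)
  # states: 0 unrelated; 1..5 on-path degree j; 6 in couple (relatedness
  # not yet drawn); 7 two homologues of one individual
  state <- rep(6L, n)
  coal <- integer(0)  # coalescence times
  coal_count <- numeric(T_switch)
  alive <- seq_len(n)
  cum_r <- cumsum(r)
  p_rel <- cum_r[5]
  for (t in 2:T_switch) {
    st <- state[alive]
    u <- stats::runif(length(st))
    new_st <- st
    died <- logical(length(st))
    # couple: draw relatedness, convert to on-path degree or unrelated
    i6 <- which(st == 6L)
    if (length(i6)) {
      d <- stats::runif(length(i6))
      deg <- findInterval(d, cum_r, left.open = TRUE) + 1L  # 1..5, 6 = unrelated
      deg[d >= p_rel] <- 0L
      st[i6] <- deg   # 0 or degree j; step applied below
      new_st[i6] <- deg
    }
    # two homologues of one individual -> its parent couple
    i7 <- which(st == 7L)
    if (length(i7)) new_st[i7] <- 6L
    # on-path degree >= 2: stay with prob 1/4, else unrelated
    j2 <- which(st >= 2L & st <= 5L)
    if (length(j2)) {
      stay <- u[j2] < 0.25
      new_st[j2] <- ifelse(stay, st[j2] - 1L, 0L)
    }
    # siblings: ascend into shared couple
    j1 <- which(st == 1L)
    if (length(j1)) {
      v <- u[j1]
      new_st[j1] <- ifelse(v < 0.5, 6L, 7L)   # different members | same member
      dd <- v >= 0.75                          # same member, same chromosome
      died[j1] <- dd
    }
    # unrelated: population coalescence
    j0 <- which(st == 0L)
    if (length(j0)) {
      dd <- u[j0] < 1 / .S_at(eff, t)
      died[j0] <- dd
      new_st[j0] <- 0L
    }
    coal_count[t] <- coal_count[t] + sum(died)
    keep <- !died
    state[alive] <- new_st
    alive <- alive[keep]
    if (!length(alive)) break
  }
  p_head <- coal_count / n
  m_tail <- 1 - sum(p_head)
  # tail proportional to the between form beyond T_switch
  bt <- tmrca_between(eff_tail)
  T_max <- max(length(bt$p), T_switch)
  p <- c(p_head, numeric(T_max - T_switch))
  if (m_tail > 0 && T_max > T_switch) {
    g <- bt$p[(T_switch + 1):T_max]
    p[(T_switch + 1):T_max] <- m_tail * g / sum(g)
  }
  structure(list(p = p, flavor = "within", eff = eff, r = r, k = k,
                 T_switch = T_switch, mc_iterations = n),
            class = "tmrca_distribution")
}

#' Expected segment density at a given TMRCA
#'
#' Mean number of segments per Morgan of length l on a chromosome of
#' length L Morgans when the TMRCA is t generations:
#' 4 t exp(-2 t l) (1 + t (L - l)).
#'
#' @param l segment length (Morgan), 0 <= l <= L.
#' @param L chromosome length (Morgan).
#' @param t TMRCA in generations (>= 1); vectorised over `t`.
#' @return expected count density per Morgan.
#' @export
segment_density <- function(l, L, t) {
  if (any(l < 0) || any(l > L)) stop("need 0 <= l <= L")
  4 * t * exp(-2 * t * l) * (1 + t * (L - l))
}

#' Expected chromosome length covered by segments in a length window
#'
#' Closed form of the integral of l * [segment_density] over [l1, l2]:
#' exp(-2 t l1) (L + 2 L t l1 - 2 t l1^2) - exp(-2 t l2) (L + 2 L t l2 - 2 t l2^2).
#' `l2 = Inf` gives the total length L recovered as l1 -> 0.
#'
#' @param l1,l2 window bounds in Morgan, 0 <= l1 <= l2 <= L or Inf.
#' @param L chromosome length (Morgan).
#' @param t TMRCA in generations; vectorised over `t`.
#' @return expected covered length in Morgan.
#' @export
expected_coverage <- function(l1, l2, L, t) {
  if (l1 > l2) stop("need l1 <= l2")
  term <- function(l) {
    if (is.infinite(l)) return(0)
    exp(-2 * t * l) * (L + 2 * L * t * l - 2 * t * l^2)
  }
  term(l1) - term(l2)
}

# sum_t P(t) * term(l, t), truncating the t-sum where exp(-2tl) vanishes
.coverage_term_sum <- function(p, l, L) {
  if (is.infinite(l)) return(0)
  if (l == 0) return(L * sum(p))
  Tl <- min(length(p), ceiling(60 / (2 * l)))
  t <- seq_len(Tl)
  sum(p[t] * exp(-2 * t * l) * (L + 2 * L * t * l - 2 * t * l^2))
}

#' Expected genomic footprint under a TMRCA distribution
#'
#' For each 1 cM (by default) length bin, sums the expected covered length
#' over the TMRCA distribution and over chromosomes, divided by the total
#' genome length. A "within" distribution yields the expected ROH
#' footprint, a "between" distribution the expected IBD footprint.
#'
#' @param dist a `tmrca_distribution`.
#' @param chrom_cM numeric vector of chromosome lengths in cM.
#' @param lmin,lmax,binsize length bins in cM (default 1 cM bins on [5, 30)).
#' @return a `footprint_curve` data.frame (`bin_start_cM`, `fraction`).
#' @export
expected_footprint <- function(dist, chrom_cM, lmin = 5, lmax = 30, binsize = 1) {
  stopifnot(inherits(dist, "tmrca_distribution"))
  if (!length(dist$p)) stop("empty TMRCA distribution")
  Lm <- chrom_cM / 100
  starts <- seq(lmin, lmax - binsize, by = binsize)
  frac <- vapply(starts, function(s) {
    l1 <- s / 100; l2 <- (s + binsize) / 100
    cov <- sum(vapply(Lm, function(L)
      .coverage_term_sum(dist$p, l1, L) - .coverage_term_sum(dist$p, l2, L),
      numeric(1)))
    cov / sum(Lm)
  }, numeric(1))
  out <- data.frame(bin_start_cM = starts, fraction = frac)
  attr(out, "mode") <- if (dist$flavor == "within") "roh" else "ibd"
  class(out) <- c("footprint_curve", "data.frame")
  out
}

#' Write a footprint curve as tab-delimited text
#'
#' @param curve a `footprint_curve`.
#' @param path output path.
#' @export
write_footprint <- function(curve, path) {
  utils::write.table(data.frame(bin_start_cM = curve$bin_start_cM,
                                expected_fraction = sprintf("%.8g", curve$fraction)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
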