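#' Call runs of homozygosity with a sliding-window algorithm
#'
#' Window-based ROH detection with the PLINK-style parameterisation:
#' windows of `window_snp` SNPs slide along each chromosome and a window is
#' "homozygous" when it contains at most `window_het` heterozygous and at
#' most `window_missing` missing calls. Each SNP is scored by the
#' proportion of overlapping windows that are homozygous and is a "hit"
#' when that proportion reaches `window_threshold` (SNPs near chromosome
#' ends overlap fewer windows, following the de-facto PLINK convention).
#' Maximal stretches of hit SNPs are then split at physical gaps larger
#' than `gap` kb, trimmed to homozygous non-missing end SNPs, and reported
#' when they contain at least `snp` SNPs, span at least `kb` kb, and have a
#' SNP density of at most `density` kb per SNP.
#'
#' @param genotype integer vector of per-site genotypes for one individual:
#'   0/2 homozygous, 1 heterozygous, NA missing; ordered like `sites`.
#' @param sites data.frame with columns `chrom`, `pos` (bp) and `cM`.
#' @param map a [genetic_map()] used to attach cM coordinates.
#' @param params list overriding any of the defaults
#'   `list(window_snp = 50, snp = 50, kb = 1500, gap = 1000, density = 50,
#'   window_missing = 5, window_het = 1, window_threshold = 0.05)`.
#' @param sample_id carrier id for the output table.
#' @return an ROH [segment_table()].
#' @export
call_roh <- function(genotype, sites, map, params = list(), sample_id = "sample") {
  p <- utils::modifyList(list(window_snp = 50L, snp = 50L, kb = 1500,
                              gap = 1000, density = 50,
                              window_missing = 5L, window_het = 1L,
                              window_threshold = 0.05), params)
  stopifnot(length(genotype) == nrow(sites))
  bad <- setdiff(unique(sites$chrom), names(map))
  if (length(bad)) stop("unmapped chromosome(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    idx <- idx[order(sites$pos[idx])]
    g <- genotype[idx]; pos <- sites$pos[idx]
    runs <- .roh_runs_chr(g, pos, p)
    if (is.null(runs)) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start_bp = pos[runs[, 1]], end_bp = pos[runs[, 2]] + 1,
      start_cM = bp_to_cM(map, ch, pos[runs[, 1]]),
      end_cM = bp_to_cM(map, ch, pos[runs[, 2]]),
      n_snp = runs[, 2] - runs[, 1] + 1L
    )
  }
  d <- do.call(rbind, out)
  if (is.null(d)) return(segment_table())
  segment_table(carrier_a = rep(sample_id, nrow(d)), carrier_b = NA_character_,
                chrom = d$chrom, start_bp = d$start_bp, end_bp = d$end_bp,
                start_cM = d$start_cM, end_cM = d$end_cM)
}

# hit-SNP runs for one chromosome; returns matrix of (start index, end index)
.roh_runs_chr <- function(g, pos, p) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  W <- min(p$window_snp, n)
  nw <- n - W + 1L
  if (nw < 1L) return(NULL)
  cs_het <- cumsum(c(0L, het)); cs_mis <- cumsum(c(0L, mis))
  wh <- cs_het[(W + 1L):(W + nw)] - cs_het[1:nw]       # hets per window
  wm <- cs_mis[(W + 1L):(W + nw)] - cs_mis[1:nw]
  wok <- as.integer(wh <= p$window_het & wm <= p$window_missing)
  # per-SNP: proportion of overlapping windows that are homozygous
  cs_ok <- cumsum(c(0L, wok))
  i <- seq_len(n)
  lo <- pmax(1L, i - W + 1L); hi <- pmin(nw, i)
  cnt_ok <- cs_ok[hi + 1L] - cs_ok[lo]
  cnt_tot <- hi - lo + 1L
  hit <- cnt_tot > 0L & (cnt_ok / cnt_tot) >= p$window_threshold
  if (!any(hit)) return(NULL)
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])
  # split segments at gaps > gap kb
  res <- list()
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1]; b <- segs[s, 2]
    if (b > a) {
      gaps <- which(diff(pos[a:b]) > p$gap * 1000) + a - 1L
      cutpts <- c(a - 1L, gaps, b)
    } else cutpts <- c(a - 1L, b)
    for (k in seq_len(length(cutpts) - 1L))
      res[[length(res) + 1L]] <- c(cutpts[k] + 1L, cutpts[k + 1L])
  }
  segs <- do.call(rbind, res)
  # trim ends to homozygous non-missing SNPs, then apply final thresholds
  keep <- list()
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1]; b <- segs[s, 2]
    while (a <= b && (mis[a] || het[a])) a <- a + 1L
    while (b >= a && (mis[b] || het[b])) b <- b - 1L
    if (a > b) next
    nsnp <- b - a + 1L
    span_kb <- (pos[b] - pos[a] + 1) / 1000
    if (nsnp >= p$snp && span_kb >= p$kb && span_kb / nsnp <= p$density)
      keep[[length(keep) + 1L]] <- c(a, b)
  }
  if (!length(keep)) return(NULL)
  do.call(rbind, keep)
}

#' Remove short ROHs overlapping centromeres
#'
#' ROHs shorter than `min_mb` Mb that overlap a centromere interval are
#' removed (they are typically artefacts of long SNP gaps); ROHs at or
#' above `min_mb` Mb are retained regardless of overlap.
#'
#' @param segments a [segment_table()].
#' @param centromeres data.frame with columns `chrom`, `start_bp`, `end_bp`.
#' @param min_mb retention threshold in Mb (default 10).
#' @return the filtered `segment_table`.
#' @export
filter_centromere <- function(segments, centromeres, min_mb = 10) {
  if (!nrow(segments)) return(segments)
  drop <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    len_mb <- (segments$end_bp[i] - segments$start_bp[i]) / 1e6
    if (len_mb >= min_mb) next
    cc <- centromeres[centromeres$chrom == segments$chrom[i], , drop = FALSE]
    if (!nrow(cc)) next
    ov <- segments$start_bp[i] < cc$end_bp & cc$start_bp < segments$end_bp[i]
    drop[i] <- any(ov)
  }
  segments[!drop, , drop = FALSE]
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH: the summed bp length of one individual's autosomal ROHs divided
#' by the autosomal genome length. ROHs must be disjoint (as emitted by
#' the caller); overlap is an error.
#'
#' @param segments ROH rows for one individual.
#' @param autosome_length_bp total autosomal length in bp.
#' @return a fraction in `[0, 1]`.
#' @export
compute_froh <- function(segments, autosome_length_bp) {
  if (!nrow(segments)) return(0)
  if (!all(is_roh(segments))) stop("compute_froh expects ROH rows only")
  if (length(unique(segments$carrier_a)) > 1L)
    stop("compute_froh expects a single individual")
  for (ch in unique(segments$chrom)) {
    d <- segments[segments$chrom == ch, ]
    d <- d[order(d$start_bp), ]
    if (nrow(d) > 1L && any(d$start_bp[-1] < d$end_bp[-nrow(d)]))
      stop("overlapping ROHs on chromosome ", ch)
  }
  tot <- sum(segments$end_bp - segments$start_bp)
  f <- tot / autosome_length_bp
  if (f > 1) stop("F_ROH > 1: segment lengths exceed the genome length")
  f
}

#' The 15 classification statistics of an ROH profile
#'
#' Only ROHs longer than 10 cM contribute. Statistic 1 is the total cM
#' length of the ten longest such ROHs (fewer than ten: sum what exists);
#' statistics 2-15 count ROHs with length in `[10,20), [20,30), ...,
#' [140,150)` cM. ROHs of 150 cM or more are counted in the last bin
#' rather than dropped, so the strongest signal is never discarded.
#'
#' @param tract_cM numeric vector of one individual's ROH lengths in cM
#'   (or a [segment_table()] of ROH rows, whose `length_cM` is used).
#' @return numeric vector of length 15.
#' @export
extract_features <- function(tract_cM) {
  if (is.data.frame(tract_cM)) tract_cM <- tract_cM$length_cM
  l <- tract_cM[tract_cM > 10]
  s1 <- sum(utils::head(sort(l, decreasing = TRUE), 10L))
  bins <- pmin(floor(l / 10), 14)   # 1 = [10,20), ..., 14 = [140, Inf)
  counts <- tabulate(bins, nbins = 14L)
  c(s1, counts)
}

#' Empirical genomic footprint of ROH or IBD segments
#'
#' The footprint in a 1 cM length bin is the genome fraction (in genetic
#' map units) covered by segments of that length class, averaged over the
#' sampling units: individuals for ROH (denominator `n`), chromosome pairs
#' in different individuals for IBD (denominator `2n(2n-2)/2`).
#'
#' @param segments a [segment_table()] (ROH rows for `mode = "roh"`, IBD
#'   rows for `mode = "ibd"`).
#' @param n_individuals number of individuals in the sample (not just
#'   segment carriers).
#' @param genome_cM total genome length in cM.
#' @param lmin,lmax length range in cM (default 5-30, the range over which
#'   chip-based calls are reliable and footprints are not dominated by
#'   noise from rare very long segments).
#' @param binsize bin width in cM.
#' @param mode `"roh"` or `"ibd"`.
#' @return data.frame of class `footprint_curve` with columns `bin_start_cM`
#'   (each point labels the beginning of its interval) and `fraction`.
#' @export
empirical_footprint <- function(segments, n_individuals, genome_cM,
                                lmin = 5, lmax = 30, binsize = 1,
                                mode = c("roh", "ibd")) {
  mode <- match.arg(mode)
  starts <- seq(lmin, lmax - binsize, by = binsize)
  denom <- if (mode == "roh") {
    if (n_individuals < 1) stop("need n_individuals >= 1")
    n_individuals
  } else {
    if (n_individuals < 2) stop("IBD footprint needs n >= 2 individuals")
    n <- n_individuals
    2 * n * (2 * n - 2) / 2
  }
  if (nrow(segments)) {
    keep <- if (mode == "roh") is_roh(segments) else !is_roh(segments)
    l <- segments$length_cM[keep]
    bin <- floor((l - lmin) / binsize) + 1L
    ok <- l >= lmin & l < lmax
    tot <- tapply(l[ok], factor(bin[ok], levels = seq_along(starts)), sum)
    tot[is.na(tot)] <- 0
  } else tot <- numeric(length(starts))
  out <- data.frame(bin_start_cM = starts,
                    fraction = as.numeric(tot) / denom / genome_cM)
  attr(out, "mode") <- mode
  class(out) <- c("footprint_curve", "data.frame")
  out
}
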