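#' @name meiosis
#' @title Gamete formation along a genetic map
#'
#' @description
#' Meiosis is simulated in genetic-map space under the Haldane model:
#' the number of crossovers on a chromosome of genetic length L Morgans is
#' Poisson(L), crossover positions are uniform in cM (no interference), and
#' the starting haplotype is chosen with probability 1/2.
#'
#' Internally every haplotype is a *mosaic*: a run-length encoding of which
#' founder haplotype each stretch of chromosome descends from
#' (`list(end = <segment end positions in cM>, id = <founder haplotype id>)`,
#' with the last end equal to the chromosome length). Autozygosity and IBD
#' are then exact set operations on founder ids, which makes truth tracts
#' cheap and noise-free. Site-level gametes are materialised from mosaics
#' only when genotypes are needed.
NULL

# --- mosaic primitives (internal) ------------------------------------------
# hot kernels live in src/mosaic.cpp; the R implementations below with the
# `_r` suffix are kept as independent references for property tests

# single-segment mosaic covering [0, len] with founder hap id
.mosaic_const <- function(len, id) list(end = len, id = as.integer(id))

.mosaic_splice <- function(h1, h2, cuts, first, len) {
  .cpp_splice(h1$end, h1$id, h2$end, h2$id, cuts, first, len)
}

# reference implementation (pure R) of the splice kernel; like the C++
# kernel it keeps every boundary (no equal-id merging)
.mosaic_splice_r <- function(h1, h2, cuts, first, len) {
  bounds <- c(0, cuts, len)
  nseg <- length(bounds) - 1L
  src <- rep_len(if (first == 1L) c(1L, 2L) else c(2L, 1L), nseg)
  ends <- vector("list", nseg); ids <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    if (b <= a) next
    h <- if (src[i] == 1L) h1 else h2
    e <- h$end
    ja <- findInterval(a, e) + 1L                    # first segment ending > a
    jb <- findInterval(b, e, left.open = TRUE) + 1L  # segment containing b
    ee <- e[ja:jb]; ee[length(ee)] <- b
    ends[[i]] <- ee
    ids[[i]] <- h$id[ja:jb]
  }
  list(end = unlist(ends, use.names = FALSE),
       id = unlist(ids, use.names = FALSE))
}

# one meiosis for one chromosome; h1/h2 parental mosaics, len in cM
.meiosis_chr <- function(h1, h2, len) {
  ncx <- stats::rpois(1L, len / 100)
  first <- if (stats::runif(1L) < 0.5) 1L else 2L
  if (ncx == 0L) return(if (first == 1L) h1 else h2)
  cuts <- sort.int(stats::runif(ncx, 0, len), method = "quick")
  .mosaic_splice(h1, h2, cuts, first, len)
}

# a gamete (list over chromosomes) from an individual ind = list(h1=, h2=);
# randomness drawn here, splicing done by the C++ kernel
.gamete <- function(ind, chrom_len) {
  ncx <- stats::rpois(length(chrom_len), chrom_len / 100)
  first <- ifelse(stats::runif(length(chrom_len)) < 0.5, 1L, 2L)
  cuts <- stats::runif(sum(ncx), 0, rep.int(chrom_len, ncx))
  .cpp_gamete(ind$h1, ind$h2, chrom_len, ncx, first, cuts)
}

# child individual from two parents
.child_of <- function(father, mother, chrom_len) {
  list(h1 = .gamete(father, chrom_len), h2 = .gamete(mother, chrom_len))
}

# founder individual with two fresh haplotype ids
.founder_ind <- function(chrom_len, id1, id2) {
  list(h1 = lapply(chrom_len, .mosaic_const, id = id1),
       h2 = lapply(chrom_len, .mosaic_const, id = id2))
}

# intervals (cM, within-chromosome) where two mosaics carry the same founder id
.mosaic_shared <- function(ha, hb) {
  x <- .cpp_shared(ha$end, ha$id, hb$end, hb$id)
  if (nrow(x) == 0L) NULL else x
}

# reference implementation (pure R) of the shared-interval scan
.mosaic_shared_r <- function(ha, hb) {
  E <- sort(unique(c(ha$end, hb$end)))
  ia <- ha$id[findInterval(E, ha$end, left.open = TRUE) + 1L]
  ib <- hb$id[findInterval(E, hb$end, left.open = TRUE) + 1L]
  eq <- ia == ib
  if (!any(eq)) return(NULL)
  S <- c(0, E[-length(E)])
  r <- rle(eq)
  hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
  keep <- r$values
  cbind(start = S[lo[keep]], end = E[hi[keep]])
}

# total cM shared between two mosaics (no interval detail)
.mosaic_shared_len <- function(ha, hb) {
  x <- .mosaic_shared(ha, hb)
  if (is.null(x)) 0 else sum(x[, 2] - x[, 1])
}

# lengths (cM) of maximal shared intervals, merged runs, as a bare vector
.mosaic_shared_lengths <- function(ha, hb) {
  x <- .mosaic_shared(ha, hb)
  if (is.null(x)) numeric(0) else x[, 2] - x[, 1]
}

# path-recombination-delimited IBD segments (see src/mosaic.cpp)
.mosaic_ibd <- function(ha, hb) {
  x <- .cpp_ibd(ha$end, ha$id, hb$end, hb$id)
  if (nrow(x) == 0L) NULL else x
}

# pure-R reference for the strict IBD extractor: walk elementary intervals,
# open/close on id equality, split shared runs at single-sided boundaries
.mosaic_ibd_r <- function(ha, hb) {
  E <- sort(unique(c(ha$end, hb$end)))
  ia <- ha$id[findInterval(E, ha$end, left.open = TRUE) + 1L]
  ib <- hb$id[findInterval(E, hb$end, left.open = TRUE) + 1L]
  eq <- ia == ib
  S <- c(0, E[-length(E)])
  bd_a <- E %in% ha$end; bd_b <- E %in% hb$end
  single <- xor(bd_a, bd_b)
  st <- numeric(0); en <- numeric(0); cur <- -1
  for (q in seq_along(E)) {
    if (eq[q] && cur < 0) cur <- S[q]
    if (!eq[q] && cur >= 0) {
      if (S[q] > cur) { st <- c(st, cur); en <- c(en, S[q]) }
      cur <- -1
    }
    if (eq[q] && cur >= 0 && single[q] && q < length(E)) {
      if (E[q] > cur) { st <- c(st, cur); en <- c(en, E[q]) }
      cur <- E[q]
    }
  }
  if (cur >= 0 && E[length(E)] > cur) {
    st <- c(st, cur); en <- c(en, E[length(E)])
  }
  if (!length(st)) NULL else cbind(start = st, end = en)
}

# --- public site-level gamete ----------------------------------------------

#' Simulate one gamete from a phased parent
#'
#' @param parent_haplotypes 2 x M integer matrix of parental alleles, columns
#'   ordered along the genome (sites of `sites`).
#' @param sites data.frame with columns `chrom` and `cM` giving each site's
#'   map position (as in a [genotype_panel()]'s `sites`).
#' @param map a [genetic_map()] supplying chromosome lengths.
#' @param seed optional integer seed.
#' @return integer vector of M gamete alleles.
#' @export
make_gamete <- function(parent_haplotypes, sites, map, seed = NULL) {
  stopifnot(is.matrix(parent_haplotypes), nrow(parent_haplotypes) == 2L,
            ncol(parent_haplotypes) == nrow(sites))
  if (!is.null(seed)) set.seed(seed)
  len <- map_lengths(map)
  chrom_len <- stats::setNames(len$cM, len$chrom)
  bad <- setdiff(unique(sites$chrom), len$chrom)
  if (length(bad)) stop("sites on chromosome(s) missing from map: ",
                        paste(bad, collapse = ", "))
  out <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    L <- chrom_len[[ch]]
    cm0 <- min(.map_chrom(map, ch)$cM)
    src <- .meiosis_chr(.mosaic_const(L, 1L), .mosaic_const(L, 2L), L)
    p <- sites$cM[idx] - cm0
    j <- findInterval(p, src$end, left.open = TRUE) + 1L
    j[j > length(src$id)] <- length(src$id)
    out[idx] <- parent_haplotypes[cbind(src$id[j], idx)]
  }
  out
}

# materialise allele vector for a mosaic given a founder haplotype matrix
# (rows = founder haplotype ids) and per-chromosome site cM offsets
.mosaic_alleles <- function(hap, site_cm_by_chr, site_idx_by_chr, hapmat) {
  out <- integer(sum(lengths(site_idx_by_chr)))
  for (ci in seq_along(hap)) {
    idx <- site_idx_by_chr[[ci]]
    if (!length(idx)) next
    h <- hap[[ci]]
    j <- findInterval(site_cm_by_chr[[ci]], h$end, left.open = TRUE) + 1L
    j[j > length(h$id)] <- length(h$id)
    out[idx] <- hapmat[cbind(h$id[j], idx)]
  }
  out
}
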