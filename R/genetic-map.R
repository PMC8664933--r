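#' Genetic maps: the bp <-> cM coordinate backbone
#'
#' A `genetic_map` stores, per chromosome, an ordered table of
#' (position in bp, map position in cM) knots. Physical positions are
#' 1-based; interpolation between knots is piecewise linear. Segment
#' coordinates throughout the package are half-open `[start, end)` in bp
#' with lengths measured in cM, so lengths are additive.
#'
#' @param chrom character vector of chromosome labels, one per knot.
#' @param bp integer physical positions (1-based).
#' @param cM genetic map positions in centimorgans.
#' @return an object of class `genetic_map`: a named list of data.frames
#'   with columns `bp` and `cM`, one per chromosome, ordered by position.
#' @export
genetic_map <- function(chrom, bp, cM) {
  stopifnot(length(chrom) == length(bp), length(bp) == length(cM))
  if (any(bp < 1)) stop("bp positions must be >= 1")
  chrom <- as.character(chrom)
  m <- lapply(split(data.frame(bp = as.numeric(bp), cM = as.numeric(cM)), chrom),
              function(d) {
                d <- d[order(d$bp), , drop = FALSE]
                if (anyDuplicated(d$bp)) stop("duplicate bp positions within a chromosome")
                if (is.unsorted(d$cM)) stop("cM must be non-decreasing in bp (non-monotone map)")
                rownames(d) <- NULL
                d
              })
  # keep chromosomes in first-appearance order, not alphabetical
  m <- m[unique(chrom)]
  structure(m, class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  len <- map_lengths(x)
  cat(sprintf("<genetic_map> %d chromosome(s), %.1f cM over %.0f bp\n",
              length(x), sum(len$cM), sum(len$bp)))
  invisible(x)
}

#' Chromosome lengths of a genetic map
#'
#' @param map a [genetic_map()].
#' @return data.frame with columns `chrom`, `bp` (span in bp) and `cM`
#'   (span in cM). Single-knot chromosomes have zero span.
#' @export
map_lengths <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  data.frame(
    chrom = names(map),
    bp = vapply(map, function(d) max(d$bp) - min(d$bp) + 1, numeric(1)),
    cM = vapply(map, function(d) max(d$cM) - min(d$cM), numeric(1)),
    stringsAsFactors = FALSE
  )
}

.map_chrom <- function(map, chrom) {
  d <- map[[as.character(chrom)]]
  if (is.null(d)) stop("unknown chromosome label: ", chrom)
  d
}

#' Interpolate between physical and genetic coordinates
#'
#' Piecewise-linear interpolation along the map knots; positions outside the
#' knot range are extrapolated with the flanking interval's rate (constant
#' cM beyond the ends for `bp_to_cM`, so off-map tails add no genetic length).
#'
#' @param map a [genetic_map()].
#' @param chrom single chromosome label.
#' @param bp,cM numeric vectors of query positions.
#' @return numeric vector of interpolated coordinates.
#' @export
bp_to_cM <- function(map, chrom, bp) {
  d <- .map_chrom(map, chrom)
  if (nrow(d) == 1L) return(rep(d$cM[1], length(bp)))
  stats::approx(d$bp, d$cM, xout = bp, rule = 2, ties = "ordered")$y
}

#' @rdname bp_to_cM
#' @export
cM_to_bp <- function(map, chrom, cM) {
  d <- .map_chrom(map, chrom)
  if (nrow(d) == 1L) return(rep(d$bp[1], length(cM)))
  # cM may be locally flat; approx() needs strictly increasing x for inversion
  keep <- !duplicated(d$cM)
  stats::approx(d$cM[keep], d$bp[keep], xout = cM, rule = 2, ties = "ordered")$y
}

#' Default synthetic genome map
#'
#' A human-like synthetic autosomal genome: 22 chromosomes totalling
#' 3,500 cM over 2.8 Gbp at a uniform 1.25 cM/Mbp. Chromosome sizes decay
#' linearly (chromosome i gets a share proportional to 23 - i), mimicking
#' the human karyotype's size range without copying it.
#'
#' @param total_cM total map length in cM.
#' @param n_chrom number of autosomes.
#' @param cM_per_Mbp recombination rate, cM per Mbp.
#' @return a [genetic_map()] with two knots per chromosome.
#' @export
uniform_genome_map <- function(total_cM = 3500, n_chrom = 22, cM_per_Mbp = 1.25) {
  share <- (n_chrom + 1 - seq_len(n_chrom)) / sum(seq_len(n_chrom))
  cm <- total_cM * share
  bp <- round(cm / cM_per_Mbp * 1e6)
  genetic_map(
    chrom = rep(as.character(seq_len(n_chrom)), each = 2),
    bp = as.vector(rbind(1, bp)),
    cM = as.vector(rbind(0, cm))
  )
}

#' Read a genetic map file
#'
#' Supported dialects:
#' * `plink_map`: whitespace-delimited, columns chrom, id, cM, bp.
#' * `hapmap_rate`: header + columns chrom, pos (bp), rate (cM/Mbp),
#'   map (cM); the cumulative `map` column is used.
#' * `two_column_cm`: columns bp, cM (single unnamed chromosome "1"),
#'   or chrom, bp, cM.
#'
#' Non-monotone cM within a chromosome is an error. Single-knot
#' chromosomes are allowed (zero genetic length) but flagged with a message.
#'
#' @param path file path.
#' @param dialect one of `"plink_map"`, `"hapmap_rate"`, `"two_column_cm"`.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, dialect = c("plink_map", "hapmap_rate", "two_column_cm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  if (dialect == "plink_map") {
    d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("plink_map requires 4 columns (chrom, id, cM, bp)")
    m <- genetic_map(d[[1]], d[[4]], d[[3]])
  } else if (dialect == "hapmap_rate") {
    d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("hapmap_rate requires 4 columns (chrom, pos, rate, map)")
    m <- genetic_map(d[[1]], d[[2]], d[[4]])
  } else {
    d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    m <- if (ncol(d) >= 3) genetic_map(d[[1]], d[[2]], d[[3]])
         else genetic_map(rep("1", nrow(d)), d[[1]], d[[2]])
  }
  single <- names(m)[vapply(m, nrow, 1L) == 1L]
  if (length(single))
    message("single-knot chromosome(s) with zero genetic length: ",
            paste(single, collapse = ", "))
  m
}

#' Write a genetic map in PLINK .map layout
#'
#' @param map a [genetic_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(names(map), function(ch) {
    d <- map[[ch]]
    data.frame(chrom = ch, id = sprintf("%s_%d", ch, seq_len(nrow(d))),
               cM = d$cM, bp = d$bp, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- data.frame(chrom = tab$chrom, id = tab$id,
                    cM = sprintf("%.10g", tab$cM),
                    bp = sprintf("%d", as.integer(tab$bp)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
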