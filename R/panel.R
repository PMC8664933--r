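#' Phased genotype panels
#'
#' A minimal container for biallelic diploid genotypes: `samples`
#' (identifiers), `sites` (data.frame chrom, pos, ref, alt, cM), and
#' `haps`, a (2 x n_samples) x n_sites integer matrix of 0/1 alleles with
#' rows 2i-1 and 2i holding sample i's two haplotypes. `phased` records
#' whether the haplotype split is meaningful.
#'
#' @param samples character sample ids.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, `cM`.
#' @param haps integer matrix of 0/1 alleles, `2 * length(samples)` rows.
#' @param phased logical.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(samples, sites, haps, phased = TRUE) {
  stopifnot(nrow(haps) == 2 * length(samples), ncol(haps) == nrow(sites))
  if (anyNA(haps) || !all(haps %in% c(0L, 1L)))
    stop("haplotypes must be 0/1 with no missing values")
  structure(list(samples = as.character(samples), sites = sites,
                 haps = haps, phased = isTRUE(phased)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d sites (%s)\n",
              length(x$samples), nrow(x$sites),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Alternate-allele frequencies of a panel
#' @param panel a [genotype_panel()].
#' @return numeric vector of per-site allele-1 frequencies.
#' @export
allele_frequencies <- function(panel) colMeans(panel$haps)

#' Diploid genotype dosages of one sample
#' @param panel a [genotype_panel()].
#' @param i sample index.
#' @return integer vector of 0/1/2 dosages.
#' @export
panel_genotype <- function(panel, i) {
  panel$haps[2L * i - 1L, ] + panel$haps[2L * i, ]
}

# split panel sites by chromosome: per-chromosome site indices and cM
# offsets from the chromosome's map start (the coordinate system mosaics use)
.panel_site_split <- function(panel, map) {
  chroms <- names(map)
  idx <- lapply(chroms, function(ch) which(panel$sites$chrom == ch))
  cm <- lapply(seq_along(chroms), function(ci) {
    cm0 <- min(map[[chroms[ci]]]$cM)
    panel$sites$cM[idx[[ci]]] - cm0
  })
  list(idx = idx, cm = cm)
}

#' Generate a founder haplotype panel
#'
#' Sites are scattered over the map's chromosomes proportionally to
#' genetic length, with allele frequencies drawn from `freq_model` and
#' haplotypes drawn independently per site (linkage-free founders:
#' ROH/IBD structure in this pipeline is created downstream by the
#' pedigree machinery, so founder LD is deliberately absent). Genotype
#' frequencies are in Hardy-Weinberg proportions by construction.
#'
#' @param n_individuals founders to generate.
#' @param map a [genetic_map()].
#' @param n_sites total number of biallelic sites.
#' @param freq_model either a function `n -> n` frequencies, or a numeric
#'   pair of Beta shape parameters; draws are folded to minor-allele
#'   frequencies and truncated to `[maf_min, 0.5]`. Default Beta(0.5, 0.5),
#'   a U-shaped spectrum resembling ascertained common variants.
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param seed integer seed.
#' @return a phased [genotype_panel()].
#' @export
gen_founder_panel <- function(n_individuals, map = uniform_genome_map(),
                              n_sites = 10000, freq_model = c(0.5, 0.5),
                              maf_min = 0.01, seed = 1) {
  set.seed(seed)
  len <- map_lengths(map)
  n_chr <- pmax(1L, round(n_sites * len$cM / sum(len$cM)))
  sites <- do.call(rbind, lapply(seq_along(len$chrom), function(ci) {
    ch <- len$chrom[ci]
    d <- .map_chrom(map, ch)
    pos <- sort(sample(seq(min(d$bp), max(d$bp)), n_chr[ci]))
    data.frame(chrom = ch, pos = pos, ref = "A", alt = "G",
               cM = bp_to_cM(map, ch, pos), stringsAsFactors = FALSE)
  }))
  m <- nrow(sites)
  if (is.function(freq_model)) {
    f <- freq_model(m)
    if (any(f < 0 | f > 1)) stop("freq_model returned frequencies outside [0, 1]")
  } else {
    # folded Beta draws, rejection-truncated to MAF >= maf_min
    f <- numeric(0)
    while (length(f) < m) {
      x <- stats::rbeta(2L * (m - length(f)) + 10L, freq_model[1], freq_model[2])
      x <- pmin(x, 1 - x)
      f <- c(f, x[x >= maf_min])
    }
    f <- f[seq_len(m)]
  }
  haps <- matrix(stats::rbinom(2L * n_individuals * m, 1L,
                               rep(f, each = 2L * n_individuals)),
                 nrow = 2L * n_individuals)
  sites$af <- f   # the model frequency each site was drawn at
  genotype_panel(sprintf("F%04d", seq_len(n_individuals)), sites, haps)
}

#' Write a genotype panel as VCF v4.2
#'
#' Biallelic sites, GT field only; `|` separators when phased, `/` when
#' not.
#'
#' @param panel a [genotype_panel()].
#' @param path output path (plain text).
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=consangkit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")), con)
  sep <- if (panel$phased) "|" else "/"
  n <- length(panel$samples)
  a1 <- panel$haps[2L * seq_len(n) - 1L, , drop = FALSE]
  a2 <- panel$haps[2L * seq_len(n), , drop = FALSE]
  gt <- matrix(paste(a1, a2, sep = sep), nrow = n)
  body <- vapply(seq_len(nrow(panel$sites)), function(j)
    paste(c(panel$sites$chrom[j], panel$sites$pos[j],
            sprintf("s%d", j), panel$sites$ref[j], panel$sites$alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Uses the Bioconductor VariantAnnotation parser (an independent
#' implementation from [write_vcf()], so round-trips genuinely exercise
#' the format). Only biallelic SNVs with GT are supported.
#'
#' @param path VCF path.
#' @param map a [genetic_map()] used to attach cM coordinates.
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path, map) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path, genome = "synthetic")
  gt <- VariantAnnotation::geno(v)$GT
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  phased <- all(grepl("\\|", gt[1, ]))
  sp <- strsplit(as.vector(t(gt)), "[|/]")
  n <- ncol(gt); m <- nrow(gt)
  al <- matrix(as.integer(unlist(sp)), nrow = 2L)
  haps <- matrix(0L, nrow = 2L * n, ncol = m)
  for (i in seq_len(n)) {
    cols <- seq.int(i, by = n, length.out = m)
    haps[2L * i - 1L, ] <- al[1L, cols]
    haps[2L * i, ] <- al[2L, cols]
  }
  cm <- numeric(m)
  for (ch in unique(chrom)) {
    w <- chrom == ch
    cm[w] <- bp_to_cM(map, ch, pos[w])
  }
  genotype_panel(colnames(gt),
                 data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            cM = cm, stringsAsFactors = FALSE),
                 haps, phased = phased)
}
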