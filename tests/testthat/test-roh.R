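# build a synthetic chromosome of SNPs with controlled genotypes: dense grid,
# one SNP per 25 kb, on the 1 cM/Mbp map
dense_sites <- function(n, start = 1e6, step = 25e3, map) {
  pos <- seq(start, by = step, length.out = n)
  data.frame(chrom = "1", pos = pos, cM = bp_to_cM(map, "1", pos))
}

test_that("ROH caller finds planted runs and respects its thresholds", {
  map <- one_chrom_map(200)
  n <- 400
  sites <- dense_sites(n, map = map)

  # all heterozygous: nothing called
  expect_equal(nrow(call_roh(rep(1L, n), sites, map)), 0L)

  # planted run: 80 homozygous SNPs spanning 2,000 kb flanked by heterozygotes
  g <- rep(1L, n)
  g[101:180] <- 0L
  tab <- call_roh(g, sites, map)
  expect_equal(nrow(tab), 1L)
  # PLINK-style per-SNP window scoring trims the outermost boundary SNP
  # (covered by too few clean windows), so allow a 2-SNP margin
  expect_lte(abs(tab$start_bp[1] - sites$pos[101]), 2 * 25e3)
  expect_lte(abs(tab$end_bp[1] - 1 - sites$pos[180]), 2 * 25e3)
  expect_gt(tab$length_cM[1], (sites$pos[176] - sites$pos[105]) / 1e6)

  # 40 homozygous SNPs over 1,000 kb: fails >= 50 SNPs and >= 1500 kb
  g <- rep(1L, n)
  g[101:140] <- 0L
  expect_equal(nrow(call_roh(g, sites, map)), 0L)

  # a single heterozygote inside a long run is tolerated (window allows 1)
  g <- rep(1L, n); g[101:220] <- 0L; g[160] <- 1L
  tab <- call_roh(g, sites, map)
  expect_equal(nrow(tab), 1L)

  # missingness up to 5 per window tolerated, more breaks the run
  g <- rep(1L, n); g[101:220] <- 0L
  g[seq(110, 150, by = 10)] <- NA  # 5 missing in any 50-SNP window
  expect_equal(nrow(call_roh(g, sites, map)), 1L)

  # internal gap > 1000 kb splits the run (each side fails 1500 kb alone)
  sites2 <- sites
  sites2$pos[201:400] <- sites2$pos[201:400] + 2e6
  sites2$cM <- bp_to_cM(map, "1", sites2$pos)
  g <- rep(1L, n); g[171:230] <- 0L
  tab <- call_roh(g, sites2, map)
  expect_true(all(tab$end_bp - tab$start_bp < 1.6e6))

  expect_error(call_roh(rep(0L, 10), data.frame(chrom = "7", pos = 1:10,
                                                cM = 1:10), map),
               "unmapped")
})

test_that("centromere filter removes only short overlapping ROHs", {
  cent <- data.frame(chrom = "1", start_bp = 50e6, end_bp = 55e6)
  seg <- function(start, end) segment_table("X", NA, "1", start, end,
                                            start / 1e6, end / 1e6)
  # 5 Mb ROH overlapping: removed
  expect_equal(nrow(filter_centromere(seg(48e6, 53e6), cent)), 0L)
  # 12 Mb ROH overlapping: retained
  expect_equal(nrow(filter_centromere(seg(48e6, 60e6), cent)), 1L)
  # 5 Mb not overlapping: retained
  expect_equal(nrow(filter_centromere(seg(60e6, 65e6), cent)), 1L)
})

test_that("F_ROH arithmetic, bounds and error cases", {
  expect_equal(compute_froh(segment_table(), 2.8e9), 0)
  seg <- segment_table("X", NA, "1", 1e6, 281e6, 1, 281)
  expect_equal(compute_froh(seg, 2.8e9), 0.1)
  ovl <- segment_table(c("X", "X"), NA, "1", c(1e6, 2e6), c(5e6, 8e6),
                       c(1, 2), c(5, 8))
  expect_error(compute_froh(ovl, 2.8e9), "overlapping")
  two <- segment_table(c("X", "Y"), NA, "1", c(1e6, 2e6), c(5e6, 8e6),
                       c(1, 2), c(5, 8))
  expect_error(compute_froh(two, 2.8e9), "single individual")
})

test_that("simulated first-cousin offspring have mean F_ROH near 1/16", {
  map <- small_map()
  co <- simulate_union_cohort("first_cousin_g1", n = 500, map = map, seed = 88)
  se <- sd(co$froh_true) / sqrt(nrow(co))
  expect_lt(abs(mean(co$froh_true) - 1 / 16), 3 * se)
})

test_that("feature extraction implements the 15 statistics", {
  expect_equal(extract_features(numeric(0)), rep(0, 15))
  # three ROHs of 12, 25, 25 cM
  f <- extract_features(c(12, 25, 25))
  expect_equal(f[1], 62)
  expect_equal(f[2], 1)   # [10,20)
  expect_equal(f[3], 2)   # [20,30)
  expect_equal(sum(f[4:15]), 0)
  # 15 ROHs of 11 cM: ten longest only in s1
  f <- extract_features(rep(11, 15))
  expect_equal(f[1], 110)
  expect_equal(f[2], 15)
  # <= 10 cM ignored; > 150 cM goes in the top bin
  f <- extract_features(c(10, 9.99, 155, 149))
  expect_equal(f[1], 155 + 149)
  expect_equal(f[15], 2)
  # permutation invariance
  set.seed(4)
  l <- runif(40, 5, 160)
  expect_equal(extract_features(l), extract_features(sample(l)))
  # segment-table input uses length_cM
  expect_equal(extract_features(toy_segments()), rep(0, 15))
})

test_that("empirical footprints follow the printed denominators", {
  # one individual, one 7.4 cM ROH, genome 100 cM
  roh <- segment_table("A", NA, "1", 1e6, 8.4e6, 1, 8.4)
  fc <- empirical_footprint(roh, 1, 100, mode = "roh")
  expect_equal(fc$fraction[fc$bin_start_cM == 7], 0.074)
  expect_equal(sum(fc$fraction), 0.074)

  # IBD, n = 2: denominator 2n(2n-2)/2 = 4
  ibd <- segment_table("A", "B", "1", 1e6, 11e6, 1, 11)
  fi <- empirical_footprint(ibd, 2, 100, mode = "ibd")
  expect_equal(fi$fraction[fi$bin_start_cM == 10], 10 / 4 / 100)

  # empty table: all-zero curve; n < 2 errors in IBD mode
  f0 <- empirical_footprint(segment_table(), 5, 100, mode = "roh")
  expect_true(all(f0$fraction == 0))
  expect_error(empirical_footprint(segment_table(), 1, 100, mode = "ibd"),
               "n >= 2")

  # conservation: sum over bins x genome x denominator = total in-range cM
  set.seed(12)
  tab <- random_segments(60, 3)
  ibd_rows <- tab[!is_roh(tab), ]
  n <- 6
  fcv <- empirical_footprint(ibd_rows, n, 3500, lmin = 0, lmax = 1000,
                             binsize = 1, mode = "ibd")
  expect_equal(sum(fcv$fraction) * 3500 * (2 * n * (n - 1)),
               sum(ibd_rows$length_cM), tolerance = 1e-9)
})

test_that("caller recovers truth tracts on noise-free dense genotypes", {
  # recall property: >= 95% of truth-tract cM recovered for tracts > 5 cM
  map <- one_chrom_map(300)
  # ~25 kb spacing so the 50 kb/SNP density threshold is comfortably met
  pool <- gen_founder_panel(40, map, n_sites = 12000, seed = 21)
  ped <- build_union_pedigree("sibling")
  recovered <- truthed <- 0
  set.seed(22)
  for (i in 1:8) {
    sim <- simulate_offspring(ped, map, founder_pool = pool)
    tt <- sim$truth_tracts[sim$truth_tracts$length_cM > 5, ]
    if (!nrow(tt)) next
    g <- sim$genotype[1, ] + sim$genotype[2, ]
    called <- call_roh(g, pool$sites, map, sample_id = "x")
    truthed <- truthed + sum(tt$length_cM)
    for (j in seq_len(nrow(tt))) {
      if (!nrow(called)) next
      ov <- pmin(called$end_cM, tt$end_cM[j]) - pmax(called$start_cM, tt$start_cM[j])
      recovered <- recovered + sum(pmax(ov, 0))
    }
  }
  expect_gt(truthed, 0)
  expect_gt(recovered / truthed, 0.95)
})
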