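test_that("effective trajectories apply the halving and extension rules", {
  # estimator output 20,000 diploids -> effective scale 10,000, any k
  tr <- ne_trajectory(1:50, rep(20000, 50))
  for (k in c(0, 0.02, 0.1))
    expect_true(all(rescale_ne(tr, k)$S == 10000))
  # constant extension beyond the horizon
  tr <- ne_trajectory(1:50, seq(40000, 21000, length.out = 50))
  eff <- rescale_ne(tr, 0, horizon = 200)
  expect_length(eff$S, 200)
  expect_true(all(eff$S[51:200] == eff$S[50]))
  # model-parameter form: S = 4 Ne_pairs (1 - 3k)
  eff <- effective_trajectory(10000, k = 0.02)
  expect_equal(eff$S[1], 4 * 10000 * (1 - 0.06))
  expect_error(effective_trajectory(10000, k = 0.3), "k must be")
  expect_error(effective_trajectory(0.1, k = 0), "exceed")
})

test_that("t_between is geometric for constant scale and normalised", {
  eff <- effective_trajectory(1, k = 0, horizon = 5)  # S = 4
  d <- tmrca_between(eff)
  expect_equal(d$p[1], 0.25)
  expect_equal(d$p[2], 0.1875)
  # the distribution is renormalised after truncating ~1e-9 tail mass
  expect_equal(d$p[1:20], 0.25 * 0.75^(0:19), tolerance = 1e-8)
  expect_equal(sum(d$p), 1, tolerance = 1e-9)

  # non-constant trajectory still normalises
  eff <- effective_trajectory(c(50, 100, 200, 400), k = 0.01)
  expect_equal(sum(tmrca_between(eff)$p), 1, tolerance = 1e-9)
})

test_that("segment density and coverage match their printed forms", {
  # t = 10, l = 0.1, L = 1: 40 e^-2 (1 + 9) approx 54.134
  expect_equal(segment_density(0.1, 1, 10), 40 * exp(-2) * 10)
  # boundary l = L
  expect_equal(segment_density(1, 1, 10), 40 * exp(-20))
  expect_error(segment_density(1.5, 1, 10), "l <= L")
  set.seed(5)
  for (i in 1:20) {
    l <- runif(1); L <- l + runif(1); t <- sample(1:60, 1)
    expect_gte(segment_density(l, L, t), 0)
  }
  # l1 = l2 -> 0; l1 = 0, l2 = Inf -> L
  expect_equal(expected_coverage(0.1, 0.1, 1.5, 7), 0)
  for (t in c(1, 5, 50, 500))
    expect_equal(expected_coverage(0, Inf, 2.3, t), 2.3)
  expect_error(expected_coverage(0.3, 0.1, 1, 5), "l1 <= l2")
})

test_that("coverage equals the quadrature of l * density (Eq. 5 oracle)", {
  set.seed(17)
  for (i in 1:12) {
    L <- runif(1, 0.5, 3)
    l1 <- runif(1, 0, L / 2); l2 <- runif(1, l1, L)
    t <- sample(1:80, 1)
    closed <- expected_coverage(l1, l2, L, t)
    quad <- integrate(function(l) l * segment_density(l, L, t), l1, l2,
                      rel.tol = 1e-10)$value
    expect_equal(closed, quad, tolerance = 1e-6)
  }
})

test_that("within distribution: r = 0 equals between; fast mass = k/(1-3k)", {
  eff <- effective_trajectory(10000, k = 0)
  w <- tmrca_within(eff, rep(0, 5), seed = 7)
  b <- tmrca_between(eff)
  n <- max(length(w$p), length(b$p))
  pad <- function(p) c(p, numeric(n - length(p)))
  expect_lt(0.5 * sum(abs(pad(w$p) - pad(b$p))), 0.01)
  expect_equal(sum(w$p), 1, tolerance = 1e-9)

  r <- c(0, 0.25, 0, 0, 0)
  k <- kinship_from_r(r)
  effk <- effective_trajectory(10000, k = k)
  w <- tmrca_within(effk, r, seed = 42)
  # 3 x MC SE + truncation allowance for recursion mass beyond t = 10
  expect_lt(abs(sum(w$p[1:10]) - k / (1 - 3 * k)), 0.002)
  expect_warning(tmrca_within(effk, r, mc_iterations = 500, seed = 1), "noisy")
})

test_that("within tail is exactly proportional to the between form", {
  r <- c(0, 0.2, 0.05, 0, 0)
  eff <- effective_trajectory(5000, k = kinship_from_r(r))
  w <- tmrca_within(eff, r, T_switch = 30, seed = 3)
  b <- tmrca_between(eff)
  idx <- 31:200
  ratio <- w$p[idx] / b$p[idx]
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
})

test_that("expected footprints: degenerate sums, k = 0 equality, monotone in k", {
  chrom_cM <- map_lengths(uniform_genome_map())$cM
  # point-mass distribution: curve equals normalised coverage at t0
  t0 <- 12
  d <- structure(list(p = c(numeric(t0 - 1), 1), flavor = "between"),
                 class = "tmrca_distribution")
  fc <- expected_footprint(d, chrom_cM, lmin = 5, lmax = 10)
  Lm <- chrom_cM / 100
  manual <- vapply(5:9, function(s)
    sum(vapply(Lm, function(L)
      expected_coverage(s / 100, (s + 1) / 100, L, t0), numeric(1))) / sum(Lm),
    numeric(1))
  expect_equal(fc$fraction, manual, tolerance = 1e-9)

  # k = 0, constant Ne: ROH curve equals IBD curve within MC error
  eff <- effective_trajectory(5000, k = 0)
  res <- run_footprint_experiment(eff, rep(0, 5), chrom_cM, seed = 2,
                                  mc_iterations = 4e5)
  expect_lt(max(abs(res$expected_roh$fraction - res$expected_ibd$fraction)),
            0.05 * max(res$expected_ibd$fraction))

  # k > 0: ROH footprint dominates IBD bin-wise, and increases with k
  prev <- NULL
  for (r2 in c(0.1, 0.2, 0.35)) {
    r <- c(0, r2, 0, 0, 0)
    effk <- effective_trajectory(5000, k = kinship_from_r(r))
    resk <- run_footprint_experiment(effk, r, chrom_cM, seed = 3,
                                     mc_iterations = 2e5)
    expect_true(all(resk$expected_roh$fraction >=
                      resk$expected_ibd$fraction - 1e-12))
    if (!is.null(prev))
      expect_true(all(resk$expected_roh$fraction > prev))
    prev <- resk$expected_roh$fraction
  }
})

test_that("footprint conservation: total coverage over all lengths is 1", {
  eff <- effective_trajectory(c(2000, 3000, 5000), k = 0.01)
  for (d in list(tmrca_between(eff),
                 tmrca_within(eff, c(0, 0.1, 0, 0, 0), seed = 1))) {
    # sum_t P(t) * c(0, Inf; L, t) / L = sum_t P(t) = 1
    total <- consangkit:::.coverage_term_sum(d$p, 0, 1.5) / 1.5
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("long segments are driven by kinship, not Ne (sensitivity)", {
  chrom_cM <- map_lengths(uniform_genome_map())$cM
  band <- function(ne, r, seed) {
    eff <- effective_trajectory(ne, k = kinship_from_r(r))
    res <- run_footprint_experiment(eff, r, chrom_cM, lmin = 10, lmax = 30,
                                    seed = seed, mc_iterations = 2e5)
    sum(res$expected_roh$fraction)
  }
  r_lo <- c(0, 0.32, 0, 0, 0)   # k = 0.32/16 = 0.02
  expect_equal(kinship_from_r(r_lo), 0.02)
  r_hi <- c(0, 0.64, 0, 0, 0)   # k = 0.04
  expect_equal(kinship_from_r(r_hi), 0.04)
  f_ne1 <- band(10000, r_lo, 1)
  f_ne2 <- band(5000, r_lo, 1)
  f_khi <- band(10000, r_hi, 1)
  expect_lt(abs(f_ne2 - f_ne1) / f_ne1, 0.10)   # halving Ne: < 10% change
  expect_gt((f_khi - f_ne1) / f_ne1, 0.50)      # doubling k: > 50% change
})

test_that("T_switch choice barely moves the footprint", {
  chrom_cM <- map_lengths(uniform_genome_map())$cM
  r <- c(0, 0.2, 0.05, 0, 0)
  eff <- effective_trajectory(10000, k = kinship_from_r(r))
  f10 <- expected_footprint(tmrca_within(eff, r, T_switch = 10, seed = 4),
                            chrom_cM)
  f40 <- expected_footprint(tmrca_within(eff, r, T_switch = 40, seed = 4),
                            chrom_cM)
  expect_lt(max(abs(f10$fraction - f40$fraction)), 1e-3)
})

test_that("the sudden historic-consanguinity change has subtle effects", {
  chrom_cM <- map_lengths(uniform_genome_map())$cM
  r <- c(0, 0.2, 0.05, 0, 0)
  eff <- effective_trajectory(10000, k = kinship_from_r(r))
  res0 <- run_footprint_experiment(eff, r, chrom_cM, seed = 6)
  res1 <- run_footprint_experiment(eff, r, chrom_cM, seed = 6,
                                   k_historic = 1e-4)
  rel <- abs(res1$expected_roh$fraction - res0$expected_roh$fraction) /
    res0$expected_roh$fraction
  expect_lt(max(rel), 0.2)   # visible but subtle, never dominant
})
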