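test_that("at-risk status is gene-set intersection", {
  ct <- abc_carriers()
  expect_equal(at_risk("A", "B", ct), 1L)
  expect_equal(at_risk("A", "C", ct), 0L)
  ct2 <- carrier_table(data.frame(id = c("A", "B"), group = "g"),
                       list(A = character(), B = "g1gene"), "g1gene")
  expect_equal(at_risk("A", "B", ct2), 0L)
  expect_error(at_risk("A", "Q", ct), "unknown individual")
})

test_that("intra-group risk on 3 individuals enumerates to 1/3", {
  est <- group_risk(abc_carriers(), "g1", "intra")
  expect_equal(est$mean, 1 / 3)
  expect_equal(est$n_pairs, 3)
})

test_that("all-identical risk statuses give zero variance", {
  ct <- carrier_table(data.frame(id = c("A", "B", "C", "D"), group = "g"),
                      list(A = "G1", B = "G1", C = "G1", D = "G1"), "G1")
  est <- group_risk(ct, "g", "intra")
  expect_equal(est$mean, 1)
  expect_equal(est$variance, 0)
})

test_that("variance formula matches brute-force evaluation on 4-individual toys", {
  # independent oracle: explicit enumeration of pairs and shared-index pair
  # covariances, then the printed moment formula
  brute_var_intra <- function(S) {
    n <- nrow(S)
    pairs <- which(upper.tri(S), arr.ind = TRUE)
    s <- S[pairs]
    v <- var(s)
    prods <- c(); mus <- c()
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      cmb <- combn(others, 2)
      for (q in seq_len(ncol(cmb)))
        prods <- c(prods, S[i, cmb[1, q]] * S[i, cmb[2, q]])
    }
    cv <- mean(prods) - mean(s)^2
    P <- n * (n - 1) / 2
    (P * v + n * (n - 1) * (n - 2) * cv) / P^2
  }
  set.seed(31)
  for (rep_i in 1:10) {
    genes <- sprintf("G%d", 1:6)
    sets <- lapply(1:4, function(i) sample(genes, sample(0:3, 1)))
    names(sets) <- LETTERS[1:4]
    ct <- carrier_table(data.frame(id = LETTERS[1:4], group = "g"),
                        sets, genes)
    S <- consangkit:::.risk_matrix(ct, LETTERS[1:4])
    if (var(S[upper.tri(S)]) == 0) next
    est <- group_risk(ct, "g", "intra")
    expect_equal(est$variance, max(brute_var_intra(S), 0), tolerance = 1e-12)
  }
})

test_that("inter-group variance matches brute force on small toys", {
  brute_var_inter <- function(S) {
    n1 <- nrow(S); n2 <- ncol(S)
    s <- as.vector(S)
    prods <- c()
    for (i in seq_len(n1)) for (j in seq_len(n2)) for (l in seq_len(n2))
      if (l != j) prods <- c(prods, S[i, j] * S[i, l])
    for (j in seq_len(n2)) for (i in seq_len(n1)) for (kk in seq_len(n1))
      if (kk != i) prods <- c(prods, S[i, j] * S[kk, j])
    cv <- mean(prods) - mean(s)^2
    (n1 * n2 * var(s) + n1 * n2 * (n1 + n2 - 2) * cv) / (n1 * n2)^2
  }
  set.seed(77)
  for (rep_i in 1:6) {
    genes <- sprintf("G%d", 1:5)
    ids <- c("a1", "a2", "a3", "b1", "b2")
    sets <- lapply(seq_along(ids), function(i) sample(genes, sample(0:3, 1)))
    names(sets) <- ids
    ct <- carrier_table(data.frame(id = ids, group = rep(c("a", "b"), c(3, 2))),
                        sets, genes)
    ids_a <- c("a1", "a2", "a3"); ids_b <- c("b1", "b2")
    S <- matrix(0L, 3, 2)
    for (i in 1:3) for (j in 1:2) S[i, j] <- at_risk(ids_a[i], ids_b[j], ct)
    if (var(as.vector(S)) == 0) next
    est <- group_risk(ct, "a", "inter")
    expect_equal(est$variance, max(brute_var_inter(S), 0), tolerance = 1e-12)
  }
})

test_that("the intra variance reduces to Var(s)/#pairs when covariance is zero", {
  # algebraic check: zero out the covariance term in the formula
  S <- consangkit:::.risk_matrix(abc_carriers(), c("A", "B", "C"))
  s <- S[upper.tri(S)]
  n <- 3; P <- n * (n - 1) / 2
  expect_equal((P * var(s) + 0) / P^2, var(s) / P)
})

test_that("permutation p-values are uniform under the null", {
  # 200 replicate null datasets (labels carry no signal); B kept moderate so
  # the suite stays fast -- the p-value grid is 1/B, handled by comparing to
  # the discrete uniform via KS on mid-ranks
  B <- 400
  set.seed(60)
  seeds <- sample.int(1e6, 200)
  ps <- vapply(seq_along(seeds), function(i) {
    ct <- gen_carrier_table(c(20, 20), c("u", "v"), n_genes = 40,
                            carrier_rate_model = 0.08, seed = seeds[i])
    permutation_test(ct, "u", B = B, seed = seeds[i] + 1)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # extreme signal: index group holds all carriers of a private shared gene
  ct <- gen_carrier_table(c(30, 30, 30), c("idx", "o1", "o2"), n_genes = 30,
                          carrier_rate_model = 0.01, seed = 4)
  ct$genes[ct$individuals$group == "idx"] <-
    lapply(ct$genes[ct$individuals$group == "idx"],
           function(g) unique(c(g, "G001")))
  pt <- permutation_test(ct, "idx", B = 2000, seed = 9)
  expect_lt(pt$p, 1 / 2000 + 1e-12)
  expect_true(pt$p_is_upper_bound)

  # determinism
  p1 <- permutation_test(ct, "idx", B = 200, seed = 5)
  p2 <- permutation_test(ct, "idx", B = 200, seed = 5)
  expect_identical(p1, p2)
})

test_that("permutation test has power against sharing_boost", {
  hits <- vapply(1:20, function(s) {
    ct <- gen_carrier_table(c(40, 40, 40), c("x", "y", "z"), n_genes = 60,
                            carrier_rate_model = 0.05, sharing_boost = 6,
                            seed = s)
    permutation_test(ct, "x", B = 200, seed = s + 999)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("largest-remainder matching reproduces the worked example", {
  # reference bin holding 20/75 of the mass -> 40 of 150 couples
  ref <- c(10, 15, 20, 12, 8, 6, 3, 1) / 75
  expect_equal(sum(largest_remainder(ref, 150)), 150L)
  expect_equal(largest_remainder(ref, 150)[3], 40L)
  expect_equal(largest_remainder(c(1, 0, 0, 0, 0, 0, 0, 0), 150),
               c(150L, rep(0L, 7)))
})

test_that("kinship-matched first-cousin sampling behaves", {
  set.seed(8)
  ct <- gen_carrier_table(80, "pop", n_genes = 50, carrier_rate_model = 0.1,
                          seed = 2)
  ids <- ct$individuals$id
  pairs <- t(combn(ids, 2))
  pk <- data.frame(i = pairs[, 1], j = pairs[, 2],
                   kinship = runif(nrow(pairs), 0, 0.4))
  ref <- c(0.05, 0.1, 20 / 75, 0.2, 0.15, 0.08, 0.04, 0.013)
  est <- matched_fc_risk(ct, pk, ref, n_pairs = 30, n_reps = 50, seed = 3)
  expect_equal(length(est$replicates), 50)
  expect_equal(sum(est$bin_counts), 30L)
  expect_true(est$mean >= 0 && est$mean <= 1)

  # all mass in one bin: every couple from that bin
  ref1 <- c(0, 0, 1, 0, 0, 0, 0, 0)
  est1 <- matched_fc_risk(ct, pk, ref1, n_pairs = 20, n_reps = 5, seed = 4)
  expect_equal(est1$bin_counts[3], 20L)
  expect_equal(sum(est1$bin_counts), 20L)

  # no shared genes anywhere: estimate 0 with SD 0
  ct0 <- gen_carrier_table(80, "pop", n_genes = 50, carrier_rate_model = 0,
                           seed = 5)
  est0 <- matched_fc_risk(ct0, pk, ref, n_pairs = 20, n_reps = 10, seed = 6)
  expect_equal(est0$mean, 0)
  expect_equal(est0$sd, 0)

  # insufficient pairs in a required bin errors
  pk_thin <- pk[pk$kinship < 0.35, ]
  expect_error(matched_fc_risk(ct, pk_thin, c(0, 0, 0, 0, 0, 0, 0, 1),
                               n_pairs = 20, n_reps = 2, seed = 7),
               "insufficient")
})

test_that("matched first-cousin pairing amplifies risk when relatives share variants", {
  # population of sib-ships: relatives share rare variants; high-kinship
  # pairs must be at much higher risk than random intra-group pairs
  set.seed(91)
  n_fam <- 40; fam_size <- 4; genes <- sprintf("G%03d", 1:120)
  ids <- sprintf("f%02d_%d", rep(1:n_fam, each = fam_size),
                 rep(1:fam_size, n_fam))
  fam <- rep(1:n_fam, each = fam_size)
  fam_genes <- lapply(1:n_fam, function(f) sample(genes, 2))  # family variants
  sets <- lapply(seq_along(ids), function(i) {
    g <- fam_genes[[fam[i]]]
    g[runif(2) < 0.5]  # each family variant carried w.p. 1/2
  })
  names(sets) <- ids
  ct <- carrier_table(data.frame(id = ids, group = "g"), sets, genes)
  pairs <- t(combn(seq_along(ids), 2))
  pk <- data.frame(i = ids[pairs[, 1]], j = ids[pairs[, 2]],
                   kinship = ifelse(fam[pairs[, 1]] == fam[pairs[, 2]],
                                    0.26, 0.01))
  ref_fc <- c(0, 0, 0, 0, 0, 1, 0, 0)     # all mass at kinship ~ 0.25-0.3
  est_fc <- matched_fc_risk(ct, pk, ref_fc, n_pairs = 30, n_reps = 40, seed = 1)
  est_bg <- group_risk(ct, "g", "intra")
  expect_gt(est_fc$mean, est_bg$mean)
})
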