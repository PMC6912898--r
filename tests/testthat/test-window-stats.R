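test_that("Weir-Cockerham components match an independent transcription", {
  # fixed difference, equal sizes, all homozygous: a = 0.5, b = c = 0
  comp <- wc_components(10, 1, 0, 10, 0, 0)
  expect_equal(comp$a, 0.5)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)
  expect_equal(window_fst(comp$a, comp$b, comp$c), 1)

  # both populations monomorphic for the same allele: all components 0
  comp0 <- wc_components(10, 0, 0, 10, 0, 0)
  expect_equal(unlist(comp0), c(a = 0, b = 0, c = 0))

  # pop1: 5 individuals, 3 alt alleles, 1 het; pop2: 5 individuals,
  # 9 alt alleles, 1 het
  got <- wc_components(5, 3 / 10, 1 / 5, 5, 9 / 10, 1 / 5)
  want <- oracle_wc(5, 3 / 10, 1 / 5, 5, 9 / 10, 1 / 5)
  expect_equal(c(got$a, got$b, got$c), unname(want), tolerance = 1e-12)

  # random sites agree with the oracle
  set.seed(7)
  for (i in 1:50) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    a1 <- sample(0:(2 * n1), 1); a2 <- sample(0:(2 * n2), 1)
    h1 <- sample(0:min(a1, 2 * n1 - a1), 1)
    h2 <- sample(0:min(a2, 2 * n2 - a2), 1)
    got <- wc_components(n1, a1 / (2 * n1), h1 / n1, n2, a2 / (2 * n2), h2 / n2)
    want <- oracle_wc(n1, a1 / (2 * n1), h1 / n1, n2, a2 / (2 * n2), h2 / n2)
    expect_equal(c(got$a, got$b, got$c), unname(want), tolerance = 1e-12)
  }
})

test_that("windowed FST is the ratio of sums and handles degenerate windows", {
  # window of only fixed differences -> exactly 1
  comp <- wc_components(rep(10, 5), rep(1, 5), rep(0, 5),
                        rep(10, 5), rep(0, 5), rep(0, 5))
  expect_identical(window_fst(comp$a, comp$b, comp$c), 1)

  # identical allele frequencies at every site -> <= 0
  set.seed(3)
  p <- runif(20, 0.1, 0.9)
  h <- 2 * p * (1 - p)
  comp <- wc_components(rep(10, 20), p, h, rep(10, 20), p, h)
  expect_lte(window_fst(comp$a, comp$b, comp$c), 1e-12)

  # all monomorphic -> NA
  comp <- wc_components(rep(10, 3), rep(0, 3), rep(0, 3),
                        rep(10, 3), rep(0, 3), rep(0, 3))
  expect_true(is.na(window_fst(comp$a, comp$b, comp$c)))

  # 20-site fixture equals sum(a)/sum(a+b+c) from the oracle
  set.seed(8)
  n1 <- sample(3:10, 20, TRUE); n2 <- sample(3:10, 20, TRUE)
  a1 <- sapply(n1, function(n) sample(0:(2 * n), 1))
  a2 <- sapply(n2, function(n) sample(0:(2 * n), 1))
  h1 <- mapply(function(a, n) sample(0:min(a, 2 * n - a), 1), a1, n1)
  h2 <- mapply(function(a, n) sample(0:min(a, 2 * n - a), 1), a2, n2)
  comp <- wc_components(n1, a1 / (2 * n1), h1 / n1, n2, a2 / (2 * n2), h2 / n2)
  om <- t(mapply(oracle_wc, n1, a1 / (2 * n1), h1 / n1,
                 n2, a2 / (2 * n2), h2 / n2))
  expect_equal(window_fst(comp$a, comp$b, comp$c),
               sum(om[, 1]) / sum(rowSums(om)), tolerance = 1e-12)
})

test_that("Dxy follows the per-site allele-frequency formula", {
  expect_equal(window_dxy(1, 0, 100)$dxy_per_snp, 1)
  d <- window_dxy(c(1, 0.5, 0), c(0, 0.5, 0.5), 100)
  expect_equal(d$dxy_per_snp, 2 / 3, tolerance = 1e-12)
  expect_equal(d$dxy_per_bp, 2 / 100, tolerance = 1e-12)
  expect_true(is.na(window_dxy(numeric(0), numeric(0), 100)$dxy_per_snp))
  # symmetry in populations
  expect_equal(window_dxy(c(0.2, 0.9), c(0.7, 0.1), 50),
               window_dxy(c(0.7, 0.1), c(0.2, 0.9), 50))
})

test_that("nucleotide diversity uses the unbiased pairwise estimator", {
  expect_equal(window_pi(0, 4, 100), 0)                 # monomorphic
  expect_equal(window_pi(2, 4, 100), 2 * 2 * 2 / (4 * 3) / 100)
  expect_gte(window_pi(c(1, 3), c(10, 8), 1000), 0)
})

test_that("Tajima's D matches an independent transcription", {
  const <- tajima_constants(10)
  expect_equal(const$a1, sum(1 / 1:9))
  # numerator zero when k = S / a1
  expect_equal(tajimas_d(5, 5 / const$a1, 10), 0, tolerance = 1e-12)
  expect_equal(tajimas_d(5, 2, 10), oracle_tajima(5, 2, 10), tolerance = 1e-12)
  expect_true(is.na(tajimas_d(0, 0, 10)))
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:40, 1); S <- sample(1:100, 1); k <- runif(1, 0, 20)
    expect_equal(tajimas_d(S, k, n), oracle_tajima(S, k, n), tolerance = 1e-12)
  }
})

test_that("fixed-difference classification is a disjoint-allele-set test", {
  expect_true(classify_fixed(0, 20, 20, 20))
  expect_true(classify_fixed(20, 20, 0, 20))
  # a heterozygote breaks fixation
  expect_false(classify_fixed(1, 20, 20, 20))
  expect_false(classify_fixed(0, 20, 19, 20))

  # 50 planted patterns vs a brute-force allele-set intersection oracle
  set.seed(10)
  n1 <- sample(2:10, 50, TRUE); n2 <- sample(2:10, 50, TRUE)
  a1 <- sapply(n1, function(n) sample(0:(2 * n), 1))
  a2 <- sapply(n2, function(n) sample(0:(2 * n), 1))
  got <- classify_fixed(a1, 2 * n1, a2, 2 * n2)
  want <- mapply(function(a1, na1, a2, na2) {
    s1 <- unique(c(if (a1 > 0) "alt", if (a1 < na1) "ref"))
    s2 <- unique(c(if (a2 > 0) "alt", if (a2 < na2) "ref"))
    length(intersect(s1, s2)) == 0
  }, a1, 2 * n1, a2, 2 * n2)
  expect_equal(got, want)

  expect_equal(count_fixed_and_df(rep(TRUE, 223), 1e5)$df, 0.00223)
  expect_equal(count_fixed_and_df(logical(0), 1e5)$df, 0)
})

test_that("compute_window_stats agrees with per-statistic recomputation", {
  # a window of 10 fixed differences, no missing data
  gt <- cbind(matrix(0L, 10, 10), matrix(2L, 10, 10))
  gm <- make_gm(gt, pos = seq(1000, 10000, 1000))
  ws <- compute_window_stats(gm, 1e5)
  expect_equal(nrow(ws), 1)
  expect_equal(ws$fst, 1)
  expect_equal(ws$dxy_per_snp, 1)
  expect_equal(ws$n_fixed, 10L)
  expect_equal(ws$df * (ws$end - ws$start + 1), ws$n_fixed)
  expect_equal(ws$pi_pop1, 0)
  expect_true(is.na(ws$tajd_pop1))  # no within-population variation

  # random genome: every field matches an independent oracle recomputation
  set.seed(12)
  n <- 200
  gt <- matrix(rbinom(n * 20, 2, rep(runif(n, 0.05, 0.95), 20)), n)
  gt[sample(length(gt), 150)] <- NA
  pos <- sort(sample.int(3e5, n))
  gm <- make_gm(gt, pos = pos, scaffold_lengths = c(scaf_1 = 3e5))
  ws <- compute_window_stats(gm, 1e5)
  for (w in seq_len(nrow(ws))) {
    rows <- which((pos - 1) %/% 1e5 == ws$window_index[w])
    L <- ws$end[w] - ws$start[w] + 1
    comp <- matrix(NA_real_, length(rows), 3)
    dxy <- pi1 <- numeric(length(rows))
    fixed <- logical(length(rows))
    S2 <- 0; k2 <- 0
    nind2 <- integer(length(rows))
    for (j in seq_along(rows)) {
      g1 <- gt[rows[j], 1:10]; g2 <- gt[rows[j], 11:20]
      n1 <- sum(!is.na(g1)); n2 <- sum(!is.na(g2))
      p1 <- sum(g1, na.rm = TRUE) / (2 * n1)
      p2 <- sum(g2, na.rm = TRUE) / (2 * n2)
      if (n1 >= 2 && n2 >= 2) {
        comp[j, ] <- oracle_wc(n1, p1, sum(g1 == 1, na.rm = TRUE) / n1,
                               n2, p2, sum(g2 == 1, na.rm = TRUE) / n2)
      }
      dxy[j] <- p1 * (1 - p2) + p2 * (1 - p1)
      ac1 <- sum(g1, na.rm = TRUE)
      if (n1 >= 1) pi1[j] <- 2 * ac1 * (2 * n1 - ac1) / ((2 * n1) * (2 * n1 - 1))
      ac2 <- sum(g2, na.rm = TRUE)
      fixed[j] <- n1 >= 1 && n2 >= 1 &&
        ((ac1 == 0 && ac2 == 2 * n2) || (ac1 == 2 * n1 && ac2 == 0))
      if (ac2 > 0 && ac2 < 2 * n2) {
        S2 <- S2 + 1
        k2 <- k2 + 2 * ac2 * (2 * n2 - ac2) / ((2 * n2) * (2 * n2 - 1))
      }
      nind2[j] <- n2
    }
    expect_equal(ws$fst[w], sum(comp[, 1], na.rm = TRUE) /
                   sum(comp, na.rm = TRUE), tolerance = 1e-12)
    expect_equal(ws$dxy_per_snp[w], mean(dxy), tolerance = 1e-12)
    expect_equal(ws$pi_pop1[w], sum(pi1) / L, tolerance = 1e-12)
    expect_equal(ws$n_fixed[w], sum(fixed))
    tab <- tabulate(nind2)
    expect_equal(ws$tajd_pop2[w], oracle_tajima(S2, k2, 2 * which.max(tab)),
                 tolerance = 1e-10)
  }
})

test_that("window statistics are symmetric under population relabelling", {
  set.seed(13)
  gt <- matrix(rbinom(600, 2, 0.4), 30)
  gm <- make_gm(gt, pos = seq_len(30) * 100L)
  # relabel: each population keeps its own genotypes, labels swap order
  swapped <- make_gm(cbind(gt[, 11:20], gt[, 1:10]),
                     pos = seq_len(30) * 100L, pops = c("B", "A"))
  ws1 <- compute_window_stats(gm, 1e5)
  ws2 <- compute_window_stats(swapped, 1e5)
  expect_equal(ws1$fst, ws2$fst, tolerance = 1e-12)
  expect_equal(ws1$dxy_per_snp, ws2$dxy_per_snp, tolerance = 1e-12)
  expect_equal(ws1$n_fixed, ws2$n_fixed)
  expect_equal(ws1$pi_pop1, ws2$pi_pop2, tolerance = 1e-12)
})

test_that("classify_fixed requires at least one called individual per population", {
  # fixation test with missing data excluded from allele counts
  g <- gt_rows(c(0, 0, NA, NA, 2, 2, 2, 2))
  gm <- make_gm(g, pops = c("A", "B"))
  s <- site_allele_stats(gm)
  expect_true(classify_fixed(s$ac1, s$na1, s$ac2, s$na2))
})
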