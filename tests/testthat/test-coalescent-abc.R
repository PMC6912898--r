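test_that("time and mutation-rate scaling are exact", {
  expect_equal(mutation_rate_per_generation(), 7.59e-9, tolerance = 1e-15)
  expect_equal(mutation_rate_per_generation(scaling_constants(5e-3, 1.0)),
               5e-3 * 1e-6, tolerance = 1e-15)
  expect_equal(mutation_rate_per_generation(scaling_constants(0, 2)), 0)
  expect_equal(years_to_generations(2.3, 2.3), 1)
  expect_equal(years_to_generations(552000, 2.3), 240000)
  expect_equal(years_to_generations(0, 5), 0)
})

test_that("prior draws respect bounds and ordering constraints", {
  set.seed(21)
  d <- sample_prior("simple_split", 10000)
  expect_true(all(d$T2 < d$T1))
  pr <- demographic_priors()
  for (p in names(d)) {
    expect_gte(min(d[[p]]), pr[[p]][1])
    expect_lte(max(d[[p]]), pr[[p]][2])
  }
  # N_NESP is unconstrained: its marginal stays uniform
  ks <- suppressWarnings(stats::ks.test(d$N_NESP, "punif", 1e3, 5e4))
  expect_gt(ks$p.value, 0.01)

  d2 <- sample_prior("ne_change", 5000)
  expect_true(all(d2$T_fall < d2$T_rise & d2$T_rise < d2$T2 & d2$T2 < d2$T1))
  d3 <- sample_prior("admixture", 5000)
  expect_true(all(d3$T_admix < d3$T2))

  set.seed(99); a <- sample_prior("admixture", 50)
  set.seed(99); b <- sample_prior("admixture", 50)
  expect_identical(a, b)
})

test_that("simulator is deterministic under a fixed seed", {
  p <- list(T1 = 9e5, T2 = 3e5, N_Ancestral = 3e5, N_AncestralNESP = 5e4,
            N_SALS = 8e4, N_NESP = 2e4)
  set.seed(31); a <- simulate_dataset("simple_split", p, n_loci = 200)
  set.seed(31); b <- simulate_dataset("simple_split", p, n_loci = 200)
  expect_identical(a, b)
  # every locus variable in the pooled sample
  tot <- a$alt1 + a$alt2
  expect_true(all(tot > 0 & tot < 40))
})

test_that("simulator recovers panmixia and split limits", {
  set.seed(32)
  pan <- simulate_dataset("simple_split",
                          list(T1 = 10, T2 = 5, N_Ancestral = 2e4,
                               N_AncestralNESP = 2e4, N_SALS = 2e4,
                               N_NESP = 2e4), n_loci = 4000)
  s <- compute_summary_stats(pan)
  expect_lt(abs(s[["fst_mean"]]), 0.02)

  # mean per-locus FST increases with T1 at fixed sizes (3-point probe)
  fst_at <- function(t1) {
    set.seed(33)
    s <- compute_summary_stats(simulate_dataset(
      "simple_split",
      list(T1 = t1, T2 = 1e5, N_Ancestral = 2e5, N_AncestralNESP = 5e4,
           N_SALS = 8e4, N_NESP = 2e4), n_loci = 3000))
    s[["fst_mean"]]
  }
  probe <- c(fst_at(4e5), fst_at(8e5), fst_at(1.5e6))
  expect_true(all(diff(probe) > 0))
})

test_that("admixture with r near 1 collapses to the simple split", {
  base <- list(T1 = 9e5, T2 = 3e5, N_Ancestral = 3e5, N_AncestralNESP = 5e4,
               N_SALS = 8e4, N_NESP = 2e4)
  set.seed(34)
  s_split <- compute_summary_stats(
    simulate_dataset("simple_split", base, n_loci = 4000))
  set.seed(34)
  s_adm <- compute_summary_stats(
    simulate_dataset("admixture", c(base, T_admix = 5e4, r = 0.999),
                     n_loci = 4000))
  expect_lt(abs(s_split[["fst_mean"]] - s_adm[["fst_mean"]]), 0.03)
})

test_that("the ten summary statistics match hand evaluation on a 5-locus set", {
  loci <- tibble::tibble(
    locus = 1:5,
    alt1 = c(0L, 20L, 10L, 4L, 0L),
    het1 = c(0L, 0L, 2L, 4L, 0L),
    alt2 = c(0L, 0L, 10L, 16L, 5L),
    het2 = c(0L, 0L, 2L, 4L, 5L)
  )
  attr(loci, "n1") <- 10; attr(loci, "n2") <- 10
  class(loci) <- c("abc_loci", class(loci))
  got <- compute_summary_stats(loci)

  # genic diversity: 20 * 2 p (1-p) / 19 per locus, scalar arithmetic
  gd <- function(ac) {
    p <- ac / 20
    20 * 2 * p * (1 - p) / 19
  }
  gd1 <- gd(c(0, 20, 10, 4, 0)); gd2 <- gd(c(0, 0, 10, 16, 5))
  expect_equal(got[["gd1_pzero"]], 3 / 5)  # p = 0 and p = 1 both monomorphic
  expect_equal(got[["gd2_pzero"]], 2 / 5)
  expect_equal(got[["gd1_mean"]], mean(gd1[gd1 > 0]), tolerance = 1e-12)
  expect_equal(got[["gd1_var"]], var(gd1[gd1 > 0]), tolerance = 1e-12)
  expect_equal(got[["gd2_mean"]], mean(gd2[gd2 > 0]), tolerance = 1e-12)

  # per-locus FST via the Weir-Cockerham oracle
  fst <- sapply(1:5, function(i) {
    w <- oracle_wc(10, loci$alt1[i] / 20, loci$het1[i] / 10,
                   10, loci$alt2[i] / 20, loci$het2[i] / 10)
    w[1] / sum(w)
  })
  fst <- fst[is.finite(fst) & fst != 0]
  expect_equal(got[["fst_mean"]], mean(fst), tolerance = 1e-12)
  expect_equal(got[["fst_var"]], var(fst), tolerance = 1e-12)

  # Nei distance
  nei <- sapply(1:5, function(i) {
    p1 <- loci$alt1[i] / 20; p2 <- loci$alt2[i] / 20
    jx <- p1^2 + (1 - p1)^2; jy <- p2^2 + (1 - p2)^2
    jxy <- p1 * p2 + (1 - p1) * (1 - p2)
    -log(jxy / sqrt(jx * jy))
  })
  nei <- nei[is.finite(nei) & nei != 0]
  expect_equal(got[["nei_mean"]], mean(nei), tolerance = 1e-12)
  expect_equal(got[["nei_var"]], var(nei), tolerance = 1e-12)
})

test_that("equal allele frequencies give zero Nei distance, excluded as zero", {
  loci <- tibble::tibble(locus = 1L, alt1 = 10L, het1 = 2L,
                         alt2 = 10L, het2 = 2L)
  attr(loci, "n1") <- 10; attr(loci, "n2") <- 10
  class(loci) <- c("abc_loci", class(loci))
  s <- compute_summary_stats(loci)
  expect_equal(s[["nei_mean"]], 0)  # no nonzero values -> reported 0
})

test_that("reference tables are reproducible and draw from the priors", {
  t1 <- build_reference_table("ne_change", n_sims = 10, n_loci = 100, seed = 41)
  t2 <- build_reference_table("ne_change", n_sims = 10, n_loci = 100, seed = 41)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 10)
  pr <- demographic_priors()
  expect_true(all(t1$T_fall < t1$T_rise & t1$T_rise < t1$T2))
  expect_true(all(t1$N_largeNESP >= pr$N_largeNESP[1] &
                    t1$N_largeNESP <= pr$N_largeNESP[2]))
})

test_that("model choice is symmetric for identical reference tables", {
  set.seed(42)
  tab <- build_reference_table("simple_split", n_sims = 600, n_loci = 300,
                               seed = 43)
  tabs <- list(tab,
               dplyr::mutate(tab, scenario = "ne_change"),
               dplyr::mutate(tab, scenario = "admixture"))
  obs <- compute_summary_stats(simulate_dataset(
    "simple_split", tab[3, ], n_loci = 300))
  ch <- abc_model_choice(obs, tabs, accept_fraction = 0.05)
  expect_equal(sum(ch$posterior$posterior), 1, tolerance = 1e-9)
  expect_true(all(abs(ch$posterior$posterior - 1 / 3) < 0.02))
})

test_that("model choice separates disjoint statistic distributions", {
  # synthetic tables whose first statistic fully separates the classes
  fake <- function(scenario, centre, n = 400) {
    stats <- matrix(rnorm(n * 10, 0, 0.05), n)
    stats[, 1] <- stats[, 1] + centre
    colnames(stats) <- paste0("ss_", divscan:::summary_stat_names())
    dplyr::bind_cols(tibble::tibble(scenario = scenario, sim_seed = seq_len(n),
                                    T1 = 5e5), tibble::as_tibble(stats))
  }
  set.seed(44)
  tabs <- list(fake("simple_split", -5), fake("ne_change", 0),
               fake("admixture", 5))
  obs <- setNames(c(5, rep(0, 9)), divscan:::summary_stat_names())
  ch <- abc_model_choice(obs, tabs, accept_fraction = 0.05)
  expect_equal(ch$posterior$posterior[ch$posterior$scenario == "admixture"],
               1, tolerance = 1e-3)
  expect_setequal(glance(ch)$chosen, "admixture")
})

test_that("parameter estimation is self-consistent at a table row", {
  set.seed(45)
  tab <- build_reference_table("simple_split", n_sims = 3000, n_loci = 500,
                               seed = 46)
  i <- 17
  obs <- as.numeric(tab[i, divscan:::stat_cols(tab)])
  names(obs) <- divscan:::summary_stat_names()
  post <- abc_parameter_estimate(obs, tab, accept_fraction = 0.02)
  est <- tidy(post)
  truth <- tab[i, est$parameter]
  # the generating row's parameters fall inside the 95% intervals
  covered <- mapply(function(p, lo, hi) {
    tv <- as.numeric(truth[[p]])
    tv >= lo && tv <= hi
  }, est$parameter, est$lower, est$upper)
  expect_gte(mean(covered), 0.5)
  expect_true(all(est$lower <= est$median & est$median <= est$upper))
})

test_that("widening the acceptance fraction widens the posterior intervals", {
  set.seed(47)
  tab <- build_reference_table("admixture", n_sims = 3000, n_loci = 500,
                               seed = 48)
  ratios <- unlist(lapply(c(5, 23, 111, 500), function(i) {
    obs <- as.numeric(tab[i, divscan:::stat_cols(tab)])
    names(obs) <- divscan:::summary_stat_names()
    w1 <- tidy(abc_parameter_estimate(obs, tab, accept_fraction = 0.01))
    w2 <- tidy(abc_parameter_estimate(obs, tab, accept_fraction = 0.1))
    (w2$upper - w2$lower) / (w1$upper - w1$lower)
  }))
  # regression adjustment can shrink individual intervals, but widening the
  # acceptance region widens or preserves them for the large majority of
  # (observed, parameter) pairs and on average
  expect_gte(mean(ratios >= 0.95), 0.8)
  expect_gt(mean(ratios), 1)
})

test_that("posterior error rate runs end to end and is deterministic", {
  tabs <- lapply(scenario_ids(), function(s) {
    build_reference_table(s, n_sims = 250, n_loci = 200,
                          seed = 50 + scenario_code(s))
  })
  obs <- compute_summary_stats(simulate_dataset(
    "admixture",
    list(T1 = 9e5, T2 = 3e5, N_Ancestral = 3e5, N_AncestralNESP = 5e4,
         N_SALS = 8e4, N_NESP = 2e4, T_admix = 5e3, r = 0.5),
    n_loci = 200))
  e1 <- posterior_error_rate(tabs, obs, n_pseudo = 20, n_closest = 50,
                             seed = 51)
  e2 <- posterior_error_rate(tabs, obs, n_pseudo = 20, n_closest = 50,
                             seed = 51)
  expect_identical(e1$error_rate, e2$error_rate)
  expect_gte(e1$error_rate, 0)
  expect_lte(e1$error_rate, 1)
  expect_equal(nrow(e1$results), 20)
})

test_that("ABC SNP selection enforces every filter and the spacing rule", {
  set.seed(52)
  n <- 300
  gt <- matrix(rbinom(n * 20, 2, rep(runif(n, 0.2, 0.8), 20)), n)
  dp <- matrix(10L, n, 20)
  gt[1:20, 1] <- NA                 # missing genotype
  dp[21:40, 3] <- 4L                # depth below 5 in one individual
  dp[41:60, ] <- 13L                # mean depth outside (8, 12)
  gt[61:80, 1:10] <- 0L             # extreme FST
  gt[61:80, 11:20] <- 2L
  pos <- seq(1, by = 25000, length.out = n)  # spacing always satisfied
  gm <- make_gm(gt, pos = pos, dp = dp)
  sets <- select_abc_snps(gm, n_per_set = 50, n_sets = 2, seed = 53)

  # brute-force pool oracle
  s <- site_allele_stats(gm)
  fst <- sapply(seq_len(n), function(i) {
    w <- oracle_wc(s$nind1[i], s$p1[i], s$het1[i] / s$nind1[i],
                   s$nind2[i], s$p2[i], s$het2[i] / s$nind2[i])
    if (sum(w) == 0) NA else w[1] / sum(w)
  })
  mu <- mean(fst, na.rm = TRUE); sdv <- sd(fst, na.rm = TRUE)
  pool <- sapply(seq_len(n), function(i) {
    all(!is.na(gt[i, ])) && all(dp[i, ] >= 5) &&
      mean(dp[i, ]) > 8 && mean(dp[i, ]) < 12 &&
      !is.na(fst[i]) && abs(fst[i] - mu) <= sdv
  })
  expect_equal(attr(sets, "pool_size"), sum(pool))
  chosen <- unlist(sets)
  expect_true(all(chosen %in% which(pool)))
  expect_equal(anyDuplicated(chosen), 0)
  for (st in sets) {
    expect_true(all(diff(sort(gm$sites$pos[st])) >= 2e4))
  }
  expect_error(select_abc_snps(gm, n_per_set = 500, n_sets = 3, seed = 1),
               "pool")
})
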