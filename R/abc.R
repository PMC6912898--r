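# --- summary statistics ----------------------------------------------------

# the ten DIYABC-style summary statistics from per-locus counts.
# m: matrix/tibble with alt1, het1, alt2, het2; n1, n2 diploid sample sizes
# (or vectors of per-locus called individuals).
summary_stat_names <- function() {
  c("gd1_mean", "gd1_var", "gd1_pzero",
    "gd2_mean", "gd2_var", "gd2_pzero",
    "fst_mean", "fst_var", "nei_mean", "nei_var")
}

summary_stats_counts <- function(alt1, het1, alt2, het2, nind1, nind2) {
  na1 <- 2 * nind1; na2 <- 2 * nind2
  p1 <- alt1 / na1; p2 <- alt2 / na2
  gd <- function(ac, na) {
    p <- ac / na
    g <- na * 2 * p * (1 - p) / (na - 1)
    g[na < 2] <- NA_real_
    g
  }
  gd1 <- gd(alt1, na1); gd2 <- gd(alt2, na2)
  h1 <- het1 / nind1; h2 <- het2 / nind2
  comp <- wc_components(nind1, p1, h1, nind2, p2, h2)
  den <- comp$a + comp$b + comp$c
  fst <- ifelse(!is.na(den) & den != 0, comp$a / den, NA_real_)
  q1 <- 1 - p1; q2 <- 1 - p2
  jx <- p1^2 + q1^2; jy <- p2^2 + q2^2
  jxy <- p1 * p2 + q1 * q2
  nei <- -log(jxy / sqrt(jx * jy))
  nz <- function(x) {
    x <- x[is.finite(x) & x != 0]
    m <- if (length(x)) mean(x) else 0
    v <- if (length(x) > 1) var(x) else 0
    c(m, v)
  }
  out <- c(
    nz(gd1), mean(gd1 == 0, na.rm = TRUE),
    nz(gd2), mean(gd2 == 0, na.rm = TRUE),
    nz(fst), nz(nei)
  )
  setNames(out, summary_stat_names())
}

#' The ten ABC summary statistics
#'
#' Per population: mean and variance of nonzero per-locus genic diversity
#' (unbiased expected heterozygosity n (1 - sum p^2) / (n - 1)) and the
#' proportion of zero-diversity loci; plus the mean and variance of
#' nonzero per-locus pairwise Weir-Cockerham FST and of nonzero per-locus
#' Nei distance -ln(Jxy / sqrt(Jx Jy)). Zero or undefined values are
#' excluded from the nonzero means/variances; a family with no nonzero
#' values reports 0.
#'
#' @param x an `abc_loci` tibble from [simulate_dataset()] or a
#'   [geno_matrix()] of unlinked loci.
#' @return Named numeric vector of length 10.
#' @export
compute_summary_stats <- function(x) {
  if (inherits(x, "abc_loci")) {
    summary_stats_counts(x$alt1, x$het1, x$alt2, x$het2,
                         attr(x, "n1"), attr(x, "n2"))
  } else if (inherits(x, "geno_matrix")) {
    s <- site_allele_stats(x)
    summary_stats_counts(s$ac1, s$het1, s$ac2, s$het2, s$nind1, s$nind2)
  } else {
    stop("x must be an abc_loci tibble or a geno_matrix", call. = FALSE)
  }
}

# --- reference tables ------------------------------------------------------

#' Build an ABC reference table for one scenario
#'
#' Draws parameter vectors from the priors, simulates a dataset of
#' `n_loci` unlinked SNP loci for each, and records the ten summary
#' statistics. Each row carries its own RNG seed so any row can be
#' replayed exactly.
#'
#' @param scenario one of [scenario_ids()].
#' @param n_sims number of simulations.
#' @param n_loci loci per simulated dataset (default 2000).
#' @param priors bounds from [demographic_priors()].
#' @param sample_sizes diploid counts `c(SALS, NESP)`.
#' @param seed optional integer seed governing the whole table.
#' @param progress print progress every 1000 rows.
#' @return tibble of class `ref_table`: scenario, per-row seed, parameter
#'   columns and `ss_*` statistic columns.
#' @export
build_reference_table <- function(scenario, n_sims, n_loci = 2000,
                                  priors = demographic_priors(),
                                  sample_sizes = c(10, 10), seed = NULL,
                                  progress = FALSE) {
  scenario <- match.arg(scenario, scenario_ids())
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max, n_sims)
  params <- sample_prior(scenario, n_sims, priors)
  scode <- scenario_code(scenario)
  n1 <- sample_sizes[1]; n2 <- sample_sizes[2]
  stats <- matrix(NA_real_, n_sims, 10)
  for (i in seq_len(n_sims)) {
    set.seed(row_seeds[i])
    par <- scenario_par_vector(scenario, params[i, ])
    m <- .sim_scenario_counts(scode, par, n_loci, n1, n2)
    stats[i, ] <- summary_stats_counts(m[, 1], m[, 2], m[, 3], m[, 4], n1, n2)
    if (progress && i %% 1000 == 0) {
      message("  ", scenario, ": ", i, " / ", n_sims)
    }
  }
  colnames(stats) <- paste0("ss_", summary_stat_names())
  out <- dplyr::bind_cols(
    tibble::tibble(scenario = scenario, sim_seed = row_seeds),
    params, tibble::as_tibble(stats)
  )
  attr(out, "scenario") <- scenario
  attr(out, "n_loci") <- n_loci
  attr(out, "sample_sizes") <- sample_sizes
  class(out) <- c("ref_table", class(out))
  out
}

stat_cols <- function(tab) grep("^ss_", names(tab), value = TRUE)

# pooled MAD standardization scale (fallback SD, fallback 1)
pooled_scale <- function(S) {
  apply(S, 2, function(x) {
    s <- mad(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    s
  })
}

obs_vector <- function(observed) {
  if (inherits(observed, c("abc_loci", "geno_matrix"))) {
    observed <- compute_summary_stats(observed)
  }
  nm <- summary_stat_names()
  if (!is.null(names(observed)) && all(nm %in% names(observed))) {
    observed <- observed[nm]
  }
  stopifnot(length(observed) == 10)
  as.numeric(observed)
}

# --- model choice ----------------------------------------------------------

#' ABC model choice by weighted multinomial logistic regression
#'
#' Pools the per-scenario reference tables, standardizes every statistic
#' by its pooled median absolute deviation, ranks rows by Euclidean
#' distance to the observed vector, keeps the closest `accept_fraction`,
#' and fits a multinomial logistic regression of scenario label on the
#' (statistic - observed) differences with Epanechnikov distance weights.
#' Posterior probabilities are the fitted class probabilities at the zero
#' vector.
#'
#' @param observed observed statistics (named vector, `abc_loci`, or
#'   [geno_matrix()]).
#' @param tables list of `ref_table` objects, one per scenario.
#' @param accept_fraction fraction of pooled rows retained (default 0.01).
#' @return Object of class `abc_choice`; `tidy()` gives the posterior
#'   probabilities, `glance()` a one-row summary.
#' @export
abc_model_choice <- function(observed, tables, accept_fraction = 0.01) {
  obs <- obs_vector(observed)
  pool <- dplyr::bind_rows(lapply(tables, function(t) {
    dplyr::bind_cols(tibble::tibble(scenario = t$scenario),
                     tibble::as_tibble(t[stat_cols(t)]))
  }))
  S <- as.matrix(pool[stat_cols(pool)])
  sc <- pooled_scale(S)
  Z <- sweep(sweep(S, 2, obs, "-"), 2, sc, "/")
  d <- sqrt(rowSums(Z^2))
  n_keep <- max(3L, ceiling(accept_fraction * nrow(pool)))
  keep <- order(d)[seq_len(min(n_keep, nrow(pool)))]
  dmax <- max(d[keep])
  w <- if (dmax > 0) 1 - (d[keep] / dmax)^2 else rep(1, length(keep))
  w[w <= 0] <- min(w[w > 0], 1e-6)
  labs <- factor(pool$scenario[keep], levels = scenario_ids())
  present <- levels(droplevels(labs))
  probs <- setNames(rep(0, 3), scenario_ids())
  if (length(present) == 1) {
    probs[present] <- 1
    flagged <- setdiff(scenario_ids(), present)
  } else {
    dat <- data.frame(label = droplevels(labs), Z[keep, , drop = FALSE])
    fit <- nnet::multinom(label ~ ., data = dat, weights = w,
                          trace = FALSE, maxit = 500, MaxNWts = 5000)
    zero <- as.data.frame(matrix(0, 1, ncol(Z)))
    names(zero) <- colnames(Z)
    p <- predict(fit, newdata = zero, type = "probs")
    if (is.null(dim(p)) && length(p) == 1) {
      # two-class fit returns P(second level)
      p <- c(1 - p, p)
      names(p) <- levels(droplevels(labs))
    }
    probs[names(p)] <- as.numeric(p)
    flagged <- setdiff(scenario_ids(), present)
  }
  probs <- pmax(probs, 0)
  probs <- probs / sum(probs)
  structure(
    list(posterior = tibble::tibble(scenario = scenario_ids(),
                                    posterior = unname(probs[scenario_ids()])),
         n_accepted = length(keep), distance_threshold = dmax,
         accept_fraction = accept_fraction, absent_scenarios = flagged),
    class = "abc_choice"
  )
}

#' @export
print.abc_choice <- function(x, ...) {
  cat("<abc_choice> posterior probabilities (", x$n_accepted,
      " accepted rows):\n", sep = "")
  for (i in seq_len(nrow(x$posterior))) {
    cat(sprintf("  %-14s %.4f\n", x$posterior$scenario[i],
                x$posterior$posterior[i]))
  }
  invisible(x)
}

#' @export
tidy.abc_choice <- function(x, ...) x$posterior

#' @export
glance.abc_choice <- function(x, ...) {
  tibble::tibble(
    chosen = x$posterior$scenario[which.max(x$posterior$posterior)],
    max_posterior = max(x$posterior$posterior),
    n_accepted = x$n_accepted,
    distance_threshold = x$distance_threshold
  )
}

# --- parameter estimation --------------------------------------------------

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  sapply(probs, function(p) x[which(cw >= p)[1]])
}

#' ABC parameter estimation with local-linear adjustment
#'
#' Retains the closest `accept_fraction` of the reference table by
#' standardized Euclidean distance, then adjusts parameters by weighted
#' local-linear regression on the statistic differences (Beaumont-style
#' regression adjustment). Time and size parameters are log-transformed
#' before adjustment and back-transformed after; the admixture proportion
#' is adjusted on its natural scale. Reported intervals are equal-tailed
#' posterior quantiles of the weighted, adjusted draws.
#'
#' @param observed observed statistics.
#' @param table a `ref_table` for the chosen scenario.
#' @param accept_fraction fraction retained (default 0.01).
#' @param ci_level credible-interval level (default 0.95).
#' @return Object of class `abc_posterior`; `tidy()` gives per-parameter
#'   median and interval bounds.
#' @export
abc_parameter_estimate <- function(observed, table, accept_fraction = 0.01,
                                   ci_level = 0.95) {
  obs <- obs_vector(observed)
  sc_names <- stat_cols(table)
  par_names <- setdiff(names(table), c("scenario", "sim_seed", sc_names))
  S <- as.matrix(table[sc_names])
  sc <- pooled_scale(S)
  Z <- sweep(sweep(S, 2, obs, "-"), 2, sc, "/")
  d <- sqrt(rowSums(Z^2))
  n_keep <- max(5L, ceiling(accept_fraction * nrow(table)))
  keep <- order(d)[seq_len(min(n_keep, nrow(table)))]
  dmax <- max(d[keep])
  w <- if (dmax > 0) 1 - (d[keep] / dmax)^2 else rep(1, length(keep))
  w[w <= 0] <- min(w[w > 0], 1e-6)

  logpar <- grepl("^[TN]_?", par_names) & par_names != "r"
  Y <- as.matrix(table[keep, par_names])
  Yt <- Y
  for (j in which(logpar)) Yt[, j] <- log(pmax(Y[, j], 1e-6))
  X <- Z[keep, , drop = FALSE]
  adjusted <- tryCatch({
    fit <- stats::lm.wfit(cbind(1, X), Yt, w)
    beta <- fit$coefficients
    if (anyNA(beta)) stop("singular design")
    Yt - X %*% beta[-1, , drop = FALSE]
  }, error = function(e) {
    warning("regression adjustment failed (", conditionMessage(e),
            "); using unadjusted rejection posterior")
    Yt
  })
  for (j in which(logpar)) adjusted[, j] <- exp(adjusted[, j])
  if ("r" %in% par_names) {
    jr <- which(par_names == "r")
    adjusted[, jr] <- pmin(pmax(adjusted[, jr], 0), 1)
  }
  alpha <- (1 - ci_level) / 2
  est <- purrr::map_dfr(seq_along(par_names), function(j) {
    qs <- weighted_quantile(adjusted[, j], w, c(alpha, 0.5, 1 - alpha))
    tibble::tibble(parameter = par_names[j], median = qs[2],
                   lower = qs[1], upper = qs[3])
  })
  structure(
    list(estimates = est,
         draws = tibble::as_tibble(as.data.frame(adjusted)) |>
           setNames(par_names),
         weights = w, n_accepted = length(keep), ci_level = ci_level,
         interval_type = "equal-tailed quantiles (HPD approximation)"),
    class = "abc_posterior"
  )
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> ", x$n_accepted, " accepted draws; ",
      round(100 * x$ci_level), "% equal-tailed intervals\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.abc_posterior <- function(x, ...) x$estimates

#' @export
glance.abc_posterior <- function(x, ...) {
  tibble::tibble(n_accepted = x$n_accepted, ci_level = x$ci_level,
                 n_parameters = nrow(x$estimates))
}

# --- posterior error rate --------------------------------------------------

#' Posterior predictive error of scenario choice
#'
#' Draws `n_pseudo` (scenario, parameter) pairs from the `n_closest`
#' pooled reference rows nearest the observed vector, simulates a fresh
#' dataset for each, classifies it with [abc_model_choice()], and reports
#' the fraction misclassified.
#'
#' @param tables list of `ref_table` objects.
#' @param observed observed statistics.
#' @param n_pseudo number of pseudo-observed datasets (default 1000).
#' @param n_closest pool of nearest rows to resample from (default 500).
#' @param accept_fraction passed to [abc_model_choice()].
#' @param seed optional seed.
#' @return List with `error_rate` and a per-replicate `results` tibble.
#' @export
posterior_error_rate <- function(tables, observed, n_pseudo = 1000,
                                 n_closest = 500, accept_fraction = 0.01,
                                 seed = NULL) {
  obs <- obs_vector(observed)
  if (!is.null(seed)) set.seed(seed)
  pool <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  S <- as.matrix(pool[stat_cols(pool)])
  sc <- pooled_scale(S)
  Z <- sweep(sweep(S, 2, obs, "-"), 2, sc, "/")
  d <- sqrt(rowSums(Z^2))
  closest <- pool[order(d)[seq_len(min(n_closest, nrow(pool)))], ]
  n_loci <- attr(tables[[1]], "n_loci") %||% 2000
  sample_sizes <- attr(tables[[1]], "sample_sizes") %||% c(10, 10)
  pick <- sample.int(nrow(closest), n_pseudo, replace = TRUE)
  results <- purrr::map_dfr(pick, function(i) {
    row <- closest[i, ]
    sim <- simulate_dataset(row$scenario, row, n_loci = n_loci,
                            sample_sizes = sample_sizes)
    ch <- abc_model_choice(sim, tables, accept_fraction)
    tibble::tibble(
      true_scenario = row$scenario,
      chosen = ch$posterior$scenario[which.max(ch$posterior$posterior)]
    )
  })
  list(error_rate = mean(results$true_scenario != results$chosen),
       results = results)
}

# --- SNP selection for the observed dataset --------------------------------

#' Select neutral, unlinked, high-confidence SNP sets for ABC
#'
#' Candidate SNPs must have no missing genotypes, per-sample depth of at
#' least `min_depth_all` in every individual, mean depth strictly inside
#' `mean_depth_range`, and per-SNP Weir-Cockerham FST within
#' `fst_sd_window` standard deviations of the genome-wide mean (to be
#' effectively neutral). Spacing of at least `min_spacing` bp is enforced
#' greedily after random shuffling, then the requested disjoint sets are
#' drawn at random without replacement.
#'
#' @param gm a [geno_matrix()] with depths.
#' @param n_per_set SNPs per set (default 2000).
#' @param n_sets number of disjoint sets (default 3).
#' @param min_depth_all minimum depth in every individual (default 5).
#' @param mean_depth_range exclusive bounds on the SNP mean depth
#'   (default `c(8, 12)`).
#' @param fst_sd_window SD multiplier for the neutrality band (default 1).
#' @param min_spacing minimum distance between selected SNPs in bp
#'   (default 20,000).
#' @param seed optional seed.
#' @return List of `n_sets` integer vectors of site indices; the filtered
#'   pool size is attached as attribute `pool_size`.
#' @export
select_abc_snps <- function(gm, n_per_set = 2000, n_sets = 3,
                            min_depth_all = 5, mean_depth_range = c(8, 12),
                            fst_sd_window = 1, min_spacing = 2e4,
                            seed = NULL) {
  if (is.null(gm$dp)) stop("depths are required for SNP selection", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- site_allele_stats(gm)
  h1 <- ifelse(s$nind1 > 0, s$het1 / s$nind1, NA_real_)
  h2 <- ifelse(s$nind2 > 0, s$het2 / s$nind2, NA_real_)
  comp <- wc_components(s$nind1, s$p1, h1, s$nind2, s$p2, h2)
  den <- comp$a + comp$b + comp$c
  fst <- ifelse(!is.na(den) & den != 0, comp$a / den, NA_real_)
  fst_mu <- mean(fst, na.rm = TRUE)
  fst_sd <- sd(fst, na.rm = TRUE)

  ok <- rowSums(is.na(gm$gt)) == 0 &
    rowSums(is.na(gm$dp) | gm$dp < min_depth_all) == 0 &
    rowMeans(gm$dp) > mean_depth_range[1] &
    rowMeans(gm$dp) < mean_depth_range[2] &
    !is.na(fst) &
    abs(fst - fst_mu) <= fst_sd_window * fst_sd
  cand <- which(ok)

  # greedy spacing after random shuffle
  cand <- cand[sample.int(length(cand))]
  accepted <- integer(0)
  by_scaf <- new.env(parent = emptyenv())
  for (i in cand) {
    scaf <- gm$sites$scaffold[i]
    pos <- gm$sites$pos[i]
    cur <- get0(scaf, envir = by_scaf, ifnotfound = numeric(0))
    if (length(cur) == 0 || min(abs(cur - pos)) >= min_spacing) {
      assign(scaf, c(cur, pos), envir = by_scaf)
      accepted <- c(accepted, i)
    }
  }
  need <- n_per_set * n_sets
  if (length(accepted) < need) {
    stop("eligible SNP pool has only ", length(accepted),
         " SNPs; need ", need, call. = FALSE)
  }
  chosen <- sample(accepted, need)
  sets <- split(chosen, rep(seq_len(n_sets), each = n_per_set))
  sets <- lapply(sets, sort)
  names(sets) <- paste0("set", seq_len(n_sets))
  attr(sets, "pool_size") <- length(accepted)
  sets
}
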