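#' Per-site allele statistics for both populations
#'
#' For every site and each of the two populations: number of called
#' individuals, called alleles, alt-allele count, heterozygote count, alt
#' frequency and observed heterozygosity. Population 1 / 2 follow the
#' order of labels in the population map.
#'
#' @param gm a [geno_matrix()].
#' @return tibble, one row per site.
#' @export
site_allele_stats <- function(gm) {
  cols <- pop_columns(gm)
  per_pop <- lapply(cols, function(idx) {
    sub <- gm$gt[, idx, drop = FALSE]
    nind <- rowSums(!is.na(sub))
    ac <- rowSums(sub, na.rm = TRUE)
    list(nind = nind, na = 2L * nind, ac = ac,
         het = rowSums(sub == 1L, na.rm = TRUE),
         p = ifelse(nind > 0, ac / (2 * nind), NA_real_))
  })
  s1 <- per_pop[[1]]; s2 <- per_pop[[2]]
  tibble::tibble(
    scaffold = gm$sites$scaffold, pos = gm$sites$pos,
    nind1 = s1$nind, na1 = s1$na, ac1 = s1$ac, het1 = s1$het, p1 = s1$p,
    nind2 = s2$nind, na2 = s2$na, ac2 = s2$ac, het2 = s2$het, p2 = s2$p
  )
}

#' Weir-Cockerham variance components for two populations
#'
#' Per-site components a (among populations), b (among individuals within
#' populations) and c (within individuals) of the Weir & Cockerham (1984)
#' FST estimator, for r = 2 populations. All arguments are vectorized.
#' Sites where either population has fewer than two called individuals get
#' `NA` components.
#'
#' @param nind1,nind2 called individuals per population.
#' @param p1,p2 alt-allele frequencies.
#' @param h1,h2 observed heterozygote frequencies (heterozygotes / called
#'   individuals).
#' @return tibble with columns `a`, `b`, `c`.
#' @export
wc_components <- function(nind1, p1, h1, nind2, p2, h2) {
  r <- 2
  nbar <- (nind1 + nind2) / r
  nc <- (r * nbar - (nind1^2 + nind2^2) / (r * nbar)) / (r - 1)
  pbar <- (nind1 * p1 + nind2 * p2) / (r * nbar)
  s2 <- (nind1 * (p1 - pbar)^2 + nind2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nind1 * h1 + nind2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- nind1 < 2 | nind2 < 2
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  tibble::tibble(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' The weighted window estimator sum(a) / sum(a + b + c) over per-site
#' variance components. May be slightly negative; never truncated.
#'
#' @param a,b,c per-site components from [wc_components()].
#' @return Numeric scalar, `NA` when no site contributes variance.
#' @export
window_fst <- function(a, b, c) {
  den <- sum(a + b + c, na.rm = TRUE)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  sum(a, na.rm = TRUE) / den
}

# mean of per-site ratios, the alternative VCFtools-style summary
window_fst_mean_ratio <- function(a, b, c) {
  den <- a + b + c
  ok <- !is.na(den) & den > 0
  if (!any(ok)) return(NA_real_)
  mean(a[ok] / den[ok])
}

#' Absolute divergence Dxy for a window
#'
#' Per-site divergence d = p1 (1 - p2) + p2 (1 - p1), averaged per SNP and
#' per bp. The per-SNP value (variant sites only) is the primary output;
#' the per-bp value divides by the window length.
#'
#' @param p1,p2 per-site alt frequencies in each population.
#' @param window_length window length in bp.
#' @return Named list with `dxy_per_snp` and `dxy_per_bp`.
#' @export
window_dxy <- function(p1, p2, window_length) {
  d <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- !is.na(d)
  if (!any(ok)) return(list(dxy_per_snp = NA_real_, dxy_per_bp = NA_real_))
  list(dxy_per_snp = mean(d[ok]),
       dxy_per_bp = sum(d[ok]) / window_length)
}

#' Nucleotide diversity (pi) per bp for one population
#'
#' Per-site contribution 2 * ac * (na - ac) / (na (na - 1)) with na called
#' alleles and ac alt alleles; monomorphic sites contribute zero.
#'
#' @param ac per-site alt-allele counts.
#' @param na per-site called-allele counts.
#' @param window_length window length in bp.
#' @return Numeric scalar (>= 0).
#' @export
window_pi <- function(ac, na, window_length) {
  ok <- !is.na(na) & na >= 2
  if (!any(ok)) return(0)
  sum(2 * ac[ok] * (na[ok] - ac[ok]) / (na[ok] * (na[ok] - 1))) / window_length
}

#' Tajima's D constants
#'
#' The standard constants a1, a2, b1, b2, c1, c2, e1, e2 of Tajima (1989)
#' for a sample of `n` sequences.
#'
#' @param n number of sequences (>= 4 for a stable test).
#' @return Named list of constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' D = (k - S / a1) / sqrt(e1 S + e2 S (S - 1)) with S segregating sites,
#' k the mean number of pairwise differences, and constants from
#' [tajima_constants()].
#'
#' @param S number of segregating sites.
#' @param k mean pairwise differences.
#' @param n number of sequences.
#' @return Numeric scalar; `NA` when S = 0.
#' @export
tajimas_d <- function(S, k, n) {
  if (is.na(S) || S == 0 || is.na(n) || n < 4) return(NA_real_)
  const <- tajima_constants(n)
  (k - S / const$a1) / sqrt(const$e1 * S + const$e2 * S * (S - 1))
}

#' Classify fixed differences
#'
#' A site is a fixed SNP when the called allele sets of the two populations
#' are disjoint: each population monomorphic, for different alleles. A
#' heterozygote in either population always prevents fixation.
#'
#' @param ac1,na1,ac2,na2 alt and called allele counts per population.
#' @return Logical vector.
#' @export
classify_fixed <- function(ac1, na1, ac2, na2) {
  called <- na1 >= 2 & na2 >= 2
  called & ((ac1 == 0 & ac2 == na2) | (ac1 == na1 & ac2 == 0))
}

#' Fixed-SNP count and density for a window
#'
#' @param fixed logical vector from [classify_fixed()].
#' @param window_length window length in bp.
#' @return Named list with `n_fixed` and `df` (= n_fixed / window_length).
#' @export
count_fixed_and_df <- function(fixed, window_length) {
  stopifnot(window_length >= 1)
  nf <- sum(fixed, na.rm = TRUE)
  list(n_fixed = nf, df = nf / window_length)
}

# modal value of a positive-integer vector (smallest mode on ties)
modal_int <- function(x) {
  x <- x[!is.na(x) & x > 0]
  if (!length(x)) return(NA_integer_)
  tab <- tabulate(x)
  which.max(tab)
}

tajima_window <- function(ac, na, nind) {
  seg <- !is.na(na) & na >= 2 & ac > 0 & ac < na
  S <- sum(seg)
  k <- sum(2 * ac[seg] * (na[seg] - ac[seg]) / (na[seg] * (na[seg] - 1)))
  tajimas_d(S, k, 2L * modal_int(nind))
}

#' Compute all per-window statistics
#'
#' One row per non-empty window: SNP count, windowed Weir-Cockerham FST
#' (ratio of sums, plus the mean-of-ratios alternative), absolute
#' divergence Dxy (per SNP and per bp), per-population nucleotide
#' diversity and Tajima's D, mean observed and expected heterozygosity,
#' and the fixed-SNP count and density df. `pi_pop1` etc. follow the
#' population-label order of the popmap (recorded in attribute `pops`).
#'
#' @param gm a filtered [geno_matrix()].
#' @param window_length window length in bp (default 100,000).
#' @return tibble, one row per non-empty window.
#' @export
compute_window_stats <- function(gm, window_length = 1e5) {
  sas <- site_allele_stats(gm)
  sas$h1 <- ifelse(sas$nind1 > 0, sas$het1 / sas$nind1, NA_real_)
  sas$h2 <- ifelse(sas$nind2 > 0, sas$het2 / sas$nind2, NA_real_)
  comp <- wc_components(sas$nind1, sas$p1, sas$h1, sas$nind2, sas$p2, sas$h2)
  sas <- dplyr::bind_cols(sas, comp)
  sas$fixed <- classify_fixed(sas$ac1, sas$na1, sas$ac2, sas$na2)
  sas$hexp1 <- ifelse(sas$na1 >= 2,
                      sas$na1 * (1 - sas$p1^2 - (1 - sas$p1)^2) / (sas$na1 - 1),
                      NA_real_)
  sas$hexp2 <- ifelse(sas$na2 >= 2,
                      sas$na2 * (1 - sas$p2^2 - (1 - sas$p2)^2) / (sas$na2 - 1),
                      NA_real_)
  sas$window_index <- window_index(sas$pos, window_length)

  wins <- make_windows(gm, window_length)
  out <- sas |>
    dplyr::group_by(.data$scaffold, .data$window_index) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      fst = window_fst(.data$a, .data$b, .data$c),
      fst_mean_ratio = window_fst_mean_ratio(.data$a, .data$b, .data$c),
      dxy_per_snp = window_dxy(.data$p1, .data$p2, 1)$dxy_per_snp,
      dxy_sum = sum(.data$p1 * (1 - .data$p2) + .data$p2 * (1 - .data$p1),
                    na.rm = TRUE),
      pi_sum1 = window_pi(.data$ac1, .data$na1, 1),
      pi_sum2 = window_pi(.data$ac2, .data$na2, 1),
      tajd_pop1 = tajima_window(.data$ac1, .data$na1, .data$nind1),
      tajd_pop2 = tajima_window(.data$ac2, .data$na2, .data$nind2),
      h_obs = mean(c(.data$h1, .data$h2), na.rm = TRUE),
      h_exp = mean(c(.data$hexp1, .data$hexp2), na.rm = TRUE),
      n_fixed = sum(.data$fixed, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::inner_join(wins, by = c("scaffold", "window_index"),
                      suffix = c("", ".grid")) |>
    dplyr::mutate(
      win_len = .data$end - .data$start + 1,
      dxy_per_bp = .data$dxy_sum / .data$win_len,
      pi_pop1 = .data$pi_sum1 / .data$win_len,
      pi_pop2 = .data$pi_sum2 / .data$win_len,
      df = .data$n_fixed / .data$win_len
    ) |>
    dplyr::select("scaffold", "window_index", "start", "end", "n_snps",
                  "fst", "fst_mean_ratio", "dxy_per_snp", "dxy_per_bp",
                  "pi_pop1", "pi_pop2", "tajd_pop1", "tajd_pop2",
                  "h_obs", "h_exp", "n_fixed", "df") |>
    dplyr::arrange(.data$scaffold, .data$window_index)
  attr(out, "pops") <- pop_labels(gm)
  attr(out, "window_length") <- window_length
  out
}
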