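# Independent oracles: literal transcriptions of the published formulas,
# deliberately scalar and loop-based so they share no code with the package.

# Weir & Cockerham (1984) variance components for r = 2 populations.
# n1, n2: called individuals; p1, p2: alt frequencies; h1, h2: observed
# heterozygote frequencies.
oracle_wc <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Tajima (1989) D from S, k (mean pairwise differences) and n sequences.
oracle_tajima <- function(S, k, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Independent plain-R structured coalescent for a clean two-population
# split (no admixture, constant sizes), with length-biased genealogy
# resampling matching SNP ascertainment. Returns per-locus counts like
# simulate_dataset(). n_per_pop diploids per population; t_split in
# generations.
oracle_split_loci <- function(n_loci, n_per_pop, n_sals, n_nesp, n_anc,
                              t_split, pool_factor = 2) {
  nl <- 2 * n_per_pop
  one_genealogy <- function() {
    pop <- rep(c(1L, 2L), each = nl)
    masks <- lapply(seq_len(2 * nl), function(i) i)
    birth <- rep(0, 2 * nl)
    alive <- rep(TRUE, 2 * nl)
    sizes <- c(n_sals, n_nesp)
    t <- 0
    bm <- vector("list", 2 * (2 * nl) - 2)
    bl <- numeric(2 * (2 * nl) - 2)
    nb <- 0
    merged_yet <- FALSE
    while (sum(alive) > 1) {
      idx <- which(alive)
      if (!merged_yet) {
        k1 <- sum(pop[idx] == 1); k2 <- sum(pop[idx] == 2)
        r1 <- k1 * (k1 - 1) / (4 * sizes[1])
        r2 <- k2 * (k2 - 1) / (4 * sizes[2])
        rate <- r1 + r2
        dt <- if (rate > 0) rexp(1, rate) else Inf
        if (t + dt >= t_split) {
          t <- t_split
          pop[] <- 1L
          sizes[1] <- n_anc
          merged_yet <- TRUE
          next
        }
        t <- t + dt
        which_pop <- if (runif(1) < r1 / rate) 1L else 2L
        cand <- idx[pop[idx] == which_pop]
      } else {
        k <- length(idx)
        t <- t + rexp(1, k * (k - 1) / (4 * sizes[1]))
        cand <- idx
      }
      ij <- sample(cand, 2)
      for (x in ij) {
        nb <- nb + 1
        bm[[nb]] <- masks[[x]]
        bl[nb] <- t - birth[x]
      }
      masks[[ij[1]]] <- c(masks[[ij[1]]], masks[[ij[2]]])
      birth[ij[1]] <- t
      alive[ij[2]] <- FALSE
    }
    list(bm = bm[seq_len(nb)], bl = bl[seq_len(nb)])
  }
  pool <- replicate(pool_factor * n_loci, one_genealogy(), simplify = FALSE)
  lens <- vapply(pool, function(g) sum(g$bl), numeric(1))
  pick <- sample.int(length(pool), n_loci, replace = TRUE, prob = lens)
  out <- matrix(0L, n_loci, 4)
  for (i in seq_len(n_loci)) {
    g <- pool[[pick[i]]]
    b <- sample.int(length(g$bl), 1, prob = g$bl)
    derived <- g$bm[[b]]
    # lineages 1..nl are population 1, paired (1,2), (3,4), ...
    dos <- integer(2 * n_per_pop)
    for (l in derived) dos[ceiling(l / 2)] <- dos[ceiling(l / 2)] + 1L
    d1 <- dos[seq_len(n_per_pop)]
    d2 <- dos[n_per_pop + seq_len(n_per_pop)]
    out[i, ] <- c(sum(d1), sum(d1 == 1), sum(d2), sum(d2 == 1))
  }
  colnames(out) <- c("alt1", "het1", "alt2", "het2")
  out
}
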