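#' Synthetic genome configuration
#'
#' Settings for the two-population synthetic SNP generator. Background
#' sites follow a Balding-Nichols model: an ancestral frequency drawn
#' uniformly on (0.05, 0.95), per-population frequencies drawn from
#' Beta(p (1 - F) / F, (1 - p)(1 - F) / F) independently for the two
#' populations, and diploid genotypes Binomial(2, p_pop). The
#' differentiation parameter F is calibrated so the realized mean window
#' Weir-Cockerham FST matches `target_background_fst`. Fixed differences
#' (dosage 0 in one population, 2 in the other) are planted at
#' `background_fixed_density` everywhere and at each planted window's own
#' `fixed_density`. Planted windows additionally use an elevated F
#' calibrated to their `target_fst`.
#'
#' Defaults emulate the observed cohort structure: 10 + 10 diploid
#' individuals, 100-kb windows, background FST 0.32 with fixed-SNP
#' density 0.00022/bp, planted windows at FST 0.6 and density 0.0013/bp,
#' and at most 20% missing genotypes.
#'
#' @param n_scaffolds number of scaffolds (default 10).
#' @param scaffold_length length of each scaffold in bp (default 1e7).
#' @param snp_density background variable-site density per bp (default
#'   6e-3, the study's realized genome-wide SNP density, so that planted
#'   fixed differences make up a few percent of SNPs as observed).
#' @param n_individuals diploid individuals per population
#'   (default `c(10, 10)`).
#' @param pops population labels.
#' @param target_background_fst genome-wide FST target (default 0.32).
#' @param background_fixed_density fixed-SNP density per bp outside
#'   planted windows (default 0.00022).
#' @param planted_windows tibble with columns `scaffold`, `window_index`
#'   and optionally `target_fst` (default 0.6), `fixed_density`
#'   (default 0.0013).
#' @param planted_genes optional tibble with `gene_id`, `scaffold`,
#'   `start`, `end` and optionally `fixed_density` for extra planted
#'   fixed sites inside the gene; by default one 20-kb gene is placed in
#'   the middle of every planted window.
#' @param missing_rate per-genotype missing probability (default 0.1,
#'   kept at or below the 20% filter).
#' @param depth_mean,depth_size negative-binomial per-genotype depth model
#'   (defaults mean 10, size 1.1, matching a mean SNP depth near 10 with
#'   SD near 10).
#' @param window_length window size in bp (default 100,000).
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config.
#' @return A list of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(n_scaffolds = 10, scaffold_length = 1e7,
                                    snp_density = 6e-3,
                                    n_individuals = c(10, 10),
                                    pops = c("SALS", "NESP"),
                                    target_background_fst = 0.32,
                                    background_fixed_density = 0.00022,
                                    planted_windows = NULL,
                                    planted_genes = NULL,
                                    missing_rate = 0.1,
                                    depth_mean = 10, depth_size = 1.1,
                                    window_length = 1e5, seed = 1) {
  stopifnot(snp_density >= 0, background_fixed_density >= 0,
            missing_rate >= 0, missing_rate <= 1,
            target_background_fst > 0, target_background_fst < 1)
  if (!is.null(planted_windows)) {
    planted_windows <- tibble::as_tibble(planted_windows)
    if (!"target_fst" %in% names(planted_windows)) {
      planted_windows$target_fst <- 0.6
    }
    if (!"fixed_density" %in% names(planted_windows)) {
      planted_windows$fixed_density <- 0.0013
    }
    if (anyDuplicated(planted_windows[c("scaffold", "window_index")])) {
      stop("planted windows overlap", call. = FALSE)
    }
    nwin <- scaffold_length %/% window_length
    if (any(planted_windows$window_index < 0 |
              planted_windows$window_index >= nwin)) {
      stop("planted window outside scaffold bounds", call. = FALSE)
    }
  }
  structure(
    list(n_scaffolds = n_scaffolds, scaffold_length = scaffold_length,
         snp_density = snp_density, n_individuals = n_individuals,
         pops = pops, target_background_fst = target_background_fst,
         background_fixed_density = background_fixed_density,
         planted_windows = planted_windows, planted_genes = planted_genes,
         missing_rate = missing_rate, depth_mean = depth_mean,
         depth_size = depth_size, window_length = window_length,
         seed = seed),
    class = "synthetic_genome_config"
  )
}

# realized mean window FST of a Balding-Nichols probe genome
bn_realized_fst <- function(f, n_per_pop, n_sites, sites_per_window = 50) {
  p <- runif(n_sites, 0.05, 0.95)
  shape <- (1 - f) / f
  p1 <- rbeta(n_sites, p * shape, (1 - p) * shape)
  p2 <- rbeta(n_sites, p * shape, (1 - p) * shape)
  g1 <- matrix(rbinom(n_sites * n_per_pop, 2, p1), n_sites)
  g2 <- matrix(rbinom(n_sites * n_per_pop, 2, p2), n_sites)
  ac1 <- rowSums(g1); ac2 <- rowSums(g2)
  h1 <- rowMeans(g1 == 1); h2 <- rowMeans(g2 == 1)
  comp <- wc_components(rep(n_per_pop, n_sites), ac1 / (2 * n_per_pop), h1,
                        rep(n_per_pop, n_sites), ac2 / (2 * n_per_pop), h2)
  win <- (seq_len(n_sites) - 1) %/% sites_per_window
  fsts <- tapply(seq_len(n_sites), win, function(i) {
    window_fst(comp$a[i], comp$b[i], comp$c[i])
  })
  mean(unlist(fsts), na.rm = TRUE)
}

#' Calibrate the Balding-Nichols differentiation parameter
#'
#' Bisection on F so that the realized mean window Weir-Cockerham FST of a
#' probe genome matches `target_fst` within `tol`. The same probe seed is
#' reused at every evaluation (common random numbers), making the realized
#' value monotone in F.
#'
#' @param target_fst target mean window FST in (0, 1).
#' @param n_per_pop diploid individuals per population (default 10).
#' @param n_probe_sites probe sites per evaluation (default 5000).
#' @param seed probe seed.
#' @param tol calibration tolerance (default 0.01).
#' @return List with `f` (calibrated parameter) and `achieved` (realized
#'   probe FST).
#' @export
calibrate_bn_parameter <- function(target_fst, n_per_pop = 10,
                                   n_probe_sites = 5000, seed = 1,
                                   tol = 0.01) {
  stopifnot(target_fst > 0, target_fst < 1)
  probe <- function(f) {
    set.seed(seed)
    bn_realized_fst(f, n_per_pop, n_probe_sites)
  }
  lo <- 0.001; hi <- 0.99
  v_lo <- probe(lo); v_hi <- probe(hi)
  if (target_fst < v_lo - tol || target_fst > v_hi + tol) {
    stop("target FST ", target_fst, " unreachable in F = [0.001, 0.99]",
         call. = FALSE)
  }
  f <- (lo + hi) / 2
  for (i in 1:40) {
    f <- (lo + hi) / 2
    v <- probe(f)
    if (abs(v - target_fst) <= tol || (hi - lo) < 1e-5) break
    if (v < target_fst) lo <- f else hi <- f
  }
  list(f = f, achieved = probe(f))
}

#' Generate a synthetic two-population genome with planted truth
#'
#' Produces a [geno_matrix()] with Balding-Nichols background divergence,
#' planted fixed differences, planted elevated windows, planted gene
#' annotations, missingness and per-sample depths, together with a truth
#' table recording everything that was planted. Bit-reproducible given
#' the config (which includes the seed).
#'
#' @param config a [synthetic_genome_config()].
#' @return List of class `synthetic_genome` with elements `geno`
#'   ([geno_matrix()]), `truth` (planted windows, per-site labels,
#'   calibrated F values), `genes` (annotation tibble) and `config`.
#' @export
generate_genome <- function(config = synthetic_genome_config()) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  set.seed(config$seed)
  L <- config$scaffold_length
  wl <- config$window_length
  nwin <- ceiling(L / wl)
  scafs <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  lens <- setNames(rep(L, length(scafs)), scafs)

  f_bg <- calibrate_bn_parameter(config$target_background_fst,
                                 config$n_individuals[1],
                                 seed = config$seed)$f
  pw <- config$planted_windows
  f_elev <- NULL
  if (!is.null(pw) && nrow(pw) > 0) {
    targets <- unique(pw$target_fst)
    f_elev <- setNames(
      vapply(targets, function(t) {
        calibrate_bn_parameter(t, config$n_individuals[1],
                               seed = config$seed + 1)$f
      }, numeric(1)),
      as.character(targets)
    )
  }

  # default planted genes: one 20-kb gene centred in each planted window
  genes <- config$planted_genes
  if (is.null(genes) && !is.null(pw) && nrow(pw) > 0) {
    mid <- pw$window_index * wl + wl / 2
    genes <- tibble::tibble(
      gene_id = sprintf("gene_%s_w%d", pw$scaffold, pw$window_index),
      scaffold = pw$scaffold,
      start = mid - 1e4, end = mid + 1e4 - 1
    )
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = character(), scaffold = character(),
                            start = numeric(), end = numeric())
  }
  genes <- tibble::as_tibble(genes)

  sites <- purrr::map_dfr(scafs, function(s) {
    planted_here <- if (!is.null(pw)) pw[pw$scaffold == s, ] else pw
    win_start <- (seq_len(nwin) - 1) * wl
    is_planted <- (seq_len(nwin) - 1) %in%
      (if (!is.null(planted_here)) planted_here$window_index else integer())

    n_bg <- rbinom(1, L, config$snp_density)
    bg_pos <- sample.int(L, n_bg)
    bg_widx <- window_index(bg_pos, wl)
    has_planted <- !is.null(planted_here) && nrow(planted_here) > 0
    bg_planted <- bg_widx %in%
      (if (has_planted) planted_here$window_index else integer())
    f_site <- rep(f_bg, n_bg)
    if (has_planted && any(bg_planted)) {
      tgt <- planted_here$target_fst[match(bg_widx[bg_planted],
                                           planted_here$window_index)]
      f_site[bg_planted] <- f_elev[as.character(tgt)]
    }
    bg <- tibble::tibble(
      scaffold = s, pos = bg_pos,
      label = ifelse(bg_planted, "planted_elevated", "background"),
      f = f_site
    )

    fx <- purrr::map_dfr(seq_len(nwin), function(w) {
      widx <- w - 1L
      this_len <- min(w * wl, L) - win_start[w]
      dens <- if (is_planted[w]) {
        planted_here$fixed_density[match(widx, planted_here$window_index)]
      } else {
        config$background_fixed_density
      }
      nf <- rbinom(1, this_len, dens)
      if (nf == 0) return(NULL)
      tibble::tibble(
        scaffold = s,
        pos = win_start[w] + sample.int(this_len, nf),
        label = if (is_planted[w]) "planted_fixed" else "background_fixed",
        f = NA_real_
      )
    })

    gn <- genes[genes$scaffold == s & !is.na(genes$scaffold), ]
    gfx <- NULL
    if (nrow(gn) > 0 && "fixed_density" %in% names(gn)) {
      gfx <- purrr::map_dfr(seq_len(nrow(gn)), function(i) {
        if (is.na(gn$fixed_density[i])) return(NULL)
        glen <- gn$end[i] - gn$start[i] + 1
        nf <- rbinom(1, glen, gn$fixed_density[i])
        if (nf == 0) return(NULL)
        tibble::tibble(scaffold = s,
                       pos = gn$start[i] - 1 + sample.int(glen, nf),
                       label = "planted_fixed", f = NA_real_)
      })
    }
    dplyr::bind_rows(bg, fx, gfx)
  })

  sites <- sites[order(sites$scaffold, sites$pos), ]
  dup <- duplicated(paste(sites$scaffold, sites$pos))
  sites <- sites[!dup, ]
  ns <- nrow(sites)
  n1 <- config$n_individuals[1]; n2 <- config$n_individuals[2]

  is_bn <- !is.na(sites$f)
  p1 <- p2 <- numeric(ns)
  p_anc <- runif(ns, 0.05, 0.95)
  shape <- (1 - sites$f) / sites$f
  p1[is_bn] <- rbeta(sum(is_bn), (p_anc * shape)[is_bn],
                     ((1 - p_anc) * shape)[is_bn])
  p2[is_bn] <- rbeta(sum(is_bn), (p_anc * shape)[is_bn],
                     ((1 - p_anc) * shape)[is_bn])
  flip <- runif(ns) < 0.5  # direction of fixed differences
  p1[!is_bn] <- ifelse(flip[!is_bn], 1, 0)
  p2[!is_bn] <- ifelse(flip[!is_bn], 0, 1)

  g1 <- matrix(rbinom(ns * n1, 2, p1), ns)
  g2 <- matrix(rbinom(ns * n2, 2, p2), ns)
  gt <- cbind(g1, g2)
  storage.mode(gt) <- "integer"
  if (config$missing_rate > 0) {
    gt[matrix(runif(length(gt)) < config$missing_rate, ns)] <- NA_integer_
  }
  dp <- matrix(rnbinom(length(gt), mu = config$depth_mean,
                       size = config$depth_size), ns)
  storage.mode(dp) <- "integer"

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))

  popmap <- tibble::tibble(
    sample = c(sprintf("%s_%02d", config$pops[1], seq_len(n1)),
               sprintf("%s_%02d", config$pops[2], seq_len(n2))),
    pop = rep(config$pops, c(n1, n2))
  )
  gm <- geno_matrix(
    tibble::tibble(scaffold = sites$scaffold, pos = as.integer(sites$pos),
                   ref = unname(ref), alt = unname(alt)),
    gt, popmap, dp = dp, scaffold_lengths = lens
  )

  truth_windows <- if (!is.null(pw) && nrow(pw) > 0) {
    dplyr::mutate(pw,
                  start = .data$window_index * wl + 1,
                  end = pmin((.data$window_index + 1) * wl, L),
                  f_elevated = f_elev[as.character(.data$target_fst)])
  } else {
    tibble::tibble(scaffold = character(), window_index = integer(),
                   target_fst = numeric(), fixed_density = numeric(),
                   start = numeric(), end = numeric(),
                   f_elevated = numeric())
  }
  structure(
    list(
      geno = gm,
      truth = list(
        planted_windows = truth_windows,
        site_labels = tibble::tibble(scaffold = sites$scaffold,
                                     pos = as.integer(sites$pos),
                                     label = sites$label),
        bn_f = f_bg, bn_f_elevated = f_elev
      ),
      genes = genes,
      config = config
    ),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> ", n_sites(x$geno), " sites on ",
      x$config$n_scaffolds, " scaffolds; ",
      nrow(x$truth$planted_windows), " planted windows, ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Write a gene annotation tibble as BED
#'
#' Converts 1-based inclusive coordinates back to BED's 0-based half-open
#' convention.
#'
#' @param genes tibble with `gene_id`, `scaffold`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  readr::write_tsv(
    tibble::tibble(chrom = genes$scaffold,
                   start = format(genes$start - 1, scientific = FALSE, trim = TRUE),
                   end = format(genes$end, scientific = FALSE, trim = TRUE),
                   name = genes$gene_id),
    path, col_names = FALSE
  )
  invisible(path)
}
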