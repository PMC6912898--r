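#' Genotype matrix container
#'
#' Holds biallelic SNP sites for a two-population cohort: a site table
#' (scaffold, 1-based position, ref/alt alleles), an integer matrix of
#' alt-allele dosages (0/1/2, `NA` = missing) with one column per sample,
#' an optional per-sample depth matrix, and the population map.
#'
#' Sites are kept strictly sorted by (scaffold, position) with no
#' duplicates; the sample order of `gt` (and `dp`) columns always matches
#' `popmap$sample`.
#'
#' @param sites tibble with columns `scaffold`, `pos`, `ref`, `alt`.
#' @param gt integer matrix, sites x samples, values in `c(0, 1, 2, NA)`.
#' @param popmap tibble with columns `sample`, `pop` (exactly two
#'   population labels, each with at least two samples).
#' @param dp optional integer matrix of per-sample read depths, same shape
#'   as `gt`.
#' @param scaffold_lengths optional named numeric vector of scaffold
#'   lengths in bp; used to truncate the final window of each scaffold.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, gt, popmap, dp = NULL, scaffold_lengths = NULL) {
  sites <- tibble::as_tibble(sites)
  stopifnot(
    all(c("scaffold", "pos", "ref", "alt") %in% names(sites)),
    is.matrix(gt), nrow(gt) == nrow(sites)
  )
  popmap <- validate_popmap(popmap)
  if (ncol(gt) != nrow(popmap)) {
    stop("gt must have one column per popmap sample", call. = FALSE)
  }
  colnames(gt) <- popmap$sample
  if (!is.null(dp)) {
    stopifnot(is.matrix(dp), all(dim(dp) == dim(gt)))
    colnames(dp) <- popmap$sample
  }
  ord <- order(sites$scaffold, sites$pos)
  if (is.unsorted(ord) || any(diff(ord) != 1)) {
    sites <- sites[ord, ]
    gt <- gt[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
  }
  dup <- duplicated(paste(sites$scaffold, sites$pos))
  if (any(dup)) {
    warning(sum(dup), " duplicate (scaffold, position) records dropped")
    sites <- sites[!dup, ]
    gt <- gt[!dup, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[!dup, , drop = FALSE]
  }
  structure(
    list(sites = sites, gt = gt, dp = dp, popmap = popmap,
         scaffold_lengths = scaffold_lengths),
    class = "geno_matrix"
  )
}

validate_popmap <- function(popmap) {
  popmap <- tibble::as_tibble(popmap)
  stopifnot(all(c("sample", "pop") %in% names(popmap)))
  if (anyDuplicated(popmap$sample)) {
    stop("duplicate sample ids in population map", call. = FALSE)
  }
  tab <- table(popmap$pop)
  if (length(tab) != 2) {
    stop("population map must contain exactly two population labels",
         call. = FALSE)
  }
  if (any(tab < 2)) {
    stop("each population needs at least two samples", call. = FALSE)
  }
  popmap
}

#' @export
print.geno_matrix <- function(x, ...) {
  tab <- table(x$popmap$pop)
  cat("<geno_matrix> ", nrow(x$sites), " sites x ", ncol(x$gt), " samples (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  cat("  scaffolds: ", length(unique(x$sites$scaffold)),
      if (!is.null(x$dp)) "; depths present" else "; no depths", "\n", sep = "")
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a [geno_matrix()].
#' @return An integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) ncol(gm$gt)

#' Subset a genotype matrix by site index
#' @param x a [geno_matrix()].
#' @param i integer or logical site index.
#' @param ... unused.
#' @export
`[.geno_matrix` <- function(x, i, ...) {
  geno_matrix(x$sites[i, , drop = FALSE], x$gt[i, , drop = FALSE],
              x$popmap, dp = if (!is.null(x$dp)) x$dp[i, , drop = FALSE],
              scaffold_lengths = x$scaffold_lengths)
}

# column indices of each population, in popmap label order
pop_columns <- function(gm) {
  labs <- unique(gm$popmap$pop)
  lapply(setNames(labs, labs), function(l) which(gm$popmap$pop == l))
}

#' Population labels of a genotype matrix
#' @param gm a [geno_matrix()].
#' @return Character vector of the two population labels.
#' @export
pop_labels <- function(gm) unique(gm$popmap$pop)
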