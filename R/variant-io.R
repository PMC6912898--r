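#' Read a sample-to-population map
#'
#' Two-column TSV (sample id, population label), no header. Exactly two
#' population labels are required, each with at least two samples.
#'
#' @param path file path.
#' @return tibble with columns `sample`, `pop`.
#' @export
read_popmap <- function(path) {
  pm <- readr::read_tsv(path, col_names = c("sample", "pop"),
                        col_types = "cc", progress = FALSE)
  validate_popmap(pm)
}

#' Read a scaffold exclusion list
#'
#' One scaffold identifier per line (e.g. scaffolds mapped to the Z
#' chromosome by synteny, excluded to avoid mixed-sex bias).
#'
#' @param path file path.
#' @return character vector of scaffold ids.
#' @export
read_exclusion_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x[nzchar(trimws(x))]
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (v4.x) with GT and optional DP FORMAT fields. Multi-allelic
#' and non-SNP records are skipped with a reported count; `./.` genotypes
#' become `NA`. Samples are reordered to the population-map order.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param popmap tibble with columns `sample`, `pop`; every sample must be
#'   present in the VCF.
#' @return A [geno_matrix()]. The number of skipped non-biallelic/non-SNP
#'   records is attached as attribute `skipped`.
#' @export
read_vcf <- function(path, popmap) {
  popmap <- validate_popmap(popmap)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  missing_samples <- setdiff(popmap$sample, colnames(v@gt)[-1])
  if (length(missing_samples)) {
    stop("popmap samples absent from VCF: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  keep <- !is.na(fix$ALT) & fix$REF %in% bases & fix$ALT %in% bases
  skipped <- sum(!keep)
  if (skipped > 0) {
    message(skipped, " non-biallelic or non-SNP records skipped")
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")[keep, popmap$sample, drop = FALSE]
  gt_chr <- gsub("|", "/", gt_chr, fixed = TRUE)
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr))
  gt[gt_chr == "0/0"] <- 0L
  gt[gt_chr %in% c("0/1", "1/0")] <- 1L
  gt[gt_chr == "1/1"] <- 2L
  dp <- NULL
  fmt <- v@gt[keep, 1]
  if (length(fmt) && any(grepl("DP", fmt, fixed = TRUE))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    )[keep, popmap$sample, drop = FALSE]
    storage.mode(dp) <- "integer"
  }
  sites <- tibble::tibble(
    scaffold = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  gm <- geno_matrix(sites, gt, popmap, dp = dp)
  attr(gm, "skipped") <- skipped
  gm
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 with GT (and DP when depths are present);
#' byte-identical output for identical inputs.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=divscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  has_dp <- !is.null(gm$dp)
  if (has_dp) {
    writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">', con)
  }
  if (!is.null(gm$scaffold_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(gm$scaffold_lengths),
                       as.integer(gm$scaffold_lengths)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$popmap$sample), collapse = "\t"), con)
  if (n_sites(gm) > 0) {
    gt_chr <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow(gm$gt))
    gt_chr[is.na(gm$gt)] <- "./."
    if (has_dp) {
      dp_chr <- ifelse(is.na(gm$dp), ".", as.character(gm$dp))
      gt_chr <- matrix(paste(gt_chr, dp_chr, sep = ":"), nrow(gt_chr))
    }
    body <- paste(
      gm$sites$scaffold, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
      ".", "PASS", ".", if (has_dp) "GT:DP" else "GT",
      apply(gt_chr, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' Site filter configuration
#'
#' Thresholds for the cohort-level SNP filters: minor allele frequency
#' (computed over pooled called alleles of both populations), per-site
#' missingness, and a depth screen that removes sites whose mean depth is
#' below `min_mean_depth` or more than `depth_sd_multiplier` standard
#' deviations above the genome-wide mean of site mean depths. Sites on
#' `excluded_scaffolds` (e.g. sex-linked) are always removed.
#'
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing_fraction maximum fraction of missing genotypes
#'   (default 0.20).
#' @param min_mean_depth minimum site mean depth (default 3).
#' @param depth_sd_multiplier SD multiplier for the high-depth screen
#'   (default 2).
#' @param excluded_scaffolds character vector of scaffold ids to drop.
#' @return A list of class `site_filter_config`.
#' @export
site_filter_config <- function(maf_min = 0.05, max_missing_fraction = 0.20,
                               min_mean_depth = 3, depth_sd_multiplier = 2,
                               excluded_scaffolds = character()) {
  stopifnot(maf_min >= 0, maf_min < 0.5,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(
    list(maf_min = maf_min, max_missing_fraction = max_missing_fraction,
         min_mean_depth = min_mean_depth,
         depth_sd_multiplier = depth_sd_multiplier,
         excluded_scaffolds = excluded_scaffolds),
    class = "site_filter_config"
  )
}

#' Apply cohort-level site filters
#'
#' Removes, in order: sites on excluded scaffolds; sites failing the depth
#' screens (genome-wide mean and SD of site mean depths are computed on the
#' input matrix, before any other filter); sites with pooled MAF below
#' `maf_min`; sites with missing fraction above `max_missing_fraction`.
#' Missing genotypes never enter allele counts.
#'
#' @param gm a [geno_matrix()].
#' @param cfg a [site_filter_config()].
#' @return List with elements `geno` (filtered [geno_matrix()]) and
#'   `report` (tibble with columns `rule`, `removed`).
#' @export
apply_site_filters <- function(gm, cfg = site_filter_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  n0 <- n_sites(gm)
  if (n0 == 0) stop("genotype matrix has no sites", call. = FALSE)
  keep <- rep(TRUE, n0)
  removed <- c(excluded_scaffold = 0L, low_depth = 0L, high_depth = 0L,
               low_maf = 0L, high_missing = 0L)

  drop_scaf <- gm$sites$scaffold %in% cfg$excluded_scaffolds
  removed["excluded_scaffold"] <- sum(drop_scaf & keep)
  keep <- keep & !drop_scaf

  if (!is.null(gm$dp)) {
    site_depth <- rowMeans(gm$dp, na.rm = TRUE)
    mu <- mean(site_depth, na.rm = TRUE)
    s <- sd(site_depth, na.rm = TRUE)
    low <- !is.na(site_depth) & site_depth < cfg$min_mean_depth
    high <- !is.na(site_depth) &
      site_depth > mu + cfg$depth_sd_multiplier * s
    removed["low_depth"] <- sum(low & keep)
    keep <- keep & !low
    removed["high_depth"] <- sum(high & keep)
    keep <- keep & !high
  } else {
    warning("no depths present; depth screen skipped")
  }

  called <- 2L * rowSums(!is.na(gm$gt))
  alt <- rowSums(gm$gt, na.rm = TRUE)
  af <- ifelse(called > 0, alt / called, NA_real_)
  maf <- pmin(af, 1 - af)
  low_maf <- is.na(maf) | maf < cfg$maf_min
  removed["low_maf"] <- sum(low_maf & keep)
  keep <- keep & !low_maf

  miss <- rowMeans(is.na(gm$gt))
  high_miss <- miss > cfg$max_missing_fraction
  removed["high_missing"] <- sum(high_miss & keep)
  keep <- keep & !high_miss

  if (!any(keep)) warning("all sites removed by filters")
  list(
    geno = gm[keep],
    report = tibble::tibble(rule = names(removed),
                            removed = unname(removed))
  )
}

#' Tile scaffolds into nonoverlapping windows
#'
#' Windows tile each scaffold from position 1 as `[1, L]`, `[L+1, 2L]`, ...
#' (1-based inclusive). A site at position p falls in window index
#' `floor((p - 1) / L)`. Windows with no sites are retained with
#' `n_snps = 0`. When scaffold lengths are known the last window is
#' truncated to the scaffold end.
#'
#' @param gm a [geno_matrix()].
#' @param length window length in bp (default 100,000).
#' @return tibble with columns `scaffold`, `window_index` (0-based),
#'   `start`, `end`, `n_snps`.
#' @export
make_windows <- function(gm, length = 1e5) {
  stopifnot(length >= 1)
  widx <- window_index(gm$sites$pos, length)
  per_scaf <- dplyr::group_by(
    tibble::tibble(scaffold = gm$sites$scaffold, widx = widx),
    .data$scaffold, .data$widx
  )
  counts <- dplyr::summarise(per_scaf, n_snps = dplyr::n(), .groups = "drop")
  scafs <- unique(gm$sites$scaffold)
  lens <- gm$scaffold_lengths
  grid <- purrr::map_dfr(scafs, function(s) {
    maxpos <- if (!is.null(lens) && s %in% names(lens)) {
      lens[[s]]
    } else {
      max(gm$sites$pos[gm$sites$scaffold == s])
    }
    nwin <- ceiling(maxpos / length)
    tibble::tibble(
      scaffold = s,
      window_index = seq_len(nwin) - 1L,
      start = (seq_len(nwin) - 1L) * length + 1,
      end = seq_len(nwin) * length
    )
  })
  # truncate the final window only when a true scaffold length is known
  if (!is.null(lens)) {
    known <- grid$scaffold %in% names(lens)
    grid$end[known] <- pmin(grid$end[known], lens[grid$scaffold[known]])
  }
  dplyr::left_join(grid, counts,
                   by = c("scaffold", "window_index" = "widx")) |>
    dplyr::mutate(n_snps = tidyr::replace_na(.data$n_snps, 0L))
}

# 0-based window index of a 1-based position
window_index <- function(pos, length) as.integer((pos - 1) %/% length)
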