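#' Scan configuration
#'
#' Settings for dual-percentile outlier detection: windows with fewer than
#' `min_snps_per_window` SNPs and scaffolds contributing fewer than
#' `min_windows_per_scaffold` retained windows are discarded before the
#' empirical percentile thresholds are computed; windows strictly above the
#' `percentile_q` quantile of both the FST and the fixed-density (df)
#' distributions form the elevated intersection.
#'
#' @param percentile_q empirical quantile for outlier calls (default 0.99).
#' @param min_snps_per_window minimum SNPs per retained window (default 10).
#' @param min_windows_per_scaffold minimum retained windows per scaffold
#'   (default 2).
#' @param gene_flank distance in bp for reporting genes near elevated
#'   regions (default 50,000).
#' @param candidate_flank flank in bp added around candidate genes
#'   (default 20,000).
#' @param ci_level level of the genome-wide FST confidence interval
#'   (default 0.95).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(percentile_q = 0.99, min_snps_per_window = 10,
                        min_windows_per_scaffold = 2, gene_flank = 5e4,
                        candidate_flank = 2e4, ci_level = 0.95) {
  stopifnot(percentile_q > 0, percentile_q < 1,
            gene_flank >= 0, candidate_flank >= 0)
  structure(
    list(percentile_q = percentile_q,
         min_snps_per_window = min_snps_per_window,
         min_windows_per_scaffold = min_windows_per_scaffold,
         gene_flank = gene_flank, candidate_flank = candidate_flank,
         ci_level = ci_level),
    class = "scan_config"
  )
}

#' Empirical percentile threshold
#'
#' Empirical quantile with linear interpolation between order statistics
#' (type 7); values strictly greater than the threshold count as "above".
#'
#' @param values numeric vector.
#' @param q quantile in (0, 1).
#' @return Numeric scalar.
#' @export
percentile_threshold <- function(values, q) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least two finite values", call. = FALSE)
  unname(quantile(values, q, type = 7))
}

#' Flag elevated windows by the dual-percentile criterion
#'
#' Applies the retention filters of the [scan_config()], computes the
#' empirical FST and df thresholds on the retained windows, and returns
#' the single-criterion flag sets, their intersection, and the contiguous
#' intersected windows merged into regions.
#'
#' @param stats window table from [compute_window_stats()].
#' @param cfg a [scan_config()].
#' @return Object of class `elevated_windows`: a list with `retained`,
#'   `thresholds`, `fst_windows`, `df_windows`, `intersection`, `regions`,
#'   and drop counts. `tidy()` returns the intersection windows,
#'   `glance()` a one-row summary.
#' @export
flag_elevated_windows <- function(stats, cfg = scan_config()) {
  stopifnot(nrow(stats) > 0)
  retained <- dplyr::filter(stats, .data$n_snps >= cfg$min_snps_per_window)
  scaf_ok <- retained |>
    dplyr::count(.data$scaffold) |>
    dplyr::filter(.data$n >= cfg$min_windows_per_scaffold)
  retained <- dplyr::semi_join(retained, scaf_ok, by = "scaffold")
  if (nrow(retained) < 100) {
    warning("fewer than 100 retained windows; percentile thresholds unstable")
  }
  thr_fst <- percentile_threshold(retained$fst, cfg$percentile_q)
  thr_df <- percentile_threshold(retained$df, cfg$percentile_q)
  fst_windows <- dplyr::filter(retained, .data$fst > thr_fst)
  df_windows <- dplyr::filter(retained, .data$df > thr_df)
  intersection <- dplyr::inner_join(
    fst_windows,
    dplyr::select(df_windows, "scaffold", "window_index"),
    by = c("scaffold", "window_index")
  )
  regions <- merge_windows(intersection)
  structure(
    list(retained = retained, thresholds = c(fst = thr_fst, df = thr_df),
         fst_windows = fst_windows, df_windows = df_windows,
         intersection = intersection, regions = regions,
         n_dropped = nrow(stats) - nrow(retained), config = cfg),
    class = "elevated_windows"
  )
}

# merge runs of consecutive window indices on a scaffold into regions
merge_windows <- function(windows) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(region_id = integer(), scaffold = character(),
                          start = numeric(), end = numeric(),
                          n_windows = integer()))
  }
  windows |>
    dplyr::arrange(.data$scaffold, .data$window_index) |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$window_index) != 1L))) |>
    dplyr::group_by(.data$scaffold, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_windows = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$scaffold, .data$start) |>
    dplyr::mutate(region_id = dplyr::row_number()) |>
    dplyr::select("region_id", "scaffold", "start", "end", "n_windows")
}

#' @export
print.elevated_windows <- function(x, ...) {
  cat("<elevated_windows>\n")
  cat("  retained windows:", nrow(x$retained),
      "(dropped:", x$n_dropped, ")\n")
  cat(sprintf("  thresholds: FST > %.4f, df > %.6f\n",
              x$thresholds["fst"], x$thresholds["df"]))
  cat("  flagged:", nrow(x$fst_windows), "by FST,", nrow(x$df_windows),
      "by df,", nrow(x$intersection), "in the intersection (",
      nrow(x$regions), "regions )\n")
  invisible(x)
}

#' @export
tidy.elevated_windows <- function(x, ...) x$intersection

#' @export
glance.elevated_windows <- function(x, ...) {
  tibble::tibble(
    n_retained = nrow(x$retained),
    n_fst_windows = nrow(x$fst_windows),
    n_fst_scaffolds = dplyr::n_distinct(x$fst_windows$scaffold),
    n_df_windows = nrow(x$df_windows),
    n_df_scaffolds = dplyr::n_distinct(x$df_windows$scaffold),
    n_elevated = nrow(x$intersection),
    n_elevated_scaffolds = dplyr::n_distinct(x$intersection$scaffold),
    n_regions = nrow(x$regions),
    fst_threshold = unname(x$thresholds["fst"]),
    df_threshold = unname(x$thresholds["df"])
  )
}

#' Read gene annotations (BED or GFF3)
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; GFF3 is read with `ape::read.gff()` and filtered to
#' `type == "gene"` records. The gene id comes from the BED name column or
#' the GFF ID/Name attribute.
#'
#' @param path annotation file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gff"`.
#' @return tibble with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotations <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
      "gff"
    } else {
      "bed"
    }
  }
  if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    tibble::tibble(
      gene_id = if (ncol(bed) >= 4) bed[[4]] else paste0("gene_", seq_len(nrow(bed))),
      scaffold = bed[[1]],
      start = as.numeric(bed[[2]]) + 1,  # 0-based half-open -> 1-based
      end = as.numeric(bed[[3]]),
      strand = if (ncol(bed) >= 6) bed[[6]] else NA_character_
    )
  } else {
    g <- ape::read.gff(path)
    g <- g[g$type == "gene", , drop = FALSE]
    id <- stringr::str_match(g$attributes, "(?:ID|Name)=([^;]+)")[, 2]
    tibble::tibble(
      gene_id = ifelse(is.na(id), paste0("gene_", seq_len(nrow(g))), id),
      scaffold = as.character(g$seqid),
      start = as.numeric(g$start), end = as.numeric(g$end),
      strand = as.character(g$strand)
    )
  }
}

#' Genes near elevated regions
#'
#' A gene is reported for a region when the gene interval expanded by
#' `flank` bp on both sides intersects the region interval on the same
#' scaffold (inclusive boundaries).
#'
#' @param regions tibble with `region_id`, `scaffold`, `start`, `end`
#'   (e.g. `$regions` of [flag_elevated_windows()]).
#' @param annotations gene tibble from [read_gene_annotations()].
#' @param flank distance in bp (default 50,000).
#' @return tibble pairing regions with nearby genes.
#' @export
genes_near <- function(regions, annotations, flank = 5e4) {
  if (nrow(regions) == 0 || nrow(annotations) == 0) {
    return(tibble::tibble(region_id = integer(), scaffold = character(),
                          gene_id = character(), gene_start = numeric(),
                          gene_end = numeric(), distance = numeric()))
  }
  dplyr::inner_join(regions, annotations, by = "scaffold",
                    suffix = c("", ".gene"), relationship = "many-to-many") |>
    dplyr::filter(.data$start.gene - flank <= .data$end,
                  .data$end.gene + flank >= .data$start) |>
    dplyr::transmute(
      .data$region_id, .data$scaffold, .data$gene_id,
      gene_start = .data$start.gene, gene_end = .data$end.gene,
      distance = pmax(0, pmax(.data$start - .data$end.gene,
                              .data$gene_start - .data$end))
    ) |>
    dplyr::arrange(.data$region_id, .data$gene_start)
}

#' Genome-wide FST confidence interval
#'
#' Normal-approximation interval mean +/- z * SD over the window FST
#' distribution.
#'
#' @param fst window FST values.
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
genomewide_ci <- function(fst, level = 0.95) {
  fst <- fst[is.finite(fst)]
  stopifnot(length(fst) >= 2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(fst)
  s <- sd(fst)
  c(lower = m - z * s, upper = m + z * s)
}

#' Divergence statistics for candidate gene regions
#'
#' For each gene, the region is the gene plus `flank` bp on each side
#' (clipped at position 1). Reports the number of variable sites, the
#' ratio-of-sums mean FST, fixed-SNP count, the percentage of variable
#' sites that are fixed, and whether the region mean FST exceeds the upper
#' bound of the genome-wide confidence interval.
#'
#' @param gm a filtered [geno_matrix()].
#' @param genes tibble from [read_gene_annotations()].
#' @param flank flank in bp (default 20,000).
#' @param ci genome-wide interval from [genomewide_ci()].
#' @return tibble, one row per gene.
#' @export
candidate_gene_stats <- function(gm, genes, flank = 2e4, ci) {
  sas <- site_allele_stats(gm)
  sas$h1 <- ifelse(sas$nind1 > 0, sas$het1 / sas$nind1, NA_real_)
  sas$h2 <- ifelse(sas$nind2 > 0, sas$het2 / sas$nind2, NA_real_)
  comp <- wc_components(sas$nind1, sas$p1, sas$h1, sas$nind2, sas$p2, sas$h2)
  sas <- dplyr::bind_cols(sas, comp)
  sas$fixed <- classify_fixed(sas$ac1, sas$na1, sas$ac2, sas$na2)
  purrr::pmap_dfr(
    genes[c("gene_id", "scaffold", "start", "end")],
    function(gene_id, scaffold, start, end) {
      lo <- max(1, start - flank)
      hi <- end + flank
      sub <- sas[sas$scaffold == scaffold & sas$pos >= lo & sas$pos <= hi, ]
      if (nrow(sub) == 0) {
        return(tibble::tibble(
          gene_id = gene_id, scaffold = scaffold,
          region_start = lo, region_end = hi, n_variable_sites = 0L,
          mean_fst = NA_real_, n_fixed = NA_integer_, pct_fixed = NA_real_,
          exceeds_ci = FALSE
        ))
      }
      nf <- sum(sub$fixed, na.rm = TRUE)
      fst <- window_fst(sub$a, sub$b, sub$c)
      tibble::tibble(
        gene_id = gene_id, scaffold = scaffold,
        region_start = lo, region_end = hi,
        n_variable_sites = nrow(sub),
        mean_fst = fst, n_fixed = as.integer(nf),
        pct_fixed = 100 * nf / nrow(sub),
        exceeds_ci = !is.na(fst) && fst > ci[["upper"]]
      )
    }
  )
}

#' Inside/outside partition summary
#'
#' Mean and SD of each window statistic inside the elevated window set
#' versus outside it, over the retained windows.
#'
#' @param stats window table from [compute_window_stats()] (or the
#'   `retained` table of an `elevated_windows` object).
#' @param elevated an `elevated_windows` object, or a tibble of windows
#'   with `scaffold` and `window_index` columns.
#' @return tibble with one row per statistic.
#' @export
summarize_partition <- function(stats, elevated) {
  if (inherits(elevated, "elevated_windows")) {
    stats <- elevated$retained
    elevated <- elevated$intersection
  }
  key <- paste(stats$scaffold, stats$window_index)
  inside <- key %in% paste(elevated$scaffold, elevated$window_index)
  vars <- c("fst", "dxy_per_snp", "df", "pi_pop1", "pi_pop2",
            "tajd_pop1", "tajd_pop2")
  purrr::map_dfr(vars, function(v) {
    x_in <- stats[[v]][inside]
    x_out <- stats[[v]][!inside]
    tibble::tibble(
      statistic = v,
      inside_mean = if (length(x_in)) mean(x_in, na.rm = TRUE) else NA_real_,
      inside_sd = if (length(x_in) > 1) sd(x_in, na.rm = TRUE) else NA_real_,
      outside_mean = if (length(x_out)) mean(x_out, na.rm = TRUE) else NA_real_,
      outside_sd = if (length(x_out) > 1) sd(x_out, na.rm = TRUE) else NA_real_,
      n_inside = length(x_in), n_outside = length(x_out),
      n_na = sum(is.na(stats[[v]]))
    )
  })
}
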