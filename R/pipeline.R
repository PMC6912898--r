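as_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

write_tsv_na <- function(x, path) {
  readr::write_tsv(x, path, na = ".")
  path
}

manifest_skeleton <- function(config, seed) {
  list(
    package = "divscan",
    version = as.character(utils::packageVersion("divscan")),
    seed = seed,
    config_hash = rlang::hash(config),
    created = "run manifest"
  )
}

#' Run the full divergence scan
#'
#' Orchestrates: read population map and VCF, apply site filters, compute
#' window statistics, flag elevated windows by the dual-percentile
#' criterion, report genes near elevated regions, score candidate-gene
#' regions, and summarize the inside/outside partition. All outputs are
#' TSV ('.' for NA) plus a JSON run manifest with per-stage counts; a
#' rerun with the same config and seed is byte-identical.
#'
#' @param config list (or YAML file path) with elements `vcf`, `popmap`,
#'   `output_dir`, and optionally `annotations`, `exclusion_list`,
#'   `window_length`, `seed`, `filters` (arguments to
#'   [site_filter_config()]) and `scan` (arguments to [scan_config()]).
#' @return Invisibly, a list with the computed tables and output paths.
#' @export
run_scan <- function(config) {
  config <- as_run_config(config)
  for (f in c("vcf", "popmap", "output_dir")) {
    if (is.null(config[[f]])) stop("run_scan config needs '", f, "'", call. = FALSE)
  }
  for (f in c("vcf", "popmap", "annotations", "exclusion_list")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("file not found: ", config[[f]], call. = FALSE)
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)

  popmap <- read_popmap(config$popmap)
  gm <- read_vcf(config$vcf, popmap)
  excl <- if (!is.null(config$exclusion_list)) {
    read_exclusion_list(config$exclusion_list)
  } else {
    character()
  }
  fcfg <- do.call(site_filter_config,
                  modifyList(config$filters %||% list(),
                             list(excluded_scaffolds = excl)))
  filt <- apply_site_filters(gm, fcfg)
  wl <- config$window_length %||% 1e5
  stats <- compute_window_stats(filt$geno, wl)
  scfg <- do.call(scan_config, config$scan %||% list())
  elev <- flag_elevated_windows(stats, scfg)
  ci <- genomewide_ci(elev$retained$fst, scfg$ci_level)
  partition <- summarize_partition(stats, elev)

  genes <- near <- candidates <- NULL
  if (!is.null(config$annotations)) {
    genes <- read_gene_annotations(config$annotations)
    near <- genes_near(elev$regions, genes, scfg$gene_flank)
    candidates <- candidate_gene_stats(filt$geno, genes,
                                       scfg$candidate_flank, ci)
  }

  out <- file.path(config$output_dir, c(
    windows = "window_stats.tsv", elevated = "elevated_windows.tsv",
    regions = "regions.bed", filter = "filter_report.tsv",
    partition = "partition_summary.tsv", genes = "genes_near_regions.tsv",
    candidates = "candidate_genes.tsv", manifest = "manifest.json"
  ))
  names(out) <- c("windows", "elevated", "regions", "filter", "partition",
                  "genes", "candidates", "manifest")
  write_tsv_na(stats, out[["windows"]])
  write_tsv_na(elev$intersection, out[["elevated"]])
  readr::write_tsv(
    tibble::tibble(chrom = elev$regions$scaffold,
                   start = format(elev$regions$start - 1, scientific = FALSE,
                                  trim = TRUE),
                   end = format(elev$regions$end, scientific = FALSE,
                                trim = TRUE),
                   name = paste0("region_", elev$regions$region_id)),
    out[["regions"]], col_names = FALSE
  )
  write_tsv_na(filt$report, out[["filter"]])
  write_tsv_na(partition, out[["partition"]])
  if (!is.null(near)) write_tsv_na(near, out[["genes"]])
  if (!is.null(candidates)) write_tsv_na(candidates, out[["candidates"]])

  manifest <- c(manifest_skeleton(config, seed), list(
    counts = list(
      snps_input = n_sites(gm) + (attr(gm, "skipped") %||% 0L),
      records_skipped = attr(gm, "skipped") %||% 0L,
      snps_after_read = n_sites(gm),
      removed_by_rule = as.list(setNames(filt$report$removed,
                                         filt$report$rule)),
      snps_final = n_sites(filt$geno),
      windows_nonempty = nrow(stats),
      windows_retained = nrow(elev$retained),
      flagged_fst = nrow(elev$fst_windows),
      flagged_df = nrow(elev$df_windows),
      elevated_windows = nrow(elev$intersection),
      elevated_regions = nrow(elev$regions)
    ),
    fst_ci = as.list(ci)
  ))
  jsonlite::write_json(manifest, out[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(geno = filt$geno, stats = stats, elevated = elev, ci = ci,
                 partition = partition, genes = genes, genes_near = near,
                 candidates = candidates, paths = out))
}

#' Run the demographic ABC analysis
#'
#' Orchestrates: obtain observed summary statistics (from a VCF plus SNP
#' selection, or from a supplied simulated dataset), build per-scenario
#' reference tables, perform model choice, estimate parameters under the
#' winning scenario, and evaluate the posterior predictive error rate.
#' `scale` multiplies the simulation sizes for desk-scale runs.
#'
#' @param config list (or YAML path) with optional elements `vcf` +
#'   `popmap` (observed data route) or `observed_scenario` +
#'   `observed_params` (synthetic route), plus `n_sims` (default 1e6),
#'   `n_loci` (2000), `n_pseudo` (1000), `n_closest` (500),
#'   `accept_fraction` (0.01), `seed`, `output_dir`.
#' @param scale multiplier applied to `n_sims` and `n_pseudo`
#'   (default 1).
#' @return Invisibly, a list with tables, model choice, posterior and
#'   error rate.
#' @export
run_abc <- function(config, scale = 1) {
  config <- as_run_config(config)
  if (is.null(config$output_dir)) stop("run_abc config needs 'output_dir'",
                                       call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  n_sims <- max(10, round((config$n_sims %||% 1e6) * scale))
  n_loci <- config$n_loci %||% 2000
  n_pseudo <- max(10, round((config$n_pseudo %||% 1000) * scale))
  n_closest <- config$n_closest %||% 500
  accept <- config$accept_fraction %||% 0.01

  if (!is.null(config$vcf)) {
    popmap <- read_popmap(config$popmap)
    gm <- read_vcf(config$vcf, popmap)
    sets <- select_abc_snps(gm, n_per_set = n_loci,
                            n_sets = config$n_sets %||% 3, seed = seed)
    observed <- compute_summary_stats(gm[sets[[1]]])
  } else {
    sc <- config$observed_scenario %||% "admixture"
    pars <- config$observed_params %||%
      as.list(sample_prior(sc, 1))
    observed <- compute_summary_stats(
      simulate_dataset(sc, pars, n_loci = n_loci)
    )
  }

  tables <- lapply(scenario_ids(), function(s) {
    build_reference_table(s, n_sims = n_sims, n_loci = n_loci,
                          seed = seed + scenario_code(s))
  })
  choice <- abc_model_choice(observed, tables, accept)
  best <- choice$posterior$scenario[which.max(choice$posterior$posterior)]
  posterior <- abc_parameter_estimate(
    observed, tables[[scenario_code(best)]], accept
  )
  err <- posterior_error_rate(tables, observed, n_pseudo = n_pseudo,
                              n_closest = n_closest,
                              accept_fraction = accept, seed = seed + 7)

  out <- file.path(config$output_dir, c(
    observed = "observed_stats.tsv", choice = "model_choice.tsv",
    posterior = "parameter_posterior.tsv", error = "error_rate.json",
    manifest = "manifest.json"
  ))
  names(out) <- c("observed", "choice", "posterior", "error", "manifest")
  write_tsv_na(tibble::tibble(statistic = names(observed),
                              value = as.numeric(observed)),
               out[["observed"]])
  write_tsv_na(choice$posterior, out[["choice"]])
  write_tsv_na(posterior$estimates, out[["posterior"]])
  jsonlite::write_json(list(error_rate = err$error_rate,
                            n_pseudo = n_pseudo, n_closest = n_closest),
                       out[["error"]], auto_unbox = TRUE, digits = NA)
  manifest <- c(manifest_skeleton(config, seed), list(
    n_sims_per_scenario = n_sims, n_loci = n_loci, n_pseudo = n_pseudo,
    chosen_scenario = best,
    interval_type = posterior$interval_type
  ))
  jsonlite::write_json(manifest, out[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(observed = observed, tables = tables, choice = choice,
                 posterior = posterior, error = err, paths = out))
}
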