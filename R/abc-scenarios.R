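#' Scaling constants for time and mutation rate
#'
#' The passerine substitution rate (3.3e-3 substitutions/site/Myr) and a
#' generation time of 2.3 years, from which the per-generation mutation
#' rate is derived.
#'
#' @param substitution_rate_per_myr substitutions per site per million
#'   years (default 3.3e-3).
#' @param generation_time_years generation time in years (default 2.3).
#' @return A named list of class `scaling_constants`.
#' @export
scaling_constants <- function(substitution_rate_per_myr = 3.3e-3,
                              generation_time_years = 2.3) {
  stopifnot(substitution_rate_per_myr >= 0, generation_time_years > 0)
  structure(
    list(substitution_rate_per_myr = substitution_rate_per_myr,
         generation_time_years = generation_time_years),
    class = "scaling_constants"
  )
}

#' Per-generation mutation rate
#'
#' substitution rate per Myr x 1e-6 x generation time in years; the
#' default constants give 7.59e-9 substitutions/site/generation.
#'
#' @param constants a [scaling_constants()].
#' @return Numeric scalar (substitutions/site/generation).
#' @export
mutation_rate_per_generation <- function(constants = scaling_constants()) {
  constants$substitution_rate_per_myr * 1e-6 * constants$generation_time_years
}

#' Convert years to generations
#'
#' @param t_years time in years.
#' @param generation_time generation time in years (default 2.3).
#' @return t_years / generation_time, continuous (no rounding).
#' @export
years_to_generations <- function(t_years, generation_time = 2.3) {
  stopifnot(generation_time > 0)
  t_years / generation_time
}

#' Demographic scenario ids
#' @return Character vector of the three scenario names.
#' @export
scenario_ids <- function() c("simple_split", "ne_change", "admixture")

scenario_code <- function(scenario) {
  match.arg(scenario, scenario_ids()) |>
    switch(simple_split = 1L, ne_change = 2L, admixture = 3L)
}

#' Uniform prior bounds for the demographic scenarios
#'
#' Times in years before present, effective sizes in diploid individuals,
#' admixture proportion r dimensionless. The bounds are the study priors:
#' T1 (species split) 400,000-1,500,000; T2 (split of the sampled
#' Nelson's lineage from the ancestral Nelson's population)
#' 100,000-500,000 with T2 < T1; N_SALS 20,000-150,000; N_NESP
#' 1,000-50,000; N_AncestralNESP 1,000-150,000; N_Ancestral
#' 100,000-500,000; size-change scenario: T_rise 50,000-200,000, T_fall
#' 10,000-50,000, N_smallNESP 1,000-50,000, N_largeNESP 50,000-100,000;
#' admixture scenario: T_admix 0-100,000 (with T_admix < T2), r
#' 0.001-0.999.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
demographic_priors <- function() {
  list(
    T1 = c(4e5, 1.5e6), T2 = c(1e5, 5e5),
    N_SALS = c(2e4, 1.5e5), N_NESP = c(1e3, 5e4),
    N_AncestralNESP = c(1e3, 1.5e5), N_Ancestral = c(1e5, 5e5),
    T_rise = c(5e4, 2e5), T_fall = c(1e4, 5e4),
    N_smallNESP = c(1e3, 5e4), N_largeNESP = c(5e4, 1e5),
    T_admix = c(0, 1e5), r = c(0.001, 0.999)
  )
}

scenario_param_names <- function(scenario) {
  base <- c("T1", "T2", "N_Ancestral", "N_AncestralNESP", "N_SALS", "N_NESP")
  switch(match.arg(scenario, scenario_ids()),
    simple_split = base,
    ne_change = c(base, "T_rise", "T_fall", "N_smallNESP", "N_largeNESP"),
    admixture = c(base, "T_admix", "r")
  )
}

#' Draw scenario parameters from the priors
#'
#' Independent uniform draws; vectors violating the scenario's ordering
#' constraints (T2 < T1; for the size-change scenario T_fall < T_rise <
#' T2; for the admixture scenario T_admix < T2) are rejected and redrawn
#' as a whole.
#'
#' @param scenario one of [scenario_ids()].
#' @param n number of draws.
#' @param priors bounds from [demographic_priors()].
#' @param max_tries bound on rejection rounds.
#' @return tibble of parameter vectors, `n` rows.
#' @export
sample_prior <- function(scenario, n = 1, priors = demographic_priors(),
                         max_tries = 1000) {
  scenario <- match.arg(scenario, scenario_ids())
  pars <- scenario_param_names(scenario)
  draw <- function(m) {
    out <- purrr::map(priors[pars], ~runif(m, .x[1], .x[2]))
    tibble::as_tibble(out)
  }
  ok_rows <- function(d) {
    ok <- d$T2 < d$T1
    if (scenario == "ne_change") ok <- ok & d$T_fall < d$T_rise & d$T_rise < d$T2
    if (scenario == "admixture") ok <- ok & d$T_admix < d$T2
    ok
  }
  out <- draw(n)
  bad <- !ok_rows(out)
  tries <- 0
  while (any(bad)) {
    tries <- tries + 1
    if (tries > max_tries) stop("prior constraints could not be satisfied")
    redraw <- draw(sum(bad))
    out[bad, ] <- redraw
    bad[bad] <- !ok_rows(redraw)
  }
  out
}

# build the 12-slot parameter vector (generations / sizes) for the C core
scenario_par_vector <- function(scenario, params, generation_time = 2.3) {
  p <- as.list(params)
  g <- function(nm, default = NA_real_) {
    if (!is.null(p[[nm]]) && !is.na(p[[nm]])) as.numeric(p[[nm]]) else default
  }
  c(
    years_to_generations(g("T1"), generation_time),
    years_to_generations(g("T2"), generation_time),
    g("N_Ancestral"), g("N_AncestralNESP"), g("N_SALS"), g("N_NESP"),
    years_to_generations(g("T_rise", 0), generation_time),
    years_to_generations(g("T_fall", 0), generation_time),
    g("N_smallNESP", 1), g("N_largeNESP", 1),
    years_to_generations(g("T_admix", 0), generation_time),
    g("r", 0.5)
  )
}

#' Simulate unlinked SNP loci under a demographic scenario
#'
#' Runs a structured Kingman coalescent per locus (backward in time,
#' pairwise coalescence rate 1/(2N) per generation within a population),
#' executing population merges at the scenario's event times, and for the
#' admixture scenario sending each sampled-Nelson's lineage at T_admix to
#' the parental Nelson's population with probability r, else to the
#' saltmarsh population. Exactly one mutation is placed per locus on a
#' branch chosen proportional to branch length, so every locus is variable
#' in the pooled sample. Lineages are paired into diploid genotypes.
#'
#' @param scenario one of [scenario_ids()].
#' @param params one-row tibble or named vector of parameters in years /
#'   diploid sizes (see [demographic_priors()]).
#' @param n_loci number of unlinked loci (default 2000).
#' @param sample_sizes diploid sample counts `c(SALS, NESP)`
#'   (default `c(10, 10)`).
#' @param generation_time years per generation (default 2.3).
#' @return tibble of class `abc_loci` with per-locus alt-allele and
#'   heterozygote counts for each population; sample sizes are kept in
#'   attributes `n1`, `n2`.
#' @export
simulate_dataset <- function(scenario, params, n_loci = 2000,
                             sample_sizes = c(10, 10),
                             generation_time = 2.3) {
  scenario <- match.arg(scenario, scenario_ids())
  par <- scenario_par_vector(scenario, params, generation_time)
  m <- .sim_scenario_counts(scenario_code(scenario), par, n_loci,
                            sample_sizes[1], sample_sizes[2])
  out <- tibble::as_tibble(m)
  out$locus <- seq_len(nrow(out))
  out <- out[c("locus", "alt1", "het1", "alt2", "het2")]
  attr(out, "n1") <- sample_sizes[1]
  attr(out, "n2") <- sample_sizes[2]
  class(out) <- c("abc_loci", class(out))
  out
}

#' Convert simulated loci to a genotype matrix
#'
#' Places each unlinked locus at 1 kb spacing on a synthetic scaffold and
#' expands the per-population counts into per-individual dosages
#' (heterozygotes assigned to the first individuals of each population,
#' which is distributionally irrelevant for exchangeable samples).
#'
#' @param loci an `abc_loci` tibble from [simulate_dataset()].
#' @param pops two population labels.
#' @return A [geno_matrix()].
#' @export
loci_to_geno <- function(loci, pops = c("SALS", "NESP")) {
  n1 <- attr(loci, "n1"); n2 <- attr(loci, "n2")
  expand <- function(alt, het, n) {
    n_hom <- (alt - het) / 2
    t(mapply(function(a, h, hm) {
      c(rep(2L, hm), rep(1L, h), rep(0L, n - hm - h))
    }, alt, het, n_hom))
  }
  gt <- cbind(expand(loci$alt1, loci$het1, n1),
              expand(loci$alt2, loci$het2, n2))
  popmap <- tibble::tibble(
    sample = c(sprintf("%s_%02d", pops[1], seq_len(n1)),
               sprintf("%s_%02d", pops[2], seq_len(n2))),
    pop = rep(pops, c(n1, n2))
  )
  sites <- tibble::tibble(scaffold = "abc_loci",
                          pos = loci$locus * 1000L,
                          ref = "A", alt = "T")
  geno_matrix(sites, gt, popmap)
}
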