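#' Configuration for an end-to-end demonstration run
#'
#' Collects the per-stage parameters of [run_pipeline()] with desk-scale
#' defaults. Every stochastic stage receives its own seed derived from the
#' single `master_seed`, so one number reproduces the whole run.
#'
#' @param master_seed Integer master seed.
#' @param fdr Nominal FDR for scaffold assignment.
#' @param min_poolX Candidate threshold on pool-X reads.
#' @param sort,codon,rad,mk,sim Named lists of overrides passed to
#'   [sort_spec()], [codon_sim_spec()], [pop_sim_spec()],
#'   [gen_mk_dataset()] (`counts` tibble) and [demography_scenario()].
#' @param n_boot,n_perm Bootstrap and permutation replicates for the
#'   divergence stage.
#' @return A `spx_config` list.
#' @export
pipeline_config <- function(master_seed = 1L, fdr = 0.025, min_poolX = 100,
                            sort = list(n_scaffolds = 1500),
                            codon = list(n_genes_per_class = 150,
                                         codons_per_gene = 80),
                            rad = list(populations = c("P1", "P2"),
                                       n_loci = c(X = 60L, A = 240L)),
                            mk = NULL, sim = list(n_loci = 2000L,
                                                  n_cycles = 8L,
                                                  burn_in = 3L),
                            n_boot = 200, n_perm = 200) {
  if (fdr <= 0 || fdr >= 0.5) abort("fdr must lie in (0, 0.5)")
  if (n_boot < 2 || n_perm < 2) abort("n_boot and n_perm must be at least 2")
  mk <- mk %||% tibble::tibble(class = c("X", "A"),
                               pn = c(140L, 1198L), ps = c(150L, 1433L),
                               dn = c(337L, 7370L), ds = c(563L, 15599L))
  structure(list(master_seed = as.integer(master_seed), fdr = fdr,
                 min_poolX = min_poolX, sort = sort, codon = codon,
                 rad = rad, mk = mk, sim = sim, n_boot = n_boot,
                 n_perm = n_perm),
            class = "spx_config")
}

#' Run the full synthetic faster-X pipeline
#'
#' Executes, in dependency order: sorted-pool simulation and X-scaffold
#' assignment; codon-alignment simulation, substitution counting,
#' bootstrap CIs and the X-vs-autosome randomization tests; RAD
#' simulation, diversity, piX/piA pairing and the population tests; the
#' McDonald-Kreitman round trip; the closed-form sex-ratio/mutation-bias
#' theory; and a founder-event simulation contrasted with a constant-size
#' run. Stage seeds are fanned out deterministically from the master seed.
#'
#' @param config A [pipeline_config()].
#' @return A list with one element per stage plus `manifest` (tibble of
#'   stage names, seeds and timings; the config hash is attached as an
#'   attribute).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "spx_config"))
  seeds <- withr_seed(config$master_seed,
                      sample.int(.Machine$integer.max - 1L, 8L))
  stages <- list()
  manifest <- list()
  run_stage <- function(name, seed, fn) {
    t0 <- Sys.time()
    res <- fn(seed)
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = name, seed = seed,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  stages$assignment <- run_stage("xassign", seeds[1], function(s) {
    spec <- do.call(sort_spec, c(config$sort, list(seed = s)))
    counts <- gen_sort_counts(spec)
    p0 <- counts |>
      normalize_pools(seed = s) |>
      compute_p0(min_poolX = config$min_poolX)
    fit <- fit_p0_mixture(p0, seed = s)
    list(fit = fit,
         table = assign_scaffolds(fit, p0, fdr = config$fdr))
  })

  stages$divergence <- run_stage("divergence", seeds[2], function(s) {
    spec <- do.call(codon_sim_spec, c(config$codon, list(seed = s)))
    counts <- gen_codon_alignments(spec) |>
      strip_untranslatable_codons() |>
      lineage_counts()
    list(
      summary = bootstrap_genes(counts, n_boot = config$n_boot, seed = s),
      test_omega_in1 = randomization_test(
        dplyr::filter(counts, .data$lineage == "ingroup1"),
        "omega_diff", "class", n_perm = config$n_perm, seed = s),
      test_ds_in1 = randomization_test(
        dplyr::filter(counts, .data$lineage == "ingroup1"),
        "dS_ratio", "class", n_perm = config$n_perm, seed = s + 1L)
    )
  })

  stages$diversity <- run_stage("diversity", seeds[3], function(s) {
    spec <- do.call(pop_sim_spec, c(config$rad, list(seed = s)))
    rad <- gen_population_rad(spec)
    blocks <- build_subalignments(rad)
    blocks$pi <- purrr::map_dbl(blocks$aln, ~ nei_pi(.x)$pi)
    pi_summary <- blocks |>
      dplyr::group_by(.data$population, .data$class) |>
      dplyr::group_modify(~ bootstrap_pi(.x$pi, n_boot = config$n_boot,
                                         seed = s)) |>
      dplyr::ungroup()
    ratios <- blocks |>
      dplyr::group_by(.data$population) |>
      dplyr::group_modify(function(g, key) {
        pair_pix_pia(g$pi[g$class == "X"], g$pi[g$class == "A"], seed = s)
      }) |>
      dplyr::ungroup()
    list(pi_summary = pi_summary, ratios = ratios,
         population_test = population_ratio_test(ratios))
  })

  stages$mk <- run_stage("mktest", seeds[4], function(s) {
    synth <- gen_mk_dataset(config$mk)
    build_mk_tables(synth$variants, synth$divergence, synth$cds,
                    synth$class_map) |>
      mk_alpha()
  })

  stages$theory <- run_stage("theory", seeds[5], function(s) {
    time_ratio <- coalescence_time_ratio(400000, 300000)
    tibble::tibble(
      quantity = c("ne_ratio_equal_sexes", "coalescence_time_ratio",
                   "miyata_alpha_k0.85", "miyata_alpha_k0.74"),
      value = c(ne_ratio(1, 1), time_ratio,
                miyata_alpha(0.85), miyata_alpha(0.74)))
  })

  stages$simulation <- run_stage("foundersim", seeds[6], function(s) {
    crash <- do.call(demography_scenario, c(config$sim, list(seed = s)))
    const <- do.call(demography_scenario,
                     c(utils::modifyList(config$sim,
                                         list(crash_frac = 1)),
                       list(seed = s + 1L)))
    list(crash = run_scenario(crash), constant = run_scenario(const))
  })

  manifest <- dplyr::bind_rows(manifest)
  attr(manifest, "config_hash") <- rlang::hash(config)
  c(stages, list(manifest = manifest))
}
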