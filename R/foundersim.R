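#' Recurrent founder-event demography for X and autosomal compartments
#'
#' Describes a population that crashes every `cycle_len` generations to a
#' fraction `crash_frac` of its size (or to an absolute number of founder
#' chromosomes) for one generation and recovers instantaneously. The X
#' compartment shares the event schedule with the autosomes, with all
#' sizes scaled by `ne_x / ne_a`. Such recurrent founder events depress
#' X diversity more than autosomal diversity (the Pool-Nielsen effect),
#' because the smaller X compartment loses diversity faster during each
#' crash and recovers it more slowly.
#'
#' @param ne_a,ne_x Diploid effective sizes of the autosomal and X
#'   compartments at full size.
#' @param mu Per-site per-generation mutation rate.
#' @param n_loci,locus_len Independent loci and their length in bp.
#' @param cycle_len Generations between crashes.
#' @param crash_frac Post-crash size as a fraction of full size (ignored
#'   when `founder_chroms` is given).
#' @param founder_chroms Optional absolute founder size in chromosomes
#'   (haploid count, on the autosomal scale; the X compartment's founder
#'   size is scaled by `ne_x / ne_a` like every other size, reflecting the
#'   smaller number of X lineages a founding propagule carries).
#' @param n_cycles Number of crash cycles simulated before the earliest
#'   history reverts to constant size.
#' @param recovery `"instant"` (default): full size restored the
#'   generation after the crash; `"exponential"`: the population grows
#'   back exponentially over the cycle, reaching full size at the next
#'   crash.
#' @param n_samples Chromosomes sampled per time point.
#' @param burn_in Cycles excluded from equilibrium summaries.
#' @param seed Integer seed.
#' @return A `demography_scenario` list.
#' @export
demography_scenario <- function(ne_a = 20000, ne_x = 15000, mu = 1.2e-8,
                                n_loci = 20000, locus_len = 100,
                                cycle_len = 50, crash_frac = 0.01,
                                founder_chroms = NULL, n_cycles = 20,
                                recovery = c("instant", "exponential"),
                                n_samples = 20, burn_in = 5, seed = 1L) {
  recovery <- match.arg(recovery)
  if (!is.null(founder_chroms)) {
    if (founder_chroms < 2) abort("founder_chroms must be at least 2")
  } else if (crash_frac <= 0 || crash_frac > 1) {
    abort("crash_frac must lie in (0, 1]")
  }
  if (ne_x > ne_a) abort("ne_x must not exceed ne_a")
  structure(list(ne_a = ne_a, ne_x = ne_x, mu = mu,
                 n_loci = as.integer(n_loci),
                 locus_len = as.integer(locus_len),
                 cycle_len = as.integer(cycle_len),
                 crash_frac = crash_frac, founder_chroms = founder_chroms,
                 n_cycles = as.integer(n_cycles), recovery = recovery,
                 n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "demography_scenario")
}

# backward piecewise-constant size history for a sample taken at forward
# generation `g` after the onset of the crash regime. Crash m occupies the
# last forward generation of cycle m, [m*cycle_len - 1, m*cycle_len);
# before the regime (forward time < 0) the size is constant at `ne`. With
# exponential recovery the population regrows from the crash size to `ne`
# over the following cycle, reaching full size at the next crash.
#' @noRd
crash_history <- function(g, ne, crash_size, cycle_len, n_cycles,
                          recovery = "instant") {
  if (g <= 0) return(list(start = 0, size = ne))
  size_at <- function(f) { # size during forward generation [f, f+1)
    if (f < 0) return(ne)
    m <- f %/% cycle_len + 1 # cycle containing f
    if (m > n_cycles) return(ne)
    if (f == m * cycle_len - 1) return(crash_size)
    if (recovery == "instant" || m == 1) return(ne)
    j <- f - (m - 1) * cycle_len # generations since last crash, 0-based
    r <- log(ne / crash_size) / (cycle_len - 1)
    min(ne, crash_size * exp(r * (j + 1)))
  }
  sizes <- c(vapply((g - 1):0, size_at, numeric(1)), ne)
  run <- rle(sizes)
  starts <- c(0, cumsum(run$lengths))[seq_along(run$values)]
  list(start = starts, size = run$values)
}

#' Simulate one genomic compartment under a piecewise-constant history
#'
#' Coalescent simulation of independent loci with infinite-sites mutation
#' under a backward piecewise-constant population-size history; diversity
#' is the mean pairwise difference per site in a sample of `n_samples`
#' chromosomes.
#'
#' @param ne_history Tibble/list with `start` (backward generations,
#'   ascending from 0) and `size` (diploid Ne per epoch; last epoch
#'   extends to infinity).
#' @param mu Per-site per-generation mutation rate.
#' @param n_loci,locus_len Loci and locus length.
#' @param n_samples Chromosomes sampled.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return Tibble `locus`, `pi` (per site).
#' @export
simulate_compartment <- function(ne_history, mu, n_loci, locus_len,
                                 n_samples = 20, seed = NULL) {
  withr_seed(seed, {
    sim <- coalsim_cpp(n_samples, n_loci, locus_len, mu,
                       as.numeric(ne_history$start),
                       as.numeric(ne_history$size), FALSE)
    tibble::tibble(locus = seq_len(n_loci), pi = sim$pi)
  })
}

#' Run a recurrent founder-event scenario for X and autosomes
#'
#' Samples both compartments at the end of each cycle (one generation
#' before the crash), from `burn_in + 1` through `n_cycles`, and returns
#' the diversity trajectory and its X/A ratio.
#'
#' @param scenario A [demography_scenario()].
#' @return Tibble `generation`, `cycle`, `pi_a`, `pi_x`, `ratio`, with
#'   the scenario attached as attribute `scenario`.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "demography_scenario"))
  crash_a <- if (!is.null(scenario$founder_chroms)) {
    scenario$founder_chroms / 2
  } else scenario$crash_frac * scenario$ne_a
  crash_x <- crash_a * scenario$ne_x / scenario$ne_a
  cycles <- seq(scenario$burn_in + 1, scenario$n_cycles)
  withr_seed(scenario$seed, {
    rows <- purrr::map(cycles, function(m) {
      g <- m * scenario$cycle_len - 1 # just before crash m
      ha <- crash_history(g, scenario$ne_a, crash_a, scenario$cycle_len,
                          scenario$n_cycles, scenario$recovery)
      hx <- crash_history(g, scenario$ne_x, crash_x, scenario$cycle_len,
                          scenario$n_cycles, scenario$recovery)
      pa <- mean(simulate_compartment(ha, scenario$mu, scenario$n_loci,
                                      scenario$locus_len,
                                      scenario$n_samples)$pi)
      px <- mean(simulate_compartment(hx, scenario$mu, scenario$n_loci,
                                      scenario$locus_len,
                                      scenario$n_samples)$pi)
      tibble::tibble(generation = g, cycle = m, pi_a = pa, pi_x = px,
                     ratio = px / pa)
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "scenario") <- scenario
  out
}

#' Summarise founder-event scenarios at dynamic equilibrium
#'
#' @param results Named list of trajectories from [run_scenario()].
#' @param n_boot Bootstrap replicates over time points for the ratio CI.
#' @param seed Integer seed.
#' @return Tibble `scenario`, `mean_ratio`, `ci_low`, `ci_high`,
#'   `n_times` (all time points in the trajectories are already
#'   post-burn-in).
#' @export
summarize_pn <- function(results, n_boot = 1000, seed = 1L) {
  if (length(results) < 2) abort("need at least 2 scenarios to compare")
  if (is.null(names(results))) {
    names(results) <- paste0("scenario_", seq_along(results))
  }
  purrr::imap(results, function(tr, nm) {
    r <- tr$ratio
    ci <- boot_percentile(length(r), n_boot, function(idx) mean(r[idx]),
                          seed)
    tibble::tibble(scenario = nm, mean_ratio = mean(r), ci_low = ci[1],
                   ci_high = ci[2], n_times = length(r))
  }) |> dplyr::bind_rows()
}

#' Plot a piX/piA trajectory
#'
#' @param result Trajectory from [run_scenario()] (or several bound
#'   together with a `scenario` column).
#' @return A ggplot object.
#' @export
plot_ratio_trajectory <- function(result) {
  check_cols(result, c("generation", "ratio"))
  p <- ggplot2::ggplot(result,
                       ggplot2::aes(x = .data$generation, y = .data$ratio))
  if ("scenario" %in% names(result)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$scenario))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed") +
    ggplot2::labs(x = "Generation", y = expression(pi[X] / pi[A])) +
    ggplot2::theme_minimal()
}
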