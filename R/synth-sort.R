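#' Specification for a synthetic flow-sorted sperm-pool experiment
#'
#' Describes a sorting design in which sperm nuclei are separated into a
#' pool without X chromosomes ("pool 0") and a pool carrying both X
#' chromosomes ("pool X"), each pool then shotgun-sequenced and the reads
#' mapped back to scaffolds. Sorting is imperfect: a fraction of X-bearing
#' nuclei contaminates pool 0 and vice versa.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param frac_x Fraction of scaffolds that are X-linked.
#' @param mean_len Mean scaffold length in bp (lengths are log-normal with
#'   sdlog 0.7).
#' @param impurity0 Fraction of X-bearing nuclei contaminating pool 0.
#' @param impurityX Fraction of X-free nuclei contaminating pool X.
#' @param depth_per_pool Expected total reads per pool.
#' @param seed Integer seed making the draw reproducible.
#' @return A `sort_spec` list.
#' @export
sort_spec <- function(n_scaffolds = 3000, frac_x = 0.12, mean_len = 1e5,
                      impurity0 = 0.12, impurityX = 0.03,
                      depth_per_pool = 1e6, seed = 1L) {
  if (frac_x < 0 || frac_x > 1) abort("frac_x must lie in [0, 1]")
  if (impurity0 < 0 || impurity0 >= 0.5 || impurityX < 0 || impurityX >= 0.5) {
    abort("impurities must lie in [0, 0.5)")
  }
  if (depth_per_pool <= 0) abort("depth_per_pool must be positive")
  n_x <- round(n_scaffolds * frac_x)
  if (n_x < 2 || n_scaffolds - n_x < 2) {
    abort("need at least 2 scaffolds per class for the mixture to be fittable")
  }
  structure(list(n_scaffolds = as.integer(n_scaffolds), frac_x = frac_x,
                 mean_len = mean_len, impurity0 = impurity0,
                 impurityX = impurityX, depth_per_pool = depth_per_pool,
                 seed = as.integer(seed)),
            class = "sort_spec")
}

#' Generate per-scaffold read counts from two sorted sperm pools
#'
#' Simulates the read-count table of a flow-sorting experiment. Each sperm
#' nucleus is haploid: X-free nuclei carry one copy of every autosome and
#' no X; X-bearing nuclei carry every autosome plus both X chromosomes.
#' Reads from a pool distribute over scaffolds in proportion to scaffold
#' length times the fraction of nuclei in that pool carrying the scaffold,
#' with Poisson counts per scaffold-pool cell.
#'
#' X-linked scaffolds therefore receive pool-0 reads only through sorting
#' impurity, so their expected P0 statistic is a small impurity-driven
#' value, while autosomal scaffolds sit near 0.5.
#'
#' @param spec A [sort_spec()].
#' @return A tibble with columns `scaffold_id`, `length`, `reads_pool0`,
#'   `reads_poolX` and the ground-truth `true_class` (`"X"`/`"A"`).
#' @export
gen_sort_counts <- function(spec) {
  stopifnot(inherits(spec, "sort_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_scaffolds
    n_x <- round(n * spec$frac_x)
    true_class <- sample(c(rep("X", n_x), rep("A", n - n_x)))
    len <- pmax(500, round(rlnorm(n, log(spec$mean_len) - 0.7^2 / 2, 0.7)))
    is_x <- true_class == "X"
    # fraction of X-bearing nuclei in each pool
    fx0 <- spec$impurity0
    fxX <- 1 - spec$impurityX
    w0 <- len * ifelse(is_x, fx0, 1)
    wX <- len * ifelse(is_x, fxX, 1)
    reads0 <- rpois(n, spec$depth_per_pool * w0 / sum(w0))
    readsX <- rpois(n, spec$depth_per_pool * wX / sum(wX))
    tibble::tibble(
      scaffold_id = sprintf("scaffold_%05d", seq_len(n)),
      length = as.integer(len),
      reads_pool0 = reads0,
      reads_poolX = readsX,
      true_class = true_class
    )
  })
}
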