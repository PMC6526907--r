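#' Expected X-to-autosome effective population size ratio
#'
#' Wright's effective-size formulas for X-linked and autosomal loci as a
#' function of the numbers of breeding males and females:
#' `Ne_X = 9 Nm Nf / (2 (2 Nm + Nf))` and `Ne_A = 4 Nm Nf / (Nm + Nf)`,
#' giving `Ne_X / Ne_A = 9 (Nm + Nf) / (8 (2 Nm + Nf))`. At an equal sex
#' ratio the ratio is 0.75. In an X1X2/0 system both X chromosomes are
#' hemizygous in males, so standard X-linkage applies unchanged.
#'
#' @param n_males,n_females Effective numbers of breeding males and females
#'   (need not be integers).
#' @return The expected ratio `Ne_X / Ne_A`, a number in (9/16, 9/8).
#' @examples
#' ne_ratio(100, 100)  # 0.75
#' ne_ratio(100, 800)  # female-biased: approaches 9/8
#' @export
ne_ratio <- function(n_males, n_females) {
  if (any(n_males <= 0) || any(n_females <= 0)) {
    abort("breeder counts must be positive")
  }
  9 * (n_males + n_females) / (8 * (2 * n_males + n_females))
}

#' Expected piX/piA under a given operational sex ratio
#'
#' Multiplies the neutral `Ne_X/Ne_A` expectation by a standardization
#' factor. The factor anchors the theoretical curve to an empirical
#' observation (e.g. the subsocial-species piX/piA divided by 0.75), so the
#' curve can be read as "expected piX/piA if the only change from the
#' anchored population were the sex ratio".
#'
#' @inheritParams ne_ratio
#' @param standardization Positive multiplier applied to the neutral
#'   expectation; `1` gives the raw Wright curve.
#' @return Expected piX/piA.
#' @export
expected_pix_pia <- function(n_males, n_females, standardization = 1) {
  if (any(standardization <= 0)) abort("standardization must be positive")
  ne_ratio(n_males, n_females) * standardization
}

#' Invert the expected piX/piA curve for the female-to-male sex ratio
#'
#' Finds the ratio `Nf/Nm` at which [expected_pix_pia()] equals a target
#' piX/piA, by bisection on the (strictly increasing) standardized curve.
#'
#' @param target_ratio Observed piX/piA to invert.
#' @param standardization As in [expected_pix_pia()].
#' @param interval Search interval for `Nf/Nm`.
#' @param tol Bisection tolerance on `Nf/Nm`.
#' @return The implied `Nf/Nm` (females per male).
#' @export
invert_sex_ratio <- function(target_ratio, standardization = 1,
                             interval = c(1e-6, 1e6), tol = 1e-6) {
  f <- function(r) expected_pix_pia(1, r, standardization) - target_ratio
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    abort(sprintf(
      "target %.4g outside attainable range [%.4g, %.4g] of the standardized curve",
      target_ratio, expected_pix_pia(1, lo, standardization),
      expected_pix_pia(1, hi, standardization)))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Male-to-female substitution-rate ratio from X/A divergence (Miyata)
#'
#' Inverts the Miyata relation `k_X/k_A = (2/3) (2 + a) / (1 + a)` for the
#' male-to-female substitution (mutation) rate ratio `a`, where `k_X/k_A`
#' is the (coalescence-adjusted) ratio of X-linked to autosomal synonymous
#' divergence. Because X chromosomes spend 1/3 of their time in males, a
#' male-biased mutation rate depresses `k_X/k_A` below 1; the relation maps
#' `k` in (2/3, 4/3] onto `a` in [0, infinity).
#'
#' @param k_ratio Adjusted X/A synonymous divergence ratio, in (2/3, 4/3].
#' @return The male-to-female substitution ratio `a = (4 - 3k)/(3k - 2)`.
#' @examples
#' miyata_alpha(1)     # 1: no sex bias
#' miyata_alpha(0.85)  # strong male bias
#' @export
miyata_alpha <- function(k_ratio) {
  if (any(k_ratio <= 2 / 3)) {
    abort("k_ratio <= 2/3 implies an infinite or negative male bias")
  }
  if (any(k_ratio > 4 / 3)) {
    abort("k_ratio > 4/3 implies a negative male-to-female ratio")
  }
  (4 - 3 * k_ratio) / (3 * k_ratio - 2)
}

#' Forward Miyata relation
#'
#' Expected X/A synonymous divergence ratio for a given male-to-female
#' substitution-rate ratio; the inverse of [miyata_alpha()].
#'
#' @param alpha_mf Male-to-female substitution ratio, non-negative.
#' @return `k_X/k_A = (2/3) (2 + alpha) / (1 + alpha)`.
#' @export
miyata_k <- function(alpha_mf) {
  if (any(alpha_mf < 0)) abort("alpha_mf must be non-negative")
  (2 / 3) * (2 + alpha_mf) / (1 + alpha_mf)
}

#' Relative X/A time to accumulate substitutions between two species
#'
#' Divergence between two species accrues over the split time plus the
#' coalescence time in their ancestor. Because ancestral `Ne_X < Ne_A`, X
#' chromosomes coalesce faster, so X-linked divergence accumulates over a
#' shorter total time. The ratio of total times is
#' `(T + 2 f N_A) / (T + 2 N_A)` with `T` the split time in generations,
#' `N_A` the ancestral diploid autosomal effective size and `f` the
#' ancestral `Ne_X/Ne_A`.
#'
#' @param t_gen Split time in generations.
#' @param n_ancestral Ancestral diploid autosomal effective population size.
#' @param ne_x_factor Ancestral `Ne_X/Ne_A` (default 0.75, equal sex ratio).
#' @return Relative X/A total divergence time, in (0, 1] for `f <= 1`.
#' @examples
#' coalescence_time_ratio(400000, 300000)  # 0.85
#' @export
coalescence_time_ratio <- function(t_gen, n_ancestral, ne_x_factor = 0.75) {
  if (any(t_gen <= 0) || any(n_ancestral <= 0) || any(ne_x_factor <= 0)) {
    abort("t_gen, n_ancestral and ne_x_factor must be positive")
  }
  (t_gen + 2 * ne_x_factor * n_ancestral) / (t_gen + 2 * n_ancestral)
}

#' Adjust an X/A divergence ratio for ancestral coalescence times
#'
#' Divides a raw X/A synonymous divergence ratio by the relative X/A
#' divergence time from [coalescence_time_ratio()], isolating the
#' mutation-rate component of the ratio.
#'
#' @param raw_ratio Observed dS_X/dS_A (or RAD divergence ratio).
#' @param time_ratio Relative X/A divergence time, in (0, 1].
#' @return The adjusted ratio `raw_ratio / time_ratio`.
#' @export
adjust_divergence_ratio <- function(raw_ratio, time_ratio) {
  if (any(time_ratio <= 0) || any(time_ratio > 1)) {
    abort("time_ratio must lie in (0, 1]")
  }
  raw_ratio / time_ratio
}

#' Evaluate the expected piX/piA curve over a sex-ratio grid
#'
#' @param nf_over_nm Grid of female-to-male ratios.
#' @inheritParams expected_pix_pia
#' @return A tibble with columns `nf_over_nm` and `expected_ratio`.
#' @export
pix_pia_curve <- function(nf_over_nm = exp(seq(log(0.05), log(20),
                                               length.out = 200)),
                          standardization = 1) {
  tibble::tibble(
    nf_over_nm = nf_over_nm,
    expected_ratio = expected_pix_pia(1, nf_over_nm, standardization)
  )
}
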