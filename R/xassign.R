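#' Equalize total read counts between the two sorted pools
#'
#' Down-samples the larger pool, read by read without replacement across
#' scaffolds (multivariate hypergeometric), so that both pools contribute
#' the same number of mapped reads before the P0 statistic is formed. The
#' smaller pool is returned unchanged.
#'
#' @param counts Tibble with columns `scaffold_id`, `reads_pool0`,
#'   `reads_poolX` (extra columns are preserved).
#' @param seed Integer seed for the subsampling draw.
#' @return The input tibble with the larger pool's counts replaced by the
#'   subsampled counts; both pool totals are equal afterwards.
#' @export
normalize_pools <- function(counts, seed = 1L) {
  check_cols(counts, c("scaffold_id", "reads_pool0", "reads_poolX"))
  tot0 <- sum(counts$reads_pool0)
  totX <- sum(counts$reads_poolX)
  if (tot0 == 0 || totX == 0) {
    abort("a pool with zero total reads cannot be normalized")
  }
  if (tot0 == totX) return(counts)
  big <- if (tot0 > totX) "reads_pool0" else "reads_poolX"
  target <- min(tot0, totX)
  counts[[big]] <- mvhyper_sample(counts[[big]], target, seed)
  counts
}

# multivariate hypergeometric draw: sample `k` items without replacement
# from cells with sizes `sizes`, by sequential univariate hypergeometrics
#' @noRd
mvhyper_sample <- function(sizes, k, seed = NULL) {
  withr_seed(seed, {
    out <- integer(length(sizes))
    remaining <- sum(sizes)
    left <- k
    for (i in seq_along(sizes)) {
      if (left == 0L) break
      xi <- rhyper(1, sizes[i], remaining - sizes[i], left)
      out[i] <- xi
      left <- left - xi
      remaining <- remaining - sizes[i]
    }
    out
  })
}

#' Compute the P0 statistic per scaffold
#'
#' P0 is the fraction of a scaffold's sorted-pool reads that come from the
#' X-free pool: `reads_pool0 / (reads_pool0 + reads_poolX)`, computed after
#' pool normalization. X-linked scaffolds receive pool-0 reads only through
#' sorting impurity, so they sit near 0; autosomal scaffolds sit near 0.5.
#' Scaffolds with fewer than `min_poolX` pool-X reads cannot have an X
#' origin assessed and are flagged as non-candidates.
#'
#' @param counts Normalized pool counts (see [normalize_pools()]).
#' @param min_poolX Minimum pool-X reads for a scaffold to be a candidate.
#' @return Tibble with `scaffold_id`, `p0`, `total_reads`, `candidate`
#'   (plus `true_class` when present in the input). Scaffolds with zero
#'   reads in both pools are dropped with a warning.
#' @export
compute_p0 <- function(counts, min_poolX = 100) {
  check_cols(counts, c("scaffold_id", "reads_pool0", "reads_poolX"))
  tot <- counts$reads_pool0 + counts$reads_poolX
  if (any(tot == 0)) {
    warn(sprintf("dropping %d scaffold(s) with no reads in either pool",
                 sum(tot == 0)))
  }
  out <- counts |>
    dplyr::filter(.data$reads_pool0 + .data$reads_poolX > 0) |>
    dplyr::mutate(
      total_reads = .data$reads_pool0 + .data$reads_poolX,
      p0 = .data$reads_pool0 / .data$total_reads,
      candidate = .data$reads_poolX >= min_poolX
    )
  keep <- intersect(c("scaffold_id", "p0", "total_reads", "candidate",
                      "true_class"), names(out))
  out[keep]
}

#' Fit a two-component beta mixture to candidate P0 values
#'
#' Separates the X-linked and autosomal P0 distributions with a
#' two-component beta mixture fitted by EM (moment-matching M-step) from
#' several random restarts. The component with the smaller mean is taken as
#' the X component; per-scaffold posterior membership probabilities are
#' returned for FDR-controlled assignment.
#'
#' @param records P0 records from [compute_p0()].
#' @param seed Integer seed controlling the EM restarts.
#' @param n_restarts Number of random restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `spx_mixture` with elements `mean_x`,
#'   `mean_a`, `shape_x`, `shape_a` (beta parameters), `weight_x`,
#'   `posterior` (tibble of `scaffold_id`, `p0`, `posterior_x`), `loglik`,
#'   `converged`, `n`.
#' @export
fit_p0_mixture <- function(records, seed = 1L, n_restarts = 5L,
                           max_iter = 500L, tol = 1e-8) {
  check_cols(records, c("scaffold_id", "p0", "candidate"))
  cand <- dplyr::filter(records, .data$candidate)
  if (nrow(cand) < 50) {
    abort("need at least 50 candidate scaffolds to fit the mixture")
  }
  x <- pmin(pmax(cand$p0, 1e-6), 1 - 1e-6)
  if (sd(x) < 1e-12) {
    fit <- list(mean_x = mean(x), mean_a = mean(x),
                shape_x = c(NA_real_, NA_real_),
                shape_a = c(NA_real_, NA_real_),
                weight_x = 0.5,
                posterior = tibble::tibble(scaffold_id = cand$scaffold_id,
                                           p0 = cand$p0, posterior_x = 0.5),
                loglik = NA_real_, converged = FALSE, n = nrow(cand))
    class(fit) <- "spx_mixture"
    return(fit)
  }
  best <- NULL
  withr_seed(seed, {
    for (r in seq_len(n_restarts)) {
      split <- quantile(x, runif(1, 0.05, 0.5))
      fit <- beta_mixture_em(x, split, max_iter, tol)
      if (is.null(best) || (fit$loglik > best$loglik)) best <- fit
    }
  })
  post <- best$posterior_x
  # smaller-mean component is X
  if (best$means[1] > best$means[2]) {
    best$means <- rev(best$means)
    best$shapes <- best$shapes[2:1]
    best$weight <- 1 - best$weight
    post <- 1 - post
  }
  out <- list(mean_x = best$means[1], mean_a = best$means[2],
              shape_x = best$shapes[[1]], shape_a = best$shapes[[2]],
              weight_x = best$weight,
              posterior = tibble::tibble(scaffold_id = cand$scaffold_id,
                                         p0 = cand$p0, posterior_x = post),
              loglik = best$loglik, converged = best$converged,
              n = nrow(cand))
  class(out) <- "spx_mixture"
  out
}

# EM for a two-component beta mixture; M-step by weighted maximum
# likelihood (moment matching only as the optimizer's starting point --
# moments are badly inflated by stray points far from a component's core)
#' @noRd
beta_mixture_em <- function(x, split, max_iter, tol) {
  z <- as.numeric(x <= split)
  z <- pmin(pmax(z, 0.01), 0.99)
  w <- mean(z)
  shapes <- list(beta_ml(x, z), beta_ml(x, 1 - z))
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- log(w) + dbeta(x, shapes[[1]][1], shapes[[1]][2], log = TRUE)
    l2 <- log1p(-w) + dbeta(x, shapes[[2]][1], shapes[[2]][2], log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    z <- 1 / (1 + exp(l2 - l1))
    w <- mean(z)
    if (w < 1e-6 || w > 1 - 1e-6) break
    shapes <- list(beta_ml(x, z, shapes[[1]]), beta_ml(x, 1 - z,
                                                       shapes[[2]]))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  means <- vapply(shapes, function(s) s[1] / (s[1] + s[2]), numeric(1))
  list(means = means, shapes = shapes, weight = w, posterior_x = z,
       loglik = ll, converged = converged)
}

# weighted beta fits: method of moments, and ML on log-shape scale
#' @noRd
beta_mom <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- max(sum(w * (x - m)^2), 1e-10)
  v <- min(v, m * (1 - m) * 0.999)
  conc <- m * (1 - m) / v - 1
  c(m * conc, (1 - m) * conc)
}

#' @noRd
beta_ml <- function(x, w, start = NULL) {
  if (is.null(start)) start <- beta_mom(x, w)
  start <- pmin(pmax(start, 1e-3), 1e6)
  # sufficient statistics of the weighted beta log-likelihood
  sw <- sum(w)
  slx <- sum(w * log(x))
  sl1x <- sum(w * log1p(-x))
  nll <- function(ls) {
    a <- exp(ls[1]); b <- exp(ls[2])
    -( (a - 1) * slx + (b - 1) * sl1x - sw * lbeta(a, b) )
  }
  fit <- tryCatch(
    optim(log(start), nll, method = "Nelder-Mead",
          control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(start)
  exp(fit$par)
}

#' @export
print.spx_mixture <- function(x, ...) {
  cat("Two-component beta mixture on P0\n")
  cat(sprintf("  n candidates: %d   converged: %s\n", x$n, x$converged))
  cat(sprintf("  X component:  mean %.4f  weight %.3f\n", x$mean_x,
              x$weight_x))
  cat(sprintf("  A component:  mean %.4f  weight %.3f\n", x$mean_a,
              1 - x$weight_x))
  cat(sprintf("  log-likelihood: %.2f\n", x$loglik))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spx_mixture <- function(x, ...) {
  tibble::tibble(
    component = c("X", "A"),
    mean = c(x$mean_x, x$mean_a),
    shape1 = c(x$shape_x[1], x$shape_a[1]),
    shape2 = c(x$shape_x[2], x$shape_a[2]),
    weight = c(x$weight_x, 1 - x$weight_x)
  )
}

#' @exportS3Method generics::glance
glance.spx_mixture <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, converged = x$converged)
}

#' Assign scaffolds to X chromosomes or autosomes at a nominal FDR
#'
#' Chooses two P0 thresholds from the fitted mixture posteriors: `t_x`, the
#' largest cutoff such that the expected fraction of autosomal scaffolds
#' among calls below it is at most `fdr`, and `t_a`, the smallest cutoff
#' such that the expected X contamination above it is at most `fdr`. The
#' expectation is computed from the fitted posteriors over scaffolds that
#' are individually more likely to belong to the called component
#' (posterior > 1/2), so a clean separation yields a threshold inside the
#' gap rather than one padded out to the nominal FDR. Scaffolds between
#' the thresholds, and non-candidates, are left unassigned.
#'
#' @param fit A converged [fit_p0_mixture()] object.
#' @param records P0 records from [compute_p0()].
#' @param fdr Nominal false discovery rate for each threshold.
#' @param force Proceed even when the mixture did not converge.
#' @return Tibble with `scaffold_id`, `p0`, `posterior_x`, `label`
#'   (`"X"`, `"AUTOSOME"` or `"UNASSIGNED"`); the thresholds and nominal
#'   FDR are attached as attributes `t_x`, `t_a`, `nominal_fdr`.
#' @export
assign_scaffolds <- function(fit, records, fdr = 0.025, force = FALSE) {
  stopifnot(inherits(fit, "spx_mixture"))
  if (fdr <= 0 || fdr >= 0.5) abort("fdr must lie in (0, 0.5)")
  if (!fit$converged && !force) {
    abort("mixture fit did not converge; rerun or use force = TRUE")
  }
  post <- dplyr::arrange(fit$posterior, .data$p0)
  n <- nrow(post)
  # X threshold: walk up from p0 = 0 through the contiguous run of
  # scaffolds that are individually more likely X than autosomal
  # (posterior > 1/2), and take the largest prefix whose expected
  # autosomal fraction stays at or below the nominal FDR. Contiguity keeps
  # the call set an interval [0, t_x) even when a heavy-tailed component
  # assigns high posteriors to stray scaffolds far from the boundary.
  xrun <- which(!(post$posterior_x > 0.5))[1]
  xrun <- if (is.na(xrun)) n else xrun - 1L
  t_x <- 0
  if (xrun > 0L) {
    cum_a <- cumsum(1 - post$posterior_x[seq_len(xrun)]) / seq_len(xrun)
    kx <- max(c(0L, which(cum_a <= fdr)))
    if (kx > 0L) {
      t_x <- if (kx == n) 1 else (post$p0[kx] + post$p0[kx + 1]) / 2
    }
  }
  # autosomal threshold: mirrored on the high-p0 side
  arun <- which(!(rev(post$posterior_x) < 0.5))[1]
  arun <- if (is.na(arun)) n else arun - 1L
  t_a <- 1
  if (arun > 0L) {
    rev_post <- rev(post$posterior_x)
    cum_x <- cumsum(rev_post[seq_len(arun)]) / seq_len(arun)
    ka <- max(c(0L, which(cum_x <= fdr)))
    if (ka > 0L) {
      t_a <- if (ka == n) 0 else (post$p0[n - ka] + post$p0[n - ka + 1]) / 2
    }
  }
  if (t_x > t_a) t_x <- t_a # keep thresholds ordered
  out <- records |>
    dplyr::left_join(dplyr::select(post, "scaffold_id", "posterior_x"),
                     by = "scaffold_id") |>
    dplyr::mutate(label = dplyr::case_when(
      !.data$candidate ~ "UNASSIGNED",
      .data$p0 < t_x ~ "X",
      .data$p0 > t_a ~ "AUTOSOME",
      TRUE ~ "UNASSIGNED"
    ))
  keep <- intersect(c("scaffold_id", "p0", "posterior_x", "candidate",
                      "label", "true_class"), names(out))
  out <- out[keep]
  attr(out, "t_x") <- t_x
  attr(out, "t_a") <- t_a
  attr(out, "nominal_fdr") <- fdr
  out
}

#' Plot the P0 distribution with the fitted mixture components
#'
#' @param fit A [fit_p0_mixture()] object.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_p0_mixture <- function(fit, bins = 60) {
  stopifnot(inherits(fit, "spx_mixture"))
  grid <- seq(0.001, 0.999, length.out = 400)
  dens <- dplyr::bind_rows(
    tibble::tibble(p0 = grid, component = "X",
                   density = fit$weight_x *
                     dbeta(grid, fit$shape_x[1], fit$shape_x[2])),
    tibble::tibble(p0 = grid, component = "A",
                   density = (1 - fit$weight_x) *
                     dbeta(grid, fit$shape_a[1], fit$shape_a[2]))
  )
  ggplot2::ggplot(fit$posterior, ggplot2::aes(x = .data$p0)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = expression(P[0]), y = "Density", colour = "Component") +
    ggplot2::theme_minimal()
}
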