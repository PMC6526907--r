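# internal helpers

# evaluate `code` under a fixed seed, restoring the caller's RNG state
#' @noRd
withr_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, globalenv())
      } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# percentile bootstrap CI of a statistic over rows of resampled indices
#' @noRd
boot_percentile <- function(n, n_boot, stat_fn, seed = NULL,
                            probs = c(0.025, 0.975)) {
  withr_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      stat_fn(sample.int(n, n, replace = TRUE))
    }, numeric(1))
    c(quantile(reps, probs[1], na.rm = TRUE, names = FALSE),
      quantile(reps, probs[2], na.rm = TRUE, names = FALSE))
  })
}

# columns-check helper for tabular inputs
#' @noRd
check_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(df)
}
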