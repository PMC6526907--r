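# shared fixture builders; everything is generated in code

# tiny pool-count table with known composition
tiny_pool_counts <- function() {
  tibble::tibble(
    scaffold_id = paste0("s", 1:4),
    length = c(1000L, 2000L, 1500L, 800L),
    reads_pool0 = c(10L, 50L, 0L, 200L),
    reads_poolX = c(90L, 50L, 150L, 180L)
  )
}

# random equal-length alignment as a named character vector, optionally
# with gaps/Ns sprinkled in
random_alignment <- function(n_seq, len, gap_frac = 0, seed = 1) {
  withr::with_seed(seed, {
    mat <- matrix(sample(c("A", "C", "G", "T"), n_seq * len, replace = TRUE),
                  nrow = n_seq)
    # make some sites polymorphic
    for (p in sample(len, max(1, len %/% 10))) {
      mat[, p] <- sample(c("A", "C", "G", "T"), 1)
      carriers <- sample(n_seq, sample(n_seq - 1, 1))
      mat[carriers, p] <- sample(c("A", "C", "G", "T"), 1)
    }
    if (gap_frac > 0) {
      idx <- sample(length(mat), round(gap_frac * length(mat)))
      mat[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
    }
    stats::setNames(apply(mat, 1, paste, collapse = ""),
                    paste0("seq", seq_len(n_seq)))
  })
}

# brute-force Nei pi: mean over pairs of (differences / comparable sites)
brute_force_pi <- function(aln) {
  mat <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
  good <- c("A", "C", "G", "T")
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% good & mat[j, ] %in% good
    if (sum(ok) == 0) next
    vals <- c(vals, sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# three-sequence codon alignment tibble from explicit sequences
triple_aln <- function(in1, in2, out, class = "A", gene_id = "g1") {
  tibble::tibble(gene_id = gene_id, class = class,
                 ingroup1 = in1, ingroup2 = in2, outgroup = out)
}
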