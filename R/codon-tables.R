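# Codon machinery shared by the codon simulator, the substitution counter
# and the variant classifier. Codons are indexed 1..64 with bases ordered
# A,C,G,T: index = 16*b1 + 4*b2 + b3 + 1 (b in 0..3).

.spx_bases <- c("A", "C", "G", "T")

.spx_cache <- new.env(parent = emptyenv())

#' @noRd
codon_index <- function(b1, b2, b3) 16L * b1 + 4L * b2 + b3 + 1L

# standard genetic code, single-letter amino acids, "*" for stop
.spx_genetic_code <- function() {
  # classic TCAG-ordered translation string
  aa_tcag <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
  )[[1]]
  ord <- c("T", "C", "A", "G")
  aa <- character(64)
  i <- 0L
  for (x in ord) for (y in ord) for (z in ord) {
    i <- i + 1L
    idx <- codon_index(match(x, .spx_bases) - 1L,
                       match(y, .spx_bases) - 1L,
                       match(z, .spx_bases) - 1L)
    aa[idx] <- aa_tcag[i]
  }
  aa
}

# Build and cache all lookup tables:
#   aa[64]            translation
#   base_mat[64,3]    0-based base at each codon position
#   syn_sites[64]     NG86 synonymous sites per codon (changes to stop = nonsyn)
#   syn_path[64,64]   pathway-averaged synonymous substitutions between codons
#   non_path[64,64]   pathway-averaged nonsynonymous substitutions
#' @noRd
codon_tables <- function() {
  if (!is.null(.spx_cache$tables)) return(.spx_cache$tables)
  aa <- .spx_genetic_code()
  base_mat <- matrix(0L, 64, 3)
  for (i in 1:64) {
    k <- i - 1L
    base_mat[i, ] <- c(k %/% 16L, (k %/% 4L) %% 4L, k %% 4L)
  }
  mult <- c(16L, 4L, 1L)

  neighbour <- function(i, pos, new_base) {
    codon_index_from <- (i - 1L) - base_mat[i, pos] * mult[pos] +
      new_base * mult[pos]
    codon_index_from + 1L
  }

  # per-codon site counts; mutations to stop codons are excluded from the
  # mutational opportunity (the evolutionary process never fixes them), so
  # S + N sites per codon can be slightly below 3
  syn_sites <- numeric(64)
  non_sites <- numeric(64)
  for (i in 1:64) {
    if (aa[i] == "*") {
      syn_sites[i] <- NA_real_; non_sites[i] <- NA_real_; next
    }
    nsyn <- 0L; nstop <- 0L
    for (pos in 1:3) for (b in 0:3) {
      if (b == base_mat[i, pos]) next
      j <- neighbour(i, pos, b)
      if (aa[j] == "*") nstop <- nstop + 1L
      else if (aa[j] == aa[i]) nsyn <- nsyn + 1L
    }
    syn_sites[i] <- nsyn / 3
    non_sites[i] <- (9L - nsyn - nstop) / 3
  }

  # pathway averaging over minimal mutational paths between two codons,
  # discarding paths through stop-codon intermediates (keep all paths if
  # every one is blocked)
  syn_path <- matrix(0, 64, 64)
  non_path <- matrix(0, 64, 64)
  perms <- list(
    `1` = matrix(1L, 1, 1),
    `2` = rbind(c(1L, 2L), c(2L, 1L)),
    `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in 1:64) for (j in 1:64) {
    if (i == j) next
    d <- which(base_mat[i, ] != base_mat[j, ])
    m <- length(d)
    pp <- perms[[as.character(m)]]
    res <- matrix(NA_real_, nrow(pp), 2) # syn, nonsyn per path
    blocked <- logical(nrow(pp))
    for (p in seq_len(nrow(pp))) {
      cur <- i; s <- 0; ns <- 0; bad <- FALSE
      for (step in seq_len(m)) {
        pos <- d[pp[p, step]]
        nxt <- neighbour(cur, pos, base_mat[j, pos])
        if (aa[nxt] == "*" && step < m) bad <- TRUE
        if (aa[nxt] == aa[cur] && aa[cur] != "*" && aa[nxt] != "*") {
          s <- s + 1
        } else {
          ns <- ns + 1
        }
        cur <- nxt
      }
      res[p, ] <- c(s, ns)
      blocked[p] <- bad
    }
    use <- if (all(blocked)) rep(TRUE, nrow(pp)) else !blocked
    syn_path[i, j] <- mean(res[use, 1])
    non_path[i, j] <- mean(res[use, 2])
  }

  .spx_cache$tables <- list(aa = aa, base_mat = base_mat,
                            syn_sites = syn_sites, non_sites = non_sites,
                            syn_path = syn_path, non_path = non_path)
  .spx_cache$tables
}

# split a vector of in-frame CDS strings into a matrix of codon indices
# (genes in rows padded with NA is not supported: all strings same length)
#' @noRd
seq_to_codons <- function(seqs) {
  n <- unique(nchar(seqs))
  if (length(n) != 1L) abort("sequences must have equal length")
  if (n %% 3L != 0L) abort("sequence length must be divisible by 3")
  chars <- matrix(match(unlist(strsplit(toupper(seqs), "")), .spx_bases) - 1L,
                  nrow = length(seqs), byrow = TRUE)
  ncod <- n %/% 3L
  idx <- matrix(NA_integer_, length(seqs), ncod)
  ok <- !is.na(chars)
  b1 <- chars[, seq(1L, n, 3L), drop = FALSE]
  b2 <- chars[, seq(2L, n, 3L), drop = FALSE]
  b3 <- chars[, seq(3L, n, 3L), drop = FALSE]
  idx[] <- ifelse(is.na(b1) | is.na(b2) | is.na(b3), NA_integer_,
                  codon_index(b1, b2, b3))
  idx
}

#' @noRd
codons_to_seq <- function(idx) {
  tb <- codon_tables()
  apply(idx, 1, function(row) {
    paste(.spx_bases[t(tb$base_mat[row, , drop = FALSE]) + 1L], collapse = "")
  })
}

#' @noRd
translate_codons <- function(idx) codon_tables()$aa[idx]
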