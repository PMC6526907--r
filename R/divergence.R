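#' Remove codons that cannot be translated in any species
#'
#' A codon column containing an N, an IUPAC ambiguity symbol or a gap in
#' any of the three species is removed from all three, keeping the
#' alignment in frame. Genes stripped to zero length are dropped with a
#' warning.
#'
#' @param aln Tibble of codon alignments with character columns
#'   `ingroup1`, `ingroup2`, `outgroup` (one row per gene; lengths per row
#'   equal and divisible by 3).
#' @return The tibble with cleaned sequences.
#' @export
strip_untranslatable_codons <- function(aln) {
  check_cols(aln, c("ingroup1", "ingroup2", "outgroup"))
  strip_one <- function(s1, s2, s3) {
    n <- nchar(s1)
    if (nchar(s2) != n || nchar(s3) != n) {
      abort("aligned sequences must have equal length")
    }
    if (n %% 3L != 0L) abort("alignment length must be divisible by 3")
    ch <- rbind(strsplit(toupper(s1), "")[[1]],
                strsplit(toupper(s2), "")[[1]],
                strsplit(toupper(s3), "")[[1]])
    bad_col <- !(ch[1, ] %in% .spx_bases) | !(ch[2, ] %in% .spx_bases) |
      !(ch[3, ] %in% .spx_bases)
    bad_codon <- colSums(matrix(bad_col, nrow = 3)) > 0
    keep_nt <- rep(!bad_codon, each = 3)
    c(paste(ch[1, keep_nt], collapse = ""),
      paste(ch[2, keep_nt], collapse = ""),
      paste(ch[3, keep_nt], collapse = ""))
  }
  stripped <- purrr::pmap(list(aln$ingroup1, aln$ingroup2, aln$outgroup),
                          strip_one)
  aln$ingroup1 <- purrr::map_chr(stripped, 1)
  aln$ingroup2 <- purrr::map_chr(stripped, 2)
  aln$outgroup <- purrr::map_chr(stripped, 3)
  empty <- nchar(aln$ingroup1) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d gene(s) with no translatable codons",
                 sum(empty)))
    aln <- aln[!empty, ]
  }
  aln
}

#' Count lineage-specific substitutions per gene
#'
#' NG86-style counting with outgroup polarization. Synonymous and
#' nonsynonymous site counts are averaged over the three sequences.
#' The ancestral base at each codon position is taken as the outgroup base
#' when it matches at least one ingroup; codons containing a position where
#' the outgroup matches neither ingroup are unassignable and excluded from
#' both sites and substitutions. Each ingroup's differences from the
#' inferred ancestral codon are classified synonymous/nonsynonymous by
#' averaging over minimal mutational pathways (stop-codon intermediates
#' excluded).
#'
#' @param aln Tibble of stripped codon alignments (see
#'   [strip_untranslatable_codons()]) with `gene_id`, `class`, sequence
#'   columns `ingroup1`, `ingroup2`, `outgroup`.
#' @return Tibble with one row per gene and lineage: `gene_id`, `class`,
#'   `lineage`, `Nd`, `Sd`, `N_sites`, `S_sites`.
#' @export
lineage_counts <- function(aln) {
  check_cols(aln, c("gene_id", "class", "ingroup1", "ingroup2", "outgroup"))
  tb <- codon_tables()
  one_gene <- function(s1, s2, so) {
    c1 <- seq_to_codons(s1)[1, ]
    c2 <- seq_to_codons(s2)[1, ]
    co <- seq_to_codons(so)[1, ]
    b1 <- tb$base_mat[c1, , drop = FALSE]
    b2 <- tb$base_mat[c2, , drop = FALSE]
    bo <- tb$base_mat[co, , drop = FALSE]
    anc_b <- ifelse(bo == b1 | bo == b2, bo, NA_integer_)
    assignable <- rowSums(is.na(anc_b)) == 0
    stops <- tb$aa[c1] == "*" | tb$aa[c2] == "*" | tb$aa[co] == "*"
    ok <- assignable & !stops
    if (!any(ok)) {
      return(c(S_sites = 0, N_sites = 0, Sd1 = 0, Nd1 = 0, Sd2 = 0, Nd2 = 0))
    }
    anc <- codon_index(anc_b[ok, 1], anc_b[ok, 2], anc_b[ok, 3])
    anc_ok <- tb$aa[anc] != "*"
    anc <- anc[anc_ok]
    u1 <- c1[ok][anc_ok]; u2 <- c2[ok][anc_ok]; uo <- co[ok][anc_ok]
    s_codon <- (tb$syn_sites[u1] + tb$syn_sites[u2] + tb$syn_sites[uo]) / 3
    n_codon <- (tb$non_sites[u1] + tb$non_sites[u2] + tb$non_sites[uo]) / 3
    S_sites <- sum(s_codon)
    N_sites <- sum(n_codon)
    d1 <- anc != u1
    d2 <- anc != u2
    c(S_sites = S_sites, N_sites = N_sites,
      Sd1 = sum(tb$syn_path[cbind(anc[d1], u1[d1])]),
      Nd1 = sum(tb$non_path[cbind(anc[d1], u1[d1])]),
      Sd2 = sum(tb$syn_path[cbind(anc[d2], u2[d2])]),
      Nd2 = sum(tb$non_path[cbind(anc[d2], u2[d2])]))
  }
  res <- purrr::pmap(list(aln$ingroup1, aln$ingroup2, aln$outgroup), one_gene)
  res <- do.call(rbind, res)
  dimnames(res) <- list(NULL, c("S_sites", "N_sites", "Sd1", "Nd1",
                                "Sd2", "Nd2"))
  dplyr::bind_rows(
    tibble::tibble(gene_id = aln$gene_id, class = aln$class,
                   lineage = "ingroup1", Nd = as.numeric(res[, "Nd1"]),
                   Sd = as.numeric(res[, "Sd1"]),
                   N_sites = as.numeric(res[, "N_sites"]),
                   S_sites = as.numeric(res[, "S_sites"])),
    tibble::tibble(gene_id = aln$gene_id, class = aln$class,
                   lineage = "ingroup2", Nd = as.numeric(res[, "Nd2"]),
                   Sd = as.numeric(res[, "Sd2"]),
                   N_sites = as.numeric(res[, "N_sites"]),
                   S_sites = as.numeric(res[, "S_sites"]))
  )
}

#' Pool per-gene substitution counts into overall dN, dS and dN/dS
#'
#' Counts are pooled before division (one overall estimate across genes,
#' not an average of per-gene ratios): `dN = sum(Nd) / sum(N_sites)`,
#' `dS = sum(Sd) / sum(S_sites)`, `omega = dN / dS`.
#'
#' @param counts Tibble from [lineage_counts()].
#' @return Tibble with one row per `lineage` x `class`: `n_genes`, `dN`,
#'   `dS`, `omega` (`omega` is `NA` when the pooled `Sd` is zero).
#' @export
pool_dnds <- function(counts) {
  check_cols(counts, c("lineage", "class", "Nd", "Sd", "N_sites", "S_sites"))
  counts |>
    dplyr::group_by(.data$lineage, .data$class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      dN = sum(.data$Nd) / sum(.data$N_sites),
      dS = sum(.data$Sd) / sum(.data$S_sites),
      omega = ifelse(sum(.data$Sd) > 0, .data$dN / .data$dS, NA_real_),
      .groups = "drop"
    )
}

#' Bootstrap confidence intervals for pooled dN, dS and dN/dS
#'
#' Resamples genes with replacement within each lineage x class group,
#' recomputes the pooled estimates, and reports percentile 2.5/97.5
#' bounds.
#'
#' @param counts Tibble from [lineage_counts()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Table-shaped tibble: `lineage`, `class`, `n_genes`, then `dN`,
#'   `dS`, `omega` each with `_lo`/`_hi` percentile bounds.
#' @export
bootstrap_genes <- function(counts, n_boot = 1000, seed = 1L) {
  check_cols(counts, c("lineage", "class", "Nd", "Sd", "N_sites", "S_sites"))
  point <- pool_dnds(counts)
  withr_seed(seed, {
    cis <- counts |>
      dplyr::group_by(.data$lineage, .data$class) |>
      dplyr::group_modify(function(g, key) {
        if (nrow(g) < 2) abort("need at least 2 genes per group to bootstrap")
        m <- as.matrix(g[, c("Nd", "Sd", "N_sites", "S_sites")])
        reps <- vapply(seq_len(n_boot), function(b) {
          s <- colSums(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE])
          dn <- s["Nd"] / s["N_sites"]
          ds <- s["Sd"] / s["S_sites"]
          c(dn, ds, if (s["Sd"] > 0) dn / ds else NA_real_)
        }, numeric(3))
        q <- apply(reps, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
        tibble::tibble(dN_lo = q[1, 1], dN_hi = q[2, 1],
                       dS_lo = q[1, 2], dS_hi = q[2, 2],
                       omega_lo = q[1, 3], omega_hi = q[2, 3])
      }) |>
      dplyr::ungroup()
  })
  dplyr::left_join(point, cis, by = c("lineage", "class")) |>
    dplyr::select("lineage", "class", "n_genes",
                  "dN", "dN_lo", "dN_hi",
                  "dS", "dS_lo", "dS_hi",
                  "omega", "omega_lo", "omega_hi")
}

#' Randomization tests for class and species contrasts
#'
#' Permutes gene labels and recomputes a contrast of pooled estimates,
#' giving a two-tailed permutation p-value with the add-one correction
#' `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`. Ratio statistics are
#' compared on the log scale.
#'
#' Statistics:
#' * `omega_diff` — difference of pooled dN/dS between the two groups;
#' * `dS_ratio` — ratio of pooled dS between the two groups;
#' * `omega_ratio_diff` — difference between lineages of the X/A dN/dS
#'   ratio (requires both lineages; permutes class within lineage pairs).
#'
#' With `permute = "class"` the chromosomal origin (X or autosome) of each
#' gene is shuffled; with `permute = "species"` the two lineages' counts
#' are swapped gene-wise with probability 1/2 (requires a single class).
#'
#' @param counts Tibble from [lineage_counts()], restricted as required by
#'   the statistic (a single lineage for `omega_diff`/`dS_ratio` with
#'   `permute = "class"`; a single class with `permute = "species"`).
#' @param statistic One of `"omega_diff"`, `"dS_ratio"`,
#'   `"omega_ratio_diff"`.
#' @param permute `"class"` or `"species"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `spx_randtest` with `statistic_observed`,
#'   `null_statistics`, `p_two_tailed`, `n_perm`.
#' @export
randomization_test <- function(counts,
                               statistic = c("omega_diff", "dS_ratio",
                                             "omega_ratio_diff"),
                               permute = c("class", "species"),
                               n_perm = 1000, seed = 1L) {
  statistic <- match.arg(statistic)
  permute <- match.arg(permute)
  check_cols(counts, c("gene_id", "class", "lineage", "Nd", "Sd",
                       "N_sites", "S_sites"))

  nd <- counts$Nd; sdv <- counts$Sd
  ns <- counts$N_sites; ss <- counts$S_sites
  genes <- unique(counts$gene_id)
  gidx <- match(counts$gene_id, genes)
  gene_class <- counts$class[match(genes, counts$gene_id)]

  pooled_w <- function(sel) {
    dsg <- sum(sdv[sel]) / sum(ss[sel])
    if (dsg == 0) return(NA_real_)
    (sum(nd[sel]) / sum(ns[sel])) / dsg
  }
  if (permute == "species" && statistic != "omega_diff") {
    abort("species permutation is defined for the omega_diff statistic")
  }
  if (permute == "species") {
    if (dplyr::n_distinct(counts$class) != 1) {
      abort("species permutation requires a single chromosome class")
    }
    lins <- sort(unique(counts$lineage))
    if (length(lins) != 2) abort("species permutation requires two lineages")
    stat_fn <- function(lin_vec) {
      pooled_w(lin_vec == lins[1]) - pooled_w(lin_vec == lins[2])
    }
  } else {
    if (statistic != "omega_ratio_diff" &&
        dplyr::n_distinct(counts$lineage) != 1) {
      abort("class permutation of this statistic requires a single lineage")
    }
    if (dplyr::n_distinct(counts$class) != 2) {
      abort("class permutation requires both chromosome classes")
    }
    lins <- sort(unique(counts$lineage))
    islin1 <- counts$lineage == lins[1]
    stat_fn <- switch(statistic,
      omega_diff = function(cls_vec) {
        pooled_w(cls_vec == "X") - pooled_w(cls_vec != "X")
      },
      dS_ratio = function(cls_vec) {
        isx <- cls_vec == "X"
        dsx <- sum(sdv[isx]) / sum(ss[isx])
        dsa <- sum(sdv[!isx]) / sum(ss[!isx])
        if (dsx == 0 || dsa == 0) return(NA_real_)
        dsx / dsa
      },
      omega_ratio_diff = function(cls_vec) {
        if (length(lins) != 2) return(NA_real_)
        isx <- cls_vec == "X"
        (pooled_w(islin1 & isx) / pooled_w(islin1 & !isx)) -
          (pooled_w(!islin1 & isx) / pooled_w(!islin1 & !isx))
      })
  }

  obs <- if (permute == "species") stat_fn(counts$lineage) else
    stat_fn(counts$class)
  withr_seed(seed, {
    null <- vapply(seq_len(n_perm), function(p) {
      if (permute == "class") {
        # permute gene-level class labels, consistently across lineages
        stat_fn(sample(gene_class)[gidx])
      } else {
        flip <- sample(c(TRUE, FALSE), length(genes), replace = TRUE)[gidx]
        lin_vec <- counts$lineage
        lin_vec[flip] <- ifelse(lin_vec[flip] == lins[1], lins[2], lins[1])
        stat_fn(lin_vec)
      }
    }, numeric(1))
  })
  if (mean(is.na(null)) > 0.10 || is.na(obs)) {
    abort("statistic undefined in more than 10% of permutations")
  }
  is_ratio <- statistic == "dS_ratio"
  cmp_obs <- if (is_ratio) abs(log(obs)) else abs(obs)
  cmp_null <- if (is_ratio) abs(log(null)) else abs(null)
  p <- (1 + sum(cmp_null >= cmp_obs, na.rm = TRUE)) / (n_perm + 1)
  structure(list(statistic_observed = obs, null_statistics = null,
                 p_two_tailed = p, n_perm = n_perm,
                 statistic = statistic, permute = permute),
            class = "spx_randtest")
}

#' @export
print.spx_randtest <- function(x, ...) {
  cat(sprintf("Randomization test (%s, permuting %s)\n", x$statistic,
              x$permute))
  cat(sprintf("  observed: %.4g   p (two-tailed, %d perms): %.4g\n",
              x$statistic_observed, x$n_perm, x$p_two_tailed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spx_randtest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic,
                 estimate = x$statistic_observed,
                 p.value = x$p_two_tailed,
                 n_perm = x$n_perm,
                 permuted = x$permute)
}

#' @exportS3Method generics::glance
glance.spx_randtest <- function(x, ...) tidy(x)

#' Derived contrasts between chromosome classes and lineages
#'
#' From a table of pooled estimates, emits the X/A synonymous-divergence
#' ratio and X/A dN/dS ratio (with percent increase) per lineage, and the
#' between-lineage percent increase in dN/dS per class.
#'
#' @param summaries Tibble with columns `lineage`, `class`, `dN`, `dS`,
#'   `omega` (e.g. from [pool_dnds()] or [bootstrap_genes()]).
#' @return Tibble with `contrast`, `lineage`/`class` context columns and
#'   `value`.
#' @export
contrast_report <- function(summaries) {
  check_cols(summaries, c("lineage", "class", "dS", "omega"))
  per_lineage <- summaries |>
    dplyr::group_by(.data$lineage) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(
      dS_ratio_XA = .data$dS[.data$class == "X"] /
        .data$dS[.data$class != "X"],
      omega_ratio_XA = .data$omega[.data$class == "X"] /
        .data$omega[.data$class != "X"],
      .groups = "drop"
    ) |>
    dplyr::mutate(omega_increase_pct = 100 * (.data$omega_ratio_XA - 1)) |>
    tidyr::pivot_longer(-"lineage", names_to = "contrast",
                        values_to = "value")
  lins <- sort(unique(summaries$lineage))
  per_class <- if (length(lins) == 2) {
    both <- summaries |>
      dplyr::group_by(.data$class) |>
      dplyr::filter(dplyr::n() == 2)
    dplyr::bind_rows(
      both |>
        dplyr::summarise(
          value = 100 * (.data$omega[.data$lineage == lins[1]] /
                           .data$omega[.data$lineage == lins[2]] - 1),
          .groups = "drop") |>
        dplyr::mutate(contrast = sprintf("omega_increase_pct_%s_vs_%s",
                                         lins[1], lins[2])),
      both |>
        dplyr::summarise(
          value = 100 * (.data$omega[.data$lineage == lins[2]] /
                           .data$omega[.data$lineage == lins[1]] - 1),
          .groups = "drop") |>
        dplyr::mutate(contrast = sprintf("omega_increase_pct_%s_vs_%s",
                                         lins[2], lins[1]))
    )
  } else NULL
  dplyr::bind_rows(per_lineage, per_class)
}
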