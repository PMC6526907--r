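#' Nei nucleotide diversity of an alignment
#'
#' Average per-site pairwise difference over all sequence pairs, with
#' pairwise deletion: each pair's denominator counts only positions where
#' both members carry an unambiguous base (gaps and Ns are excluded for
#' that pair only). This is the classic Nei & Li estimator as computed by
#' `ape`'s raw pairwise distances.
#'
#' @param aln A named character vector of equal-length sequences, a
#'   character matrix (one row per sequence), or an `ape::DNAbin` matrix.
#' @return A one-row tibble with `pi` (per site) and `n_sites` (alignment
#'   width); `pi` is `NA` when no pair has comparable sites.
#' @export
nei_pi <- function(aln) {
  bin <- as_dnabin(aln)
  if (nrow(bin) < 2) abort("need at least 2 sequences")
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  pi <- if (all(is.nan(d))) NA_real_ else mean(d[!is.nan(d)])
  tibble::tibble(pi = pi, n_sites = ncol(bin))
}

#' @noRd
as_dnabin <- function(aln) {
  if (inherits(aln, "DNAbin")) return(as.matrix(aln))
  if (is.character(aln) && is.null(dim(aln))) {
    n <- unique(nchar(aln))
    if (length(n) != 1) abort("sequences must have equal length")
    aln <- matrix(unlist(strsplit(tolower(aln), "")), nrow = length(aln),
                  byrow = TRUE)
  }
  ape::as.DNAbin(tolower(aln))
}

#' Concatenate RAD loci into equal-length subalignments
#'
#' Per population and chromosome class, concatenates locus alignments in a
#' deterministic order (scaffold, then position), writing gap rows for
#' individuals missing at a locus. The universal block length `L` is set
#' so the population with the smallest X-chromosome coverage has
#' `target_min_blocks` blocks (`L = floor(min X total length /
#' target_min_blocks)`), identical across all populations and classes.
#' Every concatenated set is cut into `floor(total / L)` blocks; the
#' remainder is discarded. Sets shorter than `L` are excluded with a
#' warning.
#'
#' @param loci Tibble as produced by [gen_population_rad()]: columns
#'   `population`, `locus_id`, `scaffold_id`, `position`, `class`, `aln`.
#' @param target_min_blocks Number of blocks for the most shallowly
#'   covered X set.
#' @return Tibble with `population`, `class`, `block`, list-column `aln`,
#'   and attribute `block_len` (the universal `L`).
#' @export
build_subalignments <- function(loci, target_min_blocks = 15) {
  check_cols(loci, c("population", "scaffold_id", "position", "class",
                     "aln"))
  widths <- loci |>
    dplyr::mutate(w = purrr::map_int(.data$aln,
                                     ~ nchar(.x[[1]]))) |>
    dplyr::group_by(.data$population, .data$class) |>
    dplyr::summarise(total = sum(.data$w), .groups = "drop")
  x_tot <- dplyr::filter(widths, .data$class == "X")
  if (nrow(x_tot) == 0) abort("no X-class loci present")
  L <- floor(min(x_tot$total) / target_min_blocks)
  if (L < 1) abort("X coverage too small for the requested block count")

  sets <- loci |>
    dplyr::arrange(.data$population, .data$class, .data$scaffold_id,
                   .data$position) |>
    dplyr::group_by(.data$population, .data$class)
  out <- sets |>
    dplyr::group_map(function(g, key) {
      cat_aln <- concat_alignments(g$aln)
      total <- nchar(cat_aln[[1]])
      nb <- floor(total / L)
      if (nb < 1) {
        warn(sprintf("set %s/%s shorter than one block; excluded",
                     key$population, key$class))
        return(NULL)
      }
      blocks <- purrr::map(seq_len(nb), function(b) {
        vapply(cat_aln, substr, character(1), (b - 1) * L + 1, b * L)
      })
      tibble::tibble(population = key$population, class = key$class,
                     block = seq_len(nb), aln = blocks)
    }) |>
    dplyr::bind_rows()
  attr(out, "block_len") <- L
  out
}

# concatenate a list of named sequence vectors, filling gap rows for
# missing individuals
#' @noRd
concat_alignments <- function(alns) {
  all_names <- sort(unique(unlist(purrr::map(alns, names))))
  pieces <- purrr::map(alns, function(a) {
    w <- nchar(a[[1]])
    out <- setNames(rep(strrep("-", w), length(all_names)), all_names)
    out[names(a)] <- unname(a)
    out
  })
  do.call(paste0, pieces) |> setNames(all_names)
}

#' Bootstrap the mean diversity over subalignment blocks
#'
#' @param pi_values Numeric vector of per-block pi (or a tibble with a
#'   `pi` column).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return One-row tibble: `mean_pi`, `ci_low`, `ci_high`, `n_blocks`.
#' @export
bootstrap_pi <- function(pi_values, n_boot = 10000, seed = 1L) {
  if (is.data.frame(pi_values)) pi_values <- pi_values$pi
  pi_values <- pi_values[!is.na(pi_values)]
  if (length(pi_values) < 2) abort("need at least 2 blocks")
  ci <- boot_percentile(length(pi_values), n_boot,
                        function(idx) mean(pi_values[idx]), seed)
  tibble::tibble(mean_pi = mean(pi_values), ci_low = ci[1], ci_high = ci[2],
                 n_blocks = length(pi_values))
}

#' Per-scaffold diversity for scaffolds with enough RAD loci
#'
#' Concatenates each scaffold's loci and computes Nei pi, keeping
#' scaffolds with at least `min_loci` loci.
#'
#' @param loci Tibble as in [build_subalignments()], for one population.
#' @param min_loci Minimum loci per scaffold.
#' @return Tibble `scaffold_id`, `class`, `n_loci`, `pi`.
#' @export
scaffold_pi <- function(loci, min_loci = 3) {
  check_cols(loci, c("scaffold_id", "class", "aln"))
  loci |>
    dplyr::group_by(.data$scaffold_id, .data$class) |>
    dplyr::filter(dplyr::n() >= min_loci) |>
    dplyr::group_modify(function(g, key) {
      cat_aln <- concat_alignments(g$aln)
      dplyr::mutate(nei_pi(cat_aln), n_loci = nrow(g))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("scaffold_id", "class", "n_loci", "pi")
}

#' Coefficient of variation of per-scaffold diversity
#'
#' CV = sample standard deviation / mean, with a bootstrap percentile CI
#' over scaffolds. Undefined (flagged `NA`) when the mean is zero, as
#' happens when diversity is saturated at zero.
#'
#' @param values Numeric vector of per-scaffold pi (or tibble with `pi`).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return One-row tibble: `cv`, `ci_low`, `ci_high`, `n`.
#' @export
scaffold_cv <- function(values, n_boot = 1000, seed = 1L) {
  if (is.data.frame(values)) values <- values$pi
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 scaffolds")
  if (mean(values) == 0) {
    warn("mean diversity is zero; CV undefined")
    return(tibble::tibble(cv = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n = length(values)))
  }
  cv_fn <- function(x) sd(x) / mean(x)
  ci <- boot_percentile(length(values), n_boot,
                        function(idx) cv_fn(values[idx]), seed)
  tibble::tibble(cv = cv_fn(values), ci_low = ci[1], ci_high = ci[2],
                 n = length(values))
}

#' Pair X subalignments with grouped autosomal subalignments
#'
#' Shuffles the autosomal blocks into as many near-equal groups as there
#' are X blocks, takes each group's median pi (the autosomal pi
#' distribution is strongly skewed when many blocks have zero diversity),
#' and pairs groups randomly with the X blocks, yielding independent
#' piX/piA ratio replicates.
#'
#' @param x_pi Numeric vector of per-X-block pi.
#' @param a_pi Numeric vector of per-autosomal-block pi (at least as many
#'   as `x_pi`).
#' @param seed Integer seed for the grouping and pairing.
#' @return Tibble `pair`, `x_value`, `a_value`, `ratio`. Pairs whose
#'   autosomal group median is zero are dropped with a warning.
#' @export
pair_pix_pia <- function(x_pi, a_pi, seed = 1L) {
  if (is.data.frame(x_pi)) x_pi <- x_pi$pi
  if (is.data.frame(a_pi)) a_pi <- a_pi$pi
  nx <- length(x_pi)
  if (nx < 2 || length(a_pi) < nx) {
    abort("need at least 2 X blocks and at least as many autosomal blocks")
  }
  withr_seed(seed, {
    grp <- sample(rep_len(seq_len(nx), length(a_pi)))
    a_median <- tapply(sample(a_pi), grp, median)
    pairing <- sample.int(nx)
  })
  out <- tibble::tibble(pair = seq_len(nx), x_value = x_pi,
                        a_value = as.numeric(a_median[pairing])) |>
    dplyr::mutate(ratio = .data$x_value / .data$a_value)
  drop <- out$a_value == 0
  if (any(drop)) {
    warn(sprintf("dropping %d pair(s) with zero autosomal group median",
                 sum(drop)))
    out <- out[!drop, ]
  }
  out
}

#' Mixed-model test of a species difference in piX/piA
#'
#' Fits `ratio ~ species + (1 | population)` by maximum likelihood and
#' compares it with the no-species model by likelihood ratio (chi-square,
#' 1 df). With a singular fit (zero estimated population variance) the
#' test falls back to a two-sample t-test on population means, which is
#' reported in the `method` column.
#'
#' @param ratios Tibble with numeric `ratio` and factors/labels `species`
#'   and `population` (at least 2 populations per species).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
species_ratio_test <- function(ratios) {
  check_cols(ratios, c("ratio", "species", "population"))
  if (dplyr::n_distinct(ratios$species) != 2) {
    abort("need exactly 2 species")
  }
  npop <- ratios |>
    dplyr::distinct(.data$species, .data$population) |>
    dplyr::count(.data$species)
  if (any(npop$n < 2)) abort("need at least 2 populations per species")
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(ratio ~ species + (1 | population), data = ratios,
               REML = FALSE)))
  if (lme4::isSingular(full)) {
    inform("singular mixed fit; falling back to a t-test on population means")
    pm <- ratios |>
      dplyr::group_by(.data$species, .data$population) |>
      dplyr::summarise(m = mean(.data$ratio), .groups = "drop")
    tt <- t.test(m ~ species, data = pm)
    return(tibble::tibble(statistic = unname(tt$statistic),
                          df = unname(tt$parameter),
                          p_value = tt$p.value,
                          method = "t-test on population means"))
  }
  null <- suppressMessages(suppressWarnings(
    lme4::lmer(ratio ~ 1 + (1 | population), data = ratios, REML = FALSE)))
  lrt <- anova(null, full)
  tibble::tibble(statistic = lrt$Chisq[2], df = lrt$Df[2],
                 p_value = lrt$`Pr(>Chisq)`[2],
                 method = "likelihood ratio, mixed model")
}

#' One-way F-test and Tukey HSD letters for populations within a species
#'
#' @param ratios Tibble with numeric `ratio` and a `population` label.
#' @return A list with `anova` (one-row tibble: `f`, `df1`, `df2`,
#'   `p_value`), `tukey` (pairwise comparisons), and `letters` (compact
#'   letter display per population).
#' @export
population_ratio_test <- function(ratios) {
  check_cols(ratios, c("ratio", "population"))
  if (dplyr::n_distinct(ratios$population) < 2) {
    abort("need at least 2 populations")
  }
  ratios$population <- factor(ratios$population)
  fit <- aov(ratio ~ population, data = ratios)
  sm <- summary(fit)[[1]]
  out_anova <- tibble::tibble(f = sm$`F value`[1], df1 = sm$Df[1],
                              df2 = sm$Df[2], p_value = sm$`Pr(>F)`[1])
  tk <- TukeyHSD(fit)$population
  tukey <- tibble::tibble(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"])
  letters <- cld_letters(levels(ratios$population), tukey)
  list(anova = out_anova, tukey = tukey, letters = letters)
}

# compact letter display by insert-and-absorb on the non-significant pairs
#' @noRd
cld_letters <- function(groups, tukey, alpha = 0.05) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(tukey))) {
    gg <- strsplit(tukey$comparison[i], "-", fixed = TRUE)[[1]]
    if (!is.na(tukey$p_adj[i]) && tukey$p_adj[i] < alpha) {
      sig[gg[1], gg[2]] <- sig[gg[2], gg[1]] <- TRUE
    }
  }
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(sig[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g); placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb sets contained in others
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && all(sets[[i]] %in% sets[[j]])) keep[i] <- FALSE
  }
  sets <- sets[keep]
  lab <- vapply(groups, function(g) {
    paste(letters[which(purrr::map_lgl(sets, ~ g %in% .x))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(population = groups, letters = lab)
}

#' Plot per-population diversity by chromosome class
#'
#' @param pi_table Tibble with `population`, `class`, `mean_pi`, `ci_low`,
#'   `ci_high` (e.g. [bootstrap_pi()] applied per population and class).
#' @return A ggplot object.
#' @export
plot_diversity <- function(pi_table) {
  check_cols(pi_table, c("population", "class", "mean_pi"))
  ggplot2::ggplot(pi_table,
                  ggplot2::aes(x = .data$population, y = .data$mean_pi,
                               fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::labs(x = "Population", y = expression(pi), fill = "Class") +
    ggplot2::theme_minimal()
}
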