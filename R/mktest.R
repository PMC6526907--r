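#' Classify a coding variant as synonymous or nonsynonymous
#'
#' Substitutes the alternate base into the reference codon and compares
#' amino acids. Stop-gain and stop-loss changes are classed `"other"` and
#' are excluded from McDonald-Kreitman counts. Vectorized over positions.
#'
#' @param cds_sequence In-frame CDS string (starting at codon position 1).
#' @param position 0-based position(s) of the variant within the CDS.
#' @param alt_base Alternate base(s), A/C/G/T.
#' @return Character vector: `"synonymous"`, `"nonsynonymous"` or
#'   `"other"`; `NA` (with a warning) where the reference codon is
#'   ambiguous.
#' @export
classify_variant <- function(cds_sequence, position, alt_base) {
  ch <- strsplit(toupper(cds_sequence), "")[[1]]
  if (any(position < 0 | position >= length(ch))) {
    abort("position outside the CDS")
  }
  tb <- codon_tables()
  codon_i <- position %/% 3L
  offset <- position %% 3L
  out <- character(length(position))
  for (v in seq_along(position)) {
    cod <- ch[(codon_i[v] * 3 + 1):(codon_i[v] * 3 + 3)]
    if (!all(cod %in% .spx_bases)) {
      warn(sprintf("ambiguous reference codon at position %d; variant skipped",
                   position[v]))
      out[v] <- NA_character_
      next
    }
    alt <- toupper(alt_base[if (length(alt_base) == 1) 1 else v])
    ref_idx <- codon_index(match(cod[1], .spx_bases) - 1L,
                           match(cod[2], .spx_bases) - 1L,
                           match(cod[3], .spx_bases) - 1L)
    cod2 <- cod
    cod2[offset[v] + 1] <- alt
    alt_idx <- codon_index(match(cod2[1], .spx_bases) - 1L,
                           match(cod2[2], .spx_bases) - 1L,
                           match(cod2[3], .spx_bases) - 1L)
    aa_ref <- tb$aa[ref_idx]; aa_alt <- tb$aa[alt_idx]
    out[v] <- if (aa_ref == "*" || aa_alt == "*") {
      "other"
    } else if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  }
  out
}

#' McDonald-Kreitman alpha from a count table
#'
#' `alpha = 1 - (Ds * Pn) / (Dn * Ps)`, the proportion of substitutions
#' fixed by adaptive evolution; the neutrality index is
#' `(Pn/Ps) / (Dn/Ds)`. Negative alpha indicates an excess of (slightly
#' deleterious) nonsynonymous polymorphism.
#'
#' @param table Tibble with columns `class`, `Pn`, `Ps`, `Dn`, `Ds` (one
#'   row per chromosome class).
#' @return The table with `neutrality_index` and `alpha` appended
#'   (`NA` where `Ps` or `Dn` is zero).
#' @export
mk_alpha <- function(table) {
  check_cols(table, c("Pn", "Ps", "Dn", "Ds"))
  if (any(table[c("Pn", "Ps", "Dn", "Ds")] < 0)) {
    abort("counts must be non-negative")
  }
  table |>
    dplyr::mutate(
      neutrality_index = ifelse(.data$Ps > 0 & .data$Dn > 0 & .data$Ds > 0,
                                (.data$Pn / .data$Ps) /
                                  (.data$Dn / .data$Ds), NA_real_),
      alpha = 1 - .data$neutrality_index
    )
}

#' Build McDonald-Kreitman tables from variants and divergence counts
#'
#' Filters variants to those inside annotated CDS with coverage at least
#' `min_cov`, classifies each against the CDS reference codon, counts
#' synonymous/nonsynonymous polymorphisms per chromosome class, and joins
#' the per-class divergence counts.
#'
#' @param variants Tibble: `scaffold_id`, `pos` (1-based), `ref`, `alt`,
#'   `dp` (coverage).
#' @param divergence Tibble: `class`, `Dn`, `Ds`.
#' @param cds Tibble: `gene`, `scaffold_id`, `start`, `end` (1-based
#'   inclusive), `strand` (only `"+"` supported), plus a named character
#'   vector of CDS sequences in `attr(cds, "sequences")` or a `sequence`
#'   column.
#' @param class_map Tibble: `scaffold_id`, `class`.
#' @param min_cov Minimum coverage for a polymorphism to be counted.
#' @return Tibble with `class`, `Pn`, `Ps`, `Dn`, `Ds`.
#' @export
build_mk_tables <- function(variants, divergence, cds, class_map,
                            min_cov = 10) {
  check_cols(variants, c("scaffold_id", "pos", "ref", "alt", "dp"))
  check_cols(divergence, c("class", "Dn", "Ds"))
  check_cols(class_map, c("scaffold_id", "class"))
  seqs <- attr(cds, "sequences")
  if (is.null(seqs) && "sequence" %in% names(cds)) {
    seqs <- setNames(cds$sequence, cds$gene)
  }
  if (is.null(seqs)) abort("cds must carry its sequences")
  v <- variants |>
    dplyr::filter(.data$dp >= min_cov) |>
    dplyr::inner_join(
      dplyr::select(cds, "gene", "scaffold_id", "start", "end"),
      by = "scaffold_id", relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    dplyr::mutate(cds_pos = .data$pos - .data$start) |>
    dplyr::left_join(class_map, by = "scaffold_id")
  if (nrow(v) > 0) {
    v$kind <- purrr::pmap_chr(
      list(v$gene, v$cds_pos, v$alt),
      function(g, p, a) classify_variant(seqs[[g]], p, a))
  } else {
    v$kind <- character(0)
  }
  pol <- v |>
    dplyr::filter(.data$kind %in% c("synonymous", "nonsynonymous")) |>
    dplyr::count(.data$class, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n",
                       values_fill = 0L)
  for (col in c("synonymous", "nonsynonymous")) {
    if (!col %in% names(pol)) pol[[col]] <- 0L
  }
  divergence |>
    dplyr::left_join(pol, by = "class") |>
    dplyr::mutate(Pn = dplyr::coalesce(.data$nonsynonymous, 0L),
                  Ps = dplyr::coalesce(.data$synonymous, 0L)) |>
    dplyr::select("class", "Pn", "Ps", "Dn", "Ds")
}
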