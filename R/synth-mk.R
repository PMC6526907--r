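#' Generate a synthetic dataset with exact McDonald-Kreitman counts
#'
#' Builds, per chromosome class, a synthetic CDS, a polymorphism table and
#' a divergence table whose classified counts reproduce the requested
#' `Pn`, `Ps`, `Dn`, `Ds` exactly. Each polymorphism occupies its own
#' glycine (GGC) codon: synonymous variants are third-position C>T
#' changes, nonsynonymous variants first-position G>A (Gly>Ser); no
#' variant creates a stop codon.
#'
#' @param counts Tibble with columns `class`, `pn`, `ps`, `dn`, `ds`
#'   (all non-negative integers).
#' @param coverage Read depth written to every variant record.
#' @return A list with `variants`, `divergence`, `cds` (annotation tibble
#'   carrying sequences) and `class_map`, ready for [build_mk_tables()].
#' @export
gen_mk_dataset <- function(counts, coverage = 30L) {
  check_cols(counts, c("class", "pn", "ps", "dn", "ds"))
  if (any(counts[c("pn", "ps", "dn", "ds")] < 0)) {
    abort("all counts must be non-negative")
  }
  if (any(counts[c("pn", "ps", "dn", "ds")] !=
          round(counts[c("pn", "ps", "dn", "ds")]))) {
    abort("counts must be integers")
  }
  gene_start <- 101L
  per_class <- purrr::pmap(counts, function(class, pn, ps, dn, ds, ...) {
    n_codons <- pn + ps
    scaffold <- paste0("scaffold_", class)
    gene <- paste0("gene_", class)
    cds_seq <- paste0("ATG", strrep("GGC", n_codons))
    # variant codons: first `pn` codons nonsynonymous, remainder synonymous
    cds_pos_non <- if (pn > 0) 3L + (seq_len(pn) - 1L) * 3L else integer(0)
    cds_pos_syn <- if (ps > 0) 3L + (pn + seq_len(ps) - 1L) * 3L + 2L else
      integer(0)
    variants <- tibble::tibble(
      scaffold_id = scaffold,
      pos = gene_start + c(cds_pos_non, cds_pos_syn),
      ref = c(rep("G", pn), rep("C", ps)),
      alt = c(rep("A", pn), rep("T", ps)),
      dp = as.integer(coverage)
    )
    cds <- tibble::tibble(gene = gene, scaffold_id = scaffold,
                          start = gene_start,
                          end = gene_start + nchar(cds_seq) - 1L,
                          strand = "+", sequence = cds_seq)
    list(variants = variants, cds = cds,
         divergence = tibble::tibble(class = class, Dn = dn, Ds = ds),
         class_map = tibble::tibble(scaffold_id = scaffold, class = class))
  })
  list(
    variants = dplyr::bind_rows(purrr::map(per_class, "variants")),
    divergence = dplyr::bind_rows(purrr::map(per_class, "divergence")),
    cds = dplyr::bind_rows(purrr::map(per_class, "cds")),
    class_map = dplyr::bind_rows(purrr::map(per_class, "class_map"))
  )
}
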