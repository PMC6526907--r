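# IUPAC two-base ambiguity codes
.spx_iupac2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
.spx_iupac_split <- list(M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                         S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))

#' Call a consensus sequence from pileup base counts
#'
#' Coverage rules: positions with depth below `mask_lo` or between
#' `mask_lo` and `mask_hi` are masked as N; positions with depth at least
#' `min_call` get the majority base, upgraded to the two-base IUPAC code
#' when the strongest minority base is supported by at least `amb_reads`
#' reads or by a frequency above `amb_frac` (inclusive OR by default; set
#' `rule = "and"` for the conjunctive reading). If more than one minority
#' base qualifies the position is masked as N with a warning.
#'
#' @param columns Tibble (or data frame) with integer columns `A`, `C`,
#'   `G`, `T` of per-position base counts, in positional order.
#' @param min_call Minimum depth to call a base.
#' @param mask_lo,mask_hi Depth band masked as N (below `mask_lo` is also
#'   masked).
#' @param amb_reads,amb_frac Minority-base support thresholds for calling
#'   an ambiguity.
#' @param rule `"or"` (default) or `"and"` combination of the two
#'   minority-support conditions.
#' @param source_id Identifier carried into the result.
#' @return A one-row tibble: `source_id`, `sequence`,
#'   `ambiguous_fraction` (IUPAC symbols only, Ns excluded), `length`.
#' @export
call_consensus <- function(columns, min_call = 8, mask_lo = 3, mask_hi = 7,
                           amb_reads = 3, amb_frac = 0.10,
                           rule = c("or", "and"), source_id = "consensus") {
  rule <- match.arg(rule)
  check_cols(columns, c("A", "C", "G", "T"))
  if (nrow(columns) == 0) abort("pileup is empty")
  cnt <- as.matrix(columns[, c("A", "C", "G", "T")])
  depth <- rowSums(cnt)
  seq_out <- character(nrow(cnt))
  for (i in seq_len(nrow(cnt))) {
    if (depth[i] < min_call) { seq_out[i] <- "N"; next }
    ord <- order(cnt[i, ], decreasing = TRUE)
    major <- .spx_bases[ord[1]]
    minor_counts <- cnt[i, ord[-1]]
    minor_frac <- minor_counts / depth[i]
    qual <- if (rule == "or") {
      minor_counts >= amb_reads | minor_frac > amb_frac
    } else {
      minor_counts >= amb_reads & minor_frac > amb_frac
    }
    qual <- qual & minor_counts > 0
    if (!any(qual)) {
      seq_out[i] <- major
    } else if (sum(qual) == 1) {
      second <- .spx_bases[ord[-1]][qual]
      pair <- paste(sort(c(major, second)), collapse = "")
      seq_out[i] <- .spx_iupac2[[pair]]
    } else {
      warn(sprintf("position %d: more than 2 bases pass the ambiguity rule",
                   i))
      seq_out[i] <- "N"
    }
  }
  sequence <- paste(seq_out, collapse = "")
  n_amb <- sum(!seq_out %in% c(.spx_bases, "N"))
  tibble::tibble(source_id = source_id, sequence = sequence,
                 ambiguous_fraction = n_amb / length(seq_out),
                 length = length(seq_out))
}

#' Keep or discard a consensus by its ambiguous-base fraction
#'
#' @param seq A one-row tibble from [call_consensus()] (or any tibble with
#'   `ambiguous_fraction`), or a raw sequence string.
#' @param max_frac Discard when the IUPAC fraction is `>= max_frac`.
#' @return Logical: `TRUE` to keep.
#' @export
filter_ambiguous <- function(seq, max_frac = 0.025) {
  frac <- if (is.character(seq)) {
    ch <- strsplit(toupper(seq), "")[[1]]
    sum(!ch %in% c(.spx_bases, "N")) / length(ch)
  } else {
    seq$ambiguous_fraction
  }
  frac < max_frac
}

#' Collapse identical reads into stacks
#'
#' Exact-identity grouping of equal-length reads; stacks supported by
#' fewer than `min_copies` identical reads are dropped.
#'
#' @param reads Character vector of equal-length reads.
#' @param min_copies Minimum stack size retained.
#' @return Tibble `sequence`, `count`, sorted by decreasing count then
#'   sequence.
#' @export
find_stacks <- function(reads, min_copies = 3) {
  if (length(reads) == 0) {
    return(tibble::tibble(sequence = character(), count = integer()))
  }
  if (length(unique(nchar(reads))) != 1) {
    abort("reads must have equal length")
  }
  tb <- table(reads)
  out <- tibble::tibble(sequence = names(tb), count = as.integer(tb)) |>
    dplyr::filter(.data$count >= min_copies) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  out
}

#' Greedy centroid clustering of stacks into a RAD reference
#'
#' Stacks (from all conspecific individuals, pooled) are visited in order
#' of decreasing total count (ties broken by sequence); each joins the
#' first existing centroid with identity strictly above `min_identity`
#' (matching columns / length over ungapped equal-length sequences), or
#' founds a new cluster. One representative (the centroid) per cluster.
#'
#' @param stacks Tibble `sequence`, `count` (counts are summed over
#'   duplicate sequences).
#' @param min_identity Identity threshold, default 0.98.
#' @return Tibble `sequence` (centroid), `count` (summed over members),
#'   `n_members`, `cluster`.
#' @export
cluster_references <- function(stacks, min_identity = 0.98) {
  check_cols(stacks, c("sequence", "count"))
  stacks <- stacks |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  if (nrow(stacks) == 0) {
    return(tibble::tibble(sequence = character(), count = integer(),
                          n_members = integer(), cluster = integer()))
  }
  if (length(unique(nchar(stacks$sequence))) != 1) {
    abort("sequences must have equal length")
  }
  len <- nchar(stacks$sequence[1])
  cent_mat <- NULL # centroid base matrix, one row per centroid
  centroids <- integer(0)
  assign_to <- integer(nrow(stacks))
  seq_mat <- matrix(unlist(strsplit(stacks$sequence, "")),
                    nrow = nrow(stacks), byrow = TRUE)
  for (i in seq_len(nrow(stacks))) {
    hit <- 0L
    if (length(centroids)) {
      ident <- rowMeans(cent_mat == matrix(seq_mat[i, ], nrow(cent_mat),
                                           len, byrow = TRUE))
      w <- which(ident > min_identity)
      if (length(w)) hit <- w[1]
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      cent_mat <- rbind(cent_mat, seq_mat[i, ])
      hit <- length(centroids)
    }
    assign_to[i] <- hit
  }
  stacks |>
    dplyr::mutate(cluster = assign_to) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(sequence = .data$sequence[1],
                     count = sum(.data$count),
                     n_members = dplyr::n(), .groups = "drop") |>
    dplyr::select("sequence", "count", "n_members", "cluster")
}

#' Remove duplicate reference sequences mapping to the same position
#'
#' Keeps exactly one representative per (scaffold, position, strand): the
#' one with the highest total stack count, ties broken by the
#' lexicographically smallest sequence.
#'
#' @param refs Tibble `sequence`, `count`, `scaffold_id`, `position`,
#'   `strand`.
#' @return The deduplicated tibble.
#' @export
dedup_by_position <- function(refs) {
  check_cols(refs, c("sequence", "count", "scaffold_id", "position",
                     "strand"))
  refs |>
    dplyr::group_by(.data$scaffold_id, .data$position, .data$strand) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Split a consensus with IUPAC ambiguities into two phased alleles
#'
#' Each two-base IUPAC position contributes one base to each allele
#' (phase is arbitrary: the alphabetically first base goes to allele 1);
#' unambiguous positions (including N) are copied to both alleles.
#' Three-base ambiguity codes cannot be diploid-phased and raise an error.
#'
#' @param sequence Consensus sequence string (or one-row tibble from
#'   [call_consensus()]).
#' @return Character vector of the two allele sequences.
#' @export
call_alleles <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  ch <- strsplit(toupper(sequence), "")[[1]]
  bad <- !ch %in% c(.spx_bases, "N", names(.spx_iupac_split))
  if (any(bad)) {
    abort(sprintf("cannot phase symbol(s): %s",
                  paste(unique(ch[bad]), collapse = ", ")))
  }
  a1 <- ch; a2 <- ch
  amb <- ch %in% names(.spx_iupac_split)
  if (any(amb)) {
    pairs <- .spx_iupac_split[ch[amb]]
    a1[amb] <- purrr::map_chr(pairs, 1)
    a2[amb] <- purrr::map_chr(pairs, 2)
  }
  c(paste(a1, collapse = ""), paste(a2, collapse = ""))
}
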