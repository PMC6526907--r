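#' Read a sorted-pool read-count table
#'
#' Tab-separated with columns `scaffold_id`, `length`, `reads_pool0`,
#' `reads_poolX` (extra columns kept).
#'
#' @param path File path.
#' @return A tibble of pool counts.
#' @export
read_pool_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(out, c("scaffold_id", "reads_pool0", "reads_poolX"),
             "pool counts file")
  out
}

#' Write an assignment table, optionally with a BED companion
#'
#' The BED file uses 0-based half-open whole-scaffold intervals with the
#' assignment label in the name column.
#'
#' @param assignment Tibble from [assign_scaffolds()].
#' @param path Output TSV path.
#' @param bed_path Optional BED output path; requires `lengths`.
#' @param lengths Named vector (or tibble with `scaffold_id`, `length`)
#'   of scaffold lengths for the BED intervals.
#' @return Invisibly, `assignment`.
#' @export
write_assignment <- function(assignment, path, bed_path = NULL,
                             lengths = NULL) {
  readr::write_tsv(assignment, path)
  if (!is.null(bed_path)) {
    if (is.null(lengths)) abort("BED output requires scaffold lengths")
    if (is.data.frame(lengths)) {
      lengths <- setNames(lengths$length, lengths$scaffold_id)
    }
    bed <- tibble::tibble(chrom = assignment$scaffold_id,
                          start = 0L,
                          end = as.integer(lengths[assignment$scaffold_id]),
                          name = assignment$label)
    readr::write_tsv(bed, bed_path, col_names = FALSE)
  }
  invisible(assignment)
}
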