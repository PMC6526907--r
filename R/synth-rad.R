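#' Specification for synthetic RAD population data
#'
#' Parameters for simulating per-population, per-locus multi-individual
#' alignments of short RAD loci with known per-site diversity. Loci are
#' independent (free recombination between loci, none within) and evolve
#' neutrally under the coalescent with infinite-sites mutation; X-linked
#' loci have their scaled diversity `theta_a * x_factor`.
#'
#' @param populations Character vector of population labels.
#' @param n_individuals Diploid individuals sampled per population (>= 5).
#' @param n_loci Named vector `c(X = , A = )` of loci per chromosome class.
#' @param locus_len Locus length in bp.
#' @param theta_a Per-site autosomal diversity (4 Ne mu).
#' @param x_factor Multiplier on theta for X-linked loci, in (0, 1.5].
#' @param loci_per_scaffold Loci placed on each synthetic scaffold, so
#'   scaffold-level pi and CV are computable.
#' @param seed Integer seed.
#' @return A `pop_sim_spec` list.
#' @export
pop_sim_spec <- function(populations = c("WRF", "PON", "KRU"),
                         n_individuals = 8L,
                         n_loci = c(X = 300L, A = 2000L),
                         locus_len = 100L, theta_a = 0.005,
                         x_factor = 0.75, loci_per_scaffold = 5L,
                         seed = 1L) {
  if (n_individuals < 5) abort("need at least 5 individuals per population")
  if (x_factor <= 0 || x_factor > 1.5) abort("x_factor must lie in (0, 1.5]")
  if (!all(c("X", "A") %in% names(n_loci))) {
    abort("n_loci needs named entries X and A")
  }
  structure(list(populations = populations,
                 n_individuals = as.integer(n_individuals),
                 n_loci = n_loci, locus_len = as.integer(locus_len),
                 theta_a = theta_a, x_factor = x_factor,
                 loci_per_scaffold = as.integer(loci_per_scaffold),
                 seed = as.integer(seed)),
            class = "pop_sim_spec")
}

#' Generate synthetic RAD locus alignments for several populations
#'
#' Simulates each locus under a constant-size neutral coalescent
#' (infinite-sites mutation, `2 * n_individuals` chromosomes per
#' population) and materialises phased allele sequences. Loci are placed
#' on synthetic scaffolds (`loci_per_scaffold` per scaffold) shared across
#' populations, so scaffold-level diversity and the X/A split are
#' well-defined downstream.
#'
#' @param spec A [pop_sim_spec()].
#' @return Tibble with `population`, `locus_id`, `scaffold_id`, `position`,
#'   `class`, and a list-column `aln` of named character vectors (one
#'   sequence per allele, names `ind<i>_a<1|2>`).
#' @export
gen_population_rad <- function(spec) {
  stopifnot(inherits(spec, "pop_sim_spec"))
  withr_seed(spec$seed, {
    n_chrom <- 2L * spec$n_individuals
    seq_names <- paste0("ind", rep(seq_len(spec$n_individuals), each = 2),
                        "_a", rep(1:2, spec$n_individuals))
    layout <- purrr::map(c("X", "A"), function(cl) {
      nl <- spec$n_loci[[cl]]
      scaf <- (seq_len(nl) - 1L) %/% spec$loci_per_scaffold + 1L
      tibble::tibble(
        locus_id = sprintf("locus_%s_%05d", cl, seq_len(nl)),
        scaffold_id = sprintf("scaffold_%s_%04d", cl, scaf),
        position = ((seq_len(nl) - 1L) %% spec$loci_per_scaffold) *
          (spec$locus_len + 900L),
        class = cl
      )
    }) |> dplyr::bind_rows()

    ne <- 1e4 # arbitrary; only theta = 4*Ne*mu matters
    out <- purrr::map(spec$populations, function(pop) {
      res <- purrr::map(c("X", "A"), function(cl) {
        theta <- spec$theta_a * if (cl == "X") spec$x_factor else 1
        sim <- coalsim_cpp(n_chrom, spec$n_loci[[cl]], spec$locus_len,
                           theta / (4 * ne), 0, ne, TRUE)
        purrr::map(sim$sites, function(locus_sites) {
          ref <- sample(.spx_bases, spec$locus_len, replace = TRUE)
          mat <- matrix(rep(ref, each = n_chrom), nrow = n_chrom)
          ns <- length(locus_sites)
          if (ns > 0) {
            pos <- sample.int(spec$locus_len, min(ns, spec$locus_len))
            for (s in seq_along(pos)) {
              alt <- sample(setdiff(.spx_bases, ref[pos[s]]), 1)
              mat[locus_sites[[s]], pos[s]] <- alt
            }
          }
          setNames(apply(mat, 1, paste, collapse = ""), seq_names)
        })
      })
      dplyr::mutate(layout, population = pop,
                    aln = c(res[[1]], res[[2]]))
    })
    dplyr::bind_rows(out) |>
      dplyr::select("population", "locus_id", "scaffold_id", "position",
                    "class", "aln")
  })
}

#' Write RAD locus alignments as multi-FASTA files
#'
#' One file per locus, named `<population>_<locus_id>.fasta`, records named
#' `<population>/<individual>/<allele>`. Output is byte-deterministic for
#' a given input table.
#'
#' @param rad Tibble from [gen_population_rad()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_rad_fasta <- function(rad, dir) {
  check_cols(rad, c("population", "locus_id", "aln"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::pmap_chr(
    list(rad$population, rad$locus_id, rad$aln),
    function(pop, loc, aln) {
      path <- file.path(dir, paste0(pop, "_", loc, ".fasta"))
      lines <- as.vector(rbind(paste0(">", pop, "/", names(aln)),
                               unname(aln)))
      writeLines(lines, path)
      path
    })
  invisible(paths)
}
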