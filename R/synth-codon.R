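#' Specification for synthetic three-species codon alignments
#'
#' Parameters for simulating gap-free codon alignments of 1:1 orthologs on
#' the fixed topology `((ingroup1, ingroup2), outgroup)`, with per-branch
#' synonymous divergence and per-branch, per-class dN/dS. The defaults
#' follow the divergence scale observed between closely related
#' *Stegodyphus* species (synonymous divergence below 1%, stronger
#' purifying selection on autosomes, lower synonymous rate on X).
#'
#' @param n_genes_per_class Genes simulated per chromosome class.
#' @param codons_per_gene Codons per gene (alignment length / 3).
#' @param branch_dS Named list `ingroup1`, `ingroup2`, `outgroup`, each a
#'   named vector `c(X = , A = )` of expected synonymous substitutions per
#'   synonymous site on that branch.
#' @param omega Named list as `branch_dS`: dN/dS per branch and class.
#' @param seed Integer seed.
#' @return A `codon_sim_spec` list.
#' @export
codon_sim_spec <- function(n_genes_per_class = 300,
                           codons_per_gene = 150,
                           branch_dS = list(
                             ingroup1 = c(X = 0.0059, A = 0.0093),
                             ingroup2 = c(X = 0.0060, A = 0.0083),
                             outgroup = c(X = 0.04, A = 0.05)),
                           omega = list(
                             ingroup1 = c(X = 0.177, A = 0.131),
                             ingroup2 = c(X = 0.140, A = 0.114),
                             outgroup = c(X = 0.15, A = 0.12)),
                           seed = 1L) {
  lin <- c("ingroup1", "ingroup2", "outgroup")
  if (!setequal(names(branch_dS), lin) || !setequal(names(omega), lin)) {
    abort("branch_dS and omega need entries ingroup1, ingroup2, outgroup")
  }
  if (any(unlist(branch_dS) < 0) || any(unlist(omega) < 0)) {
    abort("branch_dS and omega must be non-negative")
  }
  structure(list(n_genes_per_class = as.integer(n_genes_per_class),
                 codons_per_gene = as.integer(codons_per_gene),
                 branch_dS = branch_dS, omega = omega,
                 seed = as.integer(seed)),
            class = "codon_sim_spec")
}

# evolve a matrix of codon indices (genes x codons) along one branch.
# Mutation events arrive at rate `ds` per nucleotide site; synonymous
# changes always fix, nonsynonymous changes fix with probability `omega`,
# mutations to stop codons never fix. With uniform mutation and NG86 site
# counting this yields E[dS] = ds and E[dN] = omega * ds.
#' @noRd
evolve_codons <- function(mat, ds, omega) {
  tb <- codon_tables()
  mult <- c(16L, 4L, 1L)
  n_nt <- length(mat) * 3L
  k <- rpois(1, ds * n_nt)
  syn <- integer(nrow(mat)); non <- integer(nrow(mat))
  if (k > 0) {
    pos <- sample.int(n_nt, k, replace = TRUE)
    cell <- (pos - 1L) %/% 3L + 1L
    cpos <- (pos - 1L) %% 3L + 1L
    gene <- (cell - 1L) %% nrow(mat) + 1L
    u_accept <- runif(k)
    b_new_pick <- sample.int(3L, k, replace = TRUE)
    for (e in seq_len(k)) {
      cur <- mat[cell[e]]
      b_old <- tb$base_mat[cur, cpos[e]]
      b_new <- (0:3)[-(b_old + 1L)][b_new_pick[e]]
      nxt <- cur + (b_new - b_old) * mult[cpos[e]]
      if (tb$aa[nxt] == "*") next
      if (tb$aa[nxt] == tb$aa[cur]) {
        mat[cell[e]] <- nxt
        syn[gene[e]] <- syn[gene[e]] + 1L
      } else if (u_accept[e] < omega) {
        mat[cell[e]] <- nxt
        non[gene[e]] <- non[gene[e]] + 1L
      }
    }
  }
  list(mat = mat, syn = syn, non = non)
}

#' Generate synthetic three-species codon alignments
#'
#' Simulates gene alignments on the topology `((ingroup1, ingroup2),
#' outgroup)` under a simple codon-site model: ancestral codons are drawn
#' uniformly from sense codons; on each branch, mutation events arrive
#' uniformly over nucleotide sites at the branch's synonymous rate,
#' synonymous changes always fix, nonsynonymous changes fix with
#' probability omega, and stop codons are forbidden. The ingroup ancestor
#' coincides with the root, so the outgroup branch carries the whole
#' outgroup divergence.
#'
#' @param spec A [codon_sim_spec()].
#' @return Tibble with `gene_id`, `class`, sequences `ingroup1`,
#'   `ingroup2`, `outgroup`, and the true per-branch fixed substitution
#'   counts (`true_syn_*`, `true_non_*`) for oracle checks.
#' @export
gen_codon_alignments <- function(spec) {
  stopifnot(inherits(spec, "codon_sim_spec"))
  tb <- codon_tables()
  sense <- which(tb$aa != "*")
  withr_seed(spec$seed, {
    out <- purrr::map(c("X", "A"), function(cl) {
      ng <- spec$n_genes_per_class
      anc <- matrix(sample(sense, ng * spec$codons_per_gene, replace = TRUE),
                    nrow = ng)
      br <- purrr::map(c(ingroup1 = "ingroup1", ingroup2 = "ingroup2",
                         outgroup = "outgroup"),
                       function(l) evolve_codons(anc, spec$branch_dS[[l]][cl],
                                                 spec$omega[[l]][cl]))
      tibble::tibble(
        gene_id = sprintf("gene_%s_%04d", cl, seq_len(ng)),
        class = cl,
        ingroup1 = codons_to_seq(br$ingroup1$mat),
        ingroup2 = codons_to_seq(br$ingroup2$mat),
        outgroup = codons_to_seq(br$outgroup$mat),
        true_syn_ingroup1 = br$ingroup1$syn,
        true_non_ingroup1 = br$ingroup1$non,
        true_syn_ingroup2 = br$ingroup2$syn,
        true_non_ingroup2 = br$ingroup2$non,
        true_syn_outgroup = br$outgroup$syn,
        true_non_outgroup = br$outgroup$non
      )
    })
    dplyr::bind_rows(out)
  })
}
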