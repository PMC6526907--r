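test_that("untranslatable codons are removed from all three species", {
  aln <- triple_aln("ATGANAGGG", "ATGAAAGGG", "ATGAAAGGG")
  out <- strip_untranslatable_codons(aln)
  expect_equal(out$ingroup1, "ATGGGG")
  expect_equal(out$ingroup2, "ATGGGG")
  expect_equal(out$outgroup, "ATGGGG")
  clean <- triple_aln("ATGAAA", "ATGAAA", "ATGAAA")
  expect_identical(strip_untranslatable_codons(clean), clean)
  # gaps and IUPAC symbols are equally fatal for the codon column
  messy <- triple_aln("ATG-AAGGGTTT", "ATGAAAGGGTRT", "ATGAAAGGGTTT")
  expect_equal(strip_untranslatable_codons(messy)$ingroup1, "ATGGGG")
  # a reversed gene strips to the same codon set (order independence)
  rev_cod <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(rev(cods), collapse = "")
  }
  fwd <- strip_untranslatable_codons(messy)
  bwd <- strip_untranslatable_codons(
    triple_aln(rev_cod("ATG-AAGGGTTT"), rev_cod("ATGAAAGGGTRT"),
               rev_cod("ATGAAAGGGTTT")))
  expect_equal(bwd$ingroup1, rev_cod(fwd$ingroup1))
  empty <- triple_aln("NNN", "AAA", "AAA")
  expect_warning(out2 <- strip_untranslatable_codons(
    dplyr::bind_rows(empty, clean)), "dropping")
  expect_equal(nrow(out2), 1)
})

test_that("substitutions are polarized onto the correct branch", {
  same <- triple_aln("ATGGGG", "ATGGGG", "ATGGGG")
  cnt <- lineage_counts(same)
  expect_true(all(cnt$Nd == 0 & cnt$Sd == 0))
  expect_true(all(cnt$S_sites > 0))

  # ingroup2 carries GGA where the others carry GGG: one synonymous
  # substitution on the ingroup2 branch (Gly in both cases)
  aln <- triple_aln("ATGGGG", "ATGGGA", "ATGGGG")
  cnt <- lineage_counts(aln)
  expect_equal(cnt$Sd[cnt$lineage == "ingroup2"], 1)
  expect_equal(cnt$Nd[cnt$lineage == "ingroup2"], 0)
  expect_equal(cnt$Sd[cnt$lineage == "ingroup1"], 0)

  # nonsynonymous change on ingroup1: ATG (Met) -> ATA (Ile)
  aln2 <- triple_aln("ATAGGG", "ATGGGG", "ATGGGG")
  cnt2 <- lineage_counts(aln2)
  expect_equal(cnt2$Nd[cnt2$lineage == "ingroup1"], 1)
  expect_equal(cnt2$Sd[cnt2$lineage == "ingroup1"], 0)

  # outgroup matching neither ingroup is unassignable: excluded entirely
  aln3 <- triple_aln("AAAGGG", "AACGGG", "AAGGGG")
  cnt3 <- lineage_counts(aln3)
  same_sites <- lineage_counts(triple_aln("GGG", "GGG", "GGG"))
  expect_equal(cnt3$S_sites[1], same_sites$S_sites[1])
})

test_that("simulated single-branch substitutions land on that branch", {
  spec <- codon_sim_spec(
    n_genes_per_class = 60, codons_per_gene = 100,
    branch_dS = list(ingroup1 = c(X = 0.02, A = 0.02),
                     ingroup2 = c(X = 0, A = 0),
                     outgroup = c(X = 0, A = 0)),
    omega = list(ingroup1 = c(X = 0.5, A = 0.5),
                 ingroup2 = c(X = 0.5, A = 0.5),
                 outgroup = c(X = 0.5, A = 0.5)),
    seed = 6)
  cnt <- lineage_counts(gen_codon_alignments(spec))
  on1 <- sum(cnt$Nd[cnt$lineage == "ingroup1"] +
               cnt$Sd[cnt$lineage == "ingroup1"])
  on2 <- sum(cnt$Nd[cnt$lineage == "ingroup2"] +
               cnt$Sd[cnt$lineage == "ingroup2"])
  expect_gte(on1 / (on1 + on2), 0.95)
})

test_that("pooling is sum-based, order-invariant and split-invariant", {
  g <- tibble::tibble(gene_id = "g", class = "A", lineage = "ingroup1",
                      Nd = 1, Sd = 2, N_sites = 1000, S_sites = 400)
  p <- pool_dnds(g)
  expect_equal(p$dN, 0.001)
  expect_equal(p$dS, 0.005)
  expect_equal(p$omega, 0.2)

  many <- tibble::tibble(
    gene_id = paste0("g", 1:6), class = "A", lineage = "ingroup1",
    Nd = c(3, 1, 0, 5, 2, 2), Sd = c(4, 2, 1, 0, 3, 2),
    N_sites = c(900, 700, 800, 1000, 600, 500),
    S_sites = c(300, 250, 260, 310, 240, 200))
  p1 <- pool_dnds(many)
  p2 <- pool_dnds(many[sample(6), ])
  expect_equal(p1$omega, p2$omega)
  split <- many
  split$Nd[1] <- split$Nd[1] / 2
  split2 <- dplyr::bind_rows(split[1, ], split[1, ])
  split2$gene_id <- c("g1a", "g1b")
  halves <- dplyr::bind_rows(split2, many[-1, ])
  halves[1:2, c("Sd", "N_sites", "S_sites")] <-
    halves[1:2, c("Sd", "N_sites", "S_sites")] / 2
  expect_equal(pool_dnds(halves)$omega, p1$omega)
  # omega equals the ratio of pooled rates by construction
  expect_equal(p1$omega, p1$dN / p1$dS)
})

test_that("gene bootstrap gives ordered, seed-stable intervals", {
  same <- tibble::tibble(
    gene_id = paste0("g", 1:5), class = "A", lineage = "ingroup1",
    Nd = 2, Sd = 3, N_sites = 800, S_sites = 300)
  ci <- bootstrap_genes(same, n_boot = 50, seed = 2)
  expect_equal(ci$omega_lo, ci$omega_hi) # identical genes: zero width
  varied <- same
  varied$Nd <- c(0, 1, 2, 5, 9)
  c1 <- bootstrap_genes(varied, n_boot = 200, seed = 3)
  c2 <- bootstrap_genes(varied, n_boot = 200, seed = 3)
  expect_identical(c1, c2)
  expect_lte(c1$omega_lo, c1$omega)
  expect_gte(c1$omega_hi, c1$omega)
})

test_that("bootstrap CIs cover the generating omega at roughly 95%", {
  hits <- vapply(1:40, function(r) {
    spec <- codon_sim_spec(
      n_genes_per_class = 50, codons_per_gene = 60,
      branch_dS = list(ingroup1 = c(X = 0.02, A = 0.02),
                       ingroup2 = c(X = 0.02, A = 0.02),
                       outgroup = c(X = 0.03, A = 0.03)),
      omega = list(ingroup1 = c(X = 0.3, A = 0.3),
                   ingroup2 = c(X = 0.3, A = 0.3),
                   outgroup = c(X = 0.3, A = 0.3)),
      seed = 1000 + r)
    cnt <- lineage_counts(gen_codon_alignments(spec))
    ci <- bootstrap_genes(
      dplyr::filter(cnt, lineage == "ingroup1", class == "A"),
      n_boot = 200, seed = r)
    ci$omega_lo <= 0.3 && 0.3 <= ci$omega_hi
  }, logical(1))
  # 40 replicates: expect coverage in a generous binomial band around 95%
  expect_gte(mean(hits), 0.80)
})

test_that("randomization test is valid on degenerate and null data", {
  # identical counts in every gene: statistic constant, p must be 1
  const <- tibble::tibble(
    gene_id = rep(paste0("g", 1:20), 1), class = rep(c("X", "A"), 10),
    lineage = "ingroup1", Nd = 2, Sd = 3, N_sites = 800, S_sites = 300)
  r <- randomization_test(const, "omega_diff", "class", n_perm = 99,
                          seed = 1)
  expect_equal(r$p_two_tailed, 1)
  expect_equal(r$statistic_observed, 0)
  expect_error(
    randomization_test(const, "omega_diff", "species", n_perm = 9),
    "single chromosome class")
})

test_that("the class randomization test detects a faster-X effect", {
  ps <- vapply(1:20, function(r) {
    spec <- codon_sim_spec(
      n_genes_per_class = 500, codons_per_gene = 250,
      branch_dS = list(ingroup1 = c(X = 0.0059, A = 0.0093),
                       ingroup2 = c(X = 0.0060, A = 0.0083),
                       outgroup = c(X = 0.04, A = 0.05)),
      omega = list(ingroup1 = c(X = 0.18, A = 0.13),
                   ingroup2 = c(X = 0.14, A = 0.11),
                   outgroup = c(X = 0.15, A = 0.12)),
      seed = 5000 + r)
    cnt <- lineage_counts(gen_codon_alignments(spec))
    randomization_test(dplyr::filter(cnt, lineage == "ingroup1"),
                       "omega_diff", "class", n_perm = 299,
                       seed = r)$p_two_tailed
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.80)
})

test_that("class contrasts reproduce ratio and percent-increase arithmetic", {
  summaries <- tibble::tibble(
    lineage = rep(c("mimosarum", "africanus"), each = 2),
    class = rep(c("X", "A"), 2),
    dN = c(0.0010, 0.0012, 0.0008, 0.0010),
    dS = c(0.0059, 0.0093, 0.0060, 0.0083),
    omega = c(0.177, 0.131, 0.140, 0.114))
  rep_tab <- contrast_report(summaries)
  get <- function(contrast, lineage = NULL) {
    sel <- rep_tab$contrast == contrast
    if (!is.null(lineage)) sel <- sel & rep_tab$lineage == lineage
    rep_tab$value[sel]
  }
  expect_equal(get("omega_ratio_XA", "mimosarum"), 0.177 / 0.131)
  expect_equal(round(get("omega_ratio_XA", "mimosarum"), 2), 1.35)
  expect_equal(round(get("omega_increase_pct", "mimosarum")), 35)
  expect_equal(get("omega_increase_pct", "africanus"),
               100 * (0.140 / 0.114 - 1))
  expect_equal(round(get("dS_ratio_XA", "africanus"), 2), 0.72)
  expect_equal(round(get("dS_ratio_XA", "mimosarum"), 2), 0.63)
  # cross-lineage autosomal increase: 0.131 vs 0.114 is 15%
  cross <- rep_tab$value[rep_tab$contrast ==
                           "omega_increase_pct_mimosarum_vs_africanus"]
  expect_equal(round(cross[rep_tab$class[rep_tab$contrast ==
    "omega_increase_pct_mimosarum_vs_africanus"] == "A"]), 15)
  equal_in <- contrast_report(dplyr::mutate(summaries, omega = 0.2,
                                            dS = 0.01))
  expect_true(all(abs(equal_in$value[grepl("ratio",
                                           equal_in$contrast)] - 1) < 1e-12))
})
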