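test_that("nei_pi matches hand enumeration and handles missing data", {
  same <- rep(strrep("ACGT", 25), 4)
  names(same) <- paste0("s", 1:4)
  expect_equal(nei_pi(same)$pi, 0)
  # 4 sequences, one biallelic site at counts 2/2: 4 of 6 pairs differ
  aln <- rep(strrep("A", 100), 4)
  substr(aln[3], 7, 7) <- "G"
  substr(aln[4], 7, 7) <- "G"
  names(aln) <- paste0("s", 1:4)
  expect_equal(nei_pi(aln)$pi, (4 / 6) / 100)
  expect_equal(nei_pi(aln)$n_sites, 100)
  expect_error(nei_pi(aln[1]), "2 sequences")
})

test_that("nei_pi equals the brute-force all-pairs oracle", {
  for (r in 1:25) {
    aln <- random_alignment(n_seq = sample(3:8, 1), len = 60,
                            gap_frac = 0.08, seed = 400 + r)
    expect_equal(nei_pi(aln)$pi, brute_force_pi(aln), tolerance = 1e-12)
  }
  # and on clean alignments
  for (r in 1:25) {
    aln <- random_alignment(n_seq = 6, len = 40, seed = 500 + r)
    expect_equal(nei_pi(aln)$pi, brute_force_pi(aln), tolerance = 1e-12)
  }
})

test_that("nei_pi is invariant to sequence order and allele phase swaps", {
  aln <- random_alignment(8, 50, seed = 9)
  expect_equal(nei_pi(aln)$pi, nei_pi(rev(aln))$pi)
  swapped <- aln
  swapped[c(1, 2)] <- swapped[c(2, 1)] # swap a diploid pair's phases
  expect_equal(nei_pi(aln)$pi, nei_pi(swapped)$pi)
})

test_that("concatenation gives the site-weighted mean of block pi", {
  a <- random_alignment(6, 40, seed = 21)
  b <- random_alignment(6, 40, seed = 22)
  ab <- paste0(a, b[names(a)])
  names(ab) <- names(a)
  expect_equal(nei_pi(ab)$pi, (nei_pi(a)$pi + nei_pi(b)$pi) / 2)
})

test_that("subalignment building fixes the universal length from X coverage", {
  spec <- pop_sim_spec(populations = c("P1", "P2"), n_individuals = 5,
                       n_loci = c(X = 31L, A = 100L), locus_len = 100L,
                       seed = 44)
  rad <- gen_population_rad(spec)
  blocks <- build_subalignments(rad, target_min_blocks = 15)
  L <- attr(blocks, "block_len")
  expect_equal(L, floor(3100 / 15))
  widths <- vapply(blocks$aln, function(b) nchar(b[[1]]), numeric(1))
  expect_true(all(widths == L))
  # block count is floor(total / L) per set
  per_set <- dplyr::count(blocks, population, class)
  expect_true(all(per_set$n[per_set$class == "X"] == 15))
  expect_true(all(per_set$n[per_set$class == "A"] == floor(10000 / L)))
})

test_that("missing individuals become gap rows in the concatenation", {
  aln1 <- random_alignment(4, 10, seed = 1)
  names(aln1) <- c("i1_a1", "i1_a2", "i2_a1", "i2_a2")
  aln2 <- random_alignment(2, 10, seed = 2)
  names(aln2) <- c("i1_a1", "i1_a2")
  loci <- tibble::tibble(population = "P", class = "X",
                         locus_id = c("l1", "l2"),
                         scaffold_id = c("s1", "s1"),
                         position = c(0L, 500L),
                         aln = list(aln1, aln2))
  blocks <- build_subalignments(loci, target_min_blocks = 2)
  cat1 <- blocks$aln[[1]]
  expect_equal(length(cat1), 4)
  expect_equal(substr(cat1[["i2_a1"]], 1, 10),
               unname(aln1["i2_a1"]))
  full <- paste0(blocks$aln[[1]][["i2_a1"]], blocks$aln[[2]][["i2_a1"]])
  expect_equal(substr(full, 11, 20), strrep("-", 10))
})

test_that("pi bootstrap has sane degenerate and stochastic behaviour", {
  expect_error(bootstrap_pi(c(0.1)), "2 blocks")
  same <- bootstrap_pi(rep(0.02, 10), n_boot = 100, seed = 1)
  expect_equal(same$ci_low, 0.02)
  expect_equal(same$ci_high, 0.02)
  v <- withr::with_seed(3, rexp(30, 100))
  b1 <- bootstrap_pi(v, n_boot = 500, seed = 7)
  b2 <- bootstrap_pi(v, n_boot = 500, seed = 7)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$mean_pi)
  expect_gte(b1$ci_high, b1$mean_pi)
})

test_that("scaffold CV matches hand arithmetic and is scale invariant", {
  cv <- scaffold_cv(c(1, 2, 3), n_boot = 50, seed = 1)
  expect_equal(cv$cv, 0.5)
  expect_equal(scaffold_cv(rep(4, 5), n_boot = 50, seed = 1)$cv, 0)
  x <- c(0.3, 0.7, 1.1, 0.2)
  expect_equal(scaffold_cv(x, n_boot = 10, seed = 1)$cv,
               scaffold_cv(10 * x, n_boot = 10, seed = 1)$cv)
  expect_warning(out <- scaffold_cv(c(0, 0, 0), n_boot = 10, seed = 1),
                 "zero")
  expect_true(is.na(out$cv))
})

test_that("scaffold pi only uses scaffolds with enough loci", {
  spec <- pop_sim_spec(populations = "P1", n_individuals = 5,
                       n_loci = c(X = 10L, A = 12L),
                       loci_per_scaffold = 5L, seed = 5)
  rad <- gen_population_rad(spec)
  sp <- scaffold_pi(rad, min_loci = 3)
  expect_true(all(sp$n_loci >= 3))
  # the A class has 12 loci on scaffolds of 5: 5 + 5 + 2 -> last dropped
  expect_equal(sum(sp$class == "A"), 2)
})

test_that("piX/piA pairing builds the documented groups and ratios", {
  x <- rep(0.5, 15)
  a <- rep(1, 150)
  pr <- pair_pix_pia(x, a, seed = 1)
  expect_equal(nrow(pr), 15)
  expect_true(all(pr$ratio == 0.5))
  expect_true(all(pr$a_value == 1))
  allsame <- pair_pix_pia(rep(0.2, 5), rep(0.2, 30), seed = 2)
  expect_true(all(allsame$ratio == 1))
  expect_error(pair_pix_pia(c(0.1), rep(1, 5)), "at least 2")
  # any 2-way grouping of (0, 0, 0, 0.4) leaves one group with median 0
  expect_warning(drop <- pair_pix_pia(c(0.1, 0.2), c(0, 0, 0, 0.4),
                                      seed = 3), "zero")
  expect_equal(nrow(drop), 1)
})

test_that("species test detects differences and validates its input", {
  mk_ratios <- function(mu_by_species, seed) {
    withr::with_seed(seed, {
      dplyr::bind_rows(lapply(names(mu_by_species), function(sp) {
        dplyr::bind_rows(lapply(1:3, function(p) {
          tibble::tibble(species = sp, population = paste0(sp, "_p", p),
                         ratio = rnorm(15, mu_by_species[[sp]], 0.1))
        }))
      }))
    })
  }
  shifted <- mk_ratios(list(a = 0.57, b = 0.75), seed = 2)
  res <- species_ratio_test(shifted)
  expect_lt(res$p_value, 0.01)
  expect_error(species_ratio_test(dplyr::filter(shifted, species == "a")),
               "2 species")
  one_pop <- dplyr::filter(shifted, population %in% c("a_p1", "b_p1"))
  expect_error(species_ratio_test(one_pop), "2 populations")
})

test_that("species test p-values are roughly uniform under the null", {
  pvals <- vapply(1:60, function(r) {
    withr::with_seed(r, {
      ratios <- dplyr::bind_rows(lapply(c("a", "b"), function(sp) {
        dplyr::bind_rows(lapply(1:3, function(p) {
          pop_eff <- rnorm(1, 0, 0.05)
          tibble::tibble(species = sp, population = paste0(sp, "_p", p),
                         ratio = 0.7 + pop_eff + rnorm(12, 0, 0.1))
        }))
      }))
    })
    suppressMessages(species_ratio_test(ratios)$p_value)
  }, numeric(1))
  # no gross anti-conservatism: small p-values at roughly nominal rate
  expect_lt(mean(pvals < 0.05), 0.18)
  expect_gt(mean(pvals > 0.5), 0.25)
})

test_that("population F-test matches the textbook one-way ANOVA", {
  same <- tibble::tibble(population = rep(c("p1", "p2"), each = 3),
                         ratio = rep(c(1, 2, 3), 2))
  res <- population_ratio_test(same)
  expect_equal(res$anova$f, 0)
  expect_equal(res$anova$p_value, 1)

  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4); g3 <- c(6, 7, 8)
  dat <- tibble::tibble(population = rep(c("p1", "p2", "p3"), each = 3),
                        ratio = c(g1, g2, g3))
  res3 <- population_ratio_test(dat)
  grand <- mean(c(g1, g2, g3))
  ssb <- 3 * sum((c(mean(g1), mean(g2), mean(g3)) - grand)^2)
  ssw <- sum((g1 - mean(g1))^2 + (g2 - mean(g2))^2 + (g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res3$anova$f, f_hand)
  expect_equal(res3$anova$df1, 2)
  expect_equal(res3$anova$df2, 6)
  # p3 is clearly separated: it gets its own letter
  letts <- res3$letters
  expect_equal(letts$letters[letts$population == "p1"],
               letts$letters[letts$population == "p2"])
  expect_false(letts$letters[letts$population == "p3"] %in%
                 letts$letters[letts$population %in% c("p1", "p2")])
})
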