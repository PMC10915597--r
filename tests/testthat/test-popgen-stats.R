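# Classical diversity statistics against brute-force oracles.

test_that("segregating sites and pi on hand-built alignments", {
  ident <- matrix(rep(c("A", "C", "G", "T", "A"), each = 4), nrow = 4)
  expect_equal(segregating_sites(ident), 0)
  expect_equal(nucleotide_diversity(ident)$total, 0)

  mat <- rbind(c("A", "A", "A", "A"),
               c("A", "C", "A", "A"),
               c("A", "C", "G", "A"),
               c("A", "C", "G", "T"))
  expect_equal(segregating_sites(mat), 3)

  two <- rbind(strsplit("ACGTACGTAC", "")[[1]],
               strsplit("ACGTACGTGT", "")[[1]])
  pi <- nucleotide_diversity(two)
  expect_equal(pi$total, 2)
  expect_equal(pi$per_site, 0.2)
  expect_error(segregating_sites(two[1, , drop = FALSE]), "at least 2")
})

test_that("watterson's estimator follows the harmonic-sum formula", {
  expect_equal(watterson_theta(0, 7), 0)
  expect_equal(watterson_theta(5, 2), 5)
  expect_equal(watterson_theta(3, 4), 3 / (1 + 1 / 2 + 1 / 3))
  expect_error(watterson_theta(3, 1), "at least 2")
})

test_that("S, pi and Tajima's D match independent oracles on random matrices", {
  set.seed(2024)
  for (r in 1:12) {
    n <- sample(4:12, 1)
    s <- sample(10:60, 1)
    miss <- sample(c(0, 0.1), 1)
    mat <- rand_binary_matrix(n, s, miss)
    if (oracle_segregating_sites(mat) == 0) next
    expect_equal(segregating_sites(mat), oracle_segregating_sites(mat))
    expect_equal(nucleotide_diversity(mat)$total, oracle_pi_total(mat),
                 tolerance = 1e-12)
    expect_equal(tajimas_d(mat), oracle_tajima_d(mat), tolerance = 1e-10)
  }
  # six random DNA sequences against the all-pairs oracle
  dna <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, replace = TRUE),
                nrow = 6)
  expect_equal(nucleotide_diversity(dna)$total, oracle_pi_total(dna))
})

test_that("Tajima's D is undefined without polymorphism and zero at pi = S/a1", {
  mono <- matrix("A", nrow = 5, ncol = 8)
  expect_true(is.na(tajimas_d(mono)))
  # a configuration whose pairwise diversity equals S/a1 exactly:
  # n = 4 (a1 = 11/6), 8 singleton columns (pi 1/2 each) and 3 doubleton
  # columns (pi 2/3 each) give pi = 6 = 11/(11/6), so the numerator of D
  # vanishes
  singleton <- c(1, 0, 0, 0)
  doubleton <- c(1, 1, 0, 0)
  mat <- cbind(matrix(rep(singleton, 8), nrow = 4),
               matrix(rep(doubleton, 3), nrow = 4))
  expect_equal(oracle_pi_total(mat), 6)
  expect_equal(tajimas_d(mat), 0)
})

test_that("pi and theta_w are invariant to row and column order", {
  set.seed(11)
  mat <- rand_binary_matrix(8, 40, 0.05)
  perm_rows <- mat[sample(nrow(mat)), ]
  perm_cols <- mat[, sample(ncol(mat))]
  expect_equal(nucleotide_diversity(perm_rows)$total,
               nucleotide_diversity(mat)$total)
  expect_equal(segregating_sites(perm_cols), segregating_sites(mat))
  expect_equal(nucleotide_diversity(perm_cols)$total,
               nucleotide_diversity(mat)$total)
})

test_that("diversity_summary bundles the statistics coherently", {
  set.seed(3)
  mat <- rand_binary_matrix(6, 50)
  ds <- diversity_summary(mat)
  expect_equal(ds$S, segregating_sites(mat))
  expect_equal(ds$pi_total, nucleotide_diversity(mat)$total)
  expect_equal(ds$theta_w_total, watterson_theta(ds$S, 6))
  expect_equal(ds$tajima_d, tajimas_d(mat))
})

test_that("snp_diversity reports per-population allele-frequency statistics", {
  tb <- simulate_snp_dataset(const_model(ne = 1e4), NULL, 400,
                             c(A = 8, B = 8, C = 8), 0.05, seed = 14,
                             constants = GEN1)
  sd_tab <- snp_diversity(tb)
  expect_setequal(sd_tab$population, c("A", "B", "C", "all"))
  expect_true(all(sd_tab$S <= sd_tab$sites))
  expect_true(all(sd_tab$pi_total >= 0))
  all_row <- sd_tab[sd_tab$population == "all", ]
  expect_gte(all_row$S, max(sd_tab$S[sd_tab$population != "all"]))
})
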