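# Structured-coalescent engine: closed-form checks, invariances,
# determinism, and agreement with an independent simulator.

test_that("pairwise coalescence time has mean 2*Ne generations", {
  m <- const_model(ne = 1e4)
  es <- expected_sfs_mc(m, NULL, c(A = 2, B = 0, C = 0), n_reps = 10000,
                        seed = 42, constants = GEN1)
  se <- stats::sd(es$tmrca) / sqrt(length(es$tmrca))
  expect_lt(abs(mean(es$tmrca) - 2e4), 3 * se)
  # n = (2,0,0): the single polymorphic cell carries all the mass
  expect_equal(es$prob[2, 1, 1], 1)
  expect_equal(sum(es$prob), 1)
})

test_that("total branch length matches theta * a_n scaling", {
  # E[S] = theta * sum(1/i) and E[S] = mu_locus * E[total length], so
  # E[L] = 4 Ne a_n
  m <- const_model(ne = 1e4)
  es <- expected_sfs_mc(m, NULL, c(A = 10, B = 0, C = 0), n_reps = 20000,
                        seed = 9, constants = GEN1)
  a_n <- sum(1 / (1:9))
  expect_lt(abs(mean(es$treelen) / (4e4 * a_n) - 1), 0.02)
})

test_that("a zero-fraction pulse leaves simulations exactly unchanged", {
  base <- const_model(ne = 5e3, tdiv_ab = 2e4, tdiv_abc = 6e4)
  pulsed <- const_model(ne = 5e3, tdiv_ab = 2e4, tdiv_abc = 6e4,
                        extra_events = list(evt_pulse(1e4, "A", "B", "p0")),
                        extra_params = list(p0 = list(fixed = 0)))
  n <- c(A = 6, B = 6, C = 4)
  e1 <- expected_sfs_mc(base, NULL, n, n_reps = 400, seed = 31,
                        constants = GEN1)
  e2 <- expected_sfs_mc(pulsed, NULL, n, n_reps = 400, seed = 31,
                        constants = GEN1)
  expect_identical(e1$prob, e2$prob)
  expect_identical(e1$tmrca, e2$tmrca)
})

test_that("a full pulse forcibly moves every destination lineage", {
  # forward A -> B with p = 1 empties B (backward) at the pulse time: B's
  # enormous size can then no longer delay coalescence, so the TMRCA
  # collapses to A's scale
  mk <- function(with_pulse) {
    extra <- if (with_pulse) list(evt_pulse(1e4, "A", "B", "p1")) else list()
    demographic_model(
      "forced", "pulse check",
      params = list(Ne_A = list(fixed = 5e3), Ne_B = list(fixed = 1e10),
                    Ne_C = list(fixed = 5e3),
                    tdiv_AB = list(fixed = 1e6), tdiv_ABC = list(fixed = 2e6),
                    p1 = list(fixed = 1)),
      events = c(list(evt_split("tdiv_AB", "A", "AB"),
                      evt_split("tdiv_AB", "B", "AB"),
                      evt_split("tdiv_ABC", "AB", "ABC"),
                      evt_split("tdiv_ABC", "C", "ABC")),
                 extra))
  }
  n <- c(A = 4, B = 4, C = 0)
  with_p <- expected_sfs_mc(mk(TRUE), NULL, n, n_reps = 300, seed = 13,
                            constants = GEN1)
  without <- expected_sfs_mc(mk(FALSE), NULL, n, n_reps = 300, seed = 13,
                             constants = GEN1)
  expect_lt(mean(with_p$tmrca), 2e5)
  expect_gt(mean(without$tmrca), 5e5)
})

test_that("a model symmetric in A and B yields a symmetric spectrum", {
  m <- const_model(ne = 2e4, tdiv_ab = 4e4, tdiv_abc = 1e5)
  es <- expected_sfs_mc(m, NULL, c(A = 4, B = 4, C = 4), n_reps = 40000,
                        seed = 5, constants = GEN1)
  marg_a <- apply(es$prob, 1, sum)
  marg_b <- apply(es$prob, 2, sum)
  expect_lt(max(abs(marg_a - marg_b)), 0.01)
})

test_that("simulated genealogies are valid ultrametric trees", {
  m <- const_model(ne = 1e4)
  tr <- simulate_genealogy(m, NULL, c(A = 4, B = 3, C = 3), seed = 2,
                           constants = GEN1)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 10)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_gt(attr(tr, "tmrca"), 0)
  tr2 <- simulate_genealogy(m, NULL, c(A = 4, B = 3, C = 3), seed = 2,
                            constants = GEN1)
  expect_identical(tr$edge.length, tr2$edge.length)
})

test_that("SNP datasets are deterministic, polymorphic and correctly sized", {
  m <- const_model(ne = 1e4)
  tb <- simulate_snp_dataset(m, NULL, 100, c(A = 4, B = 4, C = 4),
                             missing_rate = 0, seed = 3, constants = GEN1)
  expect_equal(dim(tb), c(100L, 6L))
  d <- rowSums(tb$geno)
  expect_true(all(d > 0 & d < 12))      # every site polymorphic
  expect_false(anyNA(tb$geno))
  tb2 <- simulate_snp_dataset(m, NULL, 100, c(A = 4, B = 4, C = 4),
                              missing_rate = 0, seed = 3, constants = GEN1)
  expect_identical(tb, tb2)
  expect_error(simulate_snp_dataset(m, NULL, 10, c(A = 3, B = 4, C = 4),
                                    seed = 1, constants = GEN1),
               "even haploid")
})

test_that("missingness matches the requested rate", {
  m <- const_model(ne = 1e4)
  tb <- simulate_snp_dataset(m, NULL, 2000, c(A = 6, B = 6, C = 6),
                             missing_rate = 0.1, seed = 8, constants = GEN1)
  n_geno <- length(tb$geno)
  se <- sqrt(0.1 * 0.9 / n_geno)
  expect_lt(abs(mean(is.na(tb$geno)) - 0.1), 3 * se)
})

test_that("per-locus SNP draws agree with the branch-length spectrum", {
  # chi-square goodness of fit of simulated SNP configurations against
  # the Monte-Carlo expected joint SFS
  m <- const_model(ne = 2e4, tdiv_ab = 4e4, tdiv_abc = 1e5)
  n <- c(A = 4, B = 4, C = 4)
  tb <- simulate_snp_dataset(m, NULL, 10000, n, 0, seed = 77,
                             constants = GEN1)
  obs <- build_joint_sfs(tb, projection_sizes = n)
  es <- expected_sfs_mc(m, NULL, n, n_reps = 60000, seed = 78,
                        constants = GEN1)
  keep <- es$prob > 5e-4
  expected_counts <- es$prob[keep] * sum(obs$counts)
  chisq <- sum((obs$counts[keep] - expected_counts)^2 / expected_counts)
  df <- sum(keep) - 1
  expect_gt(stats::pchisq(chisq, df, lower.tail = FALSE), 0.01)
})

test_that("TMRCA and tree length agree with an independent coalescent simulator", {
  ms <- msprime_oracle(n_reps = 3000, seed = 7)
  reps <- 3000
  ours <- list(
    single = expected_sfs_mc(const_model(ne = 1e4), NULL,
                             c(A = 10, B = 0, C = 0), n_reps = reps,
                             seed = 101, constants = GEN1),
    split = expected_sfs_mc(const_model(ne = 2e4, tdiv_ab = 5000,
                                        tdiv_abc = 5e7), NULL,
                            c(A = 8, B = 8, C = 0), n_reps = reps,
                            seed = 102, constants = GEN1),
    growth = expected_sfs_mc(
      const_model(ne = 1e5,
                  extra_events = list(evt_growth("A", 1e-3, time = 0),
                                      evt_size_change(4000, "A", 1e3))),
      NULL, c(A = 10, B = 0, C = 0), n_reps = reps, seed = 103,
      constants = GEN1))
  for (sc in names(ours)) {
    for (q in c("tmrca", "treelen")) {
      mine <- ours[[sc]][[q]]
      theirs_mean <- ms[[sc]][[if (q == "tmrca") "tmrca" else "tlen"]]
      theirs_sd <- ms[[sc]][[if (q == "tmrca") "tmrca_sd" else "tlen_sd"]]
      se <- sqrt(stats::var(mine) / reps + theirs_sd^2 / reps)
      expect_lt(abs(mean(mine) - theirs_mean), 3.5 * se,
                label = paste(sc, q, "difference"))
    }
  }
})
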