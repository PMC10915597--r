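# Composite likelihood, multi-start optimization, bootstrap mechanics.

toy_expected <- function(p, n = c(2, 0, 0)) {
  # hand-built expected_sfs over the two polymorphic cells of n=(2,0,0)
  # or arbitrary vector p laid into the (3,1,1) array
  prob <- array(0, dim = n + 1L)
  prob[seq_along(p) + 1L] <- p
  structure(list(prob = prob, se = prob * 0,
                 n = stats::setNames(n, c("A", "B", "C")),
                 n_reps = 1L, folded = FALSE), class = "expected_sfs")
}

toy_observed <- function(counts, n = c(2, 0, 0)) {
  arr <- array(0, dim = n + 1L)
  arr[seq_along(counts) + 1L] <- counts
  structure(list(counts = arr,
                 m = stats::setNames(as.integer(n), c("A", "B", "C")),
                 folded = FALSE,
                 dropped = c(monomorphic = 0, below_threshold = 0L),
                 input_sites = sum(counts)), class = "joint_sfs")
}

test_that("composite log-likelihood matches per-site product oracles", {
  # all mass in one cell with probability one
  expect_equal(composite_loglik(toy_observed(c(5, 0)), toy_expected(c(1, 0))), 0)
  # 3-cell toy: n = (5,3,2), pi = (0.5,0.3,0.2) against independent
  # per-site product
  obs <- toy_observed(c(5, 3, 2), n = c(3, 0, 0))
  exp3 <- toy_expected(c(0.5, 0.3, 0.2), n = c(3, 0, 0))
  oracle <- sum(log(c(rep(0.5, 5), rep(0.3, 3), rep(0.2, 2))))
  expect_equal(composite_loglik(obs, exp3), oracle)
  # empirical frequencies maximize the multinomial likelihood
  phat <- c(5, 3, 2) / 10
  base <- composite_loglik(obs, toy_expected(phat, n = c(3, 0, 0)))
  for (eps in c(0.02, -0.03)) {
    pert <- phat + c(eps, -eps, 0)
    expect_lt(composite_loglik(obs, toy_expected(pert, n = c(3, 0, 0))), base)
  }
  # observed mass on a zero-probability cell draws the floor
  expect_warning(
    ll <- composite_loglik(toy_observed(c(4, 1)), toy_expected(c(1, 0))),
    "zero expected mass")
  expect_equal(ll, 1 * log(1e-30))
  expect_error(
    composite_loglik(toy_observed(c(1, 1), n = c(2, 0, 0)),
                     toy_expected(c(0.5, 0.5, 0, 0), n = c(3, 0, 0))),
    "different projected sizes")
})

test_that("optimization is deterministic and monotone in the number of starts", {
  m <- anchored_template()
  tb <- simulate_snp_dataset(m, c(tdiv_AB = 3e5, tdiv_ABC = 9e5), 300,
                             c(A = 6, B = 6, C = 6), 0, seed = 21)
  obs <- build_joint_sfs(tb)
  cfg1 <- opt_config(n_starts = 1, mc_reps = 200, maxit = 60, seed = 5)
  f1a <- optimize_model(m, obs, cfg1)
  f1b <- optimize_model(m, obs, cfg1)
  expect_identical(f1a$params, f1b$params)
  expect_identical(f1a$lnL, f1b$lnL)
  f5 <- optimize_model(m, obs, opt_config(n_starts = 5, mc_reps = 200,
                                          maxit = 60, seed = 5))
  expect_gte(f5$lnL, f1a$lnL)
  expect_equal(f5$k, 2L)
  expect_equal(nrow(f5$starts), 5)
})

test_that("effective sizes are recovered once the time scale is pinned", {
  # the SFS shape identifies times/Ne ratios; with the divergence times
  # held at their generating values the sizes become estimable
  truth_ne <- 2e5
  m <- demographic_model(
    "ne-only", "size estimation",
    params = list(Ne_A = list(lower = 1e4, upper = 2e6),
                  Ne_B = list(lower = 1e4, upper = 2e6),
                  Ne_C = list(lower = 1e4, upper = 2e6),
                  tdiv_AB = list(fixed = 5e5), tdiv_ABC = list(fixed = 1.2e6)),
    events = list(evt_split("tdiv_AB", "A", "AB"),
                  evt_split("tdiv_AB", "B", "AB"),
                  evt_split("tdiv_ABC", "AB", "ABC"),
                  evt_split("tdiv_ABC", "C", "ABC")))
  errs <- sapply(1:10, function(r) {
    tb <- simulate_snp_dataset(m, c(Ne_A = truth_ne, Ne_B = truth_ne,
                                    Ne_C = truth_ne), 2000,
                               c(A = 8, B = 8, C = 8), 0, seed = 30 + r)
    obs <- build_joint_sfs(tb, projection_sizes = c(A = 6, B = 6, C = 6))
    fit <- optimize_model(m, obs, opt_config(n_starts = 4, mc_reps = 600,
                                             maxit = 150,
                                             seed = as.integer(60 + r)))
    abs(fit$params[["Ne_C"]] / truth_ne - 1)
  })
  expect_lt(median(errs), 0.25)
})

test_that("a super-model never fits worse than its nested sub-model", {
  cat_c <- build_catalog("caerulescens", models = c("II", "III"))
  tb <- simulate_snp_dataset(cat_c$II,
                             c(Ne_A = 2e5, Ne_B = 2e5, Ne_C = 2e5,
                               tdiv_AB = 5e5, tdiv_ABC = 1.2e6),
                             800, c(A = 8, B = 8, C = 8), 0, seed = 40)
  obs <- build_joint_sfs(tb, projection_sizes = c(A = 6, B = 6, C = 6))
  f2 <- optimize_model(cat_c$II, obs,
                       opt_config(n_starts = 2, mc_reps = 800, maxit = 150,
                                  seed = 41L))
  f3 <- optimize_model(cat_c$III, obs,
                       opt_config(n_starts = 2, mc_reps = 800, maxit = 150,
                                  seed = 42L),
                       extra_starts = list(warm_from_nested(cat_c$III, f2)))
  rs <- rescore_fits(list(f2, f3), obs, mc_reps = 8000, seed = 43)
  expect_gte(rs[[2]]$lnL, rs[[1]]$lnL - 5)  # within MC noise tolerance
})

test_that("the bootstrap is degenerate for fully fixed models and its percentiles match a sort oracle", {
  fixed <- const_model(ne = 1e4, tdiv_ab = 3e4, tdiv_abc = 8e4)
  bt <- parametric_bootstrap(fixed, NULL, n_loci = 50,
                             sample_config = c(A = 4, B = 4, C = 4),
                             n_boot = 3,
                             config = opt_config(n_starts = 1, mc_reps = 100,
                                                 maxit = 20, seed = 2L),
                             constants = GEN1)
  expect_true(all(bt$ci$upper == bt$ci$lower))

  m <- anchored_template()
  fit_params <- c(tdiv_AB = 3e5, tdiv_ABC = 9e5)
  bt2 <- parametric_bootstrap(m, fit_params, n_loci = 200,
                              sample_config = c(A = 6, B = 6, C = 6),
                              n_boot = 8,
                              config = opt_config(n_starts = 1, mc_reps = 250,
                                                  maxit = 60, seed = 3L))
  expect_equal(bt2$n_failed, 0)
  for (p in bt2$ci$param) {
    est <- sort(bt2$estimates[, p])
    lo_oracle <- est[ceiling(0.025 * length(est))]
    hi_oracle <- est[ceiling(0.975 * length(est))]
    expect_equal(bt2$ci$lower[bt2$ci$param == p], lo_oracle)
    expect_equal(bt2$ci$upper[bt2$ci$param == p], hi_oracle)
  }
})
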