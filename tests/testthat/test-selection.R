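# AIC arithmetic, ranking tables and the shared-divergence comparison.

test_that("aic matches direct arithmetic", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-5262.392335, 14), 2 * 14 + 2 * 5262.392335)
  expect_equal(aic(-6273.820533, 13), 2 * 13 + 2 * 6273.820533)
  expect_error(aic(NaN, 2), "non-finite")
  expect_error(aic(-10, -1), "non-negative")
})

test_that("rank_models orders, ranks strictly and flags duplicates", {
  single <- rank_models(data.frame(model_name = "I", lnL = -10, k = 2))
  expect_equal(single$delta_aic, 0)
  expect_equal(single$weight, 1)
  expect_equal(single$rank, 1L)

  df <- data.frame(model_name = c("X", "III", "IV"),
                   lnL = c(-5262.392335, -5261.258098, -5480.279081),
                   k = c(14, 16, 18))
  rt <- rank_models(df)
  expect_equal(rt$model_name, c("X", "III", "IV"))
  expect_equal(rt$rank, 1:3)
  expect_setequal(rt$model_name, df$model_name)  # a permutation
  expect_equal(rt$weight, exp(-rt$delta_aic / 2))
  norm <- rank_models(df, normalize = TRUE)
  expect_equal(sum(norm$weight), 1)
  expect_error(rank_models(rbind(df, df[1, ])), "duplicate")
})

test_that("ranking TSVs round-trip at full precision including tiny weights", {
  pub <- published_rankings("mentalis")
  rt <- rank_models(pub[, c("model_name", "model_type", "lnL", "k")])
  path <- tempfile(fileext = ".tsv")
  write_ranking_tsv(rt, path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  expect_equal(ncol(raw), 7)
  back <- read_ranking_tsv(path)
  expect_equal(back$lnL, rt$lnL)
  expect_equal(back$delta_aic, rt$delta_aic)
  expect_equal(back$weight, rt$weight)
  # the printed magnitude of the large-gap row survives serialization
  w_iv <- back$weight[back$model_name == "IV"]
  expect_lt(abs(w_iv / 4.32e-97 - 1), 0.01)
})

test_that("shared-divergence comparison enforces inputs and counts parameters", {
  m <- anchored_template()
  tb <- simulate_snp_dataset(m, c(tdiv_AB = 2e5, tdiv_ABC = 8e5), 150,
                             c(A = 4, B = 4, C = 4), 0, seed = 70)
  obs <- build_joint_sfs(tb)
  expect_error(test_shared_divergence(list(a = obs), m, "ABC"),
               "at least 2 taxa")

  tb2 <- simulate_snp_dataset(m, c(tdiv_AB = 2e5, tdiv_ABC = 8e5), 150,
                              c(A = 4, B = 4, C = 4), 0, seed = 71)
  obs2 <- build_joint_sfs(tb2)
  cfg <- opt_config(n_starts = 1, mc_reps = 150, maxit = 40, seed = 72L)
  cd <- test_shared_divergence(list(a = obs, b = obs2), m, "ABC", cfg)
  # one shared time replaces T-1 free times
  expect_equal(cd$k_shared, cd$k_free - 1L)
  expect_equal(cd$k_free, 4L)
  expect_true(cd$preferred %in% c("shared", "free"))
  expect_equal(cd$aic_shared, 2 * cd$k_shared - 2 * cd$lnL_shared)
  # a fixed split time in the template is rejected
  fixed_tmpl <- const_model()
  expect_error(test_shared_divergence(list(a = obs, b = obs2), fixed_tmpl,
                                      "ABC", cfg),
               "not a free symbol|fixed in model")
})
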