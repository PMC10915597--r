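# Packaged validation experiments: simulation studies with known truth
# that exercise the whole pipeline at desk scale. The defaults are the
# scaled-down study conditions used by the test suite and by
# scripts/acceptance.R; the methods vignette discusses the choices.

#' Expected-SFS oracle check
#'
#' Single constant-size population of `n` haploids: the normalized
#' expected SFS is analytically proportional to 1/i. Returns the maximum
#' relative error of the Monte-Carlo estimate across cells.
#'
#' @param n Haploid sample size.
#' @param n_reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return Maximum relative error (scalar).
#' @export
validate_sfs_oracle <- function(n = 10, n_reps = 1e5, seed = 1L) {
  m <- single_pop_const()
  es <- expected_sfs_mc(m, NULL, c(A = n, B = 0, C = 0), n_reps = n_reps,
                        seed = seed)
  i <- seq_len(n - 1)
  analytic <- (1 / i) / sum(1 / i)
  mc <- es$prob[i + 1, 1, 1]
  max(abs(mc - analytic) / analytic)
}

single_pop_const <- function(ne = 1e4) {
  demographic_model(
    "single", "constant size",
    params = list(Ne_A = list(fixed = ne), Ne_B = list(fixed = ne),
                  Ne_C = list(fixed = ne),
                  tdiv_AB = list(fixed = 1e9), tdiv_ABC = list(fixed = 2e9)),
    events = list(evt_split("tdiv_AB", "A", "AB"),
                  evt_split("tdiv_AB", "B", "AB"),
                  evt_split("tdiv_ABC", "AB", "ABC"),
                  evt_split("tdiv_ABC", "C", "ABC")))
}

# the shared-divergence template: constant sizes fixed at a declared
# reference so that split times are identifiable in years (see the
# methods vignette on the scale invariance of SNP-only spectra)
codiv_template <- function(ne_ref = 2e5) {
  demographic_model(
    "anchored-null", "Divergences (anchored scale)",
    params = list(Ne_A = list(fixed = ne_ref), Ne_B = list(fixed = ne_ref),
                  Ne_C = list(fixed = ne_ref),
                  tdiv_AB = list(lower = 1e4, upper = 1e7),
                  tdiv_ABC = list(lower = 1e4, upper = 1e7)),
    events = list(evt_split("tdiv_AB", "A", "AB"),
                  evt_split("tdiv_AB", "B", "AB"),
                  evt_split("tdiv_ABC", "AB", "ABC"),
                  evt_split("tdiv_ABC", "C", "ABC")))
}

#' Divergence-time recovery experiment
#'
#' Simulates datasets under the four-pulse divergence-with-migration
#' model at the Variable Antshrike preset truth (scaled to `n_loci`
#' unlinked SNPs, 8 diploids per population, 1.5% missing genotypes) and
#' refits the model, returning the ratio of estimated to true outer
#' divergence time per replicate. `anchored = TRUE` fixes the effective
#' sizes at the scenario reference (2e5 diploids) before fitting, which
#' makes the time scale identifiable; the default free-size fit is
#' subject to the size-time scaling ridge discussed in the vignette.
#'
#' @param n_replicates Number of simulated datasets.
#' @param n_loci SNPs per dataset.
#' @param n_starts,mc_reps,maxit Optimizer settings per fit.
#' @param anchored Fix the effective sizes at the scenario reference.
#' @param seed Integer seed.
#' @return Numeric vector of `tdiv_ABC` estimate/truth ratios.
#' @export
validate_recovery <- function(n_replicates = 10, n_loci = 2000,
                              n_starts = 20, mc_reps = 150, maxit = 150,
                              anchored = FALSE, seed = 1L) {
  pres <- table5_presets()$caerulescens_like
  truth <- pres$params
  fit_model <- if (anchored) anchor_sizes(pres$model, 2e5) else pres$model
  vapply(seq_len(n_replicates), function(r) {
    tb <- simulate_snp_dataset(pres$model, truth, n_loci,
                               c(A = 16, B = 16, C = 16),
                               missing_rate = 0.015,
                               seed = derive_seed(seed, 100 + r))
    obs <- build_joint_sfs(tb, projection_sizes = c(A = 6, B = 6, C = 6))
    fit <- optimize_model(fit_model, obs,
                          opt_config(n_starts = n_starts, mc_reps = mc_reps,
                                     maxit = maxit,
                                     seed = as.integer(derive_seed(seed, 200 + r))))
    fit$params[["tdiv_ABC"]] / truth[["tdiv_ABC"]]
  }, 0)
}

#' Parametric-bootstrap coverage experiment
#'
#' For each outer replicate, simulates a dataset under the Variable
#' Antshrike preset truth, fits the generating model, runs a scaled
#' parametric bootstrap and records whether the percentile 95% interval
#' for the outer divergence time covers the truth.
#'
#' @param n_outer Outer replicates.
#' @param n_loci SNPs per dataset.
#' @param n_boot Bootstrap replicates per outer replicate.
#' @param anchored Fix the effective sizes at the scenario reference.
#' @param seed Integer seed.
#' @return Logical vector of coverage indicators.
#' @export
validate_coverage <- function(n_outer = 20, n_loci = 300, n_boot = 8,
                              anchored = FALSE, seed = 1L) {
  pres <- table5_presets()$caerulescens_like
  truth <- pres$params
  fit_model <- if (anchored) anchor_sizes(pres$model, 2e5) else pres$model
  proj <- c(A = 6, B = 6, C = 6)
  vapply(seq_len(n_outer), function(r) {
    tb <- simulate_snp_dataset(pres$model, truth, n_loci,
                               c(A = 8, B = 8, C = 8), 0,
                               seed = derive_seed(seed, 300 + r))
    obs <- build_joint_sfs(tb, projection_sizes = proj)
    fit <- optimize_model(fit_model, obs,
                          opt_config(n_starts = 2, mc_reps = 350,
                                     maxit = 85,
                                     seed = as.integer(derive_seed(seed, 400 + r))))
    bt <- parametric_bootstrap(fit_model, fit$params, n_loci,
                               c(A = 8, B = 8, C = 8), n_boot = n_boot,
                               config = opt_config(n_starts = 1,
                                                   mc_reps = 300,
                                                   maxit = 75,
                                                   seed = as.integer(derive_seed(seed, 500 + r))),
                               projection_sizes = proj)
    ci <- bt$ci[bt$ci$param == "tdiv_ABC", ]
    ci$lower <= truth[["tdiv_ABC"]] && truth[["tdiv_ABC"]] <= ci$upper
  }, TRUE)
}

#' Barrier-model discrimination experiment
#'
#' Simulates data under the no-migration (geographic-barrier) candidate
#' of the Variable Antshrike catalog and asks whether AIC ranks it above
#' two migration candidates. Migration fits are warm-started from the
#' barrier fit (they nest it), and all candidates are re-scored under
#' common random numbers before ranking.
#'
#' @param n_replicates Simulated datasets.
#' @param n_loci SNPs per dataset.
#' @param seed Integer seed.
#' @return Logical vector: barrier model ranked first.
#' @export
validate_discrimination <- function(n_replicates = 20, n_loci = 1000,
                                    seed = 1L) {
  cat_c <- build_catalog("caerulescens", models = c("II", "III", "V"))
  barrier <- cat_c$II
  truth <- c(Ne_A = 2e5, Ne_B = 2e5, Ne_C = 2e5, tdiv_AB = 5e5,
             tdiv_ABC = 1.2e6)
  proj <- c(A = 6, B = 6, C = 6)
  warm_from <- function(mig_model, fit_ii) {
    p <- midpoint_params(mig_model)
    shared <- intersect(names(p), names(fit_ii$params))
    p[shared] <- fit_ii$params[shared]
    b <- param_bounds(mig_model)
    psyms <- intersect(grep("^p2?_", names(p), value = TRUE), rownames(b))
    p[psyms] <- b[psyms, "lower"]
    p
  }
  vapply(seq_len(n_replicates), function(r) {
    tb <- simulate_snp_dataset(barrier, truth, n_loci, c(A = 8, B = 8, C = 8),
                               0, seed = derive_seed(seed, 600 + r))
    obs <- build_joint_sfs(tb, projection_sizes = proj)
    cfg <- function(i) opt_config(n_starts = 3, mc_reps = 1200, maxit = 150,
                                  seed = as.integer(derive_seed(seed, 700 + 10 * r + i)))
    f_ii <- optimize_model(barrier, obs, cfg(1))
    fits <- c(list(f_ii), lapply(c("III", "V"), function(nm) {
      optimize_model(cat_c[[nm]], obs, cfg(match(nm, names(cat_c))),
                     extra_starts = list(warm_from(cat_c[[nm]], f_ii)))
    }))
    fits <- rescore_fits(fits, obs, mc_reps = 6000,
                         seed = derive_seed(seed, 800 + r))
    rank_models(fits)$model_name[1] == "II"
  }, TRUE)
}

#' Shared-divergence discrimination experiment
#'
#' Two synthetic taxa are simulated from the anchored constant-size
#' template, either with identical outer divergence times or with times
#' differing four-fold, and [test_shared_divergence()] is asked which
#' hypothesis AIC prefers.
#'
#' @param n_replicates Replicates per scenario.
#' @param scenario `"identical"` or `"fourfold"`.
#' @param n_loci SNPs per taxon.
#' @param seed Integer seed.
#' @return Character vector of preferred hypotheses.
#' @export
validate_codivergence <- function(n_replicates = 20,
                                  scenario = c("identical", "fourfold"),
                                  n_loci = 800, seed = 1L) {
  scenario <- match.arg(scenario)
  tmpl <- codiv_template()
  t2 <- if (scenario == "identical") 8e5 else 2e5
  tab2 <- if (scenario == "identical") 3e5 else 1e5
  vapply(seq_len(n_replicates), function(r) {
    sim <- function(tab, tabc, s) {
      tb <- simulate_snp_dataset(tmpl, c(tdiv_AB = tab, tdiv_ABC = tabc),
                                 n_loci, c(A = 8, B = 8, C = 8), 0, seed = s)
      build_joint_sfs(tb)
    }
    o1 <- sim(3e5, 8e5, derive_seed(seed, 900 + r))
    o2 <- sim(tab2, t2, derive_seed(seed, 1000 + r))
    cd <- test_shared_divergence(
      list(taxon1 = o1, taxon2 = o2), tmpl, "ABC",
      opt_config(n_starts = 2, mc_reps = 1600, maxit = 150,
                 seed = as.integer(derive_seed(seed, 1100 + r))))
    cd$preferred
  }, "")
}

#' Neutrality-statistic calibration experiment
#'
#' Simulates infinite-sites loci for a constant-size population and for
#' a population that expanded recently (a 100-fold size increase), and
#' returns the mean Tajima's D of each regime over replicates with at
#' least one segregating site.
#'
#' @param n_reps Replicate loci per regime.
#' @param n Haploid sequences per locus.
#' @param seed Integer seed.
#' @return Named list with `neutral` and `expansion` mean D.
#' @export
validate_neutrality <- function(n_reps = 500, n = 20, seed = 1L) {
  neutral_model <- single_pop_const(ne = 1e4)
  theta <- 5  # 4 Ne mu_locus
  mu_locus <- theta / (4 * 1e4)
  sims <- simulate_infinite_sites(neutral_model, NULL, n_reps,
                                  c(A = n, B = 0, C = 0), mu_locus,
                                  seed = derive_seed(seed, 1),
                                  constants = evo_constants(gen_time = 1))
  d_neutral <- vapply(sims, function(mat) {
    if (ncol(mat) == 0) return(NA_real_)
    tajimas_d(mat)
  }, 0)
  exp_model <- demographic_model(
    "expansion", "recent expansion",
    params = list(Ne_A = list(fixed = 1e5), Ne_B = list(fixed = 1e5),
                  Ne_C = list(fixed = 1e5),
                  tdiv_AB = list(fixed = 1e9), tdiv_ABC = list(fixed = 2e9)),
    events = list(evt_split("tdiv_AB", "A", "AB"),
                  evt_split("tdiv_AB", "B", "AB"),
                  evt_split("tdiv_ABC", "AB", "ABC"),
                  evt_split("tdiv_ABC", "C", "ABC"),
                  evt_size_change(2e4, "A", 1e3)))
  sims2 <- simulate_infinite_sites(exp_model, NULL, n_reps,
                                   c(A = n, B = 0, C = 0), 2.5e-6,
                                   seed = derive_seed(seed, 2),
                                   constants = evo_constants(gen_time = 1))
  d_exp <- vapply(sims2, function(mat) {
    if (ncol(mat) == 0) return(NA_real_)
    tajimas_d(mat)
  }, 0)
  list(neutral = mean(d_neutral, na.rm = TRUE),
       expansion = mean(d_exp, na.rm = TRUE))
}
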