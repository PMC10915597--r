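#' Parametric bootstrap confidence intervals
#'
#' Simulates replicate SNP datasets of `n_loci` unlinked sites under the
#' fitted parameters, refits the same model to each, and returns
#' percentile 95% intervals (2.5% and 97.5% sort-based quantiles) of the
#' free-parameter estimates. The full-analysis convention is 100
#' replicates; scale down for quick runs.
#'
#' @param model A [demographic_model()].
#' @param fitted_params Named parameter values (e.g. `fit$params` from
#'   [optimize_model()]).
#' @param n_loci SNPs per replicate dataset.
#' @param sample_config Haploid sample sizes `c(A =, B =, C =)` used to
#'   simulate replicates (even counts; diploid genotypes are formed).
#' @param n_boot Number of bootstrap replicates.
#' @param config An [opt_config()] for the refits (its seed also drives
#'   the replicate simulations).
#' @param missing_rate Per-genotype missingness applied to replicates.
#' @param projection_sizes Projection used when building each replicate's
#'   spectrum; default is [build_joint_sfs()]'s.
#' @param constants An [evo_constants()].
#' @return Object of class `bootstrap_result`: `ci` (per-parameter 2.5%
#'   and 97.5% percentiles), the matrix of per-replicate `estimates`, the
#'   replicate count and the number of failed refits (excluded).
#' @export
parametric_bootstrap <- function(model, fitted_params, n_loci,
                                 sample_config, n_boot = 100L,
                                 config = opt_config(),
                                 missing_rate = 0,
                                 projection_sizes = NULL,
                                 constants = evo_constants()) {
  stopifnot(n_boot >= 1)
  viol <- validate_model(model, fitted_params)
  if (length(viol)) {
    stop("fitted parameters invalid:\n  ", paste(viol, collapse = "\n  "))
  }
  bounds <- param_bounds(model)
  free_names <- rownames(bounds)
  ests <- matrix(NA_real_, nrow = n_boot, ncol = max(length(free_names), 0),
                 dimnames = list(NULL, free_names))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    res <- tryCatch({
      dat <- simulate_snp_dataset(model, fitted_params, n_loci,
                                  sample_config, missing_rate,
                                  seed = derive_seed(config$seed, 500000 + b),
                                  constants = constants)
      sfs <- build_joint_sfs(dat, projection_sizes)
      cfg <- config
      cfg$seed <- as.integer(derive_seed(config$seed, 600000 + b))
      # warm-start every refit at the generating (fitted) parameters,
      # the usual practice for parametric-bootstrap refits
      fit <- optimize_model(model, sfs, cfg, constants = constants,
                            extra_starts = list(fitted_params))
      fit$params[free_names]
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      message("bootstrap replicate ", b, " failed: ", conditionMessage(res))
    } else if (length(free_names)) {
      ests[b, ] <- res
    }
  }
  ok <- if (length(free_names)) !is.na(ests[, 1]) else rep(TRUE, n_boot)
  if (length(free_names) && !any(ok)) stop("all bootstrap replicates failed")
  ci <- if (length(free_names)) {
    data.frame(
      param = free_names,
      lower = apply(ests[ok, , drop = FALSE], 2,
                    stats::quantile, probs = 0.025, type = 1, names = FALSE),
      upper = apply(ests[ok, , drop = FALSE], 2,
                    stats::quantile, probs = 0.975, type = 1, names = FALSE),
      row.names = NULL)
  } else {
    # fully fixed model: every replicate refit returns the declared values
    vals <- resolve_params(model)
    data.frame(param = names(vals), lower = unname(vals),
               upper = unname(vals), row.names = NULL)
  }
  structure(list(ci = ci, estimates = ests, n_boot = n_boot,
                 n_failed = n_failed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Parametric bootstrap: ", x$n_boot, " replicate(s), ",
      x$n_failed, " failed\n", sep = "")
  print(x$ci, row.names = FALSE)
  invisible(x)
}
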