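# Multi-start bounded optimization of the Monte-Carlo composite
# likelihood. Each start fixes the simulator seed for all of its
# likelihood evaluations (common random numbers), which turns the noisy MC
# objective into a deterministic function that a derivative-free local
# search can descend; independent starts use fresh random-number streams
# and fresh log-uniform initial points.

#' Optimizer settings
#'
#' @param n_starts Number of independent optimization starts (the full
#'   analysis default is 100; scale down for quick runs).
#' @param mc_reps Monte-Carlo genealogy replicates per likelihood
#'   evaluation.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param seed Integer seed controlling start points and the per-start
#'   common-random-number streams.
#' @param prob_floor Probability floor for observed cells with zero
#'   expected Monte-Carlo mass during optimization. Milder than the
#'   reporting default of [composite_loglik()] so that tail cells do not
#'   dominate the search.
#' @return A list of class `opt_config`.
#' @export
opt_config <- function(n_starts = 100L, mc_reps = 300L, maxit = 300L,
                       seed = 1L, prob_floor = 1e-8) {
  stopifnot(n_starts >= 1, mc_reps >= 1, maxit >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 mc_reps = as.integer(mc_reps),
                 maxit = as.integer(maxit), seed = as.integer(seed),
                 prob_floor = prob_floor),
            class = "opt_config")
}

# smooth penalty for structurally invalid parameter sets (e.g. a pulse
# older than the split merging its populations); guides the search back
# into the valid region
violation_penalty <- function(model, params) {
  values <- resolve_params(model, params)
  topo <- parse_topology(model$topology)
  st <- tryCatch(split_times(model, values), error = function(e) NULL)
  if (is.null(st)) return(1)
  pen <- 0
  if (st[["outer"]] < st[["inner"]]) {
    pen <- pen + (log(st[["inner"]]) - log(st[["outer"]]))^2 + 1
  }
  for (e in model$events) {
    if (e$kind != "pulse") next
    tm <- resolve_field(e$time, values)
    tmerge <- pair_merge_time(e$source, e$dest, topo, st)
    if (tm > tmerge) pen <- pen + (log(tm) - log(tmerge))^2 + 1
  }
  pen
}

#' Fit a demographic model to an observed joint SFS
#'
#' Maximizes the multinomial composite likelihood over the model's free
#' parameters. Parameters are searched on the log scale within their
#' declared bounds; each start draws a log-uniform initial point and runs
#' a bounded Nelder-Mead descent of the common-random-numbers Monte-Carlo
#' objective. The best start wins; exact likelihood ties are broken toward
#' the smaller log-parameter norm. The expected SFS is simulated at the
#' observed spectrum's projected sizes.
#'
#' @param model A [demographic_model()] whose free-parameter bounds are
#'   all positive.
#' @param observed A `joint_sfs` (see [build_joint_sfs()]).
#' @param config An [opt_config()].
#' @param constants An [evo_constants()].
#' @param extra_starts Optional list of named parameter vectors used as
#'   additional deterministic start points (e.g. warm starts from a fit
#'   of a nested model). The geometric bounds midpoint is always start 1;
#'   remaining starts up to `config$n_starts` are log-uniform draws.
#' @return An object of class `fit_result`: best parameter set (`params`),
#'   maximized `lnL`, free-parameter count `k`, and a per-start table
#'   (`starts`) with initial points, converged log-likelihoods and
#'   evaluation counts.
#' @export
optimize_model <- function(model, observed, config = opt_config(),
                           constants = evo_constants(),
                           extra_starts = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(observed, "joint_sfs"),
            inherits(config, "opt_config"))
  bounds <- param_bounds(model)
  k <- nrow(bounds)
  sample_config <- observed$m

  make_objective <- function(crn_seed) {
    force(crn_seed)
    function(u) {
      if (any(!is.finite(u))) return(1e12)
      lo <- log(bounds[, "lower"]); hi <- log(bounds[, "upper"])
      out_of_box <- pmax(lo - u, 0) + pmax(u - hi, 0)
      if (any(out_of_box > 0)) return(1e10 * (1 + sum(out_of_box^2)))
      params <- stats::setNames(exp(u), rownames(bounds))
      pen <- violation_penalty(model, params)
      if (pen > 0) return(1e8 * (1 + pen))
      expected <- expected_sfs_mc(model, params, sample_config,
                                  n_reps = config$mc_reps, seed = crn_seed,
                                  constants = constants, check = FALSE)
      ll <- suppressWarnings(
        composite_loglik(observed, expected, prob_floor = config$prob_floor))
      if (!is.finite(ll)) return(1e12)
      -ll
    }
  }

  if (k == 0L) {
    params <- resolve_params(model)
    crn <- derive_seed(config$seed, 1)
    expected <- expected_sfs_mc(model, params, sample_config,
                                n_reps = config$mc_reps, seed = crn,
                                constants = constants)
    ll <- suppressWarnings(
      composite_loglik(observed, expected, prob_floor = config$prob_floor))
    starts <- data.frame(start = 1L, crn_seed = crn, lnL = ll,
                         convergence = 0L, fevals = 1L)
    return(structure(list(model = model, model_name = model$name,
                          params = params, lnL = ll, k = 0L,
                          starts = starts, config = config),
                     class = "fit_result"))
  }

  if (any(bounds[, "lower"] <= 0)) {
    stop("free-parameter bounds must be positive for log-scale search")
  }
  lo <- log(bounds[, "lower"]); hi <- log(bounds[, "upper"])
  all_finite <- all(is.finite(lo)) && all(is.finite(hi))
  if (!all_finite) stop("free-parameter bounds must be finite")

  det_starts <- c(
    list((lo + hi) / 2),  # geometric midpoint of the bounds (log scale)
    lapply(extra_starts, function(p) {
      full <- resolve_params(model, p)
      pmin(pmax(log(full[rownames(bounds)]), lo), hi)
    }))
  n_total <- max(config$n_starts, length(det_starts))
  records <- vector("list", n_total)
  best <- NULL
  for (s in seq_len(n_total)) {
    crn <- derive_seed(config$seed, s)
    u0 <- if (s <= length(det_starts)) {
      unname(det_starts[[s]])
    } else {
      with_local_seed(derive_seed(config$seed, 100000 + s), {
        lo + stats::runif(k) * (hi - lo)
      })
    }
    obj <- make_objective(crn)
    fit <- if (k == 1L) {
      o <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-3)
      list(par = o$minimum, value = o$objective, convergence = 0L,
           counts = c(`function` = NA_integer_))
    } else {
      f1 <- stats::optim(u0, obj, method = "Nelder-Mead",
                         control = list(maxit = config$maxit, reltol = 1e-9))
      if (f1$convergence != 0L) {
        # restart from the found optimum when the iteration budget was
        # exhausted: re-inflating the collapsed simplex routinely
        # escapes premature convergence
        f2 <- stats::optim(f1$par, obj, method = "Nelder-Mead",
                           control = list(maxit = config$maxit,
                                          reltol = 1e-9))
        if (f2$value <= f1$value) {
          f2$counts <- f1$counts + f2$counts
          f1 <- f2
        }
      }
      f1
    }
    par <- pmin(pmax(fit$par, lo), hi)
    rec <- data.frame(start = s, crn_seed = crn, lnL = -fit$value,
                      convergence = as.integer(fit$convergence),
                      fevals = as.integer(fit$counts[["function"]]))
    for (j in seq_len(k)) rec[[paste0("init_", rownames(bounds)[j])]] <- exp(u0[j])
    records[[s]] <- rec
    cand <- list(u = par, lnL = -fit$value, norm = sqrt(sum(par^2)))
    if (is.null(best) || cand$lnL > best$lnL ||
        (cand$lnL == best$lnL && cand$norm < best$norm)) {
      best <- cand
    }
  }
  if (!is.finite(best$lnL) || best$lnL <= -1e7) {
    stop("objective non-finite or invalid at every start")
  }
  free <- stats::setNames(exp(best$u), rownames(bounds))
  params <- resolve_params(model, free)
  at_bound <- rownames(bounds)[best$u <= lo + 1e-8 | best$u >= hi - 1e-8]
  structure(list(model = model, model_name = model$name, params = params,
                 lnL = best$lnL, k = k, starts = do.call(rbind, records),
                 at_bound = at_bound, config = config),
            class = "fit_result")
}

#' Re-score fitted models under common random numbers
#'
#' Re-evaluates each fit's composite log-likelihood at its optimized
#' parameters using one shared simulator seed and (typically) more
#' Monte-Carlo replicates than were affordable during optimization. AIC
#' differences between models are then free of between-fit Monte-Carlo
#' seed noise, which matters when candidate models differ by a few
#' likelihood units.
#'
#' @param fits List of `fit_result` objects fitted to `observed`.
#' @param observed The `joint_sfs` the fits were made to.
#' @param mc_reps Monte-Carlo replicates for re-scoring.
#' @param seed Shared seed.
#' @param prob_floor Probability floor (see [composite_loglik()]).
#' @param constants An [evo_constants()].
#' @return The list of fits with updated `lnL` elements.
#' @export
rescore_fits <- function(fits, observed, mc_reps = 2000L, seed = 1L,
                         prob_floor = 1e-8, constants = evo_constants()) {
  stopifnot(all(vapply(fits, inherits, TRUE, "fit_result")))
  lapply(fits, function(f) {
    expected <- expected_sfs_mc(f$model, f$params, observed$m,
                                n_reps = mc_reps, seed = seed,
                                constants = constants)
    f$lnL <- suppressWarnings(
      composite_loglik(observed, expected, prob_floor = prob_floor))
    f
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit of model ", x$model_name, ": lnL = ", format(x$lnL),
      ", k = ", x$k, " (", nrow(x$starts), " start(s))\n", sep = "")
  if (length(x$at_bound)) {
    cat("  parameters at bounds: ", paste(x$at_bound, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
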