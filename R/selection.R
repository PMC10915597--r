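# AIC-based ranking of fitted models and the cross-taxon shared-divergence
# comparison.

#' Akaike information criterion
#'
#' @param lnL Maximized log-likelihood (finite).
#' @param k Number of free parameters (>= 0).
#' @return `2 k - 2 lnL`.
#' @export
aic <- function(lnL, k) {
  if (any(!is.finite(lnL))) stop("non-finite log-likelihood")
  if (any(k < 0)) stop("k must be non-negative")
  2 * k - 2 * lnL
}

#' Rank candidate models by AIC
#'
#' Computes `delta_AIC_i = AIC_i - min(AIC)` and the relative likelihood
#' `w_i = exp(-delta_AIC_i / 2)`, the convention in which the best model
#' has weight 1 (set `normalize = TRUE` for weights that sum to one).
#' Rows are sorted by delta-AIC with ties broken by model name and ranked
#' strictly 1, 2, 3, ...
#'
#' @param fits A list of `fit_result` objects, or a data frame with
#'   columns `model_name`, `lnL`, `k` and optionally `model_type`.
#' @param normalize Divide weights by their sum.
#' @return A `ranking_table` data frame with columns `rank`,
#'   `model_type`, `model_name`, `lnL`, `k`, `delta_aic`, `weight`.
#' @examples
#' fits <- data.frame(model_name = c("X", "III"),
#'                    lnL = c(-5262.392335, -5261.258098), k = c(14, 16))
#' rank_models(fits)
#' @export
rank_models <- function(fits, normalize = FALSE) {
  df <- if (is.data.frame(fits)) {
    fits
  } else {
    stopifnot(length(fits) >= 1,
              all(vapply(fits, inherits, TRUE, "fit_result")))
    data.frame(
      model_name = vapply(fits, function(f) f$model_name, ""),
      model_type = vapply(fits, function(f) f$model$model_type %||% "", ""),
      lnL = vapply(fits, function(f) f$lnL, 0),
      k = vapply(fits, function(f) f$k, 0L))
  }
  stopifnot(all(c("model_name", "lnL", "k") %in% names(df)), nrow(df) >= 1)
  if (anyDuplicated(df$model_name)) stop("duplicate model names")
  if (is.null(df$model_type)) df$model_type <- ""
  a <- aic(df$lnL, df$k)
  delta <- a - min(a)
  w <- exp(-delta / 2)
  if (normalize) w <- w / sum(w)
  ord <- order(delta, df$model_name)
  out <- data.frame(rank = seq_len(nrow(df)),
                    model_type = df$model_type[ord],
                    model_name = df$model_name[ord],
                    lnL = df$lnL[ord], k = df$k[ord],
                    delta_aic = delta[ord], weight = w[ord])
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Write and read a model-ranking table
#'
#' Tab-separated, seven columns (rank, model type, model name,
#' log-likelihood, parameter count, delta-AIC, weight) at full float
#' precision; weights below double precision print as 0. Round-trips
#' through `read_ranking_tsv()`.
#'
#' @param ranking A `ranking_table` from [rank_models()].
#' @param path Output path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranking_table"))
  fmt <- function(x) sprintf("%.17g", x)
  df <- data.frame(rank = ranking$rank, model_type = ranking$model_type,
                   model_name = ranking$model_name,
                   loglik = fmt(ranking$lnL),
                   n_parameters = ranking$k,
                   delta_aic = fmt(ranking$delta_aic),
                   weight = fmt(ranking$weight))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "character",
                                         "numeric", "integer", "numeric",
                                         "numeric"))
  names(df)[names(df) == "loglik"] <- "lnL"
  names(df)[names(df) == "n_parameters"] <- "k"
  names(df)[names(df) == "weight"] <- "weight"
  class(df) <- c("ranking_table", "data.frame")
  df
}

# symbol of the divergence-time parameter for the named split
split_symbol <- function(model, which_split = c("AB", "ABC")) {
  which_split <- match.arg(which_split)
  topo <- parse_topology(model$topology)
  parent <- if (which_split == "AB") topo$anc1 else topo$root
  for (e in model$events) {
    if (e$kind == "split" && e$parent == parent) {
      if (!is.character(e$time)) {
        stop("the ", which_split, " split time is not a free symbol in ",
             "model ", model$name)
      }
      if (!is_free_param(model$params[[e$time]])) {
        stop("the ", which_split, " split time (", e$time,
             ") is fixed in model ", model$name)
      }
      return(e$time)
    }
  }
  stop("no ", which_split, " split found in model ", model$name)
}

#' Shared versus independent divergence times across taxa
#'
#' Tests whether two or more taxa share the timing of one divergence by
#' profile likelihood over a common grid of candidate split times. For
#' every taxon, the composite log-likelihood is profiled at each grid
#' time (the remaining parameters re-optimized with the split time held
#' fixed) under taxon-specific common random numbers, so each profile
#' curve is a deterministic function of the data and the seed. The free
#' hypothesis takes each taxon's own curve maximum; the shared hypothesis
#' maximizes the summed curves over one common time. Because both
#' hypotheses read the same curves, their likelihood difference is free
#' of Monte-Carlo seed noise and is non-negative by construction, and the
#' comparison reduces to AIC with the shared model saving `T - 1`
#' parameters for `T` taxa.
#'
#' @param observed_list Named list (>= 2) of `joint_sfs` objects, one per
#'   taxon.
#' @param models A single template [demographic_model()] applied to every
#'   taxon, or a list of per-taxon models; the named split time must be a
#'   free parameter in each.
#' @param which_split `"AB"` (inner divergence) or `"ABC"` (outer).
#' @param config An [opt_config()] for the inner profile fits.
#' @param n_grid Number of log-spaced candidate split times spanning the
#'   intersection of the taxa's bounds.
#' @param constants An [evo_constants()].
#' @return Object of class `codiv_comparison`: per-taxon free optima
#'   (`free_fits`: parameters, profile log-likelihood, k), the shared
#'   solution (`shared_params`, `shared_tdiv`), both total AICs, the
#'   profile curves, and the `preferred` hypothesis (lower total AIC).
#' @export
test_shared_divergence <- function(observed_list, models,
                                   which_split = c("AB", "ABC"),
                                   config = opt_config(), n_grid = 21L,
                                   constants = evo_constants()) {
  which_split <- match.arg(which_split)
  if (!is.list(observed_list) || length(observed_list) < 2) {
    stop("need at least 2 taxa to compare divergence times")
  }
  stopifnot(all(vapply(observed_list, inherits, TRUE, "joint_sfs")),
            n_grid >= 5)
  n_taxa <- length(observed_list)
  taxa <- names(observed_list) %||% paste0("taxon", seq_len(n_taxa))
  if (inherits(models, "demographic_model")) {
    models <- rep(list(models), n_taxa)
  }
  stopifnot(length(models) == n_taxa)
  syms <- vapply(models, split_symbol, "", which_split = which_split)

  bounds_list <- lapply(models, param_bounds)
  grid_lo <- max(vapply(seq_len(n_taxa),
                        function(i) bounds_list[[i]][syms[i], "lower"], 0))
  grid_hi <- min(vapply(seq_len(n_taxa),
                        function(i) bounds_list[[i]][syms[i], "upper"], 0))
  if (grid_lo >= grid_hi) stop("split-time bounds do not overlap across taxa")
  grid <- exp(seq(log(grid_lo), log(grid_hi), length.out = n_grid))

  curves <- matrix(NA_real_, nrow = n_taxa, ncol = n_grid,
                   dimnames = list(taxa, NULL))
  sols <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    sols[[i]] <- vector("list", n_grid)
    cfg_i <- config
    cfg_i$seed <- as.integer(derive_seed(config$seed, 10 + i))
    other <- if (which_split == "ABC") "AB" else "ABC"
    osym <- tryCatch(split_symbol(models[[i]], other),
                     error = function(e) NULL)
    prev <- NULL
    for (g in seq_len(n_grid)) {
      mi <- models[[i]]
      mi$params[[syms[i]]] <- list(fixed = grid[g])
      if (!is.null(osym)) {
        # pinning one split time narrows the other's admissible box
        b <- models[[i]]$params[[osym]]
        if (which_split == "ABC") {
          new_hi <- min(b$upper, grid[g])
          mi$params[[osym]] <- if (new_hi <= b$lower) {
            list(fixed = min(b$lower, grid[g]))
          } else list(lower = b$lower, upper = new_hi)
        } else {
          new_lo <- max(b$lower, grid[g])
          mi$params[[osym]] <- if (new_lo >= b$upper) {
            list(fixed = max(b$upper, grid[g]))
          } else list(lower = new_lo, upper = b$upper)
        }
      }
      fit_g <- tryCatch(
        optimize_model(mi, observed_list[[i]], cfg_i, constants = constants,
                       extra_starts = if (is.null(prev)) NULL else
                         list(prev)),
        error = function(e) NULL)
      if (is.null(fit_g)) {
        curves[i, g] <- -Inf
        next
      }
      curves[i, g] <- fit_g$lnL
      full <- fit_g$params
      full[[syms[i]]] <- grid[g]
      sols[[i]][[g]] <- full
      prev <- fit_g$params
    }
  }

  g_free <- apply(curves, 1, which.max)
  lnL_free <- sum(curves[cbind(seq_len(n_taxa), g_free)])
  total_curve <- colSums(curves)
  g_shared <- which.max(total_curve)
  lnL_shared <- total_curve[g_shared]

  k_t <- vapply(models, count_free_parameters, 0L)
  k_free <- sum(k_t)
  k_shared <- k_free - (n_taxa - 1L)
  aic_free <- aic(lnL_free, k_free)
  aic_shared <- aic(lnL_shared, k_shared)

  free_fits <- lapply(seq_len(n_taxa), function(i) {
    list(params = sols[[i]][[g_free[i]]], lnL = curves[i, g_free[i]],
         k = k_t[i], tdiv = grid[g_free[i]])
  })
  names(free_fits) <- taxa
  shared_params <- lapply(seq_len(n_taxa), function(i) sols[[i]][[g_shared]])
  names(shared_params) <- taxa

  structure(list(
    which_split = which_split, taxa = taxa, grid = grid, curves = curves,
    free_fits = free_fits, shared_params = shared_params,
    shared_tdiv = grid[g_shared],
    lnL_free = lnL_free, lnL_shared = lnL_shared,
    k_free = k_free, k_shared = k_shared,
    aic_free = aic_free, aic_shared = aic_shared,
    preferred = if (aic_shared <= aic_free) "shared" else "free"),
    class = "codiv_comparison")
}

#' @export
print.codiv_comparison <- function(x, ...) {
  cat("Shared-divergence comparison (", x$which_split, " split, ",
      length(x$taxa), " taxa)\n", sep = "")
  cat(sprintf("  free : lnL = %.3f, k = %d, AIC = %.3f\n",
              x$lnL_free, x$k_free, x$aic_free))
  cat(sprintf("  shared: lnL = %.3f, k = %d, AIC = %.3f (tdiv = %.0f y)\n",
              x$lnL_shared, x$k_shared, x$aic_shared, x$shared_tdiv))
  cat("  preferred hypothesis: ", x$preferred, "\n", sep = "")
  invisible(x)
}
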