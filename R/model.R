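# Event-based three-population demographic models.
#
# A model couples (1) a rooted topology over the leaf populations A, B, C,
# (2) a named parameter table with box bounds (a parameter with degenerate
# bounds, declared `fixed`, is not optimized), (3) a per-population Ne map,
# and (4) an ordered event list whose fields reference parameter symbols.
# Times are years; conversion to generations happens at simulation time.

parse_topology <- function(topology) {
  m <- regmatches(topology,
                  regexec("^\\(\\(([ABC]),([ABC])\\),([ABC])\\)$", topology))[[1]]
  if (length(m) != 4L || anyDuplicated(m[2:4]) > 0L ||
      !setequal(m[2:4], c("A", "B", "C"))) {
    stop("topology must be of the form ((X,Y),Z) over populations A, B, C")
  }
  inner <- sort(m[2:3])
  list(inner = inner, outer = m[4],
       anc1 = paste(inner, collapse = ""), root = "ABC")
}

#' Construct a three-population demographic model
#'
#' @param name Model name (e.g. `"VI"`).
#' @param model_type Descriptive category, e.g. `"Migrations and
#'   divergence"`.
#' @param params Named list of parameter declarations. Each element is
#'   either `list(lower =, upper =)` (a free parameter, optimized on log
#'   scale within the bounds) or `list(fixed = value)` (held constant;
#'   counted as zero free parameters).
#' @param events List of [events] built with `evt_*()` constructors. The
#'   split events must describe the given topology: the two inner leaves
#'   merging into their ancestor at one time, then that ancestor and the
#'   outer leaf merging into the root.
#' @param ne Named map from population label (leaves and ancestors) to a
#'   parameter symbol, a number, or `"tied"`. `"tied"` (ancestors only)
#'   copies the resolved Ne of the outer-leaf lineage, the default when an
#'   ancestral size is not estimated.
#' @param topology Rooted shape over the leaves, default `"((A,B),C)"`.
#' @param status Provenance flag for catalog files: `"transcribed"` or
#'   `"inferred"`.
#' @return An object of class `demographic_model`.
#' @seealso [build_catalog()], [validate_model()], [count_free_parameters()]
#' @export
demographic_model <- function(name, model_type, params, events,
                              ne = NULL, topology = "((A,B),C)",
                              status = "inferred") {
  topo <- parse_topology(topology)
  if (is.null(ne)) {
    ne <- list(A = "Ne_A", B = "Ne_B", C = "Ne_C")
    ne[[topo$anc1]] <- "tied"
    ne[[topo$root]] <- "tied"
  }
  for (lab in c("A", "B", "C", topo$anc1, topo$root)) {
    if (is.null(ne[[lab]])) {
      ne[[lab]] <- if (lab %in% c(topo$anc1, topo$root)) "tied" else
        stop("ne map is missing leaf population ", lab)
    }
  }
  stopifnot(is.list(params), length(names(params)) == length(params))
  for (sym in names(params)) {
    p <- params[[sym]]
    ok <- (is.list(p) && !is.null(p$fixed)) ||
      (is.list(p) && is_scalar_number(p$lower) && is_scalar_number(p$upper) &&
         p$lower <= p$upper)
    if (!ok) stop("parameter ", sym, " must declare {lower, upper} or {fixed}")
  }
  stopifnot(all(vapply(events, inherits, TRUE, "demographic_event")))
  model <- structure(
    list(name = name, model_type = model_type, topology = topology,
         status = status, ne = ne, params = params, events = events),
    class = "demographic_model")
  split_times(model)  # errors if the splits do not form the topology's tree
  model
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model ", x$name, " (", x$model_type, ")\n", sep = "")
  cat("  topology: ", x$topology, "; free parameters: ",
      count_free_parameters(x), "\n", sep = "")
  cat("  events:\n")
  for (e in x$events) { cat("    "); print(e) }
  invisible(x)
}

is_free_param <- function(p) {
  is.null(p$fixed) && p$lower < p$upper
}

#' Number of free parameters of a model
#'
#' Counts the parameters whose declared bounds are non-degenerate; this is
#' the `k` that enters the AIC.
#'
#' @param model A [demographic_model()].
#' @return Integer count.
#' @export
count_free_parameters <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  sum(vapply(model$params, is_free_param, TRUE))
}

#' Free-parameter bounds of a model
#'
#' @param model A [demographic_model()].
#' @return A matrix with columns `lower`, `upper` and one row per free
#'   parameter.
#' @export
param_bounds <- function(model) {
  free <- Filter(is_free_param, model$params)
  out <- cbind(lower = vapply(free, function(p) p$lower, 0),
               upper = vapply(free, function(p) p$upper, 0))
  rownames(out) <- names(free)
  out
}

# Full parameter vector: fixed values filled in, free values taken from
# `params` (named numeric). Errors on missing free parameters.
resolve_params <- function(model, params = NULL) {
  out <- numeric(0)
  for (sym in names(model$params)) {
    p <- model$params[[sym]]
    if (!is.null(p$fixed)) {
      out[sym] <- p$fixed
    } else if (!is.null(params) && sym %in% names(params)) {
      out[sym] <- params[[sym]]
    } else if (p$lower == p$upper) {
      out[sym] <- p$lower
    } else {
      stop("no value supplied for free parameter ", sym)
    }
  }
  out
}

#' Midpoint parameter set of a model
#'
#' Geometric midpoint of each free parameter's bounds (bounds here span
#' orders of magnitude, so the log-scale middle is the natural center);
#' fixed parameters at their declared values.
#'
#' @param model A [demographic_model()].
#' @return Named numeric vector over all model parameters.
#' @export
midpoint_params <- function(model) {
  vals <- vapply(names(model$params), function(sym) {
    p <- model$params[[sym]]
    if (!is.null(p$fixed)) return(as.double(p$fixed))
    if (p$lower > 0) sqrt(p$lower * p$upper) else (p$lower + p$upper) / 2
  }, 0)
  names(vals) <- names(model$params)
  vals
}

#' Anchor a model's population sizes at a reference value
#'
#' Returns the model with every effective-size parameter (symbols
#' starting with `Ne`) fixed at `ne_ref`. With SNP-only joint-SFS data
#' the composite likelihood is invariant to jointly rescaling all sizes
#' and times, so absolute divergence times are only identified relative
#' to an assumed size (or, equivalently, a mutation-rate anchor);
#' fixing the sizes at a declared reference makes time estimation
#' well-posed, at the cost of conditioning every time estimate on that
#' reference.
#'
#' @param model A [demographic_model()].
#' @param ne_ref Reference diploid effective size.
#' @return The anchored `demographic_model` (free-parameter count drops
#'   by the number of previously free size parameters).
#' @export
anchor_sizes <- function(model, ne_ref) {
  stopifnot(inherits(model, "demographic_model"), ne_ref > 0)
  for (sym in grep("^Ne", names(model$params), value = TRUE)) {
    model$params[[sym]] <- list(fixed = ne_ref)
  }
  model
}

resolve_field <- function(x, values) {
  if (is.character(x)) {
    if (!x %in% names(values)) stop("unknown parameter symbol: ", x)
    unname(values[[x]])
  } else {
    as.double(x)
  }
}

# times of the two splits; also validates the split events against the
# topology (two inner leaves into anc1 at equal times, anc1 + outer leaf
# into the root at equal times).
split_times <- function(model, values = NULL) {
  topo <- parse_topology(model$topology)
  splits <- Filter(function(e) e$kind == "split", model$events)
  if (length(splits) != 4L) {
    stop("model must contain exactly 4 split events (two per divergence)")
  }
  child <- vapply(splits, function(e) e$child, "")
  parent <- vapply(splits, function(e) e$parent, "")
  inner_i <- which(parent == topo$anc1)
  outer_i <- which(parent == topo$root)
  if (length(inner_i) != 2L || !setequal(child[inner_i], topo$inner) ||
      length(outer_i) != 2L ||
      !setequal(child[outer_i], c(topo$anc1, topo$outer))) {
    stop("split events do not describe topology ", model$topology)
  }
  tin <- lapply(splits[inner_i], function(e) e$time)
  tou <- lapply(splits[outer_i], function(e) e$time)
  if (!identical(tin[[1]], tin[[2]]) || !identical(tou[[1]], tou[[2]])) {
    stop("the two split events of one divergence must share a time")
  }
  if (is.null(values)) return(invisible(NULL))
  c(inner = resolve_field(tin[[1]], values),
    outer = resolve_field(tou[[1]], values))
}

# merge time (in the values of `st`) of a pair of population labels
pair_merge_time <- function(p1, p2, topo, st) {
  if (all(c(p1, p2) %in% topo$inner)) st[["inner"]] else st[["outer"]]
}

#' Validate a parameter set against a model
#'
#' Checks bounds, event-level constraints (non-negative times, admixture
#' fractions in \[0, 1\], positive sizes, bottleneck strengths in (0, 1)),
#' the ordering of the two divergence times, and that every admixture pulse
#' is no older than the split that merges its source and destination.
#' Violations are returned as data, not thrown.
#'
#' @param model A [demographic_model()].
#' @param params Named numeric vector of values for the free parameters
#'   (fixed parameters are filled in automatically).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_model <- function(model, params = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  values <- resolve_params(model, params)
  out <- character(0)
  tol <- 1e-9
  for (sym in names(model$params)) {
    p <- model$params[[sym]]
    if (is.null(p$fixed)) {
      lo <- p$lower; hi <- p$upper
      v <- values[[sym]]
      if (v < lo - tol * max(1, abs(lo)) || v > hi + tol * max(1, abs(hi))) {
        out <- c(out, sprintf("%s = %g outside bounds [%g, %g]", sym, v, lo, hi))
      }
    }
  }
  topo <- parse_topology(model$topology)
  st <- split_times(model, values)
  if (st[["outer"]] < st[["inner"]]) {
    out <- c(out, sprintf(
      "outer divergence time (%g) is more recent than inner (%g)",
      st[["outer"]], st[["inner"]]))
  }
  for (lab in names(model$ne)) {
    spec <- model$ne[[lab]]
    if (identical(spec, "tied")) next
    v <- resolve_field(spec, values)
    if (!is.finite(v) || v <= 0) {
      out <- c(out, sprintf("Ne of %s = %g must be positive", lab, v))
    }
  }
  for (e in model$events) {
    tm <- resolve_field(e$time, values)
    if (tm < 0) out <- c(out, sprintf("%s event time %g is negative", e$kind, tm))
    if (e$kind == "pulse") {
      p <- resolve_field(e$fraction, values)
      if (p < 0 || p > 1) {
        out <- c(out, sprintf("pulse fraction %g outside [0, 1]", p))
      }
      tmerge <- pair_merge_time(e$source, e$dest, topo, st)
      if (tm > tmerge + tol * max(1, tmerge)) {
        out <- c(out, sprintf(
          "pulse %s -> %s at %g postdates the split merging them (%g)",
          e$source, e$dest, tm, tmerge))
      }
    }
    if (e$kind == "size_change") {
      v <- resolve_field(e$new_ne, values)
      if (v <= 0) out <- c(out, sprintf("size change to Ne = %g must be positive", v))
    }
    if (e$kind == "bottleneck") {
      s <- resolve_field(e$strength, values)
      if (s <= 0 || s >= 1) {
        out <- c(out, sprintf("bottleneck strength %g outside (0, 1)", s))
      }
    }
  }
  out
}

# --- compilation to the simulator's numeric encoding ----------------------

pop_index <- function(lab, topo) {
  idx <- c(A = 0, B = 1, C = 2)
  idx[[topo$anc1]] <- 3
  idx[[topo$root]] <- 4
  if (!lab %in% names(idx)) stop("unknown population label: ", lab)
  idx[[lab]]
}

EV_CODE <- c(split = 1, pulse = 2, size_change = 3, growth = 4,
             bottleneck = 5)

# Resolve symbols, convert years to generations, and emit the numeric
# arguments the C++ simulator takes. A pulse touching the inner ancestor at
# a time more recent than the inner divergence is interpreted as acting on
# the A-B pair jointly and is expanded into two leaf-level pulses whose
# combined intensity equals the declared fraction.
compile_model <- function(model, params = NULL, constants = evo_constants(),
                          check = TRUE) {
  values <- resolve_params(model, params)
  if (check) {
    viol <- validate_model(model, params)
    if (length(viol)) {
      stop("invalid parameter set:\n  ", paste(viol, collapse = "\n  "))
    }
  }
  topo <- parse_topology(model$topology)
  st <- split_times(model, values)

  ne0 <- numeric(5)
  for (lab in c("A", "B", "C")) {
    ne0[pop_index(lab, topo) + 1] <- resolve_field(model$ne[[lab]], values)
  }
  outer_ne <- ne0[pop_index(topo$outer, topo) + 1]
  for (lab in c(topo$anc1, topo$root)) {
    spec <- model$ne[[lab]]
    ne0[pop_index(lab, topo) + 1] <-
      if (identical(spec, "tied")) outer_ne else resolve_field(spec, values)
  }

  g0 <- numeric(5)
  rows <- list()
  add_row <- function(time_gen, kind, a, b, val, prio) {
    rows[[length(rows) + 1]] <<- c(time_gen, EV_CODE[[kind]], a, b, val, prio)
  }
  for (e in model$events) {
    tm_y <- resolve_field(e$time, values)
    tm <- tm_y / constants$gen_time
    if (e$kind == "split") {
      add_row(tm, "split", pop_index(e$child, topo), pop_index(e$parent, topo),
              0, 1)
    } else if (e$kind == "pulse") {
      p <- resolve_field(e$fraction, values)
      if (p <= 0) next  # a zero pulse is a no-op: compiled away so that it
                        # cannot perturb the simulator's random stream
      inner_pair_pulse <- (e$source == topo$anc1 || e$dest == topo$anc1) &&
        tm_y < st[["inner"]]
      if (inner_pair_pulse) {
        half <- p / 2
        if (e$dest == topo$anc1) {
          # forward: source seeds both inner leaves, half the mass each
          for (leaf in topo$inner) {
            add_row(tm, "pulse", pop_index(e$source, topo),
                    pop_index(leaf, topo), half, 0)
          }
        } else {
          # forward: the joint inner pair seeds dest; backward a dest
          # lineage ends in either inner leaf with probability p/2
          l1 <- topo$inner[1]; l2 <- topo$inner[2]
          q2 <- if (half >= 1) 1 else half / (1 - half)
          add_row(tm, "pulse", pop_index(l1, topo), pop_index(e$dest, topo),
                  half, 0)
          add_row(tm, "pulse", pop_index(l2, topo), pop_index(e$dest, topo),
                  q2, 0)
        }
      } else {
        add_row(tm, "pulse", pop_index(e$source, topo),
                pop_index(e$dest, topo), p, 0)
      }
    } else if (e$kind == "size_change") {
      add_row(tm, "size_change", pop_index(e$pop, topo), 0,
              resolve_field(e$new_ne, values), 0)
    } else if (e$kind == "growth") {
      g <- resolve_field(e$rate, values)
      if (tm == 0) {
        g0[pop_index(e$pop, topo) + 1] <- g
      } else {
        add_row(tm, "growth", pop_index(e$pop, topo), 0, g, 0)
      }
    } else if (e$kind == "bottleneck") {
      add_row(tm, "bottleneck", pop_index(e$pop, topo), 0,
              resolve_field(e$strength, values), 0)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, nrow = 0, ncol = 6)
  if (nrow(ev) > 1) {
    ev <- ev[order(ev[, 1], ev[, 6]), , drop = FALSE]
  }
  list(npop = 5L, ne0 = ne0, g0 = g0,
       events = ev[, 1:5, drop = FALSE], topo = topo, values = values)
}

# haploid sample configuration over the three leaves
as_sample_config <- function(sample_config) {
  if (is.null(names(sample_config))) names(sample_config) <- c("A", "B", "C")
  stopifnot(setequal(names(sample_config), c("A", "B", "C")),
            all(sample_config >= 0))
  n <- as.integer(sample_config[c("A", "B", "C")])
  if (sum(n) < 2) stop("need at least two sampled allele copies in total")
  if (sum(n) > 60) stop("total haploid sample size must be <= 60")
  c(n, 0L, 0L)
}
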