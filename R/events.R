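# Demographic event vocabulary. An event field holding a parameter symbol
# (character) is resolved against a parameter set at simulation time; a
# numeric field is a fixed value. All times are in years before present.

event_kinds <- c("split", "pulse", "size_change", "growth", "bottleneck")

new_event <- function(kind, fields) {
  stopifnot(kind %in% event_kinds)
  structure(c(list(kind = kind), fields), class = "demographic_event")
}

chk_ref <- function(x, what) {
  if (!(is.character(x) && length(x) == 1L) && !is_scalar_number(x)) {
    stop(what, " must be a parameter symbol or a single number")
  }
  x
}

#' Demographic events
#'
#' Constructors for the events a [demographic_model()] is built from.
#' Times are years before present; fields may be numbers or parameter
#' symbols (character) resolved from a parameter set when the model is
#' simulated.
#'
#' * `evt_split(time, child, parent)`: at `time`, lineages of `child` merge
#'   into `parent` (looking backward in time). Two leaf populations joining
#'   an ancestor are written as two split events at the same time.
#' * `evt_pulse(time, source, dest, fraction)`: instantaneous admixture in
#'   which, forward in time, a proportion `fraction` of `dest` derives from
#'   `source` at `time`. Applied backward as independent per-lineage
#'   reassignment with probability `fraction`.
#' * `evt_size_change(time, pop, new_ne)`: `pop` has diploid size `new_ne`
#'   at all times older than `time`.
#' * `evt_growth(pop, rate, time = 0)`: `pop` grew exponentially forward in
#'   time at `rate` per generation up to `time` years ago (so, looking
#'   backward, its size shrinks at that rate beyond `time`).
#' * `evt_bottleneck(time, pop, strength)`: at times older than `time` the
#'   population size is multiplied by `strength` (in (0, 1)).
#'
#' @param time Event time in years (number or symbol).
#' @param child,parent,pop,source,dest Population labels, e.g. `"A"`,
#'   `"B"`, `"C"`, `"AB"`, `"ABC"`.
#' @param fraction Admixture proportion in \[0, 1\] (number or symbol).
#' @param new_ne Diploid effective size (number or symbol).
#' @param rate Per-generation exponential growth rate (number or symbol).
#' @param strength Size multiplier in (0, 1) (number or symbol).
#' @return A `demographic_event` object.
#' @name events
NULL

#' @rdname events
#' @export
evt_split <- function(time, child, parent) {
  new_event("split", list(time = chk_ref(time, "time"),
                          child = child, parent = parent))
}

#' @rdname events
#' @export
evt_pulse <- function(time, source, dest, fraction) {
  new_event("pulse", list(time = chk_ref(time, "time"), source = source,
                          dest = dest, fraction = chk_ref(fraction, "fraction")))
}

#' @rdname events
#' @export
evt_size_change <- function(time, pop, new_ne) {
  new_event("size_change", list(time = chk_ref(time, "time"), pop = pop,
                                new_ne = chk_ref(new_ne, "new_ne")))
}

#' @rdname events
#' @export
evt_growth <- function(pop, rate, time = 0) {
  new_event("growth", list(time = chk_ref(time, "time"), pop = pop,
                           rate = chk_ref(rate, "rate")))
}

#' @rdname events
#' @export
evt_bottleneck <- function(time, pop, strength) {
  new_event("bottleneck", list(time = chk_ref(time, "time"), pop = pop,
                               strength = chk_ref(strength, "strength")))
}

#' @export
print.demographic_event <- function(x, ...) {
  f <- function(v) if (is.character(v)) v else format(v)
  desc <- switch(x$kind,
    split = paste0("split @", f(x$time), "y: ", x$child, " -> ", x$parent),
    pulse = paste0("pulse @", f(x$time), "y: ", x$source, " -> ", x$dest,
                   " (p = ", f(x$fraction), ")"),
    size_change = paste0("size @", f(x$time), "y: ", x$pop, " Ne = ",
                         f(x$new_ne)),
    growth = paste0("growth to @", f(x$time), "y: ", x$pop, " rate = ",
                    f(x$rate)),
    bottleneck = paste0("bottleneck @", f(x$time), "y: ", x$pop,
                        " strength = ", f(x$strength)))
  cat(desc, "\n")
  invisible(x)
}
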