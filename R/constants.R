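#' Evolutionary constants for time scaling
#'
#' Bundles the per-site, per-generation mutation rate and the generation
#' time used to convert between years and generations. Defaults are the
#' values commonly adopted for thamnophilid antbirds: a mutation rate of
#' 2.5e-9 substitutions/site/generation and a generation time of 2.33
#' years.
#'
#' @param mu Mutation rate, substitutions per site per generation. Must be
#'   positive.
#' @param gen_time Generation time in years. Must be positive.
#' @return An object of class `evo_constants`.
#' @examples
#' evo_constants()
#' evo_constants(mu = 1e-8, gen_time = 1)
#' @export
evo_constants <- function(mu = 2.5e-9, gen_time = 2.33) {
  stopifnot(is_scalar_number(mu), mu > 0,
            is_scalar_number(gen_time), gen_time > 0)
  structure(list(mu = mu, gen_time = gen_time), class = "evo_constants")
}

#' @export
print.evo_constants <- function(x, ...) {
  cat("Evolutionary constants\n")
  cat("  mutation rate : ", format(x$mu), " /site/generation\n", sep = "")
  cat("  generation time: ", format(x$gen_time), " years\n", sep = "")
  invisible(x)
}

#' Convert between years and generations
#'
#' @param t Time(s) in years (or generations for the inverse). Must be
#'   non-negative.
#' @param constants An [evo_constants()] object.
#' @return Numeric vector of times in generations (or years).
#' @examples
#' years_to_generations(233, evo_constants()) # 100 generations
#' @export
years_to_generations <- function(t, constants = evo_constants()) {
  stopifnot(inherits(constants, "evo_constants"))
  if (any(t < 0, na.rm = TRUE)) stop("time must be non-negative")
  t / constants$gen_time
}

#' @rdname years_to_generations
#' @export
generations_to_years <- function(t, constants = evo_constants()) {
  stopifnot(inherits(constants, "evo_constants"))
  if (any(t < 0, na.rm = TRUE)) stop("time must be non-negative")
  t * constants$gen_time
}
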