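# Data-driven model catalogs. Each candidate model is one YAML document;
# the defaults shipped with the package live under a versioned directory
# (inst/models/<version>/<profile>/<name>.yaml) with one profile per study
# taxon. Files carry a `status` flag: "transcribed" models are pinned by a
# published parameter listing, "inferred" ones are composed from the
# published category descriptions.

CATALOG_VERSION <- "1.0"

#' Location of the shipped model catalogs
#'
#' @param version Catalog version string.
#' @return Path to the versioned catalog directory.
#' @export
model_catalog_dir <- function(version = CATALOG_VERSION) {
  system.file("models", version, package = "sfsdemo", mustWork = TRUE)
}

#' Available catalog profiles
#'
#' @param version Catalog version string.
#' @return Character vector of profile names (one per study taxon).
#' @export
catalog_profiles <- function(version = CATALOG_VERSION) {
  sort(list.dirs(model_catalog_dir(version), recursive = FALSE,
                 full.names = FALSE))
}

event_to_list <- function(e) {
  out <- unclass(e)
  attributes(out) <- list(names = names(out))
  out
}

event_from_list <- function(x) {
  kind <- x$kind
  switch(kind,
    split = evt_split(x$time, x$child, x$parent),
    pulse = evt_pulse(x$time, x$source, x$dest, x$fraction),
    size_change = evt_size_change(x$time, x$pop, x$new_ne),
    growth = evt_growth(x$pop, x$rate, x$time %||% 0),
    bottleneck = evt_bottleneck(x$time, x$pop, x$strength),
    stop("unknown event kind in model file: ", kind))
}

#' Read and write model files
#'
#' Models serialize to YAML, one document per model; `read_model()` and
#' `write_model()` round-trip structurally.
#'
#' @param path File path.
#' @param model A [demographic_model()].
#' @return `read_model()` returns a `demographic_model`; `write_model()`
#'   returns `path` invisibly.
#' @export
read_model <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("name", "type", "topology", "params", "events")) {
    if (is.null(x[[f]])) stop("model file ", path, " is missing field ", f)
  }
  demographic_model(
    name = x$name, model_type = x$type, topology = x$topology,
    status = x$status %||% "inferred", ne = x$ne,
    params = x$params, events = lapply(x$events, event_from_list))
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  doc <- list(name = model$name, type = model$model_type,
              status = model$status, topology = model$topology,
              ne = model$ne, params = model$params,
              events = lapply(model$events, event_to_list))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Build a candidate-model catalog for a taxon profile
#'
#' Loads the declared candidate models for one profile, in catalog order
#' (roman-numeral model names). Taxon-specific overrides can replace a
#' model file or restrict the set of models.
#'
#' @param taxon_profile Profile name (see [catalog_profiles()]) or a
#'   directory containing model YAML files.
#' @param models Optional character vector restricting which model names to
#'   load; unknown names are an error.
#' @param overrides Optional named list mapping model names to replacement
#'   file paths or `demographic_model` objects.
#' @param version Catalog version string.
#' @return Named list of [demographic_model()] objects.
#' @export
build_catalog <- function(taxon_profile, models = NULL, overrides = NULL,
                          version = CATALOG_VERSION) {
  dir <- if (dir.exists(taxon_profile)) taxon_profile else
    file.path(model_catalog_dir(version), taxon_profile)
  if (!dir.exists(dir)) {
    stop("unknown catalog profile: ", taxon_profile,
         " (available: ", paste(catalog_profiles(version), collapse = ", "), ")")
  }
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  cat_models <- lapply(files, read_model)
  names(cat_models) <- vapply(cat_models, function(m) m$name, "")
  if (anyDuplicated(names(cat_models))) stop("duplicate model names in catalog")
  cat_models <- cat_models[catalog_order(names(cat_models))]
  if (!is.null(overrides)) {
    if (is.null(names(overrides))) stop("malformed override: must be named by model")
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      m <- if (inherits(ov, "demographic_model")) ov else read_model(ov)
      cat_models[[nm]] <- m
    }
    cat_models <- cat_models[catalog_order(names(cat_models))]
  }
  if (!is.null(models)) {
    missing <- setdiff(models, names(cat_models))
    if (length(missing)) {
      stop("unknown model name(s): ", paste(missing, collapse = ", "))
    }
    cat_models <- cat_models[intersect(names(cat_models), models)]
  }
  cat_models
}

# catalog order: roman-numeral names numerically, anything else after, by name
catalog_order <- function(x) {
  v <- suppressWarnings(as.integer(utils::as.roman(x)))
  v[is.na(v)] <- .Machine$integer.max
  order(v, x)
}
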