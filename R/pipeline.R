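# End-to-end orchestration: simulate (or load) SNP data, reduce to a
# joint SFS, fit a model catalog, rank by AIC, bootstrap the best model,
# and summarize diversity. Stages write into one run directory and are
# skipped when their outputs already exist, so interrupted runs resume.

#' Run the analysis pipeline
#'
#' @param config A list, or path to a YAML file, with entries:
#' \describe{
#'   \item{out_dir}{Run directory (required).}
#'   \item{constants}{Optional `list(mu =, gen_time =)`.}
#'   \item{data}{Either `list(preset = <table5 preset name>)` (optionally
#'     `n_per_pop`, `seed`) to simulate, or `list(vcf =, pop_map =)` to
#'     load. Required.}
#'   \item{one_snp_per_locus}{Apply the unlinked-SNP filter (default
#'     TRUE).}
#'   \item{projection}{Optional haploid projection sizes `c(A,B,C)`.}
#'   \item{catalog}{`list(profile =, models = NULL)` choosing candidate
#'     models (required for the fitting stage).}
#'   \item{optimizer}{Arguments for [opt_config()].}
#'   \item{bootstrap}{`list(n_boot =)` or NULL to skip.}
#'   \item{stats}{Write per-population diversity statistics (default
#'     TRUE).}
#' }
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  fail <- function(stage, msg) {
    rec <- list(stage = stage, error = msg, time = format(Sys.time()))
    try(jsonlite::write_json(rec, file.path(config$out_dir %||% ".",
                                            "pipeline_error.json"),
                             auto_unbox = TRUE), silent = TRUE)
    stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config field out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  constants <- do.call(evo_constants, config$constants %||% list())
  log_path <- file.path(out_dir, "pipeline.log")
  logln <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                             "\n", sep = "", file = log_path, append = TRUE)
  logln("run_pipeline in ", out_dir)

  # --- data stage -------------------------------------------------------
  if (is.null(config$data)) stop("config field data is required")
  vcf_path <- file.path(out_dir, "dataset.vcf")
  map_path <- file.path(out_dir, "popmap.tsv")
  if (!is.null(config$data$preset)) {
    if (!file.exists(vcf_path)) {
      presets <- table5_presets(n_per_pop = config$data$n_per_pop %||% 8L,
                                seed = config$data$seed %||% 1L)
      if (!config$data$preset %in% names(presets)) {
        fail("simulate", paste0("unknown preset ", config$data$preset))
      }
      preset <- presets[[config$data$preset]]
      tbl <- simulate_snp_dataset(preset$model, preset$params,
                                  preset$n_loci,
                                  rep(2L * preset$n_per_pop, 3),
                                  preset$missing_rate, seed = preset$seed,
                                  constants = constants)
      write_vcf(tbl, vcf_path)
      write_pop_map(tbl$pop, map_path)
      logln("simulated preset ", preset$name)
    }
  } else {
    if (is.null(config$data$vcf)) fail("data", "config field data$vcf is required")
    if (is.null(config$data$pop_map)) {
      fail("data", "config field data$pop_map is required")
    }
    vcf_path <- config$data$vcf
    map_path <- config$data$pop_map
  }
  pop_map <- read_pop_map(map_path)
  table <- tryCatch(read_vcf(vcf_path, pop_map),
                    error = function(e) fail("read", conditionMessage(e)))
  if (isTRUE(config$one_snp_per_locus %||% TRUE)) {
    table <- select_one_snp_per_locus(table,
                                      seed = config$data$seed %||% 1L)
  }

  # --- sfs stage --------------------------------------------------------
  sfs_path <- file.path(out_dir, "observed.sfs.gz")
  if (file.exists(sfs_path)) {
    observed <- read_sfs(sfs_path)
  } else {
    observed <- build_joint_sfs(table,
                                projection_sizes = config$projection)
    write_sfs(observed, sfs_path)
    logln("built SFS: ", sum(observed$counts), " retained sites")
  }

  # --- stats stage ------------------------------------------------------
  if (isTRUE(config$stats %||% TRUE)) {
    stats_path <- file.path(out_dir, "diversity.tsv")
    if (!file.exists(stats_path)) {
      utils::write.table(snp_diversity(table), stats_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  # --- fit + rank stage -------------------------------------------------
  if (!is.null(config$catalog)) {
    ranking_path <- file.path(out_dir, "ranking.tsv")
    fits_path <- file.path(out_dir, "fits.rds")
    ocfg <- do.call(opt_config, config$optimizer %||% list())
    if (!file.exists(ranking_path)) {
      catalog <- tryCatch(
        build_catalog(config$catalog$profile,
                      models = config$catalog$models),
        error = function(e) fail("fit", conditionMessage(e)))
      fits <- lapply(catalog, function(m) {
        logln("fitting model ", m$name)
        cfg <- ocfg
        cfg$seed <- as.integer(derive_seed(ocfg$seed,
                                           match(m$name, names(catalog))))
        optimize_model(m, observed, cfg, constants = constants)
      })
      fits <- rescore_fits(fits, observed,
                           mc_reps = 4L * ocfg$mc_reps,
                           seed = derive_seed(ocfg$seed, 424242),
                           prob_floor = ocfg$prob_floor,
                           constants = constants)
      saveRDS(fits, fits_path)
      ranking <- rank_models(fits)
      write_ranking_tsv(ranking, ranking_path)
      logln("ranked ", nrow(ranking), " models")
    } else {
      fits <- readRDS(fits_path)
      ranking <- read_ranking_tsv(ranking_path)
    }

    # --- bootstrap stage ------------------------------------------------
    if (!is.null(config$bootstrap)) {
      boot_path <- file.path(out_dir, "bootstrap.tsv")
      if (!file.exists(boot_path)) {
        best_name <- ranking$model_name[1]
        best <- fits[[best_name]]
        nhap <- observed$m  # refit at the analysis projection sizes
        bres <- parametric_bootstrap(
          best$model, best$params,
          n_loci = round(sum(observed$counts)),
          sample_config = nhap,
          n_boot = config$bootstrap$n_boot %||% 100L,
          config = ocfg, projection_sizes = observed$m,
          constants = constants)
        est <- as.data.frame(bres$estimates)
        utils::write.table(cbind(replicate = seq_len(nrow(est)), est),
                           boot_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(bres$ci, file.path(out_dir, "bootstrap_ci.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        logln("bootstrap: ", bres$n_boot, " replicates, ",
              bres$n_failed, " failed")
      }
    }
  }

  meta <- list(seed = config$optimizer$seed %||% 1L,
               data_seed = config$data$seed %||% 1L,
               mu = constants$mu, gen_time = constants$gen_time,
               package_version = as.character(utils::packageVersion("sfsdemo")),
               r_version = R.version.string)
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
  invisible(out_dir)
}
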