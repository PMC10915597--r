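#' Published model-ranking inputs
#'
#' The printed ranking tables of the two taxa whose published rows are
#' internally consistent (the Plain Antvireo and the Rufous-capped /
#' Rufous-winged antshrike complex): model name and category, reported
#' maximized log-likelihood, free-parameter count, delta-AIC and relative
#' Akaike weight. The log-likelihood and k columns are inputs for
#' [rank_models()]; the delta-AIC and weight columns are the printed
#' values they should reproduce.
#'
#' @param taxon `"mentalis"` or `"ruficapillus"`.
#' @return Data frame with columns `model_name`, `model_type`, `lnL`,
#'   `k`, `delta_aic`, `weight`.
#' @export
published_rankings <- function(taxon = c("mentalis", "ruficapillus")) {
  taxon <- match.arg(taxon)
  path <- system.file("extdata",
                      paste0("published_ranking_", taxon, ".tsv"),
                      package = "sfsdemo", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = c("character", "character", "numeric",
                                   "integer", "numeric", "numeric"))
}
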