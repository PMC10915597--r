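#' Per-population diversity statistics from a SNP genotype table
#'
#' Allele-frequency versions of the classical statistics for unphased
#' diploid SNP data: per site with `d` derived among `n` called copies,
#' heterozygosity contributes `2 d (n - d) / (n (n - 1))` to pi; S counts
#' sites polymorphic within the population; theta_W and Tajima's D use
#' the population's median called-copy number.
#'
#' @param table A `genotype_table`.
#' @return Data frame with one row per population (plus `"all"`):
#'   `population`, `n_copies`, `sites`, `S`, `pi_total`, `theta_w_total`,
#'   `tajima_d`.
#' @export
snp_diversity <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  groups <- c(as.list(stats::setNames(c("A", "B", "C"), c("A", "B", "C"))),
              list(all = c("A", "B", "C")))
  rows <- lapply(names(groups), function(gname) {
    cols <- which(table$pop %in% groups[[gname]])
    if (!length(cols)) return(NULL)
    g <- table$geno[, cols, drop = FALSE]
    called <- 2L * rowSums(!is.na(g))
    d <- rowSums(g, na.rm = TRUE)
    use <- called >= 4L
    poly <- use & d > 0 & d < called
    S <- sum(poly)
    pi_total <- sum(2 * d[use] * (called[use] - d[use]) /
                      (called[use] * (called[use] - 1)))
    n_eff <- if (any(use)) as.integer(stats::median(called[use])) else 0L
    td <- if (S > 0 && n_eff >= 4) {
      cst <- tajima_constants(n_eff)
      (pi_total - S / cst$a1) /
        sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    } else NA_real_
    data.frame(population = gname, n_copies = n_eff, sites = sum(use),
               S = S, pi_total = pi_total,
               theta_w_total = if (n_eff >= 2) watterson_theta(S, n_eff)
                               else NA_real_,
               tajima_d = td)
  })
  do.call(rbind, rows)
}
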