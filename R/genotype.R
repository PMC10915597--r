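# GenotypeTable: per-site diploid genotypes (derived-allele counts 0/1/2,
# NA = missing) with locus identifiers and population assignments.

new_genotype_table <- function(geno, locus, pop, ancestral_known = TRUE,
                               skipped = c(multiallelic = 0L, indel = 0L,
                                           non_snp = 0L)) {
  stopifnot(is.matrix(geno), length(locus) == nrow(geno),
            length(pop) == ncol(geno))
  if (any(nchar(locus) == 0)) stop("locus IDs must be non-empty")
  if (!all(pop %in% c("A", "B", "C"))) {
    stop("population assignments must be among A, B, C")
  }
  structure(list(geno = geno, locus = as.character(locus),
                 pop = pop, ancestral_known = isTRUE(ancestral_known),
                 skipped = skipped),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table: ", nrow(x$geno), " biallelic SNPs x ",
      ncol(x$geno), " diploid samples\n", sep = "")
  cat("  loci: ", length(unique(x$locus)),
      "; populations: ", paste(sprintf("%s=%d", names(table(x$pop)),
                                       table(x$pop)), collapse = " "),
      "\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%; ancestral state %s\n",
              100 * miss, if (x$ancestral_known) "known" else "unknown"))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Retain one random SNP per locus
#'
#' Mirrors the unlinked-SNP reduction used upstream of SFS-based
#' inference: for every locus with at least one SNP, a single site is kept
#' uniformly at random. Deterministic under `seed`; the retained sites
#' keep their original order, and a table that already has one SNP per
#' locus is returned unchanged.
#'
#' @param table A `genotype_table`.
#' @param seed Integer seed.
#' @return A `genotype_table` with one site per locus.
#' @export
select_one_snp_per_locus <- function(table, seed = 1L) {
  stopifnot(inherits(table, "genotype_table"))
  idx_by_locus <- split(seq_along(table$locus), table$locus)
  keep <- with_local_seed(seed, {
    vapply(idx_by_locus, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, 0L)
  })
  keep <- sort(unname(keep))
  out <- table
  out$geno <- table$geno[keep, , drop = FALSE]
  out$locus <- table$locus[keep]
  out
}

pop_samples <- function(table, pop) which(table$pop == pop)
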