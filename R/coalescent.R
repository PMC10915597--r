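# R-facing wrappers around the compiled structured-coalescent engine.

#' Simulate one genealogy under a demographic model
#'
#' Runs the structured coalescent backward in time under the model's
#' events (splits, admixture pulses, size changes, growth, bottlenecks)
#' and returns the realized genealogy as an `ape` tree. Branch lengths are
#' in generations; tips are labelled by population (`A1`, `A2`, ..., `B1`,
#' ...).
#'
#' @param model A [demographic_model()].
#' @param params Named values for the model's free parameters.
#' @param sample_config Haploid sample sizes, named vector
#'   `c(A =, B =, C =)`; total at most 60 allele copies.
#' @param seed Integer seed; identical inputs give identical genealogies.
#' @param constants An [evo_constants()] used to convert event times from
#'   years to generations.
#' @return An `ape::phylo` object with attribute `"tmrca"` (generations).
#' @export
simulate_genealogy <- function(model, params = NULL, sample_config,
                               seed = 1L, constants = evo_constants()) {
  cm <- compile_model(model, params, constants)
  nsam <- as_sample_config(sample_config)
  res <- .cpp_simulate_genealogy(cm$npop, cm$ne0, cm$g0, cm$events, nsam,
                                 as.double(seed))
  ntip <- res$n_tips
  merges <- res$merges
  times <- res$times
  node_time <- c(rep(0, ntip), rep(NA_real_, ntip - 1))
  # the engine numbers internal nodes in coalescence order with the root
  # last; ape wants the root to be ntip + 1
  last <- 2L * ntip - 1L
  remap <- function(id) ifelse(id <= ntip, id, ntip + 1L + (last - id))
  edge <- matrix(0L, nrow = 2L * (ntip - 1L), ncol = 2L)
  edge_len <- numeric(nrow(edge))
  for (i in seq_len(nrow(merges))) {
    node_time[merges[i, 3]] <- times[i]
    for (j in 1:2) {
      child <- merges[i, j]
      k <- 2L * (i - 1L) + j
      edge[k, ] <- c(remap(merges[i, 3]), remap(child))
      edge_len[k] <- times[i] - node_time[child]
    }
  }
  labels <- character(ntip)
  pos <- 0
  for (p in c("A", "B", "C")) {
    np <- as_sample_config(sample_config)[match(p, c("A", "B", "C"))]
    if (np > 0) labels[pos + seq_len(np)] <- paste0(p, seq_len(np))
    pos <- pos + np
  }
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = labels, Nnode = ntip - 1L),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "tmrca") <- res$tmrca
  tree
}

#' Monte-Carlo expected joint site frequency spectrum
#'
#' Estimates the expected joint SFS of a model by simulating replicate
#' genealogies: each branch contributes its length to the cell of its
#' subtended configuration `(i_A, i_B, i_C)`; cells are then normalized to
#' sum to one over the polymorphic configurations. Monte-Carlo standard
#' errors are derived from the replicate-level variance of each cell
#' (ratio-estimator approximation).
#'
#' @inheritParams simulate_genealogy
#' @param n_reps Number of replicate genealogies (>= 1).
#' @param check Validate the parameter set before simulating. Callers
#'   that have already screened the parameters (e.g. the optimizer's
#'   objective) can skip the re-check.
#' @return An object of class `expected_sfs`: a list with `prob` and `se`
#'   arrays of dimension `(n_A + 1, n_B + 1, n_C + 1)`, haploid sizes `n`,
#'   replicate count, and per-replicate `tmrca`/`treelen` summaries.
#' @export
expected_sfs_mc <- function(model, params = NULL, sample_config,
                            n_reps = 1000L, seed = 1L,
                            constants = evo_constants(), check = TRUE) {
  stopifnot(n_reps >= 1)
  cm <- compile_model(model, params, constants, check = check)
  nsam <- as_sample_config(sample_config)
  res <- .cpp_expected_sfs(cm$npop, cm$ne0, cm$g0, cm$events, nsam,
                           as.integer(n_reps), as.double(seed))
  n <- nsam[1:3]
  dims <- n + 1L
  total <- array(res$total, dim = dims)
  totsq <- array(res$totsq, dim = dims)
  mono <- monomorphic_cells(n)
  total[mono] <- 0
  totsq[mono] <- 0
  grand <- sum(total)
  if (grand <= 0) stop("zero total branch length; cannot normalize")
  prob <- total / grand
  mean_len <- grand / n_reps
  cell_mean <- total / n_reps
  cell_var <- pmax(totsq / n_reps - cell_mean^2, 0)
  se <- sqrt(cell_var / n_reps) / mean_len
  structure(list(prob = prob, se = se, n = stats::setNames(n, c("A", "B", "C")),
                 n_reps = n_reps, folded = FALSE,
                 tmrca = res$tmrca, treelen = res$treelen),
            class = "expected_sfs")
}

# linear indices of the two configurations monomorphic in the total sample
monomorphic_cells <- function(n) {
  dims <- n + 1L
  first <- 1L
  last <- prod(dims)
  c(first, last)
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat("Expected joint SFS (", x$n_reps, " MC replicates)\n", sep = "")
  cat("  haploid sizes: A=", x$n[1], " B=", x$n[2], " C=", x$n[3], "\n",
      sep = "")
  cat("  polymorphic cells with mass: ", sum(x$prob > 0), "\n", sep = "")
  invisible(x)
}

#' Simulate a dataset of unlinked biallelic SNPs
#'
#' Each locus contributes exactly one segregating site: a genealogy is
#' simulated per locus and a branch is chosen with probability
#' proportional to its length (the infinite-sites placement of a single
#' observed SNP). Allele copies are paired into diploid genotypes in
#' sample order, and genotypes are masked independently with probability
#' `missing_rate`. The ancestral state is known (unfolded data).
#'
#' @inheritParams simulate_genealogy
#' @param n_loci Number of loci (= SNPs) to simulate.
#' @param missing_rate Per-genotype missingness probability in \[0, 1).
#' @return A `genotype_table` (see [read_vcf()]): sites x samples matrix
#'   of diploid derived-allele counts with locus IDs and population
#'   assignments.
#' @export
simulate_snp_dataset <- function(model, params = NULL, n_loci,
                                 sample_config, missing_rate = 0,
                                 seed = 1L, constants = evo_constants()) {
  stopifnot(n_loci >= 1, missing_rate >= 0, missing_rate < 1)
  nsam <- as_sample_config(sample_config)
  if (any(nsam[1:3] %% 2L != 0L)) {
    stop("diploid output needs even haploid sample counts per population")
  }
  cm <- compile_model(model, params, constants)
  hap <- .cpp_simulate_snps(cm$npop, cm$ne0, cm$g0, cm$events, nsam,
                            as.integer(n_loci), as.double(derive_seed(seed, 1)))
  n_dip <- nsam[1:3] %/% 2L
  pops <- rep(c("A", "B", "C"), n_dip)
  geno <- hap[, seq(1, ncol(hap), by = 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), by = 2), drop = FALSE]
  if (missing_rate > 0) {
    mask <- with_local_seed(derive_seed(seed, 2), {
      matrix(stats::runif(length(geno)) < missing_rate, nrow = nrow(geno))
    })
    geno[mask] <- NA_integer_
  }
  samples <- paste0(pops, stats::ave(seq_along(pops), pops, FUN = seq_along))
  colnames(geno) <- samples
  locus <- sprintf("locus%05d", seq_len(n_loci))
  new_genotype_table(geno, locus = locus,
                     pop = stats::setNames(pops, samples),
                     ancestral_known = TRUE)
}

#' Simulate infinite-sites haplotypes
#'
#' Simulates replicate loci under the model and drops mutations on the
#' genealogy as a Poisson process (rate `locus_mu` per generation for the
#' whole locus), yielding 0/1 haplotype matrices with one column per
#' segregating site. Used for sequence-level diversity statistics.
#'
#' @inheritParams simulate_genealogy
#' @param n_reps Number of independent loci.
#' @param locus_mu Per-generation mutation rate of the whole locus
#'   (per-site rate times locus length).
#' @return List of `n_reps` 0/1 matrices (rows = haploid sequences).
#' @export
simulate_infinite_sites <- function(model, params = NULL, n_reps,
                                    sample_config, locus_mu, seed = 1L,
                                    constants = evo_constants()) {
  stopifnot(n_reps >= 1, locus_mu > 0)
  cm <- compile_model(model, params, constants)
  nsam <- as_sample_config(sample_config)
  .cpp_simulate_infsites(cm$npop, cm$ne0, cm$g0, cm$events, nsam,
                         as.integer(n_reps), locus_mu, as.double(seed))
}
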