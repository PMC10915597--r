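# Classical diversity and neutrality statistics for aligned sequence
# matrices (character bases) or 0/1 haplotype matrices. Missing data
# handling: ambiguity codes, gaps, N and NA are missing; pairwise-complete
# sites for pi, a minimum-call threshold per column for S and Tajima's D.

# logical matrix of valid (non-missing) calls
valid_calls <- function(mat) {
  if (is.character(mat)) {
    matrix(toupper(mat) %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  } else {
    !is.na(mat)
  }
}

as_state <- function(mat) {
  m <- if (is.character(mat)) toupper(mat) else mat
  m[!valid_calls(mat)] <- NA
  m
}

col_threshold <- function(n) min(4L, n)

#' Segregating sites
#'
#' Number of columns carrying at least two distinct non-missing states,
#' among columns with at least `min(4, n)` non-missing calls.
#'
#' @param mat Alignment matrix: rows = sequences, columns = sites;
#'   character bases or 0/1.
#' @return Integer count.
#' @export
segregating_sites <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 sequences")
  st <- as_state(mat)
  thr <- col_threshold(nrow(mat))
  sum(apply(st, 2, function(col) {
    col <- col[!is.na(col)]
    length(col) >= thr && length(unique(col)) >= 2
  }))
}

#' Nucleotide diversity
#'
#' Mean number of pairwise differences across all unordered sequence
#' pairs, counted over pairwise-complete sites. The per-site value is the
#' mean over pairs of (differences / pairwise-complete sites).
#'
#' @inheritParams segregating_sites
#' @return List with `total` (mean pairwise differences) and `per_site`.
#' @export
nucleotide_diversity <- function(mat) {
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 sequences")
  st <- as_state(mat)
  total <- 0
  per_site <- 0
  n_pairs <- 0L
  any_complete <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(st[i, ]) & !is.na(st[j, ])
      d <- sum(st[i, ok] != st[j, ok])
      total <- total + d
      if (any(ok)) {
        per_site <- per_site + d / sum(ok)
        any_complete <- TRUE
      }
      n_pairs <- n_pairs + 1L
    }
  }
  if (!any_complete) stop("no pairwise-complete sites")
  list(total = total / n_pairs, per_site = per_site / n_pairs)
}

#' Watterson's estimator
#'
#' `theta_W = S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (>= 2).
#' @return The estimate (in the units of `S`, i.e. per locus).
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("need at least 2 sequences")
  stopifnot(S >= 0)
  S / sum(1 / seq_len(n - 1))
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the Tajima (1989)
#' constants computed from the number of sequences. Undefined (returns
#' `NA`) when there are no segregating sites. Negative values indicate an
#' excess of rare variants, the signature of population expansion.
#'
#' @inheritParams segregating_sites
#' @return The statistic, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(mat) {
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 sequences")
  S <- segregating_sites(mat)
  if (S == 0) return(NA_real_)
  pi_total <- nucleotide_diversity(mat)$total
  cst <- tajima_constants(n)
  (pi_total - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Per-alignment diversity summary
#'
#' @inheritParams segregating_sites
#' @return One-row data frame with `n`, `valid_sites`, `S`, `pi_total`,
#'   `pi_per_site`, `theta_w_total`, `theta_w_per_site`, `tajima_d`.
#' @export
diversity_summary <- function(mat) {
  n <- nrow(mat)
  S <- segregating_sites(mat)
  pi <- nucleotide_diversity(mat)
  thr <- col_threshold(n)
  valid <- sum(apply(valid_calls(mat), 2, sum) >= thr)
  tw <- watterson_theta(S, n)
  data.frame(n = n, valid_sites = valid, S = S,
             pi_total = pi$total, pi_per_site = pi$per_site,
             theta_w_total = tw,
             theta_w_per_site = if (valid > 0) tw / valid else NA_real_,
             tajima_d = tajimas_d(mat))
}
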