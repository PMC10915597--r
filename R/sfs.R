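# Joint site-frequency spectra: construction from genotype tables with
# hypergeometric projection over missing data, folding, and a gzip text
# serialization.

new_joint_sfs <- function(counts, m, folded, dropped, input_sites) {
  dim(counts) <- unname(dim(counts))
  structure(list(counts = counts,
                 m = stats::setNames(as.integer(m), c("A", "B", "C")),
                 folded = isTRUE(folded),
                 dropped = dropped, input_sites = input_sites),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("Joint SFS (", if (x$folded) "folded" else "unfolded", ")\n", sep = "")
  cat("  projected sizes: A=", x$m[1], " B=", x$m[2], " C=", x$m[3], "\n",
      sep = "")
  cat(sprintf("  retained mass: %.4g of %d input sites\n", sum(x$counts),
              x$input_sites))
  cat(sprintf("  dropped: %.4g monomorphic-after-projection, %d below-threshold\n",
              x$dropped[["monomorphic"]], x$dropped[["below_threshold"]]))
  invisible(x)
}

#' Hypergeometric projection of one site
#'
#' Distribution of the derived-allele count after downsampling a site with
#' `i` derived among `n` called copies to `m` copies without replacement:
#' `P(j) = C(i, j) C(n - i, m - j) / C(n, m)`. This is how sites with
#' missing genotypes contribute fractional mass to a fixed-size spectrum.
#'
#' @param i Derived-allele count at the site (`0 <= i <= n`).
#' @param n Called allele copies at the site.
#' @param m Target (projected) number of copies (`1 <= m <= n`).
#' @return Numeric probability vector over `j = 0..m`; sums to one.
#' @examples
#' project_site(2, 4, 2) # (1/6, 4/6, 1/6)
#' @export
project_site <- function(i, n, m) {
  stopifnot(i >= 0, i <= n, m >= 1)
  if (m > n) stop("projection size m exceeds called copies n at this site")
  stats::dhyper(0:m, i, n - i, m)
}

#' Build a joint SFS from a genotype table
#'
#' Tabulates each site's joint derived-allele configuration at fixed
#' projected haploid sizes. Sites with missing genotypes contribute their
#' expected (hypergeometric) projection mass, so counts may be fractional;
#' sites with fewer called copies than the projection size in some
#' population are dropped (`below_threshold`), and projection mass landing
#' in the configurations monomorphic across the total sample is dropped as
#' `monomorphic`. Retained mass plus drops always equals the input site
#' count.
#'
#' @param table A `genotype_table`.
#' @param projection_sizes Haploid target sizes `c(A =, B =, C =)`.
#'   Default: 80% of the per-population maximum called copies (rounded
#'   down, even).
#' @param folded Fold the spectrum onto minor-allele configurations
#'   (joint fold on the total minor allele).
#' @return A `joint_sfs`.
#' @export
build_joint_sfs <- function(table, projection_sizes = NULL, folded = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- c("A", "B", "C")
  idx <- lapply(pops, function(p) which(table$pop == p))
  names(idx) <- pops
  n_sites <- nrow(table$geno)
  called <- lapply(pops, function(p) {
    g <- table$geno[, idx[[p]], drop = FALSE]
    2L * rowSums(!is.na(g))
  })
  names(called) <- pops
  derived <- lapply(pops, function(p) {
    g <- table$geno[, idx[[p]], drop = FALSE]
    as.integer(rowSums(g, na.rm = TRUE))
  })
  names(derived) <- pops
  if (is.null(projection_sizes)) {
    projection_sizes <- vapply(pops, function(p) {
      mx <- if (n_sites) max(called[[p]]) else 2L * length(idx[[p]])
      2L * floor(0.8 * mx / 2)
    }, 0)
  }
  if (is.null(names(projection_sizes))) names(projection_sizes) <- pops
  m <- stats::setNames(as.integer(projection_sizes[pops]), pops)
  if (any(m < 0) || all(m == 0)) stop("invalid projection sizes")
  for (p in pops) {
    if (m[[p]] > 2L * length(idx[[p]])) {
      stop("projection size for ", p, " exceeds available copies")
    }
  }
  dims <- m + 1L
  counts <- array(0, dim = dims)
  dropped_mono <- 0
  dropped_thresh <- 0L
  full <- n_sites > 0 &&
    all(vapply(pops, function(p) all(called[[p]] == m[[p]]), TRUE))
  if (full) {
    # no projection needed: direct tabulation
    cell <- 1L + derived[["A"]] +
      dims[1] * (derived[["B"]] + dims[2] * derived[["C"]])
    tab <- tabulate(cell, nbins = prod(dims))
    counts <- array(as.double(tab), dim = dims)
    mono <- monomorphic_cells(m)
    dropped_mono <- sum(counts[mono])
    counts[mono] <- 0
  } else if (n_sites > 0) {
    mono <- monomorphic_cells(m)
    proj <- function(p, s) {
      if (m[[p]] == 0L) 1 else
        project_site(derived[[p]][s], called[[p]][s], m[[p]])
    }
    for (s in seq_len(n_sites)) {
      if (any(vapply(pops, function(p) called[[p]][s] < m[[p]], TRUE))) {
        dropped_thresh <- dropped_thresh + 1L
        next
      }
      mass <- outer(outer(proj("A", s), proj("B", s)), proj("C", s))
      dropped_mono <- dropped_mono + sum(mass[mono])
      mass[mono] <- 0
      counts <- counts + mass
    }
  }
  out <- new_joint_sfs(counts, m, folded = FALSE,
                       dropped = c(monomorphic = dropped_mono,
                                   below_threshold = dropped_thresh),
                       input_sites = n_sites)
  if (folded) fold_sfs(out) else out
}

# Map every configuration to its minor-allele representative: the member
# of the pair {cfg, m - cfg} with the smaller total derived count
# (lexicographic tie-break at exactly half).
fold_cell_map <- function(m) {
  dims <- m + 1L
  grid <- as.matrix(expand.grid(iA = 0:m[1], iB = 0:m[2], iC = 0:m[3]))
  comp <- sweep(-grid, 2, m, "+")
  tot <- rowSums(grid)
  M <- sum(m)
  use_comp <- tot > M - tot |
    (2 * tot == M & (comp[, 1] < grid[, 1] |
                       (comp[, 1] == grid[, 1] & comp[, 2] < grid[, 2]) |
                       (comp[, 1] == grid[, 1] & comp[, 2] == grid[, 2] &
                          comp[, 3] < grid[, 3])))
  rep_cfg <- grid
  rep_cfg[use_comp, ] <- comp[use_comp, ]
  1L + rep_cfg[, 1] + dims[1] * (rep_cfg[, 2] + dims[2] * rep_cfg[, 3])
}

#' Fold a spectrum onto minor-allele configurations
#'
#' Joint folding on the total minor allele: a configuration and its
#' complement are combined, the representative being the one whose total
#' derived count is below half (lexicographic tie-break at exactly half).
#' Idempotent.
#'
#' @param x A `joint_sfs` or `expected_sfs`.
#' @return Object of the same class with `folded = TRUE`.
#' @export
fold_sfs <- function(x) UseMethod("fold_sfs")

#' @export
fold_sfs.joint_sfs <- function(x) {
  if (x$folded) return(x)
  map <- fold_cell_map(x$m)
  folded <- array(0, dim = dim(x$counts))
  mass <- as.vector(x$counts)
  for (cell in which(mass != 0)) {
    folded[map[cell]] <- folded[map[cell]] + mass[cell]
  }
  x$counts <- folded
  x$folded <- TRUE
  x
}

#' @export
fold_sfs.expected_sfs <- function(x) {
  if (x$folded) return(x)
  map <- fold_cell_map(x$n)
  prob <- array(0, dim = dim(x$prob))
  var <- array(0, dim = dim(x$prob))
  pv <- as.vector(x$prob); sv <- as.vector(x$se)
  for (cell in which(pv != 0 | sv != 0)) {
    prob[map[cell]] <- prob[map[cell]] + pv[cell]
    var[map[cell]] <- var[map[cell]] + sv[cell]^2
  }
  x$prob <- prob
  x$se <- sqrt(var)
  x$folded <- TRUE
  x
}

#' Serialize a joint SFS
#'
#' Gzip-compressed text: header lines carry the projected sizes, folded
#' flag, dropped-site accounting and input site count; one line per
#' non-empty cell follows. `read_sfs()` restores the object exactly.
#'
#' @param sfs A `joint_sfs`.
#' @param path Output path (conventionally `*.sfs.gz`).
#' @return `write_sfs()`: `path`, invisibly. `read_sfs()`: a `joint_sfs`.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "joint_sfs"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  header <- c("#sfsdemo-joint-sfs v1",
              paste("#sizes:", paste(sfs$m, collapse = " ")),
              paste("#folded:", sfs$folded),
              paste("#dropped_monomorphic:",
                    format(sfs$dropped[["monomorphic"]], digits = 17)),
              paste("#dropped_below_threshold:",
                    sfs$dropped[["below_threshold"]]),
              paste("#input_sites:", sfs$input_sites))
  nz <- which(as.vector(sfs$counts) != 0)
  cfg <- arrayInd(nz, dim(sfs$counts)) - 1L
  body <- sprintf("%d %d %d %s", cfg[, 1], cfg[, 2], cfg[, 3],
                  format(as.vector(sfs$counts)[nz], digits = 17))
  writeLines(c(header, body), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- tryCatch(readLines(gzfile(path)),
                    error = function(e) stop("cannot read SFS file ", path,
                                             ": ", conditionMessage(e)),
                    warning = function(w) stop("corrupt SFS file ", path,
                                               ": ", conditionMessage(w)))
  if (length(lines) < 6 || lines[1] != "#sfsdemo-joint-sfs v1") {
    stop("not an sfsdemo SFS file: ", path)
  }
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, ":"), lines, value = TRUE)
    if (length(ln) != 1) stop("SFS header missing field ", key)
    trimws(sub(paste0("^#", key, ":"), "", ln))
  }
  m <- as.integer(strsplit(hdr("sizes"), " +")[[1]])
  if (length(m) != 3 || anyNA(m)) stop("malformed sizes header")
  folded <- as.logical(hdr("folded"))
  dropped <- c(monomorphic = as.numeric(hdr("dropped_monomorphic")),
               below_threshold = as.integer(hdr("dropped_below_threshold")))
  input_sites <- as.integer(hdr("input_sites"))
  body <- lines[!startsWith(lines, "#")]
  counts <- array(0, dim = m + 1L)
  if (length(body)) {
    parts <- do.call(rbind, strsplit(trimws(body), " +"))
    if (ncol(parts) != 4) stop("malformed SFS cell line")
    cfg <- apply(parts[, 1:3, drop = FALSE], 2, as.integer)
    if (is.null(dim(cfg))) cfg <- matrix(cfg, nrow = 1)
    if (any(cfg < 0) || any(cfg > matrix(m, nrow(cfg), 3, byrow = TRUE))) {
      stop("SFS cell outside declared shape")
    }
    counts[cfg + 1L] <- as.numeric(parts[, 4])
  }
  new_joint_sfs(counts, m, folded, dropped, input_sites)
}
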