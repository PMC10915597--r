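# VCF input (via vcfR) and output, and the two-column population map.

#' Read a population map
#'
#' Two-column tab-separated file: sample name, population (A/B/C). No
#' header.
#'
#' @param path File path.
#' @return Named character vector mapping sample to population.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (anyDuplicated(df$sample)) stop("duplicate sample in population map")
  if (!all(df$population %in% c("A", "B", "C"))) {
    stop("population map entries must be among A, B, C")
  }
  stats::setNames(df$population, df$sample)
}

#' @rdname read_pop_map
#' @param pop_map Named character vector (sample -> population).
#' @export
write_pop_map <- function(pop_map, path) {
  utils::write.table(data.frame(sample = names(pop_map),
                                population = unname(pop_map)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNPs from a VCF file
#'
#' Loads a VCF (v4.x, plain or gzipped), keeps biallelic SNP records only
#' (multiallelic sites and indels are skipped, with counts reported via
#' `message()` and stored in the result), and returns diploid
#' derived-allele counts. The locus identifier of every site is its CHROM
#' field. The ancestral allele is taken from the `AA` INFO tag when every
#' retained record carries one; otherwise the REF allele is used and the
#' table is flagged for folded-spectrum use with a warning.
#'
#' @param path VCF file path.
#' @param pop_map Named character vector (sample -> population A/B/C),
#'   e.g. from [read_pop_map()]. Every sample in the VCF must be mapped.
#' @return A `genotype_table`.
#' @export
read_vcf <- function(path, pop_map) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF ", path, ": ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    warning("VCF ", path, " has no variant records")
    samples <- colnames(vcf@gt)[-1]
    check_pop_map(samples, pop_map)
    return(new_genotype_table(
      matrix(integer(0), nrow = 0, ncol = length(samples),
             dimnames = list(NULL, samples)),
      locus = character(0), pop = pop_map[samples]))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  keep <- !multi & !indel
  skipped <- c(multiallelic = sum(multi), indel = sum(indel),
               non_snp = 0L)
  if (any(!keep)) {
    message("read_vcf: skipped ", sum(multi), " multiallelic and ",
            sum(indel), " indel record(s)")
  }
  samples <- colnames(vcf@gt)[-1]
  check_pop_map(samples, pop_map)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec,
                                     dimnames = list(NULL, samples))
  gt <- gt[keep, , drop = FALSE]
  counts <- alt_allele_counts(gt)
  # ancestral allele from the AA INFO tag, per retained record
  info <- fix[keep, "INFO"]
  has_aa <- grepl("(^|;)AA=", info)
  aa <- rep(NA_character_, length(info))
  aa[has_aa] <- sub(".*(^|;)AA=([^;]+).*", "\\2", info[has_aa])
  ancestral_known <- !anyNA(aa) && length(aa) > 0
  if (ancestral_known) {
    flip <- aa == alt[keep]
    counts[flip, ] <- 2L - counts[flip, , drop = FALSE]
  } else if (nrow(counts) > 0) {
    warning("no complete AA (ancestral allele) INFO tag; treating REF as ",
            "ancestral -- prefer folded spectra for this table")
  }
  locus <- fix[keep, "CHROM"]
  colnames(counts) <- samples
  new_genotype_table(counts, locus = locus, pop = pop_map[samples],
                     ancestral_known = ancestral_known, skipped = skipped)
}

check_pop_map <- function(samples, pop_map) {
  missing <- setdiff(samples, names(pop_map))
  if (length(missing)) {
    stop("sample(s) absent from pop_map: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

alt_allele_counts <- function(gt) {
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  valid <- !is.na(gt) & (sep == "/" | sep == "|") &
    a1 %in% c("0", "1") & a2 %in% c("0", "1")
  out[valid] <- as.integer(a1[valid]) + as.integer(a2[valid])
  out
}

#' Write a genotype table as VCF v4.2
#'
#' Serializes a `genotype_table` to a plain-text VCF. Each site becomes
#' one record with CHROM = locus ID, REF the ancestral and ALT the derived
#' allele (written as A/G), an `AA` INFO tag, and unphased GT genotypes
#' (`./.` for missing).
#'
#' @param table A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  samples <- colnames(table$geno)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sfsdemo",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(table$geno)), function(i) {
    g <- table$geno[i, ]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(table$locus[i], "1", ".", "A", "G", ".", "PASS", "AA=A", "GT",
            gt), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a FASTA alignment as a character matrix
#'
#' Sequences must share one length (ragged input is an error). Bases are
#' upper-cased; IUPAC ambiguity codes, `N` and gaps are preserved and
#' treated as missing by the diversity statistics.
#'
#' @param path FASTA file path.
#' @return Character matrix, rows = sequences (named), columns = sites.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0) stop("no sequences in FASTA file ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  mat <- toupper(as.character(as.matrix(seqs)))
  rownames(mat) <- names(seqs)
  mat
}
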