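# VCF/FASTA input, SNP filters, projection, folding and serialization.

make_table <- function(n_loci = 50, miss = 0, seed = 1) {
  simulate_snp_dataset(const_model(ne = 1e4), NULL, n_loci,
                       c(A = 4, B = 4, C = 4), missing_rate = miss,
                       seed = seed, constants = GEN1)
}

test_that("VCF round-trips a simulated genotype table", {
  tb <- make_table(60, miss = 0.1, seed = 4)
  dir <- withr::local_tempdir()
  write_vcf(tb, file.path(dir, "x.vcf"))
  write_pop_map(tb$pop, file.path(dir, "x.popmap.tsv"))
  tb2 <- read_vcf(file.path(dir, "x.vcf"),
                  read_pop_map(file.path(dir, "x.popmap.tsv")))
  expect_identical(unname(tb2$geno), unname(tb$geno))
  expect_identical(tb2$locus, tb$locus)
  expect_identical(unname(tb2$pop), unname(tb$pop))
  expect_true(tb2$ancestral_known)
})

test_that("multiallelic and indel records are skipped with counts", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "mixed.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "L1\t5\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1",
    "L2\t9\t.\tA\tG,T\t.\tPASS\tAA=A\tGT\t0/1\t0/2",   # multiallelic
    "L3\t2\t.\tAT\tA\t.\tPASS\tAA=A\tGT\t0/1\t0/0",    # indel
    "L4\t7\t.\tC\tT\t.\tPASS\tAA=T\tGT\t0/0\t0/1"      # ALT ancestral
  ), vcf)
  pm <- c(s1 = "A", s2 = "B")
  expect_message(tb <- read_vcf(vcf, pm), "skipped 1 multiallelic and 1 indel")
  expect_equal(nrow(tb$geno), 2)
  expect_equal(tb$locus, c("L1", "L4"))
  # AA=T flips the derived-allele counts at L4
  expect_equal(unname(tb$geno[2, ]), c(2L, 1L))
})

test_that("empty VCF bodies warn and missing samples error", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "empty.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"
  ), vcf)
  expect_warning(tb <- read_vcf(vcf, c(s1 = "A")), "no variant records")
  expect_equal(nrow(tb$geno), 0)
  tb2 <- make_table(5)
  write_vcf(tb2, file.path(dir, "y.vcf"))
  expect_error(read_vcf(file.path(dir, "y.vcf"), c(A1 = "A")),
               "absent from pop_map")
})

test_that("one-SNP-per-locus selection is uniform, idempotent and order-stable", {
  tb <- make_table(10)
  tb$locus <- c("l1", "l1", "l2", rep(sprintf("l%d", 3:9), 1))
  out <- select_one_snp_per_locus(tb, seed = 1)
  expect_equal(nrow(out$geno), 9)
  expect_false(is.unsorted(match(out$locus, unique(tb$locus))))
  # idempotence
  out2 <- select_one_snp_per_locus(out, seed = 99)
  expect_identical(out2$geno, out$geno)
  # uniformity over positions: 600 loci of 3 SNPs each, with the
  # within-locus position encoded in the first genotype column
  big <- make_table(1800, seed = 6)
  big$locus <- rep(sprintf("L%04d", 1:600), each = 3)
  big$geno[, 1] <- rep(0:2, 600)
  picked <- select_one_snp_per_locus(big, seed = 11)
  expect_equal(nrow(picked$geno), 600)
  freq <- tabulate(picked$geno[, 1] + 1L, 3) / 600
  se <- sqrt((1 / 3) * (2 / 3) / 600)
  expect_true(all(abs(freq - 1 / 3) < 3.5 * se))
})

test_that("hypergeometric projection matches enumeration and is unbiased", {
  expect_equal(project_site(2, 4, 2), c(1, 4, 1) / 6)
  expect_equal(project_site(4, 4, 3), c(0, 0, 0, 1))  # all derived
  expect_equal(project_site(2, 5, 5), c(0, 0, 1, 0, 0, 0))  # identity
  expect_error(project_site(1, 3, 4), "exceeds")
  for (n in c(4, 7, 12)) {
    for (i in 0:n) {
      for (m in 1:n) {
        p <- project_site(i, n, m)
        expect_equal(sum(p), 1)
        expect_equal(sum(p * 0:m) / m, i / n)  # E[j]/m = i/n
      }
    }
  }
})

test_that("joint SFS tabulation, conservation and drops are exact", {
  tb <- make_table(400, miss = 0, seed = 5)
  full <- c(A = 4, B = 4, C = 4)
  sfs <- build_joint_sfs(tb, projection_sizes = full)
  # direct tabulation oracle
  ora <- array(0, dim = unname(full) + 1L)
  for (s in seq_len(nrow(tb$geno))) {
    d <- vapply(c("A", "B", "C"), function(p) {
      sum(tb$geno[s, tb$pop == p])
    }, 0)
    ora[d[1] + 1, d[2] + 1, d[3] + 1] <- ora[d[1] + 1, d[2] + 1, d[3] + 1] + 1
  }
  ora[1, 1, 1] <- 0
  ora[5, 5, 5] <- 0
  expect_equal(sfs$counts, ora)
  expect_equal(sum(sfs$counts) + sum(sfs$dropped), 400)

  tb10 <- make_table(400, miss = 0.1, seed = 7)
  sfs10 <- build_joint_sfs(tb10, projection_sizes = c(A = 3, B = 3, C = 3))
  expect_lt(abs(sum(sfs10$counts) + sum(sfs10$dropped) - 400), 1e-9)

  # a table fixed derived everywhere drops all sites
  fixed <- tb
  fixed$geno[] <- 2L
  sfs_fixed <- build_joint_sfs(fixed, projection_sizes = full)
  expect_equal(sum(sfs_fixed$counts), 0)
  expect_equal(unname(sfs_fixed$dropped[["monomorphic"]]), 400)
})

test_that("folding is idempotent and mass-preserving", {
  tb <- make_table(300, miss = 0.05, seed = 9)
  sfs <- build_joint_sfs(tb, projection_sizes = c(A = 4, B = 4, C = 4))
  f1 <- fold_sfs(sfs)
  f2 <- fold_sfs(f1)
  expect_equal(f1$counts, f2$counts)
  expect_equal(sum(f1$counts), sum(sfs$counts))
  expect_true(f1$folded)
  es <- expected_sfs_mc(const_model(ne = 1e4), NULL, c(A = 4, B = 4, C = 4),
                        n_reps = 500, seed = 3, constants = GEN1)
  fe <- fold_sfs(es)
  expect_equal(sum(fe$prob), 1)
  expect_equal(fold_sfs(fe)$prob, fe$prob)
})

test_that("SFS files round-trip and corrupt input errors", {
  tb <- make_table(100, miss = 0.08, seed = 10)
  sfs <- build_joint_sfs(tb)
  path <- tempfile(fileext = ".sfs.gz")
  write_sfs(sfs, path)
  back <- read_sfs(path)
  expect_equal(back, sfs)

  hand <- tempfile(fileext = ".sfs.gz")
  con <- gzfile(hand, "wb")
  writeLines(c("#sfsdemo-joint-sfs v1", "#sizes: 2 2 2", "#folded: FALSE",
               "#dropped_monomorphic: 0.5", "#dropped_below_threshold: 1",
               "#input_sites: 4", "1 0 0 2", "2 1 0 0.5"), con)
  close(con)
  parsed <- read_sfs(hand)
  expect_equal(parsed$counts[2, 1, 1], 2)
  expect_equal(parsed$counts[3, 2, 1], 0.5)
  expect_equal(parsed$input_sites, 4L)

  bad <- tempfile(fileext = ".sfs.gz")
  raw_bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw_bytes[1:(length(raw_bytes) %/% 2)], bad)
  expect_error(read_sfs(bad))
})

test_that("FASTA alignments load as matrices with ambiguity masking downstream", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "aln.fasta")
  writeLines(c(">s1", "ACGTACGTAA", ">s2", "ACGTACGTAA", ">s3",
               "ACGTNCGTAA"), fa)
  mat <- read_fasta_alignment(fa)
  expect_equal(dim(mat), c(3L, 10L))
  expect_equal(unname(mat[3, 5]), "N")
  expect_equal(segregating_sites(mat), 0)  # N is missing, not a state

  ragged <- file.path(dir, "bad.fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACGTA"), ragged)
  expect_error(read_fasta_alignment(ragged), "ragged")
  empty <- file.path(dir, "empty.fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta_alignment(empty))
})
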