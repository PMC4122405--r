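test_that("FASTA alignments are parsed into site matrices", {
  f <- tempfile(fileext = ".fa")
  # two identical sequences: no sites, all columns invariant
  write_fasta_lines(rep("ACGTACGT", 2), f)
  h <- read_alignment(f)
  expect_equal(n_site(h), 0L)
  expect_equal(h$n_invariant, 8L)
  expect_equal(h$seq_len, 8)

  # 4 sequences differing at 2 columns; positions = 0-based indices
  write_fasta_lines(c("AAGA", "AAGA", "ATGA", "ATGC"), f)
  h <- read_alignment(f)
  expect_equal(n_site(h), 2L)
  expect_equal(h$positions, c(1, 3))
  expect_equal(h$n_invariant, 2L)
  # alphabetical coding: A=0, T=1 at col 2; A=0, C=1 at col 4
  expect_equal(h$alleles[, 1], c(0L, 0L, 1L, 1L))
  expect_equal(h$alleles[, 2], c(0L, 0L, 0L, 1L))

  write_fasta_lines(c("ACGT", "ACG"), f)
  expect_error(read_alignment(f), "unequal")
  write_fasta_lines(c("AC!T", "ACGT"), f)
  expect_error(read_alignment(f), "IUPAC")
})

test_that("columns with three states are dropped, N treated as missing", {
  f <- tempfile(fileext = ".fa")
  write_fasta_lines(c("AAC", "ATC", "AGC", "ANC"), f)
  h <- read_alignment(f)
  expect_equal(n_site(h), 0L)
  expect_equal(attr(h, "n_multiallelic"), 1L)
})

test_that("FASTA write -> read round trip is the identity", {
  set.seed(71)
  for (i in 1:5) {
    m <- matrix(rbinom(6 * 8, 1, 0.4), 6, 8)
    # keep only polymorphic columns, as read_alignment would
    keep <- colSums(m) > 0 & colSums(m) < 6
    m <- m[, keep, drop = FALSE]
    if (!ncol(m)) next
    h <- hap_matrix(m, seq_len(ncol(m)) - 1)
    f <- tempfile(fileext = ".fa")
    write_fasta(h, f)
    h2 <- read_alignment(f)
    expect_equal(h2$alleles, h$alleles, ignore_attr = TRUE)
    expect_equal(h2$positions, h$positions)
  }
})

test_that("phased VCF reading handles het, skip and round-trip cases", {
  f <- tempfile(fileext = ".vcf")
  # one phased het in one diploid sample -> 2 x 1 matrix with a 0 and a 1
  write_vcf_lines("1\t101\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1", "ind1", f)
  h <- read_phased_vcf(f)
  expect_equal(dim(h$alleles), c(2L, 1L))
  expect_setequal(h$alleles[, 1], c(0L, 1L))
  expect_equal(h$positions, 100)      # 1-based VCF -> 0-based internal

  # triallelic and unphased records are skipped with a count
  write_vcf_lines(c("1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
                    "1\t201\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1",
                    "1\t301\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"),
                  "ind1", f)
  h <- read_phased_vcf(f)
  expect_equal(n_site(h), 1L)
  expect_equal(attr(h, "n_skipped"), 2L)
})

test_that("VCF write -> read round trip preserves the matrix", {
  set.seed(72)
  m <- matrix(rbinom(8 * 5, 1, 0.5), 8, 5)
  m[colSums(m) == 0 | colSums(m) == 8] <- 1L  # ensure polymorphic-ish
  h <- hap_matrix(m, positions = c(10, 25, 40, 41, 90),
                  allele0 = rep("A", 5), allele1 = rep("G", 5))
  f <- tempfile(fileext = ".vcf.gz")
  write_phased_vcf(h, f)
  h2 <- read_phased_vcf(f)
  expect_equal(h2$alleles, h$alleles, ignore_attr = TRUE)
  expect_equal(h2$positions, h$positions)
})

test_that("polarization matches the outgroup and flags third states", {
  h <- toy_hap(c("0101", "0011", "1100"), polarized = FALSE)
  # outgroup equal to haplotype 1: that haplotype becomes all-ancestral
  og <- outgroup_seq(as.character(h$alleles[1, ]))
  hp <- polarize(h, og)
  expect_true(hp$polarized)
  expect_equal(unname(hp$alleles[1, ]), rep(0L, 4))

  # outgroup third state at a site -> flagged unpolarized
  og2 <- outgroup_seq(c("0", "2", "0", "1"))
  hp2 <- polarize(h, og2)
  expect_equal(hp2$unpolarized, c(FALSE, TRUE, FALSE, FALSE))

  # complementing the outgroup at one site complements that column
  og3 <- outgroup_seq(c("1", "0", "0", "0"))   # differs from og at site 1
  hp3 <- polarize(h, og3)
  expect_equal(hp3$alleles[, 1], 1L - polarize(h, outgroup_seq(
    c("0", "0", "0", "0")))$alleles[, 1])
  expect_equal(hp3$alleles[, -1],
               polarize(h, outgroup_seq(c("0", "0", "0", "0")))$alleles[, -1])
})

test_that("ms-style text blocks round trip", {
  set.seed(73)
  mats <- replicate(3, {
    m <- matrix(rbinom(5 * 4, 1, 0.5), 5, 4)
    hap_matrix(m, positions = sort(runif(4)) * 1000, polarized = TRUE)
  }, simplify = FALSE)
  f <- tempfile()
  write_ms(mats, f, region_len = 1000)
  back <- read_ms(f, region_len = 1000)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$alleles, mats[[k]]$alleles, ignore_attr = TRUE)
    expect_equal(back[[k]]$positions, mats[[k]]$positions,
                 tolerance = 1e-2)
  }
})

test_that("hap_matrix validates its invariants", {
  expect_error(hap_matrix(matrix(0L, 2, 2), c(5, 5)), "increasing")
  expect_error(hap_matrix(matrix(2L, 2, 1), 0), "biallelic")
  expect_error(hap_matrix(matrix(0L, 2, 2), 1), "one entry per column")
})
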