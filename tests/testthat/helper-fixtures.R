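# shared fixture builders; everything is generated in code

toy_hap <- function(rows, positions = NULL, polarized = TRUE) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  hap_matrix(m, positions = positions %||% (seq_len(ncol(m)) - 1),
             polarized = polarized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fasta_lines <- function(seqs, path) {
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0(">s", i), seqs[i]))), path)
  path
}

# minimal phased VCF writer for fixtures
write_vcf_lines <- function(records, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(samples, collapse = "\t")))
  writeLines(c(hdr, records), path)
  path
}

# brute-force mean pairwise Hamming distance (oracle for pi)
pi_bruteforce <- function(alleles) {
  n <- nrow(alleles)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(alleles[i, ]) & !is.na(alleles[j, ])
    # pairwise-complete per column: accumulate per-column contributions
    tot <- tot + sum(alleles[i, ok] != alleles[j, ok])
    np <- np + 1
  }
  tot / np
}

# per-column pairwise-complete pi oracle (matches diversity_summary's rule)
pi_pairwise_complete <- function(alleles) {
  out <- 0
  for (j in seq_len(ncol(alleles))) {
    x <- alleles[, j][!is.na(alleles[, j])]
    nj <- length(x)
    if (nj < 2) next
    d <- sum(x)
    out <- out + 2 * d * (nj - d) / (nj * (nj - 1))
  }
  out
}

# Levene probability of a heterozygote count, oracle for hwe_exact
levene_prob <- function(n_het, nA, na) {
  n <- (nA + na) / 2
  rare <- min(nA, na)
  hr <- (rare - n_het) / 2
  hc <- (max(nA, na) - n_het) / 2
  exp(lfactorial(n) - lfactorial(hr) - lfactorial(n_het) -
        lfactorial(hc) + n_het * log(2) +
        lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
}
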