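#' Phased haplotype matrix
#'
#' The central container of the package: an `n_hap x n_site` matrix of
#' derived-allele indicators (0 = ancestral, 1 = derived, `NA` = missing)
#' for phased haplotypes, together with the physical position of every
#' segregating site.  All statistics and simulators in the package consume
#' and produce this class.
#'
#' Coordinates are 0-based and half-open internally; VCF input/output is
#' converted at the boundary.  Sites are biallelic SNVs only.  Before
#' [polarize()] is applied the 0/1 coding is arbitrary (alphabetical for
#' FASTA input, REF/ALT for VCF input) and `polarized` is `FALSE`.
#'
#' @param alleles integer matrix (haplotypes in rows, sites in columns)
#'   with entries 0, 1 or `NA`.
#' @param positions numeric vector of physical site coordinates (bp,
#'   0-based), strictly increasing, one per column.
#' @param site_ids optional character vector of site identifiers
#'   (e.g. rs numbers).
#' @param sample_ids optional character vector of haplotype labels.
#' @param region optional list `(chrom, start, end)`, half-open.
#' @param polarized logical; `TRUE` once 0 is known to be the ancestral
#'   state at every non-flagged site.
#' @param unpolarized logical vector, one per site; `TRUE` marks sites
#'   where the outgroup carried a third state so the ancestral allele is
#'   unknown.  Such sites are excluded from polarization-dependent
#'   statistics.
#' @param n_invariant number of monomorphic columns seen in the source
#'   alignment (needed for per-site diversity).
#' @param seq_len total sequence length in bp when known (segregating
#'   plus invariant sites), used to report per-site diversity.
#' @param allele0,allele1 optional character vectors giving the base
#'   coded 0 resp. 1 at each site.
#'
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, positions, site_ids = NULL,
                       sample_ids = NULL, region = NULL,
                       polarized = FALSE, unpolarized = NULL,
                       n_invariant = 0L, seq_len = NULL,
                       allele0 = NULL, allele1 = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != length(positions))
    stop("`positions` must have one entry per column of `alleles`")
  if (ncol(alleles) > 1L && any(diff(positions) <= 0))
    stop("`positions` must be strictly increasing")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("alleles must be 0, 1 or NA (biallelic sites only)")
  if (is.null(unpolarized)) unpolarized <- rep(FALSE, ncol(alleles))
  structure(
    list(alleles = alleles,
         positions = as.numeric(positions),
         site_ids = site_ids,
         sample_ids = sample_ids,
         region = region,
         polarized = isTRUE(polarized),
         unpolarized = unpolarized,
         n_invariant = as.integer(n_invariant),
         seq_len = seq_len,
         allele0 = allele0,
         allele1 = allele1),
    class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes x %d segregating sites%s\n",
              nrow(x$alleles), ncol(x$alleles),
              if (x$polarized) " (polarized)" else ""))
  if (!is.null(x$seq_len))
    cat(sprintf("  sequence length %d bp (%d invariant columns)\n",
                as.integer(x$seq_len), x$n_invariant))
  if (!is.null(x$region))
    cat(sprintf("  region %s:%d-%d\n", x$region$chrom,
                x$region$start, x$region$end))
  invisible(x)
}

#' @rdname hap_matrix
#' @param x object to query.
#' @export
n_hap <- function(x) nrow(x$alleles)

#' @rdname hap_matrix
#' @export
n_site <- function(x) ncol(x$alleles)

#' Outgroup sequence for polarization
#'
#' A single aligned outgroup (e.g. chimpanzee) restricted to the
#' segregating-site positions of a [hap_matrix()].  Used only to orient
#' alleles as ancestral/derived and for divergence-based mutation-rate
#' estimates.
#'
#' @param alleles character (bases) or integer (0/1) vector, one entry
#'   per site of the target matrix.
#' @return An object of class `outgroup_seq`.
#' @export
outgroup_seq <- function(alleles) {
  structure(list(alleles = as.character(alleles)), class = "outgroup_seq")
}

iupac_chars <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", ".")

#' Read a FASTA alignment into a haplotype matrix
#'
#' Reads an equal-length FASTA alignment (one record per phased
#' haplotype), extracts the biallelic variable columns as segregating
#' sites and counts monomorphic columns as invariant sites.  The allele
#' that sorts first alphabetically is coded 0; use [polarize()] with an
#' outgroup to obtain ancestral/derived coding.
#'
#' Columns containing more than two distinct bases are dropped (the
#' package analyses biallelic SNPs only); their count is recorded in the
#' `n_multiallelic` attribute.  `N` and `-` are treated as missing.
#'
#' @param path FASTA file.
#' @param region optional list `(chrom, start, end)`; when supplied,
#'   site positions are reported as `start + column index`, otherwise as
#'   0-based column indices.
#' @return A [hap_matrix()] with `seq_len` set to the alignment width.
#' @export
read_alignment <- function(path, region = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2L) stop("alignment must contain at least 2 records")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment records have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  if (!all(m %in% iupac_chars))
    stop("alignment contains non-IUPAC characters")
  m[m %in% c("N", "-", ".")] <- NA_character_
  offset <- if (is.null(region)) 0 else region$start
  keep <- integer(0); a0 <- character(0); a1 <- character(0)
  n_inv <- 0L; n_multi <- 0L
  cols <- vector("list", 0L)
  for (j in seq_len(ncol(m))) {
    obs <- sort(unique(m[, j][!is.na(m[, j])]))
    if (length(obs) <= 1L) {
      n_inv <- n_inv + 1L
    } else if (length(obs) == 2L) {
      keep <- c(keep, j)
      a0 <- c(a0, obs[1L]); a1 <- c(a1, obs[2L])
      cols[[length(cols) + 1L]] <- as.integer(m[, j] == obs[2L])
    } else {
      n_multi <- n_multi + 1L
    }
  }
  alle <- if (length(keep)) do.call(cbind, cols) else
    matrix(integer(0), nrow = nrow(m), ncol = 0L)
  out <- hap_matrix(alle, positions = offset + (keep - 1),
                    sample_ids = names(seqs), region = region,
                    n_invariant = n_inv, seq_len = ncol(m),
                    allele0 = a0, allele1 = a1)
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Write a haplotype matrix as a FASTA alignment of its variable columns
#'
#' The inverse of [read_alignment()] restricted to segregating sites:
#' each haplotype becomes one record whose j-th character is the base
#' coded by column j.  Matrices without stored base labels (e.g.
#' simulator output) are written with 0 = `A`, 1 = `C`.
#'
#' @param mat a [hap_matrix()].
#' @param path output file.
#' @export
write_fasta <- function(mat, path) {
  a0 <- mat$allele0 %||% rep("A", n_site(mat))
  a1 <- mat$allele1 %||% rep("C", n_site(mat))
  ch <- matrix("N", nrow = n_hap(mat), ncol = n_site(mat))
  for (j in seq_len(n_site(mat))) {
    ch[, j] <- ifelse(is.na(mat$alleles[, j]), "N",
                      ifelse(mat$alleles[, j] == 1L, a1[j], a0[j]))
  }
  seqs <- apply(ch, 1L, paste0, collapse = "")
  ids <- mat$sample_ids %||% paste0("hap", seq_len(n_hap(mat)))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Keeps biallelic SNV records with fully phased GT fields and expands
#' each diploid sample into two haplotype rows.  Multiallelic, unphased,
#' non-SNV and missing-genotype records are skipped; the number skipped
#' is recorded in the `n_skipped` attribute.  1-based VCF positions are
#' converted to the package's 0-based internal coordinates.
#'
#' @param path VCF file (plain or bgzip).
#' @param region optional list `(chrom, start, end)` half-open, 0-based;
#'   records outside it are ignored.
#' @return A [hap_matrix()] with REF coded 0 and ALT coded 1.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  pos0 <- as.numeric(fix[, "POS"]) - 1
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- rep(TRUE, nrow(fix)); n_skip <- 0L
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  gtf <- sub(":.*$", "", gt[, -1L, drop = FALSE])
  phased <- apply(gtf, 1L, function(g)
    all(grepl("^[01]\\|[01]$", g)))
  ok <- snv & phased
  n_skip <- sum(!ok)
  if (!is.null(region)) {
    inside <- pos0 >= region$start & pos0 < region$end &
      fix[, "CHROM"] == region$chrom
    ok <- ok & inside
  }
  idx <- which(ok)
  if (length(idx) > 1L) idx <- idx[order(pos0[idx])]
  rows <- 2L * length(samples)
  alle <- matrix(NA_integer_, nrow = rows, ncol = length(idx))
  for (k in seq_along(idx)) {
    g <- gtf[idx[k], ]
    alle[, k] <- as.integer(rbind(substr(g, 1L, 1L), substr(g, 3L, 3L)))
  }
  ids <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  out <- hap_matrix(alle, positions = pos0[idx],
                    site_ids = fix[idx, "ID"], sample_ids = ids,
                    region = region,
                    allele0 = ref[idx], allele1 = alt[idx])
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write a haplotype matrix as a phased VCF
#'
#' Adjacent haplotype rows (1,2), (3,4), ... are paired into diploid
#' samples with phased GT fields.  Internal 0-based positions are
#' written 1-based.
#'
#' @param mat a [hap_matrix()] with an even number of haplotypes.
#' @param path output file; vcfR writes bgzip so a `.vcf.gz` suffix is
#'   used (appended if absent).
#' @return The path written, invisibly.
#' @export
write_phased_vcf <- function(mat, path) {
  if (n_hap(mat) %% 2L != 0L)
    stop("need an even number of haplotypes to form diploid samples")
  if (!grepl("\\.vcf\\.gz$", path)) path <- paste0(path, ".vcf.gz")
  n_ind <- n_hap(mat) %/% 2L
  chrom <- if (!is.null(mat$region)) mat$region$chrom else "1"
  fix <- cbind(CHROM = rep(chrom, n_site(mat)),
               POS = as.character(as.integer(mat$positions + 1)),
               ID = mat$site_ids %||% rep(".", n_site(mat)),
               REF = mat$allele0 %||% rep("A", n_site(mat)),
               ALT = mat$allele1 %||% rep("C", n_site(mat)),
               QUAL = rep(".", n_site(mat)),
               FILTER = rep("PASS", n_site(mat)),
               INFO = rep(".", n_site(mat)))
  gt <- matrix("", nrow = n_site(mat), ncol = n_ind + 1L)
  gt[, 1L] <- "GT"
  for (i in seq_len(n_ind)) {
    h1 <- mat$alleles[2L * i - 1L, ]; h2 <- mat$alleles[2L * i, ]
    g <- paste0(ifelse(is.na(h1), ".", h1), "|", ifelse(is.na(h2), ".", h2))
    gt[, i + 1L] <- g
  }
  colnames(gt) <- c("FORMAT", paste0("ind", seq_len(n_ind)))
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    paste0("##contig=<ID=", chrom, ">"),
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Polarize a haplotype matrix against an outgroup
#'
#' Recodes every site so that the allele matching the outgroup is 0
#' (ancestral).  Sites where the outgroup carries a third state are
#' flagged `unpolarized` and are excluded from polarization-dependent
#' statistics; they are never guessed.
#'
#' Applying `polarize` twice with outgroups that differ at one site
#' complements exactly that column (polarization is an involution with
#' respect to complementing the outgroup).
#'
#' @param mat a [hap_matrix()].
#' @param outgroup an [outgroup_seq()] aligned to `mat$positions` (bases
#'   when `mat` stores base labels, otherwise "0"/"1").
#' @return A polarized [hap_matrix()].
#' @export
polarize <- function(mat, outgroup) {
  og <- outgroup$alleles
  if (length(og) != n_site(mat))
    stop("outgroup must have one allele per site")
  a0 <- mat$allele0 %||% rep("0", n_site(mat))
  a1 <- mat$allele1 %||% rep("1", n_site(mat))
  unpol <- rep(FALSE, n_site(mat))
  alle <- mat$alleles
  for (j in seq_len(n_site(mat))) {
    if (is.na(og[j]) || (og[j] != a0[j] && og[j] != a1[j])) {
      unpol[j] <- TRUE
    } else if (og[j] == a1[j]) {
      alle[, j] <- 1L - alle[, j]
      tmp <- a0[j]; a0[j] <- a1[j]; a1[j] <- tmp
    }
  }
  out <- mat
  out$alleles <- alle
  out$allele0 <- if (is.null(mat$allele0)) NULL else a0
  out$allele1 <- if (is.null(mat$allele1)) NULL else a1
  out$polarized <- TRUE
  out$unpolarized <- unpol
  out
}

#' Read ms-style simulation output
#'
#' Parses the classic text format used by Hudson's ms and msHOT: one
#' block per replicate opened by `//`, a `segsites:` line, a
#' `positions:` line with coordinates scaled on `[0, 1)`, then one 0/1
#' string per haplotype.  Positions are rescaled to `[0, region_len)`.
#'
#' @param path text file of ms output (header lines are ignored).
#' @param region_len region length in bp used to unscale positions
#'   (default 1, i.e. keep the scaled coordinates).
#' @return A list of polarized [hap_matrix()] objects (ms output is
#'   ancestral/derived by construction).
#' @export
read_ms <- function(path, region_len = 1) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    seg <- as.integer(sub("^segsites:\\s*", "", lines[i + 1L]))
    if (seg == 0L) {
      out[[k]] <- hap_matrix(matrix(integer(0), 0, 0), numeric(0),
                             polarized = TRUE)
      next
    }
    pos <- as.numeric(strsplit(sub("^positions:\\s*", "",
                                   lines[i + 2L]), "\\s+")[[1L]])
    j <- i + 3L
    haps <- character(0)
    while (j <= length(lines) && grepl("^[01]+$", lines[j])) {
      haps <- c(haps, lines[j]); j <- j + 1L
    }
    alle <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
    # guard against duplicated scaled positions from low-precision output
    p <- pos * region_len
    while (any(diff(p) <= 0)) p[c(FALSE, diff(p) <= 0)] <-
        p[c(FALSE, diff(p) <= 0)] + 1e-9 * region_len
    out[[k]] <- hap_matrix(alle, positions = p, polarized = TRUE)
  }
  out
}

#' Write haplotype matrices as ms-style text
#'
#' @param mats a list of [hap_matrix()] objects (one replicate each).
#' @param path output file.
#' @param region_len region length in bp used to rescale positions onto
#'   `[0, 1)`.
#' @param cmdline first line of the file (by convention the generating
#'   command).
#' @export
write_ms <- function(mats, path, region_len = 1,
                     cmdline = "sweepsel") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(cmdline, ""), con)
  for (m in mats) {
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", n_site(m)), con)
    if (n_site(m) > 0L) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", m$positions / region_len),
                             collapse = " ")), con)
      writeLines(apply(m$alleles, 1L, paste0, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
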