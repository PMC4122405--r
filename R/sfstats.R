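#' Site-frequency-spectrum and haplotype diversity summary
#'
#' Computes the classical per-sample diversity quantities from a phased
#' haplotype matrix: number of segregating sites S, nucleotide diversity
#' pi (mean pairwise difference), haplotype diversity Hd, Watterson's
#' theta and the unfolded site frequency spectrum.
#'
#' Pi uses pairwise-complete observations at columns with missing data;
#' the SFS uses complete-case derived counts.  When `mat` is polarized,
#' sites flagged `unpolarized` contribute to S, pi and Hd but not to the
#' SFS (their derived allele is unknown).
#'
#' @param mat a [hap_matrix()] with at least 2 haplotypes.
#' @param seq_len sequence length in bp for per-site pi; defaults to
#'   `mat$seq_len` when present.
#' @return An object of class `diversity_summary` with fields `n`, `S`,
#'   `pi_region` (per region), `pi_site` (per site, `NA` when the
#'   sequence length is unknown), `Hd`, `theta_w`, `sfs` (counts of
#'   sites with derived count i, i = 1..n-1, `NA` when unpolarized),
#'   `eta_s` (derived singletons) and `hap_counts`.
#' @export
diversity_summary <- function(mat, seq_len = NULL) {
  n <- n_hap(mat)
  if (n < 2L) stop("need at least 2 haplotypes")
  seq_len <- seq_len %||% mat$seq_len
  alle <- mat$alleles
  S <- 0L
  pi_region <- 0
  sfs <- rep(0L, max(n - 1L, 1L))
  use_sfs <- mat$polarized
  for (j in seq_len(ncol(alle))) {
    x <- alle[, j]
    ok <- !is.na(x)
    nj <- sum(ok)
    if (nj < 2L) next
    d <- sum(x[ok])
    if (d == 0L || d == nj) next
    S <- S + 1L
    # mean pairwise difference at this column, pairwise-complete
    pi_region <- pi_region + 2 * d * (nj - d) / (nj * (nj - 1))
    if (use_sfs && !mat$unpolarized[j] && nj == n) sfs[d] <- sfs[d] + 1L
  }
  # haplotype diversity on complete haplotypes
  complete <- !apply(is.na(alle), 1L, any)
  Hd <- NA_real_
  hap_counts <- integer(0)
  if (sum(complete) >= 2L) {
    nc <- sum(complete)
    keys <- apply(alle[complete, , drop = FALSE], 1L, paste0,
                  collapse = "")
    hap_counts <- as.integer(table(keys))
    f <- hap_counts / nc
    Hd <- nc / (nc - 1) * (1 - sum(f^2))
  }
  a1 <- sum(1 / seq_len(n - 1L))
  structure(
    list(n = n, S = S, pi_region = pi_region,
         pi_site = if (is.null(seq_len)) NA_real_ else pi_region / seq_len,
         Hd = Hd, theta_w = S / a1,
         sfs = if (use_sfs) sfs else rep(NA_integer_, n - 1L),
         eta_s = if (use_sfs) sfs[1L] else NA_integer_,
         hap_counts = hap_counts, seq_len = seq_len),
    class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "diversity_summary: n = %d, S = %d, pi(region) = %.4f, Hd = %.3f\n",
    x$n, x$S, x$pi_region, x$Hd))
  if (!is.na(x$pi_site))
    cat(sprintf("  pi(per site) = %.5g over %d bp\n", x$pi_site,
                as.integer(x$seq_len)))
  invisible(x)
}

# Tajima (1989) normalisation constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
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
#' D contrasts mean pairwise diversity with Watterson's estimator;
#' negative values indicate an excess of rare variants, the footprint of
#' a recent sweep or expansion.
#'
#' @param summary a [diversity_summary()], or a [hap_matrix()] (summarised
#'   on the fly).
#' @return The D statistic, or `NA` (with a warning-free explicit null)
#'   when S = 0 so the statistic is undefined.
#' @export
tajimas_d <- function(summary) {
  if (inherits(summary, "hap_matrix")) summary <- diversity_summary(summary)
  n <- summary$n; S <- summary$S
  if (S == 0L) return(NA_real_)
  k <- tajima_constants(n)
  (summary$pi_region - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Fu and Li's D (outgroup version)
#'
#' Contrasts the total number of mutations with the number observed on
#' external branches (derived singletons), using the Fu & Li (1993)
#' variance coefficients.  Requires polarized data: the singleton class
#' is the *derived*-singleton count.
#'
#' @param summary a [diversity_summary()] of a polarized matrix, or a
#'   polarized [hap_matrix()].
#' @param eta_s derived-singleton count; defaults to the summary's.
#' @return The D statistic (`NA` when S = 0).
#' @export
fu_li_d <- function(summary, eta_s = NULL) {
  if (inherits(summary, "hap_matrix")) {
    if (!summary$polarized) stop("fu_li_d requires a polarized matrix")
    summary <- diversity_summary(summary)
  }
  if (is.null(eta_s)) eta_s <- summary$eta_s
  if (is.na(eta_s)) stop("fu_li_d requires polarized data (derived singletons)")
  n <- summary$n
  eta <- sum(summary$sfs)      # polarizable mutations
  if (eta == 0L) return(NA_real_)
  an <- sum(1 / seq_len(n - 1L))
  bn <- sum(1 / seq_len(n - 1L)^2)
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  (eta - an * eta_s) / sqrt(uD * eta + vD * eta^2)
}

#' Fay and Wu's H and Zeng's E
#'
#' High-frequency-derived-allele statistics from the unfolded SFS.
#' `H_raw` is the original pi - theta_H contrast; `H_norm` is the
#' normalised version (pi - theta_L)/sd and `E` is (theta_L -
#' theta_W)/sd, both with the Zeng et al. (2006) variances evaluated at
#' theta-hat = theta_W and theta-squared-hat = S(S-1)/(a1^2 + a2).
#'
#' @param summary a [diversity_summary()] of a polarized matrix, or a
#'   polarized [hap_matrix()].
#' @return A list with `H_raw`, `H_norm`, `E`, `theta_H`, `theta_L`
#'   (all `NA` when S = 0).
#' @export
zeng_h_e <- function(summary) {
  if (inherits(summary, "hap_matrix")) {
    if (!summary$polarized) stop("zeng_h_e requires a polarized matrix")
    summary <- diversity_summary(summary)
  }
  n <- summary$n
  if (any(is.na(summary$sfs)))
    stop("zeng_h_e requires polarized data (unfolded SFS)")
  S <- sum(summary$sfs)
  if (S == 0L)
    return(list(H_raw = NA_real_, H_norm = NA_real_, E = NA_real_,
                theta_H = NA_real_, theta_L = NA_real_))
  i <- seq_len(n - 1L)
  Si <- summary$sfs
  # pi restricted to polarized sites, to keep the contrasts consistent
  pi_pol <- sum(2 * Si * i * (n - i)) / (n * (n - 1))
  theta_H <- sum(2 * Si * i^2) / (n * (n - 1))
  theta_L <- sum(i * Si) / (n - 1)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  bn1 <- bn + 1 / n^2
  theta_w <- S / an
  theta2 <- S * (S - 1) / (an^2 + bn)
  var_H <- (n - 2) / (6 * (n - 1)) * theta_w +
    (18 * n^2 * (3 * n + 2) * bn1 -
       (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2) * theta2
  var_E <- (n / (2 * (n - 1)) - 1 / an) * theta_w +
    (bn / an^2 + 2 * (n / (n - 1))^2 * bn -
       2 * (n * bn - n + 1) / ((n - 1) * an) -
       (3 * n + 1) / (n - 1)) * theta2
  list(H_raw = pi_pol - theta_H,
       H_norm = (pi_pol - theta_L) / sqrt(var_H),
       E = (theta_L - theta_w) / sqrt(var_E),
       theta_H = theta_H, theta_L = theta_L)
}

#' Ewens-Watterson haplotype homozygosity
#'
#' F = sum of squared haplotype frequencies; elevated when one haplotype
#' dominates the sample, as after a sweep.
#'
#' @param mat a [hap_matrix()] (complete haplotypes only are counted).
#' @return F in (0, 1].
#' @export
ew_homozygosity <- function(mat) {
  s <- if (inherits(mat, "diversity_summary")) mat else diversity_summary(mat)
  f <- s$hap_counts / sum(s$hap_counts)
  sum(f^2)
}
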