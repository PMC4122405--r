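#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value summing the probabilities of all tables (with the
#' margins fixed) whose hypergeometric probability does not exceed that
#' of the observed table — the common two-sided convention, stated here
#' because conventions differ.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has an empty margin")
  stats::fisher.test(table)$p.value
}

#' Cochran-Armitage trend test for a 2 x K genotype table
#'
#' Tests for a linear trend in case proportion across ordered genotype
#' columns (default scores 0, 1, 2 = derived-allele dose).  The
#' asymptotic mode uses the normal approximation of the score
#' statistic; the exact mode enumerates all tables with the observed
#' margins (conditional distribution: multivariate hypergeometric) and
#' sums the probabilities of tables whose |statistic| is at least the
#' observed one.  Enumeration is used when the number of candidate
#' tables is at most `max_tables`; beyond that a seeded Monte-Carlo
#' permutation sample of `mc_reps` tables is used.
#'
#' @param table 2 x K matrix, rows = groups (e.g. case/control),
#'   columns ordered by dose.
#' @param scores column scores (default 0 ... K-1).
#' @param mode `"asymptotic"` or `"exact"`.
#' @param max_tables enumeration budget (default 1e4).
#' @param mc_reps Monte-Carlo permutations when enumeration is too
#'   large.
#' @return A list with `statistic` (standardised trend Z), `p`, and
#'   `mode_used`.
#' @export
ca_trend <- function(table, scores = NULL,
                     mode = c("asymptotic", "exact"),
                     max_tables = 1e4, mc_reps = 1e5) {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop("table must have 2 rows")
  K <- ncol(table)
  if (K < 2L) stop("need at least 2 genotype columns")
  scores <- scores %||% (seq_len(K) - 1)
  n_k <- colSums(table); N <- sum(table); R <- sum(table[1L, ])
  if (R == 0 || R == N || all(n_k == 0))
    stop("degenerate margins")
  trend_T <- function(r) sum(scores * r)            # r = case row
  # conditional mean/variance of T given margins
  sbar <- sum(scores * n_k) / N
  varT <- R * (N - R) / (N - 1) / N *
    sum(n_k * (scores - sbar)^2)
  if (varT <= 0) stop("degenerate margins (no score variance)")
  T_obs <- trend_T(table[1L, ])
  Z <- (T_obs - R * sbar) / sqrt(varT)
  if (mode == "asymptotic")
    return(list(statistic = Z, p = 2 * stats::pnorm(-abs(Z)),
                mode_used = "asymptotic"))
  # exact: enumerate case-row vectors r with sum R, 0 <= r_k <= n_k;
  # only columns 2..K are free (column 1 is fixed by the margin)
  n_cand <- prod(pmin(n_k[-1L], R) + 1)
  dev_obs <- abs(T_obs - R * sbar)
  log_denom <- lchoose(N, R)
  if (n_cand <= max_tables) {
    grid <- as.matrix(expand.grid(lapply(n_k[-1L], function(m)
      0:min(m, R))))
    r1 <- R - rowSums(grid)
    ok <- r1 >= 0 & r1 <= n_k[1L]
    grid <- cbind(r1[ok], grid[ok, , drop = FALSE])
    logp <- apply(grid, 1L, function(r)
      sum(lchoose(n_k, r)) - log_denom)
    Tv <- as.vector(grid %*% scores)
    p <- sum(exp(logp[abs(Tv - R * sbar) >= dev_obs - 1e-9]))
    return(list(statistic = Z, p = min(1, p), mode_used = "exact"))
  }
  # Monte-Carlo permutation: sample case rows hypergeometrically
  doses <- rep(scores, n_k)
  Tsim <- vapply(seq_len(mc_reps), function(i)
    sum(sample(doses, R)), numeric(1))
  p <- (1 + sum(abs(Tsim - R * sbar) >= dev_obs - 1e-9)) / (mc_reps + 1)
  list(statistic = Z, p = p, mode_used = "monte-carlo")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the allele counts, the probability of
#' each possible heterozygote count follows the Levene distribution.
#' Two two-sided conventions are exposed: `"selome"` (sum of all
#' heterozygote counts whose probability does not exceed the observed
#' one — "sum of equal or less likely outcomes", the default) and
#' `"dost"` (double the smaller one-sided tail, capped at 1), which is
#' what several genetics packages report.
#'
#' @param counts genotype counts `(AA, Aa, aa)` (any orientation).
#' @param pvaluetype `"selome"` or `"dost"`.
#' @return The exact p-value (1 for a monomorphic sample).
#' @export
hwe_exact <- function(counts, pvaluetype = c("selome", "dost")) {
  pvaluetype <- match.arg(pvaluetype)
  counts <- as.integer(round(counts))
  if (length(counts) != 3L || any(counts < 0))
    stop("need 3 non-negative genotype counts")
  n <- sum(counts)
  if (n == 0L) stop("no individuals")
  nA <- 2L * counts[1L] + counts[2L]
  na <- 2L * counts[3L] + counts[2L]
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) %/% 2L
    hom_com <- (max(nA, na) - h) %/% 2L
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_com) + h * log(2) +
      lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  }, numeric(1))
  p_obs <- logp[hets == counts[2L]]
  if (!length(p_obs)) stop("heterozygote count inconsistent with alleles")
  if (pvaluetype == "selome")
    return(min(1, sum(exp(logp[logp <= p_obs + 1e-12]))))
  lower <- sum(exp(logp[hets <= counts[2L]]))
  upper <- sum(exp(logp[hets >= counts[2L]]))
  min(1, 2 * min(lower, upper))
}

#' Allelic odds ratio with Wald confidence interval
#'
#' OR = ad/bc on a 2 x 2 allele-count table with the usual log-scale
#' 95 percent CI.  If any cell is zero, the Haldane-Anscombe 0.5
#' continuity correction is applied to every cell and flagged.
#'
#' @param table 2 x 2 allele counts: rows = groups, columns = alleles.
#' @return A list with `or`, `ci_95`, `corrected`.
#' @export
allelic_or <- function(table) {
  t0 <- as.matrix(table)
  corrected <- any(t0 == 0)
  if (corrected) t0 <- t0 + 0.5
  or <- (t0[1, 1] * t0[2, 2]) / (t0[1, 2] * t0[2, 1])
  se <- sqrt(sum(1 / t0))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(or = or, ci_95 = ci, corrected = corrected)
}

#' Two-proportion Z test (pooled variance)
#'
#' @param p1,n1 first sample proportion and size.
#' @param p2,n2 second sample proportion and size.
#' @return A list with `z` and two-sided `p` (p = 1 when the pooled
#'   proportion is degenerate at 0 or 1).
#' @export
two_proportion_z <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 > 0, n2 > 0)
  pool <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) return(list(z = 0, p = 1))
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' D = p_AB - p_A p_B on the derived (1) alleles; D' = |D| / D_max;
#' r^2 = D^2 / (p_A p_a p_B p_b).  Haplotypes with missing data at
#' either site are dropped.
#'
#' @param mat a [hap_matrix()].
#' @param site_i,site_j column indices of two polymorphic sites.
#' @return A list with `D`, `D_prime`, `r2`, `n_hap`.
#' @export
ld_pair <- function(mat, site_i, site_j) {
  x <- mat$alleles[, site_i]; y <- mat$alleles[, site_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("both sites must be polymorphic")
  pAB <- mean(x == 1L & y == 1L)
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, D_prime = abs(D) / Dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       n_hap = length(x))
}

#' Correlation of allele frequency with UV irradiation
#'
#' Pearson correlation of per-band allele frequencies against annual UV
#' irradiation, with the two-sided t-test p-value.  An index of bands
#' to exclude supports the with/without-outlier-band comparison (the
#' published analysis repeats the correlation with and without the
#' Canary Islands band).
#'
#' @param bands data frame with columns `uv` and `freq` (>= 3 rows
#'   after exclusion).
#' @param exclude optional row indices to drop.
#' @return A list with `r`, `p`, `n`; `r` is `NA` with a `degenerate`
#'   flag when either variable has zero variance.
#' @export
uv_correlation <- function(bands, exclude = NULL) {
  if (!is.null(exclude)) bands <- bands[-exclude, , drop = FALSE]
  if (nrow(bands) < 3L) stop("need at least 3 bands")
  if (stats::sd(bands$freq) == 0 || stats::sd(bands$uv) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(bands),
                degenerate = TRUE))
  ct <- stats::cor.test(bands$uv, bands$freq)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(bands),
       degenerate = FALSE)
}
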