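#' Null distribution of SFS statistics under a demography
#'
#' Simulates `reps` neutral replicates under the supplied demographic
#' model and recombination map, redrawing theta and rho per replicate
#' from `sampler` when given, and records the per-replicate statistics
#' needed by the simulation tests: Tajima's D, normalised Fay & Wu's H,
#' Zeng's E, Ewens-Watterson homozygosity F and the number of
#' segregating sites S.
#'
#' When `condition_S` is supplied, replicates whose S differs from it by
#' more than `S_tol` (relative) are rejected and re-simulated, so the
#' null is conditioned on the observed number of segregating sites.
#'
#' @param model a [demographic_model()].
#' @param map a [recomb_map()].
#' @param sampler a [scaled_param_sampler()], or NULL to use fixed
#'   `theta` (and the map's rho).
#' @param theta fixed scaled mutation rate when `sampler` is NULL.
#' @param reps number of retained replicates (>= 100 recommended).
#' @param condition_S optional observed S to condition on.
#' @param S_tol relative tolerance for the conditioning (default 0.2).
#' @param max_tries simulation budget when conditioning.
#' @return An object of class `null_distribution`: a data frame of
#'   statistics plus a `fingerprint` attribute recording the model,
#'   sampler and replicate count.
#' @export
null_distribution <- function(model, map, sampler = NULL, theta = NULL,
                              reps = 1000, condition_S = NULL,
                              S_tol = 0.2, max_tries = 50 * reps) {
  if (is.null(sampler) && is.null(theta))
    stop("supply either a sampler or a fixed theta")
  stat_row <- function(h) {
    if (n_site(h) == 0L)
      return(data.frame(D = NA_real_, H_norm = NA_real_, E = NA_real_,
                        F = 1, S = 0L))
    ds <- diversity_summary(h)
    z <- zeng_h_e(ds)
    data.frame(D = tajimas_d(ds), H_norm = z$H_norm, E = z$E,
               F = ew_homozygosity(ds), S = ds$S)
  }
  rows <- vector("list", reps)
  got <- 0L; tries <- 0L
  while (got < reps) {
    if (tries >= max_tries)
      stop(sprintf(
        "S-conditioning accepted only %d/%d replicates in %d simulations",
        got, reps, tries))
    block <- min(reps - got, 200L)
    pars <- if (is.null(sampler))
      data.frame(theta = rep(theta, block), rho = rep(map$rho, block))
    else sample_scaled_params(sampler, block)
    sims <- simulate_neutral(model, map, theta = pars$theta,
                             reps = block, rho = pars$rho)
    tries <- tries + block
    for (h in sims) {
      if (!is.null(condition_S) &&
          abs(n_site(h) - condition_S) > S_tol * condition_S) next
      got <- got + 1L
      rows[[got]] <- stat_row(h)
      if (got >= reps) break
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fingerprint") <- list(
    model = model, sampler = sampler, theta = theta, reps = reps,
    condition_S = condition_S, S_tol = S_tol)
  class(out) <- c("null_distribution", class(out))
  out
}

#' Empirical (Monte-Carlo) p-value
#'
#' Plus-one corrected tail probability: p = (1 + number of replicates at
#' least as extreme as the observation) / (R + 1), so p is never zero
#' and lies in \[1/(R+1), 1\].
#'
#' @param observed observed statistic.
#' @param null numeric vector of null replicates (NAs dropped).
#' @param tail `"lower"` (extreme = `<= observed`) or `"upper"`.
#' @return The p-value.
#' @export
empirical_pvalue <- function(observed, null, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  null <- null[!is.na(null)]
  if (!length(null)) stop("empty null distribution")
  extreme <- if (tail == "lower") sum(null <= observed)
             else sum(null >= observed)
  (1 + extreme) / (length(null) + 1)
}

#' Compound DH and DHEW tests
#'
#' Compound tests for a recent or completed sweep with the one-sided
#' directions fixed a priori: Tajima's D low, normalised Fay & Wu's H
#' low, Ewens-Watterson homozygosity F high.
#'
#' Two quantities are reported per compound.  `p_DH_joint` /
#' `p_DHEW_joint` are the raw Monte-Carlo joint tail probabilities
#' (plus-one corrected): the proportion of null replicates with every
#' component at least as extreme as observed.  Because the joint tail
#' of dependent components is not uniform under the null, the joint
#' probability is reported as a descriptive quantity, not as the test's
#' p-value.
#'
#' The calibrated p-values `p_DH` / `p_DHEW` implement the
#' compound-rejection construction: the test rejects at level alpha
#' when *every* component is individually extreme at a common
#' component-wise level chosen so the compound size equals alpha.
#' Operationally, each replicate (and the observation) is reduced to
#' M = max of its component-wise marginal empirical p-values, and the
#' calibrated p is the plus-one empirical probability of a null M at
#' least as small as the observed M.  M is a probability-integral
#' transform, so the calibrated p is uniform under the null and
#' rejection at 5 percent has 5 percent size.
#'
#' @param observed named list or vector with components `D`, `H_norm`
#'   and `F`.
#' @param null a [null_distribution()] (or data frame with columns `D`,
#'   `H_norm`, `F`).
#' @return A list with `p_DH`, `p_DHEW` (calibrated) and
#'   `p_DH_joint`, `p_DHEW_joint` (raw joint tails).
#' @export
dh_dhew <- function(observed, null) {
  observed <- as.list(observed)
  for (k in c("D", "H_norm", "F"))
    if (is.null(observed[[k]]) || is.na(observed[[k]]))
      stop("observed statistic `", k, "` is missing")
  for (k in c("D", "H_norm", "F"))
    if (is.null(null[[k]])) stop("null lacks component `", k, "`")
  ok <- !is.na(null$D) & !is.na(null$H_norm) & !is.na(null$F)
  D <- null$D[ok]; H <- null$H_norm[ok]; F <- null$F[ok]
  R <- length(D)
  if (!R) stop("empty null distribution")
  dh <- D <= observed$D & H <= observed$H_norm
  dhew <- dh & F >= observed$F
  # calibrated construction: marginal p's within the null, reduced to
  # their maximum; ecdf-style ranks give the component-wise levels
  pD_null <- rank(D) / R
  pH_null <- rank(H) / R
  pF_null <- rank(-F) / R
  pD_obs <- sum(D <= observed$D) / R
  pH_obs <- sum(H <= observed$H_norm) / R
  pF_obs <- sum(F >= observed$F) / R
  M_dh <- pmax(pD_null, pH_null)
  M_dhew <- pmax(M_dh, pF_null)
  m_dh_obs <- max(pD_obs, pH_obs)
  m_dhew_obs <- max(m_dh_obs, pF_obs)
  list(p_DH = (1 + sum(M_dh <= m_dh_obs)) / (R + 1),
       p_DHEW = (1 + sum(M_dhew <= m_dhew_obs)) / (R + 1),
       p_DH_joint = (1 + sum(dh)) / (R + 1),
       p_DHEW_joint = (1 + sum(dhew)) / (R + 1))
}

#' Selection-test report for one sample
#'
#' Convenience wrapper running the full battery on an observed matrix
#' against a prepared null: raw empirical p-values for D, normalised H,
#' E and EW homozygosity, plus the compound DH/DHEW p-values, with
#' optional Bonferroni adjustment across a stated number of sample
#' groups (as applied across population panels downstream).
#'
#' @param mat observed polarized [hap_matrix()].
#' @param null a [null_distribution()].
#' @param n_groups number of parallel tests for the Bonferroni column
#'   (default 1 = no adjustment).
#' @return A data frame with columns `stat`, `value`, `p`, `p_bonf`.
#' @export
selection_tests <- function(mat, null, n_groups = 1) {
  ds <- diversity_summary(mat)
  z <- zeng_h_e(ds)
  obs <- list(D = tajimas_d(ds), H_norm = z$H_norm, E = z$E,
              F = ew_homozygosity(ds))
  comp <- dh_dhew(obs, null)
  p <- c(D = empirical_pvalue(obs$D, null$D, "lower"),
         H_norm = empirical_pvalue(obs$H_norm, null$H_norm, "lower"),
         E = empirical_pvalue(obs$E, null$E, "lower"),
         F = empirical_pvalue(obs$F, null$F, "upper"),
         DH = comp$p_DH, DHEW = comp$p_DHEW)
  val <- c(obs$D, obs$H_norm, obs$E, obs$F, NA, NA)
  data.frame(stat = names(p), value = val, p = unname(p),
             p_bonf = pmin(1, unname(p) * n_groups))
}
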