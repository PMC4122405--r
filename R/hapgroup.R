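#' Partition haplotypes by their allele at a core SNP
#'
#' Splits a haplotype matrix into the carriers of the derived core
#' allele and the non-carriers (ancestral haplogroup).  The core column
#' itself is removed from both sub-matrices, so downstream statistics
#' are computed on the remaining sites only.
#'
#' @param mat a [hap_matrix()].
#' @param core_site core column index (must be polymorphic).
#' @return An object of class `haplogroup_partition` with fields
#'   `carriers`, `non_carriers` (both [hap_matrix()]), `core_site`,
#'   `core_freq` and per-group `too_small` flags (fewer than 4
#'   haplotypes leaves Tajima's D effectively undefined).
#' @export
partition_by_core <- function(mat, core_site) {
  col <- mat$alleles[, core_site]
  der <- which(col == 1L); anc <- which(col == 0L)
  if (!length(der) || !length(anc))
    stop("core site is monomorphic; cannot partition")
  sub <- function(rows) {
    keep <- setdiff(seq_len(n_site(mat)), core_site)
    hap_matrix(mat$alleles[rows, keep, drop = FALSE],
               positions = mat$positions[keep],
               site_ids = mat$site_ids[keep],
               sample_ids = mat$sample_ids[rows],
               region = mat$region, polarized = mat$polarized,
               unpolarized = mat$unpolarized[keep],
               seq_len = mat$seq_len)
  }
  structure(list(carriers = sub(der), non_carriers = sub(anc),
                 core_site = core_site,
                 core_freq = length(der) / (length(der) + length(anc)),
                 too_small = c(carriers = length(der) < 4L,
                               non_carriers = length(anc) < 4L)),
            class = "haplogroup_partition")
}

# per-group Tajima's D on a sub-matrix, dropping sites monomorphic
# within the group (diversity_summary already ignores them)
group_tajima <- function(sub) tajimas_d(diversity_summary(sub))

#' Haplogroup-specific Tajima's D with matched coalescent p-values
#'
#' Computes Tajima's D separately for the derived and ancestral
#' haplogroups at a core SNP, and obtains empirical p-values from
#' coalescent simulations matched the way the published procedure
#' prescribes: a core SNP is designated at the *last* segregating site
#' of each simulated replicate; replicates are accepted only when the
#' simulated core-allele frequency is within `freq_tol` of the observed
#' one; within accepted replicates the carrier (resp. non-carrier)
#' sub-matrices are retained only when their number of segregating
#' sites is within `s_tol` (relative) of the observed group's; Tajima's
#' D is computed per retained replicate and the p-value is the plus-one
#' empirical tail probability.
#'
#' The derived haplogroup is tested lower-tail (the sweep signature);
#' the ancestral one upper-tail; `tail = "two.sided"` doubles the
#' smaller tail.
#'
#' @param part a [haplogroup_partition()] of the observed data.
#' @param model a [demographic_model()].
#' @param map a [recomb_map()].
#' @param theta scaled mutation rate for the simulations (or a
#'   [scaled_param_sampler()] to redraw per replicate).
#' @param freq_tol absolute tolerance on the core-allele frequency
#'   (default 0.10, the published allowance).
#' @param s_tol relative tolerance on the group's segregating sites
#'   (default 0.20, the published allowance).
#' @param target_accepted retained replicates to aim for per group.
#' @param max_sims simulation budget.
#' @param tail `"one.sided"` (derived lower, ancestral upper) or
#'   `"two.sided"`.
#' @return A list with `D_derived`, `p_derived`, `D_ancestral`,
#'   `p_ancestral`, `n_retained` (per group) and `n_simulated`.
#' @export
matched_tajima_pvalue <- function(part, model, map, theta,
                                  freq_tol = 0.10, s_tol = 0.20,
                                  target_accepted = 500L,
                                  max_sims = 100 * target_accepted,
                                  tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  if (any(part$too_small))
    stop("both haplogroups need at least 4 haplotypes for a defined D")
  D_obs <- c(derived = group_tajima(part$carriers),
             ancestral = group_tajima(part$non_carriers))
  S_obs <- c(derived = diversity_summary(part$carriers)$S,
             ancestral = diversity_summary(part$non_carriers)$S)
  null_D <- list(derived = numeric(0), ancestral = numeric(0))
  n_sim <- 0L
  block <- 100L
  sampler <- if (inherits(theta, "scaled_param_sampler")) theta else NULL
  while (min(lengths(null_D)) < target_accepted && n_sim < max_sims) {
    pars <- if (is.null(sampler))
      data.frame(theta = rep_len(theta, block),
                 rho = rep_len(map$rho, block))
    else sample_scaled_params(sampler, block)
    sims <- simulate_neutral(model, map, theta = pars$theta,
                             reps = block, rho = pars$rho)
    n_sim <- n_sim + block
    for (h in sims) {
      if (n_site(h) < 2L) next
      core <- n_site(h)                      # core SNP at the last position
      f_sim <- mean(h$alleles[, core])
      if (abs(f_sim - part$core_freq) > freq_tol) next
      ps <- tryCatch(partition_by_core(h, core), error = function(e) NULL)
      if (is.null(ps)) next
      for (grp in c("derived", "ancestral")) {
        sub <- if (grp == "derived") ps$carriers else ps$non_carriers
        if (n_hap(sub) < 4L) next
        S_grp <- diversity_summary(sub)$S
        if (abs(S_grp - S_obs[[grp]]) > s_tol * S_obs[[grp]]) next
        d <- group_tajima(sub)
        if (!is.na(d)) null_D[[grp]] <- c(null_D[[grp]], d)
      }
    }
  }
  if (min(lengths(null_D)) < 10L)
    stop(sprintf(paste0(
      "too few retained replicates (derived %d, ancestral %d) after %d",
      " simulations; acceptance rates %.2f%% / %.2f%%"),
      length(null_D$derived), length(null_D$ancestral), n_sim,
      100 * length(null_D$derived) / n_sim,
      100 * length(null_D$ancestral) / n_sim))
  pval <- function(obs, null, direction) {
    p1 <- empirical_pvalue(obs, null, direction)
    if (tail == "one.sided") p1
    else min(1, 2 * min(p1, empirical_pvalue(
      obs, null, if (direction == "lower") "upper" else "lower")))
  }
  list(D_derived = unname(D_obs["derived"]),
       p_derived = pval(D_obs[["derived"]], null_D$derived, "lower"),
       D_ancestral = unname(D_obs["ancestral"]),
       p_ancestral = pval(D_obs[["ancestral"]], null_D$ancestral, "upper"),
       n_retained = lengths(null_D), n_simulated = n_sim,
       null_D = null_D)
}
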