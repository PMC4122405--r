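#' Mutation rate from outgroup divergence (Jukes-Cantor)
#'
#' Converts an observed per-site mismatch proportion against an outgroup
#' into a Jukes-Cantor-corrected divergence d = -(3/4) ln(1 - 4p/3) and
#' then into a mutation rate per site per year, d / (2 * divergence
#' time), assuming equal rates on both branches.  Optionally returns the
#' per-generation rate.
#'
#' @param p_mismatch proportion of mismatching sites, in \[0, 0.75).
#' @param divergence_years split time of the outgroup in years (e.g.
#'   6e6 for chimpanzee).
#' @param per_generation if `TRUE`, multiply by `gen_time`.
#' @param gen_time generation time in years (default 29).
#' @return The mutation rate (per site per year, or per generation).
#' @export
jc69_rate <- function(p_mismatch, divergence_years,
                      per_generation = FALSE, gen_time = 29) {
  if (p_mismatch < 0 || p_mismatch >= 0.75)
    stop("mismatch proportion must be in [0, 0.75): JC69 saturates")
  d <- -0.75 * log(1 - 4 * p_mismatch / 3)
  rate <- d / (2 * divergence_years)
  if (per_generation) rate * gen_time else rate
}

#' Extended haplotype homozygosity at a target site
#'
#' Among the haplotypes carrying `core_allele` at the core site, EHH at
#' a target site is the probability that two randomly drawn carriers
#' are identical over the whole span from core to target (inclusive of
#' both): sum over extended-haplotype classes h of C(c_h, 2) / C(c, 2).
#'
#' @param mat a [hap_matrix()].
#' @param core_site column index of the core SNP.
#' @param core_allele 0 or 1; carriers are rows with this allele.
#' @param target_site column index of the target SNP.
#' @return EHH in \[0, 1\]; 1 when target equals core.
#' @export
ehh_at <- function(mat, core_site, core_allele = 1L, target_site) {
  carriers <- which(mat$alleles[, core_site] == core_allele)
  c_n <- length(carriers)
  if (c_n < 2L) stop("need at least 2 carriers of the core allele")
  if (target_site == core_site) return(1)
  span <- if (target_site > core_site) core_site:target_site
          else target_site:core_site
  keys <- apply(mat$alleles[carriers, span, drop = FALSE], 1L,
                paste0, collapse = "")
  ch <- table(keys)
  sum(choose(ch, 2)) / choose(c_n, 2)
}

#' EHH decay curve on one side of the core
#'
#' Computes [ehh_at()] for every site on the chosen side of the core,
#' reporting distances scaled so that 1.0 equals `region_len` (the
#' region analysed, e.g. 100 kb).
#'
#' @param mat a [hap_matrix()].
#' @param core_site core column index.
#' @param core_allele core allele (default derived, 1).
#' @param side `"upstream"` (sites left of the core) or `"downstream"`.
#' @param region_len scaling length in bp; defaults to the span from
#'   core to the region end implied by the positions present.
#' @return An object of class `ehh_curve`: data frame with `distance`
#'   (scaled, increasing) and `ehh`, plus `side` and `core_site`
#'   attributes.  The point (0, 1) at the core is always included.
#' @export
ehh_curve <- function(mat, core_site, core_allele = 1L,
                      side = c("downstream", "upstream"),
                      region_len = NULL) {
  side <- match.arg(side)
  pos <- mat$positions
  idx <- if (side == "downstream") which(pos > pos[core_site])
         else which(pos < pos[core_site])
  if (side == "upstream") idx <- rev(idx)
  region_len <- region_len %||% max(abs(pos - pos[core_site]), 1)
  d <- abs(pos[idx] - pos[core_site]) / region_len
  e <- vapply(idx, function(j) ehh_at(mat, core_site, core_allele, j),
              numeric(1))
  out <- data.frame(distance = c(0, d), ehh = c(1, e))
  structure(out, side = side, core_site = core_site,
            class = c("ehh_curve", class(out)))
}

# step-function lookup: EHH at the furthest site within scaled distance d
ehh_value_at_distance <- function(curve, d) {
  ok <- curve$distance <= d
  if (!any(ok)) return(1)
  curve$ehh[max(which(ok))]
}

#' Simulation-matched 95 percent EHH envelope
#'
#' Builds the null envelope for an EHH scan the way the published
#' procedure does: (1) reject simulated replicates whose SNP count is
#' not within `snp_tol` (relative) of the observed count, or whose
#' number of core-allele carriers does not match the observed count
#' exactly; (2) compute each accepted replicate's EHH curve from its
#' core; (3) at each listed scaled distance, select the replicates whose
#' EHH value attains the `percentile` of the accepted distribution (ties
#' included); (4) pool all selected replicates' curve points, remove
#' duplicated distances and enforce monotone non-increase scanning
#' outward from the core.
#'
#' Simulated replicates use their closest segregating site to the
#' requested core position as core; the observed carrier count is
#' matched exactly, as the filter prescribes.
#'
#' @param sims list of simulated [hap_matrix()] replicates.
#' @param observed the observed [hap_matrix()].
#' @param core_site core column index in `observed`.
#' @param core_allele core allele in `observed` (default 1).
#' @param side which side of the core to analyse.
#' @param distances scaled distances at which percentile selection is
#'   done (default 0.1 ... 0.5).
#' @param percentile envelope level (default 0.95).
#' @param snp_tol relative tolerance on the simulated SNP count
#'   (default 0.1).
#' @param sim_core_freq_match if no simulated site has exactly the
#'   observed carrier count the replicate is rejected; this is the
#'   published exact-match rule.
#' @param min_accepted minimum accepted replicates (default 100).
#' @return An object of class `ehh_envelope`: data frame with
#'   `distance` and `cutoff` (non-increasing, deduplicated), with
#'   attributes `n_accepted` and `acceptance_rate`.
#' @export
build_envelope <- function(sims, observed, core_site, core_allele = 1L,
                           side = c("downstream", "upstream"),
                           distances = seq(0.1, 0.5, by = 0.1),
                           percentile = 0.95, snp_tol = 0.1,
                           sim_core_freq_match = TRUE,
                           min_accepted = 100L) {
  side <- match.arg(side)
  S_obs <- n_site(observed)
  c_obs <- sum(observed$alleles[, core_site] == core_allele)
  core_pos <- observed$positions[core_site]
  region_len <- if (!is.null(observed$region))
    observed$region$end - observed$region$start
  else max(abs(observed$positions - core_pos))
  curves <- list()
  for (h in sims) {
    if (abs(n_site(h) - S_obs) > snp_tol * S_obs) next
    if (n_site(h) < 2L) next
    # core in the simulated replicate: site nearest the observed core
    # position whose derived count equals the observed carrier count
    cnt <- colSums(h$alleles == 1L)
    cand <- which(cnt == c_obs)
    if (!length(cand)) { if (sim_core_freq_match) next else
      cand <- which.min(abs(cnt - c_obs)) }
    j <- cand[which.min(abs(h$positions[cand] - core_pos))]
    curves[[length(curves) + 1L]] <-
      ehh_curve(h, j, 1L, side, region_len = region_len)
  }
  n_acc <- length(curves)
  if (n_acc < min_accepted)
    stop(sprintf(
      "only %d of %d replicates passed the filters (%.1f%%); need %d",
      n_acc, length(sims), 100 * n_acc / max(length(sims), 1L),
      min_accepted))
  # percentile selection at each listed distance
  selected <- logical(n_acc)
  for (d in distances) {
    vals <- vapply(curves, ehh_value_at_distance, numeric(1), d = d)
    cut <- stats::quantile(vals, percentile, names = FALSE, type = 1)
    selected <- selected | vals == cut
  }
  pts <- do.call(rbind, curves[selected])
  pts <- pts[order(pts$distance, -pts$ehh), ]
  pts <- pts[!duplicated(pts$distance), ]          # dedupe distances
  pts$ehh <- cummin(pts$ehh)                       # enforce EHH_{i+1} <= EHH_i
  out <- data.frame(distance = pts$distance, cutoff = pts$ehh)
  structure(out, n_accepted = n_acc,
            acceptance_rate = n_acc / max(length(sims), 1L),
            percentile = percentile, side = side,
            class = c("ehh_envelope", class(out)))
}

#' Flag where an observed EHH curve exceeds the null envelope
#'
#' The envelope is interpolated piecewise-linearly between its points;
#' observed curve points beyond the envelope support use the nearest
#' envelope value.  A distance is flagged when the observed EHH strictly
#' exceeds the cutoff.
#'
#' @param observed an [ehh_curve()].
#' @param envelope an [ehh_envelope()].
#' @return A data frame `distance`, `ehh`, `cutoff`, `exceeds`.
#' @export
ehh_significance <- function(observed, envelope) {
  if (max(observed$distance) < min(envelope$distance) ||
      min(observed$distance) > max(envelope$distance))
    stop("observed curve and envelope have disjoint distance supports")
  cut <- stats::approx(envelope$distance, envelope$cutoff,
                       xout = observed$distance, rule = 2)$y
  data.frame(distance = observed$distance, ehh = observed$ehh,
             cutoff = cut, exceeds = observed$ehh > cut)
}
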