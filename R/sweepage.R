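#' Genetic map distance helpers
#'
#' Convert a physical interval to Morgans under a [recomb_map()].  The
#' map's scaled rate rho = 4*N0*r refers to the whole region; the
#' per-generation recombination fraction is rho/(4*N0), distributed
#' along the region proportionally to the basal rate times the hotspot
#' multipliers.
#'
#' @param map a [recomb_map()].
#' @param from_bp,to_bp interval endpoints (bp).
#' @param N diploid size used to unscale rho.
#' @return Map length in Morgans.
#' @export
map_morgans <- function(map, from_bp, to_bp, N = 10000) {
  if (to_bp < from_bp) { tmp <- from_bp; from_bp <- to_bp; to_bp <- tmp }
  hs <- map$hotspots
  mass_at <- function(x) {
    # basal mass up to x plus hotspot excess
    m <- x
    if (nrow(hs)) {
      ov <- pmin(pmax(x - hs$start, 0), hs$end - hs$start)
      m <- m + sum(ov * (hs$mult - 1))
    }
    m
  }
  frac <- (mass_at(to_bp) - mass_at(from_bp)) / map$region_len
  frac * map$rho / (4 * N)
}

#' Consensus ancestral (sweeping) haplotype among carriers
#'
#' Per-site majority allele among the carriers of the selected allele;
#' ties go to the derived allele (the allele expected on the sweeping
#' background).
#'
#' @param carriers a [hap_matrix()] of carrier haplotypes.
#' @return Integer vector of 0/1 alleles, one per site.
#' @export
consensus_ancestral_haplotype <- function(carriers) {
  if (n_hap(carriers) < 2L) stop("need at least 2 carriers")
  cnt <- colSums(carriers$alleles == 1L, na.rm = TRUE)
  tot <- colSums(!is.na(carriers$alleles))
  as.integer(cnt >= tot / 2)           # tie -> derived
}

#' Ancestral-segment endpoints for one carrier by an absorbing HMM
#'
#' Scans outward from the core on each side with a two-state chain:
#' state A ("still on the ancestral background") emits a match to the
#' consensus with probability 1 - eps; state B ("recombined",
#' absorbing) emits the consensus allele with the background allele
#' frequency.  The per-interval switch probability is
#' 1 - exp(-rho_interval * tau) with rho_interval the interval's
#' per-generation map length and tau the switch scale (of the order of
#' the sweep duration in generations).  The most likely switch interval
#' is found by exhaustive enumeration over the m + 1 switch hypotheses
#' (equivalent to Viterbi for an absorbing chain); the endpoint is the
#' midpoint of the switch interval, or the window edge (censored) when
#' "never switched" wins.
#'
#' @param carrier integer vector, the carrier's alleles.
#' @param ancestral consensus alleles from
#'   [consensus_ancestral_haplotype()].
#' @param positions site positions (bp), aligned with `carrier`.
#' @param core_site core column index; the carrier must match the
#'   consensus there.
#' @param bg_freq per-site frequency of the consensus allele in the
#'   whole sample (emission probability in state B).
#' @param map a [recomb_map()] (used with `N` for interval map lengths);
#'   ignored when `switch_prob` is given.
#' @param N diploid size for unscaling the map.
#' @param eps genotyping/mutation error rate in state A (default 0.01).
#' @param tau switch scale in generations.
#' @param switch_prob optional fixed per-interval switch probability
#'   overriding the map-based one.
#' @param window bp window half-open `(left, right)` bounding the scan;
#'   defaults to the span of `positions`.
#' @return A list with `left`, `right` (endpoint bp), `censored_left`,
#'   `censored_right`.
#' @export
hmm_segment_endpoints <- function(carrier, ancestral, positions,
                                  core_site, bg_freq, map = NULL,
                                  N = 10000, eps = 0.01, tau = 1000,
                                  switch_prob = NULL, window = NULL) {
  if (carrier[core_site] != ancestral[core_site])
    stop("carrier does not match the consensus at the core site")
  window <- window %||% c(min(positions), max(positions))
  one_side <- function(idx, edge) {
    m <- length(idx)
    if (m == 0L)
      return(list(end = edge, censored = TRUE))
    match_j <- carrier[idx] == ancestral[idx]
    eA <- ifelse(match_j, 1 - eps, eps)
    eB <- ifelse(match_j, bg_freq[idx], 1 - bg_freq[idx])
    eB <- pmin(pmax(eB, 1e-6), 1 - 1e-6)
    bounds <- c(positions[core_site], positions[idx])
    if (is.null(switch_prob)) {
      p_sw <- vapply(seq_len(m), function(i)
        1 - exp(-map_morgans(map, bounds[i], bounds[i + 1L], N) * tau),
        numeric(1))
    } else p_sw <- rep_len(switch_prob, m)
    p_sw <- pmin(pmax(p_sw, 1e-12), 1 - 1e-12)
    # hypothesis k = stayed A through marker k, switched in interval k+1
    ll <- numeric(m + 1L)
    for (k in 0:m) {
      v <- sum(log(1 - p_sw[seq_len(k)])) + sum(log(eA[seq_len(k)]))
      if (k < m)
        v <- v + log(p_sw[k + 1L]) + sum(log(eB[(k + 1L):m]))
      ll[k + 1L] <- v
    }
    k_hat <- which.max(ll) - 1L
    if (k_hat == m) list(end = edge, censored = TRUE)
    else list(end = (bounds[k_hat + 1L] + bounds[k_hat + 2L]) / 2,
              censored = FALSE)
  }
  left_idx <- rev(which(positions < positions[core_site]))
  right_idx <- which(positions > positions[core_site])
  L <- one_side(left_idx, window[1L])
  R <- one_side(right_idx, window[2L])
  list(left = L$end, right = R$end,
       censored_left = L$censored, censored_right = R$censored)
}

#' Ancestral-segment endpoints for all carriers
#'
#' Runs [hmm_segment_endpoints()] for every carrier of the derived core
#' allele against the carrier consensus.
#'
#' @param mat a [hap_matrix()].
#' @param core_site core column index.
#' @param map a [recomb_map()].
#' @param N diploid size.
#' @param eps state-A error rate.
#' @param tau switch scale in generations.
#' @param window optional scan window `(left, right)` in bp.
#' @return An object of class `ancestral_segments`: data frame with
#'   columns `left`, `right`, `censored_left`, `censored_right`, plus
#'   attributes `core_pos` and `window`.
#' @export
ancestral_segments <- function(mat, core_site, map, N = 10000,
                               eps = 0.01, tau = 1000, window = NULL) {
  carriers_rows <- which(mat$alleles[, core_site] == 1L)
  if (length(carriers_rows) < 2L) stop("need at least 2 carriers")
  keep <- seq_len(n_site(mat))
  sub <- mat$alleles[carriers_rows, , drop = FALSE]
  cons <- {
    cnt <- colSums(sub == 1L, na.rm = TRUE)
    tot <- colSums(!is.na(sub))
    as.integer(cnt >= tot / 2)
  }
  bg <- vapply(keep, function(j) {
    f1 <- mean(mat$alleles[, j] == 1L, na.rm = TRUE)
    if (cons[j] == 1L) f1 else 1 - f1
  }, numeric(1))
  window <- window %||% c(min(mat$positions), max(mat$positions))
  rows <- lapply(seq_along(carriers_rows), function(i) {
    e <- hmm_segment_endpoints(sub[i, ], cons, mat$positions, core_site,
                               bg, map = map, N = N, eps = eps,
                               tau = tau, window = window)
    data.frame(left = e$left, right = e$right,
               censored_left = e$censored_left,
               censored_right = e$censored_right)
  })
  out <- do.call(rbind, rows)
  structure(out, core_pos = mat$positions[core_site], window = window,
            class = c("ancestral_segments", class(out)))
}

#' Sweep duration under a deterministic logistic trajectory
#'
#' Time for an allele with selective advantage s to rise from a single
#' copy, x0 = 1/(2N), to its present frequency:
#' T = (1/s) * ln( p (1 - x0) / ((1 - p) x0) ) generations.
#'
#' @param s selection coefficient (> 0).
#' @param p_now present-day derived frequency (x0 < p_now < 1).
#' @param N diploid population size.
#' @return Sweep duration in generations.
#' @export
sweep_duration <- function(s, p_now, N) {
  if (s <= 0) stop("s must be positive")
  x0 <- 1 / (2 * N)
  if (p_now <= x0 || p_now >= 1)
    stop("p_now must lie strictly between 1/(2N) and 1")
  log(p_now * (1 - x0) / ((1 - p_now) * x0)) / s
}

# expected breakpoints per Morgan over the sweep: integral of (1 - x(t))
# over the logistic trajectory, which has the closed form ln(p/x0)/s
sweep_lambda <- function(s, p_now, N) {
  x0 <- 1 / (2 * N)
  log(p_now / x0) / s
}

#' Maximum-likelihood selection coefficient and allele age from
#' ancestral-segment endpoints
#'
#' Composite likelihood over the per-chromosome, per-side endpoints of
#' the unbroken ancestral haplotype, under a star-genealogy
#' approximation of the sweep: during a sweep of duration T(s) the
#' recombination events that move a lineage off the sweeping background
#' accrue at intensity lambda(s) = integral over the sweep of
#' (1 - x(t)) dt = ln(p_now * 2N)/s per Morgan.  An observed endpoint at
#' map distance m from the core contributes log lambda - lambda * m; a
#' side censored at the window edge contributes -lambda * m_edge.  The
#' estimate is the grid argmax, the 95 percent CI the profile set
#' \{s : logL >= max - 1.92\}, and the age T(s_hat) * gen_time years.
#'
#' @param segments an [ancestral_segments()] data frame (attributes
#'   `core_pos` and `window` required, as produced by that function).
#' @param map a [recomb_map()].
#' @param p_now present-day derived-allele frequency.
#' @param N diploid population size (default 10000).
#' @param s_grid grid of candidate s values (default 200 log-spaced
#'   points on 1e-3 ... 1e-1).
#' @param gen_time generation time in years (default 29).
#' @return An object of class `sweep_fit`: list with `s_hat`, `ci_95`,
#'   `T_gen`, `age_years`, `age_ci_years`, `loglik` (data frame over
#'   the grid), `n_informative` and `all_censored` flag.
#' @export
fit_sweep <- function(segments, map, p_now, N = 10000,
                      s_grid = exp(seq(log(1e-3), log(1e-1),
                                       length.out = 200)),
                      gen_time = 29) {
  core_pos <- attr(segments, "core_pos")
  window <- attr(segments, "window")
  if (is.null(core_pos) || is.null(window))
    stop("segments must carry core_pos and window attributes")
  m_left <- vapply(segments$left, function(b)
    map_morgans(map, b, core_pos, N), numeric(1))
  m_right <- vapply(segments$right, function(b)
    map_morgans(map, core_pos, b, N), numeric(1))
  m_edge_l <- map_morgans(map, window[1L], core_pos, N)
  m_edge_r <- map_morgans(map, core_pos, window[2L], N)
  obs_m <- c(m_left[!segments$censored_left],
             m_right[!segments$censored_right])
  cens_m <- c(rep(m_edge_l, sum(segments$censored_left)),
              rep(m_edge_r, sum(segments$censored_right)))
  n_inf <- length(obs_m)
  if (n_inf < 10L)
    warning("fewer than 10 informative (uncensored) segment sides; ",
            "the likelihood is weakly informed")
  ll <- vapply(s_grid, function(s) {
    lam <- sweep_lambda(s, p_now, N)
    sum(log(lam) - lam * obs_m) - lam * sum(cens_m)
  }, numeric(1))
  all_cens <- n_inf == 0L
  i_hat <- which.max(ll)
  in_ci <- ll >= ll[i_hat] - stats::qchisq(0.95, 1) / 2
  s_hat <- s_grid[i_hat]
  ci <- range(s_grid[in_ci])
  T_gen <- sweep_duration(s_hat, p_now, N)
  structure(list(
    s_hat = s_hat, ci_95 = ci, T_gen = T_gen,
    age_years = T_gen * gen_time,
    age_ci_years = rev(vapply(ci, function(s)
      sweep_duration(s, p_now, N) * gen_time, numeric(1))),
    loglik = data.frame(s = s_grid, loglik = ll),
    n_informative = n_inf, all_censored = all_cens,
    gen_time = gen_time, p_now = p_now, N = N),
    class = "sweep_fit")
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat(sprintf(
    "sweep_fit: s_hat = %.4f (95%% CI %.4f-%.4f)%s\n",
    x$s_hat, x$ci_95[1], x$ci_95[2],
    if (x$all_censored) " [all sides censored: lower bound only]" else ""))
  cat(sprintf("  duration %.0f generations; age %.0f years (CI %.0f-%.0f)\n",
              x$T_gen, x$age_years, x$age_ci_years[1], x$age_ci_years[2]))
  invisible(x)
}

#' Fit the sweep model directly from haplotypes (two-pass)
#'
#' Convenience pipeline: extract ancestral segments with a pilot switch
#' scale, fit, re-extract with tau set to the fitted sweep duration and
#' refit.
#'
#' @inheritParams ancestral_segments
#' @inheritParams fit_sweep
#' @param tau_pilot initial switch scale in generations.
#' @return A [fit_sweep()] result; the segments used are attached as
#'   attribute `segments`.
#' @export
fit_sweep_from_haplotypes <- function(mat, core_site, map, p_now = NULL,
                                      N = 10000, eps = 0.01,
                                      tau_pilot = 1000,
                                      s_grid = exp(seq(log(1e-3),
                                                       log(1e-1),
                                                       length.out = 200)),
                                      gen_time = 29, window = NULL) {
  p_now <- p_now %||% mean(mat$alleles[, core_site] == 1L)
  seg <- ancestral_segments(mat, core_site, map, N, eps, tau_pilot,
                            window)
  fit <- fit_sweep(seg, map, p_now, N, s_grid, gen_time)
  seg2 <- ancestral_segments(mat, core_site, map, N, eps,
                             tau = max(fit$T_gen, 1), window)
  fit2 <- fit_sweep(seg2, map, p_now, N, s_grid, gen_time)
  attr(fit2, "segments") <- seg2
  fit2
}

#' Simulate segment endpoints from the sweep likelihood model
#'
#' Draws per-side breakpoint map distances from the exponential
#' distribution with rate lambda(s), censoring at the window edges, and
#' converts them to physical positions under a uniform map.  This is
#' the generative counterpart of [fit_sweep()] used for parameter
#' recovery.
#'
#' @param n_chrom number of carrier chromosomes.
#' @param s true selection coefficient.
#' @param p_now present-day frequency.
#' @param N diploid size.
#' @param map a uniform [recomb_map()].
#' @param core_pos core position (bp).
#' @param window scan window `(left, right)` bp.
#' @return An [ancestral_segments()]-shaped data frame.
#' @export
simulate_endpoints <- function(n_chrom, s, p_now, N, map, core_pos,
                               window = c(0, map$region_len)) {
  lam <- sweep_lambda(s, p_now, N)
  morg_per_bp <- map$rho / (4 * N) / map$region_len
  draw_side <- function(edge_bp) {
    m <- stats::rexp(n_chrom, lam)
    bp <- m / morg_per_bp
    cens <- bp >= abs(edge_bp - core_pos)
    pos <- ifelse(cens, edge_bp,
                  core_pos + sign(edge_bp - core_pos) * bp)
    list(pos = pos, cens = cens)
  }
  L <- draw_side(window[1L]); R <- draw_side(window[2L])
  out <- data.frame(left = L$pos, right = R$pos,
                    censored_left = L$cens, censored_right = R$cens)
  structure(out, core_pos = core_pos, window = window,
            class = c("ancestral_segments", class(out)))
}
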