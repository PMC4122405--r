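#' Demographic model in ms scaling
#'
#' Describes an island/split demography the way Hudson's ms does: `npop`
#' populations with present-day relative sizes (units of the reference
#' diploid size N0), exponential growth rates (ms alpha), a migration
#' matrix with entries 4*N0*m, and a list of timed events replayed
#' backward in time.  Times are in units of 4*N0 generations.
#'
#' Supported event kinds (mirroring the ms flags):
#' * `merge` (`-ej t i j`): lineages of population i join population j;
#'   migration into and out of i is switched off.
#' * `size` (`-en t i x`): population i set to size x, growth reset to 0.
#' * `growth` (`-eg t i a`): growth rate of population i set to a.
#' * `migration` (`-em t i j x`): single migration entry set;
#'   (`-ema t matrix`): full matrix replaced (pass `matrix =`).
#'
#' @param sample_sizes integer vector, haplotypes sampled per population.
#' @param sizes present-day sizes in units of N0 (default all 1).
#' @param growth ms growth rates alpha (default all 0).
#' @param migration npop x npop matrix of 4*N0*m entries (default 0).
#' @param events list of lists with fields `time`, `kind` and
#'   kind-specific parameters `i`, `j`, `x`, `matrix`.
#' @param N0 reference diploid size; only used when converting scaled
#'   times to generations or years (default 10000).
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(sample_sizes, sizes = NULL, growth = NULL,
                              migration = NULL, events = list(),
                              N0 = 10000) {
  npop <- length(sample_sizes)
  sizes <- sizes %||% rep(1, npop)
  growth <- growth %||% rep(0, npop)
  migration <- migration %||% matrix(0, npop, npop)
  stopifnot(length(sizes) == npop, length(growth) == npop,
            nrow(migration) == npop, ncol(migration) == npop)
  if (any(migration < 0)) stop("migration rates must be non-negative")
  diag(migration) <- 0
  times <- vapply(events, function(e) e$time, numeric(1))
  if (length(times) > 1L && any(diff(order(times)) < 0)) {
    events <- events[order(times)]
    times <- sort(times)
  }
  if (length(times) && any(times < 0))
    stop("event times must be non-negative")
  structure(list(npop = npop, sample_sizes = as.integer(sample_sizes),
                 sizes = sizes, growth = growth, migration = migration,
                 events = events, N0 = N0),
            class = "demographic_model")
}

#' The three-population Out-of-Africa model used for the European nulls
#'
#' The Gutenkunst et al. Out-of-Africa demography exactly as encoded in
#' the ms-style command used for the European-sample simulations:
#' African, European and East-Asian populations with present sizes
#' 1.68202 / 3.73683 / 7.29205 N0, exponential growth 116.010723 and
#' 160.246047 in the two non-African populations, the printed migration
#' matrix, the Asian-European merge at 0.028985 (followed by a
#' bottleneck to 0.287184 and a migration-rate change), the
#' Eurasian-African merge at 0.197963 and the ancestral size change at
#' 0.303501.  Only the European deme is sampled (224 haplotypes by
#' default, matching the 1KGP South+North European chromosome count used
#' with this model).
#'
#' @param n_eur haplotypes to sample from the European population.
#' @param N0 reference diploid size.
#' @return A [demographic_model()].
#' @export
ooa_model <- function(n_eur = 224, N0 = 10000) {
  mig <- matrix(c(0,        0.881098, 0.561966,
                  0.881098, 0,        2.79746,
                  0.561966, 2.79746,  0), 3, 3, byrow = TRUE)
  mig2 <- matrix(c(0,       7.29314, 0,
                   7.29314, 0,       0,
                   0,       0,       0), 3, 3, byrow = TRUE)
  demographic_model(
    sample_sizes = c(0L, n_eur, 0L),
    sizes = c(1.68202, 3.73683, 7.29205),
    growth = c(0, 116.010723, 160.246047),
    migration = mig,
    events = list(
      list(time = 0.028985, kind = "merge", i = 3, j = 2),
      list(time = 0.028985, kind = "size", i = 2, x = 0.287184),
      list(time = 0.028985, kind = "migration", matrix = mig2),
      list(time = 0.197963, kind = "merge", i = 2, j = 1),
      list(time = 0.303501, kind = "size", i = 1, x = 1)),
    N0 = N0)
}

#' Recombination map with hotspot intervals
#'
#' A basal scaled recombination rate plus hotspot intervals with
#' intensity multipliers, the msHOT `-v` representation.  The basal rate
#' is the regional average excluding hotspots; hotspots multiply it
#' locally.
#'
#' @param region_len region length in bp.
#' @param rho basal scaled recombination rate 4*N0*r for the whole
#'   region.
#' @param hotspots data frame with columns `start`, `end` (bp, 0-based
#'   half-open, within the region, non-overlapping) and `mult`
#'   (multiplier >= 1); or NULL for a uniform map.
#' @return An object of class `recomb_map`.
#' @export
recomb_map <- function(region_len, rho, hotspots = NULL) {
  if (is.null(hotspots))
    hotspots <- data.frame(start = numeric(0), end = numeric(0),
                           mult = numeric(0))
  hotspots <- hotspots[order(hotspots$start), , drop = FALSE]
  if (nrow(hotspots)) {
    if (any(hotspots$start < 0) || any(hotspots$end > region_len))
      stop("hotspot intervals must lie within the region")
    if (any(hotspots$end <= hotspots$start))
      stop("hotspot intervals must have positive width")
    if (nrow(hotspots) > 1L &&
        any(hotspots$start[-1L] < hotspots$end[-nrow(hotspots)]))
      stop("hotspot intervals must not overlap")
    if (any(hotspots$mult < 1)) stop("hotspot multipliers must be >= 1")
  }
  structure(list(region_len = region_len, rho = rho,
                 hotspots = hotspots),
            class = "recomb_map")
}

#' Hotspot maps from the two flanking-region simulation commands
#'
#' The downstream (3') and upstream (5') 100 kb recombination maps used
#' for the EHH null simulations, with the hotspot intervals and
#' multipliers exactly as given on the two msHOT command lines.  The two
#' regions have their own maps and are analysed independently.
#'
#' @param side `"downstream"` or `"upstream"`.
#' @param rho basal scaled recombination rate for the 100 kb region
#'   (sampled per replicate in the published procedure; the default here
#'   is only a placeholder mean).
#' @return A [recomb_map()].
#' @export
slc45a2_flank_map <- function(side = c("downstream", "upstream"),
                              rho = 40) {
  side <- match.arg(side)
  hs <- if (side == "downstream") {
    data.frame(start = c(12348, 15953, 18158, 36693, 64619),
               end   = c(15952, 18157, 18718, 39560, 66167),
               mult  = c(4, 27, 3, 5, 5))
  } else {
    data.frame(start = c(71, 5720, 8494),
               end   = c(5719, 8493, 9611),
               mult  = c(5, 15, 5))
  }
  recomb_map(region_len = 100000, rho = rho, hotspots = hs)
}

#' Sampler for per-replicate theta and rho
#'
#' The null simulations redraw theta and rho for every replicate from a
#' normal distribution with standard deviation equal to the mean,
#' redrawing until the value is positive (the model requires positive
#' rates; the truncation rule is part of the sampler's contract).
#'
#' @param mean_theta,mean_rho positive means of the scaled mutation and
#'   recombination rates.
#' @return An object of class `scaled_param_sampler`.
#' @export
scaled_param_sampler <- function(mean_theta, mean_rho) {
  if (mean_theta <= 0 || mean_rho <= 0)
    stop("means must be positive")
  structure(list(mean_theta = mean_theta, mean_rho = mean_rho),
            class = "scaled_param_sampler")
}

#' Draw (theta, rho) pairs
#'
#' Each value is Normal(mean, sd = mean), redrawn until positive.
#' Reproducible under `set.seed`.
#'
#' @param sampler a [scaled_param_sampler()].
#' @param reps number of pairs.
#' @param sd_frac standard deviation as a fraction of the mean
#'   (default 1, the published rule; 0 gives degenerate draws equal to
#'   the mean).
#' @return A data frame with columns `theta` and `rho`.
#' @export
sample_scaled_params <- function(sampler, reps, sd_frac = 1) {
  draw <- function(m) {
    if (sd_frac == 0) return(rep(m, reps))
    out <- numeric(reps)
    for (i in seq_len(reps)) {
      x <- stats::rnorm(1L, m, sd_frac * m)
      while (x <= 0) x <- stats::rnorm(1L, m, sd_frac * m)
      out[i] <- x
    }
    out
  }
  data.frame(theta = draw(sampler$mean_theta),
             rho = draw(sampler$mean_rho))
}

# flatten a demographic model's events into the C++ encoding
flatten_events <- function(model) {
  kinds <- c(merge = 0L, size = 1L, growth = 2L, migration = 3L)
  time <- numeric(0); kind <- integer(0)
  ei <- integer(0); ej <- integer(0); ex <- numeric(0)
  for (e in model$events) {
    if (e$kind == "migration" && !is.null(e$matrix)) {
      m <- e$matrix
      for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
        if (i == j) next
        time <- c(time, e$time); kind <- c(kind, 3L)
        ei <- c(ei, i - 1L); ej <- c(ej, j - 1L); ex <- c(ex, m[i, j])
      }
    } else {
      time <- c(time, e$time); kind <- c(kind, kinds[[e$kind]])
      ei <- c(ei, (e$i %||% 1L) - 1L); ej <- c(ej, (e$j %||% 1L) - 1L)
      ex <- c(ex, e$x %||% 0)
    }
  }
  ord <- order(time)
  list(time = time[ord], kind = kind[ord], i = ei[ord], j = ej[ord],
       x = ex[ord])
}

map_to_cpp <- function(map) {
  hs <- map$hotspots
  list(l = hs$start / map$region_len, r = hs$end / map$region_len,
       f = hs$mult, rho = map$rho, region_len = map$region_len)
}

cpp_rep_to_hap <- function(rep, region_len) {
  hap_matrix(rep$alleles, positions = rep$positions * region_len,
             polarized = TRUE)
}

#' Simulate neutral haplotypes under a demographic model
#'
#' Hudson-style coalescent with recombination under the given
#' demography; each replicate yields `sum(sample_sizes)` haplotypes with
#' ancestral/derived coding (infinite-sites mutations on the marginal
#' trees) and physical positions on `[0, region_len)`.
#'
#' @param model a [demographic_model()].
#' @param map a [recomb_map()] (use `rho = 0` for no recombination).
#' @param theta scaled mutation rate 4*N0*mu*L for the region; either a
#'   single value used for all replicates or a vector of length `reps`
#'   (e.g. from [sample_scaled_params()]).
#' @param reps number of replicates.
#' @param rho optional per-replicate vector of scaled recombination
#'   rates overriding `map$rho` (hotspot structure is kept).
#' @return A list of `reps` polarized [hap_matrix()] objects; each
#'   carries a `breakpoints` attribute with the recombination breakpoint
#'   positions (bp) realised in that replicate.
#' @export
simulate_neutral <- function(model, map, theta, reps, rho = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(map, "recomb_map"), reps >= 1)
  ev <- flatten_events(model)
  mc <- map_to_cpp(map)
  theta <- rep_len(theta, reps)
  rho <- if (is.null(rho)) rep_len(mc$rho, reps) else rep_len(rho, reps)
  out <- vector("list", reps)
  # group identical (theta, rho) to amortise the C++ call
  for (i in seq_len(reps)) {
    r <- sim_coalescent_cpp(model$sample_sizes, model$sizes,
                            model$growth, model$migration,
                            ev$time, ev$kind, ev$i, ev$j, ev$x,
                            theta[i], rho[i], mc$l, mc$r, mc$f, 1L)[[1L]]
    h <- cpp_rep_to_hap(r, mc$region_len)
    attr(h, "breakpoints") <- r$breakpoints * mc$region_len
    out[[i]] <- h
  }
  out
}

#' Sweep specification
#'
#' Parameters of a selective sweep at a core site: the per-generation
#' selective advantage `s` of the derived allele, its present-day
#' frequency, the physical position of the selected site and the
#' diploid population size.
#'
#' @param s selection coefficient, > 0.
#' @param p_now present-day derived-allele frequency, in (0, 1).
#' @param core_pos position of the selected site (bp).
#' @param N diploid population size.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(s, p_now, core_pos, N = 10000) {
  if (s <= 0) stop("s must be positive")
  if (p_now <= 0 || p_now >= 1) stop("p_now must be in (0, 1)")
  structure(list(s = s, p_now = p_now, core_pos = core_pos, N = N),
            class = "sweep_spec")
}

#' Simulate haplotypes carrying a selective sweep
#'
#' Structured coalescent in a single population of constant diploid size
#' `spec$N`, conditioned on a deterministic logistic trajectory of the
#' selected allele from 1/(2N) up to its present frequency.  The number
#' of sampled carriers is drawn binomially and rejected until the
#' realised carrier fraction is within `freq_tol` of `spec$p_now`; the
#' first `n_der` haplotypes of each replicate are the carriers and the
#' core site appears as an extra column at `spec$core_pos`.
#'
#' @param n haplotypes per replicate.
#' @param map a [recomb_map()].
#' @param theta scaled mutation rate (single value or per-replicate
#'   vector).
#' @param spec a [sweep_spec()].
#' @param reps number of replicates.
#' @param freq_tol rejection tolerance on the realised carrier fraction
#'   (default 0.02).
#' @param max_rejections per replicate (default 1000).
#' @return A list of polarized [hap_matrix()] objects; each has a
#'   `core_index` attribute giving the core column.
#' @export
simulate_sweep <- function(n, map, theta, spec, reps, freq_tol = 0.02,
                           max_rejections = 1000) {
  stopifnot(inherits(map, "recomb_map"), inherits(spec, "sweep_spec"))
  mc <- map_to_cpp(map)
  theta <- rep_len(theta, reps)
  out <- vector("list", reps)
  for (i in seq_len(reps)) {
    n_der <- NA_integer_
    for (try in seq_len(max_rejections)) {
      cand <- stats::rbinom(1L, n, spec$p_now)
      if (cand >= 2L && cand < n &&
          abs(cand / n - spec$p_now) <= freq_tol) { n_der <- cand; break }
    }
    if (is.na(n_der))
      stop("could not realise the requested sweep frequency within ",
           max_rejections, " rejections")
    r <- sim_sweep_cpp(n, n_der, theta[i], mc$rho, mc$l, mc$r, mc$f,
                       spec$s, spec$N, spec$core_pos / mc$region_len,
                       1L)[[1L]]
    h <- cpp_rep_to_hap(r, mc$region_len)
    # insert the core column at its physical position
    core_col <- as.integer(seq_len(n) <= n_der)
    at <- findInterval(spec$core_pos, h$positions)
    alle <- cbind(h$alleles[, seq_len(at), drop = FALSE], core_col,
                  if (at < n_site(h))
                    h$alleles[, (at + 1L):n_site(h), drop = FALSE])
    pos <- append(h$positions, spec$core_pos, after = at)
    hm <- hap_matrix(alle, positions = pos, polarized = TRUE)
    attr(hm, "core_index") <- at + 1L
    out[[i]] <- hm
  }
  out
}
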