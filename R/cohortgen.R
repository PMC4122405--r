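#' Cohort model for the synthetic phenotype generator
#'
#' Parameters of the generative model behind [generate_cohort()],
#' [generate_case_control()] and [generate_geo_frequencies()]:
#' the derived ("light", F) allele frequency; per-genotype skin
#' reflectance means (instrument units at 685 nm, higher = lighter) and
#' a common SD; per-genotype hair and eye colour category
#' probabilities; the allelic melanoma odds ratio; and the UV-band
#' frequency line.
#'
#' The default reflectance means (FF 73, FL 69, LL 66; SD 3) are
#' calibration constants chosen so that the reflectance extremes of a
#' 500-individual cohort reproduce the observed group ranges
#' (60.67-79.67) and extreme-group allele frequencies; they are
#' configuration, not estimates.
#'
#' @param allele_freq frequency of the derived F allele (default 0.88,
#'   the frequency observed in the resequenced sample).
#' @param reflectance_means named vector for genotypes FF, FL, LL.
#' @param reflectance_sd common SD of reflectance noise.
#' @param hair_probs,eye_probs matrices (genotype x category) of
#'   category probabilities; rows FF, FL, LL must sum to 1.  Defaults
#'   encode darker hair/eyes being more likely for L carriers.
#' @param melanoma_or allelic odds ratio of the F allele for melanoma
#'   (default 4, of the order implied by the case/control genotype
#'   counts).
#' @param uv_bands annual UV irradiation per band (J/m^2).
#' @param uv_intercept,uv_slope allele-frequency line over UV.
#' @param uv_n binomial sample size (chromosomes) per band.
#' @return An object of class `cohort_model`.
#' @export
cohort_model <- function(allele_freq = 0.88,
                         reflectance_means = c(FF = 73, FL = 69, LL = 66),
                         reflectance_sd = 3,
                         hair_probs = NULL, eye_probs = NULL,
                         melanoma_or = 4,
                         uv_bands = c(24500, 26500, 28500, 30500,
                                      33000, 43400),
                         uv_intercept = 1.85, uv_slope = -4e-5,
                         uv_n = 50) {
  if (allele_freq <= 0 || allele_freq >= 1)
    stop("allele_freq must be in (0, 1)")
  if (melanoma_or <= 0) stop("melanoma_or must be positive")
  hair_probs <- hair_probs %||% rbind(
    FF = c(black = 0.05, dark_brown = 0.25, light = 0.70),
    FL = c(black = 0.15, dark_brown = 0.40, light = 0.45),
    LL = c(black = 0.35, dark_brown = 0.40, light = 0.25))
  eye_probs <- eye_probs %||% rbind(
    FF = c(dark = 0.35, light = 0.65),
    FL = c(dark = 0.55, light = 0.45),
    LL = c(dark = 0.75, light = 0.25))
  for (m in list(hair_probs, eye_probs))
    if (any(abs(rowSums(m) - 1) > 1e-8) || any(m < 0))
      stop("category probabilities must be non-negative and sum to 1")
  structure(list(allele_freq = allele_freq,
                 reflectance_means = reflectance_means,
                 reflectance_sd = reflectance_sd,
                 hair_probs = hair_probs, eye_probs = eye_probs,
                 melanoma_or = melanoma_or, uv_bands = uv_bands,
                 uv_intercept = uv_intercept, uv_slope = uv_slope,
                 uv_n = uv_n),
            class = "cohort_model")
}

geno_levels <- c("FF", "FL", "LL")

hwe_genotype_probs <- function(p) {
  # p = frequency of F; genotype order FF, FL, LL
  c(p^2, 2 * p * (1 - p), (1 - p)^2)
}

sample_category <- function(probs_matrix, genotypes) {
  cats <- colnames(probs_matrix)
  vapply(genotypes, function(g)
    sample(cats, 1L, prob = probs_matrix[g, ]), character(1))
}

#' Generate a synthetic phenotyped cohort
#'
#' Draws `n` individuals with Hardy-Weinberg genotypes at the L374F
#' locus, genotype-dependent Gaussian skin reflectance, and hair/eye
#' colour categories.  Bit-reproducible under `set.seed`.
#'
#' @param model a [cohort_model()].
#' @param n cohort size (default 500).
#' @return A `cohort_table` data frame with columns `id`, `genotype`
#'   (FF/FL/LL), `f_dose` (derived-allele count 2/1/0), `reflectance`,
#'   `hair`, `eye`.
#' @export
generate_cohort <- function(model, n = 500) {
  g <- sample(geno_levels, n, replace = TRUE,
              prob = hwe_genotype_probs(model$allele_freq))
  refl <- model$reflectance_means[g] +
    stats::rnorm(n, 0, model$reflectance_sd)
  out <- data.frame(
    id = seq_len(n), genotype = g,
    f_dose = c(FF = 2L, FL = 1L, LL = 0L)[g],
    reflectance = as.numeric(refl),
    hair = sample_category(model$hair_probs, g),
    eye = sample_category(model$eye_probs, g))
  class(out) <- c("cohort_table", class(out))
  out
}

#' Reflectance extremes of a cohort
#'
#' Returns the most and least pigmented subsets by rank on reflectance
#' (lower reflectance = darker skin): the `n_dark` lowest and `n_light`
#' highest values, the sampling design used for the resequencing panel
#' (34 + 34 out of 500).
#'
#' @param cohort a [generate_cohort()] table.
#' @param n_dark,n_light subset sizes (default 34 each).
#' @return A list with `dark` and `light` cohort subsets.
#' @export
extreme_groups <- function(cohort, n_dark = 34L, n_light = 34L) {
  ord <- order(cohort$reflectance)
  list(dark = cohort[ord[seq_len(n_dark)], ],
       light = cohort[ord[(nrow(cohort) - n_light + 1L):nrow(cohort)], ])
}

#' Generate a melanoma case-control set
#'
#' Controls are drawn in Hardy-Weinberg proportions at the model's
#' allele frequency; cases follow a multiplicative per-allele odds
#' model: P(genotype | case) is proportional to the control genotype
#' probability times OR^dose.  With OR = 1 cases and controls coincide
#' in expectation.
#'
#' @param model a [cohort_model()].
#' @param n_cases,n_controls sample sizes.
#' @return A `cohort_table` data frame with columns `genotype`,
#'   `f_dose`, `status` ("case"/"control").
#' @export
generate_case_control <- function(model, n_cases, n_controls) {
  q <- hwe_genotype_probs(model$allele_freq)
  w <- q * model$melanoma_or^(2:0)
  gc_ <- sample(geno_levels, n_cases, replace = TRUE, prob = w / sum(w))
  gk <- sample(geno_levels, n_controls, replace = TRUE, prob = q)
  out <- data.frame(
    genotype = c(gc_, gk),
    f_dose = c(FF = 2L, FL = 1L, LL = 0L)[c(gc_, gk)],
    status = rep(c("case", "control"), c(n_cases, n_controls)))
  class(out) <- c("cohort_table", class(out))
  out
}

#' Genotype count table from a cohort
#'
#' @param cohort a `cohort_table` with `genotype` (and optionally
#'   `status`).
#' @param by optional column to split rows by (e.g. "status").
#' @return Matrix of genotype counts ordered FF, FL, LL (derived-allele
#'   dose 2, 1, 0).
#' @export
genotype_counts <- function(cohort, by = NULL) {
  f <- factor(cohort$genotype, levels = geno_levels)
  if (is.null(by)) {
    t(as.matrix(table(f)))
  } else {
    as.matrix(table(cohort[[by]], f))
  }
}

#' Generate per-UV-band allele frequencies
#'
#' Per band, the expected frequency is `clip(intercept + slope * UV)`
#' and the realised one is a binomial draw of `n` chromosomes, giving
#' the allele-frequency cline over the UV gradient.
#'
#' @param model a [cohort_model()] (fields `uv_bands`, `uv_intercept`,
#'   `uv_slope`, `uv_n`), or NULL to pass the pieces directly.
#' @param bands,intercept,slope,n overrides of the model fields.
#' @param noise if `FALSE`, return the expected frequencies without
#'   binomial noise.
#' @return Data frame with `uv`, `freq`, `n`.
#' @export
generate_geo_frequencies <- function(model = cohort_model(),
                                     bands = model$uv_bands,
                                     intercept = model$uv_intercept,
                                     slope = model$uv_slope,
                                     n = model$uv_n, noise = TRUE) {
  mu <- pmin(pmax(intercept + slope * bands, 0), 1)
  freq <- if (noise) stats::rbinom(length(bands), n, mu) / n else mu
  data.frame(uv = bands, freq = freq, n = n)
}
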