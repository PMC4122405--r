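Package: sweepsel
Title: Haplotype-Based Selection Scans, Coalescent Null Models, and
    Sweep Age Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterising recent positive
    selection at a candidate locus from phased haplotype data, built
    around the analysis of the SLC45A2 L374F pigmentation allele in
    South Europeans.  Implements site-frequency-spectrum neutrality
    statistics (Tajima's D, Fu and Li's D, Fay and Wu's H, Zeng's E,
    Ewens-Watterson homozygosity) with Monte-Carlo p-values under an
    Out-of-Africa demographic model, the compound DH/DHEW tests, an
    extended-haplotype-homozygosity (EHH) scan with a
    simulation-matched 95 percent envelope, haplogroup-specific
    Tajima's D with frequency- and S-matched coalescent nulls, and
    maximum-likelihood estimation of the sweep selection coefficient
    and allele age from ancestral-haplotype endpoints.  Includes a
    Hudson-style coalescent simulator with recombination hotspots,
    population growth, migration and timed demographic events, a
    trajectory-conditioned sweep simulator, and generators for
    synthetic cohort data (reflectance, hair/eye colour, melanoma
    case-control, UV-band allele-frequency clines) together with the
    matching association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
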