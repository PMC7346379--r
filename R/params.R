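#' Phasing parameters
#'
#' Bundles every tunable of the long-range phasing (LRP) and haplotype
#' library imputation (HLI) algorithms.  Defaults follow the values used for
#' large multi-array livestock datasets: at most 10 surrogate votes per
#' allele, 10% genotype disagreement allowed between surrogate pairs, an 80%
#' phased threshold for library admission, a 200-allele minimum overlap for
#' haplotype identity, and zero mismatches when clustering near-identical
#' library haplotypes.
#'
#' @param core_length Number of SNPs per core (cores are phased
#'   independently).  About 10% of the chromosome is a good choice.
#' @param subset_size Number of individuals per random phasing subset; LRP
#'   runs within subsets to avoid an all-against-all surrogate search.
#' @param max_surrogates Maximum number of surrogate (chain) votes used per
#'   allele.
#' @param surrogate_disagree_frac Fraction of shared markers allowed to be
#'   opposing homozygotes between a pair of surrogates.
#' @param min_shared_markers Minimum number of markers genotyped in both
#'   individuals before surrogacy is tested (guards against spurious
#'   surrogates under multi-array missingness).
#' @param min_phased_frac_library Minimum fraction of the carrier's
#'   genotyped core SNPs that must be phased before a haplotype is admitted
#'   to the library.
#' @param min_match_alleles Minimum number of co-observed alleles before two
#'   haplotypes can be identified as the same haplotype.
#' @param library_cluster_mismatches Allele mismatches tolerated when
#'   matching/clustering haplotypes (0 = exact on co-observed positions).
#' @param max_surrogate_depth Maximum length of a surrogate-of-surrogate
#'   chain.
#' @param consensus_agreement_frac Minimum vote share the plurality allele
#'   needs before it is accepted; ties resolve to unphased.
#' @param rng_seed Integer seed driving all randomness (subset assignment).
#' @return An object of class `phasing_params`.
#' @export
phasing_params <- function(core_length = 500L,
                           subset_size = 5000L,
                           max_surrogates = 10L,
                           surrogate_disagree_frac = 0.10,
                           min_shared_markers = 100L,
                           min_phased_frac_library = 0.80,
                           min_match_alleles = 200L,
                           library_cluster_mismatches = 0L,
                           max_surrogate_depth = 10L,
                           consensus_agreement_frac = 0.9,
                           rng_seed = 1L) {
  p <- list(core_length = as.integer(core_length),
            subset_size = as.integer(subset_size),
            max_surrogates = as.integer(max_surrogates),
            surrogate_disagree_frac = as.numeric(surrogate_disagree_frac),
            min_shared_markers = as.integer(min_shared_markers),
            min_phased_frac_library = as.numeric(min_phased_frac_library),
            min_match_alleles = as.integer(min_match_alleles),
            library_cluster_mismatches = as.integer(library_cluster_mismatches),
            max_surrogate_depth = as.integer(max_surrogate_depth),
            consensus_agreement_frac = as.numeric(consensus_agreement_frac),
            rng_seed = as.integer(rng_seed))
  fracs <- c("surrogate_disagree_frac", "min_phased_frac_library",
             "consensus_agreement_frac")
  for (f in fracs)
    if (is.na(p[[f]]) || p[[f]] < 0 || p[[f]] > 1)
      stopf("%s must be in [0, 1]", f)
  counts <- c("core_length", "subset_size", "max_surrogates",
              "min_shared_markers", "min_match_alleles",
              "max_surrogate_depth")
  for (f in counts)
    if (is.na(p[[f]]) || p[[f]] < 1L) stopf("%s must be a positive count", f)
  if (p$library_cluster_mismatches < 0L)
    stopf("library_cluster_mismatches must be >= 0")
  structure(p, class = "phasing_params")
}

#' @export
print.phasing_params <- function(x, ...) {
  cat("Phasing parameters:\n")
  for (f in names(x)) cat(sprintf("  %-27s %s\n", f, format(x[[f]])))
  invisible(x)
}
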