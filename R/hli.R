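#' Haplotype library imputation for one core
#'
#' Iterates to a fixed point over all individuals and gametes.  Each pass
#' has two sweeps, both in input order.  In the fill sweep, every partially
#' phased gamete is matched against the core's haplotype library as it
#' stood at the start of the pass; unphased positions are filled with the
#' consensus allele of the matching entries at positions where they
#' unanimously agree (and the fill is consistent with the genotype and the
#' opposite gamete), and the opposite gamete is completed from the
#' genotype.  In the submission sweep, newly extended (or not yet
#' submitted) haplotypes are offered to the library (see
#' [update_library()]), and near-identical entries are then clustered.
#' Passes stop when a sweep phases no new allele and leaves the library
#' unchanged; the phased-allele count is non-decreasing across passes and
#' the loop always terminates.
#'
#' @param gcore Genotype matrix restricted to the core (individuals x core
#'   SNPs, NA missing), rows named by identifier.
#' @param pairs List with `pat`/`mat` matrices over the core (the partial
#'   phase from LRP; alleles 0/1, `NA` unphased).
#' @param library_core Library entries for this core (possibly loaded from a
#'   previous run; may be empty).
#' @param params A [phasing_params()] object.
#' @return List with updated `pairs`, `library_core` and `n_passes`.
#' @export
hli_phase_core <- function(gcore, pairs, library_core, params) {
  n <- nrow(gcore)
  L <- ncol(gcore)
  ids <- rownames(gcore)
  fin <- finish_pair_from_genotype(gcore, pairs$pat, pairs$mat)
  pat <- fin$pat; mat <- fin$mat
  genotyped <- !is.na(gcore)
  codesT <- t(gcore)
  codesT[is.na(codesT)] <- -1L
  storage.mode(codesT) <- "integer"
  lcx <- lcx_from_compact(library_core)
  submitted <- matrix(FALSE, n, 2L)
  hap_version <- matrix(0L, n, 2L)
  rejected_hv <- matrix(-1L, n, 2L) # hap version at last rejected submission
  max_pass <- sum(is.na(pat)) + sum(is.na(mat)) + lcx$n + 2L
  n_passes <- 0L
  repeat {
    n_passes <- n_passes + 1L
    # fill sweep against the library as of the start of the pass
    patT <- t(pat); patT[is.na(patT)] <- -1L
    matT <- t(mat); matT[is.na(matT)] <- -1L
    storage.mode(patT) <- "integer"; storage.mode(matT) <- "integer"
    fl <- cpp_hli_fill(patT, matT, codesT, lcx$haps, lcx$alleles, lcx$known,
                       lcx$n, params$min_match_alleles,
                       params$library_cluster_mismatches)
    new_alleles <- fl$n_filled
    chg <- fl$changed
    if (new_alleles > 0) {
      pat <- t(fl$pat); pat[pat < 0L] <- NA_integer_
      mat <- t(fl$mat); mat[mat < 0L] <- NA_integer_
      rownames(pat) <- rownames(mat) <- ids
      hap_version <- hap_version + chg
    }
    # submission sweep: changed gametes plus those never admitted whose
    # haplotype moved since the last rejection
    lib_changed <- FALSE
    for (i in seq_len(n)) {
      for (gam in 1:2) {
        if (!(chg[i, gam] == 1L ||
              (!submitted[i, gam] &&
                 rejected_hv[i, gam] != hap_version[i, gam]))) next
        h <- if (gam == 1L) pat[i, ] else mat[i, ]
        action <- lcx_update(lcx, hap_to_internal(h), c(ids[i], gam),
                             genotyped[i, ], params)
        if (action == "rejected") {
          rejected_hv[i, gam] <- hap_version[i, gam]
        } else {
          submitted[i, gam] <- TRUE
          lib_changed <- TRUE
        }
      }
    }
    if (lib_changed) lcx_maintain(lcx, params)
    if ((new_alleles == 0 && !lib_changed) || n_passes >= max_pass) break
  }
  list(pairs = list(pat = pat, mat = mat),
       library_core = lcx_to_compact(lcx), n_passes = n_passes)
}
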