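#' Randomly partition individuals into phasing subsets
#'
#' Subsets are disjoint and cover every individual: LRP then runs within
#' each subset, which bounds the quadratic surrogate search.  Membership is
#' random (no relatedness-aware clustering) and each individual belongs to
#' exactly one subset.  All subsets have exactly `subset_size` members
#' except the last, which holds the remainder; a remainder smaller than half
#' a subset is folded into the previous subset.
#'
#' @param ids Character vector of individual identifiers.
#' @param subset_size Target subset size (>= 2).
#' @param rng_seed Integer seed for the random assignment.
#' @return List of character vectors partitioning `ids`.
#' @export
make_subsets <- function(ids, subset_size, rng_seed = 1L) {
  subset_size <- as.integer(subset_size)
  if (is.na(subset_size) || subset_size < 2L)
    stopf("subset_size must be at least 2")
  n <- length(ids)
  perm <- with_seed(rng_seed, sample.int(n))
  shuffled <- ids[perm]
  if (n <= subset_size) return(list(shuffled))
  k <- n %/% subset_size
  r <- n %% subset_size
  sizes <- rep(subset_size, k)
  if (r > 0L) {
    if (r < subset_size / 2) sizes[k] <- sizes[k] + r
    else sizes <- c(sizes, r)
  }
  split(shuffled, rep(seq_along(sizes), sizes))
}

#' Subsetted long-range phasing
#'
#' Runs LRP independently within each random subset of individuals and
#' merges the per-individual results (the disjoint union over subsets).
#' Pedigree links are used only when both individuals fall in the same
#' subset.  Haplotype library imputation is applied afterwards on the merged
#' data (see [phase_genotypes()]); this function returns the merged LRP
#' phase only.
#'
#' @param genotypes Genotype matrix.
#' @param ped A [pedigree()] or `NULL`.
#' @param params A [phasing_params()] object.
#' @param cores Optional core matrix from [partition_cores()]; defaults to
#'   partitioning all SNPs with `params$core_length`.
#' @param subsets Optional precomputed subsets from [make_subsets()].
#' @return List with `pat`/`mat` full-chromosome phase matrices
#'   (individuals x SNPs, rows in input order), `cores`, and `subsets`.
#' @export
phase_by_subsets <- function(genotypes, ped = NULL, params = phasing_params(),
                             cores = NULL, subsets = NULL) {
  ids <- rownames(genotypes)
  n_snps <- ncol(genotypes)
  if (is.null(cores)) cores <- partition_cores(n_snps, params$core_length)
  if (is.null(subsets))
    subsets <- make_subsets(ids, params$subset_size, params$rng_seed)
  pat <- matrix(NA_integer_, nrow(genotypes), n_snps, dimnames =
                  list(ids, NULL))
  mat <- pat
  for (sub in subsets) {
    # members are processed in input order so that results do not depend on
    # the random draw order within a subset (single-subset run == whole-set
    # run, bit for bit)
    idx <- sort(match(sub, ids))
    gsub <- genotypes[idx, , drop = FALSE]
    packed <- pack_genotypes(gsub)
    for (ci in seq_len(nrow(cores))) {
      core <- cores[ci, ]
      graph <- build_surrogate_graph(packed, core, params)
      res <- phase_core_lrp(graph, ped = ped, genotypes = gsub)
      pat[idx, core_cols(core)] <- res$pat
      mat[idx, core_cols(core)] <- res$mat
    }
  }
  list(pat = pat, mat = mat, cores = cores, subsets = subsets)
}
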