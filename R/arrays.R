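#' Build a multi-array genotyping scheme
#'
#' Emulates datasets in which individuals are genotyped on different,
#' partially overlapping SNP arrays.  Presets:
#' \describe{
#'   \item{`"single"`}{one array covering every SNP, all individuals.}
#'   \item{`"two-md"`}{two medium-density arrays of equal size with a given
#'     pairwise overlap (default 60% of an array), individuals assigned
#'     1:1.}
#'   \item{`"three-md"`}{three medium-density arrays with roughly 50-65%
#'     pairwise overlap, individuals assigned 1:1:1.}
#'   \item{`"md-hd"`}{a medium-density array nested inside a high-density
#'     array covering all SNPs, individuals assigned 9:1 (MD:HD).}
#' }
#' The union of the arrays always equals the full SNP set.  A custom scheme
#' can be given as `list(arrays = <list of SNP index vectors>, ratio =
#' <numeric>)`.
#'
#' @param preset Preset name or custom specification list.
#' @param n_snps Total number of SNPs.
#' @param n_ind Number of individuals to assign.
#' @param overlap Pairwise overlap fraction for the two-md preset
#'   (fraction of one array's SNPs shared with the other).
#' @param md_frac Fraction of SNPs on the medium-density array of the
#'   md-hd preset (default the 6711/49,579 bovine MD:HD ratio).
#' @param rng_seed Integer seed for SNP sampling and assignment.
#' @return An object of class `array_scheme`: `arrays` (list of sorted
#'   1-based SNP index vectors), `assignment` (array index per individual),
#'   `preset`.
#' @export
build_array_scheme <- function(preset, n_snps, n_ind, overlap = 0.6,
                               md_frac = 6711 / 49579, rng_seed = 1L) {
  n_snps <- as.integer(n_snps); n_ind <- as.integer(n_ind)
  with_seed(rng_seed, {
    if (is.list(preset)) {
      arrays <- lapply(preset$arrays, function(a) sort(as.integer(a)))
      ratio <- preset$ratio %||% rep(1, length(arrays))
      name <- preset$name %||% "custom"
      cov <- sort(unique(unlist(arrays)))
      if (!identical(cov, seq_len(n_snps)))
        stopf("custom arrays must jointly cover all %d SNPs", n_snps)
    } else if (preset == "single") {
      arrays <- list(seq_len(n_snps)); ratio <- 1; name <- preset
    } else if (preset == "two-md") {
      if (overlap <= 0 || overlap >= 1) stopf("overlap must be in (0, 1)")
      s <- round(n_snps / (2 - overlap))
      o <- 2L * as.integer(s) - n_snps
      if (o < 1L || o >= n_snps)
        stopf("infeasible overlap %.2f for %d SNPs", overlap, n_snps)
      perm <- sample.int(n_snps)
      shared <- perm[seq_len(o)]
      rest <- perm[-seq_len(o)]
      half <- length(rest) %/% 2L
      arrays <- list(sort(c(shared, rest[seq_len(half)])),
                     sort(c(shared, rest[(half + 1L):length(rest)])))
      ratio <- c(1, 1); name <- preset
    } else if (preset == "three-md") {
      pats <- list(c(1L, 2L, 3L), c(1L, 2L), c(1L, 3L), c(2L, 3L), 1L, 2L, 3L)
      w <- c(0.30, 0.10, 0.10, 0.10, 0.40 / 3, 0.40 / 3, 0.40 / 3)
      draw <- sample.int(length(pats), n_snps, replace = TRUE, prob = w)
      arrays <- lapply(1:3, function(a)
        sort(which(vapply(draw, function(d) a %in% pats[[d]], logical(1L)))))
      # guarantee full coverage (sampling already covers every SNP)
      ratio <- c(1, 1, 1); name <- preset
    } else if (preset == "md-hd") {
      md <- sort(sample.int(n_snps, max(1L, round(md_frac * n_snps))))
      arrays <- list(md, seq_len(n_snps))
      ratio <- c(9, 1); name <- preset
    } else {
      stopf("unknown array preset '%s'", preset)
    }
    counts <- diff(round(cumsum(c(0, ratio)) / sum(ratio) * n_ind))
    assignment <- sample(rep.int(seq_along(arrays), counts))
    structure(list(arrays = arrays, assignment = as.integer(assignment),
                   preset = name),
              class = "array_scheme")
  })
}

#' @export
print.array_scheme <- function(x, ...) {
  cat(sprintf("Array scheme '%s': %d arrays (%s SNPs), %d individuals\n",
              x$preset, length(x$arrays),
              paste(lengths(x$arrays), collapse = "/"),
              length(x$assignment)))
  invisible(x)
}

#' Mask true genotypes according to an array scheme
#'
#' The observed genotype is the allele sum of the two true haplotypes at
#' SNPs on the individual's array, and missing elsewhere.
#'
#' @param pop A `true_population`.
#' @param scheme An `array_scheme` whose assignment covers the population.
#' @return Genotype matrix with `NA` at off-array SNPs.
#' @export
mask_genotypes <- function(pop, scheme) {
  n_ind <- length(pop$ids)
  if (length(scheme$assignment) != n_ind)
    stopf("array assignment covers %d individuals but population has %d",
          length(scheme$assignment), n_ind)
  g <- pop$hap1 + pop$hap2
  n_snps <- ncol(g)
  off <- lapply(scheme$arrays, function(a) setdiff(seq_len(n_snps), a))
  for (a in seq_along(scheme$arrays)) {
    rows <- which(scheme$assignment == a)
    if (length(rows) && length(off[[a]])) g[rows, off[[a]]] <- NA_integer_
  }
  genotype_matrix(g, pop$ids)
}
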