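#' Bit-pack a genotype matrix
#'
#' Genotypes are stored as three disjoint bit planes per individual —
#' homozygous reference (code 0), homozygous alternate (code 2) and missing
#' — so that pairwise marker comparisons reduce to bitwise AND/OR plus a
#' population count over whole blocks of SNPs.  Heterozygotes are implied by
#' no plane being set.
#'
#' @param genotypes Genotype matrix (see [genotype_matrix()]).
#' @param block_bits SNPs per bit block (internal width, 1-32; the value
#'   never affects any result).
#' @return An object of class `packed_genotypes`.
#' @export
pack_genotypes <- function(genotypes, block_bits = 32L) {
  block_bits <- as.integer(block_bits)
  planes <- cpp_pack(genotypes, block_bits)
  structure(list(ids = rownames(genotypes),
                 n_snps = ncol(genotypes),
                 block_bits = block_bits,
                 hom_ref = planes$hom_ref,
                 hom_alt = planes$hom_alt,
                 miss = planes$miss),
            class = "packed_genotypes")
}

#' Unpack bit-packed genotypes
#' @param packed A `packed_genotypes` object.
#' @return The original genotype matrix.
#' @export
unpack_genotypes <- function(packed) {
  codes <- cpp_unpack(packed$hom_ref, packed$hom_alt, packed$miss,
                      packed$n_snps, packed$block_bits)
  genotype_matrix(codes, packed$ids)
}

#' @export
print.packed_genotypes <- function(x, ...) {
  cat(sprintf("Bit-packed genotypes: %d individuals x %d SNPs (%d-bit blocks)\n",
              length(x$ids), x$n_snps, x$block_bits))
  invisible(x)
}

# column subset of a packed object (individuals), keeping packing
packed_subset <- function(packed, idx) {
  structure(list(ids = packed$ids[idx],
                 n_snps = packed$n_snps,
                 block_bits = packed$block_bits,
                 hom_ref = packed$hom_ref[, idx, drop = FALSE],
                 hom_alt = packed$hom_alt[, idx, drop = FALSE],
                 miss = packed$miss[, idx, drop = FALSE]),
            class = "packed_genotypes")
}

#' Opposing-homozygote and shared-marker counts for a pair
#'
#' Counts, within a core, the SNPs where one individual is homozygous
#' reference and the other homozygous alternate (opposing homozygotes —
#' proof the pair shares no haplotype spanning that SNP), and the SNPs where
#' both genotypes are observed (shared markers).  Computed on the packed
#' planes with population counts.
#'
#' @param packed A `packed_genotypes` object.
#' @param i,j Individual identifiers or row indices.
#' @param core A core as `c(start, end)`, 0-based half-open; default the
#'   whole SNP range.
#' @return Named integer vector `c(n_opposing, n_shared)`.
#' @export
opposing_and_shared <- function(packed, i, j, core = c(0L, packed$n_snps)) {
  if (is.character(i)) i <- match(i, packed$ids)
  if (is.character(j)) j <- match(j, packed$ids)
  res <- cpp_pair_counts(packed$hom_ref, packed$hom_alt, packed$miss,
                         as.integer(i) - 1L, as.integer(j) - 1L,
                         as.integer(core[1L]), as.integer(core[2L]),
                         packed$block_bits, packed$n_snps)
  c(n_opposing = res[1L], n_shared = res[2L])
}

#' Complete the second haplotype from genotype and first haplotype
#'
#' At homozygous SNPs the complement equals genotype/2; at heterozygous SNPs
#' it is the opposite of the known allele; it is missing where the genotype
#' is missing or the known allele is missing at a heterozygous SNP.  A
#' homozygous genotype that contradicts the known allele is a conflict: by
#' default the position is blanked to missing (tolerance to genotyping
#' error) and reported via the `conflicts` attribute; `on_conflict =
#' "error"` aborts instead.
#'
#' @param genotype Integer vector of genotype codes (NA = missing).
#' @param hap Integer vector of alleles 0/1 (NA = missing), same length.
#' @param on_conflict `"blank"` (default) or `"error"`.
#' @return Allele vector of the complementary haplotype, with an integer
#'   attribute `conflicts` (1-based positions).
#' @export
complement_from_genotype <- function(genotype, hap,
                                     on_conflict = c("blank", "error")) {
  on_conflict <- match.arg(on_conflict)
  if (length(genotype) != length(hap))
    stopf("genotype and haplotype lengths differ (%d vs %d)",
          length(genotype), length(hap))
  conflicts <- which(!is.na(genotype) & genotype != 1L & !is.na(hap) &
                       hap != genotype %/% 2L)
  if (length(conflicts) && on_conflict == "error")
    stopf("haplotype conflicts with homozygous genotype at position(s) %s",
          paste(utils::head(conflicts, 10L), collapse = ", "))
  out <- rep(NA_integer_, length(genotype))
  hom <- !is.na(genotype) & genotype != 1L
  out[hom] <- genotype[hom] %/% 2L
  het <- !is.na(genotype) & genotype == 1L & !is.na(hap)
  out[het] <- 1L - hap[het]
  out[conflicts] <- NA_integer_
  attr(out, "conflicts") <- conflicts
  out
}

#' Partition SNPs into cores
#'
#' Cores are consecutive half-open SNP intervals of `core_length` SNPs that
#' tile the chromosome; a terminal remainder shorter than half a core is
#' absorbed into the final core, otherwise it stands as its own core.
#'
#' @param n_snps Total number of SNPs.
#' @param core_length SNPs per core.
#' @return Integer matrix with columns `start`, `end` (0-based half-open).
#' @export
partition_cores <- function(n_snps, core_length) {
  n_snps <- as.integer(n_snps); core_length <- as.integer(core_length)
  if (is.na(core_length) || core_length < 1L)
    stopf("core_length must be a positive count")
  if (n_snps < 1L) stopf("n_snps must be positive")
  if (core_length > n_snps)
    stopf("core_length (%d) exceeds the number of SNPs (%d)", core_length,
          n_snps)
  k <- n_snps %/% core_length
  r <- n_snps %% core_length
  starts <- (0:(k - 1L)) * core_length
  if (r > 0L && r >= core_length / 2) starts <- c(starts, k * core_length)
  ends <- c(starts[-1L], n_snps)
  cbind(start = as.integer(starts), end = as.integer(ends))
}

# 1-based R column indices of a core
core_cols <- function(core) (core[1L] + 1L):core[2L]
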