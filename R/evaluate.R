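#' Phasing accuracy against simulated truth
#'
#' For each individual and core, both assignments of the inferred haplotype
#' pair to the true pair are evaluated and the better one kept (cores are
#' phased independently, so no cross-core gamete identity is claimed).  An
#' allele is correct when non-missing and equal to truth under that
#' assignment, incorrect when non-missing and unequal, and unphased when
#' missing.  The three percentages sum to 100.
#'
#' @param inferred List with `pat`/`mat` matrices (individuals x SNPs) and a
#'   `cores` matrix, as returned by the phasing functions; or a
#'   `haplophase_fit`.
#' @param truth A `true_population` covering the same individuals and SNPs.
#' @param genotypes Genotype matrix (defines which SNPs each individual was
#'   genotyped at); required when `snp_scope = "genotyped"`.
#' @param scope `"heterozygous"` (default; SNPs where the true genotype is
#'   1, the only sites where phasing is informative) or `"all"`.
#' @param snp_scope `"all"` (default: score every SNP, including off-array
#'   SNPs imputed through the library) or `"genotyped"`.
#' @param individuals Optional identifiers restricting the evaluation (e.g.
#'   one breed or one generation).
#' @return An object of class `phasing_stats` with `percent_correct`,
#'   `percent_unphased`, `percent_incorrect` and the underlying counts.
#' @export
phasing_statistics <- function(inferred, truth, genotypes = NULL,
                               scope = c("heterozygous", "all"),
                               snp_scope = c("all", "genotyped"),
                               individuals = NULL) {
  scope <- match.arg(scope)
  snp_scope <- match.arg(snp_scope)
  pat <- inferred$pat
  mat <- inferred$mat
  cores <- inferred$cores
  ids <- rownames(pat)
  t_idx <- match(ids, truth$ids)
  if (anyNA(t_idx)) stopf("inferred individuals missing from truth")
  T1 <- truth$hap1[t_idx, , drop = FALSE]
  T2 <- truth$hap2[t_idx, , drop = FALSE]
  if (!identical(dim(pat), dim(T1)))
    stopf("inferred (%d x %d) and truth (%d x %d) dimensions differ",
          nrow(pat), ncol(pat), nrow(T1), ncol(T1))
  keep <- if (is.null(individuals)) seq_along(ids)
          else which(ids %in% individuals)
  if (!length(keep)) stopf("no individuals to evaluate")
  in_scope <- matrix(TRUE, length(keep), ncol(pat))
  if (scope == "heterozygous")
    in_scope <- (T1[keep, , drop = FALSE] + T2[keep, , drop = FALSE]) == 1L
  if (snp_scope == "genotyped") {
    if (is.null(genotypes)) stopf("genotypes required for snp_scope='genotyped'")
    in_scope <- in_scope & !is.na(genotypes[ids[keep], , drop = FALSE])
  }
  n_correct <- n_incorrect <- n_unphased <- 0
  for (ci in seq_len(nrow(cores))) {
    cc <- core_cols(cores[ci, ])
    A <- pat[keep, cc, drop = FALSE]; B <- mat[keep, cc, drop = FALSE]
    U <- T1[keep, cc, drop = FALSE]; V <- T2[keep, cc, drop = FALSE]
    sc <- in_scope[, cc, drop = FALSE]
    cA <- !is.na(A) & sc; cB <- !is.na(B) & sc
    corr1 <- rowSums(cA & A == U, na.rm = TRUE) +
      rowSums(cB & B == V, na.rm = TRUE)
    corr2 <- rowSums(cA & A == V, na.rm = TRUE) +
      rowSums(cB & B == U, na.rm = TRUE)
    corr <- pmax(corr1, corr2)
    nonmiss <- rowSums(cA) + rowSums(cB)
    n_correct <- n_correct + sum(corr)
    n_incorrect <- n_incorrect + sum(nonmiss - corr)
    n_unphased <- n_unphased + sum(2L * rowSums(sc) - nonmiss)
  }
  total <- n_correct + n_incorrect + n_unphased
  pct <- function(x) if (total == 0) 0 else 100 * x / total
  structure(list(scope = scope, snp_scope = snp_scope,
                 percent_correct = pct(n_correct),
                 percent_unphased = pct(n_unphased),
                 percent_incorrect = pct(n_incorrect),
                 n_correct = n_correct, n_incorrect = n_incorrect,
                 n_unphased = n_unphased, n_total = total),
            class = "phasing_stats")
}

#' @export
print.phasing_stats <- function(x, ...) {
  cat(sprintf("Phasing accuracy (%s loci, %s SNPs):\n", x$scope, x$snp_scope))
  cat(sprintf("  correct   %6.2f%%\n  unphased  %6.2f%%\n  incorrect %6.2f%%\n",
              x$percent_correct, x$percent_unphased, x$percent_incorrect))
  invisible(x)
}

#' Average phasing statistics across groups
#'
#' Unweighted mean of the percentages across groups (e.g. across breeds or
#' across generations); counts are summed for reference.
#'
#' @param stats_list Non-empty list of `phasing_stats` with identical
#'   scopes.
#' @return A `phasing_stats` object.
#' @export
aggregate_stats <- function(stats_list) {
  if (!length(stats_list)) stopf("empty statistics list")
  scopes <- vapply(stats_list, function(s) paste(s$scope, s$snp_scope),
                   character(1L))
  if (length(unique(scopes)) != 1L)
    stopf("cannot aggregate statistics with mixed scopes")
  m <- function(f) mean(vapply(stats_list, `[[`, numeric(1L), f))
  s <- function(f) sum(vapply(stats_list, `[[`, numeric(1L), f))
  structure(list(scope = stats_list[[1L]]$scope,
                 snp_scope = stats_list[[1L]]$snp_scope,
                 percent_correct = m("percent_correct"),
                 percent_unphased = m("percent_unphased"),
                 percent_incorrect = m("percent_incorrect"),
                 n_correct = s("n_correct"), n_incorrect = s("n_incorrect"),
                 n_unphased = s("n_unphased"), n_total = s("n_total")),
            class = "phasing_stats")
}

#' Concatenate per-core phase results into a whole-chromosome phase
#'
#' Cores can be phased in separate processes; their outputs are stitched
#' back in core order and are byte-identical to a single run with the same
#' seed and parameters.
#'
#' @param core_results List of per-core results, each a list with `core`
#'   (`c(start, end)`), `pat` and `mat` matrices over the core's SNPs; any
#'   order.
#' @param n_snps Total number of SNPs the cores must tile.
#' @return List with full `pat`/`mat` matrices and the `cores` matrix.
#' @export
concat_core_results <- function(core_results, n_snps) {
  if (!length(core_results)) stopf("no core results supplied")
  starts <- vapply(core_results, function(x) as.integer(x$core[1L]),
                   integer(1L))
  ends <- vapply(core_results, function(x) as.integer(x$core[2L]),
                 integer(1L))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; core_results <- core_results[o]
  if (starts[1L] != 0L)
    stopf("missing core output covering SNPs [0, %d)", starts[1L])
  for (k in seq_along(starts)[-1L]) {
    if (starts[k] > ends[k - 1L])
      stopf("missing core output covering SNPs [%d, %d)", ends[k - 1L],
            starts[k])
    if (starts[k] < ends[k - 1L])
      stopf("overlapping core outputs at SNP %d", starts[k])
  }
  if (ends[length(ends)] != n_snps)
    stopf("missing core output covering SNPs [%d, %d)", ends[length(ends)],
          n_snps)
  ids <- rownames(core_results[[1L]]$pat)
  pat <- do.call(cbind, lapply(core_results, `[[`, "pat"))
  mat <- do.call(cbind, lapply(core_results, `[[`, "mat"))
  rownames(pat) <- rownames(mat) <- ids
  list(pat = pat, mat = mat, cores = cbind(start = starts, end = ends))
}
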