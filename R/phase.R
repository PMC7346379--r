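#' Phase genotypes by subsetted long-range phasing and haplotype library
#' imputation
#'
#' The main entry point.  The chromosome is split into cores of consecutive
#' SNPs, phased independently.  Within each core, individuals are phased by
#' long-range phasing (LRP) inside random subsets — surrogate parents are
#' detected by the absence of opposing homozygotes over shared markers, and
#' alleles are set by consensus of homozygous surrogates, recursively
#' through surrogates of surrogates — and the merged partial haplotypes are
#' completed by haplotype library imputation (HLI), which matches partial
#' haplotypes (possibly observed on different SNP arrays) against a shared
#' library of possibly partial haplotypes, iterated to a fixed point.  A
#' library from a previous run can seed the process.
#'
#' @param genotypes Genotype matrix (see [genotype_matrix()] /
#'   [read_genotypes()]).
#' @param ped Optional [pedigree()]; orients paternal/maternal sides.
#' @param params A [phasing_params()] object.
#' @param library Optional `haplotype_library` from a previous run
#'   ([load_library()]); entries seed HLI from the first pass.
#' @param core_index Optional integer vector of core indices (1-based) to
#'   phase; other SNPs stay unphased in the result.  Per-core runs can be
#'   recombined with [concat_core_results()] and are identical to a single
#'   run.
#' @param verbose Print per-core progress.
#' @return An object of class `haplophase_fit`: phase matrices `pat`/`mat`
#'   (individuals x SNPs; `NA` = unphased), the updated `library`, `cores`,
#'   `subsets`, `params` and per-core `core_results`.
#' @seealso [phasing_statistics()], [write_phase()], [save_library()]
#' @export
phase_genotypes <- function(genotypes, ped = NULL, params = phasing_params(),
                            library = NULL, core_index = NULL,
                            verbose = FALSE) {
  ids <- rownames(genotypes)
  n_snps <- ncol(genotypes)
  cores <- partition_cores(n_snps, params$core_length)
  which_cores <- seq_len(nrow(cores))
  if (!is.null(core_index)) {
    core_index <- as.integer(core_index)
    if (any(core_index < 1L | core_index > nrow(cores)))
      stopf("core_index out of range 1..%d", nrow(cores))
    which_cores <- sort(unique(core_index))
  }
  subsets <- make_subsets(ids, min(params$subset_size, length(ids)),
                          params$rng_seed)
  if (!is.null(library) && !inherits(library, "haplotype_library"))
    stopf("library must be a haplotype_library")
  out_lib <- haplotype_library(cores)
  pat <- matrix(NA_integer_, length(ids), n_snps, dimnames = list(ids, NULL))
  mat <- pat
  core_results <- vector("list", length(which_cores))
  for (k in seq_along(which_cores)) {
    ci <- which_cores[k]
    core <- cores[ci, ]
    cc <- core_cols(core)
    L <- length(cc)
    if (verbose)
      message(sprintf("core %d/%d [%d, %d)", ci, nrow(cores), core[1L],
                      core[2L]))
    cpat <- matrix(NA_integer_, length(ids), L, dimnames = list(ids, NULL))
    cmat <- cpat
    for (sub in subsets) {
      idx <- sort(match(sub, ids))
      gsub <- genotypes[idx, , drop = FALSE]
      packed <- pack_genotypes(gsub)
      graph <- build_surrogate_graph(packed, core, params)
      res <- phase_core_lrp(graph, ped = ped, genotypes = gsub)
      cpat[idx, ] <- res$pat
      cmat[idx, ] <- res$mat
    }
    lib_core <- seed_library_core(library, ci, L)
    gcore <- genotypes[, cc, drop = FALSE]
    hli <- hli_phase_core(gcore, list(pat = cpat, mat = cmat), lib_core,
                          params)
    pat[, cc] <- hli$pairs$pat
    mat[, cc] <- hli$pairs$mat
    out_lib$entries[[ci]] <- hli$library_core
    core_results[[k]] <- list(core = core, pat = hli$pairs$pat,
                              mat = hli$pairs$mat, n_passes = hli$n_passes)
  }
  structure(list(ids = ids, pat = pat, mat = mat, cores = cores,
                 core_index = which_cores, core_results = core_results,
                 library = out_lib, subsets = subsets, params = params,
                 n_snps = n_snps,
                 genotyped = !is.na(genotypes),
                 call = match.call()),
            class = "haplophase_fit")
}

# pick the prior-library entries for core ci, checking length compatibility
seed_library_core <- function(library, ci, core_length) {
  if (is.null(library) || ci > length(library$entries) ||
      is.null(library$entries[[ci]]))
    return(empty_library_core(core_length))
  lc <- library$entries[[ci]]
  if (ncol(lc$haps) && nrow(lc$haps) != core_length)
    stopf("prior library core %d has length %d but the core has %d SNPs",
          ci - 1L, nrow(lc$haps), core_length)
  if (!ncol(lc$haps)) return(empty_library_core(core_length))
  lc
}

#' @export
print.haplophase_fit <- function(x, ...) {
  ph <- mean(!is.na(x$pat[, unlist(lapply(x$core_index, function(ci)
    core_cols(x$cores[ci, ])))])) * 100
  cat(sprintf("Phased %d individuals x %d SNPs (%d of %d cores)\n",
              length(x$ids), x$n_snps, length(x$core_index), nrow(x$cores)))
  cat(sprintf("  subset size %d (%d subsets), core length %d\n",
              x$params$subset_size, length(x$subsets),
              x$params$core_length))
  cat(sprintf("  %.1f%% of alleles phased in the processed cores\n", ph))
  invisible(x)
}

#' @export
summary.haplophase_fit <- function(object, ...) {
  cc <- unlist(lapply(object$core_index, function(ci)
    core_cols(object$cores[ci, ])))
  phased <- !is.na(object$pat[, cc, drop = FALSE]) &
    !is.na(object$mat[, cc, drop = FALSE])
  ne <- vapply(object$library$entries, function(e)
    if (is.null(e)) 0L else ncol(e$haps), integer(1L))
  res <- list(n_individuals = length(object$ids), n_snps = object$n_snps,
              n_cores = nrow(object$cores),
              cores_run = length(object$core_index),
              frac_fully_phased = mean(phased),
              library_entries = sum(ne),
              params = object$params)
  class(res) <- "summary.haplophase_fit"
  res
}

#' @export
print.summary.haplophase_fit <- function(x, ...) {
  cat(sprintf("Haplotype phasing of %d individuals x %d SNPs\n",
              x$n_individuals, x$n_snps))
  cat(sprintf("  cores run: %d of %d\n", x$cores_run, x$n_cores))
  cat(sprintf("  allele slots phased (both gametes): %.2f%%\n",
              100 * x$frac_fully_phased))
  cat(sprintf("  haplotype library entries: %d\n", x$library_entries))
  invisible(x)
}

#' @export
plot.haplophase_fit <- function(x, ...) {
  cc <- sort(unlist(lapply(x$core_index, function(ci)
    core_cols(x$cores[ci, ]))))
  frac <- colMeans(!is.na(x$pat[, cc, drop = FALSE]))
  graphics::plot(cc, frac, type = "l", xlab = "SNP index",
                 ylab = "fraction of individuals phased",
                 main = "Phased fraction along the chromosome",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$cores[, "start"] + 0.5, lty = 3, col = "grey")
  invisible(x)
}

#' Run the full simulate-phase-evaluate pipeline
#'
#' Thin orchestration over the package functions, driven by a configuration
#' list, writing phase, library and statistics files.  Fields:
#' \describe{
#'   \item{`genotype_file`, `pedigree_file`}{input files (alternatively
#'     `simulate`).}
#'   \item{`simulate`}{a [sim_params()] object: simulate a population and
#'     phase its masked genotypes instead of reading files.}
#'   \item{`array_preset`}{array scheme preset for the simulated data
#'     (default `"single"`).}
#'   \item{`params`}{a [phasing_params()] object.}
#'   \item{`library_in`}{optional path of a prior haplotype library.}
#'   \item{`core_index`}{optional cores to run (see [phase_genotypes()]).}
#'   \item{`evaluate`}{logical: compute accuracy statistics (needs
#'     `simulate` truth); aggregated per breed and per generation.}
#'   \item{`out_dir`}{output directory.}
#' }
#'
#' @param config Configuration list.
#' @return List with the fit and (when evaluated) the statistics table,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% "."
  params <- config$params %||% phasing_params()
  if (!inherits(params, "phasing_params"))
    stopf("config$params must be a phasing_params object")
  truth <- NULL
  if (!is.null(config$simulate)) {
    sp <- config$simulate
    if (!inherits(sp, "sim_params"))
      stopf("config$simulate must be a sim_params object")
    truth <- simulate_population(sp)
    scheme <- build_array_scheme(config$array_preset %||% "single",
                                 ncol(truth$hap1), length(truth$ids),
                                 rng_seed = sp$rng_seed)
    genotypes <- mask_genotypes(truth, scheme)
    ped <- truth$pedigree
  } else {
    if (is.null(config$genotype_file))
      stopf("config needs either 'simulate' or 'genotype_file'")
    genotypes <- read_genotypes(config$genotype_file)
    ped <- if (!is.null(config$pedigree_file))
      read_pedigree(config$pedigree_file) else NULL
  }
  if (params$core_length > ncol(genotypes))
    stopf("core_length (%d) exceeds the number of SNPs (%d)",
          params$core_length, ncol(genotypes))
  library <- if (!is.null(config$library_in)) load_library(config$library_in)
             else NULL
  fit <- phase_genotypes(genotypes, ped = ped, params = params,
                         library = library, core_index = config$core_index,
                         verbose = isTRUE(config$verbose))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_phase(fit$pat, fit$mat, file.path(out_dir, "phase.txt"))
  save_library(fit$library, file.path(out_dir, "library.txt"))
  stats_tab <- NULL
  if (isTRUE(config$evaluate)) {
    if (is.null(truth)) stopf("evaluation requires simulated truth")
    stats_tab <- stats_table(fit, truth, genotypes)
    utils::write.table(stats_tab, file.path(out_dir, "stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(fit = fit, stats = stats_tab, truth = truth,
                 genotypes = genotypes))
}

# accuracy table: overall plus per-breed and per-generation averages,
# all-loci and heterozygous-loci scopes side by side
stats_table <- function(fit, truth, genotypes) {
  inf <- list(pat = fit$pat, mat = fit$mat,
              cores = fit$cores[fit$core_index, , drop = FALSE])
  row_of <- function(label, inds) {
    a <- phasing_statistics(inf, truth, genotypes, scope = "all",
                            individuals = inds)
    h <- phasing_statistics(inf, truth, genotypes, scope = "heterozygous",
                            individuals = inds)
    data.frame(scenario = label,
               all_correct = a$percent_correct,
               all_unphased = a$percent_unphased,
               all_incorrect = a$percent_incorrect,
               het_correct = h$percent_correct,
               het_unphased = h$percent_unphased,
               het_incorrect = h$percent_incorrect)
  }
  rows <- list(row_of("overall", NULL))
  agg_over <- function(label, groups) {
    per <- lapply(groups, function(g) {
      h <- phasing_statistics(inf, truth, genotypes, scope = "heterozygous",
                              individuals = g)
      a <- phasing_statistics(inf, truth, genotypes, scope = "all",
                              individuals = g)
      list(a = a, h = h)
    })
    a <- aggregate_stats(lapply(per, `[[`, "a"))
    h <- aggregate_stats(lapply(per, `[[`, "h"))
    data.frame(scenario = label,
               all_correct = a$percent_correct,
               all_unphased = a$percent_unphased,
               all_incorrect = a$percent_incorrect,
               het_correct = h$percent_correct,
               het_unphased = h$percent_unphased,
               het_incorrect = h$percent_incorrect)
  }
  breeds <- split(truth$ids, truth$breed)
  gens <- split(truth$ids, truth$generation)
  if (length(breeds) > 1L)
    rows[[length(rows) + 1L]] <- agg_over("mean_per_breed", breeds)
  if (length(gens) > 1L)
    rows[[length(rows) + 1L]] <- agg_over("mean_per_generation", gens)
  do.call(rbind, rows)
}
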