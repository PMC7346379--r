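# minimal truth container for statistics tests
mini_truth <- function(h1, h2, ids = rownames(h1)) {
  rownames(h1) <- rownames(h2) <- ids
  structure(list(ids = ids, hap1 = h1, hap2 = h2),
            class = "true_population")
}

test_that("perfect and globally swapped phases both score 100% correct", {
  set.seed(1)
  n <- 6L; L <- 40L
  h1 <- matrix(rbinom(n * L, 1L, 0.5), n)
  h2 <- matrix(rbinom(n * L, 1L, 0.5), n)
  ids <- sprintf("I%d", 1:n)
  truth <- mini_truth(h1, h2, ids)
  cores <- partition_cores(L, 20L)
  inf <- list(pat = truth$hap1, mat = truth$hap2, cores = cores)
  s <- phasing_statistics(inf, truth, scope = "all")
  expect_equal(s$percent_correct, 100)
  expect_equal(s$percent_incorrect, 0)
  expect_equal(s$percent_unphased, 0)
  # swapped orientation scores identically
  inf2 <- list(pat = truth$hap2, mat = truth$hap1, cores = cores)
  s2 <- phasing_statistics(inf2, truth, scope = "all")
  expect_equal(s2$percent_correct, 100)
  # heterozygous scope restricts to true-genotype-1 sites only
  sh <- phasing_statistics(inf, truth, scope = "heterozygous")
  expect_equal(sh$n_total, 2L * sum(h1 + h2 == 1L))
})

test_that("random partial inferences equal the recount oracle", {
  set.seed(2)
  for (rep in 1:25) {
    n <- 10L; L <- 60L
    h1 <- matrix(rbinom(n * L, 1L, 0.5), n)
    h2 <- matrix(rbinom(n * L, 1L, 0.5), n)
    ids <- sprintf("I%d", 1:n)
    truth <- mini_truth(h1, h2, ids)
    pat <- matrix(sample(c(0L, 1L, NA), n * L, TRUE), n,
                  dimnames = list(ids, NULL))
    mat <- matrix(sample(c(0L, 1L, NA), n * L, TRUE), n,
                  dimnames = list(ids, NULL))
    cores <- partition_cores(L, 60L) # one core: matches the oracle's scope
    inf <- list(pat = pat, mat = mat, cores = cores)
    for (sc in c("heterozygous", "all")) {
      s <- phasing_statistics(inf, truth, scope = sc)
      o <- oracle_phase_accuracy(pat, mat, truth,
                                 scope_het = sc == "heterozygous")
      expect_equal(s$percent_correct, o[["correct"]])
      expect_equal(s$percent_unphased, o[["unphased"]])
      expect_equal(s$percent_incorrect, o[["incorrect"]])
      expect_equal(s$percent_correct + s$percent_unphased +
                     s$percent_incorrect, 100, tolerance = 1e-9)
    }
  }
})

test_that("genotyped-only scope drops off-array SNPs from scoring", {
  set.seed(3)
  n <- 4L; L <- 30L
  h1 <- matrix(rbinom(n * L, 1L, 0.5), n)
  h2 <- matrix(rbinom(n * L, 1L, 0.5), n)
  ids <- sprintf("I%d", 1:n)
  truth <- mini_truth(h1, h2, ids)
  g <- genotype_matrix(h1 + h2, ids)
  g[, 1:10] <- NA # nobody genotyped on the first 10 SNPs
  inf <- list(pat = truth$hap1, mat = truth$hap2,
              cores = partition_cores(L, L))
  s_all <- phasing_statistics(inf, truth, g, scope = "all",
                              snp_scope = "all")
  s_gt <- phasing_statistics(inf, truth, g, scope = "all",
                             snp_scope = "genotyped")
  expect_equal(s_all$n_total, 2 * n * L)
  expect_equal(s_gt$n_total, 2 * n * (L - 10L))
})

test_that("aggregate_stats averages percentages unweighted", {
  s1 <- structure(list(scope = "heterozygous", snp_scope = "all",
                       percent_correct = 100, percent_unphased = 0,
                       percent_incorrect = 0, n_correct = 10L,
                       n_incorrect = 0L, n_unphased = 0L, n_total = 10L),
                  class = "phasing_stats")
  s2 <- s1
  s2$percent_correct <- 90; s2$percent_unphased <- 10
  s2$n_correct <- 90L; s2$n_unphased <- 10L; s2$n_total <- 100L
  agg <- aggregate_stats(list(s1, s2))
  expect_equal(agg$percent_correct, 95)
  expect_equal(agg$percent_unphased, 5)
  expect_equal(agg$n_total, 110)
  expect_identical(aggregate_stats(list(s1, s1, s1))$percent_correct, 100)
  s3 <- s1
  s3$scope <- "all"
  expect_error(aggregate_stats(list(s1, s3)), "mixed scopes")
  expect_error(aggregate_stats(list()), "empty")
  # aggregate of k random stats equals the arithmetic-mean oracle
  set.seed(4)
  k <- 7L
  stats <- lapply(1:k, function(i) {
    x <- s1
    p <- as.vector(stats::rmultinom(1L, 100L, c(1, 1, 1))) # sums to 100
    x$percent_correct <- p[1L]; x$percent_unphased <- p[2L]
    x$percent_incorrect <- p[3L]
    x
  })
  agg <- aggregate_stats(stats)
  expect_equal(agg$percent_correct,
               mean(vapply(stats, `[[`, numeric(1L), "percent_correct")))
})

test_that("per-core runs concatenate to the single-run result exactly", {
  pop <- bred_population(12, 20, 1, 90, 5, seed = 21L)
  params <- phasing_params(core_length = 30L, subset_size = 20L,
                           min_shared_markers = 10L, min_match_alleles = 15L,
                           rng_seed = 4L)
  whole <- phase_genotypes(pop$genotypes, pop$pedigree, params)
  parts <- lapply(1:3, function(ci)
    phase_genotypes(pop$genotypes, pop$pedigree, params, core_index = ci))
  cat_res <- concat_core_results(
    lapply(parts, function(p) p$core_results[[1L]]), n_snps = 90L)
  expect_identical(cat_res$pat, whole$pat)
  expect_identical(cat_res$mat, whole$mat)
  # shuffled order gives the identical result
  cat_res2 <- concat_core_results(
    lapply(parts[c(2L, 3L, 1L)], function(p) p$core_results[[1L]]),
    n_snps = 90L)
  expect_identical(cat_res2$pat, whole$pat)
  # missing and overlapping cores are rejected with the offending range
  expect_error(concat_core_results(
    lapply(parts[c(1L, 3L)], function(p) p$core_results[[1L]]),
    n_snps = 90L), "\\[30, 60\\)")
  expect_error(concat_core_results(
    lapply(parts[c(1L, 1L, 2L, 3L)], function(p) p$core_results[[1L]]),
    n_snps = 90L), "overlapping")
})

test_that("run_pipeline writes phase, library and stats deterministically", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(
    simulate = sim_params(n_snps = 80L, split_generations = c(6L, 2L),
                          split_counts = c(2L, 1L),
                          n_generations_selection = 2L, n_sires = 3L,
                          n_dams = 10L, n_offspring_per_breed_gen = 20L,
                          n_qtn = 20L, founder_pop_size = 30L,
                          n_candidate_sites = 400L, rng_seed = 5L),
    array_preset = "two-md",
    params = phasing_params(core_length = 40L, subset_size = 60L,
                            min_shared_markers = 10L,
                            min_match_alleles = 15L, rng_seed = 6L),
    evaluate = TRUE, out_dir = out1)
  r1 <- run_pipeline(config)
  config$out_dir <- out2
  r2 <- run_pipeline(config)
  for (f in c("phase.txt", "library.txt", "stats.tsv")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  stats <- utils::read.delim(file.path(out1, "stats.tsv"))
  expect_identical(colnames(stats)[1L], "scenario")
  expect_true(all(abs(rowSums(stats[, c("het_correct", "het_unphased",
                                        "het_incorrect")]) - 100) < 0.01))
  # phase file round-trips against the fit
  ph <- read_phase(file.path(out1, "phase.txt"))
  expect_identical(ph$hap1, r1$fit$pat)
  # core_length larger than the chromosome is rejected up front
  bad <- config
  bad$params <- phasing_params(core_length = 200L)
  expect_error(run_pipeline(bad), "exceeds")
})
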