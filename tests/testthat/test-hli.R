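# small helper: library core with given entries (NA-coded allele vectors)
lib_with <- function(L, entries, counts = rep(1L, length(entries))) {
  haps <- vapply(entries, haplophase:::hap_to_internal, integer(L))
  haplophase:::lc_repack(list(haps = matrix(haps, nrow = L),
                              counts = as.integer(counts),
                              carriers = rep(list(character(0)),
                                             length(entries))))
}

test_that("match_haplotype applies the co-observed and mismatch rules", {
  L <- 300L
  set.seed(10)
  base <- sample(0:1, L, replace = TRUE)
  lc <- lib_with(L, list(base))
  params <- phasing_params(min_match_alleles = 200L)
  # 250 co-observed, 0 mismatches -> match
  h <- base
  h[1:50] <- NA
  expect_identical(match_haplotype(h, lc, params), 1L)
  # 150 co-observed with threshold 200 -> no match
  h2 <- base
  h2[1:150] <- NA
  expect_identical(match_haplotype(h2, lc, params), integer(0))
  # 250 co-observed, 1 mismatch, allowance 0 -> no match
  h3 <- base
  h3[1:50] <- NA
  h3[60] <- 1L - h3[60]
  expect_identical(match_haplotype(h3, lc, params), integer(0))
  # allowance 1 admits the single mismatch
  expect_identical(
    match_haplotype(h3, lc, phasing_params(min_match_alleles = 200L,
                                           library_cluster_mismatches = 1L)),
    1L)
})

test_that("merging complementary partial haplotypes unions their positions", {
  L <- 40L
  set.seed(3)
  truth <- sample(0:1, L, replace = TRUE)
  a <- truth; a[21:40] <- NA     # observed on the first half + overlap
  b <- truth; b[1:10] <- NA      # observed on the rest
  lc <- lib_with(L, list(a, b))
  m <- merge_library_entries(lc, c(1L, 2L))
  out <- m$library_core
  expect_identical(ncol(out$haps), 1L)
  expect_identical(out$haps[, 1L], haplophase:::hap_to_internal(truth))
  expect_identical(out$counts, 2L)
  # merging an identical copy: alleles unchanged, counts summed
  lc2 <- lib_with(L, list(truth, truth), counts = c(3L, 4L))
  m2 <- merge_library_entries(lc2, c(1L, 2L))
  expect_identical(m2$library_core$haps[, 1L],
                   haplophase:::hap_to_internal(truth))
  expect_identical(m2$library_core$counts, 7L)
  # conflicting sources refuse to merge
  confl <- truth
  confl[5L] <- 1L - confl[5L]
  lc3 <- lib_with(L, list(truth, confl))
  expect_error(merge_library_entries(lc3, c(1L, 2L)), "conflict")
})

test_that("a bridging haplotype merges pairwise-unlinked partials", {
  # three partial entries observed on disjoint thirds cannot match each
  # other, but one complete haplotype matches all three: one merged entry
  L <- 90L
  set.seed(4)
  truth <- sample(0:1, L, replace = TRUE)
  parts <- list(replace(rep(NA_integer_, L), 1:30, truth[1:30]),
                replace(rep(NA_integer_, L), 31:60, truth[31:60]),
                replace(rep(NA_integer_, L), 61:90, truth[61:90]))
  lc <- lib_with(L, parts)
  params <- phasing_params(min_match_alleles = 25L,
                           min_phased_frac_library = 0.8)
  out <- update_library(lc, truth, c("bridge", 1L), rep(TRUE, L), params)
  expect_identical(attr(out, "action"), "merged")
  expect_identical(ncol(out$haps), 1L)
  expect_identical(out$haps[, 1L], haplophase:::hap_to_internal(truth))
})

test_that("update_library rejects under-phased and conflict-splits", {
  L <- 100L
  set.seed(6)
  truth <- sample(0:1, L, replace = TRUE)
  params <- phasing_params(min_match_alleles = 30L,
                           min_phased_frac_library = 0.8)
  lc <- haplophase:::empty_library_core(L)
  # 70% phased with threshold 80% -> rejected
  h <- truth
  h[sample.int(L, 30L)] <- NA
  out <- update_library(lc, h, c("x", 1L), rep(TRUE, L), params)
  expect_identical(attr(out, "action"), "rejected")
  expect_identical(ncol(out$haps), 0L)
  # the phased-fraction denominator is the carrier's genotyped SNPs: the
  # same haplotype is admissible for a carrier genotyped only where phased
  genotyped <- !is.na(h)
  out2 <- update_library(lc, h, c("x", 1L), genotyped, params)
  expect_identical(attr(out2, "action"), "inserted")
  # candidate matching two entries that conflict with each other is
  # inserted as a new entry, leaving the matches untouched
  e1 <- truth
  e2 <- truth
  e2[10L] <- 1L - e2[10L]
  e1[95:100] <- NA # make the two entries distinct but both matchable
  lc2 <- lib_with(L, list(e1, e2))
  cand <- truth
  cand[10L] <- NA # avoids the site where e1/e2 disagree
  out3 <- update_library(lc2, cand, c("y", 2L), rep(TRUE, L), params)
  expect_identical(attr(out3, "action"), "inserted")
  expect_identical(ncol(out3$haps), 3L)
})

test_that("one fully phased gamete resolves its partner in one pass", {
  L <- 60L
  set.seed(12)
  t1 <- sample(0:1, L, replace = TRUE)
  t2 <- sample(0:1, L, replace = TRUE)
  g <- matrix(t1 + t2, 1L, dimnames = list("A", NULL))
  pairs <- list(pat = matrix(as.integer(t1), 1L, dimnames = list("A", NULL)),
                mat = matrix(NA_integer_, 1L, L, dimnames = list("A", NULL)))
  res <- hli_phase_core(g, pairs, haplophase:::empty_library_core(L),
                        phasing_params(min_match_alleles = 30L))
  expect_identical(res$pairs$mat["A", ], as.integer(t2))
})

test_that("empty library and under-phased haplotypes terminate immediately", {
  L <- 50L
  set.seed(13)
  g <- rand_geno(5, L, miss_frac = 0)
  # nothing phased at heterozygous sites, so no haplotype reaches 80%
  pairs <- list(pat = matrix(NA_integer_, 5, L, dimnames =
                               list(rownames(g), NULL)),
                mat = matrix(NA_integer_, 5, L, dimnames =
                               list(rownames(g), NULL)))
  res <- hli_phase_core(g, pairs,
                        haplophase:::empty_library_core(L),
                        phasing_params(min_match_alleles = 30L,
                                       min_phased_frac_library = 0.99))
  expect_identical(ncol(res$library_core$haps), 0L)
  expect_lte(res$n_passes, 2L)
})

test_that("HLI completes founder-haplotype populations from partial phase", {
  # 20 individuals drawn from 3 founder haplotypes; LRP-like partial input:
  # a random half of each true haplotype blanked
  set.seed(14)
  L <- 120L
  founders <- matrix(rbinom(3L * L, 1L, 0.5), 3L, L)
  n <- 20L
  f1 <- sample.int(3L, n, replace = TRUE)
  f2 <- sample.int(3L, n, replace = TRUE)
  h1 <- founders[f1, , drop = FALSE]
  h2 <- founders[f2, , drop = FALSE]
  ids <- sprintf("I%02d", seq_len(n))
  rownames(h1) <- rownames(h2) <- ids
  g <- genotype_matrix(h1 + h2, ids)
  pat <- h1; mat <- h2
  # seed the library from two individuals left fully phased; blank the rest
  for (i in 3:n) {
    drop1 <- sample.int(L, round(0.45 * L))
    pat[i, drop1] <- NA
    mat[i, ] <- complement_from_genotype(g[i, ], pat[i, ])
  }
  params <- phasing_params(min_match_alleles = 40L,
                           min_phased_frac_library = 0.5)
  res <- hli_phase_core(g, list(pat = pat, mat = mat),
                        haplophase:::empty_library_core(L), params)
  acc <- oracle_phase_accuracy(res$pairs$pat, res$pairs$mat,
                               list(hap1 = h1, hap2 = h2), scope_het = TRUE)
  expect_identical(acc[["incorrect"]], 0)
  expect_gt(acc[["correct"]], 99)
  # no HLI fill ever contradicts a genotype
  hom <- g != 1L
  expect_true(all(res$pairs$pat[hom] == g[hom] %/% 2L))
  het <- g == 1L
  expect_true(all(res$pairs$pat[het] != res$pairs$mat[het], na.rm = TRUE))
})

test_that("phased count is monotone and the library deduplicates", {
  set.seed(15)
  pop <- bred_population(10, 20, 1, 100, 4, seed = 15L)
  params <- phasing_params(min_shared_markers = 20L,
                           min_match_alleles = 40L)
  graph <- build_surrogate_graph(pack_genotypes(pop$genotypes), c(0L, 100L),
                                 params)
  lrp <- phase_core_lrp(graph, ped = pop$pedigree,
                        genotypes = pop$genotypes)
  before <- sum(!is.na(lrp$pat)) + sum(!is.na(lrp$mat))
  res <- hli_phase_core(pop$genotypes, lrp,
                        haplophase:::empty_library_core(100L), params)
  after <- sum(!is.na(res$pairs$pat)) + sum(!is.na(res$pairs$mat))
  expect_gte(after, before)
  # maintenance invariant: no two remaining entries match each other
  lc <- res$library_core
  n <- ncol(lc$haps)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      cnt <- haplophase:::cpp_hap_match_counts_packed_n(
        lc$alleles[, a], lc$known[, a],
        lc$alleles[, (a + 1L):n, drop = FALSE],
        lc$known[, (a + 1L):n, drop = FALSE], n - a)
      expect_true(all(cnt[, 1L] < params$min_match_alleles |
                        cnt[, 2L] > params$library_cluster_mismatches))
    }
  }
})

test_that("merging is order-independent for pairwise-compatible sets", {
  L <- 60L
  set.seed(16)
  truth <- sample(0:1, L, replace = TRUE)
  parts <- lapply(list(1:25, 20:45, 40:60), function(ix)
    replace(rep(NA_integer_, L), ix, truth[ix]))
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  outs <- lapply(perms, function(p) {
    lc <- lib_with(L, parts[p])
    m <- merge_library_entries(lc, 1:3)
    m$library_core$haps[, 1L]
  })
  expect_identical(outs[[1L]], outs[[2L]])
  expect_identical(outs[[1L]], outs[[3L]])
  expect_identical(outs[[1L]], haplophase:::hap_to_internal(truth))
})

test_that("a loaded library seeds phasing of a new dataset", {
  # build a library from one run, save/load it, and use it to phase an
  # individual whose LRP phase is empty
  L <- 60L
  set.seed(17)
  t1 <- sample(0:1, L, replace = TRUE)
  t2 <- sample(0:1, L, replace = TRUE)
  while (sum(t1 != t2) < 10) t2 <- sample(0:1, L, replace = TRUE)
  lc <- lib_with(L, list(t1, t2), counts = c(5L, 4L))
  lib <- haplotype_library(cbind(start = 0L, end = L))
  lib$entries[[1L]] <- lc
  f <- withr::local_tempfile()
  save_library(lib, f)
  lib2 <- load_library(f)
  g <- matrix(t1 + t2, 1L, dimnames = list("N", NULL))
  part <- as.integer(t1)
  part[sample.int(L, round(0.5 * L))] <- NA # partial phase for gamete 1
  pairs <- list(pat = matrix(part, 1L, dimnames = list("N", NULL)),
                mat = matrix(NA_integer_, 1L, L, dimnames = list("N", NULL)))
  params <- phasing_params(min_match_alleles = 20L,
                           min_phased_frac_library = 0.5)
  res <- hli_phase_core(g, pairs, lib2$entries[[1L]], params)
  acc <- oracle_phase_accuracy(res$pairs$pat, res$pairs$mat,
                               list(hap1 = matrix(t1, 1L),
                                    hap2 = matrix(t2, 1L)))
  expect_identical(acc[["incorrect"]], 0)
  expect_identical(acc[["unphased"]], 0) # the prior library completes both
})
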