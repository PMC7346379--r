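test_that("partition_cores tiles the chromosome with the remainder rule", {
  expect_identical(partition_cores(100L, 50L),
                   cbind(start = c(0L, 50L), end = c(50L, 100L)))
  # remainder 5 < 25 is absorbed into the final core
  expect_identical(partition_cores(105L, 50L),
                   cbind(start = c(0L, 50L), end = c(50L, 105L)))
  # remainder 30 >= 25 stands as its own core
  expect_identical(partition_cores(130L, 50L),
                   cbind(start = c(0L, 50L, 100L), end = c(50L, 100L, 130L)))
  expect_error(partition_cores(100L, 0L), "positive")
  expect_error(partition_cores(10L, 50L), "exceeds")
  # tiling property for random sizes
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(10:500, 1L)
    cl <- sample.int(n, 1L)
    cores <- partition_cores(n, cl)
    expect_identical(unname(cores[1L, "start"]), 0L)
    expect_identical(unname(cores[nrow(cores), "end"]), n)
    if (nrow(cores) > 1L)
      expect_identical(unname(cores[-1L, "start"]), unname(cores[-nrow(cores), "end"]))
  }
})

test_that("opposing_and_shared matches hand-worked example and identity", {
  g <- genotype_matrix(rbind(c(0L, 2L, 1L, NA), c(2L, 2L, NA, 0L)),
                       c("a", "b"))
  p <- pack_genotypes(g)
  expect_identical(opposing_and_shared(p, "a", "b", c(0L, 4L)),
                   c(n_opposing = 1L, n_shared = 2L))
  expect_identical(opposing_and_shared(p, "a", "a", c(0L, 4L)),
                   c(n_opposing = 0L, n_shared = 3L))
})

test_that("surrogate graph equals the exhaustive pairwise oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 20L
    L <- sample(40:80, 1L)
    g <- rand_geno(n, L, miss_frac = runif(1, 0, 0.4))
    params <- phasing_params(min_shared_markers = sample(5:20, 1L),
                             surrogate_disagree_frac = runif(1, 0, 0.3))
    core <- c(0L, L)
    graph <- build_surrogate_graph(pack_genotypes(g), core, params)
    oracle <- oracle_surrogate_edges(g, core, params$min_shared_markers,
                                     params$surrogate_disagree_frac)
    got <- graph$edges[order(graph$edges[, 1L], graph$edges[, 2L]), ,
                       drop = FALSE]
    expect_equal(unname(got), unname(oracle))
  }
})

test_that("surrogacy rule boundaries behave as specified", {
  # n_shared below the floor: never tested, never a surrogate
  g <- genotype_matrix(rbind(c(0L, 0L, NA, NA), c(0L, 0L, 0L, 0L)),
                       c("a", "b"))
  params <- phasing_params(min_shared_markers = 3L)
  graph <- build_surrogate_graph(pack_genotypes(g), c(0L, 4L), params)
  expect_identical(nrow(graph$edges), 0L)
  # boundary: n_opposing == floor(0.10 * n_shared) still qualifies
  set.seed(2)
  L <- 100L
  gi <- rep(0L, L)
  gj <- rep(0L, L)
  gj[1:10] <- 2L # exactly 10 opposing out of 100 shared
  g <- genotype_matrix(rbind(gi, gj), c("a", "b"))
  graph <- build_surrogate_graph(pack_genotypes(g), c(0L, L),
                                 phasing_params(min_shared_markers = 10L))
  expect_identical(nrow(graph$edges), 1L)
  expect_identical(unname(graph$edges[1L, "n_opposing"]), 10L)
})

test_that("raising min_shared_markers never adds surrogate edges", {
  set.seed(21)
  g <- rand_geno(25, 60, miss_frac = 0.3)
  packed <- pack_genotypes(g)
  prev <- NULL
  for (ms in c(5L, 15L, 25L, 40L)) {
    graph <- build_surrogate_graph(packed, c(0L, 60L),
                                   phasing_params(min_shared_markers = ms))
    keys <- paste(graph$edges[, 1L], graph$edges[, 2L])
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("pedigree-based side partition labels sire and ambiguous cases", {
  # i heterozygous everywhere; sire and dam fully homozygous and opposing
  # each other, so they are surrogates of i but not of each other
  L <- 40L
  i <- rep(1L, L)
  sire <- rep(0L, L)
  dam <- rep(2L, L)
  g <- genotype_matrix(rbind(i, sire, dam), c("i", "s", "d"))
  ped <- pedigree(c("i", "s", "d"), c("s", "0", "0"), c("d", "0", "0"))
  params <- phasing_params(min_shared_markers = 10L)
  graph <- build_surrogate_graph(pack_genotypes(g), c(0L, L), params)
  sides <- partition_sides(graph, ped, "i")
  expect_identical(sides[["s"]], "paternal")
  expect_identical(sides[["d"]], "maternal")
  # a surrogate of both sire and dam is unknown
  both <- rep(1L, L)
  g2 <- genotype_matrix(rbind(i, sire, dam, both), c("i", "s", "d", "x"))
  graph2 <- build_surrogate_graph(pack_genotypes(g2), c(0L, L), params)
  sides2 <- partition_sides(graph2, ped, "i")
  expect_identical(sides2[["x"]], "unknown")
})

test_that("anchor clustering recovers the true side split from founders", {
  # individuals built from 4 founder haplotypes; i carries founders 1|2;
  # paternal-sharers carry founder 1, maternal-sharers founder 2
  set.seed(33)
  L <- 120L
  F <- matrix(rbinom(4L * L, 1L, 0.5), 4L, L)
  # i carries founders 1|2; the p-group shares only founder 1 with i, the
  # m-group only founder 2, and the groups share no founder with each other
  h <- list(c(1L, 2L), c(1L, 3L), c(1L, 3L), c(2L, 4L), c(2L, 4L))
  hm <- t(vapply(h, function(fp) F[fp[1L], ] + F[fp[2L], ], integer(L)))
  ids <- c("i", "p1", "p2", "m1", "m2")
  g <- genotype_matrix(hm, ids)
  params <- phasing_params(min_shared_markers = 20L,
                           surrogate_disagree_frac = 0)
  graph <- build_surrogate_graph(pack_genotypes(g), c(0L, L), params)
  sides <- partition_sides(graph, NULL, "i")
  pat_set <- names(sides)[sides == "paternal"]
  mat_set <- names(sides)[sides == "maternal"]
  p_group <- intersect(c("p1", "p2"), names(sides))
  m_group <- intersect(c("m1", "m2"), names(sides))
  expect_gte(length(p_group), 1L)
  expect_gte(length(m_group), 1L)
  if (all(p_group %in% pat_set)) {
    expect_true(all(m_group %in% mat_set))
  } else {
    # the anchor attached to the maternal haplotype: sides swap
    expect_true(all(p_group %in% mat_set))
    expect_true(all(m_group %in% pat_set))
  }
})

test_that("bulk side assignment equals per-individual partition_sides", {
  set.seed(44)
  pop <- bred_population(20, 25, 2, 80, 6, seed = 9L)
  params <- phasing_params(min_shared_markers = 20L,
                           min_match_alleles = 30L)
  graph <- build_surrogate_graph(pack_genotypes(pop$genotypes), c(0L, 80L),
                                 params)
  for (ped in list(NULL, pop$pedigree)) {
    bulk <- haplophase:::assign_sides_all(graph, ped)
    for (i in seq_len(graph$n)) {
      lo <- graph$adj_ptr[i]; hi <- graph$adj_ptr[i + 1L]
      if (hi == lo) next
      got <- c("unknown", "paternal", "maternal")[bulk[(lo + 1L):hi] + 1L]
      want <- unname(partition_sides(graph, ped, i))
      expect_identical(got, want)
    }
  }
})

test_that("single-surrogate vote phases and complement fills the het site", {
  # i heterozygous at every SNP, one fully homozygous-0 surrogate
  L <- 60L
  g <- genotype_matrix(rbind(rep(1L, L), rep(0L, L)), c("i", "s"))
  ped <- pedigree(c("i", "s"), c("s", "0"), c("0", "0"))
  params <- phasing_params(min_shared_markers = 10L)
  graph <- build_surrogate_graph(pack_genotypes(g), c(0L, L), params)
  res <- phase_core_lrp(graph, ped = ped, genotypes = g)
  expect_true(all(res$pat["i", ] == 0L))
  expect_true(all(res$mat["i", ] == 1L))
})

test_that("split or sub-threshold votes stay unphased (tie toward missing)", {
  # vote kernel directly: i het at the single SNP, two paternal surrogates
  # voting opposite alleles -> tied vote, no call
  codes <- matrix(c(1L, 0L, 2L), nrow = 1L) # i het, s1 hom-0, s2 hom-2
  adj_ptr <- c(0L, 2L, 3L, 4L)
  adj_idx <- c(1L, 2L, 0L, 0L)
  side <- c(1L, 1L, 1L, 1L)
  v <- haplophase:::cpp_lrp_votes(codes, adj_ptr, adj_idx, side,
                                  10L, 10L, 0.9)
  expect_identical(v$pat[1L, 1L], -1L)
  # 8 vs 2 split: share 0.8 < 0.9 -> still no call
  codes <- matrix(c(1L, rep(0L, 8L), rep(2L, 2L)), nrow = 1L)
  adj_ptr <- c(0L, 10L, rep(11:20, 1L))
  adj_ptr <- c(0L, 10L, 10L + seq_len(10L))
  adj_idx <- c(1:10, rep(0L, 10L))
  side <- rep(1L, 20L)
  v <- haplophase:::cpp_lrp_votes(codes, adj_ptr, adj_idx, side,
                                  10L, 10L, 0.9)
  expect_identical(v$pat[1L, 1L], -1L)
  # but with consensus 0.7 the 8-vote plurality is accepted
  v <- haplophase:::cpp_lrp_votes(codes, adj_ptr, adj_idx, side,
                                  10L, 10L, 0.7)
  expect_identical(v$pat[1L, 1L], 0L)
})

test_that("chain voting reaches homozygous surrogates of surrogates", {
  # i - s1 (het everywhere) - s2 (hom 0): depth-2 chain must vote
  L <- 60L
  g <- genotype_matrix(rbind(rep(1L, L), rep(1L, L), rep(0L, L)),
                       c("i", "s1", "s2"))
  ped <- pedigree(c("i", "s1", "s2"), c("s1", "s2", "0"), c("0", "0", "0"))
  params <- phasing_params(min_shared_markers = 10L)
  graph <- build_surrogate_graph(pack_genotypes(g), c(0L, L), params)
  res <- phase_core_lrp(graph, ped = ped, genotypes = g)
  expect_true(all(res$pat["i", ] == 0L))
  expect_true(all(res$mat["i", ] == 1L))
})

test_that("LRP phases founder-haplotype populations consistently with truth", {
  pop <- bred_population(16, 34, 1, 100, 4, seed = 5L)
  params <- phasing_params(min_shared_markers = 20L)
  graph <- build_surrogate_graph(pack_genotypes(pop$genotypes), c(0L, 100L),
                                 params)
  res <- phase_core_lrp(graph, ped = pop$pedigree, genotypes = pop$genotypes)
  acc <- oracle_phase_accuracy(res$pat, res$mat, pop$truth)
  expect_gt(acc[["correct"]], 60)
  expect_lt(acc[["incorrect"]], 2)
  # every phased allele is consistent with the genotype
  for (nm in c("pat", "mat")) {
    h <- res[[nm]]
    gmat <- pop$genotypes
    hom <- !is.na(gmat) & gmat != 1L
    expect_true(all(h[hom] == gmat[hom] %/% 2L, na.rm = TRUE))
  }
  het <- !is.na(pop$genotypes) & pop$genotypes == 1L
  both <- het & !is.na(res$pat) & !is.na(res$mat)
  expect_true(all(res$pat[both] != res$mat[both]))
  # deterministic
  res2 <- phase_core_lrp(graph, ped = pop$pedigree,
                         genotypes = pop$genotypes)
  expect_identical(res, res2)
})
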