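# shared fixtures and independent per-SNP oracles (no bit operations)

# random genotype matrix with missing values
rand_geno <- function(n, L, miss_frac = 0.2) {
  codes <- matrix(sample(c(0L, 1L, 2L), n * L, replace = TRUE), n, L)
  if (miss_frac > 0) {
    k <- round(miss_frac * n * L)
    codes[sample.int(n * L, k)] <- NA_integer_
  }
  genotype_matrix(codes, sprintf("R%03d", seq_len(n)))
}

# per-SNP loop oracle for opposing/shared counts
oracle_pair_counts <- function(gi, gj) {
  opp <- 0L
  sh <- 0L
  for (p in seq_along(gi)) {
    a <- gi[p]; b <- gj[p]
    if (!is.na(a) && !is.na(b)) {
      sh <- sh + 1L
      if ((a == 0L && b == 2L) || (a == 2L && b == 0L)) opp <- opp + 1L
    }
  }
  c(n_opposing = opp, n_shared = sh)
}

# exhaustive pairwise surrogate-graph oracle
oracle_surrogate_edges <- function(g, core, min_shared, disagree_frac) {
  cc <- (core[1L] + 1L):core[2L]
  n <- nrow(g)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cnt <- oracle_pair_counts(g[i, cc], g[j, cc])
      if (cnt["n_shared"] >= min_shared &&
          cnt["n_opposing"] <= floor(disagree_frac * cnt["n_shared"]))
        out <- rbind(out, c(i, j, cnt[["n_opposing"]], cnt[["n_shared"]]))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 4)
  colnames(out) <- c("i", "j", "n_opposing", "n_shared")
  out
}

# population bred from a fixed set of founder haplotypes, without
# recombination: every individual carries two founder haplotypes intact, so
# truth is exact and surrogacy is guaranteed within founder-sharing groups
founder_population <- function(n, L, n_founders, seed = 1L) {
  set.seed(seed)
  founders <- matrix(rbinom(n_founders * L, 1L, 0.5), n_founders, L)
  f1 <- sample.int(n_founders, n, replace = TRUE)
  f2 <- sample.int(n_founders, n, replace = TRUE)
  h1 <- founders[f1, , drop = FALSE]
  h2 <- founders[f2, , drop = FALSE]
  ids <- sprintf("F%03d", seq_len(n))
  rownames(h1) <- rownames(h2) <- ids
  list(genotypes = genotype_matrix(h1 + h2, ids),
       hap1 = h1, hap2 = h2, f1 = f1, f2 = f2, founders = founders,
       truth = structure(list(ids = ids, hap1 = h1, hap2 = h2),
                         class = "true_population"))
}

# pedigree-structured founder-haplotype population: founders draw intact
# haplotypes from a founder pool; offspring inherit one intact parental
# haplotype per gamete (no recombination), across `gens` generations
bred_population <- function(n_founders_pop, n_off_per_gen, gens, L,
                            n_founder_haps, seed = 1L) {
  set.seed(seed)
  founders <- matrix(rbinom(n_founder_haps * L, 1L, 0.5), n_founder_haps, L)
  id <- sire <- dam <- character(0)
  h1 <- h2 <- NULL
  sex <- character(0)
  for (k in seq_len(n_founders_pop)) {
    id <- c(id, sprintf("G0_%03d", k))
    sire <- c(sire, NA); dam <- c(dam, NA)
    h1 <- rbind(h1, founders[sample.int(n_founder_haps, 1L), ])
    h2 <- rbind(h2, founders[sample.int(n_founder_haps, 1L), ])
  }
  sex <- sample(rep(c("M", "F"), length.out = n_founders_pop))
  for (g in seq_len(gens)) {
    prev <- which(grepl(sprintf("^G%d_", g - 1L), id))
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    new_sex <- character(0)
    for (k in seq_len(n_off_per_gen)) {
      s <- sample(males, 1L); d <- sample(females, 1L)
      id <- c(id, sprintf("G%d_%03d", g, k))
      sire <- c(sire, id[s]); dam <- c(dam, id[d])
      h1 <- rbind(h1, if (runif(1) < 0.5) h1[s, ] else h2[s, ])
      h2 <- rbind(h2, if (runif(1) < 0.5) h1[d, ] else h2[d, ])
      new_sex <- c(new_sex, sample(c("M", "F"), 1L))
    }
    sex <- c(sex, new_sex)
  }
  rownames(h1) <- rownames(h2) <- id
  list(genotypes = genotype_matrix(h1 + h2, id),
       pedigree = pedigree(id, ifelse(is.na(sire), "0", sire),
                           ifelse(is.na(dam), "0", dam)),
       hap1 = h1, hap2 = h2, founders = founders,
       truth = structure(list(ids = id, hap1 = h1, hap2 = h2),
                         class = "true_population"))
}

# orientation-free per-individual accuracy against truth
oracle_phase_accuracy <- function(pat, mat, truth, scope_het = TRUE) {
  n_correct <- n_incorrect <- n_unphased <- 0L
  for (i in seq_len(nrow(pat))) {
    t1 <- truth$hap1[i, ]; t2 <- truth$hap2[i, ]
    sc <- if (scope_het) (t1 + t2) == 1L else rep(TRUE, length(t1))
    a <- pat[i, sc]; b <- mat[i, sc]
    u <- t1[sc]; v <- t2[sc]
    c1 <- sum(a == u, na.rm = TRUE) + sum(b == v, na.rm = TRUE)
    c2 <- sum(a == v, na.rm = TRUE) + sum(b == u, na.rm = TRUE)
    corr <- max(c1, c2)
    nonmiss <- sum(!is.na(a)) + sum(!is.na(b))
    n_correct <- n_correct + corr
    n_incorrect <- n_incorrect + (nonmiss - corr)
    n_unphased <- n_unphased + (2L * sum(sc) - nonmiss)
  }
  tot <- n_correct + n_incorrect + n_unphased
  c(correct = 100 * n_correct / tot, unphased = 100 * n_unphased / tot,
    incorrect = 100 * n_incorrect / tot)
}
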