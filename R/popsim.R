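#' Simulation parameters for the breed-structured test populations
#'
#' The defaults describe the reference scenario the package is tested
#' against: a 1-Morgan chromosome; a single ancestral breed splitting into
#' three breeds 400 generations ago, each splitting again into three or four
#' breeds 50 generations ago (ten breeds in total); ten generations of
#' within-breed truncation selection with 25 sires and 500 dams producing
#' 1000 offspring per breed and generation; 10,000 quantitative trait
#' nucleotides with standard-normal effects; and SNPs retained at a
#' base-generation minor allele frequency of at least 0.05.  At desk scale,
#' pass smaller values (fewer breeds/generations/offspring, fewer SNPs).
#'
#' @param n_snps Number of SNPs retained on the simulated chromosome.
#' @param chrom_length Chromosome length in Morgans.
#' @param split_generations `c(older, recent)` generations ago of the two
#'   breed splits.
#' @param split_counts Integer vector, daughters per old breed at the recent
#'   split (its length is the number of old breeds).
#' @param n_generations_selection Generations of truncation selection.
#' @param n_sires,n_dams Parents selected per breed and generation.
#' @param n_offspring_per_breed_gen Offspring per breed and generation.
#' @param n_qtn Quantitative trait nucleotides (standard-normal effects).
#' @param maf_min Minimum base-generation minor allele frequency for a SNP.
#' @param heritability Narrow-sense heritability of the selection trait.
#' @param founder_pop_size Diploid individuals per breed during the neutral
#'   (Wright-Fisher) history and at the base generation.
#' @param n_candidate_sites Polymorphic candidate sites tracked through the
#'   neutral history (must comfortably exceed `n_snps + n_qtn`).
#' @param mutation_rate Per-site per-gamete mutation probability during the
#'   neutral history.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_snps = 8771L,
                       chrom_length = 1,
                       split_generations = c(400L, 50L),
                       split_counts = c(3L, 3L, 4L),
                       n_generations_selection = 10L,
                       n_sires = 25L,
                       n_dams = 500L,
                       n_offspring_per_breed_gen = 1000L,
                       n_qtn = 10000L,
                       maf_min = 0.05,
                       heritability = 0.3,
                       founder_pop_size = 1050L,
                       n_candidate_sites = NULL,
                       mutation_rate = 1e-4,
                       rng_seed = 1L) {
  p <- list(n_snps = as.integer(n_snps), chrom_length = as.numeric(chrom_length),
            split_generations = as.integer(split_generations),
            split_counts = as.integer(split_counts),
            n_generations_selection = as.integer(n_generations_selection),
            n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
            n_offspring_per_breed_gen = as.integer(n_offspring_per_breed_gen),
            n_qtn = as.integer(n_qtn), maf_min = as.numeric(maf_min),
            heritability = as.numeric(heritability),
            founder_pop_size = as.integer(founder_pop_size),
            n_candidate_sites = if (is.null(n_candidate_sites))
              as.integer(2L * (as.integer(n_snps) + as.integer(n_qtn)))
            else as.integer(n_candidate_sites),
            mutation_rate = as.numeric(mutation_rate),
            rng_seed = as.integer(rng_seed))
  if (any(vapply(p[c("n_snps", "n_generations_selection", "n_sires", "n_dams",
                     "n_offspring_per_breed_gen", "n_qtn",
                     "founder_pop_size", "n_candidate_sites")],
                 function(x) is.na(x) || x < 1L, logical(1L))))
    stopf("all counts must be positive")
  if (p$maf_min <= 0 || p$maf_min >= 0.5) stopf("maf_min must be in (0, 0.5)")
  if (p$heritability < 0 || p$heritability > 1)
    stopf("heritability must be in [0, 1]")
  if (length(p$split_generations) != 2L ||
      p$split_generations[1L] <= p$split_generations[2L])
    stopf("split_generations must be c(older, recent) with older > recent")
  structure(p, class = "sim_params")
}

#' Simulate one meiosis
#'
#' Crossovers follow a Poisson process with no interference: the crossover
#' count is Poisson with mean `chrom_length` (in Morgans) and breakpoints
#' are uniform along the chromosome; the starting haplotype is chosen with
#' probability 1/2.  Uses the current RNG state.
#'
#' @param h1,h2 Parent's two haplotypes (allele vectors of equal length).
#' @param positions SNP positions in Morgans, non-decreasing within
#'   `[0, chrom_length]`.
#' @param chrom_length Chromosome length in Morgans.
#' @return A gamete: allele vector where every allele equals one of the
#'   parent's alleles at that SNP.
#' @export
meiosis <- function(h1, h2, positions, chrom_length = 1) {
  n_x <- stats::rpois(1L, chrom_length)
  start <- sample.int(2L, 1L) - 1L
  if (n_x == 0L) return(if (start == 0L) h1 else h2)
  breaks <- sort(stats::runif(n_x, 0, chrom_length))
  choice <- (start + findInterval(positions, breaks)) %% 2L
  g <- h1
  sw <- choice == 1L
  g[sw] <- h2[sw]
  g
}

# one neutral Wright-Fisher generation: random mating with recombination
# and symmetric per-site mutation; pool is a 2N x S 0/1 matrix
wf_generation <- function(pool, positions, chrom_length, mutation_rate) {
  n_ind <- nrow(pool) %/% 2L
  out <- matrix(0L, nrow(pool), ncol(pool))
  parents <- sample.int(n_ind, 2L * n_ind, replace = TRUE)
  for (k in seq_len(2L * n_ind)) {
    pr <- parents[k]
    out[k, ] <- meiosis(pool[2L * pr - 1L, ], pool[2L * pr, ], positions,
                        chrom_length)
  }
  n_mut <- stats::rpois(1L, mutation_rate * length(out))
  if (n_mut > 0L) {
    at <- sample.int(length(out), n_mut, replace = TRUE)
    out[at] <- 1L - out[at]
  }
  out
}

#' Simulate a breed-structured population under selection, with truth
#'
#' Three stages.  (1) A neutral forward Wright-Fisher history with
#' recombination and mutation runs through the breed-split tree (one
#' ancestral breed, an older split into `length(split_counts)` breeds, a
#' recent split into `sum(split_counts)` breeds), a scaled stand-in for a
#' coalescent simulation of base haplotypes.  (2) Sites segregating with
#' base-generation minor allele frequency of at least `maf_min` become SNP
#' candidates; `n_snps` of them are retained and `n_qtn` further sites get
#' standard-normal QTN effects.  (3) Each breed undergoes
#' `n_generations_selection` rounds of truncation selection on phenotype
#' (genetic value plus environmental noise per the heritability): the top
#' `n_sires` males and `n_dams` females are mated at random (with
#' replacement) to produce `n_offspring_per_breed_gen` offspring.
#'
#' Complete haplotypes, pedigree, breed and generation labels, phenotypes
#' and the selection log are retained as truth.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `true_population`.
#' @export
simulate_population <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$rng_seed, simulate_population_impl(params))
}

simulate_population_impl <- function(params) {
  S <- params$n_candidate_sites
  N <- params$founder_pop_size
  positions <- sort(stats::runif(S, 0, params$chrom_length))
  # stage 1: neutral history through the breed-split tree
  p0 <- stats::rbeta(S, 0.5, 0.5)
  ancestral <- matrix(stats::rbinom(2L * N * S, 1L, rep(p0, each = 2L * N)),
                      nrow = 2L * N)
  gens_old <- params$split_generations[1L] - params$split_generations[2L]
  old_pools <- vector("list", length(params$split_counts))
  for (b in seq_along(params$split_counts)) {
    pool <- ancestral
    for (g in seq_len(gens_old))
      pool <- wf_generation(pool, positions, params$chrom_length,
                            params$mutation_rate)
    old_pools[[b]] <- pool
  }
  pools <- vector("list", sum(params$split_counts))
  bi <- 0L
  for (b in seq_along(params$split_counts)) {
    for (d in seq_len(params$split_counts[b])) {
      bi <- bi + 1L
      pool <- old_pools[[b]]
      for (g in seq_len(params$split_generations[2L]))
        pool <- wf_generation(pool, positions, params$chrom_length,
                              params$mutation_rate)
      pools[[bi]] <- pool
    }
  }
  n_breeds <- length(pools)
  # stage 2: MAF filter at the base generation (all breeds pooled)
  freq <- Reduce(`+`, lapply(pools, colSums)) / (n_breeds * 2L * N)
  maf <- pmin(freq, 1 - freq)
  candidates <- which(maf >= params$maf_min)
  if (length(candidates) < params$n_snps)
    stopf(paste("only %d candidate sites pass the MAF filter but n_snps = %d;",
                "increase founder_pop_size (or n_candidate_sites)"),
          length(candidates), params$n_snps)
  snp_idx <- sort(sample(candidates, params$n_snps))
  qtn_pool <- setdiff(candidates, snp_idx)
  if (length(qtn_pool) >= params$n_qtn) {
    qtn_idx <- sort(sample(qtn_pool, params$n_qtn))
  } else {
    qtn_idx <- sort(sample(candidates, params$n_qtn,
                           replace = length(candidates) < params$n_qtn))
  }
  qtn_effects <- stats::rnorm(params$n_qtn)
  # restrict to the sites needed downstream
  used <- sort(unique(c(snp_idx, qtn_idx)))
  snp_in_used <- match(snp_idx, used)
  qtn_in_used <- match(qtn_idx, used)
  positions_used <- positions[used]
  pools <- lapply(pools, function(p) p[, used, drop = FALSE])
  # stage 3: truncation selection within each breed
  gv_of <- function(h1, h2) {
    dosage <- h1[qtn_in_used] + h2[qtn_in_used]
    sum(dosage * qtn_effects)
  }
  # environmental variance from the base-generation genetic variance
  base_gv <- unlist(lapply(pools, function(p) {
    vapply(seq_len(N), function(k) gv_of(p[2L * k - 1L, ], p[2L * k, ]),
           numeric(1L))
  }))
  var_g <- stats::var(base_gv)
  h2 <- params$heritability
  var_e <- if (h2 <= 0 || var_g <= 0) 1 else var_g * (1 - h2) / h2
  records <- list()
  sel_log <- list()
  for (b in seq_len(n_breeds)) {
    pool <- pools[[b]]
    cur <- list(
      id = sprintf("B%02d_G00_%05d", b, seq_len(N)),
      sire = rep(NA_character_, N), dam = rep(NA_character_, N),
      sex = sample(rep(c("M", "F"), length.out = N)),
      hap1 = pool[2L * seq_len(N) - 1L, , drop = FALSE],
      hap2 = pool[2L * seq_len(N), , drop = FALSE])
    cur$gv <- vapply(seq_len(N), function(k) gv_of(cur$hap1[k, ],
                                                   cur$hap2[k, ]),
                     numeric(1L))
    cur$phen <- cur$gv + stats::rnorm(N, 0, sqrt(var_e))
    records[[length(records) + 1L]] <-
      data.frame(id = cur$id, sire = cur$sire, dam = cur$dam, sex = cur$sex,
                 breed = b, generation = 0L, gv = cur$gv, phen = cur$phen,
                 stringsAsFactors = FALSE)
    haps1 <- cur$hap1[, snp_in_used, drop = FALSE]
    haps2 <- cur$hap2[, snp_in_used, drop = FALSE]
    rownames(haps1) <- rownames(haps2) <- cur$id
    hap_store <- list(haps1, haps2)
    for (g in seq_len(params$n_generations_selection)) {
      males <- which(cur$sex == "M")
      females <- which(cur$sex == "F")
      if (length(males) < params$n_sires)
        stopf("breed %d generation %d: only %d males for %d sires", b, g,
              length(males), params$n_sires)
      if (length(females) < params$n_dams)
        stopf("breed %d generation %d: only %d females for %d dams", b, g,
              length(females), params$n_dams)
      sires <- males[order(cur$phen[males], decreasing = TRUE)[
        seq_len(params$n_sires)]]
      dams <- females[order(cur$phen[females], decreasing = TRUE)[
        seq_len(params$n_dams)]]
      sel_log[[length(sel_log) + 1L]] <-
        data.frame(breed = b, generation = g,
                   mean_phen_males = mean(cur$phen[males]),
                   mean_phen_sires = mean(cur$phen[sires]),
                   mean_phen_females = mean(cur$phen[females]),
                   mean_phen_dams = mean(cur$phen[dams]))
      n_off <- params$n_offspring_per_breed_gen
      s_pick <- sires[sample.int(length(sires), n_off, replace = TRUE)]
      d_pick <- dams[sample.int(length(dams), n_off, replace = TRUE)]
      h1 <- matrix(0L, n_off, length(used))
      h2 <- matrix(0L, n_off, length(used))
      for (k in seq_len(n_off)) {
        h1[k, ] <- meiosis(cur$hap1[s_pick[k], ], cur$hap2[s_pick[k], ],
                           positions_used, params$chrom_length)
        h2[k, ] <- meiosis(cur$hap1[d_pick[k], ], cur$hap2[d_pick[k], ],
                           positions_used, params$chrom_length)
      }
      nxt <- list(
        id = sprintf("B%02d_G%02d_%05d", b, g, seq_len(n_off)),
        sire = cur$id[s_pick], dam = cur$id[d_pick],
        sex = sample(rep(c("M", "F"), length.out = n_off)),
        hap1 = h1, hap2 = h2)
      nxt$gv <- vapply(seq_len(n_off), function(k) gv_of(h1[k, ], h2[k, ]),
                       numeric(1L))
      nxt$phen <- nxt$gv + stats::rnorm(n_off, 0, sqrt(var_e))
      records[[length(records) + 1L]] <-
        data.frame(id = nxt$id, sire = nxt$sire, dam = nxt$dam,
                   sex = nxt$sex, breed = b, generation = g, gv = nxt$gv,
                   phen = nxt$phen, stringsAsFactors = FALSE)
      s1 <- h1[, snp_in_used, drop = FALSE]
      s2 <- h2[, snp_in_used, drop = FALSE]
      rownames(s1) <- rownames(s2) <- nxt$id
      hap_store[[1L]] <- rbind(hap_store[[1L]], s1)
      hap_store[[2L]] <- rbind(hap_store[[2L]], s2)
      cur <- nxt
    }
    if (b == 1L) {
      all_h1 <- hap_store[[1L]]; all_h2 <- hap_store[[2L]]
    } else {
      all_h1 <- rbind(all_h1, hap_store[[1L]])
      all_h2 <- rbind(all_h2, hap_store[[2L]])
    }
  }
  tab <- do.call(rbind, records)
  tab <- tab[match(rownames(all_h1), tab$id), ]
  ped <- pedigree(tab$id, tab$sire, tab$dam)
  structure(list(ids = tab$id,
                 pedigree = ped,
                 hap1 = all_h1, hap2 = all_h2,
                 breed = tab$breed, generation = tab$generation,
                 sex = tab$sex, genetic_value = tab$gv, phenotype = tab$phen,
                 positions = positions_used[snp_in_used],
                 qtn = list(positions = positions[qtn_idx],
                            effects = qtn_effects),
                 selection_log = do.call(rbind, sel_log),
                 params = params),
            class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  cat(sprintf(paste0("Simulated population: %d individuals (%d breeds, ",
                     "generations 0-%d), %d SNPs\n"),
              length(x$ids), max(x$breed), max(x$generation),
              ncol(x$hap1)))
  invisible(x)
}

#' True genotypes of a simulated population
#' @param pop A `true_population`.
#' @return Genotype matrix (allele sums of the two true haplotypes).
#' @export
true_genotypes <- function(pop) {
  genotype_matrix(pop$hap1 + pop$hap2, pop$ids)
}
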