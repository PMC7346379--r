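#' Build the surrogate graph for a core
#'
#' Two individuals are surrogates (likely share a haplotype spanning the
#' core) when they have at least `min_shared_markers` markers genotyped in
#' both, and the number of opposing homozygotes among those shared markers
#' is at most `floor(surrogate_disagree_frac * n_shared)`.  The disagreement
#' allowance tolerates genotyping error; the shared-marker floor guards
#' against spurious surrogacy when individuals genotyped on different arrays
#' observe few markers in common.  The all-against-all search runs on the
#' bit-packed planes; adjacency lists are kept sorted by evidence quality
#' (fewest opposing homozygotes, then most shared markers) so that voting
#' consumes the most reliable surrogates first.
#'
#' @param packed `packed_genotypes` for the individual subset.
#' @param core Core as `c(start, end)`, 0-based half-open.
#' @param params A [phasing_params()] object.
#' @return An object of class `surrogate_graph` with the qualifying pairs
#'   (`edges`, 1-based) and a CSR adjacency; sides are assigned later.
#' @export
build_surrogate_graph <- function(packed, core, params) {
  g <- cpp_build_graph(packed$hom_ref, packed$hom_alt, packed$miss,
                       as.integer(core[1L]), as.integer(core[2L]),
                       packed$block_bits, packed$n_snps,
                       params$min_shared_markers,
                       params$surrogate_disagree_frac)
  edges <- g$edges
  if (nrow(edges)) {
    edges[, "i"] <- edges[, "i"] + 1L
    edges[, "j"] <- edges[, "j"] + 1L
  }
  structure(list(ids = packed$ids, n = length(packed$ids), edges = edges,
                 adj_ptr = g$adj_ptr, adj_idx = g$adj_idx,
                 adj_opp = g$adj_opp, adj_sh = g$adj_sh,
                 core = core, params = params, packed = packed),
            class = "surrogate_graph")
}

#' @export
print.surrogate_graph <- function(x, ...) {
  cat(sprintf("Surrogate graph: %d individuals, %d surrogate pairs, core [%d, %d)\n",
              x$n, nrow(x$edges), x$core[1L], x$core[2L]))
  invisible(x)
}

# 1-based neighbour indices of individual i, in evidence-quality order
graph_neighbors <- function(graph, i) {
  lo <- graph$adj_ptr[i]
  hi <- graph$adj_ptr[i + 1L]
  if (hi == lo) integer(0) else graph$adj_idx[(lo + 1L):hi] + 1L
}

# parallel n_shared values for i's neighbours
graph_shared <- function(graph, i) {
  lo <- graph$adj_ptr[i]
  hi <- graph$adj_ptr[i + 1L]
  if (hi == lo) integer(0) else graph$adj_sh[(lo + 1L):hi]
}

#' Partition an individual's surrogates into paternal and maternal sides
#'
#' With a pedigree, a surrogate is paternal when it is the sire, or a
#' surrogate of the sire; maternal symmetrically; a surrogate qualifying for
#' both sides, or neither, is labeled unknown and excluded from
#' side-specific voting.  Without pedigree information (or when neither
#' parent is available in the subset) sides are anchored arbitrarily: the
#' surrogate sharing most markers with the individual becomes the paternal
#' anchor, surrogates of the anchor join the paternal side, surrogates with
#' an opposing-homozygote conflict against the anchor (beyond the
#' disagreement allowance, with enough shared markers to test) form the
#' maternal side, and the rest stay unknown.
#'
#' @param graph A `surrogate_graph`.
#' @param ped A [pedigree()] or `NULL`.
#' @param i Individual identifier or index.
#' @return Character vector of sides (`"paternal"`, `"maternal"`,
#'   `"unknown"`) named by surrogate identifier.
#' @export
partition_sides <- function(graph, ped, i) {
  if (is.character(i)) i <- match(i, graph$ids)
  nb <- graph_neighbors(graph, i)
  if (!length(nb)) return(structure(character(0), names = character(0)))
  params <- graph$params
  sire_idx <- dam_idx <- NA_integer_
  if (!is.null(ped)) {
    par <- ped_parents(ped, graph$ids[i])
    sire_idx <- match(par[["sire"]], graph$ids)
    dam_idx <- match(par[["dam"]], graph$ids)
  }
  if (!is.na(sire_idx) || !is.na(dam_idx)) {
    pq <- mq <- rep(FALSE, length(nb))
    if (!is.na(sire_idx))
      pq <- nb == sire_idx | nb %in% graph_neighbors(graph, sire_idx)
    if (!is.na(dam_idx))
      mq <- nb == dam_idx | nb %in% graph_neighbors(graph, dam_idx)
    lab <- integer(length(nb))
    lab[pq & !mq] <- 1L
    lab[mq & !pq] <- 2L
  } else {
    # anchor clustering
    sh <- graph_shared(graph, i)
    anchor <- nb[which.max(sh)]
    lab <- integer(length(nb))
    pat <- nb == anchor | nb %in% graph_neighbors(graph, anchor)
    lab[pat] <- 1L
    for (k in which(!pat)) {
      cnt <- opposing_and_shared(graph$packed, nb[k], anchor, graph$core)
      if (cnt[["n_shared"]] >= params$min_shared_markers &&
          cnt[["n_opposing"]] >
            floor(params$surrogate_disagree_frac * cnt[["n_shared"]]))
        lab[k] <- 2L
    }
  }
  out <- c("unknown", "paternal", "maternal")[lab + 1L]
  names(out) <- graph$ids[nb]
  out
}

# side labels for every adjacency slot at once (C++ bulk path; equals
# partition_sides applied per individual)
assign_sides_all <- function(graph, ped) {
  n <- graph$n
  sire <- dam <- rep(-1L, n)
  if (!is.null(ped)) {
    k <- match(graph$ids, ped$id)
    sire <- match(ped$sire[k], graph$ids)
    dam <- match(ped$dam[k], graph$ids)
    sire[is.na(sire)] <- 0L
    dam[is.na(dam)] <- 0L
    sire <- sire - 1L
    dam <- dam - 1L
  }
  packed <- graph$packed
  cpp_assign_sides(graph$adj_ptr, graph$adj_idx, graph$adj_sh, sire, dam,
                   packed$hom_ref, packed$hom_alt, packed$miss,
                   as.integer(graph$core[1L]), as.integer(graph$core[2L]),
                   packed$block_bits, packed$n_snps,
                   graph$params$min_shared_markers,
                   graph$params$surrogate_disagree_frac)
}

#' Long-range phasing of one core
#'
#' For each individual, each side and each core SNP, votes are collected
#' over surrogate chains: the chain starts with a surrogate on that side,
#' continues through surrogates-of-surrogates that are heterozygous or
#' missing at the SNP, and ends at the first individual homozygous at the
#' SNP, whose allele is the vote.  At most `max_surrogates` votes are used,
#' preferring the shortest chains (and, within a depth, the most reliable
#' surrogates), down to depth `max_surrogate_depth`.  The allele is set
#' when one allele holds a strict plurality with vote share at least
#' `consensus_agreement_frac`; otherwise it stays unphased.  The opposite
#' gamete is then completed from the genotype, and the output never
#' contradicts the genotype: homozygous SNPs are phased directly and
#' contradictory votes at heterozygous SNPs are blanked.
#'
#' @param graph A `surrogate_graph` built for the core.
#' @param ped A [pedigree()] or `NULL`; used to orient sides.
#' @param genotypes Optional genotype matrix for the same individuals (saves
#'   an unpack).
#' @return List with matrices `pat` and `mat` (individuals x core SNPs,
#'   alleles 0/1, `NA` unphased), rows named by identifier.
#' @export
phase_core_lrp <- function(graph, ped = NULL, genotypes = NULL) {
  params <- graph$params
  core <- graph$core
  if (is.null(genotypes)) genotypes <- unpack_genotypes(graph$packed)
  gcore <- genotypes[, core_cols(core), drop = FALSE]
  codes <- t(gcore)
  codes[is.na(codes)] <- -1L
  storage.mode(codes) <- "integer"
  side <- assign_sides_all(graph, ped)
  votes <- cpp_lrp_votes(codes, graph$adj_ptr, graph$adj_idx, side,
                         params$max_surrogates, params$max_surrogate_depth,
                         params$consensus_agreement_frac)
  pat <- t(votes$pat)
  mat <- t(votes$mat)
  pat[pat < 0L] <- NA_integer_
  mat[mat < 0L] <- NA_integer_
  res <- finish_pair_from_genotype(gcore, pat, mat)
  rownames(res$pat) <- rownames(res$mat) <- graph$ids
  res
}

# enforce genotype consistency and fill by complementation (vectorized)
finish_pair_from_genotype <- function(g, pat, mat) {
  hom <- !is.na(g) & g != 1L
  forced <- g %/% 2L
  pat[hom] <- forced[hom]
  mat[hom] <- forced[hom]
  het <- !is.na(g) & g == 1L
  clash <- het & !is.na(pat) & !is.na(mat) & pat == mat
  pat[clash] <- NA_integer_
  mat[clash] <- NA_integer_
  fill_m <- het & !is.na(pat) & is.na(mat)
  mat[fill_m] <- 1L - pat[fill_m]
  fill_p <- het & is.na(pat) & !is.na(mat)
  pat[fill_p] <- 1L - mat[fill_p]
  list(pat = pat, mat = mat)
}
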