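#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Genotype codes are ints: 0, 1, 2, NA (missing).  Haplotype alleles are
// ints: 0, 1, -1 (missing/unphased).  Packed planes are n_blocks x n_ind
// integer matrices; each block holds `block_bits` SNPs (LSB = lowest SNP
// index within the block).  Only block_bits <= 32 is supported; bits beyond
// n_snps are zero in every plane.

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  x = x - ((x >> 1) & 0x55555555u);
  x = (x & 0x33333333u) + ((x >> 2) & 0x33333333u);
  x = (x + (x >> 4)) & 0x0F0F0F0Fu;
  return (int)((x * 0x01010101u) >> 24);
#endif
}

// mask with bits lo..hi (inclusive) set, 0 <= lo <= hi <= 31
static inline uint32_t bit_range_mask(int lo, int hi) {
  uint64_t m = ((uint64_t(1) << (hi - lo + 1)) - 1) << lo;
  return (uint32_t)m;
}

// [[Rcpp::export]]
List cpp_pack(IntegerMatrix codes, int block_bits) {
  if (block_bits < 1 || block_bits > 32)
    stop("block_bits must be in 1..32");
  int n_ind = codes.nrow(), n_snps = codes.ncol();
  int n_blocks = (n_snps + block_bits - 1) / block_bits;
  IntegerMatrix hom_ref(n_blocks, n_ind), hom_alt(n_blocks, n_ind),
      miss(n_blocks, n_ind);
  for (int i = 0; i < n_ind; ++i) {
    for (int p = 0; p < n_snps; ++p) {
      int g = codes(i, p);
      int b = p / block_bits, o = p % block_bits;
      uint32_t bit = uint32_t(1) << o;
      if (g == NA_INTEGER) {
        miss(b, i) = (int)((uint32_t)miss(b, i) | bit);
      } else if (g == 0) {
        hom_ref(b, i) = (int)((uint32_t)hom_ref(b, i) | bit);
      } else if (g == 2) {
        hom_alt(b, i) = (int)((uint32_t)hom_alt(b, i) | bit);
      } else if (g != 1) {
        stop("invalid genotype code %d at individual %d, SNP %d", g, i + 1,
             p + 1);
      }
    }
  }
  return List::create(_["hom_ref"] = hom_ref, _["hom_alt"] = hom_alt,
                      _["miss"] = miss);
}

// [[Rcpp::export]]
IntegerMatrix cpp_unpack(IntegerMatrix hom_ref, IntegerMatrix hom_alt,
                         IntegerMatrix miss, int n_snps, int block_bits) {
  int n_ind = hom_ref.ncol();
  IntegerMatrix codes(n_ind, n_snps);
  for (int i = 0; i < n_ind; ++i) {
    for (int p = 0; p < n_snps; ++p) {
      int b = p / block_bits, o = p % block_bits;
      uint32_t bit = uint32_t(1) << o;
      if ((uint32_t)miss(b, i) & bit)
        codes(i, p) = NA_INTEGER;
      else if ((uint32_t)hom_ref(b, i) & bit)
        codes(i, p) = 0;
      else if ((uint32_t)hom_alt(b, i) & bit)
        codes(i, p) = 2;
      else
        codes(i, p) = 1;
    }
  }
  return codes;
}

// opposing homozygotes and shared (both-observed) marker counts for one
// pair over SNP range [start, end) (0-based half-open)
static void pair_counts_core(const int *hr_i, const int *ha_i, const int *mi_i,
                             const int *hr_j, const int *ha_j, const int *mi_j,
                             int start, int end, int block_bits, int n_snps,
                             int *opposing, int *shared) {
  int opp = 0, sh = 0;
  if (end > start) {
    int b0 = start / block_bits, b1 = (end - 1) / block_bits;
    for (int b = b0; b <= b1; ++b) {
      int lo = (b == b0) ? start % block_bits : 0;
      int hi = (b == b1) ? (end - 1) % block_bits : block_bits - 1;
      uint32_t m = bit_range_mask(lo, hi);
      uint32_t o = ((uint32_t)hr_i[b] & (uint32_t)ha_j[b]) |
                   ((uint32_t)ha_i[b] & (uint32_t)hr_j[b]);
      uint32_t nm = ~((uint32_t)mi_i[b] | (uint32_t)mi_j[b]);
      opp += popcount32(o & m);
      sh += popcount32(nm & m);
    }
  }
  *opposing = opp;
  *shared = sh;
}

// [[Rcpp::export]]
IntegerVector cpp_pair_counts(IntegerMatrix hom_ref, IntegerMatrix hom_alt,
                              IntegerMatrix miss, int i, int j, int start,
                              int end, int block_bits, int n_snps) {
  // i, j are 0-based column indices
  int nb = hom_ref.nrow();
  const int *hr = INTEGER(hom_ref), *ha = INTEGER(hom_alt),
            *mi = INTEGER(miss);
  int opp, sh;
  pair_counts_core(hr + (size_t)nb * i, ha + (size_t)nb * i,
                   mi + (size_t)nb * i, hr + (size_t)nb * j,
                   ha + (size_t)nb * j, mi + (size_t)nb * j, start, end,
                   block_bits, n_snps, &opp, &sh);
  return IntegerVector::create(opp, sh);
}

// all-against-all surrogate detection within a core.  Returns the edge
// list (i, j, n_opposing, n_shared; 0-based, i < j) together with a CSR
// adjacency whose neighbour lists are sorted by evidence quality: fewest
// opposing homozygotes, then most shared markers, then index.  Chain voting
// consumes neighbours in this order.
// [[Rcpp::export]]
List cpp_build_graph(IntegerMatrix hom_ref, IntegerMatrix hom_alt,
                     IntegerMatrix miss, int start, int end, int block_bits,
                     int n_snps, int min_shared, double disagree_frac) {
  int n_ind = hom_ref.ncol(), nb = hom_ref.nrow();
  const int *hr = INTEGER(hom_ref), *ha = INTEGER(hom_alt),
            *mi = INTEGER(miss);
  std::vector<int> ei, ej, eo, es;
  for (int i = 0; i < n_ind; ++i) {
    const int *hri = hr + (size_t)nb * i, *hai = ha + (size_t)nb * i,
              *mii = mi + (size_t)nb * i;
    for (int j = i + 1; j < n_ind; ++j) {
      int opp, sh;
      pair_counts_core(hri, hai, mii, hr + (size_t)nb * j,
                       ha + (size_t)nb * j, mi + (size_t)nb * j, start, end,
                       block_bits, n_snps, &opp, &sh);
      if (sh >= min_shared && opp <= (int)std::floor(disagree_frac * sh)) {
        ei.push_back(i);
        ej.push_back(j);
        eo.push_back(opp);
        es.push_back(sh);
      }
    }
  }
  size_t ne = ei.size();
  IntegerMatrix edges(ne, 4);
  for (size_t e = 0; e < ne; ++e) {
    edges(e, 0) = ei[e];
    edges(e, 1) = ej[e];
    edges(e, 2) = eo[e];
    edges(e, 3) = es[e];
  }
  colnames(edges) = CharacterVector::create("i", "j", "n_opposing",
                                            "n_shared");
  // CSR with both directions
  std::vector<int> deg(n_ind, 0);
  for (size_t e = 0; e < ne; ++e) { ++deg[ei[e]]; ++deg[ej[e]]; }
  IntegerVector adj_ptr(n_ind + 1);
  for (int v = 0; v < n_ind; ++v) adj_ptr[v + 1] = adj_ptr[v] + deg[v];
  size_t tot = 2 * ne;
  IntegerVector adj_idx(tot), adj_opp(tot), adj_sh(tot);
  std::vector<int> fill(n_ind, 0);
  for (size_t e = 0; e < ne; ++e) {
    int a = ei[e], b = ej[e];
    int pa = adj_ptr[a] + fill[a]++;
    adj_idx[pa] = b; adj_opp[pa] = eo[e]; adj_sh[pa] = es[e];
    int pb = adj_ptr[b] + fill[b]++;
    adj_idx[pb] = a; adj_opp[pb] = eo[e]; adj_sh[pb] = es[e];
  }
  // per-node quality sort
  std::vector<int> ord;
  std::vector<int> ti, to, ts;
  for (int v = 0; v < n_ind; ++v) {
    int lo = adj_ptr[v], hi = adj_ptr[v + 1];
    int m = hi - lo;
    if (m < 2) continue;
    ord.resize(m);
    for (int k = 0; k < m; ++k) ord[k] = lo + k;
    std::sort(ord.begin(), ord.end(), [&](int x, int y) {
      if (adj_opp[x] != adj_opp[y]) return adj_opp[x] < adj_opp[y];
      if (adj_sh[x] != adj_sh[y]) return adj_sh[x] > adj_sh[y];
      return adj_idx[x] < adj_idx[y];
    });
    ti.assign(m, 0); to.assign(m, 0); ts.assign(m, 0);
    for (int k = 0; k < m; ++k) {
      ti[k] = adj_idx[ord[k]];
      to[k] = adj_opp[ord[k]];
      ts[k] = adj_sh[ord[k]];
    }
    for (int k = 0; k < m; ++k) {
      adj_idx[lo + k] = ti[k];
      adj_opp[lo + k] = to[k];
      adj_sh[lo + k] = ts[k];
    }
  }
  return List::create(_["edges"] = edges, _["adj_ptr"] = adj_ptr,
                      _["adj_idx"] = adj_idx, _["adj_opp"] = adj_opp,
                      _["adj_sh"] = adj_sh);
}

// Paternal/maternal side labels for every (individual, neighbour) pair of
// the surrogate graph (1 paternal, 2 maternal, 0 unknown), the bulk
// counterpart of the per-individual R function.
//
// With a parent available in the set (sire/dam as 0-based index, -1 when
// absent): a surrogate qualifies paternally when it is the sire or a
// surrogate of the sire, maternally symmetrically; qualifying for both or
// neither leaves it unknown.  Without parents, anchor clustering: the
// surrogate sharing most markers (first in adjacency on ties) anchors the
// paternal side; surrogates of the anchor are paternal; surrogates with an
// opposing-homozygote conflict against the anchor beyond the disagreement
// allowance (given enough shared markers to test) are maternal.
// [[Rcpp::export]]
IntegerVector cpp_assign_sides(IntegerVector adj_ptr, IntegerVector adj_idx,
                               IntegerVector adj_sh, IntegerVector sire,
                               IntegerVector dam, IntegerMatrix hom_ref,
                               IntegerMatrix hom_alt, IntegerMatrix miss,
                               int start, int end, int block_bits, int n_snps,
                               int min_shared, double disagree_frac) {
  int n_ind = adj_ptr.size() - 1;
  int nb = hom_ref.nrow();
  const int *hr = INTEGER(hom_ref), *ha = INTEGER(hom_alt),
            *mi = INTEGER(miss);
  IntegerVector side(adj_idx.size());
  std::vector<int> stamp(n_ind, -1), stamp2(n_ind, -1);
  int cur = -1;
  for (int i = 0; i < n_ind; ++i) {
    int lo = adj_ptr[i], hi = adj_ptr[i + 1];
    if (lo == hi) continue;
    int s = sire[i], d = dam[i];
    ++cur;
    if (s >= 0 || d >= 0) {
      if (s >= 0)
        for (int e = adj_ptr[s]; e < adj_ptr[s + 1]; ++e)
          stamp[adj_idx[e]] = cur;
      if (d >= 0)
        for (int e = adj_ptr[d]; e < adj_ptr[d + 1]; ++e)
          stamp2[adj_idx[e]] = cur;
      for (int e = lo; e < hi; ++e) {
        int v = adj_idx[e];
        bool pq = (s >= 0) && (v == s || stamp[v] == cur);
        bool mq = (d >= 0) && (v == d || stamp2[v] == cur);
        side[e] = (pq && !mq) ? 1 : (mq && !pq) ? 2 : 0;
      }
      continue;
    }
    // anchor clustering
    int best = lo;
    for (int e = lo + 1; e < hi; ++e)
      if (adj_sh[e] > adj_sh[best]) best = e;
    int anchor = adj_idx[best];
    for (int e = adj_ptr[anchor]; e < adj_ptr[anchor + 1]; ++e)
      stamp[adj_idx[e]] = cur;
    const int *hra = hr + (size_t)nb * anchor, *haa = ha + (size_t)nb * anchor,
              *mia = mi + (size_t)nb * anchor;
    for (int e = lo; e < hi; ++e) {
      int v = adj_idx[e];
      if (v == anchor || stamp[v] == cur) {
        side[e] = 1;
      } else {
        int opp, sh;
        pair_counts_core(hr + (size_t)nb * v, ha + (size_t)nb * v,
                         mi + (size_t)nb * v, hra, haa, mia, start, end,
                         block_bits, n_snps, &opp, &sh);
        if (sh >= min_shared && opp > (int)std::floor(disagree_frac * sh))
          side[e] = 2;
      }
    }
  }
  return side;
}

// Surrogate-chain consensus voting for one core.
//
// codes: core SNPs x n_ind genotype codes (0/1/2, -1 missing)
// adj_ptr/adj_idx: CSR adjacency of the (unlabeled) surrogate graph,
//   0-based, neighbour lists sorted by evidence quality; side is parallel
//   to adj_idx (1 paternal, 2 maternal, 0 unknown, w.r.t. the row
//   individual).
// Voting at SNP p for individual i, side s: breadth-first over chains whose
// first link has side s; a discovered individual homozygous at p
// contributes one vote (its allele) and is not expanded;
// heterozygous-or-missing individuals are expanded through all their
// surrogates.  Votes accumulate in increasing chain depth (adjacency order
// within a depth) and stop at max_surrogates or depth max_depth.  The
// allele is set when one allele holds a strict plurality with share >=
// consensus_frac.
// [[Rcpp::export]]
List cpp_lrp_votes(IntegerMatrix codes, IntegerVector adj_ptr,
                   IntegerVector adj_idx, IntegerVector side,
                   int max_surrogates, int max_depth, double consensus_frac) {
  int n_core = codes.nrow(), n_ind = codes.ncol();
  IntegerMatrix pat(n_core, n_ind), mat(n_core, n_ind);
  std::fill(pat.begin(), pat.end(), -1);
  std::fill(mat.begin(), mat.end(), -1);
  std::vector<int> stamp(n_ind, -1);
  std::vector<int> frontier, next_frontier;
  frontier.reserve(n_ind);
  next_frontier.reserve(n_ind);
  const int *ap = INTEGER(adj_ptr), *ai = INTEGER(adj_idx),
            *as = INTEGER(side), *cd = INTEGER(codes);
  int cur = 0;
  for (int i = 0; i < n_ind; ++i) {
    for (int s = 1; s <= 2; ++s) {
      bool any_first = false;
      for (int e = ap[i]; e < ap[i + 1]; ++e)
        if (as[e] == s) { any_first = true; break; }
      if (!any_first) continue;
      IntegerMatrix &out = (s == 1) ? pat : mat;
      for (int p = 0; p < n_core; ++p) {
        int gi = cd[(size_t)n_core * i + p];
        if (gi == 0 || gi == 2) continue; // genotype-forced by the caller
        ++cur;
        stamp[i] = cur;
        frontier.clear();
        int v0 = 0, v1 = 0;
        // depth 1: first links on this side, voting at discovery
        for (int e = ap[i]; e < ap[i + 1] && v0 + v1 < max_surrogates; ++e) {
          if (as[e] != s) continue;
          int v = adj_idx[e];
          if (stamp[v] == cur) continue;
          stamp[v] = cur;
          int gv = cd[(size_t)n_core * v + p];
          if (gv == 0) ++v0;
          else if (gv == 2) ++v1;
          else frontier.push_back(v);
        }
        int depth = 1;
        while (!frontier.empty() && depth < max_depth &&
               v0 + v1 < max_surrogates) {
          next_frontier.clear();
          for (size_t k = 0; k < frontier.size() && v0 + v1 < max_surrogates;
               ++k) {
            int u = frontier[k];
            for (int e = ap[u]; e < ap[u + 1] && v0 + v1 < max_surrogates;
                 ++e) {
              int v = ai[e];
              if (stamp[v] == cur) continue;
              stamp[v] = cur;
              int gv = cd[(size_t)n_core * v + p];
              if (gv == 0) ++v0;
              else if (gv == 2) ++v1;
              else next_frontier.push_back(v);
            }
          }
          std::swap(frontier, next_frontier);
          ++depth;
        }
        int tot = v0 + v1;
        if (tot >= 1) {
          if (v0 > v1 && (double)v0 / tot >= consensus_frac)
            out(p, i) = 0;
          else if (v1 > v0 && (double)v1 / tot >= consensus_frac)
            out(p, i) = 1;
        }
      }
    }
  }
  return List::create(_["pat"] = pat, _["mat"] = mat);
}

// in-place column write / copy on preallocated package-internal buffers
// (bypasses R's copy-on-write; only ever used on matrices owned by the
// mutable library handle)
// [[Rcpp::export]]
void cpp_set_col(IntegerMatrix M, int col, IntegerVector v) {
  if (v.size() != M.nrow()) stop("column length mismatch");
  std::copy(v.begin(), v.end(), M.begin() + (size_t)M.nrow() * (col - 1));
}

// [[Rcpp::export]]
void cpp_copy_col(IntegerMatrix M, int from, int to) {
  int nr = M.nrow();
  std::copy(M.begin() + (size_t)nr * (from - 1),
            M.begin() + (size_t)nr * from,
            M.begin() + (size_t)nr * (to - 1));
}

// entries (0-based) among the first n_used columns that match entry `a`:
// co-observed >= min_match with zero mismatches, excluding `a` itself
// [[Rcpp::export]]
IntegerVector cpp_lib_matches_of(IntegerMatrix A, IntegerMatrix K, int n_used,
                                 int a, int min_match) {
  int nb = A.nrow();
  const int *la = INTEGER(A), *lk = INTEGER(K);
  const int *aa = la + (size_t)nb * a, *ak = lk + (size_t)nb * a;
  std::vector<int> out;
  for (int b = 0; b < n_used; ++b) {
    if (b == a) continue;
    const int *ba = la + (size_t)nb * b, *bk = lk + (size_t)nb * b;
    int co = 0;
    bool mm = false;
    for (int blk = 0; blk < nb; ++blk) {
      uint32_t both = (uint32_t)ak[blk] & (uint32_t)bk[blk];
      co += popcount32(both);
      if (both & ((uint32_t)aa[blk] ^ (uint32_t)ba[blk])) { mm = true; break; }
    }
    if (!mm && co >= min_match) out.push_back(b);
  }
  return wrap(out);
}

// first pair of library entries (0-based, a < b among the first n_used
// columns) that co-observe >= min_match positions with zero mismatches;
// c(-1, -1) when none — the dedup step of library maintenance
// [[Rcpp::export]]
IntegerVector cpp_lib_first_match(IntegerMatrix A, IntegerMatrix K,
                                  int n_used, int min_match) {
  int nb = A.nrow();
  const int *la = INTEGER(A), *lk = INTEGER(K);
  for (int a = 0; a + 1 < n_used; ++a) {
    const int *aa = la + (size_t)nb * a, *ak = lk + (size_t)nb * a;
    for (int b = a + 1; b < n_used; ++b) {
      const int *ba = la + (size_t)nb * b, *bk = lk + (size_t)nb * b;
      int co = 0;
      bool mm = false;
      for (int blk = 0; blk < nb; ++blk) {
        uint32_t both = (uint32_t)ak[blk] & (uint32_t)bk[blk];
        co += popcount32(both);
        if (both & ((uint32_t)aa[blk] ^ (uint32_t)ba[blk])) { mm = true; break; }
      }
      if (!mm && co >= min_match) return IntegerVector::create(a, b);
    }
  }
  return IntegerVector::create(-1, -1);
}

// packed haplotype-vs-library counts over the first n_used entry columns:
// co-observed = popcount(known_h & known_e), mismatches = popcount of the
// co-observed XOR of the allele planes
// [[Rcpp::export]]
IntegerMatrix cpp_hap_match_counts_packed_n(IntegerVector ha,
                                            IntegerVector hk,
                                            IntegerMatrix A, IntegerMatrix K,
                                            int n_used) {
  int nb = A.nrow();
  if (ha.size() != nb || hk.size() != nb)
    stop("packed haplotype length does not match library");
  if (n_used > A.ncol()) stop("n_used exceeds library capacity");
  IntegerMatrix res(n_used, 2);
  const int *pa = INTEGER(ha), *pk = INTEGER(hk), *la = INTEGER(A),
            *lk = INTEGER(K);
  for (int e = 0; e < n_used; ++e) {
    const int *ea = la + (size_t)nb * e, *ek = lk + (size_t)nb * e;
    int co = 0, mm = 0;
    for (int b = 0; b < nb; ++b) {
      uint32_t both = (uint32_t)pk[b] & (uint32_t)ek[b];
      co += popcount32(both);
      mm += popcount32(both & ((uint32_t)pa[b] ^ (uint32_t)ea[b]));
    }
    res(e, 0) = co;
    res(e, 1) = mm;
  }
  colnames(res) = CharacterVector::create("co_observed", "mismatches");
  return res;
}

// pack haplotype columns (alleles 0/1, -1 missing) into allele/known bit
// planes; 32 SNPs per block, LSB first
// [[Rcpp::export]]
List cpp_pack_alleles(IntegerMatrix haps) {
  int L = haps.nrow(), n = haps.ncol();
  int nb = (L + 31) / 32;
  if (nb == 0) nb = 1;
  IntegerMatrix A(nb, n), K(nb, n);
  for (int e = 0; e < n; ++e) {
    for (int p = 0; p < L; ++p) {
      int v = haps(p, e);
      if (v < 0) continue;
      int b = p / 32, o = p % 32;
      uint32_t bit = uint32_t(1) << o;
      K(b, e) = (int)((uint32_t)K(b, e) | bit);
      if (v == 1) A(b, e) = (int)((uint32_t)A(b, e) | bit);
    }
  }
  return List::create(_["alleles"] = A, _["known"] = K);
}

// One fill sweep of haplotype library imputation over all individuals, in
// input order, against a fixed (start-of-sweep) library.
//
// pat/mat: L x n allele matrices (0/1, -1 unphased); codes: L x n genotype
// codes (0/1/2, -1 missing); libH: L x E entry alleles (-1 missing); libA /
// libK: packed allele/known planes of the entries (32-SNP blocks).
//
// For each gamete: match against the library (co-observed >= min_match,
// mismatches <= max_mm), fill unphased positions where all matching entries
// unanimously agree and the fill is consistent with the genotype and the
// opposite gamete, then complete the opposite gamete from the genotype.
// Returns updated matrices, per-gamete change flags and the fill count.
// [[Rcpp::export]]
List cpp_hli_fill(IntegerMatrix pat, IntegerMatrix mat, IntegerMatrix codes,
                  IntegerMatrix libH, IntegerMatrix libA, IntegerMatrix libK,
                  int n_used, int min_match, int max_mm) {
  int L = pat.nrow(), n = pat.ncol();
  int E = n_used;
  int nb = libA.nrow();
  if (E > libH.ncol()) stop("n_used exceeds library capacity");
  IntegerMatrix npat(clone(pat)), nmat(clone(mat));
  IntegerMatrix changed(n, 2);
  long long filled = 0;
  if (E == 0)
    return List::create(_["pat"] = npat, _["mat"] = nmat,
                        _["changed"] = changed, _["n_filled"] = 0);
  std::vector<uint32_t> ha(nb), hk(nb);
  std::vector<int> matches;
  const int *lh = INTEGER(libH), *la = INTEGER(libA), *lk = INTEGER(libK);
  for (int i = 0; i < n; ++i) {
    for (int gam = 0; gam < 2; ++gam) {
      IntegerMatrix &self = (gam == 0) ? npat : nmat;
      IntegerMatrix &oth = (gam == 0) ? nmat : npat;
      // pack current gamete
      std::fill(ha.begin(), ha.end(), 0u);
      std::fill(hk.begin(), hk.end(), 0u);
      for (int p = 0; p < L; ++p) {
        int v = self(p, i);
        if (v < 0) continue;
        hk[p / 32] |= uint32_t(1) << (p % 32);
        if (v == 1) ha[p / 32] |= uint32_t(1) << (p % 32);
      }
      matches.clear();
      for (int e = 0; e < E; ++e) {
        const int *ea = la + (size_t)nb * e, *ek = lk + (size_t)nb * e;
        int co = 0, mm = 0;
        for (int b = 0; b < nb; ++b) {
          uint32_t both = hk[b] & (uint32_t)ek[b];
          co += popcount32(both);
          mm += popcount32(both & (ha[b] ^ (uint32_t)ea[b]));
          if (mm > max_mm) break;
        }
        if (mm <= max_mm && co >= min_match) matches.push_back(e);
      }
      if (matches.empty()) continue;
      bool any_change = false;
      for (int p = 0; p < L; ++p) {
        if (self(p, i) >= 0) continue;
        int a = -1;
        bool conflict = false;
        for (size_t k = 0; k < matches.size(); ++k) {
          int v = lh[(size_t)L * matches[k] + p];
          if (v < 0) continue;
          if (a < 0) a = v;
          else if (a != v) { conflict = true; break; }
        }
        if (a < 0 || conflict) continue;
        int g = codes(p, i);
        if (g == 0 && a != 0) continue;
        if (g == 2 && a != 1) continue;
        if (g == 1) {
          int o = oth(p, i);
          if (o >= 0 && o == a) continue; // would contradict the genotype
        }
        self(p, i) = a;
        ++filled;
        any_change = true;
      }
      if (any_change) {
        changed(i, gam) = 1;
        // complete the opposite gamete from the genotype
        for (int p = 0; p < L; ++p) {
          if (oth(p, i) >= 0) continue;
          int g = codes(p, i);
          if (g == 0 || g == 2) {
            oth(p, i) = g / 2;
            ++filled;
            changed(i, 1 - gam) = 1;
          } else if (g == 1 && self(p, i) >= 0) {
            oth(p, i) = 1 - self(p, i);
            ++filled;
            changed(i, 1 - gam) = 1;
          }
        }
      }
    }
  }
  return List::create(_["pat"] = npat, _["mat"] = nmat,
                      _["changed"] = changed,
                      _["n_filled"] = (double)filled);
}

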