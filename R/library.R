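# Haplotype library container.
#
# Entries of one core hold: an allele vector over the core with -1 for
# missing (a partial haplotype observed on a SNP subset), a frequency
# count, and a carrier set of "<individual>#<gamete>" keys.  Alongside the
# allele matrix, bit-packed allele/known planes (32 SNPs per int block) are
# maintained so matching reduces to AND/XOR plus population counts.
#
# Two representations exist.  The public `library_core` is a plain list
# (value semantics): haps (L x E, -1 coded), alleles/known (packed), counts,
# carriers.  Internally a mutable environment handle ("lcx") with
# capacity-doubling column storage is used so that the many appends,
# merges and removals of an HLI run do not each reallocate the library;
# the exported functions are thin wrappers that convert at the boundary.

carrier_key <- function(id, gamete) paste0(id, "#", gamete)

# ---- public (compact, value-semantics) representation -------------------

empty_library_core <- function(core_length) {
  nb <- max(1L, (as.integer(core_length) + 31L) %/% 32L)
  list(haps = matrix(integer(0), nrow = core_length, ncol = 0L),
       alleles = matrix(integer(0), nrow = nb, ncol = 0L),
       known = matrix(integer(0), nrow = nb, ncol = 0L),
       counts = integer(0), carriers = list())
}

# rebuild the packed planes from the allele matrix (after bulk loads)
lc_repack <- function(lc) {
  pk <- cpp_pack_alleles(lc$haps)
  lc$alleles <- pk$alleles
  lc$known <- pk$known
  lc
}

# alleles with NA at the API edge -> internal -1 coding
hap_to_internal <- function(h) {
  h <- as.integer(h)
  h[is.na(h)] <- -1L
  h
}

# ---- mutable handle ------------------------------------------------------
#
# Carrier bookkeeping uses a hash map key -> entry id plus a union-find
# alias table: when entries merge, the old ids are aliased to the merged
# entry's id and the carrier records never move.  col_of maps a live entry
# id to its storage column; ncarr counts carriers per column.

lcx_new <- function(core_length, capacity = 64L) {
  nb <- max(1L, (as.integer(core_length) + 31L) %/% 32L)
  e <- new.env(parent = emptyenv())
  e$L <- as.integer(core_length)
  e$nb <- nb
  e$n <- 0L
  e$haps <- matrix(-1L, core_length, capacity)
  e$alleles <- matrix(0L, nb, capacity)
  e$known <- matrix(0L, nb, capacity)
  e$counts <- integer(capacity)
  e$ncarr <- integer(capacity)
  e$entry_ids <- integer(capacity)
  e$next_id <- 1L
  e$alias <- integer(0)    # indexed by entry id; 0 = dead, self = live
  e$col_of <- integer(0)   # indexed by entry id; 0 = not stored
  e$cmap <- new.env(hash = TRUE, parent = emptyenv())
  e$dirty <- integer(0)  # entry ids appended since the last maintenance
  e
}

lcx_resolve <- function(e, eid) {
  al <- e$alias
  while (al[eid] != eid) {
    eid <- al[eid]
    if (eid == 0L) return(0L)
  }
  eid
}

lcx_from_compact <- function(lc) {
  n <- ncol(lc$haps)
  e <- lcx_new(nrow(lc$haps), capacity = max(64L, 2L * n))
  for (k in seq_len(n))
    lcx_append(e, lc$haps[, k], lc$counts[k], lc$carriers[[k]])
  e
}

lcx_to_compact <- function(e) {
  n <- e$n
  sel <- seq_len(n)
  carriers <- rep(list(character(0)), n)
  keys <- ls(e$cmap)
  if (length(keys)) {
    cols <- vapply(keys, function(k) {
      eid <- lcx_resolve(e, get(k, envir = e$cmap))
      if (eid == 0L) 0L else e$col_of[eid]
    }, integer(1L))
    for (k in which(cols > 0L))
      carriers[[cols[k]]] <- c(carriers[[cols[k]]], keys[k])
  }
  list(haps = e$haps[, sel, drop = FALSE],
       alleles = e$alleles[, sel, drop = FALSE],
       known = e$known[, sel, drop = FALSE],
       counts = e$counts[sel],
       carriers = carriers)
}

lcx_grow <- function(e) {
  cap <- ncol(e$haps)
  new_cap <- 2L * cap
  h <- matrix(-1L, e$L, new_cap); h[, seq_len(cap)] <- e$haps; e$haps <- h
  a <- matrix(0L, e$nb, new_cap); a[, seq_len(cap)] <- e$alleles
  e$alleles <- a
  k <- matrix(0L, e$nb, new_cap); k[, seq_len(cap)] <- e$known; e$known <- k
  e$counts <- c(e$counts, integer(cap))
  e$ncarr <- c(e$ncarr, integer(cap))
  e$entry_ids <- c(e$entry_ids, integer(cap))
  invisible(e)
}

lcx_new_id <- function(e) {
  eid <- e$next_id
  e$next_id <- eid + 1L
  if (eid > length(e$alias)) {
    e$alias <- c(e$alias, integer(max(64L, length(e$alias))))
    e$col_of <- c(e$col_of, integer(max(64L, length(e$col_of))))
  }
  e$alias[eid] <- eid
  eid
}

lcx_append <- function(e, h, count, carriers = character(0)) {
  if (e$n == ncol(e$haps)) lcx_grow(e)
  k <- e$n + 1L
  cpp_set_col(e$haps, k, h)
  pk <- cpp_pack_alleles(matrix(h, ncol = 1L))
  cpp_set_col(e$alleles, k, pk$alleles[, 1L])
  cpp_set_col(e$known, k, pk$known[, 1L])
  e$counts[k] <- as.integer(count)
  e$ncarr[k] <- length(carriers)
  eid <- lcx_new_id(e)
  e$entry_ids[k] <- eid
  e$col_of[eid] <- k
  e$n <- k
  e$dirty <- c(e$dirty, eid)
  for (key in carriers) assign(key, eid, envir = e$cmap)
  k
}

# remove entries by column index: the last active column is swapped into
# the hole (deterministic; entry order is not part of the contract).
# Carrier records of removed entries survive as dead aliases unless the
# caller re-aliases them (merge does).
lcx_remove <- function(e, cols) {
  for (k in sort(unique(as.integer(cols)), decreasing = TRUE)) {
    n <- e$n
    dead <- e$entry_ids[k]
    e$alias[dead] <- 0L
    e$col_of[dead] <- 0L
    if (k < n) {
      cpp_copy_col(e$haps, n, k)
      cpp_copy_col(e$alleles, n, k)
      cpp_copy_col(e$known, n, k)
      e$counts[k] <- e$counts[n]
      e$ncarr[k] <- e$ncarr[n]
      e$entry_ids[k] <- e$entry_ids[n]
      e$col_of[e$entry_ids[n]] <- k
    }
    e$entry_ids[n] <- 0L
    e$n <- n - 1L
  }
  invisible(e)
}

# matching entry columns for a packed haplotype
lcx_match_packed <- function(e, ha, hk, params) {
  if (e$n == 0L) return(integer(0))
  cnt <- cpp_hap_match_counts_packed_n(ha, hk, e$alleles, e$known, e$n)
  which(as.vector(cnt[, 1L]) >= params$min_match_alleles &
          as.vector(cnt[, 2L]) <= params$library_cluster_mismatches)
}

lcx_match <- function(e, h, params) {
  pk <- cpp_pack_alleles(matrix(h, ncol = 1L))
  lcx_match_packed(e, pk$alleles[, 1L], pk$known[, 1L], params)
}

# first allele observed by any source per position (sources must agree)
merge_alleles <- function(src) {
  m <- src[, 1L]
  for (k in seq_len(ncol(src))[-1L]) {
    miss <- m < 0L
    if (!any(miss)) break
    m[miss] <- src[miss, k]
  }
  m
}

# pairwise conflict test among columns of an L x k matrix (-1 coded)
any_pairwise_conflict <- function(m) {
  k <- ncol(m)
  if (k < 2L) return(FALSE)
  for (a in seq_len(k - 1L)) {
    ha <- m[, a]
    for (b in (a + 1L):k) {
      hb <- m[, b]
      if (any(ha >= 0L & hb >= 0L & ha != hb)) return(TRUE)
    }
  }
  FALSE
}

# merge entries (and optionally an extra haplotype) into one; returns the
# merged entry's column.  Old entry ids are aliased to the merged id, so
# carriers follow without being touched.
lcx_merge <- function(e, cols, h = NULL, check = TRUE) {
  cols <- as.integer(cols)
  src <- e$haps[, cols, drop = FALSE]
  if (!is.null(h)) src <- cbind(src, h, deparse.level = 0L)
  if (check && any_pairwise_conflict(src))
    stopf("cannot merge: sources conflict at a co-observed position")
  merged <- merge_alleles(src)
  count <- sum(e$counts[cols])
  ncarr <- sum(e$ncarr[cols])
  old_ids <- e$entry_ids[cols]
  lcx_remove(e, cols)
  k <- lcx_append(e, merged, count)
  e$ncarr[k] <- ncarr
  e$alias[old_ids] <- e$entry_ids[k]
  k
}

# column currently holding a carrier key, or 0
lcx_carrier_col <- function(e, key) {
  eid <- e$cmap[[key]]
  if (is.null(eid)) return(0L)
  eid <- lcx_resolve(e, eid)
  if (eid == 0L) 0L else e$col_of[eid]
}

# drop a carrier key from whichever entry holds it, decrementing the count;
# entries left with no count and no carriers are removed
lcx_remove_carrier <- function(e, key) {
  k <- lcx_carrier_col(e, key)
  if (k == 0L) {
    if (!is.null(e$cmap[[key]])) rm(list = key, envir = e$cmap)
    return(invisible(FALSE))
  }
  rm(list = key, envir = e$cmap)
  e$counts[k] <- e$counts[k] - 1L
  e$ncarr[k] <- e$ncarr[k] - 1L
  if (e$counts[k] <= 0L && e$ncarr[k] <= 0L) lcx_remove(e, k)
  invisible(TRUE)
}

# admit a candidate haplotype: reject / insert / merge (see update_library)
lcx_update <- function(e, h, carrier, genotyped, params) {
  denom <- sum(genotyped)
  frac <- if (denom == 0L) 0 else sum(h >= 0L & genotyped) / denom
  if (frac < params$min_phased_frac_library) return("rejected")
  key <- carrier_key(carrier[1L], carrier[2L])
  lcx_remove_carrier(e, key)
  matches <- lcx_match(e, h, params)
  if (length(matches)) {
    src <- cbind(e$haps[, matches, drop = FALSE], h, deparse.level = 0L)
    if (!any_pairwise_conflict(src)) {
      k <- lcx_merge(e, matches, h, check = FALSE)
      e$counts[k] <- e$counts[k] + 1L
      if (lcx_carrier_col(e, key) != k) {
        assign(key, e$entry_ids[k], envir = e$cmap)
        e$ncarr[k] <- e$ncarr[k] + 1L
      }
      return("merged")
    }
    # matched entries cannot all be the same haplotype: keep them, add new
  }
  lcx_append(e, h, 1L, key)
  "inserted"
}

# merge mutually matching, conflict-free entry pairs until none remain.
# Only entries appended since the last maintenance (the dirty queue) can be
# part of a new matching pair: every clean entry was checked against all
# entries present when it went clean.
lcx_maintain <- function(e, params) {
  changed <- FALSE
  while (length(e$dirty)) {
    eid <- e$dirty[1L]
    e$dirty <- e$dirty[-1L]
    eid <- lcx_resolve(e, eid)
    if (eid == 0L) next
    k <- e$col_of[eid]
    if (k == 0L || e$n < 2L) next
    hits <- cpp_lib_matches_of(e$alleles, e$known, e$n, k - 1L,
                               params$min_match_alleles) + 1L
    if (length(hits)) {
      # merge pairwise-compatible hits with k; incompatible ones stay
      src <- e$haps[, c(k, hits), drop = FALSE]
      if (any_pairwise_conflict(src)) {
        ok <- integer(0)
        cur <- e$haps[, k]
        for (b in hits) {
          cand <- e$haps[, b]
          if (!any(cur >= 0L & cand >= 0L & cur != cand)) {
            trial <- cand
            m <- cur < 0L
            trial[m] <- cand[m]
            # ensure pairwise compatibility with already accepted hits
            okc <- TRUE
            for (o in ok) {
              ho <- e$haps[, o]
              if (any(ho >= 0L & cand >= 0L & ho != cand)) { okc <- FALSE; break }
            }
            if (okc) ok <- c(ok, b)
          }
        }
        hits <- ok
      }
      if (length(hits)) {
        lcx_merge(e, c(k, hits), check = FALSE)
        changed <- TRUE
      }
    }
  }
  changed
}

# ---- public API ----------------------------------------------------------

#' Create an empty haplotype library
#'
#' @param cores Core matrix from [partition_cores()], or `NULL` when the
#'   core layout is implied by entry lengths (as after [load_library()]).
#' @param n_cores Number of cores when `cores` is `NULL`.
#' @return An object of class `haplotype_library`.
#' @export
haplotype_library <- function(cores = NULL, n_cores = if (is.null(cores)) 0L
                              else nrow(cores)) {
  entries <- vector("list", n_cores)
  if (!is.null(cores))
    for (ci in seq_len(n_cores))
      entries[[ci]] <- empty_library_core(cores[ci, 2L] - cores[ci, 1L])
  structure(list(cores = cores, entries = entries),
            class = "haplotype_library")
}

#' @export
print.haplotype_library <- function(x, ...) {
  ne <- vapply(x$entries, function(e) if (is.null(e)) 0L else ncol(e$haps),
               integer(1L))
  cat(sprintf("Haplotype library: %d cores, %d entries\n", length(x$entries),
              sum(ne)))
  invisible(x)
}

#' Match a partial haplotype against the library entries of a core
#'
#' An entry matches when the number of positions observed in both the
#' haplotype and the entry is at least `min_match_alleles` and the number of
#' mismatches among those positions is at most
#' `library_cluster_mismatches`.  Requiring many co-observed alleles guards
#' against identifying two distinct haplotypes that were genotyped on
#' different arrays and happen to agree on a few overlapping SNPs.  Counts
#' are computed on bit-packed planes.
#'
#' @param h Allele vector over the core (0/1, `NA` or -1 missing).
#' @param library_core Library entries of one core.
#' @param params A [phasing_params()] object.
#' @return Integer vector of matching entry indices.
#' @export
match_haplotype <- function(h, library_core, params) {
  if (ncol(library_core$haps) == 0L) return(integer(0))
  pk <- cpp_pack_alleles(matrix(hap_to_internal(h), ncol = 1L))
  cnt <- cpp_hap_match_counts_packed_n(pk$alleles[, 1L], pk$known[, 1L],
                                       library_core$alleles,
                                       library_core$known,
                                       ncol(library_core$haps))
  which(as.vector(cnt[, 1L]) >= params$min_match_alleles &
          as.vector(cnt[, 2L]) <= params$library_cluster_mismatches)
}

#' Merge library entries (and optionally a new haplotype) into one
#'
#' The sources must be pairwise conflict-free at co-observed positions.  The
#' merged entry is observed on the union of the sources' observed positions
#' (each allele taken from whichever source observes it), carries the union
#' of the carrier sets, and sums the frequency counts.  The replaced entries
#' are removed and the merged entry appended; entry order within a core
#' carries no meaning.
#'
#' @param library_core Library entries of one core.
#' @param entry_ids Indices of the entries to merge.
#' @param h Optional additional allele vector merged in (contributes alleles
#'   but no count; the caller accounts for the new carrier).
#' @return List with the updated `library_core` and `merged_id`.
#' @export
merge_library_entries <- function(library_core, entry_ids, h = NULL) {
  e <- lcx_from_compact(library_core)
  if (!is.null(h)) h <- hap_to_internal(h)
  k <- lcx_merge(e, entry_ids, h)
  list(library_core = lcx_to_compact(e), merged_id = k)
}

#' Insert or merge a candidate haplotype into a core's library
#'
#' The candidate is rejected when its phased fraction — computed over the
#' carrier's genotyped SNPs within the core — is below
#' `min_phased_frac_library`.  Otherwise it is matched against the library:
#' with no match it is inserted as a new entry; when all matched entries are
#' pairwise compatible they are merged with the candidate (duplicate
#' partial haplotypes from different arrays collapse to one); when the
#' matched entries conflict with each other (they cannot be the same
#' haplotype) the candidate is inserted as a new entry and the matched
#' entries are left untouched.
#'
#' @param library_core Library entries of one core.
#' @param h Candidate allele vector over the core (NA/-1 missing).
#' @param carrier Length-2 vector `c(individual_id, gamete)`.
#' @param genotyped Logical vector over the core: the carrier's genotyped
#'   SNPs (the phased-fraction denominator).
#' @param params A [phasing_params()] object.
#' @return The updated `library_core`, with attribute `action` one of
#'   `"rejected"`, `"inserted"`, `"merged"`.
#' @export
update_library <- function(library_core, h, carrier, genotyped, params) {
  e <- lcx_from_compact(library_core)
  action <- lcx_update(e, hap_to_internal(h), carrier, genotyped, params)
  out <- lcx_to_compact(e)
  attr(out, "action") <- action
  out
}
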