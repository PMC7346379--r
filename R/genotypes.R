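#' Construct and validate a genotype matrix
#'
#' Genotypes are stored as a plain integer matrix, one row per individual
#' (row names are the identifiers) and one column per SNP.  Codes are 0
#' (homozygous reference), 1 (heterozygous), 2 (homozygous alternate) and
#' `NA` (missing, e.g. a SNP absent from the individual's array).
#'
#' @param codes Integer matrix (or coercible) of genotype codes.
#' @param ids Character vector of unique individual identifiers; defaults to
#'   existing row names.
#' @return A validated integer genotype matrix with row names.
#' @export
genotype_matrix <- function(codes, ids = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(ids)) ids <- paste0("ID", seq_len(nrow(codes)))
  ids <- as.character(ids)
  if (length(ids) != nrow(codes))
    stopf("length(ids) (%d) != number of rows (%d)", length(ids), nrow(codes))
  if (anyDuplicated(ids)) stopf("individual identifiers must be unique")
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) {
    w <- which(bad)[1L]
    stopf("invalid genotype code %s at row %d, SNP %d",
          codes[w], (w - 1L) %% nrow(codes) + 1L, (w - 1L) %/% nrow(codes) + 1L)
  }
  rownames(codes) <- ids
  codes
}

#' Construct and validate a pedigree
#'
#' @param id Character vector of individual identifiers.
#' @param sire,dam Character vectors of parent identifiers; `NA` (or `"0"`)
#'   means unknown.  Parents that are not themselves listed as individuals
#'   are recorded as external founders.
#' @return A `data.frame` with columns `id`, `sire`, `dam` and attribute
#'   `external_founders`; class `c("pedigree", "data.frame")`.
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  sire[sire %in% "0"] <- NA_character_
  dam[dam %in% "0"] <- NA_character_
  if (anyDuplicated(id)) stopf("duplicated individual in pedigree: %s",
                               id[duplicated(id)][1L])
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stopf("individual '%s' is listed as its own parent", id[self[1L]])
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  # cycle check: no individual may be its own ancestor (iterative DFS)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  state <- integer(length(id)) # 0 unvisited, 1 in progress, 2 done
  for (v in seq_along(id)) {
    if (state[v] != 0L) next
    stack <- list(c(v, 0L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      u <- fr[1L]
      if (fr[2L] == 0L) {
        if (state[u] == 1L)
          stopf("pedigree contains a cycle involving '%s'", id[u])
        state[u] <- 1L
        stack[[length(stack)]] <- c(u, 1L)
        for (pu in c(si[u], di[u]))
          if (!is.na(pu) && state[pu] != 2L) {
            if (state[pu] == 1L)
              stopf("pedigree contains a cycle involving '%s'", id[pu])
            stack[[length(stack) + 1L]] <- c(pu, 0L)
          }
      } else {
        state[u] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  ext <- sort(unique(c(sire[!is.na(sire) & !(sire %in% id)],
                       dam[!is.na(dam) & !(dam %in% id)])))
  attr(ped, "external_founders") <- ext
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# sire/dam of one individual (NA if unknown or individual absent)
ped_parents <- function(ped, ind) {
  k <- match(ind, ped$id)
  if (is.na(k)) return(c(sire = NA_character_, dam = NA_character_))
  c(sire = ped$sire[k], dam = ped$dam[k])
}
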