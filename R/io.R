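#' Read a genotype file
#'
#' Whitespace-delimited text, one individual per line: identifier followed
#' by one code per SNP (0/1/2, with `missing_code` for missing).
#'
#' @param path File path.
#' @param missing_code Integer code used on disk for missing genotypes
#'   (default 9).
#' @return A genotype matrix (see [genotype_matrix()]).
#' @export
read_genotypes <- function(path, missing_code = 9L) {
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("genotype file is empty: %s", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L)
    stopf("unequal row lengths in %s: line %d has %d fields, line 1 has %d",
          path, which(lens != lens[1L])[1L], lens[lens != lens[1L]][1L],
          lens[1L])
  if (lens[1L] < 2L) stopf("genotype rows need an id and at least one SNP")
  ids <- vapply(toks, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(toks, function(tk) as.integer(tk[-1L]), integer(lens[1L] - 1L)))
  codes <- t(vals)
  ok <- codes %in% c(0L, 1L, 2L, as.integer(missing_code)) & !is.na(codes)
  if (!all(ok)) {
    w <- which(!ok)[1L]
    ln <- (w - 1L) %% nrow(codes) + 1L
    stopf("invalid genotype code on line %d of %s", ln, path)
  }
  codes[codes == as.integer(missing_code)] <- NA_integer_
  genotype_matrix(codes, ids)
}

#' Write a genotype file
#'
#' @param genotypes Genotype matrix.
#' @param path Output path.
#' @param missing_code Code written for missing genotypes (default 9).
#' @export
write_genotypes <- function(genotypes, path, missing_code = 9L) {
  g <- genotypes
  g[is.na(g)] <- as.integer(missing_code)
  lines <- paste(rownames(genotypes), apply(g, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pedigree file
#'
#' Three whitespace-delimited columns: individual, sire, dam; `0` marks an
#' unknown parent.
#'
#' @param path File path.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stopf("pedigree file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 3L)
    stopf("pedigree file must have 3 columns, found %d", ncol(tab))
  pedigree(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Write a pedigree file
#' @param ped Pedigree object.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  s <- ped$sire; d <- ped$dam
  s[is.na(s)] <- "0"; d[is.na(d)] <- "0"
  writeLines(paste(ped$id, s, d), path)
  invisible(path)
}

#' Write phased haplotypes
#'
#' Two lines per individual (gamete 1 then gamete 2): identifier followed by
#' one allele per SNP, with 9 for unphased.
#'
#' @param hap1,hap2 Integer matrices (individuals x SNPs) with alleles 0/1
#'   and `NA` for unphased; row names are identifiers.
#' @param path Output path.
#' @export
write_phase <- function(hap1, hap2, path) {
  stopifnot(identical(dim(hap1), dim(hap2)))
  h1 <- hap1; h2 <- hap2
  h1[is.na(h1)] <- 9L; h2[is.na(h2)] <- 9L
  ids <- rownames(hap1) %||% paste0("ID", seq_len(nrow(hap1)))
  lines <- character(2L * nrow(h1))
  lines[c(TRUE, FALSE)] <- paste(ids, apply(h1, 1L, paste, collapse = " "))
  lines[c(FALSE, TRUE)] <- paste(ids, apply(h2, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read phased haplotypes
#' @param path File written by [write_phase()].
#' @return List with `ids`, `hap1`, `hap2` (NA = unphased).
#' @export
read_phase <- function(path) {
  if (!file.exists(path)) stopf("phase file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2L != 0L)
    stopf("phase file %s has an odd number of lines (%d)", path,
          length(lines))
  toks <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L)
    stopf("unequal row lengths in phase file %s", path)
  ids1 <- vapply(toks[c(TRUE, FALSE)], `[[`, "", 1L)
  ids2 <- vapply(toks[c(FALSE, TRUE)], `[[`, "", 1L)
  if (!identical(ids1, ids2))
    stopf("phase file %s: gamete lines of an individual must be adjacent",
          path)
  vals <- vapply(toks, function(tk) as.integer(tk[-1L]),
                 integer(lens[1L] - 1L))
  m <- t(vals)
  m[m == 9L] <- NA_integer_
  if (!all(m %in% c(0L, 1L) | is.na(m)))
    stopf("phase file %s contains alleles outside {0,1,9}", path)
  h1 <- m[c(TRUE, FALSE), , drop = FALSE]
  h2 <- m[c(FALSE, TRUE), , drop = FALSE]
  rownames(h1) <- rownames(h2) <- ids1
  list(ids = ids1, hap1 = h1, hap2 = h2)
}

LIBRARY_FORMAT_HEADER <- "#haplophase-library v1"

#' Save a haplotype library
#'
#' Text format, one entry per line: 0-based core index, allele string over
#' the core (characters 0/1 with 9 for missing), frequency count.  Carrier
#' sets are not persisted.
#'
#' @param library A `haplotype_library` object.
#' @param path Output path.
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "haplotype_library"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(LIBRARY_FORMAT_HEADER, con)
  for (ci in seq_along(library$entries)) {
    lc <- library$entries[[ci]]
    if (is.null(lc) || ncol(lc$haps) == 0L) next
    for (e in seq_len(ncol(lc$haps))) {
      al <- lc$haps[, e]
      al[al < 0L] <- 9L
      writeLines(sprintf("%d %s %d", ci - 1L, paste(al, collapse = ""),
                         lc$counts[e]), con)
    }
  }
  invisible(path)
}

#' Load a haplotype library
#'
#' Inverse of [save_library()]; loaded entries have empty carrier sets and
#' may seed the phasing of a new dataset.
#'
#' @param path File path.
#' @return A `haplotype_library` object (core ranges unknown; entry lengths
#'   define core lengths).
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stopf("library file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != LIBRARY_FORMAT_HEADER)
    stopf("%s is not a haplotype library file (missing header)", path)
  lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  lib <- haplotype_library(cores = NULL, n_cores = 0L)
  if (!length(lines)) return(lib)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad)) stopf("malformed library line %d in %s", bad[1L] + 1L, path)
  core_idx <- as.integer(vapply(toks, `[[`, "", 1L)) + 1L
  alstr <- vapply(toks, `[[`, "", 2L)
  counts <- as.integer(vapply(toks, `[[`, "", 3L))
  if (any(grepl("[^019]", alstr)))
    stopf("library file %s contains allele characters outside {0,1,9}", path)
  n_cores <- max(core_idx)
  lib$entries <- vector("list", n_cores)
  for (ci in seq_len(n_cores)) {
    sel <- which(core_idx == ci)
    if (!length(sel)) {
      lib$entries[[ci]] <- empty_library_core(0L)
      next
    }
    L <- nchar(alstr[sel[1L]])
    if (any(nchar(alstr[sel]) != L))
      stopf("library file %s: entries of core %d differ in length", path,
            ci - 1L)
    haps <- vapply(strsplit(alstr[sel], ""), function(ch) {
      a <- as.integer(ch)
      a[a == 9L] <- -1L
      a
    }, integer(L))
    haps <- matrix(haps, nrow = L)
    lib$entries[[ci]] <- lc_repack(
      list(haps = haps, counts = counts[sel],
           carriers = rep(list(character(0)), length(sel))))
  }
  lib
}

#' Export phased genotypes to VCF
#'
#' Write-only convenience export.  GT uses `|` where both alleles are
#' phased, `/` where only the unphased genotype is known, and `./.` where
#' the genotype is missing.
#'
#' @param genotypes Genotype matrix.
#' @param hap1,hap2 Phase matrices as in [write_phase()].
#' @param path Output path.
#' @param chrom Chromosome name used in the CHROM column.
#' @export
write_vcf <- function(genotypes, hap1, hap2, path, chrom = "1") {
  n_snps <- ncol(genotypes)
  ids <- rownames(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (p in seq_len(n_snps)) {
    g <- genotypes[, p]
    a1 <- hap1[, p]; a2 <- hap2[, p]
    gt <- ifelse(is.na(g), "./.",
          ifelse(!is.na(a1) & !is.na(a2), paste0(a1, "|", a2),
          ifelse(g == 0L, "0/0", ifelse(g == 2L, "1/1", "0/1"))))
    writeLines(paste(c(chrom, p, paste0("snp", p), "A", "B", ".", ".", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an optional SNP map file
#'
#' Two whitespace-delimited columns: SNP name and position in Morgans,
#' non-decreasing.  Positions feed [meiosis()] and position-aware reports;
#' all phasing operates on SNP indices and never requires a map.
#'
#' @param path File path.
#' @return A `data.frame` with columns `name` and `position`.
#' @export
read_snp_map <- function(path) {
  if (!file.exists(path)) stopf("SNP map file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("character", "numeric"))
  if (ncol(tab) != 2L) stopf("SNP map must have 2 columns (name, position)")
  if (is.unsorted(tab[[2L]]))
    stopf("SNP map positions must be non-decreasing")
  data.frame(name = tab[[1L]], position = tab[[2L]],
             stringsAsFactors = FALSE)
}
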