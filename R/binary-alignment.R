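#' Binary character alignment
#'
#' A taxa-by-characters 0/1 matrix with site-pattern compression, the input
#' to the two-state likelihood machinery.  Identical columns are collapsed
#' into patterns with integer weights; likelihoods computed on the
#' compressed patterns are identical to the uncompressed ones.
#'
#' @param x A 0/1 matrix (rows = taxa) or a profile tibble with a
#'   `genome_id` column.
#' @return An object of class `binary_alignment` with elements `taxa`,
#'   `characters` (raw taxa x sites matrix), `patterns` (taxa x n_pattern),
#'   `weights`, `site_pattern` (site -> pattern index) and `n_sites`.
#' @export
binary_alignment <- function(x) {
  m <- if (is.data.frame(x)) profile_to_matrix(x) else {
    m0 <- as.matrix(x)
    storage.mode(m0) <- "integer"
    m0
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (any(is.na(m)) || any(!m %in% c(0L, 1L))) {
    abort("alignment characters must all be 0 or 1")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate taxon ids")
  key <- apply(m, 2, paste, collapse = "")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  patterns <- m[, first, drop = FALSE]
  weights <- as.integer(tabulate(pat_id, nbins = sum(first)))
  structure(
    list(taxa = rownames(m), characters = m, patterns = patterns,
         weights = weights, site_pattern = pat_id, n_sites = ncol(m)),
    class = "binary_alignment"
  )
}

#' @export
print.binary_alignment <- function(x, ...) {
  cat(sprintf("binary_alignment: %d taxa x %d sites (%d unique patterns)\n",
              length(x$taxa), x$n_sites, length(x$weights)))
  invisible(x)
}

#' @rdname binary_alignment
#' @param alignment A `binary_alignment`.
#' @return `constant_sites()`: integer indices of constant columns.
#' @export
constant_sites <- function(alignment) {
  cs <- colSums(alignment$patterns)
  const_pat <- which(cs == 0L | cs == length(alignment$taxa))
  which(alignment$site_pattern %in% const_pat)
}

#' Write a profile as a binary fasta file
#'
#' Each record is one genome; the "sequence" is the unwrapped 0/1 string of
#' VOG presences.  The VOG column order is stored in a sidecar TSV so the
#' character set is fixed and runs are reproducible.
#'
#' @param profile Profile tibble.
#' @param path Output `.bfa` path.
#' @param sidecar Path for the column-order TSV (default `<path>.cols.tsv`).
#' @return `path`, invisibly.
#' @export
write_binary_fasta <- function(profile, path,
                               sidecar = paste0(path, ".cols.tsv")) {
  m <- profile_to_matrix(profile)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    abort("cannot write an empty profile as binary fasta")
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(m), "\n", seqs), path, sep = "\n")
  readr::write_tsv(
    tibble::tibble(column = seq_len(ncol(m)), vog_id = colnames(m)),
    sidecar
  )
  invisible(path)
}

#' Read a binary fasta file
#'
#' Inverse of [write_binary_fasta()]: reading back a written profile
#' reproduces it bit-exactly, including genome and column order.
#'
#' @param path `.bfa` path.
#' @param sidecar Column-order TSV; `NULL` columns are left unnamed
#'   (`site1`, `site2`, ...).
#' @return A [binary_alignment()].
#' @export
read_binary_fasta <- function(path, sidecar = paste0(path, ".cols.tsv")) {
  if (!file.exists(path)) abort(paste0("binary fasta not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || hdr[[1]] != TRUE) abort("malformed binary fasta: no header")
  rec <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("binary fasta records have unequal lengths")
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  if (any(!chars %in% c("0", "1"))) abort("binary fasta contains characters other than 0/1")
  m <- matrix(as.integer(chars), nrow = length(ids),
              dimnames = list(ids, NULL))
  if (!is.null(sidecar) && file.exists(sidecar)) {
    cols <- readr::read_tsv(sidecar, show_col_types = FALSE)
    if (nrow(cols) != ncol(m)) abort("sidecar column count does not match binary fasta")
    colnames(m) <- cols$vog_id
  } else {
    colnames(m) <- paste0("site", seq_len(ncol(m)))
  }
  binary_alignment(m)
}

#' Convert a binary alignment back to a profile tibble
#'
#' @param alignment A `binary_alignment`.
#' @return A profile tibble (`genome_id` + 0/1 columns).
#' @export
alignment_to_profile <- function(alignment) {
  profile_from_matrix(alignment$characters)
}
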