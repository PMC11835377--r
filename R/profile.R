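#' Build a binary genome-by-VOG occurrence profile
#'
#' Combines best-hit assignments into a wide 0/1 tibble: one row per genome,
#' one column per VOG family, cell 1 iff the genome carries at least one gene
#' whose best hit is that family.  Genomes without any hit keep an all-zero
#' row, so the row set is always exactly `genomes`.
#'
#' @param best_hits Tibble from [assign_best_vog()].
#' @param genomes Either a character vector of genome ids or a metadata
#'   data frame with a `genome_id` column; defines the rows and their order.
#' @param vog_universe Optional character vector fixing the column set and
#'   order (absent families yield all-zero columns).  Default: the sorted
#'   union of observed VOGs.
#' @return A tibble with a `genome_id` column followed by integer 0/1
#'   VOG columns.
#' @export
build_profile_matrix <- function(best_hits, genomes, vog_universe = NULL) {
  genome_ids <- if (is.data.frame(genomes)) genomes$genome_id else as.character(genomes)
  if (anyDuplicated(genome_ids)) abort("duplicate genome ids in `genomes`")
  unknown <- setdiff(unique(best_hits$genome_id), genome_ids)
  if (length(unknown) > 0L) {
    abort(paste0("hits reference genome(s) absent from `genomes`: ",
                 paste(unknown, collapse = ", ")))
  }
  vogs <- if (is.null(vog_universe)) {
    sort(unique(best_hits$vog_id))
  } else {
    if (anyDuplicated(vog_universe)) abort("duplicate ids in `vog_universe`")
    as.character(vog_universe)
  }
  m <- matrix(0L, nrow = length(genome_ids), ncol = length(vogs),
              dimnames = list(genome_ids, vogs))
  obs <- dplyr::distinct(best_hits, .data$genome_id, .data$vog_id)
  obs <- obs[obs$vog_id %in% vogs, , drop = FALSE]
  if (nrow(obs) > 0L) {
    m[cbind(match(obs$genome_id, genome_ids), match(obs$vog_id, vogs))] <- 1L
  }
  profile_from_matrix(m)
}

#' Convert between profile tibbles and base matrices
#'
#' @param profile A profile tibble (`genome_id` + 0/1 columns).
#' @return `profile_to_matrix()`: an integer matrix with genome rownames;
#'   `profile_from_matrix()`: the corresponding tibble.
#' @export
profile_to_matrix <- function(profile) {
  stopifnot(is.data.frame(profile), "genome_id" %in% names(profile))
  m <- as.matrix(profile[setdiff(names(profile), "genome_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- profile$genome_id
  if (any(is.na(m)) || any(!m %in% c(0L, 1L))) {
    abort("profile cells must all be 0 or 1")
  }
  m
}

#' @rdname profile_to_matrix
#' @param m An integer 0/1 matrix with genome rownames and VOG colnames.
#' @export
profile_from_matrix <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(genome_id = rownames(m)), out)
}

#' Restrict a profile to VOGs above a prevalence threshold
#'
#' Keeps VOG columns present in at least `ceiling(fraction * n_genomes)`
#' genomes ("present in a minimum percent of genomes").  The canonical
#' marker-set fractions are 0.02, 0.01, 0.005 and 0.0025, but any fraction
#' in (0, 1] is accepted.  Genome rows are unchanged.
#'
#' @param profile Profile tibble.
#' @param fraction Minimum prevalence as a fraction of genomes, in (0, 1].
#' @return The column-subset profile tibble.
#' @export
subset_by_prevalence <- function(profile, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1]")
  }
  m <- profile_to_matrix(profile)
  if (nrow(m) == 0L) abort("profile has no genomes")
  min_count <- ceiling(fraction * nrow(m))
  keep <- colSums(m) >= min_count
  if (!any(keep)) {
    warn(sprintf("no VOG reaches prevalence %g (>= %d genomes); all columns dropped",
                 fraction, min_count))
  }
  dplyr::select(profile, "genome_id", dplyr::all_of(colnames(m)[keep]))
}

#' Drop genomes carrying too few marker families
#'
#' Keeps genomes whose profile row contains at least `min_vogs` distinct
#' VOGs, the minimum-information filter applied before tree inference.
#'
#' @param profile Profile tibble.
#' @param min_vogs Minimum number of distinct VOGs present (default 5).
#' @return The row-subset profile tibble.
#' @export
filter_genomes_min_vogs <- function(profile, min_vogs = 5L) {
  if (min_vogs < 1L) abort("`min_vogs` must be >= 1")
  m <- profile_to_matrix(profile)
  keep <- rowSums(m) >= min_vogs
  if (!any(keep)) {
    abort(sprintf(
      "all %d genomes removed: no genome has >= %d VOGs (max observed: %d)",
      nrow(m), min_vogs, if (nrow(m)) max(rowSums(m)) else 0L))
  }
  profile[keep, , drop = FALSE]
}

#' Read/write profile matrices as TSV
#'
#' @param profile Profile tibble.
#' @param path Output path.
#' @return `read_profile_tsv()` returns the profile tibble.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  vog_cols <- setdiff(names(out), "genome_id")
  out[vog_cols] <- lapply(out[vog_cols], as.integer)
  out
}
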