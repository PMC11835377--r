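#' Euclidean distances between genome profiles
#'
#' For binary rows the Euclidean distance is the square root of the number
#' of differing VOGs.
#'
#' @param profile Profile tibble (>= 2 genomes).
#' @return A symmetric numeric matrix.
#' @export
euclidean_profile_distances <- function(profile) {
  m <- profile_to_matrix(profile)
  if (nrow(m) < 2L) abort("need >= 2 genomes")
  as.matrix(dist(m, method = "euclidean"))
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA agglomeration (`hclust(method = "average")`) on a distance
#' matrix.  Leaves are sorted lexicographically before clustering so the
#' result does not depend on the input row order, even under tied
#' distances.
#'
#' @param distmat Square symmetric matrix with zero diagonal.
#' @return An `hclust` object.
#' @export
average_linkage <- function(distmat) {
  if (any(is.na(distmat))) abort("distance matrix contains NA/NaN")
  if (nrow(distmat) != ncol(distmat)) abort("distance matrix must be square")
  ord <- order(rownames(distmat))
  hclust(as.dist(distmat[ord, ord, drop = FALSE]), method = "average")
}

#' Cut a dendrogram at a fixed height
#'
#' `cutree` semantics: genomes joined by merges at height `<= h` share a
#' cluster.  The default height of 5 on Euclidean profile distances means
#' genomes differing in at most 25 VOGs (sqrt(25) = 5) can be grouped.
#'
#' @param dendrogram An `hclust` object from [average_linkage()].
#' @param h Cut height (>= 0, default 5).
#' @return A tibble with columns `genome_id`, `cluster_id`.
#' @export
cut_at_height <- function(dendrogram, h = 5) {
  if (h < 0) abort("`h` must be >= 0")
  cl <- cutree(dendrogram, h = h)
  tibble::tibble(genome_id = names(cl), cluster_id = as.integer(cl))
}

#' Choose one representative genome per cluster
#'
#' Representative = the genome with the most VOGs present; ties broken by
#' the longest genome, then by lexicographically smallest id.
#'
#' @param assignment Tibble from [cut_at_height()].
#' @param profile Profile tibble covering the assigned genomes.
#' @param genome_meta Optional metadata with `genome_id`, `length_bp`
#'   (lengths default to 0 when absent).
#' @return `assignment` with added columns `n_vogs` and
#'   `is_representative` (exactly one `TRUE` per cluster).
#' @export
pick_representatives <- function(assignment, profile, genome_meta = NULL) {
  m <- profile_to_matrix(profile)
  n_vogs <- rowSums(m)[assignment$genome_id]
  len <- if (!is.null(genome_meta)) {
    genome_meta$length_bp[match(assignment$genome_id, genome_meta$genome_id)]
  } else {
    rep(0, nrow(assignment))
  }
  len[is.na(len)] <- 0
  assignment |>
    dplyr::mutate(n_vogs = as.integer(n_vogs), .length = len) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::arrange(dplyr::desc(.data$n_vogs), dplyr::desc(.data$.length),
                   .data$genome_id, .by_group = TRUE) |>
    dplyr::mutate(is_representative = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster_id, .data$genome_id) |>
    dplyr::select(-".length")
}

#' Dereplicate genomes by profile clustering
#'
#' The full redundancy-reduction stage: Euclidean distances between binary
#' profiles, average-linkage clustering, a fixed-height cut (default 5),
#' and one representative per cluster.
#'
#' @param profile Profile tibble.
#' @param genome_meta Optional metadata (`genome_id`, `length_bp`).
#' @param height Cut height (default 5).
#' @return A tibble `genome_id`, `cluster_id`, `n_vogs`,
#'   `is_representative`.
#' @export
dereplicate_profiles <- function(profile, genome_meta = NULL, height = 5) {
  dm <- euclidean_profile_distances(profile)
  dn <- average_linkage(dm)
  cut_at_height(dn, h = height) |>
    pick_representatives(profile, genome_meta)
}
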