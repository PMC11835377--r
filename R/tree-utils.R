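#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two unrooted
#' trees (both trees must share the same leaf set).
#'
#' @param tree_a,tree_b ape `phylo` objects.
#' @return A non-negative integer; 0 iff the unrooted topologies agree.
#' @export
robinson_foulds <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    abort("trees must share the same leaf set")
  }
  as.integer(phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b)))
}

#' Test labelled groups for monophyly on an unrooted tree
#'
#' A label is monophyletic iff some edge of the unrooted tree separates
#' exactly the labelled taxa from the rest (singleton and whole-tree labels
#' are trivially monophyletic).
#'
#' @param tree ape `phylo`.
#' @param label_map Named character vector (names = taxa, values = labels)
#'   or a data frame with columns `genome_id`/`taxon` and `label`.
#' @return A tibble with columns `label`, `n_taxa`, `monophyletic`.
#' @export
check_clade_monophyly <- function(tree, label_map) {
  if (is.data.frame(label_map)) {
    id_col <- intersect(c("genome_id", "taxon"), names(label_map))[[1]]
    label_map <- setNames(as.character(label_map$label), label_map[[id_col]])
  }
  missing <- setdiff(names(label_map), tree$tip.label)
  if (length(missing) > 0L) {
    abort(paste0("labelled taxa absent from tree: ",
                 paste(missing, collapse = ", ")))
  }
  n <- length(tree$tip.label)
  clades <- lapply(ape::prop.part(tree), function(idx) tree$tip.label[idx])
  labels <- unique(label_map)
  purrr::map_dfr(labels, function(lb) {
    members <- names(label_map)[label_map == lb]
    k <- length(members)
    mono <- if (k <= 1L || k >= n - 1L) {
      TRUE
    } else {
      any(vapply(clades, function(cl) {
        setequal(cl, members) || setequal(cl, setdiff(tree$tip.label, members))
      }, logical(1)))
    }
    tibble::tibble(label = lb, n_taxa = k, monophyletic = mono)
  })
}
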