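#' Tidy a fitted two-state tree
#'
#' @param x A `gtr2_fit`.
#' @param ... Unused.
#' @return One row per edge: `parent`, `child`, `child_label` (tip label or
#'   `NA`), `branch_length`.
#' @export
tidy.gtr2_fit <- function(x, ...) {
  tr <- x$tree
  n_tip <- length(tr$tip.label)
  tibble::tibble(
    parent = tr$edge[, 1L],
    child = tr$edge[, 2L],
    child_label = ifelse(tr$edge[, 2L] <= n_tip,
                         tr$tip.label[tr$edge[, 2L]], NA_character_),
    branch_length = tr$edge.length)
}

#' One-row summary of a fitted two-state tree
#'
#' @param x A `gtr2_fit`.
#' @param ... Unused.
#' @return A tibble with `log_likelihood`, `pi1`, `n_taxa`, `n_sites`,
#'   `n_patterns`, `asc`, `nni_rounds`, `tree_length`.
#' @export
glance.gtr2_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    pi1 = x$model$pi1,
    n_taxa = x$n_taxa,
    n_sites = x$n_sites,
    n_patterns = x$n_patterns,
    asc = x$use_asc,
    nni_rounds = x$nni_rounds,
    tree_length = sum(x$tree$edge.length))
}
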