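#' Heatmap of a binary VOG profile
#'
#' @param profile Profile tibble.
#' @param order_genomes,order_vogs Cluster rows/columns for display.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, order_genomes = TRUE, order_vogs = TRUE) {
  m <- profile_to_matrix(profile)
  if (order_genomes && nrow(m) > 2L) {
    m <- m[hclust(dist(m), method = "average")$order, , drop = FALSE]
  }
  if (order_vogs && ncol(m) > 2L) {
    m <- m[, hclust(dist(t(m)), method = "average")$order, drop = FALSE]
  }
  long <- profile_from_matrix(m) |>
    tidyr::pivot_longer(-"genome_id", names_to = "vog_id",
                        values_to = "present") |>
    dplyr::mutate(genome_id = factor(.data$genome_id, levels = rownames(m)),
                  vog_id = factor(.data$vog_id, levels = colnames(m)))
  ggplot2::ggplot(long, ggplot2::aes(.data$vog_id, .data$genome_id,
                                     fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "grey20"),
                               name = "present") +
    ggplot2::labs(x = "VOG family", y = "genome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Density of genome-profile correlations by size class
#'
#' @param corr_tbl Long tibble from [genome_correlation_distributions()].
#' @return A ggplot object: one density per genome-length bin with its
#'   median marked.
#' @export
plot_genome_correlations <- function(corr_tbl) {
  meds <- dplyr::distinct(corr_tbl, .data$bin, .data$bin_median)
  ggplot2::ggplot(corr_tbl, ggplot2::aes(.data$r, colour = .data$bin)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = meds,
                        ggplot2::aes(xintercept = .data$bin_median,
                                     colour = .data$bin),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "pairwise Pearson r of VOG profiles",
                  colour = "genome length") +
    ggplot2::theme_minimal()
}

#' Plot a fitted two-state tree
#'
#' A minimal rectangular cladogram of the ML tree with branch lengths in
#' expected flips per character.
#'
#' @param object A `gtr2_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gtr2_fit <- function(object, ...) {
  tr <- ape::reorder.phylo(object$tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1L]
  x <- numeric(n_node); y <- numeric(n_node)
  # depths by preorder, heights by postorder
  for (i in rev(seq_len(nrow(tr$edge)))) {
    x[tr$edge[i, 2L]] <- x[tr$edge[i, 1L]] + tr$edge.length[[i]]
  }
  y[seq_len(n_tip)] <- seq_len(n_tip)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]
    y[p] <- mean(y[kids[[as.character(p)]]])
  }
  seg <- tibble::tibble(
    x = x[tr$edge[, 1L]], xend = x[tr$edge[, 2L]],
    y = y[tr$edge[, 2L]], yend = y[tr$edge[, 2L]])
  vert <- tibble::tibble(
    x = x[tr$edge[, 1L]], xend = x[tr$edge[, 1L]],
    y = y[tr$edge[, 1L]], yend = y[tr$edge[, 2L]])
  tips <- tibble::tibble(x = x[seq_len(n_tip)], y = y[seq_len(n_tip)],
                         label = tr$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(seg, vert),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.2))) +
    ggplot2::labs(x = "expected flips per character", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}
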