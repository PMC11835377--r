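#' Pairwise Pearson correlations between VOG columns
#'
#' Standard Pearson r on the binary presence columns.  Columns with zero
#' variance (all-present or all-absent) have undefined correlations; they
#' are recorded as `NA` and excluded from downstream clustering.
#'
#' @param profile Profile tibble (>= 2 genomes).
#' @return A symmetric correlation matrix with unit diagonal where defined.
#' @export
pearson_vog_correlations <- function(profile) {
  m <- profile_to_matrix(profile)
  if (nrow(m) < 2L) abort("need >= 2 genomes")
  keep <- apply(m, 2L, function(x) length(unique(x)) > 1L)
  r <- matrix(NA_real_, ncol(m), ncol(m),
              dimnames = list(colnames(m), colnames(m)))
  if (any(keep)) {
    r[keep, keep] <- cor(m[, keep, drop = FALSE])
  }
  r
}

#' Detect co-occurring VOG sets
#'
#' Clusters VOG families on the dissimilarity `1 - r` with average linkage
#' and cuts at height `1 - r_min` (default 0.3, i.e. families correlated
#' above r = 0.7 stay together), keeping clusters with at least `min_size`
#' families.  Zero-variance families are excluded.  The returned sets are
#' disjoint (each VOG belongs to at most one set).
#'
#' @param corr Correlation matrix from [pearson_vog_correlations()].
#' @param r_min Correlation threshold (default 0.7).
#' @param min_size Minimum set size (default 3).
#' @return A tibble with `set_id`, `size` and a list-column `vog_ids`.
#' @export
detect_cooccurring_sets <- function(corr, r_min = 0.7, min_size = 3L) {
  ok <- !is.na(diag(corr))
  corr <- corr[ok, ok, drop = FALSE]
  empty <- tibble::tibble(set_id = integer(), size = integer(),
                          vog_ids = list())
  if (ncol(corr) < 2L) return(empty)
  d <- 1 - corr
  diag(d) <- 0
  hc <- average_linkage(d)
  cl <- cutree(hc, h = 1 - r_min)
  sets <- split(names(cl), cl)
  sets <- sets[vapply(sets, length, integer(1)) >= min_size]
  if (length(sets) == 0L) return(empty)
  sets <- sets[order(vapply(sets, min, character(1)))]
  tibble::tibble(set_id = seq_along(sets),
                 size = unname(vapply(sets, length, integer(1))),
                 vog_ids = unname(lapply(sets, sort)))
}

#' Assign member genomes to a co-occurring VOG set
#'
#' A genome belongs to a set iff it carries strictly more than `min_frac`
#' (default 80%) of the set's families.
#'
#' @param profile Profile tibble.
#' @param vog_set Character vector of the set's VOG ids, or one row of the
#'   tibble from [detect_cooccurring_sets()].
#' @param min_frac Strict membership threshold (default 0.8).
#' @return Character vector of member genome ids.
#' @export
assign_set_members <- function(profile, vog_set, min_frac = 0.8) {
  vogs <- if (is.data.frame(vog_set)) vog_set$vog_ids[[1L]] else as.character(vog_set)
  m <- profile_to_matrix(profile)
  missing <- setdiff(vogs, colnames(m))
  if (length(missing) > 0L) {
    abort(paste0("set VOG(s) absent from profile: ", paste(missing, collapse = ", ")))
  }
  frac <- rowSums(m[, vogs, drop = FALSE]) / length(vogs)
  rownames(m)[frac > min_frac]
}

#' @rdname assign_set_members
#' @param sets Tibble from [detect_cooccurring_sets()].
#' @return `assign_all_set_members()`: the sets tibble with list-column
#'   `member_genomes` and count `n_members`.
#' @export
assign_all_set_members <- function(profile, sets, min_frac = 0.8) {
  members <- lapply(sets$vog_ids, function(v) {
    assign_set_members(profile, v, min_frac = min_frac)
  })
  dplyr::mutate(sets, member_genomes = members,
                n_members = vapply(members, length, integer(1)))
}

#' Fraction of genomes carrying a conserved VOG set, by size class
#'
#' Splits genomes at `size_cut_bp` (default 100 kb) and reports, per class,
#' the fraction of genomes that belong to at least one co-occurring set.
#'
#' @param profile Profile tibble.
#' @param sets Tibble from [detect_cooccurring_sets()] (members are
#'   computed here with `min_frac`).
#' @param genome_meta Metadata with `genome_id`, `length_bp`.
#' @param size_cut_bp Size threshold in bases (default 1e5).
#' @param min_frac Membership threshold (default 0.8).
#' @return A tibble `size_class`, `n_genomes`, `n_with_set`, `fraction`.
#' @export
size_class_fraction_with_sets <- function(profile, sets, genome_meta,
                                          size_cut_bp = 1e5,
                                          min_frac = 0.8) {
  with_sets <- if (nrow(sets) > 0L) {
    unique(unlist(lapply(sets$vog_ids, function(v) {
      assign_set_members(profile, v, min_frac = min_frac)
    })))
  } else {
    character(0)
  }
  genome_meta |>
    dplyr::filter(.data$genome_id %in% profile$genome_id) |>
    dplyr::mutate(size_class = ifelse(.data$length_bp > size_cut_bp,
                                      paste0("> ", size_cut_bp / 1000, " kbp"),
                                      paste0("<= ", size_cut_bp / 1000, " kbp")),
                  has_set = .data$genome_id %in% with_sets) |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(n_genomes = dplyr::n(),
                     n_with_set = sum(.data$has_set),
                     fraction = mean(.data$has_set), .groups = "drop")
}

#' Pairwise genome-profile correlations stratified by genome size
#'
#' Within each genome-length bin, computes Pearson correlations between the
#' profile vectors of every genome pair; the per-bin median summarises how
#' much conserved architecture a size class shares.
#'
#' @param profile Profile tibble.
#' @param genome_meta Metadata with `genome_id`, `length_bp`.
#' @param bins Numeric breakpoints in kbp (passed to `cut`; default
#'   `c(0, 50, 100, 200, Inf)`).
#' @return A long tibble `bin`, `genome_a`, `genome_b`, `r`, `bin_median`
#'   (per-bin median repeated on each row).
#' @export
genome_correlation_distributions <- function(profile, genome_meta,
                                             bins = c(0, 50, 100, 200, Inf)) {
  m <- profile_to_matrix(profile)
  meta <- genome_meta[match(rownames(m), genome_meta$genome_id), ]
  bin <- cut(meta$length_bp / 1000, breaks = bins, include.lowest = TRUE)
  out <- purrr::map_dfr(levels(bin)[table(bin) >= 2L], function(b) {
    sub <- m[which(bin == b), , drop = FALSE]
    keep <- apply(sub, 1L, function(x) stats::sd(x) > 0)
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) < 2L) return(NULL)
    r <- cor(t(sub))
    idx <- which(upper.tri(r), arr.ind = TRUE)
    tibble::tibble(bin = b,
                   genome_a = rownames(sub)[idx[, 1L]],
                   genome_b = rownames(sub)[idx[, 2L]],
                   r = r[idx])
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(bin = character(), genome_a = character(),
                          genome_b = character(), r = numeric(),
                          bin_median = numeric()))
  }
  out |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(bin_median = median(.data$r)) |>
    dplyr::ungroup()
}

#' Cross-tabulate marker families between two functional groups
#'
#' Counts, for every pair of one group-A VOG and one group-B VOG (e.g. a
#' terminase family and a capsid family), the number of genomes carrying
#' both.  A genome with several families of a group contributes to every
#' pair it carries.  The long format suits alluvial-style plotting.
#'
#' @param profile Profile tibble.
#' @param group_map Data frame with columns `vog_id`, `group`.
#' @param group_a,group_b The two group labels to cross-tabulate.
#' @return A tibble `vog_a`, `vog_b`, `n_genomes` (pairs with zero genomes
#'   are omitted).
#' @export
marker_crosstab <- function(profile, group_map, group_a, group_b) {
  m <- profile_to_matrix(profile)
  vogs_a <- intersect(group_map$vog_id[group_map$group == group_a], colnames(m))
  vogs_b <- intersect(group_map$vog_id[group_map$group == group_b], colnames(m))
  if (length(vogs_a) == 0L || length(vogs_b) == 0L) {
    return(tibble::tibble(vog_a = character(), vog_b = character(),
                          n_genomes = integer()))
  }
  counts <- t(m[, vogs_a, drop = FALSE]) %*% m[, vogs_b, drop = FALSE]
  idx <- which(counts > 0, arr.ind = TRUE)
  tibble::tibble(vog_a = vogs_a[idx[, 1L]], vog_b = vogs_b[idx[, 2L]],
                 n_genomes = as.integer(counts[idx])) |>
    dplyr::arrange(.data$vog_a, .data$vog_b)
}

#' Mann-Whitney U test for trait enrichment
#'
#' Two-sided Mann-Whitney U comparing per-genome counts between two groups
#' (e.g. anti-defense genes in jumbo vs smaller phages).  When both groups
#' have at most 8 observations the p-value is computed by exact enumeration
#' over all label assignments (ties handled exactly); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param values_large,values_small Numeric vectors of per-genome counts.
#' @return A one-row tibble `U` (statistic of the first group), `p_value`,
#'   `method`.
#' @export
test_enrichment <- function(values_large, values_small) {
  x <- as.numeric(values_large); y <- as.numeric(values_small)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) abort("both groups must be non-empty")
  u_stat <- function(xs, ys) {
    r <- rank(c(xs, ys))
    sum(r[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= 8L && n2 <= 8L) {
    pooled <- c(x, y)
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(c(x, y))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    p <- min(p, 1)
    method <- "normal approximation"
  }
  tibble::tibble(U = U, p_value = p, method = method)
}
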