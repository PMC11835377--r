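#' Pairwise Hamming distances between alignment rows
#'
#' Proportion of characters at which two taxa differ; used to seed the
#' neighbour-joining starting tree.
#'
#' @param alignment A [binary_alignment()] (>= 2 taxa).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
hamming_distance_matrix <- function(alignment) {
  X <- alignment$patterns
  w <- alignment$weights
  if (nrow(X) < 2L) abort("need >= 2 taxa")
  Xw <- sweep(X, 2L, w, `*`)
  rs <- as.numeric(Xw %*% rep(1, ncol(X)))
  cross <- Xw %*% t(X)
  d <- (outer(rs, rep(1, length(rs))) + outer(rep(1, length(rs)), rs) - 2 * cross) /
    alignment$n_sites
  diag(d) <- 0
  dimnames(d) <- list(alignment$taxa, alignment$taxa)
  d
}

#' Neighbour-joining starting tree
#'
#' Standard NJ agglomeration (via ape) on a distance matrix; on additive
#' distances it reproduces the generating topology and branch lengths.
#'
#' @param distmat Symmetric distance matrix over >= 3 taxa.
#' @return An unrooted ape `phylo`.
#' @export
neighbor_joining <- function(distmat) {
  if (nrow(distmat) < 3L) abort("need >= 3 taxa for neighbour joining")
  ape::nj(as.dist(distmat))
}

default_branch_bounds <- function() c(1e-8, 50)

# Per-branch Brent sweeps until the lnL gain in a full sweep is < tol.
branch_sweeps <- function(setup, pi1, use_asc, tol = 1e-6, max_sweeps = 50L,
                          bounds = default_branch_bounds()) {
  el <- pmin(pmax(setup$tree$edge.length, bounds[[1]]), bounds[[2]])
  cur <- total_loglik(setup, el, pi1, use_asc)
  if (!is.finite(cur)) abort("non-finite log-likelihood at starting branch lengths")
  trace <- cur
  lb <- log(bounds)
  for (sweep in seq_len(max_sweeps)) {
    before <- cur
    for (i in seq_along(el)) {
      # Brent on log(t): the likelihood plateaus for saturated branches, and
      # on the log scale the plateau no longer dominates the bracket
      f <- function(lx) {
        el2 <- el; el2[[i]] <- exp(lx)
        total_loglik(setup, el2, pi1, use_asc)
      }
      opt <- optimize(f, interval = lb, maximum = TRUE,
                      tol = max(tol * 1e-2, 1e-8))
      # consider the bracket ends too (Brent never lands exactly on them)
      cand_x <- c(opt$maximum, lb)
      cand_y <- c(opt$objective, f(lb[[1]]), f(lb[[2]]))
      best <- which.max(cand_y)
      if (cand_y[[best]] >= cur) {
        el[[i]] <- exp(cand_x[[best]])
        cur <- cand_y[[best]]
      }
    }
    trace <- c(trace, cur)
    if (cur - before < tol) break
  }
  list(edge_length = el, log_likelihood = cur, trace = trace)
}

#' Optimise branch lengths by iterated one-dimensional search
#'
#' Each branch in turn is maximised by Brent search on
#' `[1e-8, 50]`, sweeping until a full sweep improves the log-likelihood by
#' less than `tol`.  The log-likelihood never decreases across sweeps.
#'
#' @param tree ape `phylo` over the alignment taxa.
#' @param model [gtr2_model()] or `pi1`.
#' @param alignment A [binary_alignment()].
#' @param use_asc Apply the ascertainment correction.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_sweeps Maximum number of full sweeps.
#' @return A `gtr2_fit` with optimised `tree$edge.length` and
#'   `loglik_trace` (one entry per sweep, non-decreasing).
#' @export
optimize_branch_lengths <- function(tree, model, alignment, use_asc = TRUE,
                                    tol = 1e-6, max_sweeps = 50L) {
  model <- as_gtr2_model(model)
  if (use_asc) check_asc_valid(alignment)
  setup <- prune_setup(tree, alignment)
  res <- branch_sweeps(setup, model$pi1, use_asc, tol = tol,
                       max_sweeps = max_sweeps)
  out_tree <- setup$tree
  out_tree$edge.length <- res$edge_length
  new_gtr2_fit(out_tree, model, res$log_likelihood, use_asc,
               alignment = alignment, loglik_trace = res$trace)
}

#' Estimate the stationary presence frequency
#'
#' One-dimensional ML estimation of `pi1` on (0.001, 0.999), alternated
#' with branch-length sweeps until the joint log-likelihood stabilises.
#' The empirical presence proportion is the starting value.  With
#' `fixed_pi1` given, no estimation is done and that model is returned.
#'
#' @param alignment A [binary_alignment()].
#' @param tree ape `phylo` with branch lengths.
#' @param use_asc Apply the ascertainment correction.
#' @param fixed_pi1 Skip estimation and return this value.
#' @param tol Convergence tolerance.
#' @param max_outer Maximum pi/branch alternations.
#' @return A [gtr2_model()]; the accompanying fit (tree with re-optimised
#'   branch lengths, log-likelihood) is attached as attribute `"fit"`.
#' @export
fit_model_frequencies <- function(alignment, tree, use_asc = TRUE,
                                  fixed_pi1 = NULL, tol = 1e-6,
                                  max_outer = 10L) {
  if (!is.null(fixed_pi1)) {
    model <- as_gtr2_model(fixed_pi1)
    attr(model, "fit") <- optimize_branch_lengths(tree, model, alignment,
                                                  use_asc = use_asc, tol = tol)
    return(model)
  }
  if (use_asc) check_asc_valid(alignment)
  setup <- prune_setup(tree, alignment)
  emp <- sum(setup$weights * colSums(setup$tip_states)) /
    (length(alignment$taxa) * alignment$n_sites)
  pi1 <- min(max(emp, 0.001), 0.999)
  el <- pmin(pmax(setup$tree$edge.length, 1e-8), 50)
  cur <- total_loglik(setup, el, pi1, use_asc)
  for (it in seq_len(max_outer)) {
    before <- cur
    opt <- optimize(function(p) total_loglik(setup, el, p, use_asc),
                    interval = c(0.001, 0.999), maximum = TRUE, tol = 1e-6)
    if (opt$objective >= cur) {
      pi1 <- opt$maximum
      cur <- opt$objective
    }
    setup$tree$edge.length <- el
    sw <- branch_sweeps(setup, pi1, use_asc, tol = tol, max_sweeps = 10L)
    el <- sw$edge_length
    cur <- sw$log_likelihood
    if (cur - before < tol) break
  }
  model <- gtr2_model(pi1)
  out_tree <- setup$tree
  out_tree$edge.length <- el
  attr(model, "fit") <- new_gtr2_fit(out_tree, model, cur, use_asc,
                                     alignment = alignment)
  model
}

#' All nearest-neighbour-interchange neighbours of a tree
#'
#' @param tree ape `phylo` (unrooted binary; stored with a basal
#'   trichotomy).
#' @return List of `phylo` objects, two per internal edge.
#' @export
nni_neighbors <- function(tree) {
  # a degree-2 root hides the split across the root; work unrooted
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2L] > n_tip)
  out <- list()
  for (i in internal) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    ch_v <- which(tree$edge[, 1L] == v)
    s_row <- setdiff(which(tree$edge[, 1L] == u), i)[[1L]]
    for (a_row in ch_v) {
      nt <- tree
      a <- nt$edge[a_row, 2L]; s <- nt$edge[s_row, 2L]
      nt$edge[a_row, 2L] <- s
      nt$edge[s_row, 2L] <- a
      # keep each subtree's stem length with the subtree
      tmp <- nt$edge.length[[a_row]]
      nt$edge.length[[a_row]] <- nt$edge.length[[s_row]]
      nt$edge.length[[s_row]] <- tmp
      # the stored edge order is no longer a postorder; force a re-sort
      attr(nt, "order") <- NULL
      out[[length(out) + 1L]] <- ape::reorder.phylo(nt, "postorder")
    }
  }
  out
}

#' Hill-climbing NNI tree search
#'
#' Starting from `start_tree`, evaluates the two NNI rearrangements of
#' every internal edge (branch lengths re-optimised with a short sweep),
#' accepts the best strictly improving move, re-optimises fully, and stops
#' when no move improves the log-likelihood by more than `epsilon` or
#' `max_rounds` is reached.  The final log-likelihood is never below the
#' starting one.
#'
#' @param start_tree ape `phylo` over the alignment taxa.
#' @param model [gtr2_model()] or `pi1`.
#' @param alignment A [binary_alignment()].
#' @param max_rounds Maximum accepted moves.
#' @param use_asc Apply the ascertainment correction.
#' @param epsilon Minimum lnL gain to accept a move (default 1e-6).
#' @return A `gtr2_fit`; `nni_rounds` records the number of accepted moves
#'   and `loglik_trace` the lnL after each.
#' @export
nni_search <- function(start_tree, model, alignment, max_rounds = 20L,
                       use_asc = TRUE, epsilon = 1e-6) {
  model <- as_gtr2_model(model)
  fit <- optimize_branch_lengths(start_tree, model, alignment,
                                 use_asc = use_asc)
  trace <- fit$log_likelihood
  rounds <- 0L
  while (rounds < max_rounds) {
    nbs <- nni_neighbors(fit$tree)
    if (length(nbs) == 0L) break
    cand <- lapply(nbs, function(nb) {
      # inherited saturated lengths put every candidate on the same
      # likelihood plateau; restart those edges at a moderate value
      nb$edge.length[nb$edge.length > 5] <- 0.5
      setup <- prune_setup(nb, alignment)
      sw <- branch_sweeps(setup, model$pi1, use_asc, tol = 1e-3,
                          max_sweeps = 3L)
      nb$edge.length <- sw$edge_length
      list(tree = nb, log_likelihood = sw$log_likelihood)
    })
    lls <- vapply(cand, `[[`, numeric(1), "log_likelihood")
    best <- which.max(lls)
    if (lls[[best]] <= fit$log_likelihood + epsilon) break
    fit <- optimize_branch_lengths(cand[[best]]$tree, model, alignment,
                                   use_asc = use_asc)
    rounds <- rounds + 1L
    trace <- c(trace, fit$log_likelihood)
  }
  fit$nni_rounds <- rounds
  fit$loglik_trace <- trace
  fit
}

#' Fit a maximum-likelihood tree to a binary profile
#'
#' The full inference stage: neighbour joining on Hamming distances gives
#' the starting tree, the stationary frequency is estimated by ML (unless
#' fixed), and NNI hill climbing with per-branch Brent optimisation
#' refines the topology, all under the ascertainment-corrected two-state
#' model.
#'
#' @param x A profile tibble or a [binary_alignment()].
#' @param use_asc Apply the ascertainment correction (default `TRUE`;
#'   requires variable characters only).
#' @param pi1 Fix the presence frequency instead of estimating it.
#' @param nni Run the NNI topology search (default `TRUE`).
#' @param max_rounds Maximum accepted NNI moves.
#' @return A `gtr2_fit`.
#' @export
fit_binary_tree <- function(x, use_asc = TRUE, pi1 = NULL, nni = TRUE,
                            max_rounds = 20L) {
  alignment <- if (inherits(x, "binary_alignment")) x else binary_alignment(x)
  if (use_asc) check_asc_valid(alignment)
  start <- neighbor_joining(hamming_distance_matrix(alignment))
  start$edge.length <- pmax(start$edge.length, 1e-8)
  model <- fit_model_frequencies(alignment, start, use_asc = use_asc,
                                 fixed_pi1 = pi1)
  start_fit <- attr(model, "fit")
  if (!nni) return(start_fit)
  fit <- nni_search(start_fit$tree, model, alignment,
                    max_rounds = max_rounds, use_asc = use_asc)
  # one more frequency pass on the final topology (cheap, usually a no-op)
  if (is.null(pi1)) {
    model2 <- fit_model_frequencies(alignment, fit$tree, use_asc = use_asc)
    fit2 <- attr(model2, "fit")
    if (fit2$log_likelihood > fit$log_likelihood) {
      fit2$nni_rounds <- fit$nni_rounds
      fit2$loglik_trace <- c(fit$loglik_trace, fit2$log_likelihood)
      fit <- fit2
    }
  }
  fit
}

#' Nonparametric bootstrap support
#'
#' Resamples characters with replacement, rebuilds the tree for each
#' replicate, and reports for every internal edge of the reference tree the
#' percentage of replicates containing that bipartition.  Resamples whose
#' columns are all constant are redrawn (the ascertainment model is defined
#' on variable characters only).
#'
#' @param alignment A [binary_alignment()].
#' @param model Optional [gtr2_model()] / `pi1` to fix during replicates
#'   (default: re-estimated per replicate).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param tree Optional reference `gtr2_fit` or `phylo`; fitted from the
#'   full alignment when missing.
#' @param use_asc Apply the ascertainment correction.
#' @param max_rounds NNI rounds per replicate.
#' @return The reference tree (`phylo`) with integer percentage supports in
#'   `node.label`.
#' @export
bootstrap_support <- function(alignment, model = NULL, n_reps = 100L,
                              seed = 42L, tree = NULL, use_asc = TRUE,
                              max_rounds = 10L) {
  if (n_reps < 1L) abort("`n_reps` must be >= 1")
  pi_fix <- if (is.null(model)) NULL else as_gtr2_model(model)$pi1
  if (is.null(tree)) {
    tree <- fit_binary_tree(alignment, use_asc = use_asc, pi1 = pi_fix)$tree
  } else if (inherits(tree, "gtr2_fit")) {
    tree <- tree$tree
  }
  n_tip <- length(alignment$taxa)
  boot_trees <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      for (try in 1:100) {
        idx <- sample.int(alignment$n_sites, alignment$n_sites, replace = TRUE)
        m <- alignment$characters[, idx, drop = FALSE]
        colnames(m) <- paste0("site", seq_len(ncol(m)))
        cs <- colSums(m)
        variable <- cs > 0L & cs < n_tip
        if (use_asc) {
          if (!any(variable)) next
          m <- m[, variable, drop = FALSE]
        }
        aln <- binary_alignment(m)
        return(fit_binary_tree(aln, use_asc = use_asc, pi1 = pi_fix,
                               max_rounds = max_rounds)$tree)
      }
      abort("bootstrap resampling produced only constant columns")
    })
  })
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  tree$node.label <- as.character(support)
  tree$node.label[[1L]] <- ""  # basal node carries no bipartition
  attr(tree, "boot_trees") <- boot_trees
  tree
}
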