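#' Two-state reversible substitution model
#'
#' The binary general time-reversible model for gene-family presence (state
#' 1) and absence (state 0) with stationary frequencies `pi0`, `pi1`.  The
#' rate matrix is normalised so one unit of branch length equals one
#' expected state flip per character (`beta = 1 / (2 pi0 pi1)`), the
#' convention used by ML tree software for binary data.
#'
#' @param pi1 Stationary frequency of presence, in (0, 1).
#' @return A list `pi0`, `pi1`, `beta` of class `gtr2_model`.
#' @export
gtr2_model <- function(pi1 = 0.5) {
  if (!is.numeric(pi1) || length(pi1) != 1L || pi1 <= 0 || pi1 >= 1) {
    abort("`pi1` must be a single number in (0, 1)")
  }
  pi0 <- 1 - pi1
  structure(list(pi0 = pi0, pi1 = pi1, beta = 1 / (2 * pi0 * pi1)),
            class = "gtr2_model")
}

#' @export
print.gtr2_model <- function(x, ...) {
  cat(sprintf("two-state GTR model: pi0 = %.4f, pi1 = %.4f (rate normalised)\n",
              x$pi0, x$pi1))
  invisible(x)
}

as_gtr2_model <- function(model) {
  if (inherits(model, "gtr2_model")) model else gtr2_model(model)
}

#' Transition probabilities of the two-state model
#'
#' Closed form of the two-state continuous-time chain:
#' `P_ij(t) = pi_j + (delta_ij - pi_j) exp(-beta t)` with
#' `beta = 1 / (2 pi0 pi1)`.  Rows sum to one and the chain satisfies
#' detailed balance `pi_i P_ij = pi_j P_ji`.
#'
#' @param model A [gtr2_model()] (or `pi1` as a number).
#' @param t Branch length (expected flips per character), `>= 0`.
#' @return A 2x2 stochastic matrix with rows/cols named `0`, `1`.
#' @export
transition_probs <- function(model, t) {
  model <- as_gtr2_model(model)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort("branch length `t` must be a single number >= 0")
  }
  e <- exp(-model$beta * t)
  matrix(c(model$pi0 + model$pi1 * e, model$pi1 * (1 - e),
           model$pi0 * (1 - e), model$pi1 + model$pi0 * e),
         nrow = 2, byrow = TRUE, dimnames = list(c("0", "1"), c("0", "1")))
}

# --- internal fast likelihood plumbing ------------------------------------

# Precompute the postorder structures needed by the C++ kernel.
# Returns list(edge, n_tip, tip_states, weights, tip_order)
prune_setup <- function(tree, alignment) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  if (!setequal(tree$tip.label, alignment$taxa)) {
    abort("tree tip labels do not match alignment taxa")
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  tip_states <- alignment$patterns[match(tree$tip.label, alignment$taxa), , drop = FALSE]
  list(tree = tree, edge = tree$edge, n_tip = length(tree$tip.label),
       tip_states = tip_states, weights = alignment$weights)
}

# Pattern log-likelihoods (unconditioned) for given edge lengths.
pattern_loglik <- function(setup, edge_length, pi1) {
  gtr2_site_loglik_cpp(setup$edge, edge_length, setup$n_tip,
                       setup$tip_states, pi1)
}

# log of the probability mass on the two constant patterns
const_mass_log <- function(setup, edge_length, pi1) {
  cm <- matrix(c(rep(0L, setup$n_tip), rep(1L, setup$n_tip)), ncol = 2)
  ll <- gtr2_site_loglik_cpp(setup$edge, edge_length, setup$n_tip, cm, pi1)
  # log(L0 + L1), stable
  mx <- max(ll)
  mx + log(sum(exp(ll - mx)))
}

# Total (optionally ASC-corrected) log-likelihood for given edge lengths.
total_loglik <- function(setup, edge_length, pi1, use_asc) {
  ll <- pattern_loglik(setup, edge_length, pi1)
  if (use_asc) {
    lc <- const_mass_log(setup, edge_length, pi1)
    # lnL = sum w_k [ln L_k - ln(1 - L_const)]
    sum(setup$weights * (ll - log1p(-exp(lc))))
  } else {
    sum(setup$weights * ll)
  }
}

check_asc_valid <- function(alignment) {
  const <- constant_sites(alignment)
  if (length(const) > 0L) {
    abort(paste0(
      "ascertainment correction requires variable characters only; ",
      "constant column(s): ", paste(head(const, 10L), collapse = ", "),
      if (length(const) > 10L) " ..." else ""))
  }
}

#' Felsenstein pruning log-likelihood
#'
#' Computes the log-likelihood of a binary alignment on a tree under the
#' two-state model by postorder conditional-likelihood propagation, with
#' optional conditioning on variable characters (Lewis-type
#' ascertainment-bias correction):
#' `lnL = sum_k w_k ln[ L_k / (1 - L_const) ]` where `L_const` is the
#' probability of the two constant patterns on the same tree and model.
#'
#' @param tree An ape `phylo` with branch lengths; leaf set must equal the
#'   alignment taxa.
#' @param model A [gtr2_model()] or `pi1`.
#' @param alignment A [binary_alignment()].
#' @param use_asc Condition on characters being variable (requires that the
#'   alignment contain no constant column).
#' @param per_site Also return the per-site (uncorrected pattern)
#'   log-likelihoods.
#' @return An object of class `gtr2_fit` with `log_likelihood`, `model`,
#'   `tree` (and `site_loglik` when `per_site = TRUE`).
#' @export
pruning_loglik <- function(tree, model, alignment, use_asc = TRUE,
                           per_site = FALSE) {
  model <- as_gtr2_model(model)
  if (use_asc) check_asc_valid(alignment)
  setup <- prune_setup(tree, alignment)
  ll <- total_loglik(setup, setup$tree$edge.length, model$pi1, use_asc)
  if (!is.finite(ll)) abort("non-finite log-likelihood")
  out <- new_gtr2_fit(tree = setup$tree, model = model, log_likelihood = ll,
                      use_asc = use_asc, alignment = alignment)
  if (per_site) {
    pll <- pattern_loglik(setup, setup$tree$edge.length, model$pi1)
    if (use_asc) {
      lc <- const_mass_log(setup, setup$tree$edge.length, model$pi1)
      pll <- pll - log1p(-exp(lc))
    }
    out$site_loglik <- pll[alignment$site_pattern]
  }
  out
}

new_gtr2_fit <- function(tree, model, log_likelihood, use_asc,
                         alignment = NULL, nni_rounds = 0L,
                         loglik_trace = numeric(0)) {
  structure(list(tree = tree, model = model,
                 log_likelihood = log_likelihood, use_asc = use_asc,
                 n_taxa = length(tree$tip.label),
                 n_sites = if (!is.null(alignment)) alignment$n_sites else NA_integer_,
                 n_patterns = if (!is.null(alignment)) length(alignment$weights) else NA_integer_,
                 nni_rounds = nni_rounds, loglik_trace = loglik_trace),
            class = "gtr2_fit")
}

#' @export
print.gtr2_fit <- function(x, ...) {
  cat(sprintf(
    "two-state ML fit: %d taxa, lnL = %.6f, pi1 = %.4f, ASC %s\n",
    x$n_taxa, x$log_likelihood, x$model$pi1,
    if (x$use_asc) "on" else "off"))
  invisible(x)
}

#' Simulate a binary alignment on a tree
#'
#' Draws the root state from the stationary distribution and evolves it
#' down the tree with [transition_probs()].  With
#' `condition_on_variable = TRUE`, constant columns are rejected and
#' redrawn, matching the sampling model assumed by the ascertainment
#' correction.
#'
#' @param tree ape `phylo` with branch lengths.
#' @param model [gtr2_model()] or `pi1`.
#' @param n_sites Number of characters to return.
#' @param seed Integer seed.
#' @param condition_on_variable Reject constant columns (default `TRUE`).
#' @param max_tries Cap on rejection rounds before failing.
#' @return A [binary_alignment()] over the tree's tip labels.
#' @export
simulate_binary_alignment <- function(tree, model, n_sites, seed = 42L,
                                      condition_on_variable = TRUE,
                                      max_tries = 1000L) {
  model <- as_gtr2_model(model)
  if (n_sites < 1L) abort("`n_sites` must be >= 1")
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  root <- tree$edge[nrow(tree$edge), 1L]
  edges_pre <- rev(seq_len(nrow(tree$edge)))  # preorder traversal

  draw <- function(n) {
    states <- matrix(NA_integer_, nrow = n_node, ncol = n)
    states[root, ] <- rbinom(n, 1L, model$pi1)
    for (i in edges_pre) {
      p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
      e <- exp(-model$beta * tree$edge.length[[i]])
      p1 <- ifelse(states[p, ] == 1L, model$pi1 + model$pi0 * e,
                   model$pi1 * (1 - e))
      states[ch, ] <- rbinom(n, 1L, p1)
    }
    states[seq_len(n_tip), , drop = FALSE]
  }

  withr::with_seed(seed, {
    cols <- matrix(NA_integer_, nrow = n_tip, ncol = 0)
    tries <- 0L
    while (ncol(cols) < n_sites) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("conditioning on variable characters failed: (near-)constant process")
      }
      got <- draw(n_sites)
      if (condition_on_variable) {
        cs <- colSums(got)
        got <- got[, cs > 0L & cs < n_tip, drop = FALSE]
      }
      cols <- cbind(cols, got)
    }
    cols <- cols[, seq_len(n_sites), drop = FALSE]
    rownames(cols) <- tree$tip.label
    colnames(cols) <- paste0("site", seq_len(n_sites))
    binary_alignment(cols)
  })
}
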