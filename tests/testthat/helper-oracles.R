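# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the likelihood oracle enumerates internal-node
# states, and the rank-test oracle counts pairs and enumerates label
# assignments directly.

# Sum over all internal-state assignments of prod(transition probs) --
# closed-form two-state chain, no pruning.
brute_force_site_lik <- function(tree, pi1, pattern_named) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  internal <- setdiff(seq_len(n_node), seq_len(n_tip))
  pi <- c(1 - pi1, pi1)
  beta <- 1 / (2 * pi[1] * pi[2])
  root <- tree$edge[nrow(tree$edge), 1]
  pat <- pattern_named[tree$tip.label]
  total <- 0
  for (a in 0:(2^length(internal) - 1)) {
    st <- integer(n_node)
    st[seq_len(n_tip)] <- pat
    st[internal] <- as.integer(intToBits(a))[seq_along(internal)]
    pr <- pi[st[root] + 1]
    for (i in seq_len(nrow(tree$edge))) {
      p <- st[tree$edge[i, 1]]; ch <- st[tree$edge[i, 2]]
      e <- exp(-beta * tree$edge.length[i])
      pr <- pr * if (p == ch) pi[ch + 1] + (1 - pi[ch + 1]) * e else pi[ch + 1] * (1 - e)
    }
    total <- total + pr
  }
  total
}

brute_force_loglik <- function(tree, pi1, char_matrix, asc = FALSE) {
  liks <- apply(char_matrix, 2, function(col) {
    brute_force_site_lik(tree, pi1, setNames(col, rownames(char_matrix)))
  })
  if (asc) {
    n <- nrow(char_matrix)
    l0 <- brute_force_site_lik(tree, pi1, setNames(rep(0L, n), rownames(char_matrix)))
    l1 <- brute_force_site_lik(tree, pi1, setNames(rep(1L, n), rownames(char_matrix)))
    sum(log(liks / (1 - l0 - l1)))
  } else {
    sum(log(liks))
  }
}

# Mann-Whitney oracle: U by pair counting, p by direct enumeration of all
# choose(n1+n2, n1) group assignments.
mw_oracle <- function(x, y) {
  U <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  us <- apply(utils::combn(length(pooled), n1), 2, function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, function(p, q) (p > q) + 0.5 * (p == q)))
  })
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-9))
}

# a random binary matrix guaranteed to contain no constant column
random_variable_matrix <- function(n_taxa, n_sites, labels) {
  repeat {
    m <- matrix(sample(0:1, n_taxa * n_sites, replace = TRUE), nrow = n_taxa,
                dimnames = list(labels, NULL))
    cs <- colSums(m)
    if (all(cs > 0 & cs < n_taxa)) return(m)
  }
}
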