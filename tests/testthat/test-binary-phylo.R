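test_that("transition probabilities match the closed form", {
  # hand value: pi = 1/2, t = ln(2)/2, beta = 2 => P01 = 0.5 (1 - e^-2t) = 0.25
  P <- transition_probs(gtr2_model(0.5), log(2) / 2)
  expect_equal(P["0", "1"], 0.25, tolerance = 1e-15)
  expect_equal(unname(transition_probs(gtr2_model(0.3), 0)), diag(2))
  Pinf <- transition_probs(gtr2_model(0.3), 1e6)
  expect_equal(unname(Pinf), matrix(c(0.7, 0.3, 0.7, 0.3), 2, byrow = TRUE),
               tolerance = 1e-12)
  for (pi1 in c(0.1, 0.25, 0.5, 0.8)) {
    for (t in c(0.01, 0.1, 0.5, 1, 5)) {
      P <- transition_probs(gtr2_model(pi1), t)
      e <- exp(-t / (2 * pi1 * (1 - pi1)))
      expect_equal(P["0", "0"], (1 - pi1) + pi1 * e, tolerance = 1e-14)
      expect_equal(rowSums(P), c("0" = 1, "1" = 1), tolerance = 1e-14)
      # detailed balance
      expect_equal((1 - pi1) * P["0", "1"], pi1 * P["1", "0"], tolerance = 1e-14)
    }
  }
  expect_error(transition_probs(gtr2_model(0.5), -0.1), ">= 0")
})

test_that("pruning equals brute-force enumeration over internal states", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    m <- random_variable_matrix(n, 5, tr$tip.label)
    pi1 <- runif(1, 0.15, 0.85)
    for (asc in c(FALSE, TRUE)) {
      ours <- pruning_loglik(tr, pi1, binary_alignment(m), use_asc = asc)
      expect_equal(ours$log_likelihood, brute_force_loglik(tr, pi1, m, asc = asc),
                   tolerance = 1e-10)
    }
  }
})

test_that("a two-taxon mismatch pattern has the closed-form likelihood", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.3);")
  aln <- binary_alignment(matrix(c(0L, 1L), 2, 1, dimnames = list(c("a", "b"), NULL)))
  fit <- pruning_loglik(tr, 0.5, aln, use_asc = FALSE)
  expect_equal(fit$log_likelihood, log(0.5 * 0.5 * (1 - exp(-2 * 0.5))),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to pattern compression and rerooting", {
  set.seed(12)
  tr <- ape::rtree(6)
  m <- random_variable_matrix(6, 40, tr$tip.label)
  dup <- m[, c(seq_len(40), sample(40, 60, replace = TRUE))]
  l1 <- pruning_loglik(tr, 0.4, binary_alignment(m), use_asc = TRUE)$log_likelihood
  w <- binary_alignment(dup)
  expect_lt(length(w$weights), ncol(dup))  # compression actually happened
  # compressed duplicate-heavy alignment == weighted sum over unique patterns
  per <- pruning_loglik(tr, 0.4, w, use_asc = TRUE, per_site = TRUE)
  expect_equal(per$log_likelihood, sum(per$site_loglik), tolerance = 1e-9)
  # rerooting leaves the likelihood unchanged (reversibility)
  for (node in c(1L, 3L, 5L)) {
    rr <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[node],
                    resolve.root = TRUE)
    l2 <- pruning_loglik(rr, 0.4, binary_alignment(m), use_asc = TRUE)$log_likelihood
    expect_equal(l2, l1, tolerance = 1e-9)
  }
})

test_that("ascertainment correction requires variable characters", {
  tr <- ape::rtree(4)
  m <- matrix(c(1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L), 4, 2,
              dimnames = list(tr$tip.label, NULL))
  expect_error(pruning_loglik(tr, 0.5, binary_alignment(m), use_asc = TRUE),
               "constant column")
  expect_silent(pruning_loglik(tr, 0.5, binary_alignment(m), use_asc = FALSE))
})

test_that("corrected pattern probabilities sum to one over variable patterns", {
  set.seed(13)
  for (n in c(4, 6)) {
    tr <- ape::rtree(n)
    pi1 <- runif(1, 0.2, 0.8)
    pats <- t(do.call(rbind, lapply(1:(2^n - 2), function(a) {
      as.integer(intToBits(a))[1:n]
    })))
    rownames(pats) <- tr$tip.label
    per <- pruning_loglik(tr, pi1, binary_alignment(pats), use_asc = TRUE,
                          per_site = TRUE)
    expect_equal(sum(exp(per$site_loglik)), 1, tolerance = 1e-8)
  }
})

test_that("Hamming distances and neighbour joining behave as stated", {
  m <- matrix(c(0L, 1L, 0L,
                0L, 1L, 1L,
                1L, 0L, 1L), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  d <- hamming_distance_matrix(binary_alignment(m))
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 1)       # complementary rows
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))

  # additive distances reproduce the generating tree exactly
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  dm <- ape::cophenetic.phylo(gen)
  nj <- neighbor_joining(dm)
  expect_equal(robinson_foulds(nj, gen), 0L)
  expect_equal(sort(nj$edge.length), sort(c(1, 2, 3, 4, 2)), tolerance = 1e-9)
  # 3 taxa: unique topology with exact closed-form lengths
  gen3 <- ape::read.tree(text = "(A:1,B:2,C:4);")
  nj3 <- neighbor_joining(ape::cophenetic.phylo(gen3))
  expect_equal(sort(nj3$edge.length), c(1, 2, 4), tolerance = 1e-9)
})

test_that("branch-length optimisation recovers a simulated divergence", {
  t_true <- 0.3
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t_true / 2, t_true / 2))
  aln <- simulate_binary_alignment(tr, 0.5, 10000, seed = 21,
                                   condition_on_variable = FALSE)
  fit <- optimize_branch_lengths(tr, 0.5, aln, use_asc = FALSE)
  t_hat <- sum(fit$tree$edge.length)
  # delta method: p = 0.5 (1 - e^-2t), var(t_hat) = p(1-p) / (n e^{-2t}^2)
  p <- 0.5 * (1 - exp(-2 * t_true))
  se <- sqrt(p * (1 - p) / 10000) / exp(-2 * t_true)
  expect_lt(abs(t_hat - t_true), 3 * se)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
})

test_that("a conflict-free shrinking branch returns the lower bound", {
  # two identical taxa plus a partly diverged outgroup: the edges joining
  # the identical pair should hit the minimum allowed length
  m <- cbind(matrix(0L, 3, 10), matrix(c(0L, 0L, 1L), 3, 5))
  rownames(m) <- c("a", "b", "c")
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  fit <- optimize_branch_lengths(tr, 0.5, binary_alignment(m), use_asc = FALSE)
  lens <- setNames(fit$tree$edge.length, fit$tree$tip.label[fit$tree$edge[, 2]])
  expect_lt(lens[["a"]], 1e-6)
  expect_lt(lens[["b"]], 1e-6)
})

test_that("stationary-frequency estimation recovers the simulating value", {
  tr <- generate_tree(6, "balanced", branch_length = 0.1, internal_length = 0.2)
  hats <- vapply(1:8, function(r) {
    aln <- simulate_binary_alignment(tr, 0.8, 800, seed = 300 + r,
                                     condition_on_variable = FALSE)
    model <- fit_model_frequencies(aln, tr, use_asc = FALSE)
    model$pi1
  }, numeric(1))
  se <- stats::sd(hats) / sqrt(length(hats))
  expect_lt(abs(mean(hats) - 0.8), 3 * se + 0.01)
  # fixed-frequency mode returns the input unchanged
  aln <- simulate_binary_alignment(tr, 0.5, 100, seed = 1)
  fixed <- fit_model_frequencies(aln, tr, fixed_pi1 = 0.37)
  expect_equal(fixed$pi1, 0.37)
})

test_that("NNI search equals the exhaustive optimum on four taxa", {
  set.seed(31)
  tr <- generate_tree(4, "balanced", branch_length = 0.1, internal_length = 0.3)
  aln <- simulate_binary_alignment(tr, 0.5, 200, seed = 44)
  topos <- list(
    ape::read.tree(text = "((g1:0.1,g2:0.1):0.1,(g3:0.1,g4:0.1):0.1);"),
    ape::read.tree(text = "((g1:0.1,g3:0.1):0.1,(g2:0.1,g4:0.1):0.1);"),
    ape::read.tree(text = "((g1:0.1,g4:0.1):0.1,(g2:0.1,g3:0.1):0.1);"))
  exhaustive <- vapply(topos, function(tp) {
    optimize_branch_lengths(tp, 0.5, aln)$log_likelihood
  }, numeric(1))
  search <- nni_search(topos[[2]], 0.5, aln)
  expect_equal(search$log_likelihood, max(exhaustive), tolerance = 1e-4)
  expect_true(all(diff(search$loglik_trace) >= -1e-9))
})

test_that("search started at a well-supported truth accepts no move", {
  tr <- generate_tree(6, "balanced", branch_length = 0.05, internal_length = 0.2)
  aln <- simulate_binary_alignment(tr, 0.5, 500, seed = 55)
  fit <- nni_search(tr, 0.5, aln)
  expect_equal(fit$nni_rounds, 0L)
  expect_equal(robinson_foulds(fit$tree, tr), 0L)
})

test_that("Robinson-Foulds distances match hand counts", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t1), 0L)
  expect_equal(robinson_foulds(t1, t2), 2L)
  cat6 <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
  bal6 <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  # shared splits: AB, ABCD; unique: ABC (caterpillar) vs CD (balanced)
  expect_equal(robinson_foulds(cat6, bal6), 2L)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf set")
})

test_that("monophyly is judged on unrooted bipartitions", {
  tr <- ape::read.tree(text = "((A1,B1),(A2,B2));")
  res <- check_clade_monophyly(tr, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_equal(res$monophyletic, c(FALSE, FALSE))
  res2 <- check_clade_monophyly(tr, c(A1 = "X", A2 = "X", B1 = "X", B2 = "X"))
  expect_true(all(res2$monophyletic))
  tr2 <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  res3 <- check_clade_monophyly(tr2, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_true(all(res3$monophyletic))
  expect_error(check_clade_monophyly(tr, c(Z9 = "A")), "absent")
})

test_that("bootstrap support is deterministic and bounded as specified", {
  tr <- generate_tree(5, "balanced", branch_length = 0.05, internal_length = 0.25)
  aln <- simulate_binary_alignment(tr, 0.5, 400, seed = 66)
  bs1 <- bootstrap_support(aln, n_reps = 8, seed = 9)
  bs2 <- bootstrap_support(aln, n_reps = 8, seed = 9)
  expect_identical(ape::write.tree(bs1), ape::write.tree(bs2))
  sup <- suppressWarnings(as.numeric(bs1$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))  # abundant compatible characters
  one <- bootstrap_support(aln, n_reps = 1, seed = 3)
  sup1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("simulation matches the closed-form flip probability", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  aln <- simulate_binary_alignment(tr, 0.5, 1e5, seed = 77,
                                   condition_on_variable = FALSE)
  p_hat <- mean(aln$characters["a", ] != aln$characters["b", ])
  p <- 0.5 * (1 - exp(-2 * 0.3))
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 1e5))
  # bit-reproducible under a fixed seed
  again <- simulate_binary_alignment(tr, 0.5, 100, seed = 77,
                                     condition_on_variable = FALSE)
  expect_identical(again$characters[, 1:100],
                   simulate_binary_alignment(tr, 0.5, 100, seed = 77,
                                             condition_on_variable = FALSE)$characters[, 1:100])
  # a zero-length star cannot yield variable columns
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  expect_error(simulate_binary_alignment(star, 0.5, 10, seed = 1,
                                         condition_on_variable = TRUE,
                                         max_tries = 5),
               "constant")
})
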