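prof_mx <- function(m, ids = NULL, vogs = NULL) {
  rownames(m) <- ids %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- vogs %||% paste0("V", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  profile_from_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("VOG correlations match hand values and flag zero variance", {
  m <- cbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L),
             c(1L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L))
  r <- pearson_vog_correlations(prof_mx(m))
  expect_equal(r["V1", "V2"], 1)
  expect_equal(r["V1", "V3"], -1)
  expect_equal(r["V1", "V4"], 0)   # (1,1,0,0) vs (1,0,1,0)
  expect_true(all(is.na(r["V5", ])))  # constant column
  expect_equal(r, t(r))
})

planted_profile <- function(n_genomes, block_sizes, n_noise, p_in = 0.95,
                            p_bg = 0.05, seed = 1) {
  withr::with_seed(seed, {
    cols <- list()
    block_id <- integer(0)
    for (b in seq_along(block_sizes)) {
      carrier <- rbinom(n_genomes, 1, 0.4)
      for (j in seq_len(block_sizes[[b]])) {
        cols[[length(cols) + 1L]] <-
          ifelse(carrier == 1L, rbinom(n_genomes, 1, p_in), rbinom(n_genomes, 1, p_bg))
        block_id <- c(block_id, b)
      }
    }
    for (j in seq_len(n_noise)) {
      cols[[length(cols) + 1L]] <- rbinom(n_genomes, 1, 0.3)
      block_id <- c(block_id, 0L)
    }
    m <- do.call(cbind, cols)
    vogs <- sprintf("VOG%03d", seq_len(ncol(m)))
    list(profile = prof_mx(m, vogs = vogs),
         truth = split(vogs, block_id)[-1])
  })
}

test_that("co-occurring sets are recovered exactly from planted blocks", {
  # one planted trio among independent families
  p1 <- planted_profile(200, 3, 10, seed = 2)
  sets1 <- detect_cooccurring_sets(pearson_vog_correlations(p1$profile))
  expect_equal(nrow(sets1), 1L)
  expect_setequal(sets1$vog_ids[[1]], p1$truth[[1]])
  # two blocks of sizes 4 and 7
  p2 <- planted_profile(200, c(4, 7), 12, seed = 3)
  sets2 <- detect_cooccurring_sets(pearson_vog_correlations(p2$profile))
  expect_equal(sort(sets2$size), c(4L, 7L))
  got <- lapply(sets2$vog_ids, sort)
  expect_true(all(vapply(p2$truth, function(tr) {
    any(vapply(got, identical, logical(1), sort(tr)))
  }, logical(1))))
  # mutually uncorrelated families yield no set
  p3 <- planted_profile(200, integer(0), 15, seed = 4)
  expect_equal(nrow(detect_cooccurring_sets(pearson_vog_correlations(p3$profile))), 0L)
})

test_that("detected sets partition the VOGs and shrink with r_min", {
  p <- planted_profile(150, c(3, 5), 20, seed = 5)
  r <- pearson_vog_correlations(p$profile)
  sets <- detect_cooccurring_sets(r, min_size = 1L)
  all_members <- unlist(sets$vog_ids)
  expect_equal(anyDuplicated(all_members), 0L)
  loose <- detect_cooccurring_sets(r, r_min = 0.5, min_size = 3L)
  strict <- detect_cooccurring_sets(r, r_min = 0.9, min_size = 3L)
  # every strict set is contained in some loose set
  for (s in strict$vog_ids) {
    expect_true(any(vapply(loose$vog_ids, function(l) all(s %in% l), logical(1))))
  }
})

test_that("set membership is strictly more than 80% of the set", {
  m <- matrix(0L, 3, 10)
  m[1, 1:8] <- 1L    # 8/10 = 0.8 exactly: NOT a member
  m[2, 1:9] <- 1L    # 0.9: member
  m[3, 1:10] <- 1L
  prof <- prof_mx(m)
  members <- assign_set_members(prof, paste0("V", 1:10))
  expect_setequal(members, c("g2", "g3"))
  # raising the threshold never grows membership
  for (f in c(0.5, 0.7, 0.9)) {
    expect_true(all(assign_set_members(prof, paste0("V", 1:10), min_frac = 0.9) %in%
                      assign_set_members(prof, paste0("V", 1:10), min_frac = f)))
  }
  expect_error(assign_set_members(prof, c("V1", "V99")), "V99")
})

test_that("size-class fractions reflect which genomes carry a set", {
  m <- rbind(c(1L, 1L, 1L, 0L), c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 1L),
             c(0L, 1L, 0L, 0L))
  prof <- prof_mx(m)
  meta <- tibble::tibble(genome_id = paste0("g", 1:4),
                         length_bp = c(150000L, 120000L, 60000L, 40000L))
  sets <- tibble::tibble(set_id = 1L, size = 3L, vog_ids = list(paste0("V", 1:3)))
  res <- size_class_fraction_with_sets(prof, sets, meta)
  large <- res[grepl(">", res$size_class), ]
  small <- res[grepl("<=", res$size_class), ]
  expect_equal(large$fraction, 1)   # only the large genomes carry the block
  expect_equal(small$fraction, 0)
  none <- size_class_fraction_with_sets(prof, sets[0, ], meta)
  expect_true(all(none$fraction == 0))
})

test_that("per-bin genome correlations report distribution and median", {
  m <- rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L),
             c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  prof <- prof_mx(m)
  meta <- tibble::tibble(genome_id = paste0("g", 1:4),
                         length_bp = c(150000L, 180000L, 30000L, 40000L))
  out <- genome_correlation_distributions(prof, meta, bins = c(0, 100, Inf))
  big <- out[out$genome_a %in% c("g1", "g2") | out$genome_b %in% c("g1", "g2"), ]
  expect_equal(big$r, 1)
  expect_equal(unique(big$bin_median), 1)
  small <- out[out$genome_a == "g3" | out$genome_b == "g3", ]
  expect_equal(small$r, -1)  # complementary profiles
})

test_that("marker cross-tabulation counts genomes carrying both families", {
  m <- rbind(c(1L, 0L, 1L, 0L),
             c(1L, 0L, 1L, 1L),
             c(0L, 1L, 0L, 0L))   # no group-B family: contributes nothing
  prof <- prof_mx(m, vogs = c("TerL1", "TerL2", "MCP1", "MCP2"))
  groups <- tibble::tibble(vog_id = c("TerL1", "TerL2", "MCP1", "MCP2"),
                           group = c("TerL", "TerL", "MCP", "MCP"))
  tab <- marker_crosstab(prof, groups, "TerL", "MCP")
  expect_equal(tab$n_genomes[tab$vog_a == "TerL1" & tab$vog_b == "MCP1"], 2L)
  expect_equal(tab$n_genomes[tab$vog_a == "TerL1" & tab$vog_b == "MCP2"], 1L)
  expect_false(any(tab$vog_a == "TerL2"))
})

test_that("the rank test matches exact enumeration, including ties", {
  res <- test_enrichment(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res$U, 9)
  expect_equal(res$p_value, 0.1)   # 2 of the 20 assignments are as extreme
  same <- test_enrichment(c(3, 5, 7, 9), c(3, 5, 7, 9))
  expect_equal(same$U, 4 * 4 / 2)
  expect_equal(same$p_value, 1)
  set.seed(17)
  for (rep in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:5, n1, replace = TRUE)   # ties on purpose
    y <- sample(0:5, n2, replace = TRUE)
    ours <- test_enrichment(x, y)
    oracle <- mw_oracle(x, y)
    expect_equal(ours$U, oracle$U)
    expect_equal(ours$p_value, oracle$p)
    if (length(unique(c(x, y))) == n1 + n2) {
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("U statistics of the two orientations always sum to n1 n2", {
  set.seed(18)
  for (rep in 1:300) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x <- rpois(n1, 3); y <- rpois(n2, 5)
    expect_equal(test_enrichment(x, y)$U + test_enrichment(y, x)$U, n1 * n2)
  }
})
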