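#' Generate a random or deterministic tree
#'
#' Yule trees are drawn as a pure-birth process; `balanced` and
#' `caterpillar` build the deterministic shapes.  Branch lengths are in
#' expected flips per character; Yule branch lengths are rescaled so their
#' mean equals `branch_length`, the deterministic shapes use it on every
#' edge.  The default of 0.3 gives a per-edge change probability of about
#' 0.23 at `pi1 = 0.5`: informative but far from saturated.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param shape `"yule"`, `"balanced"` or `"caterpillar"`.
#' @param branch_length Terminal edge length (or mean edge length for
#'   Yule).
#' @param internal_length Internal edge length for the deterministic
#'   shapes (default: same as `branch_length`).  Binary characters lose
#'   signal with overall depth (tip-pair correlation decays as
#'   `exp(-2 * path length)`), so well-separated benchmark trees keep
#'   terminal edges short and internal edges long *relative* to them
#'   rather than long in absolute terms.
#' @param seed Integer seed (Yule only).
#' @return An ape `phylo` with tips `g1..gN`.
#' @export
generate_tree <- function(n_taxa, shape = c("yule", "balanced", "caterpillar"),
                          branch_length = 0.3, internal_length = branch_length,
                          seed = 42L) {
  shape <- match.arg(shape)
  if (n_taxa < 3L) abort("`n_taxa` must be >= 3")
  tips <- paste0("g", seq_len(n_taxa))
  if (shape == "yule") {
    tree <- withr::with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
    tree$tip.label <- tips
    tree$edge.length <- tree$edge.length * branch_length / mean(tree$edge.length)
    tree$edge.length <- pmax(tree$edge.length, 1e-6)
    return(tree)
  }
  build <- function(ids) {
    if (length(ids) == 1L) return(paste0(ids, ":", branch_length))
    halves <- if (shape == "balanced") {
      k <- ceiling(length(ids) / 2)
      list(ids[seq_len(k)], ids[-seq_len(k)])
    } else {
      list(ids[-length(ids)], ids[length(ids)])
    }
    paste0("(", build(halves[[1]]), ",", build(halves[[2]]),
           "):", internal_length)
  }
  halves <- if (shape == "balanced") {
    k <- ceiling(n_taxa / 2)
    list(tips[seq_len(k)], tips[-seq_len(k)])
  } else {
    list(tips[-n_taxa], tips[n_taxa])
  }
  txt <- paste0("(", build(halves[[1]]), ",", build(halves[[2]]), ");")
  ape::read.tree(text = txt)
}

# disjoint clades of size 2..n-2, largest candidate pool first
pick_disjoint_clades <- function(tree, n_blocks, seed) {
  n <- length(tree$tip.label)
  parts <- lapply(ape::prop.part(tree), function(i) tree$tip.label[i])
  parts <- parts[vapply(parts, length, integer(1)) >= 2 &
                   vapply(parts, length, integer(1)) <= n - 2]
  if (length(parts) == 0L) abort("tree has no internal clade of usable size")
  withr::with_seed(seed, {
    parts <- sample(parts)
    # prefer family-sized clades (around a third of the taxa): planted
    # blocks on 2-tip clades are too fragile to carry signal
    sizes <- vapply(parts, length, integer(1))
    parts <- parts[order(abs(sizes - n / 3))]
    chosen <- list()
    used <- character(0)
    for (p in parts) {
      if (length(intersect(p, used)) == 0L) {
        chosen[[length(chosen) + 1L]] <- p
        used <- c(used, p)
      }
      if (length(chosen) == n_blocks) break
    }
    if (length(chosen) < n_blocks) {
      abort(sprintf("only %d disjoint clades available for %d blocks",
                    length(chosen), n_blocks))
    }
    chosen
  })
}

#' Simulate genome profiles with planted structure
#'
#' Background VOG characters evolve along the tree under the two-state
#' model; each planted family block is a group of VOGs present in one
#' clade's genomes with probability `block_fidelity` and elsewhere with
#' probability `(1 - block_fidelity) * pi1`.  Mosaicism is caricatured as
#' whole-block transplantation between leaves: each block is copied from a
#' random donor to a random recipient `Pois(mosaic_swap_rate * n_taxa)`
#' times.
#'
#' @param tree ape `phylo` from [generate_tree()].
#' @param n_vogs Number of background characters.
#' @param pi1 Stationary presence frequency of the background process.
#' @param n_family_blocks Number of planted clade-linked blocks.
#' @param block_size VOGs per block.
#' @param block_fidelity In-clade presence probability, in (0, 1].
#' @param mosaic_swap_rate Expected transplants per block per taxon.
#' @param condition_on_variable Reject constant background columns.
#' @param seed Integer seed.
#' @return A list (class `vog_simulation`) with `profile` (tibble),
#'   `blocks` (tibble `vog_id`, `block_id`), `block_clades` (list of tip
#'   sets), `genome_meta` (lengths 30-90 kb; planted-clade family labels)
#'   and `tree`.
#' @export
generate_profiles <- function(tree, n_vogs = 300L, pi1 = 0.3,
                              n_family_blocks = 0L, block_size = 8L,
                              block_fidelity = 0.95, mosaic_swap_rate = 0,
                              condition_on_variable = TRUE, seed = 42L) {
  stopifnot(block_fidelity > 0, block_fidelity <= 1, mosaic_swap_rate >= 0)
  aln <- simulate_binary_alignment(tree, pi1, n_vogs, seed = seed,
                                   condition_on_variable = condition_on_variable)
  m <- aln$characters
  colnames(m) <- sprintf("VOG%05d", seq_len(n_vogs))
  taxa <- rownames(m)
  blocks <- tibble::tibble(vog_id = character(), block_id = integer())
  clades <- list()
  if (n_family_blocks > 0L) {
    clades <- pick_disjoint_clades(tree, n_family_blocks, seed = seed + 1L)
    bm <- withr::with_seed(seed + 2L, {
      cols <- lapply(seq_len(n_family_blocks), function(b) {
        inside <- taxa %in% clades[[b]]
        p <- ifelse(inside, block_fidelity, (1 - block_fidelity) * pi1)
        matrix(rbinom(length(taxa) * block_size, 1L, rep(p, block_size)),
               nrow = length(taxa))
      })
      do.call(cbind, cols)
    })
    colnames(bm) <- sprintf("VOG%05d", n_vogs + seq_len(ncol(bm)))
    blocks <- tibble::tibble(
      vog_id = colnames(bm),
      block_id = rep(seq_len(n_family_blocks), each = block_size))
    if (mosaic_swap_rate > 0) {
      bm <- withr::with_seed(seed + 3L, {
        for (b in seq_len(n_family_blocks)) {
          cols_b <- which(blocks$block_id == b)
          n_events <- rpois(1L, mosaic_swap_rate * length(taxa))
          for (ev in seq_len(n_events)) {
            pair <- sample(length(taxa), 2L)
            bm[pair[[2L]], cols_b] <- bm[pair[[1L]], cols_b]
          }
        }
        bm
      })
    }
    m <- cbind(m, bm)
  }
  meta <- withr::with_seed(seed + 4L, {
    fam <- rep("unassigned", length(taxa))
    for (b in seq_along(clades)) fam[taxa %in% clades[[b]]] <- paste0("family", b)
    tibble::tibble(genome_id = taxa,
                   length_bp = as.integer(round(runif(length(taxa), 3e4, 9e4))),
                   family_label = fam, source_label = "synthetic")
  })
  structure(list(profile = profile_from_matrix(m), blocks = blocks,
                 block_clades = clades, genome_meta = meta, tree = tree,
                 pi1 = pi1, seed = seed),
            class = "vog_simulation")
}

#' @export
print.vog_simulation <- function(x, ...) {
  cat(sprintf("vog_simulation: %d genomes x %d VOGs, %d planted block(s)\n",
              nrow(x$profile), ncol(x$profile) - 1L,
              length(unique(x$blocks$block_id))))
  invisible(x)
}

#' Emit a gene-level hit table realising a profile
#'
#' For every present (genome, VOG) cell, emits 1-3 gene hits whose best
#' (highest-bitscore) hit is the true family, plus optional decoy hits to
#' other families at `(0.5, 0.95)` times the top score and junk rows above
#' the E-value threshold.  Parsing, filtering and best-hit assignment of
#' the emitted table reproduces the input profile exactly.
#'
#' @param profile Profile tibble.
#' @param path Optional output TSV path.
#' @param seed Integer seed.
#' @param decoy_rate Probability a gene gets a decoy hit.
#' @param junk_rate Expected junk (E >= 1e-5) rows per present cell.
#' @param tie_decoys Give decoys the *same* bitscore as the top hit (with a
#'   larger E-value), exercising the tie-break path.
#' @return The hit tibble (`gene_id`, `genome_id`, `vog_id`, `bitscore`,
#'   `evalue`), invisibly if `path` is given.
#' @export
profiles_to_hit_table <- function(profile, path = NULL, seed = 42L,
                                  decoy_rate = 0.5, junk_rate = 0.05,
                                  tie_decoys = FALSE) {
  m <- profile_to_matrix(profile)
  vogs <- colnames(m)
  rows <- withr::with_seed(seed, {
    cells <- which(m == 1L, arr.ind = TRUE)
    if (nrow(cells) > 0L) {
      n_genes <- sample(3L, nrow(cells), replace = TRUE)
      genome <- rep(rownames(m)[cells[, 1L]], n_genes)
      vog <- rep(vogs[cells[, 2L]], n_genes)
      ord <- order(genome)
      genome <- genome[ord]; vog <- vog[ord]
      gene_no <- stats::ave(seq_along(genome), genome, FUN = seq_along)
      n <- length(genome)
      top_score <- runif(n, 60, 150)
      top_eval <- 10^-runif(n, 6, 30)
      true_hits <- tibble::tibble(
        gene_id = paste0(genome, "_", gene_no), genome_id = genome,
        vog_id = vog, bitscore = top_score, evalue = top_eval)
      decoys <- NULL
      if (length(vogs) > 1L) {
        has_decoy <- runif(n) < decoy_rate
        if (any(has_decoy)) {
          dv <- sample(vogs, sum(has_decoy), replace = TRUE)
          clash <- dv == vog[has_decoy]
          while (any(clash)) {
            dv[clash] <- sample(vogs, sum(clash), replace = TRUE)
            clash <- dv == vog[has_decoy]
          }
          nd <- sum(has_decoy)
          decoys <- tibble::tibble(
            gene_id = true_hits$gene_id[has_decoy],
            genome_id = genome[has_decoy], vog_id = dv,
            bitscore = if (tie_decoys) top_score[has_decoy] else
              top_score[has_decoy] * runif(nd, 0.5, 0.95),
            evalue = if (tie_decoys) pmin(top_eval[has_decoy] * 10, 9e-6) else
              10^-runif(nd, 6, 30))
        }
      }
    } else {
      true_hits <- decoys <- NULL
      genome <- character(0)
      gene_no <- integer(0)
    }
    n_junk <- rpois(nrow(m), junk_rate * pmax(rowSums(m), 1L))
    junk <- NULL
    if (sum(n_junk) > 0L) {
      jg <- rep(rownames(m), n_junk)
      per_genome_max <- vapply(rownames(m), function(g) {
        k <- gene_no[genome == g]
        if (length(k)) max(k) else 0L
      }, integer(1))
      off <- stats::ave(seq_along(jg), jg, FUN = seq_along)
      junk <- tibble::tibble(
        gene_id = paste0(jg, "_", per_genome_max[jg] + off), genome_id = jg,
        vog_id = sample(vogs, length(jg), replace = TRUE),
        bitscore = runif(length(jg), 10, 40),
        evalue = 10^-runif(length(jg), 0, 4.9))
    }
    hits <- dplyr::bind_rows(true_hits, decoys, junk)
    if (nrow(hits) == 0L) hits <- empty_hits()
    hits[sample(nrow(hits)), ]
  })
  if (!is.null(path)) {
    readr::write_tsv(rows, path)
    return(invisible(rows))
  }
  rows
}

# spacer whose three forward frames each contain TAA, TAG and TGA, so every
# candidate code terminates in intergenic sequence; the second unit plants
# their reverse complements for the reverse frames
stop_soup <- function() {
  fwd <- "TAATAGTGA"
  rev <- "TTATCACTA"  # revcomp contains TAG, TGA, TAA
  paste0(fwd, "C", fwd, "C", fwd, "C", rev, "C", rev, "C", rev, "C")
}

#' Generate a genome with a planted genetic code
#'
#' Builds a genome of wall-to-wall forward ORFs separated by stop-dense
#' spacers.  Gene bodies avoid the planted code's stop codons but are
#' salted with the stops of the *other* codes (and with codons whose
#' reverse complements are stops), so reading the genome under any
#' non-planted candidate code fragments the genes.  Coding density under
#' the planted code lands within about 0.05 of `target_density`.
#'
#' @param code_id Planted NCBI table (11, 6, 14 and 15 are the recoverable
#'   choices; see the package vignette on stop-set nesting).
#' @param length_bp Genome length (default 15000).
#' @param target_density Desired coding density under the planted code.
#' @param seed Integer seed.
#' @param min_len Minimum ORF length (as in [call_orfs()]).
#' @return A list: `sequence`, `code_id`, `orfs` (truth tibble),
#'   `density` (realised, from the truth ORFs).
#' @export
generate_coded_genome <- function(code_id, length_bp = 15000L,
                                  target_density = 0.9, seed = 42L,
                                  min_len = 90L) {
  spec <- genetic_code_spec(code_id)
  soup <- stop_soup()
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  safe <- setdiff(all_codons, spec$stop_codons)
  terminator <- intersect(c("TAA", "TGA", "TAG"), spec$stop_codons)[[1L]]
  # Disruptor cassette: codon pieces that are innocuous in the planted
  # reading frame but place stop triplets of every *other* candidate code
  # in all six frames -- aligned stops (TGA/TAG/TAA), junction stops in the
  # +1/+2 frames, and CTA/TTA/TCA (whose reverse complements are stops) for
  # the reverse frames.  Without them a naive six-frame caller finds long
  # spurious ORFs in the shifted frames under every code.  Pieces whose
  # aligned codons are stops of the planted code are dropped; the order
  # interleaves the single-stop codes' disruptors so no frame goes more
  # than ~15 codons without a stop under any non-planted code.
  cassette <- c("TGA", "TAG", "TCA", "CTA", "CTGACT", "CTAGGT", "GTCAAC",
              "GCTAAC", "GGTGAC", "GGTAGC", "GGTCAC", "GCCTAC", "TAA",
              "TTA", "CTAACT", "GTTAAC", "GGTAAC", "GGTTAC")
  cassette <- cassette[!vapply(cassette, function(m) {
    cs <- substring(m, seq(1L, nchar(m) - 2L, 3L), seq(3L, nchar(m), 3L))
    any(cs %in% spec$stop_codons)
  }, logical(1))]

  withr::with_seed(seed, {
    if (length_bp < min_len + 2L * nchar(soup)) {
      seq <- paste(sample(bases, length_bp, replace = TRUE), collapse = "")
      return(list(sequence = seq, code_id = spec$code_id,
                  orfs = empty_orfs(), density = 0))
    }
    pieces <- soup
    pos <- nchar(soup)
    covered <- 0L
    orf_start <- integer(0); orf_end <- integer(0)
    repeat {
      need <- target_density * length_bp - covered
      if (need < min_len + 3L) break
      k <- sample(100:400, 1L)                 # codons incl. terminator
      k <- min(k, max(31L, floor(need / 3) + 1L))
      if (pos + 3L * k + nchar(soup) > length_bp) {
        k <- (length_bp - pos - nchar(soup)) %/% 3L
        if (k < 31L) break
      }
      body_n <- k - 2L
      body <- character(0)
      n_cod <- 0L
      pc <- sample.int(length(cassette), 1L)  # random phase into the cassette
      while (n_cod < body_n) {
        piece <- cassette[[pc]]
        pc <- if (pc == length(cassette)) 1L else pc + 1L
        if (runif(1) < 0.3) {
          piece <- paste0(piece, safe[[sample.int(length(safe), 1L)]])
        }
        body <- c(body, piece)
        n_cod <- n_cod + nchar(piece) %/% 3L
      }
      body <- substr(paste(body, collapse = ""), 1L, 3L * body_n)
      gene <- paste0("ATG", body, terminator)
      orf_start <- c(orf_start, pos)
      orf_end <- c(orf_end, pos + 3L * (k - 1L))
      pieces <- c(pieces, gene)
      pos <- pos + nchar(gene)
      covered <- covered + 3L * (k - 1L)
      # spacer sized to hold the local coding fraction near the target
      s_len <- max(nchar(soup),
                   round(3 * k * (1 - target_density) / target_density))
      s_len <- min(s_len, length_bp - pos)
      if (s_len <= 0L) break
      spacer <- substr(strrep(soup, ceiling(s_len / nchar(soup))), 1L, s_len)
      pieces <- c(pieces, spacer)
      pos <- pos + s_len
    }
    if (pos < length_bp) {
      fill <- length_bp - pos
      pieces <- c(pieces, substr(strrep(soup, ceiling(fill / nchar(soup))), 1L, fill))
    }
    seq <- paste(pieces, collapse = "")
    orfs <- tibble::tibble(start = orf_start, end = orf_end,
                           strand = "+", frame = orf_start %% 3L,
                           length = orf_end - orf_start)
    list(sequence = seq, code_id = spec$code_id, orfs = orfs,
         density = coding_density(orfs, length_bp))
  })
}

#' Write named sequences as a FASTA file
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
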