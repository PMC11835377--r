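test_that("code specifications carry the NCBI stop-codon reassignments", {
  expect_setequal(genetic_code_spec(11)$stop_codons, c("TAA", "TAG", "TGA"))
  expect_setequal(genetic_code_spec(15)$stop_codons, c("TAA", "TGA"))  # TAG recoded
  expect_setequal(genetic_code_spec(6)$stop_codons, "TGA")
  expect_setequal(genetic_code_spec(14)$stop_codons, "TAG")
  sp <- genetic_code_spec(23)
  expect_length(intersect(sp$stop_codons, sp$start_codons), 0)
  expect_error(genetic_code_spec(7), "unsupported")
})

test_that("the ORF caller finds a constructed start-to-stop gene", {
  s <- paste0("ATG", strrep("GCT", 30), "TAA")
  o <- call_orfs(s, 11)
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 0L)
  expect_equal(o$length, 93L)   # stop codon excluded
  expect_equal(o$strand, "+")
  expect_equal(nrow(call_orfs(strrep("N", 500), 11)), 0L)
  expect_equal(nrow(call_orfs("ATGTAA", 11)), 0L)  # shorter than min_len
})

test_that("stop-codon reassignment changes which ORFs are read", {
  # TGA mid-gene: under the standard code it truncates both halves below
  # min_len; under table 25 (TGA reassigned) the gene reads through
  s <- paste0("ATG", strrep("GCT", 20), "TGA", strrep("GCT", 20), "TAA")
  expect_equal(nrow(call_orfs(s, 11)), 0L)
  o25 <- call_orfs(s, 25)
  expect_equal(nrow(o25), 1L)
  expect_equal(o25$length, 3L + 60L + 3L + 60L)
})

test_that("reverse-strand ORFs are reported in forward coordinates", {
  gene <- paste0("ATG", strrep("GCT", 30), "TAA")
  s <- paste0("CCCCC", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene))), "CCCCC")
  o <- call_orfs(s, 11)
  expect_equal(nrow(o), 1L)
  expect_equal(o$strand, "-")
  expect_equal(o$start, 5L + 3L)   # stop codon (3 nt) sits before the ORF
  expect_equal(o$length, 93L)
})

test_that("coding density is the interval union over the genome", {
  expect_equal(coding_density(tibble::tibble(start = integer(), end = integer()), 100), 0)
  one <- tibble::tibble(start = 0L, end = 1000L)
  expect_equal(coding_density(one, 1000), 1)
  two <- tibble::tibble(start = c(0L, 150L), end = c(300L, 450L))
  expect_equal(coding_density(two, 1000), 0.45)
  # invariant to duplication and order; monotone under adding an ORF
  expect_equal(coding_density(two[c(2, 1, 1, 2), ], 1000), 0.45)
  expect_gte(coding_density(rbind(two, tibble::tibble(start = 600L, end = 699L)), 1000),
             coding_density(two, 1000))
})

# A genome whose only ORF covers exactly `covered` of `total` bases under
# the standard code: ATG + body + TAA, padded with stop-dense spacer.
exact_density_genome <- function(covered, total) {
  n_body <- covered / 3 - 1
  gene <- paste0("ATG", strrep("GCT", n_body), "TAA")
  pad <- total - nchar(gene)
  soup <- "TAATAGTGACTAATAGTGACTAATAGTGAC"
  paste0(gene, substr(strrep(soup, ceiling(pad / nchar(soup))), 1, pad))
}

test_that("the Standard-11 shortcut is strict at 80% coding density", {
  g80 <- exact_density_genome(240, 300)
  g81 <- exact_density_genome(243, 300)
  expect_equal(coding_density(call_orfs(g80, 11), 300), 0.80)
  expect_equal(coding_density(call_orfs(g81, 11), 300), 0.81)
  # exactly 0.80: not over the threshold, alternatives ARE evaluated
  at <- select_genetic_code(g80, codes = c(11L, 15L))
  expect_equal(at$codes_evaluated[[1]], c(11L, 15L))
  expect_equal(at$code_id, 11L)   # density tie breaks to the lowest table
  # 0.81: the shortcut fires and no alternative is scored
  over <- select_genetic_code(g81, codes = c(11L, 15L))
  expect_equal(over$codes_evaluated[[1]], 11L)
  expect_equal(over$code_id, 11L)
  expect_error(select_genetic_code(g80, codes = c(4L, 15L)), "table 11")
  expect_error(select_genetic_code(""), "empty")
})

test_that("a TAG-recoded genome is assigned code 15 over the standard code", {
  g <- generate_coded_genome(15, length_bp = 12000, target_density = 0.85,
                             seed = 207)
  expect_lt(abs(g$density - 0.85), 0.05)
  sel <- select_genetic_code(g$sequence, codes = c(11L, 15L))
  expect_equal(sel$code_id, 15L)
  expect_lt(sel$density_code11, 0.5)
})

test_that("planted codes are recovered over the full candidate list", {
  for (cid in c(11L, 6L, 14L)) {
    for (s in 1:2) {
      g <- generate_coded_genome(cid, length_bp = 12000, seed = 1000L * cid + s)
      sel <- select_genetic_code(g$sequence)
      expect_equal(sel$code_id, cid)
      if (cid == 11L) expect_equal(sel$codes_evaluated[[1]], 11L)
    }
  }
})

test_that("multi-record FASTA scoring keeps records independent", {
  g6 <- generate_coded_genome(6, length_bp = 9000, seed = 31)
  g11 <- generate_coded_genome(11, length_bp = 9000, seed = 32)
  f <- withr::local_tempfile(fileext = ".fna")
  write_genome_fasta(c(pA = g6$sequence, pB = g11$sequence), f)
  res <- select_genetic_code_fasta(f)
  expect_equal(res$code_id[match(c("pA", "pB"), res$genome_id)], c(6L, 11L))
})
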