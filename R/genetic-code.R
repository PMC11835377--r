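#' Candidate genetic codes
#'
#' The NCBI translation tables scanned when selecting a genome's genetic
#' code: 1, 2, 3, 4, 5, 6, 9, 10, 11, 12, 13, 14, 15, 16, 21, 22, 23, 24,
#' 25 (the tables supported by prokaryotic gene callers).
#'
#' @return Integer vector of NCBI table numbers.
#' @export
candidate_genetic_codes <- function() {
  c(1L, 2L, 3L, 4L, 5L, 6L, 9L, 10L, 11L, 12L, 13L, 14L, 15L, 16L,
    21L, 22L, 23L, 24L, 25L)
}

#' Genetic-code specification
#'
#' Stop codons are taken from the NCBI translation tables (via Biostrings),
#' so e.g. table 15 reassigns TAG and keeps TAA/TGA as stops.  Start codons
#' default to the common prokaryotic set ATG/GTG/TTG.
#'
#' @param code_id NCBI translation table number.
#' @param start_codons Character vector of start codons.
#' @return A list with `code_id`, `stop_codons`, `start_codons`
#'   (class `genetic_code_spec`).
#' @export
genetic_code_spec <- function(code_id, start_codons = c("ATG", "GTG", "TTG")) {
  code_id <- as.integer(code_id)
  if (!code_id %in% candidate_genetic_codes()) {
    abort(paste0("unsupported genetic code table: ", code_id))
  }
  gc <- Biostrings::getGeneticCode(as.character(code_id))
  stops <- names(gc)[gc == "*"]
  if (length(intersect(stops, start_codons)) > 0L) {
    start_codons <- setdiff(start_codons, stops)
  }
  structure(list(code_id = code_id, stop_codons = stops,
                 start_codons = start_codons),
            class = "genetic_code_spec")
}

#' Call open reading frames in all six frames
#'
#' A deliberately simple ORF caller: in every frame on both strands, each
#' stop-to-stop segment yields at most one ORF, running from the first start
#' codon after the previous stop to the next in-frame stop.  The stop codon
#' is excluded from the reported interval; a terminating stop is required
#' (no read-through over the sequence end).  Codons containing N are read
#' through (neither start nor stop).
#'
#' @param sequence A nucleotide string over A/C/G/T/N (or a `DNAString`).
#' @param code A [genetic_code_spec()] (or NCBI table number).
#' @param min_len Minimum ORF length in nucleotides (multiple of 3,
#'   default 90).
#' @return A tibble with 0-based half-open intervals: `start`, `end`,
#'   `strand` (`+`/`-`), `frame` (0..2 on its strand), `length`.
#' @export
call_orfs <- function(sequence, code, min_len = 90L) {
  if (!inherits(code, "genetic_code_spec")) code <- genetic_code_spec(code)
  if (min_len %% 3L != 0L || min_len < 3L) abort("`min_len` must be a positive multiple of 3")
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  if (L < min_len) return(empty_orfs())
  rc <- revcomp(s)
  out <- list()
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else rc
    for (frame in 0:2) {
      orfs <- orfs_in_frame(str_seq, L, frame, code, min_len)
      if (nrow(orfs) == 0L) next
      if (strand == "-") {
        tmp_start <- L - orfs$end
        orfs$end <- L - orfs$start
        orfs$start <- tmp_start
      }
      orfs$strand <- strand
      orfs$frame <- frame
      out[[length(out) + 1L]] <- orfs
    }
  }
  if (length(out) == 0L) return(empty_orfs())
  res <- dplyr::bind_rows(out)
  res$length <- res$end - res$start
  dplyr::arrange(res[c("start", "end", "strand", "frame", "length")],
                 .data$start, .data$end, .data$strand)
}

empty_orfs <- function() {
  tibble::tibble(start = integer(), end = integer(), strand = character(),
                 frame = integer(), length = integer())
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# ORFs in one frame of one strand; coordinates 0-based on that strand.
orfs_in_frame <- function(s, L, frame, code, min_len) {
  n_codon <- (L - frame) %/% 3L
  if (n_codon < min_len %/% 3L + 1L) return(empty_orfs())
  starts0 <- frame + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, starts0 + 1L, starts0 + 3L)
  is_stop <- codons %in% code$stop_codons
  is_start <- codons %in% code$start_codons
  stop_idx <- which(is_stop)
  if (length(stop_idx) == 0L) return(empty_orfs())
  seg_begin <- c(1L, head(stop_idx, -1L) + 1L)
  res_start <- integer(0)
  res_end <- integer(0)
  for (i in seq_along(stop_idx)) {
    lo <- seg_begin[[i]]
    hi <- stop_idx[[i]] - 1L
    if (hi < lo) next
    st <- which(is_start[lo:hi])
    if (length(st) == 0L) next
    first_start <- lo + st[[1L]] - 1L
    len <- 3L * (stop_idx[[i]] - first_start)
    if (len >= min_len) {
      res_start <- c(res_start, starts0[[first_start]])
      res_end <- c(res_end, starts0[[first_start]] + len)
    }
  }
  tibble::tibble(start = res_start, end = res_end,
                 strand = NA_character_, frame = NA_integer_,
                 length = res_end - res_start)
}

#' Coding density of a genome
#'
#' Fraction of genome bases covered by at least one ORF.  The base-interval
#' union is used (not summed ORF lengths), so overlapping six-frame ORFs
#' cannot push the density above 1.
#'
#' @param orfs ORF tibble from [call_orfs()].
#' @param genome_length Genome length in bases (> 0).
#' @return A number in `[0, 1]`.
#' @export
coding_density <- function(orfs, genome_length) {
  if (genome_length <= 0) abort("`genome_length` must be > 0")
  if (nrow(orfs) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = orfs$start + 1L, end = orfs$end))
  sum(IRanges::width(ir)) / genome_length
}

#' Select a genome's genetic code by coding density
#'
#' Implements the density-maximisation rule with the Standard-11 shortcut:
#' the genome is first scored under table 11; if its coding density exceeds
#' `shortcut_threshold` (strictly), table 11 is returned *without* testing
#' the alternatives (avoiding over-prediction of short genes under
#' stop-poor codes).  Otherwise every candidate code is scored and the
#' highest-density one returned, ties broken to the lowest table number.
#'
#' @param sequence Nucleotide string (or `DNAString`).
#' @param codes Integer vector of candidate tables; must contain 11.
#' @param shortcut_threshold Density above which the standard code is
#'   accepted outright (default 0.80, strict `>`).
#' @param min_len Minimum ORF length passed to [call_orfs()].
#' @return A one-row tibble: `code_id`, `density`, `density_code11`, and a
#'   list-column `codes_evaluated` with the tables actually scored.
#' @export
select_genetic_code <- function(sequence, codes = candidate_genetic_codes(),
                                shortcut_threshold = 0.80, min_len = 90L) {
  s <- as.character(sequence)
  if (!nzchar(s)) abort("empty sequence")
  codes <- as.integer(codes)
  if (!11L %in% codes) abort("candidate `codes` must include table 11")
  d11 <- coding_density(call_orfs(s, 11L, min_len), nchar(s))
  if (d11 > shortcut_threshold) {
    return(tibble::tibble(code_id = 11L, density = d11, density_code11 = d11,
                          codes_evaluated = list(11L)))
  }
  dens <- vapply(codes, function(cid) {
    if (cid == 11L) d11 else coding_density(call_orfs(s, cid, min_len), nchar(s))
  }, numeric(1))
  ord <- order(-dens, codes)
  best <- ord[[1L]]
  tibble::tibble(code_id = codes[[best]], density = dens[[best]],
                 density_code11 = d11, codes_evaluated = list(codes))
}

#' Score every record of a genome FASTA for its genetic code
#'
#' @param fasta Path to a (multi-record) nucleotide FASTA.
#' @param ... Passed to [select_genetic_code()].
#' @return A tibble with one row per record: `genome_id`, `code_id`,
#'   `density`, `density_code11`.
#' @export
select_genetic_code_fasta <- function(fasta, ...) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  purrr::map2_dfr(as.character(seqs), names(seqs), function(s, id) {
    res <- select_genetic_code(s, ...)
    tibble::tibble(genome_id = sub("\\s.*$", "", id),
                   code_id = res$code_id, density = res$density,
                   density_code11 = res$density_code11)
  })
}
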