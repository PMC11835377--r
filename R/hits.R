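#' Read a per-gene homology hit table
#'
#' Reads gene-to-VOG homology hits either from an `hmmsearch --tblout` file
#' or from a plain five-column TSV (`gene_id`, `genome_id`, `vog_id`,
#' `bitscore`, `evalue`), applying the E-value screen used to call a hit
#' significant.  The screen is a *strict* inequality: a row whose E-value
#' equals `evalue_max` is discarded.
#'
#' In the tblout dialect there is no genome column; the genome id is derived
#' from the gene id by stripping a trailing `_<index>` (the usual
#' gene-numbering convention of prokaryotic gene callers), unless an explicit
#' `genome_map` is supplied.
#'
#' @param path Path to the hit table.
#' @param evalue_max Retain hits with `evalue < evalue_max` (strict).
#' @param format `"auto"` (default), `"tblout"` or `"tsv"`.
#' @param genome_map Optional data frame with columns `gene_id`, `genome_id`
#'   overriding the derived genome ids.
#' @param on_malformed `"warn"` (report offending line numbers and drop the
#'   rows) or `"error"`.
#' @return A tibble with columns `gene_id`, `genome_id`, `vog_id`,
#'   `bitscore`, `evalue`.
#' @export
parse_hit_table <- function(path, evalue_max = 1e-5,
                            format = c("auto", "tblout", "tsv"),
                            genome_map = NULL,
                            on_malformed = c("warn", "error")) {
  format <- match.arg(format)
  on_malformed <- match.arg(on_malformed)
  if (!file.exists(path)) {
    abort(paste0("hit table not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(body) == 0L) {
    warn(paste0("hit table is empty: ", path))
    return(empty_hits())
  }
  if (format == "auto") {
    n_fields <- length(strsplit(trimws(body[[1]]), "\\s+")[[1]])
    format <- if (n_fields >= 18L || any(grepl("^#", lines))) "tblout" else "tsv"
  }
  fields <- strsplit(trimws(body), "\\s+")

  if (format == "tblout") {
    ok_len <- vapply(fields, length, integer(1)) >= 6L
    raw <- tibble::tibble(
      line = line_no[ok_len],
      gene_id = vapply(fields[ok_len], `[[`, "", 1L),
      vog_id = vapply(fields[ok_len], `[[`, "", 3L),
      bitscore = suppressWarnings(as.numeric(vapply(fields[ok_len], `[[`, "", 6L))),
      evalue = suppressWarnings(as.numeric(vapply(fields[ok_len], `[[`, "", 5L)))
    )
    raw$genome_id <- if (is.null(genome_map)) {
      sub("_[0-9]+$", "", raw$gene_id)
    } else {
      genome_map$genome_id[match(raw$gene_id, genome_map$gene_id)]
    }
    bad <- line_no[!ok_len]
  } else {
    ok_len <- vapply(fields, length, integer(1)) >= 5L
    raw <- tibble::tibble(
      line = line_no[ok_len],
      gene_id = vapply(fields[ok_len], `[[`, "", 1L),
      genome_id = vapply(fields[ok_len], `[[`, "", 2L),
      vog_id = vapply(fields[ok_len], `[[`, "", 3L),
      bitscore = suppressWarnings(as.numeric(vapply(fields[ok_len], `[[`, "", 4L))),
      evalue = suppressWarnings(as.numeric(vapply(fields[ok_len], `[[`, "", 5L)))
    )
    # tolerate a header row
    if (nrow(raw) > 0L && is.na(raw$bitscore[[1]]) &&
        tolower(raw$gene_id[[1]]) %in% c("gene_id", "gene")) {
      raw <- raw[-1L, ]
    }
    bad <- line_no[!ok_len]
  }

  bad_num <- raw$line[is.na(raw$bitscore) | is.na(raw$evalue) | raw$evalue < 0]
  bad <- sort(c(bad, bad_num))
  if (length(bad) > 0L) {
    msg <- paste0("malformed hit rows at line(s) ", paste(bad, collapse = ", "),
                  " in ", path)
    if (on_malformed == "error") abort(msg) else warn(msg)
    raw <- raw[!raw$line %in% bad_num, ]
  }

  out <- dplyr::filter(raw, .data$evalue < evalue_max)
  dplyr::select(out, "gene_id", "genome_id", "vog_id", "bitscore", "evalue")
}

empty_hits <- function() {
  tibble::tibble(gene_id = character(), genome_id = character(),
                 vog_id = character(), bitscore = numeric(),
                 evalue = numeric())
}

#' Keep each gene's best VOG hit
#'
#' Resolves multi-family hits by keeping, per gene, the hit with the highest
#' bitscore.  Ties are broken by lower E-value, then by lexicographically
#' smallest VOG id, so the result does not depend on the input row order.
#'
#' @param hits A hit tibble as returned by [parse_hit_table()].
#' @return A tibble with exactly one row per `(genome_id, gene_id)`.
#' @export
assign_best_vog <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits |>
    dplyr::arrange(.data$genome_id, .data$gene_id,
                   dplyr::desc(.data$bitscore), .data$evalue, .data$vog_id) |>
    dplyr::distinct(.data$genome_id, .data$gene_id, .keep_all = TRUE)
}
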