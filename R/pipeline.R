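#' Run the full profile-to-phylogeny pipeline
#'
#' Chains the stages: parse hits -> best-hit assignment -> profile matrix
#' -> prevalence subset -> minimum-VOG genome filter -> binary fasta ->
#' ascertainment-corrected ML tree, with optional dereplication,
#' co-occurrence analysis and bootstrap.  All outputs plus a manifest
#' (resolved parameters, input checksums, seed) are written to `out_dir`;
#' reruns with the same inputs and seed are byte-identical for the binary
#' fasta and the Newick tree.
#'
#' @param hits Path to a hit table (tblout or TSV).
#' @param genome_meta Path to a metadata TSV (`genome_id`, `length_bp`,
#'   optional `family_label`, `source_label`), or a data frame.
#' @param out_dir Output directory (created if missing).
#' @param evalue_max Hit E-value threshold (strict `<`; default 1e-5).
#' @param fraction Prevalence threshold (default 0.005).
#' @param min_vogs Minimum VOGs per genome (default 5).
#' @param use_asc Ascertainment correction for the tree stage.
#' @param boot Bootstrap replicates (0 = none).
#' @param derep_height Dereplication cut height (`NULL` = skip).
#' @param cooccur Also run the co-occurrence stage.
#' @param r_min,member_frac Co-occurrence parameters.
#' @param seed Integer seed for the stochastic stages.
#' @return Invisibly, a list with the fitted tree (`gtr2_fit`), the final
#'   profile and the manifest.
#' @export
run_pipeline <- function(hits, genome_meta, out_dir,
                         evalue_max = 1e-5, fraction = 0.005, min_vogs = 5L,
                         use_asc = TRUE, boot = 0L, derep_height = NULL,
                         cooccur = FALSE, r_min = 0.7, member_frac = 0.8,
                         seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  file.create(log_path)

  meta <- stage("metadata", {
    if (is.character(genome_meta)) {
      if (!file.exists(genome_meta)) {
        abort(paste0("genome metadata not found: ", genome_meta))
      }
      readr::read_tsv(genome_meta, show_col_types = FALSE)
    } else {
      tibble::as_tibble(genome_meta)
    }
  })

  hit_tbl <- stage("parse_hits", parse_hit_table(hits, evalue_max = evalue_max))
  logf("parsed %d significant hits (E < %g)", nrow(hit_tbl), evalue_max)

  best <- stage("best_hit", assign_best_vog(hit_tbl))
  profile <- stage("profile", build_profile_matrix(best, meta))
  write_profile_tsv(profile, file.path(out_dir, "profile.tsv"))
  logf("profile: %d genomes x %d VOGs", nrow(profile), ncol(profile) - 1L)

  sub <- stage("subset", subset_by_prevalence(profile, fraction))
  filt <- stage("filter", filter_genomes_min_vogs(sub, min_vogs))
  write_profile_tsv(filt, file.path(out_dir, "profile_filtered.tsv"))
  logf("after prevalence %g and >= %d VOGs: %d genomes x %d VOGs",
       fraction, min_vogs, nrow(filt), ncol(filt) - 1L)

  bfa <- file.path(out_dir, "profile.bfa")
  stage("binarize", write_binary_fasta(filt, bfa))

  fit <- stage("tree", {
    aln <- read_binary_fasta(bfa)
    if (use_asc) {
      const <- constant_sites(aln)
      if (length(const) > 0L) {
        logf("dropping %d constant column(s) for the ascertainment-corrected model",
             length(const))
        keep <- setdiff(seq_len(aln$n_sites), const)
        aln <- binary_alignment(aln$characters[, keep, drop = FALSE])
      }
    }
    fit_binary_tree(aln, use_asc = use_asc)
  })
  tree_out <- fit$tree
  if (boot > 0L) {
    tree_out <- stage("bootstrap", {
      bootstrap_support(alignment_from_fit(filt, use_asc), n_reps = boot,
                        seed = seed, tree = fit, use_asc = use_asc)
    })
  }
  ape::write.tree(tree_out, file.path(out_dir, "tree.nwk"))
  logf("ML tree: lnL = %.6f, pi1 = %.4f, %d NNI round(s)",
       fit$log_likelihood, fit$model$pi1, fit$nni_rounds)

  if (!is.null(derep_height)) {
    derep <- stage("dereplicate",
                   dereplicate_profiles(filt, meta, height = derep_height))
    readr::write_tsv(derep, file.path(out_dir, "clusters.tsv"))
    logf("dereplication at height %g: %d clusters", derep_height,
         length(unique(derep$cluster_id)))
  }

  if (isTRUE(cooccur)) {
    stage("cooccurrence", {
      corr <- pearson_vog_correlations(profile)
      sets <- detect_cooccurring_sets(corr, r_min = r_min)
      sets_m <- assign_all_set_members(profile, sets, min_frac = member_frac)
      flat <- dplyr::mutate(
        sets_m,
        vog_ids = vapply(.data$vog_ids, paste, "", collapse = ","),
        member_genomes = vapply(.data$member_genomes, paste, "", collapse = ","))
      readr::write_tsv(flat, file.path(out_dir, "cooccurring_sets.tsv"))
      logf("co-occurrence: %d set(s) at r > %g", nrow(sets), r_min)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vogtree")),
    inputs = list(
      hits = if (is.character(hits)) normalizePath(hits) else "in-memory",
      hits_md5 = if (is.character(hits)) unname(tools::md5sum(hits)) else NA,
      genome_meta = if (is.character(genome_meta)) normalizePath(genome_meta) else "in-memory"),
    parameters = list(evalue_max = evalue_max, fraction = fraction,
                      min_vogs = min_vogs, use_asc = use_asc, boot = boot,
                      derep_height = derep_height, cooccur = cooccur,
                      r_min = r_min, member_frac = member_frac, seed = seed),
    results = list(n_genomes = nrow(filt), n_vogs = ncol(filt) - 1L,
                   log_likelihood = fit$log_likelihood,
                   pi1 = fit$model$pi1))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, profile = filt, manifest = manifest,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

alignment_from_fit <- function(profile, use_asc) {
  aln <- binary_alignment(profile)
  if (use_asc) {
    const <- constant_sites(aln)
    if (length(const) > 0L) {
      keep <- setdiff(seq_len(aln$n_sites), const)
      aln <- binary_alignment(aln$characters[, keep, drop = FALSE])
    }
  }
  aln
}
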