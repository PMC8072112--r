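# End-to-end orchestration: simulate (or load) -> annotate -> SSP/SHM ->
# dedup/features/stereotypy -> usage statistics, with a manifest recording
# the seed and configuration hash so a run is reproducible byte for byte.

#' Run the full repertoire analysis
#'
#' Two entry modes:
#' \itemize{
#'   \item synthetic mode (default): simulate a cohort under `sim`, annotate
#'     it against the base germline, call SSP-corrected mutations, then run
#'     the downstream accounting and statistics;
#'   \item pre-annotated mode (`rearrangement` given): skip simulation,
#'     alignment and mutation calling, and run deduplication, features,
#'     stereotypy and statistics directly on an existing rearrangement table
#'     (tibble or TSV path). Useful for published clone tables that lack raw
#'     nucleotide sequences.
#' }
#'
#' Outputs written under `outdir`: `rearrangement.tsv`, `ssp_table.tsv`
#' (synthetic mode), `features.tsv`, `canonical_clones.tsv`,
#' `stereotypes.tsv`, `summary.json`, `manifest.json`.
#'
#' @param outdir Output directory (created if needed).
#' @param sim A [sim_config()] for synthetic mode.
#' @param rearrangement Optional pre-annotated rearrangement table (tibble or
#'   path to a TSV) switching to pre-annotated mode.
#' @param expansion_min_fraction,expansion_min_count Expansion thresholds for
#'   [canonicalize_clones()].
#' @param ssp_min_fraction,ssp_min_mice SSP thresholds for [call_ssps()].
#' @param d_min_len,v_identity_floor Annotation thresholds, see
#'   [annotate_clones()].
#' @param mc_reps,stats_seed Monte Carlo settings for [chi_square_tests()].
#' @param verbose Log stage boundaries with record counts.
#' @return (Invisibly) a list with the stage results: `rearrangement`,
#'   `ssp_table`, `canonical`, `features`, `stereotypes`, `summary`,
#'   `manifest`.
#' @export
run_full_analysis <- function(outdir,
                              sim = sim_config(),
                              rearrangement = NULL,
                              expansion_min_fraction = 0.20,
                              expansion_min_count = 2L,
                              ssp_min_fraction = 0.5,
                              ssp_min_mice = 2L,
                              d_min_len = 5L,
                              v_identity_floor = 60,
                              mc_reps = 2000L,
                              stats_seed = 1L,
                              verbose = FALSE) {
  if (v_identity_floor < 0 || v_identity_floor > 100) {
    stop_ighrep("v_identity_floor must be within [0, 100]")
  }
  if (ssp_min_fraction <= 0 || ssp_min_fraction > 1) {
    stop_ighrep("ssp_min_fraction must be in (0, 1]")
  }
  if (expansion_min_fraction < 0 || expansion_min_fraction > 1) {
    stop_ighrep("expansion_min_fraction must be within [0, 1]")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[ighrep] ", ...)

  ssp_table <- NULL
  if (is.null(rearrangement)) {
    say("simulating cohort (seed ", sim$seed, ")")
    cohort <- simulate_cohort(sim)
    say("annotating ", nrow(cohort$clones), " clone records")
    ann <- annotate_clones(cohort$clones, cohort$germline,
                           d_min_len = d_min_len,
                           v_identity_floor = v_identity_floor)
    say("annotation failures: ", sum(!ann$annotation_ok))
    mut <- call_mutations(ann, min_fraction = ssp_min_fraction,
                          min_mice = ssp_min_mice)
    rearr <- mut$rearrangement
    ssp_table <- mut$ssp_table
    config_fingerprint <- rlang::hash(unclass(sim))
  } else {
    rearr <- if (is.character(rearrangement)) {
      say("reading pre-annotated rearrangement table: ", rearrangement)
      read_rearrangement_table(rearrangement)
    } else {
      as_tibble(rearrangement)
    }
    config_fingerprint <- rlang::hash(rearr)
  }

  say("canonicalizing ", nrow(rearr), " records")
  usable <- if ("annotation_ok" %in% names(rearr)) {
    rearr[rearr$annotation_ok, ]
  } else {
    rearr
  }
  canonical <- canonicalize_clones(usable,
                                   expansion_min_fraction,
                                   expansion_min_count)
  feats <- hcdr3_features(canonical$cdr3_aa)
  canonical$length <- feats$length
  canonical$pI <- feats$pI
  expanded <- canonical[canonical$is_expanded, ]
  stereo <- detect_stereotypes(canonical)

  status <- mutation_status_summary(canonical)
  status_expanded <- if (nrow(expanded) > 0L) {
    mutation_status_summary(canonical, expanded_only = TRUE)
  } else {
    c(UM = NA_real_, M = NA_real_)
  }
  usage_v <- frequency_table(canonical, "V", "gene")
  chi <- NULL
  if ("genotype" %in% names(usable) &&
      length(unique(usable$genotype)) >= 2L) {
    tab_df <- usable
    tab_df$v_subgroup <- if ("v_subgroup" %in% names(tab_df)) {
      tab_df$v_subgroup
    } else {
      segment_subgroup(tab_df$v_call)
    }
    tab <- table(tab_df$v_subgroup, tab_df$genotype)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
      chi <- chi_square_tests(tab, mc_reps = mc_reps, seed = stats_seed)
    }
  }

  summary <- list(
    n_records = nrow(rearr),
    n_canonical = nrow(canonical),
    n_expanded = nrow(expanded),
    percent_um = unname(status[["UM"]]),
    percent_m = unname(status[["M"]]),
    percent_um_expanded = unname(status_expanded[["UM"]]),
    stereotyped_percent = stereo$stereotyped_percent,
    n_stereotype_sets = nrow(stereo$sets),
    hcdr3_length = as.list(summarize_features(canonical, "length")),
    hcdr3_pi = as.list(summarize_features(canonical, "pI")),
    v_gene_usage = usage_v,
    subgroup_genotype_tests = chi
  )

  # outputs
  files <- character()
  w <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    files <<- c(files, name)
    p
  }
  if (all(rearrangement_columns() %in% names(rearr))) {
    write_rearrangement_table(rearr, file.path(outdir, "rearrangement.tsv"))
    files <- c(files, "rearrangement.tsv")
  }
  if (!is.null(ssp_table)) w(ssp_table, "ssp_table.tsv")
  w(cbind(sequence = canonical$cdr3_aa, feats[, -1]), "features.tsv")
  w(canonical, "canonical_clones.tsv")
  w(stereo$sets, "stereotypes.tsv")
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, "summary.json")

  manifest <- list(
    package = "ighrep",
    version = as.character(utils::packageVersion("ighrep")),
    mode = if (is.null(rearrangement)) "synthetic" else "preannotated",
    seed = if (is.null(rearrangement)) sim$seed else NA,
    stats_seed = stats_seed,
    config_hash = config_fingerprint,
    thresholds = list(
      expansion_min_fraction = expansion_min_fraction,
      expansion_min_count = expansion_min_count,
      ssp_min_fraction = ssp_min_fraction,
      ssp_min_mice = ssp_min_mice,
      d_min_len = d_min_len,
      v_identity_floor = v_identity_floor
    ),
    outputs = c(files, "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("wrote ", length(manifest$outputs), " files to ", outdir)
  invisible(list(rearrangement = rearr, ssp_table = ssp_table,
                 canonical = canonical, features = feats,
                 stereotypes = stereo, summary = summary,
                 manifest = manifest))
}
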