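# Clonotype accounting: deduplication across tissues and allotransplants,
# expansion flags, stereotypy detection and HCDR3 similarity search.

#' Collapse clone records into canonical clones
#'
#' Applies the counting rules used for all frequency statistics: identical
#' clones (same HCDR3) found in different tissues of the same mouse are
#' counted once, and clones recovered from allotransplanted F1 recipients are
#' attributed to (and collapsed into) their parental mouse. A canonical clone
#' is expanded when some sample shows it in at least `expansion_min_count`
#' colonies making up at least `expansion_min_fraction` of that sample.
#'
#' @param annotations Tibble of HCDR3-bearing clone rows with columns
#'   `mouse_id`, `tissue`, `cdr3_aa`, `v_call`, `d_call`, `j_call`,
#'   `mutation_status`, `colony_count`, `is_allotransplant`,
#'   `parental_mouse_id`, and optionally `sample_total` (colonies sequenced in
#'   the record's sample; otherwise the per-(mouse, tissue) sum of
#'   `colony_count` is used). Rows with `NA` HCDR3 are dropped.
#' @param expansion_min_fraction,expansion_min_count Expansion thresholds
#'   (defaults 0.20 and 2).
#' @return A tibble with one row per (parental mouse, HCDR3): `mouse_id`,
#'   `cdr3_aa`, `v_call`, `d_call`, `j_call`, `mutation_status`, `tissues`,
#'   `max_fraction`, `max_count`, `is_expanded`, `n_records`.
#' @export
canonicalize_clones <- function(annotations, expansion_min_fraction = 0.20,
                                expansion_min_count = 2L) {
  df <- annotations
  df <- df[!is.na(df$cdr3_aa) & nzchar(df$cdr3_aa), ]
  if (nrow(df) == 0L) stop_ighrep("no HCDR3-bearing clones to canonicalize")
  bad <- df$is_allotransplant & is.na(df$parental_mouse_id)
  if (any(bad)) {
    stop_ighrep("allotransplant record(s) without parental_mouse_id: ",
                paste(df$mouse_id[bad], collapse = ", "))
  }
  if (!"sample_total" %in% names(df)) {
    df <- df %>%
      group_by(.data$mouse_id, .data$tissue) %>%
      mutate(sample_total = sum(.data$colony_count)) %>%
      ungroup()
  }
  df$parent <- ifelse(df$is_allotransplant, df$parental_mouse_id, df$mouse_id)
  df$fraction <- df$colony_count / df$sample_total
  df %>%
    group_by(.data$parent, .data$cdr3_aa) %>%
    arrange(.data$is_allotransplant, desc(.data$fraction), .by_group = TRUE) %>%
    summarise(
      v_call = .data$v_call[1L],
      d_call = .data$d_call[1L],
      j_call = .data$j_call[1L],
      mutation_status = .data$mutation_status[1L],
      tissues = paste(sort(unique(.data$tissue)), collapse = ","),
      max_fraction = max(.data$fraction),
      max_count = max(.data$colony_count),
      is_expanded = any(.data$colony_count >= expansion_min_count &
                          .data$fraction >= expansion_min_fraction),
      n_records = n(),
      .groups = "drop"
    ) %>%
    rename(mouse_id = "parent") %>%
    arrange(.data$mouse_id, .data$cdr3_aa)
}

#' Unmutated/mutated composition of canonical clones
#'
#' @param canonical Canonical-clone tibble from [canonicalize_clones()].
#' @param expanded_only Restrict to expanded clones.
#' @return Named numeric vector `c(UM = , M = )`, percentages rounded to the
#'   nearest integer.
#' @export
mutation_status_summary <- function(canonical, expanded_only = FALSE) {
  df <- if (expanded_only) canonical[canonical$is_expanded, ] else canonical
  if (nrow(df) == 0L) stop_ighrep("no canonical clones to summarise")
  c(UM = round(100 * mean(df$mutation_status == "UM")),
    M = round(100 * mean(df$mutation_status == "M")))
}

#' Detect stereotyped HCDR3 across mice
#'
#' A stereotype set is a group of canonical clones with identical
#' (anchor-stripped) HCDR3 spanning at least two distinct parental mice —
#' identical receptors in unrelated individuals implying shared antigen
#' selection. With `max_distance = 1`, near-identical HCDR3 of the same
#' length differing at a single residue are merged into the same set
#' (single-linkage).
#'
#' @param canonical Canonical-clone tibble.
#' @param max_distance 0 (exact identity, default) or 1 (Hamming <= 1 mode).
#' @return A list: `sets` (tibble `cdr3_aa`, `n_mice`, `n_clones`,
#'   `mouse_ids`) and `stereotyped_percent` (percent of canonical clones
#'   belonging to any set).
#' @export
detect_stereotypes <- function(canonical, max_distance = 0L) {
  df <- canonical
  if (nrow(df) == 0L) {
    return(list(sets = tibble(cdr3_aa = character(), n_mice = integer(),
                              n_clones = integer(), mouse_ids = character()),
                stereotyped_percent = 0))
  }
  df$set_key <- df$cdr3_aa
  if (max_distance >= 1L) {
    df$set_key <- hamming_cluster(df$cdr3_aa)
  }
  sets <- df %>%
    group_by(.data$set_key) %>%
    summarise(
      cdr3_aa = paste(sort(unique(.data$cdr3_aa)), collapse = "/"),
      n_mice = n_distinct(.data$mouse_id),
      n_clones = n(),
      mouse_ids = paste(sort(unique(.data$mouse_id)), collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$n_mice >= 2L) %>%
    select("cdr3_aa", "n_mice", "n_clones", "mouse_ids") %>%
    arrange(desc(.data$n_mice), .data$cdr3_aa)
  list(
    sets = sets,
    stereotyped_percent = 100 * sum(sets$n_clones) / nrow(df)
  )
}

# Single-linkage clusters of equal-length sequences at Hamming distance <= 1;
# returns a cluster label per input sequence.
hamming_cluster <- function(seqs) {
  u <- unique(seqs)
  n <- length(u)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (nchar(u[i]) != nchar(u[j])) next
      d <- sum(strsplit(u[i], "")[[1L]] != strsplit(u[j], "")[[1L]])
      if (d <= 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- u[roots]
  labels[match(seqs, u)]
}

#' Similarity search of an HCDR3 against an annotated reference set
#'
#' Global alignment against each reference HCDR3 with match +1, mismatch 0
#' (+0.5 when the pair is BLOSUM62-positive, counted as similar), gap -1.
#' Percent similarity is 100 x identities / alignment columns. Queries are
#' short (6-17 residues), so exhaustive global alignment replaces heuristic
#' database search.
#'
#' @param query HCDR3 amino-acid string.
#' @param reference Tibble with columns `cdr3_aa` and `antigen` (annotation
#'   label of the reference receptor).
#' @param min_similarity Reporting threshold in percent (default 75).
#' @return Tibble of hits at or above the threshold, sorted by descending
#'   similarity: `cdr3_aa`, `antigen`, `similarity`.
#' @export
similarity_search <- function(query, reference, min_similarity = 75) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop_ighrep("reference set is empty")
  }
  check_aa(query, "query")
  check_aa(reference$cdr3_aa, "reference cdr3_aa")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  aa <- AA_STANDARD
  sm <- matrix(0, length(aa), length(aa), dimnames = list(aa, aa))
  sm[blosum[aa, aa] > 0] <- 0.5
  diag(sm) <- 1
  alns <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(reference$cdr3_aa),
    subject = Biostrings::AAString(query),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 1
  )
  sim <- 100 * Biostrings::nmatch(alns) / Biostrings::nchar(alns)
  out <- tibble(cdr3_aa = reference$cdr3_aa, antigen = reference$antigen,
                similarity = round(sim, 1))
  out %>%
    filter(.data$similarity >= min_similarity) %>%
    arrange(desc(.data$similarity), .data$cdr3_aa)
}
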