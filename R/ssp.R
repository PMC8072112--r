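# Discrimination of strain-specific polymorphisms (SSP) from somatic
# hypermutation (SHM). Rationale: SHM introduces any of the four nucleotides
# essentially at random across clones, so a mismatch showing the SAME
# substituted nucleotide at the SAME germline position in most clones of a
# gene, across several individuals, is an inherited polymorphism of the
# mouse strain rather than a somatic event. Mismatch counts are corrected by
# removing SSP-attributed mismatches before the unmutated/mutated (UM/M)
# classification.

#' Group annotated clones by IGHV gene for SSP calling
#'
#' Groups are keyed by `v_call` across all genotypes and mice; groups with
#' fewer than 3 clones are flagged ineligible (their mismatches cannot be
#' cross-validated and remain uncorrected SHM candidates).
#'
#' @param annotations Rearrangement tibble from [annotate_clones()].
#' @param min_clones Minimum group size for SSP calling (default 3).
#' @return A tibble: `v_call`, `n_clones`, `n_mice`, `eligible`.
#' @export
group_clones_by_gene <- function(annotations, min_clones = 3L) {
  if (nrow(annotations) == 0L) {
    return(tibble(v_call = character(), n_clones = integer(),
                  n_mice = integer(), eligible = logical()))
  }
  annotations %>%
    group_by(.data$v_call) %>%
    summarise(n_clones = n(), n_mice = n_distinct(.data$mouse_id),
              .groups = "drop") %>%
    mutate(eligible = .data$n_clones >= min_clones)
}

#' Call strain-specific polymorphisms within one gene group
#'
#' A (position, observed nucleotide) mismatch is an SSP iff it is shared by
#' more than `min_fraction` of the group's clones (strict majority at the
#' default 0.5) AND is seen in at least `min_mice` distinct mice. Requiring
#' the same substituted nucleotide — not merely the same position — is what
#' makes recurrence statistically informative.
#'
#' @param group Rearrangement tibble rows sharing one `v_call`, carrying the
#'   `v_mismatches` list column and `mouse_id`.
#' @param min_fraction Fraction of clones (exclusive threshold) in (0, 1].
#' @param min_mice Minimum distinct mice carrying the mismatch.
#' @return SSP table entries sorted by position: `gene`, `position`,
#'   `germline_nt`, `observed_nt`, `support`, `n_mice`, `n_group`.
#' @export
call_ssps <- function(group, min_fraction = 0.5, min_mice = 2L) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop_ighrep("min_fraction must be in (0, 1]")
  }
  empty <- tibble(gene = character(), position = integer(),
                  germline_nt = character(), observed_nt = character(),
                  support = integer(), n_mice = integer(),
                  n_group = integer())
  if (nrow(group) == 0L) return(empty)
  gene <- unique(group$v_call)
  if (length(gene) != 1L) stop_ighrep("group must share a single v_call")
  n_group <- nrow(group)
  mm <- bind_rows(lapply(seq_len(n_group), function(i) {
    m <- group$v_mismatches[[i]]
    if (nrow(m) == 0L) return(NULL)
    mutate(m, mouse_id = group$mouse_id[i])
  }))
  if (is.null(mm) || nrow(mm) == 0L) return(empty)
  tall <- mm %>%
    group_by(.data$position, .data$germline_nt, .data$observed_nt) %>%
    summarise(support = n(), n_mice = n_distinct(.data$mouse_id),
              .groups = "drop")
  tall %>%
    filter(.data$support > min_fraction * n_group,
           .data$n_mice >= min_mice) %>%
    mutate(gene = gene, n_group = n_group) %>%
    select("gene", "position", "germline_nt", "observed_nt", "support",
           "n_mice", "n_group") %>%
    arrange(.data$position)
}

#' Correct a clone's mismatch count for strain polymorphisms
#'
#' Mismatches matching an SSP entry at the same position with the same
#' observed nucleotide are attributed to polymorphism; the remainder are
#' somatic. The SHM percent uses the clone's aligned V length as denominator
#' and is reported to 2 decimals.
#'
#' @param mismatches Tibble of the clone's V mismatches (`position`,
#'   `germline_nt`, `observed_nt`).
#' @param ssps SSP table for the clone's gene (possibly empty).
#' @param aligned_length Aligned V length in nt.
#' @return One-row tibble: `raw_mismatches`, `ssp_count`, `shm_count`,
#'   `shm_percent`, `mutation_status`.
#' @export
compute_corrected_shm <- function(mismatches, ssps, aligned_length) {
  raw <- nrow(mismatches)
  is_ssp <- if (raw == 0L || nrow(ssps) == 0L) {
    logical(raw)
  } else {
    paste(mismatches$position, mismatches$observed_nt) %in%
      paste(ssps$position, ssps$observed_nt)
  }
  ssp_count <- sum(is_ssp)
  shm_count <- raw - ssp_count
  shm_percent <- round(100 * shm_count / aligned_length, 2)
  tibble(
    raw_mismatches = raw,
    ssp_count = as.integer(ssp_count),
    shm_count = as.integer(shm_count),
    shm_percent = shm_percent,
    mutation_status = classify_status(shm_percent)
  )
}

#' Classify mutation status from the SHM percent
#'
#' Unmutated (UM) means at least 98% identity to the germline after SSP
#' correction, i.e. an SHM percent of at most 2; above 2 is mutated (M). The
#' boundary is inclusive on the UM side.
#'
#' @param shm_percent Numeric vector of corrected SHM percentages (>= 0).
#' @return Character vector of `"UM"` / `"M"`.
#' @export
classify_status <- function(shm_percent) {
  if (any(is.na(shm_percent)) || any(shm_percent < 0)) {
    stop_ighrep("shm_percent must be non-negative")
  }
  ifelse(shm_percent <= 2.0, "UM", "M")
}

#' SSP-corrected mutation calls for a whole cohort
#'
#' Applies [group_clones_by_gene()], [call_ssps()] per eligible gene and
#' [compute_corrected_shm()] per clone. Clones of ineligible groups (< 3
#' clones of the gene) are classified from uncorrected mismatch counts and
#' flagged `ssp_uncorrected = TRUE`.
#'
#' @param annotations Rearrangement tibble from [annotate_clones()]. Rows
#'   with `annotation_ok = FALSE` are passed through unclassified.
#' @param min_fraction,min_mice SSP thresholds, see [call_ssps()].
#' @param min_clones Minimum group size for eligibility.
#' @return A list: `rearrangement` (the input with `ssp_count`, `shm_count`,
#'   `shm_percent`, `mutation_status`, `ssp_uncorrected` filled) and
#'   `ssp_table` (all SSP entries across genes).
#' @export
call_mutations <- function(annotations, min_fraction = 0.5, min_mice = 2L,
                           min_clones = 3L) {
  ann <- annotations
  ann$ssp_uncorrected <- FALSE
  groups <- group_clones_by_gene(ann[ann$annotation_ok, ], min_clones)
  ssp_tables <- list()
  for (g in groups$v_call[groups$eligible]) {
    rows <- ann[ann$annotation_ok & ann$v_call == g, ]
    ssp_tables[[g]] <- call_ssps(rows, min_fraction, min_mice)
  }
  ssp_table <- if (length(ssp_tables) > 0L) {
    bind_rows(ssp_tables)
  } else {
    call_ssps(ann[0L, ])
  }
  for (i in seq_len(nrow(ann))) {
    if (!ann$annotation_ok[i]) next
    g <- ann$v_call[i]
    eligible <- g %in% groups$v_call[groups$eligible]
    ssps <- if (eligible) ssp_tables[[g]] else ssp_table[0L, ]
    call <- compute_corrected_shm(ann$v_mismatches[[i]], ssps,
                                  ann$v_aligned_length[i])
    ann$ssp_count[i] <- call$ssp_count
    ann$shm_count[i] <- call$shm_count
    ann$shm_percent[i] <- call$shm_percent
    ann$mutation_status[i] <- call$mutation_status
    ann$ssp_uncorrected[i] <- !eligible
  }
  list(rearrangement = ann, ssp_table = ssp_table)
}
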