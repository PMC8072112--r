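# Germline V/D/J assignment, isotype calling and HCDR3 extraction. This is a
# defined best-match assignment standing in for database annotation tools:
# V and J calls maximise an end-gap-free (overlap) alignment score, the D
# call is the longest exact junction match, and the junction is read in the
# germline V frame from the conserved 2nd-CYS through the J W-G-x-G
# tryptophan.

#' Default amplification primers
#'
#' The degenerate IGHV framework-1 forward primer and the constant-region
#' reverse primers used to amplify IgM/IgG/IgA transcripts.
#'
#' @return Named list of IUPAC nucleotide strings: `v_fwd`, `ch_mu`,
#'   `ch_gamma`, `ch_alpha`.
#' @export
default_primers <- function() DEFAULT_PRIMERS

DEFAULT_PRIMERS <- list(
  v_fwd = "SARGTBMAGCTGSAGSAGTCWGG",
  ch_mu = "CAGATCTCTGTTTTTGCCTCGTA",
  ch_gamma = "ATGCAAGGCTTACACCACAATCC",
  ch_alpha = "TAATAGGAGGAGGAGGAGTAGGAC"
)

#' Match a degenerate (IUPAC) primer against a sequence
#'
#' A primer character matches a sequence base iff the base belongs to the
#' character's IUPAC expansion (e.g. `S` = G/C, `N` = any). Both the primer
#' and its reverse complement are searched.
#'
#' @param sequence Nucleotide string (ACGT).
#' @param primer IUPAC nucleotide string.
#' @param max_mismatch Maximum number of violated positions per window.
#' @return A tibble of hits sorted by position: `position` (1-based start on
#'   `sequence`), `mismatches`, `strand` (`"+"` primer as given, `"-"` its
#'   reverse complement).
#' @export
match_iupac_primer <- function(sequence, primer, max_mismatch = 0L) {
  if (max_mismatch < 0L) stop_ighrep("max_mismatch must be >= 0")
  primer <- toupper(primer)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", primer)) {
    stop_ighrep("primer contains non-IUPAC characters")
  }
  check_nt(toupper(sequence), "sequence")
  subj <- Biostrings::DNAString(toupper(sequence))
  one_strand <- function(p, strand) {
    pat <- Biostrings::DNAString(p)
    if (length(pat) > length(subj)) {
      return(tibble(position = integer(), mismatches = integer(),
                    strand = character()))
    }
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                     fixed = "subject")
    # with max.mismatch > 0 matchPattern also reports windows hanging over
    # the sequence ends; only fully contained windows count
    hits <- hits[Biostrings::start(hits) >= 1L &
                   Biostrings::end(hits) <= length(subj)]
    if (length(hits) == 0L) {
      return(tibble(position = integer(), mismatches = integer(),
                    strand = character()))
    }
    mm <- Biostrings::neditStartingAt(pat, subj,
                                      starting.at = Biostrings::start(hits),
                                      fixed = "subject")
    tibble(position = Biostrings::start(hits), mismatches = as.integer(mm),
           strand = strand)
  }
  fwd <- one_strand(primer, "+")
  rev <- one_strand(revcomp(primer), "-")
  arrange(bind_rows(fwd, rev), .data$position, .data$strand)
}

#' Assign the isotype of a clone from constant-region primer sites
#'
#' Searches the CH-mu, CH-gamma and CH-alpha primer sites (either strand) and
#' returns the isotype whose site is found with the fewest mismatches. Ties
#' and no-hits return `"unknown"`.
#'
#' @param sequence Clone nucleotide sequence.
#' @param primers Primer list as [default_primers()].
#' @param max_mismatch Per-window mismatch tolerance (default 0: the primers
#'   are short and diagnostic).
#' @return One of `"IgM"`, `"IgG"`, `"IgA"`, `"unknown"`.
#' @export
assign_isotype <- function(sequence, primers = default_primers(),
                           max_mismatch = 0L) {
  iso <- c(ch_mu = "IgM", ch_gamma = "IgG", ch_alpha = "IgA")
  best <- vapply(names(iso), function(p) {
    hits <- match_iupac_primer(sequence, primers[[p]], max_mismatch)
    if (nrow(hits) == 0L) Inf else min(hits$mismatches)
  }, numeric(1))
  if (all(is.infinite(best))) return("unknown")
  top <- which(best == min(best))
  if (length(top) > 1L) return("unknown")
  unname(iso[top])
}

# Longest exact contiguous substring of `region` present in `d_seq`.
longest_shared_substring <- function(region, d_seq) {
  max_l <- min(nchar(region), nchar(d_seq))
  for (l in rev(seq_len(max_l))) {
    starts <- seq_len(nchar(region) - l + 1L)
    subs <- unique(substring(region, starts, starts + l - 1L))
    if (any(vapply(subs, grepl, logical(1), x = d_seq, fixed = TRUE))) {
      return(l)
    }
  }
  0L
}

# Alignment scoring used for V and J assignment (overlap alignment, so the
# amplicon may start inside FR1 and segments may be trimmed).
align_params <- function(match = 1, mismatch = -1, gap_open = 4,
                         gap_extend = 1) {
  list(
    mat = Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                   mismatch = mismatch,
                                                   baseOnly = TRUE),
    gap_open = gap_open, gap_extend = gap_extend
  )
}

# Align all clone sequences against one germline segment; returns the
# PairwiseAlignments object (patterns = clones, subject = germline).
align_to_segment <- function(clone_seqs, segment_seq, params) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(clone_seqs),
    subject = Biostrings::DNAString(segment_seq),
    type = "overlap",
    substitutionMatrix = params$mat,
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend
  )
}

# Best segment per clone by score, ties broken by higher identity then
# lexicographic name. `alns` is a list (per segment name) of
# PairwiseAlignments over the same clone set.
pick_best_segment <- function(alns, n_clones) {
  names_sorted <- sort(names(alns))
  score_m <- vapply(names_sorted, function(g) Biostrings::score(alns[[g]]),
                    numeric(n_clones))
  ident_m <- vapply(names_sorted, function(g) {
    100 * Biostrings::nmatch(alns[[g]]) / Biostrings::nchar(alns[[g]])
  }, numeric(n_clones))
  if (n_clones == 1L) {
    score_m <- matrix(score_m, nrow = 1L, dimnames = list(NULL, names_sorted))
    ident_m <- matrix(ident_m, nrow = 1L, dimnames = list(NULL, names_sorted))
  }
  vapply(seq_len(n_clones), function(i) {
    cand <- which(score_m[i, ] == max(score_m[i, ]))
    if (length(cand) > 1L) {
      cand <- cand[ident_m[i, cand] == max(ident_m[i, cand])]
    }
    names_sorted[cand[1L]]  # columns are name-sorted: first = lexicographic
  }, character(1))
}

#' Annotate clone records with germline V/D/J calls, isotype and HCDR3
#'
#' For each clone: the V call maximises an end-gap-free alignment score
#' (match +1, mismatch -1, gap open -4, gap extend -1; ties broken by higher
#' identity then name); the J call is assigned the same way on the region 3'
#' of the V alignment; the D call is the D gene with the longest exact
#' contiguous match (>= `d_min_len`) inside the junction between V and J. The
#' junction is translated in the germline V frame from the conserved 2nd-CYS
#' codon; the HCDR3 (`cdr3_aa`) strips the Cys and the J-Trp anchors.
#' `v_identity` is 100 x matches / aligned columns (gaps count against).
#'
#' Clones whose best V identity falls below `v_identity_floor` are flagged
#' (`annotation_ok = FALSE`, a reason in `fail_reason`) and should be
#' excluded downstream.
#'
#' @param clones Clone-record tibble ([read_clone_fasta()] or
#'   [simulate_cohort()]`$clones`).
#' @param germline Germline tibble with at least one segment of each type.
#' @param primers Primer set for isotype assignment.
#' @param d_min_len Minimum exact D match length (default 5).
#' @param v_identity_floor Minimum acceptable V identity percent (default 60).
#' @param max_mismatch_isotype Mismatch tolerance for isotype primers.
#' @return A rearrangement tibble (one row per clone record) with the
#'   standard columns plus `v_sequence_name`-level internals used by the
#'   SSP/SHM stage: `v_mismatches` (list of per-clone mismatch tables with
#'   `position`, `germline_nt`, `observed_nt`), `v_aligned_length`,
#'   `annotation_ok`, `fail_reason`.
#' @export
annotate_clones <- function(clones, germline, primers = default_primers(),
                            d_min_len = 5L, v_identity_floor = 60,
                            max_mismatch_isotype = 0L) {
  if (v_identity_floor < 0 || v_identity_floor > 100) {
    stop_ighrep("v_identity_floor must be within [0, 100]")
  }
  vs <- germline[germline$segment_type == "V", ]
  ds <- germline[germline$segment_type == "D", ]
  js <- germline[germline$segment_type == "J", ]
  if (nrow(vs) == 0L || nrow(ds) == 0L || nrow(js) == 0L) {
    stop_ighrep("germline must contain at least one V, one D and one J segment")
  }
  params <- align_params()
  n <- nrow(clones)

  v_alns <- lapply(setNames(vs$sequence, vs$name), align_to_segment,
                   clone_seqs = clones$sequence, params = params)
  v_call <- pick_best_segment(v_alns, n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    aln <- v_alns[[v_call[i]]][i]
    v_seq <- vs$sequence[vs$name == v_call[i]]
    v_ident <- round(100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln), 2)
    row <- list(
      sequence_id = clones$record_id[i],
      v_call = v_call[i], d_call = NA_character_, j_call = NA_character_,
      v_identity = v_ident,
      junction_aa = NA_character_, cdr3_aa = NA_character_,
      productive = FALSE,
      isotype = assign_isotype(clones$sequence[i], primers,
                               max_mismatch_isotype),
      v_aligned_length = Biostrings::nchar(aln),
      v_mismatches = list(tibble(position = integer(),
                                 germline_nt = character(),
                                 observed_nt = character())),
      annotation_ok = TRUE, fail_reason = NA_character_
    )
    if (v_ident < v_identity_floor) {
      row$annotation_ok <- FALSE
      row$fail_reason <- "v_identity_below_floor"
      out[[i]] <- row
      next
    }
    p0 <- Biostrings::start(Biostrings::pattern(aln))
    s0 <- Biostrings::start(Biostrings::subject(aln))
    s1 <- Biostrings::end(Biostrings::subject(aln))
    p1 <- Biostrings::end(Biostrings::pattern(aln))
    # mismatches and divergence are quantified on the V region through the
    # conserved Cys codon only: 3' of it the junction's trimming and
    # N-additions make germline attribution ambiguous
    cys_end <- v_cys_start(v_seq) + 2L
    if (is.na(cys_end)) cys_end <- nchar(v_seq)
    mm <- Biostrings::mismatchTable(aln)
    mm <- mm[mm$SubjectStart <= cys_end, , drop = FALSE]
    row$v_mismatches <- list(tibble(
      position = as.integer(mm$SubjectStart),
      germline_nt = as.character(mm$SubjectSubstring),
      observed_nt = as.character(mm$PatternSubstring)
    ))
    row$v_aligned_length <- min(s1, cys_end) - s0 + 1L
    has_indel <- Biostrings::nindel(aln)@insertion[1L, "WidthSum"] > 0 ||
      Biostrings::nindel(aln)@deletion[1L, "WidthSum"] > 0

    # J on the 3' region downstream of the V alignment
    rest_start <- p1 + 1L
    clone_seq <- clones$sequence[i]
    if (rest_start <= nchar(clone_seq) - 20L) {
      rest <- substr(clone_seq, rest_start, nchar(clone_seq))
      j_alns <- lapply(setNames(js$sequence, js$name), align_to_segment,
                       clone_seqs = rest, params = params)
      row$j_call <- pick_best_segment(j_alns, 1L)
      j_aln <- j_alns[[row$j_call]]
      j_start_clone <- rest_start +
        Biostrings::start(Biostrings::pattern(j_aln)) - 1L
      # D: longest exact match inside the junction between V end and J start
      if (j_start_clone - rest_start >= d_min_len) {
        region <- substr(clone_seq, rest_start, j_start_clone - 1L)
        lens <- vapply(ds$sequence, longest_shared_substring,
                       integer(1), region = region)
        best <- max(lens)
        if (best >= d_min_len) {
          cand <- sort(ds$name[lens == best])
          row$d_call <- cand[1L]
        }
      }
    }

    hc <- extract_hcdr3(clone_seq, v_seq, p0, s0, has_indel)
    row$junction_aa <- hc$junction_aa
    row$cdr3_aa <- hc$cdr3_aa
    row$productive <- hc$productive
    if (!is.na(hc$reason)) row$fail_reason <- hc$reason
    out[[i]] <- row
  }
  ann <- bind_rows(lapply(out, function(r) {
    as_tibble(r[setdiff(names(r), "v_mismatches")])
  }))
  ann$v_mismatches <- lapply(out, function(r) r$v_mismatches[[1L]])
  res <- bind_rows(ann)
  res <- dplyr::bind_cols(
    clones[, c("mouse_id", "genotype", "tissue", "sequence", "colony_count",
               "is_allotransplant", "parental_mouse_id")],
    res
  )
  res$ssp_count <- NA_integer_
  res$shm_count <- NA_integer_
  res$shm_percent <- NA_real_
  res$mutation_status <- NA_character_
  res[, c(rearrangement_columns(), "v_aligned_length", "v_mismatches",
          "annotation_ok", "fail_reason")]
}

#' Extract the junction and HCDR3 of an aligned clone
#'
#' Locates the conserved 2nd-CYS as the clone codon aligned to the germline
#' V's final in-frame cysteine, translates from there in the V frame, and
#' takes the junction through the tryptophan of the first in-frame W-G-x-G
#' motif (the J anchor). `cdr3_aa` strips both anchor residues. The clone is
#' productive when both anchors are found in frame and the junction is
#' stop-free.
#'
#' @param clone_seq Clone nucleotide sequence.
#' @param v_germline_seq Germline sequence of the assigned V.
#' @param pattern_start,subject_start 1-based starts of the V alignment on
#'   the clone and the germline.
#' @param has_indel Whether the V alignment contains indels (position mapping
#'   is then ambiguous and extraction is abandoned).
#' @return A list: `junction_aa`, `cdr3_aa`, `productive`, `reason` (NA when
#'   extraction succeeded).
#' @export
extract_hcdr3 <- function(clone_seq, v_germline_seq, pattern_start,
                          subject_start, has_indel = FALSE) {
  fail <- function(reason) {
    list(junction_aa = NA_character_, cdr3_aa = NA_character_,
         productive = FALSE, reason = reason)
  }
  if (has_indel) return(fail("v_indel"))
  cys <- v_cys_start(v_germline_seq)
  if (is.na(cys)) return(fail("no_germline_cys"))
  clone_cys <- pattern_start + (cys - subject_start)
  if (clone_cys < 1L || clone_cys + 2L > nchar(clone_seq)) {
    return(fail("cys_outside_alignment"))
  }
  aa <- translate_nt(substr(clone_seq, clone_cys, nchar(clone_seq)))
  if (substr(aa, 1L, 1L) != "C") return(fail("cys_lost"))
  w <- regexpr("WG.G", aa)[1L]
  if (w == -1L) return(fail("no_j_trp"))
  junction <- substr(aa, 1L, w)
  productive <- !grepl("*", junction, fixed = TRUE)
  list(
    junction_aa = junction,
    cdr3_aa = substr(junction, 2L, nchar(junction) - 1L),
    productive = productive,
    reason = if (productive) NA_character_ else "stop_in_junction"
  )
}
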