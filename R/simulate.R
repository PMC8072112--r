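# Synthetic IGHV-D-J repertoire generator. Emulates the statistical structure
# the analysis assumes: a base ("database") germline pool, a strain germline
# derived from it by planting strain-specific polymorphisms (SSPs) shared by
# every clone of the cohort, clonal V-D-J rearrangements with junction
# trimming and N-additions, per-clone somatic hypermutation (SHM) drawn from
# an unmutated/mutated mixture, and genotype-dependent clonal expansion
# (mono/oligoclonal dominance only in the double-transgenic +/+ group).
# Every random choice is recorded in a ground-truth channel.

# FR1 head matching the degenerate V forward primer used for amplification.
SIM_V_HEAD <- "GAGGTGCAGCTGGAGGAGTCTGG"

# J 5' overhangs (trimmed into during rearrangement; they encode the typical
# ...FDV / ...FAY / ...FDY / ...YAMDY C-terminal CDR3 residues) followed by
# the conserved WGQGTSVTVSS frame-4 region carrying the J tryptophan motif.
SIM_J_PREFIX <- c("TACTGGTACTTCGACGTC", "TTTGCTTAC", "TTTGACTAC",
                  "TATGCTATGGATTAT")
SIM_J_CONST <- "TGGGGTCAAGGAACCTCAGTCACCGTCTCCTCA"

# V 3' tails beyond the conserved Cys codon (first CDR3 residues, e.g. "AR").
SIM_V_TAIL <- c("GCAAGA", "GCAAGC", "GCAACC", "GGAAGA")

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(IGHREP_NT, 3L, replace = TRUE), collapse = "")
      if (!cod %in% STOP_CODONS) break
    }
    out[i] <- cod
  }
  out
}

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic-repertoire generator. Defaults encode
#' the study conditions of the mouse CLL/SLL cohort the package analyses:
#' 5/4/3/8 mice for genotypes -/-, +/-, -/+, +/+ (the genotyping counts of the
#' source cohort), 5-15 colonies sequenced per sample, a per-site SSP rate of
#' 0.0254 (the reported 2.54% average strain divergence), SHM per-site rates
#' of 0-2% for unmutated and 2-5% for mutated founders with a 15% mutated
#' fraction, and Dirichlet clonal-fraction concentrations that make +/+
#' samples mono/oligoclonal (alpha 0.1) and all other genotypes polyclonal
#' (alpha 10).
#'
#' @param n_mice_per_genotype Named integer vector over `-/-`, `+/-`, `-/+`,
#'   `+/+`.
#' @param colonies_per_sample Integer range (length 2) of colonies sequenced
#'   per sample.
#' @param n_v,n_d,n_j Number of germline V, D and J segments.
#' @param v_length V segment length in nt (must be a multiple of 3, >= 120;
#'   includes a 6-nt tail 3' of the conserved Cys codon).
#' @param ssp_rate Per-site probability that a V position carries a
#'   strain-specific polymorphism.
#' @param shm_rate_um,shm_rate_m Per-site SHM rate ranges (uniform draws) for
#'   unmutated- and mutated-component founders.
#' @param prob_mutated_clone Probability a founder clone is drawn from the
#'   mutated component.
#' @param expansion_dirichlet_alpha Named numeric vector (per genotype) of
#'   Dirichlet concentrations controlling clonal dominance.
#' @param trim_max Maximum nt trimmed per junction side.
#' @param n_insert_max Maximum N-nucleotides per junction side.
#' @param stereotype_fraction Fraction of +/+ mice sharing a planted founder
#'   HCDR3 (0 disables planting; at least 2 mice are used when > 0).
#' @param second_tissue_fraction Fraction of +/+ mice sampled in a second
#'   tissue (blood) in addition to spleen.
#' @param allotransplant_fraction Fraction of +/+ mice whose dominant clone is
#'   allotransplanted into an F1 recipient.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration and this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mice_per_genotype = c(`-/-` = 5L, `+/-` = 4L,
                                               `-/+` = 3L, `+/+` = 8L),
                       colonies_per_sample = c(5L, 15L),
                       n_v = 8L, n_d = 4L, n_j = 4L,
                       v_length = 294L,
                       ssp_rate = 0.0254,
                       shm_rate_um = c(0, 0.02),
                       shm_rate_m = c(0.02, 0.05),
                       prob_mutated_clone = 0.15,
                       expansion_dirichlet_alpha = c(`-/-` = 10, `+/-` = 10,
                                                     `-/+` = 10, `+/+` = 0.1),
                       trim_max = 3L,
                       n_insert_max = 6L,
                       stereotype_fraction = 0.3,
                       second_tissue_fraction = 0.25,
                       allotransplant_fraction = 0.25,
                       seed = 1L) {
  cfg <- list(
    n_mice_per_genotype = n_mice_per_genotype,
    colonies_per_sample = as.integer(colonies_per_sample),
    n_v = as.integer(n_v), n_d = as.integer(n_d), n_j = as.integer(n_j),
    v_length = as.integer(v_length),
    ssp_rate = ssp_rate,
    shm_rate_um = shm_rate_um, shm_rate_m = shm_rate_m,
    prob_mutated_clone = prob_mutated_clone,
    expansion_dirichlet_alpha = expansion_dirichlet_alpha,
    trim_max = as.integer(trim_max),
    n_insert_max = as.integer(n_insert_max),
    stereotype_fraction = stereotype_fraction,
    second_tissue_fraction = second_tissue_fraction,
    allotransplant_fraction = allotransplant_fraction,
    seed = as.integer(seed)
  )
  rates <- c(cfg$ssp_rate, cfg$shm_rate_um, cfg$shm_rate_m,
             cfg$prob_mutated_clone)
  if (any(rates < 0 | rates > 1)) {
    stop_ighrep("all rates must be in [0, 1]")
  }
  if (any(cfg$colonies_per_sample < 1L) || any(cfg$colonies_per_sample > 50L) ||
      cfg$colonies_per_sample[1L] > cfg$colonies_per_sample[2L]) {
    stop_ighrep("colonies_per_sample must be an increasing range within [1, 50]")
  }
  if (any(cfg$expansion_dirichlet_alpha <= 0)) {
    stop_ighrep("expansion_dirichlet_alpha must be > 0")
  }
  if (!setequal(names(cfg$n_mice_per_genotype), GENOTYPES) ||
      !setequal(names(cfg$expansion_dirichlet_alpha), GENOTYPES)) {
    stop_ighrep("n_mice_per_genotype and expansion_dirichlet_alpha must be ",
                "named over the four genotypes ",
                paste(GENOTYPES, collapse = " "))
  }
  if (cfg$v_length %% 3L != 0L || cfg$v_length < 120L) {
    stop_ighrep("v_length must be a multiple of 3 and >= 120")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a base germline reference pool
#'
#' Random but structurally realistic segments: V genes share a conserved FR1
#' head matching the degenerate amplification primer and end in a Y-Y-C motif
#' (the conserved 2nd-CYS) followed by a 6-nt CDR3-initiating tail; J genes
#' carry a trimmable 5' overhang followed by the conserved W-G-Q-G frame; D
#' genes are short random segments. Subgroup labels cycle over the murine
#' IGHV1/IGHV5/IGHV14/IGHV3 families.
#'
#' @param n_v,n_d,n_j Segment counts.
#' @param v_length V length in nt (multiple of 3, includes the 6-nt tail).
#' @param seed Optional integer seed.
#' @return A germline tibble (`name`, `segment_type`, `subgroup`, `sequence`,
#'   `functionality`).
#' @export
make_base_germline <- function(n_v = 8L, n_d = 4L, n_j = 4L,
                               v_length = 294L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (v_length %% 3L != 0L || v_length < 120L) {
    stop_ighrep("v_length must be a multiple of 3 and >= 120")
  }
  v_fams <- rep(c("IGHV1", "IGHV5", "IGHV14", "IGHV3"), length.out = n_v)
  n_cod <- (v_length - 6L) %/% 3L
  v_seq <- vapply(seq_len(n_v), function(i) {
    head_fill <- sample(IGHREP_NT, 1L)  # completes codon 8 (GG + x, glycine)
    mid <- random_codons(n_cod - 8L - 3L)
    tail6 <- sample(SIM_V_TAIL, 1L)
    paste0(SIM_V_HEAD, head_fill, paste(mid, collapse = ""),
           "TAT", "TAC", "TGT", tail6)
  }, character(1))
  v <- tibble(
    name = sprintf("%s-S%02d*01", v_fams, seq_len(n_v)),
    segment_type = "V", subgroup = v_fams, sequence = v_seq,
    functionality = "F"
  )
  d_fams <- rep(c("D1", "D2", "D3", "D4"), length.out = n_d)
  # D segments are whole non-stop codons (12-21 nt) so an untrimmed,
  # uninserted V-D-J concatenation is open in the V reading frame
  d_seq <- vapply(seq_len(n_d), function(i) {
    paste(random_codons(sample(4:7, 1L)), collapse = "")
  }, character(1))
  d <- tibble(
    name = sprintf("IGHD%s-S%02d", sub("^D", "", d_fams), seq_len(n_d)),
    segment_type = "D", subgroup = d_fams, sequence = d_seq,
    functionality = "F"
  )
  j_pref <- if (n_j <= length(SIM_J_PREFIX)) {
    SIM_J_PREFIX[seq_len(n_j)]
  } else {
    c(SIM_J_PREFIX,
      vapply(seq_len(n_j - length(SIM_J_PREFIX)), function(i) {
        paste(random_codons(sample(3:5, 1L)), collapse = "")
      }, character(1)))
  }
  j <- tibble(
    name = sprintf("IGHJ%d", seq_len(n_j)),
    segment_type = "J", subgroup = sprintf("IGHJ%d", seq_len(n_j)),
    sequence = paste0(j_pref, SIM_J_CONST),
    functionality = "F"
  )
  bind_rows(v, d, j)
}

# 1-based start of the conserved 2nd-CYS codon on a germline V (the last Cys
# of the in-frame translation; the canonical V ends Y-Y-C + short tail).
v_cys_start <- function(v_sequence) {
  aa <- translate_nt(v_sequence)
  pos <- gregexpr("C", aa, fixed = TRUE)[[1L]]
  if (pos[1L] == -1L) return(NA_integer_)
  3L * pos[length(pos)] - 2L
}

#' Derive a strain germline by planting strain-specific polymorphisms
#'
#' Each V segment independently receives Binomial(n, ssp_rate) substitutions
#' at uniform positions 5' of the conserved Cys codon, with uniform
#' alternative nucleotides. All clones of a simulated cohort are rearranged
#' from this one strain germline, which is what makes SSPs conserved across
#' individuals while SHM is not. D and J segments are left unchanged (the
#' analysis quantifies divergence on the V region only).
#'
#' @param base Germline tibble.
#' @param ssp_rate Per-site substitution probability in [0, 1].
#' @param seed Optional integer seed.
#' @return A list: `germline` (the strain pool) and `ssp_truth`, a tibble of
#'   planted substitutions (`gene`, `position`, `germline_nt`, `strain_nt`).
#' @export
derive_strain_germline <- function(base, ssp_rate = 0.0254, seed = NULL) {
  if (ssp_rate < 0 || ssp_rate > 1) stop_ighrep("ssp_rate must be in [0, 1]")
  if (!is.null(seed)) withr::local_seed(seed)
  strain <- base
  truth <- list()
  vi <- which(base$segment_type == "V")
  for (i in vi) {
    seq0 <- base$sequence[i]
    n_elig <- v_cys_start(seq0) - 1L
    k <- rbinom(1L, n_elig, ssp_rate)
    if (k == 0L) next
    pos <- sort(sample.int(n_elig, k))
    chars <- strsplit(seq0, "")[[1L]]
    old <- chars[pos]
    new <- vapply(old, function(nt) sample(setdiff(IGHREP_NT, nt), 1L),
                  character(1), USE.NAMES = FALSE)
    chars[pos] <- new
    strain$sequence[i] <- paste(chars, collapse = "")
    truth[[length(truth) + 1L]] <- tibble(
      gene = base$name[i], position = pos, germline_nt = old, strain_nt = new
    )
  }
  ssp_truth <- if (length(truth) > 0L) {
    bind_rows(truth)
  } else {
    tibble(gene = character(), position = integer(),
           germline_nt = character(), strain_nt = character())
  }
  list(germline = strain, ssp_truth = ssp_truth)
}

# Draw a junction spec: trims, N-insert strings, with the J tryptophan kept
# in the V reading frame and no stop codon (and no premature W-G-x-G) in the
# junction. Returns NULL if no valid draw is found within the retry budget.
draw_junction_spec <- function(v_seq, d_seq, j_seq, cfg,
                               max_retries = 50L) {
  j_prefix_len <- nchar(j_seq) - nchar(SIM_J_CONST)
  cys <- v_cys_start(v_seq)
  v_len <- nchar(v_seq)
  tail_len <- v_len - cys - 2L  # nt 3' of the Cys codon
  for (try in seq_len(max_retries)) {
    t1 <- sample(0:min(cfg$trim_max, tail_len), 1L)
    t_d5 <- sample(0:cfg$trim_max, 1L)
    t_d3 <- sample(0:cfg$trim_max, 1L)
    # keep >= 8 nt of D so the exact-match D assignment stays identifiable
    # even when the V or J alignment absorbs a few junction nucleotides
    d_kept <- nchar(d_seq) - t_d5 - t_d3
    if (d_kept < 8L) next
    t4 <- sample(0:min(cfg$trim_max, j_prefix_len - 6L), 1L)
    n1 <- sample(0:cfg$n_insert_max, 1L)
    n2 <- sample(0:cfg$n_insert_max, 1L)
    # shift n2 so the distance from the Cys codon to the J Trp codon is a
    # multiple of 3 (frame-consistent, hence productive, junction)
    base_len <- (3L + tail_len - t1) + n1 + d_kept + (j_prefix_len - t4)
    n2 <- n2 + (3L - (base_len + n2) %% 3L) %% 3L
    if (n2 > cfg$n_insert_max) n2 <- n2 - 3L
    if (n2 < 0L) next
    ins1 <- paste(sample(IGHREP_NT, n1, replace = TRUE), collapse = "")
    ins2 <- paste(sample(IGHREP_NT, n2, replace = TRUE), collapse = "")
    spec <- list(t1 = t1, t_d5 = t_d5, t_d3 = t_d3, t4 = t4,
                 ins1 = ins1, ins2 = ins2,
                 j_prefix_kept = substr(j_seq, t4 + 1L, j_prefix_len))
    jn <- junction_nt(v_seq, d_seq, spec)
    aa <- translate_nt(jn)
    # reject stops within the junction and chance W-G-x-G upstream of the
    # real J tryptophan (checked in the context of the J constant frame)
    if (grepl("*", aa, fixed = TRUE)) next
    aa_ctx <- translate_nt(paste0(jn, substr(SIM_J_CONST, 4L,
                                             nchar(SIM_J_CONST))))
    if (regexpr("WG.G", aa_ctx)[1L] != nchar(aa)) next
    return(spec)
  }
  NULL
}

# Junction nucleotides from the Cys codon through the J Trp codon inclusive.
junction_nt <- function(v_seq, d_seq, spec) {
  cys <- v_cys_start(v_seq)
  v_kept <- substr(v_seq, cys, nchar(v_seq) - spec$t1)
  d_kept <- substr(d_seq, spec$t_d5 + 1L, nchar(d_seq) - spec$t_d3)
  paste0(v_kept, spec$ins1, d_kept, spec$ins2, spec$j_prefix_kept, "TGG")
}

#' Simulate one clonal V-D-J rearrangement
#'
#' Builds the clone sequence `V[1..len-t1] + N1 + D[t5+1..len-t3] + N2 +
#' J[t4+1..len] + constant region`, with trims and N-additions drawn under
#' `cfg` so the junction is frame-consistent and stop-free, then applies
#' per-site SHM substitutions restricted to the V portion 5' of the conserved
#' Cys codon (divergence is quantified on the V region; junction diversity
#' comes from trimming and N-addition).
#'
#' @param v,d,j Single-row germline tibbles (strain pool).
#' @param cfg A [sim_config()].
#' @param shm_rate Per-site SHM rate for this clone.
#' @param exclude_positions V positions unavailable to SHM (the gene's
#'   planted SSP positions, keeping SHM and SSP disjoint per clone).
#' @param spec Optional pre-drawn junction spec (used to plant shared,
#'   stereotyped junctions across mice).
#' @param nonproductive If `TRUE`, a 1-nt frameshift is introduced in the
#'   junction after drawing it.
#' @param constant_region Nucleotides appended 3' of J (defaults to a short
#'   IgM constant-region stub containing the CH-mu primer site).
#' @return A list: `sequence`, `truth` (one-row tibble of planted values),
#'   `spec`.
#' @export
simulate_clone <- function(v, d, j, cfg, shm_rate = 0,
                           exclude_positions = integer(),
                           spec = NULL, nonproductive = FALSE,
                           constant_region = NULL) {
  if (is.null(spec)) {
    spec <- draw_junction_spec(v$sequence, d$sequence, j$sequence, cfg)
    if (is.null(spec)) {
      stop_ighrep("could not draw a frame-consistent, stop-free junction for ",
                  v$name, "/", d$name, "/", j$name)
    }
  }
  cys <- v_cys_start(v$sequence)
  v_kept <- substr(v$sequence, 1L, nchar(v$sequence) - spec$t1)
  d_kept <- substr(d$sequence, spec$t_d5 + 1L, nchar(d$sequence) - spec$t_d3)
  ins2 <- spec$ins2
  if (nonproductive) {  # frameshift: drop or add one junction N nucleotide
    ins2 <- if (nchar(ins2) > 0L) {
      substr(ins2, 1L, nchar(ins2) - 1L)
    } else {
      paste0(ins2, sample(IGHREP_NT, 1L))
    }
  }
  j_kept <- paste0(spec$j_prefix_kept, SIM_J_CONST)
  if (is.null(constant_region)) {
    constant_region <- paste0("GAGTCA", revcomp(DEFAULT_PRIMERS$ch_mu))
  }
  # SHM on the V portion 5' of the Cys codon, avoiding the gene's SSPs
  elig <- setdiff(seq_len(min(cys - 1L, nchar(v_kept))), exclude_positions)
  n_shm <- rbinom(1L, length(elig), shm_rate)
  shm_pos <- integer(0)
  chars <- strsplit(v_kept, "")[[1L]]
  if (n_shm > 0L) {
    shm_pos <- sort(sample(elig, n_shm))
    chars[shm_pos] <- vapply(chars[shm_pos], function(nt) {
      sample(setdiff(IGHREP_NT, nt), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  v_mut <- paste(chars, collapse = "")
  sequence <- paste0(v_mut, spec$ins1, d_kept, ins2, j_kept, constant_region)
  junction_aa <- translate_nt(junction_nt(v$sequence, d$sequence, spec))
  cdr3_aa <- substr(junction_aa, 2L, nchar(junction_aa) - 1L)
  # divergence is quantified on the V region through the Cys codon, the same
  # convention the annotation stage uses
  aligned_len <- cys + 2L
  shm_percent <- round(100 * n_shm / aligned_len, 2)
  truth <- tibble(
    v_call = v$name, d_call = d$name, j_call = j$name,
    cdr3_aa = if (nonproductive) NA_character_ else cdr3_aa,
    junction_aa = if (nonproductive) NA_character_ else junction_aa,
    productive = !nonproductive,
    n_shm = n_shm,
    shm_positions = list(shm_pos),
    shm_rate = shm_rate,
    aligned_v_length = aligned_len,
    shm_percent = shm_percent,
    mutation_status = ifelse(shm_percent <= 2, "UM", "M")
  )
  list(sequence = sequence, truth = truth, spec = spec)
}

#' Clonal colony counts under a symmetric Dirichlet-multinomial
#'
#' Draws the colony counts of `n_founders` candidate clones in a sample of
#' `n_colonies` sequenced colonies: clone fractions are symmetric
#' Dirichlet(alpha), colonies multinomial. Small alpha gives mono/oligoclonal
#' dominance; large alpha gives polyclonal samples.
#'
#' @param n_colonies Number of colonies sequenced.
#' @param n_founders Number of candidate clones.
#' @param alpha Dirichlet concentration (> 0).
#' @return Integer vector of length `n_founders` summing to `n_colonies`.
#' @export
draw_clonal_counts <- function(n_colonies, n_founders, alpha) {
  if (alpha <= 0) stop_ighrep("alpha must be > 0")
  w <- rgamma(n_founders, shape = alpha)
  if (sum(w) == 0) w <- rep(1, n_founders)
  as.integer(rmultinom(1L, n_colonies, w / sum(w)))
}

#' Simulate a full cohort with ground truth
#'
#' Generates the base germline pool, derives the strain germline (shared by
#' every clone), and for each mouse draws founder rearrangements and
#' genotype-dependent clonal expansions. A configurable set of +/+ mice share
#' one planted (stereotyped) founder junction; a fraction of +/+ mice are
#' sampled in a second tissue with the same founders, and a fraction have
#' their dominant clone allotransplanted into an F1 recipient.
#'
#' @param cfg A [sim_config()].
#' @return A list: `clones` (clone-record tibble), `germline` (the base pool
#'   the annotation stage aligns against), `strain_germline`, and `truth`
#'   (list with `ssp` tibble, `clones` per-record tibble, and the planted
#'   stereotype HCDR3).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  base <- make_base_germline(cfg$n_v, cfg$n_d, cfg$n_j, cfg$v_length)
  st <- derive_strain_germline(base, cfg$ssp_rate)
  strain <- st$germline
  vs <- strain[strain$segment_type == "V", ]
  ds <- strain[strain$segment_type == "D", ]
  js <- strain[strain$segment_type == "J", ]
  ssp_by_gene <- split(st$ssp_truth$position, st$ssp_truth$gene)

  draw_rate <- function() {
    if (runif(1) < cfg$prob_mutated_clone) {
      runif(1, cfg$shm_rate_m[1], cfg$shm_rate_m[2])
    } else {
      runif(1, cfg$shm_rate_um[1], cfg$shm_rate_um[2])
    }
  }
  new_founder <- function(spec = NULL, vdj = NULL) {
    if (is.null(vdj)) {
      vdj <- list(v = vs[sample.int(nrow(vs), 1L), ],
                  d = ds[sample.int(nrow(ds), 1L), ],
                  j = js[sample.int(nrow(js), 1L), ])
    }
    cl <- simulate_clone(vdj$v, vdj$d, vdj$j, cfg, shm_rate = draw_rate(),
                         exclude_positions = ssp_by_gene[[vdj$v$name]] %||%
                           integer(),
                         spec = spec)
    cl$vdj <- vdj
    cl
  }

  # planted stereotype: one junction spec shared by several +/+ mice
  n_pp <- cfg$n_mice_per_genotype[["+/+"]]
  n_st_mice <- if (cfg$stereotype_fraction > 0 && n_pp >= 2L) {
    max(2L, ceiling(cfg$stereotype_fraction * n_pp))
  } else {
    0L
  }
  st_spec <- NULL
  st_vdj <- NULL
  st_cdr3 <- NA_character_
  if (n_st_mice > 0L) {
    st_vdj <- list(v = vs[1L, ], d = ds[1L, ], j = js[1L, ])
    seed_clone <- new_founder(vdj = st_vdj)
    st_spec <- seed_clone$spec
    st_cdr3 <- seed_clone$truth$cdr3_aa
  }

  clone_rows <- list()
  truth_rows <- list()
  mouse_no <- 0L
  for (gt in GENOTYPES) {
    n_mice <- cfg$n_mice_per_genotype[[gt]]
    alpha <- cfg$expansion_dirichlet_alpha[[gt]]
    st_mice <- if (gt == "+/+" && n_st_mice > 0L) seq_len(n_st_mice) else integer()
    for (m in seq_len(n_mice)) {
      mouse_no <- mouse_no + 1L
      mouse_id <- sprintf("m%02d", mouse_no)
      n_col <- sample(cfg$colonies_per_sample[1L]:cfg$colonies_per_sample[2L], 1L)
      founders <- lapply(seq_len(n_col), function(i) new_founder())
      if (m %in% st_mice) {
        founders[[1L]] <- new_founder(spec = st_spec, vdj = st_vdj)
      }
      tissues <- "spleen"
      if (gt == "+/+" && runif(1) < cfg$second_tissue_fraction) {
        tissues <- c(tissues, "blood")
      }
      dominant <- NULL
      for (tis in tissues) {
        counts <- draw_clonal_counts(n_col, length(founders), alpha)
        if (m %in% st_mice && counts[1L] == 0L) {
          top <- which.max(counts)
          counts[top] <- counts[top] - 1L
          counts[1L] <- 1L
        }
        keep <- which(counts > 0L)
        if (tis == tissues[1L]) dominant <- keep[which.max(counts[keep])]
        for (fi in keep) {
          f <- founders[[fi]]
          rec_id <- sprintf("%s_%s_f%02d", mouse_id, tis, fi)
          clone_rows[[length(clone_rows) + 1L]] <- tibble(
            record_id = rec_id, mouse_id = mouse_id, genotype = gt,
            tissue = tis, is_allotransplant = FALSE,
            parental_mouse_id = NA_character_,
            sequence = f$sequence, colony_count = counts[fi]
          )
          truth_rows[[length(truth_rows) + 1L]] <-
            mutate(f$truth, record_id = rec_id, mouse_id = mouse_id,
                   genotype = gt, tissue = tis,
                   clone_fraction = counts[fi] / n_col)
        }
      }
      if (gt == "+/+" && runif(1) < cfg$allotransplant_fraction) {
        f <- founders[[dominant]]
        f1_id <- paste0(mouse_id, "F1")
        rec_id <- sprintf("%s_node_f%02d", f1_id, dominant)
        clone_rows[[length(clone_rows) + 1L]] <- tibble(
          record_id = rec_id, mouse_id = f1_id, genotype = gt,
          tissue = "node", is_allotransplant = TRUE,
          parental_mouse_id = mouse_id,
          sequence = f$sequence, colony_count = n_col
        )
        truth_rows[[length(truth_rows) + 1L]] <-
          mutate(f$truth, record_id = rec_id, mouse_id = f1_id,
                 genotype = gt, tissue = "node", clone_fraction = 1)
      }
    }
  }
  clones <- bind_rows(clone_rows)
  truth_clones <- bind_rows(truth_rows)
  list(
    clones = clones,
    germline = base,
    strain_germline = strain,
    truth = list(
      ssp = st$ssp_truth,
      clones = truth_clones,
      stereotype_cdr3 = st_cdr3,
      n_stereotype_mice = n_st_mice
    ),
    config = cfg
  )
}

#' Write a simulated cohort to disk
#'
#' Emits `clones.fasta`, `sample_sheet.tsv`, `germline_V/D/J.fasta` (base
#' pool) and `truth.json` under `dir`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(cohort$clones$sequence)
  names(seqs) <- cohort$clones$record_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "clones.fasta"))
  sheet <- cohort$clones[, c("record_id", "mouse_id", "genotype", "tissue",
                             "is_allotransplant", "parental_mouse_id",
                             "colony_count")]
  write.table(as.data.frame(sheet), file.path(dir, "sample_sheet.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  for (ty in c("V", "D", "J")) {
    write_germline_fasta(
      cohort$germline[cohort$germline$segment_type == ty, ],
      file.path(dir, sprintf("germline_%s.fasta", ty))
    )
  }
  truth <- cohort$truth
  truth$clones$shm_positions <- lapply(truth$clones$shm_positions, as.integer)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
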