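# V/D/J assignment, primer matching, isotype calls and HCDR3 extraction.

test_that("degenerate primer matching follows the IUPAC expansions", {
  hits <- match_iupac_primer("GAGGTGCAGCTGGAGGAGTCTGG",
                             "SARGTBMAGCTGSAGSAGTCWGG", max_mismatch = 0)
  expect_equal(hits$position, 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$strand, "+")

  expect_equal(nrow(match_iupac_primer("TTTT", "AAAA", 0)), 1L)  # revcomp hit
  expect_equal(match_iupac_primer("TTTT", "AAAA", 0)$strand, "-")
  expect_equal(nrow(match_iupac_primer("TTTT", "CCCC", 0)), 0L)
  expect_equal(nrow(match_iupac_primer("ACGT", "N", 0)), 8L)  # both strands
  expect_error(match_iupac_primer("ACGT", "AXGT", 0), "IUPAC")
})

test_that("primer matching agrees with a brute-force scan oracle", {
  set.seed(12)
  for (i in 1:25) {
    seqn <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
    primer <- paste(sample(names(ighrep:::IUPAC_NT), 6, replace = TRUE),
                    collapse = "")
    mm <- sample(0:2, 1)
    got <- as.data.frame(match_iupac_primer(seqn, primer, mm))
    want <- primer_scan_oracle(seqn, primer, mm)
    rownames(got) <- NULL; rownames(want) <- NULL
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("isotype is called from the best constant-region primer site", {
  p <- default_primers()
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  stub <- paste(rep("ACGTG", 10), collapse = "")
  expect_equal(assign_isotype(paste0(stub, rc(p$ch_mu))), "IgM")
  expect_equal(assign_isotype(paste0(stub, rc(p$ch_gamma))), "IgG")
  expect_equal(assign_isotype(paste0(stub, rc(p$ch_alpha))), "IgA")
  # tie between two primer sites -> unknown; no site -> unknown
  expect_equal(assign_isotype(paste0(stub, rc(p$ch_mu), rc(p$ch_gamma))),
               "unknown")
  expect_equal(assign_isotype(stub), "unknown")
})

test_that("zero-variation clones recover the planted calls exactly", {
  g <- make_base_germline(seed = 14)
  st <- derive_strain_germline(g, ssp_rate = 0, seed = 1)
  v <- g[g$segment_type == "V", ][3, ]
  d <- g[g$segment_type == "D", ][2, ]
  j <- g[g$segment_type == "J", ][2, ]
  cfg <- sim_config(seed = 1)
  set.seed(2)
  cl <- simulate_clone(v, d, j, cfg, shm_rate = 0)
  clones <- tibble::tibble(record_id = "c1", mouse_id = "m1",
                           genotype = "+/+", tissue = "spleen",
                           is_allotransplant = FALSE,
                           parental_mouse_id = NA_character_,
                           sequence = cl$sequence, colony_count = 1L)
  ann <- annotate_clones(clones, g)
  expect_equal(ann$v_call, v$name)
  expect_equal(ann$d_call, d$name)
  expect_equal(ann$j_call, j$name)
  expect_equal(ann$v_identity, 100)
  expect_true(ann$productive)
  expect_equal(ann$cdr3_aa, cl$truth$cdr3_aa)
  expect_equal(ann$isotype, "IgM")
})

test_that("v_identity reflects planted substitutions arithmetically", {
  g <- make_base_germline(seed = 15)
  v <- g[g$segment_type == "V", ][1, ]
  d <- g[g$segment_type == "D", ][1, ]
  j <- g[g$segment_type == "J", ][1, ]
  cfg <- sim_config(trim_max = 0, n_insert_max = 0, seed = 1)
  set.seed(4)
  cl <- simulate_clone(v, d, j, cfg, shm_rate = 0)
  # plant exactly 3 substitutions in the V (positions clear of the head
  # so the alignment stays full-length)
  chars <- strsplit(cl$sequence, "")[[1]]
  for (pos in c(50L, 120L, 200L)) {
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
  }
  clones <- tibble::tibble(record_id = "c1", mouse_id = "m1",
                           genotype = "+/+", tissue = "spleen",
                           is_allotransplant = FALSE,
                           parental_mouse_id = NA_character_,
                           sequence = paste(chars, collapse = ""),
                           colony_count = 1L)
  ann <- annotate_clones(clones, g)
  expect_equal(ann$v_call, v$name)
  expect_equal(ann$v_identity, round(100 * 291 / 294, 2))  # 98.98
  expect_equal(nrow(ann$v_mismatches[[1]]), 3L)
  expect_equal(ann$v_mismatches[[1]]$position, c(50L, 120L, 200L))
})

test_that("v_identity is invariant to record relabeling and 3' constant sequence", {
  coh <- simulate_cohort(small_cfg(seed = 16))
  clones <- coh$clones[1:5, ]
  ann1 <- annotate_clones(clones, coh$germline)
  relabeled <- clones
  relabeled$record_id <- paste0("relabel_", seq_len(nrow(relabeled)))
  ann2 <- annotate_clones(relabeled, coh$germline)
  expect_equal(ann1$v_identity, ann2$v_identity)
  extended <- clones
  extended$sequence <- paste0(extended$sequence, "GATTACAGATTACA")
  ann3 <- annotate_clones(extended, coh$germline)
  expect_equal(ann1$v_identity, ann3$v_identity)
  expect_equal(ann1$cdr3_aa, ann3$cdr3_aa)
})

test_that("short junction matches yield no D call", {
  g <- make_base_germline(seed = 17)
  v <- g[g$segment_type == "V", ][1, ]
  j <- g[g$segment_type == "J", ][2, ]
  # a 4-nt junction cannot host a match reaching the 5-nt threshold
  seqn <- paste0(v$sequence, "CCCC", j$sequence)
  clones <- tibble::tibble(record_id = "c1", mouse_id = "m1",
                           genotype = "+/+", tissue = "spleen",
                           is_allotransplant = FALSE,
                           parental_mouse_id = NA_character_,
                           sequence = seqn, colony_count = 1L)
  ann <- annotate_clones(clones, g)
  expect_true(is.na(ann$d_call))
})

test_that("gene calls and HCDR3 round-trip on a low-SHM cohort", {
  cfg <- small_cfg(seed = 18, prob_mutated_clone = 0)
  coh <- simulate_cohort(cfg)
  ann <- annotate_clones(coh$clones, coh$germline)
  tr <- coh$truth$clones
  m <- dplyr::inner_join(ann, tr, by = c(sequence_id = "record_id"),
                         suffix = c("", ".t"))
  expect_equal(nrow(m), nrow(ann))
  d_ok <- ifelse(is.na(m$d_call.t), is.na(m$d_call),
                 !is.na(m$d_call) & m$d_call == m$d_call.t)
  expect_gte(mean(m$v_call == m$v_call.t & m$j_call == m$j_call.t & d_ok),
             0.99)
  prod <- m$productive.t
  expect_true(all(m$cdr3_aa[prod] == m$cdr3_aa.t[prod]))
  expect_true(all(m$isotype == "IgM"))
})

test_that("junction defects are flagged nonproductive with a reason", {
  g <- make_base_germline(seed = 19)
  v <- g[g$segment_type == "V", ][1, ]
  j <- g[g$segment_type == "J", ][2, ]
  # internal stop codon (TAA) in frame within the junction
  seq_stop <- paste0(v$sequence, "TAATAA", substr(j$sequence, 1, 9),
                     "TGGGGTCAAGGAACCTCAGTCACCGTCTCCTCA")
  # frameshifted junction: V-to-J offset not a multiple of 3
  seq_shift <- paste0(v$sequence, "AC", j$sequence)
  clones <- tibble::tibble(record_id = c("stop", "shift"),
                           mouse_id = "m1", genotype = "+/+",
                           tissue = "spleen", is_allotransplant = FALSE,
                           parental_mouse_id = NA_character_,
                           sequence = c(seq_stop, seq_shift),
                           colony_count = 1L)
  ann <- annotate_clones(clones, g)
  expect_false(any(ann$productive))
  stop_row <- ann[ann$sequence_id == "stop", ]
  expect_equal(stop_row$fail_reason, "stop_in_junction")
  expect_match(stop_row$junction_aa, "\\*")
  shift_row <- ann[ann$sequence_id == "shift", ]
  expect_true(is.na(shift_row$cdr3_aa))
})
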