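# Synthetic repertoire generator: determinism, planted-truth bookkeeping and
# the statistical behaviour of its components.

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(ssp_rate = 1.5), "rates")
  expect_error(sim_config(colonies_per_sample = c(0, 10)), "colonies")
  expect_error(sim_config(expansion_dirichlet_alpha =
                            c(`-/-` = 0, `+/-` = 1, `-/+` = 1, `+/+` = 1)),
               "alpha")
  expect_error(sim_config(v_length = 100), "multiple of 3")
})

test_that("base germline segments satisfy the reference invariants", {
  g <- make_base_germline(n_v = 6, n_d = 4, n_j = 4, seed = 2)
  expect_equal(sum(g$segment_type == "V"), 6L)
  lens <- nchar(g$sequence)
  expect_true(all(lens[g$segment_type == "V"] == 294L))
  expect_true(all(lens[g$segment_type == "D"] >= 5 &
                    lens[g$segment_type == "D"] <= 40))
  expect_true(all(lens[g$segment_type == "J"] >= 20 &
                    lens[g$segment_type == "J"] <= 80))
  expect_true(all(grepl("^[ACGT]+$", g$sequence)))
  # V genes translate without stops and end with the conserved Cys + tail
  for (s in g$sequence[g$segment_type == "V"]) {
    aa <- ighrep:::translate_nt(substr(s, 1, 288))
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_equal(substr(aa, 94, 96), paste0("YY", "C"))
    expect_equal(ighrep:::v_cys_start(s), 286L)
  }
})

test_that("strain derivation plants the expected number of polymorphisms", {
  base <- make_base_germline(n_v = 8, seed = 4)
  # rate 0: identical germline, empty truth
  st0 <- derive_strain_germline(base, ssp_rate = 0, seed = 1)
  expect_identical(st0$germline$sequence, base$sequence)
  expect_equal(nrow(st0$ssp_truth), 0L)
  # rate 1: every eligible position (5' of the Cys codon) substituted
  st1 <- derive_strain_germline(base, ssp_rate = 1, seed = 1)
  per_gene <- table(st1$ssp_truth$gene)
  expect_true(all(per_gene == 285L))
  expect_true(all(st1$ssp_truth$germline_nt != st1$ssp_truth$strain_nt))
  # binomial expectation at the default rate over replicates
  counts <- vapply(1:40, function(i) {
    nrow(derive_strain_germline(base, ssp_rate = 0.0254, seed = i)$ssp_truth)
  }, numeric(1)) / 8
  expected <- 285 * 0.0254
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(40) + 1e-9)
  expect_error(derive_strain_germline(base, ssp_rate = -0.1), "ssp_rate")
})

test_that("clone simulation is an exact concatenation when nothing varies", {
  g <- make_base_germline(seed = 6)
  v <- g[g$segment_type == "V", ][1, ]
  d <- g[g$segment_type == "D", ][1, ]
  j <- g[g$segment_type == "J", ][1, ]
  cfg <- sim_config(trim_max = 0, n_insert_max = 0, seed = 1)
  set.seed(1)
  cl <- simulate_clone(v, d, j, cfg, shm_rate = 0)
  stub <- paste0("GAGTCA",
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(default_primers()$ch_mu))))
  expect_equal(cl$sequence,
               paste0(v$sequence, d$sequence, j$sequence, stub))
  expect_equal(cl$truth$n_shm, 0L)
  expect_equal(cl$truth$shm_percent, 0)
  # junction translates C ... W with the anchors stripped in cdr3_aa
  expect_match(cl$truth$junction_aa, "^C.*W$")
  expect_equal(cl$truth$cdr3_aa,
               substr(cl$truth$junction_aa, 2,
                      nchar(cl$truth$junction_aa) - 1))
})

test_that("per-clone SHM counts follow the binomial expectation", {
  g <- make_base_germline(seed = 8)
  v <- g[g$segment_type == "V", ][1, ]
  d <- g[g$segment_type == "D", ][1, ]
  j <- g[g$segment_type == "J", ][1, ]
  cfg <- sim_config(seed = 1)
  set.seed(42)
  n <- vapply(1:300, function(i) {
    simulate_clone(v, d, j, cfg, shm_rate = 0.01)$truth$n_shm
  }, integer(1))
  expect_lt(abs(mean(n) - 285 * 0.01), 3 * sd(n) / sqrt(300))
})

test_that("requested nonproductive clones fail the productivity check", {
  g <- make_base_germline(seed = 10)
  v <- g[g$segment_type == "V", ][1, ]
  d <- g[g$segment_type == "D", ][1, ]
  j <- g[g$segment_type == "J", ][4, ]
  cfg <- sim_config(seed = 1)
  set.seed(3)
  cl <- simulate_clone(v, d, j, cfg, shm_rate = 0, nonproductive = TRUE)
  clones <- tibble::tibble(record_id = "np1", mouse_id = "m1",
                           genotype = "+/+", tissue = "spleen",
                           is_allotransplant = FALSE,
                           parental_mouse_id = NA_character_,
                           sequence = cl$sequence, colony_count = 1L)
  ann <- annotate_clones(clones, g)
  expect_false(ann$productive[1])
})

test_that("cohorts are byte-identical under a fixed seed and disjointness holds", {
  c1 <- simulate_cohort(small_cfg(seed = 5))
  c2 <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(c1$clones, c2$clones)
  expect_identical(c1$truth$ssp, c2$truth$ssp)
  c3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(c1$clones$sequence, c3$clones$sequence))

  # per clone, planted SHM positions never coincide with the gene's SSPs
  ssp_by_gene <- split(c1$truth$ssp$position, c1$truth$ssp$gene)
  tr <- c1$truth$clones
  for (i in seq_len(nrow(tr))) {
    overlap <- intersect(tr$shm_positions[[i]],
                         ssp_by_gene[[tr$v_call[i]]])
    expect_length(overlap, 0)
  }
  # clonal fractions per sample sum to 1
  frac <- tapply(tr$clone_fraction, paste(tr$mouse_id, tr$tissue), sum)
  expect_true(all(abs(frac - 1) < 1e-9))
})

test_that("Dirichlet concentration controls clonal dominance", {
  set.seed(77)
  max_frac <- function(alpha) {
    vapply(1:300, function(i) {
      max(draw_clonal_counts(10L, 10L, alpha)) / 10
    }, numeric(1))
  }
  # reference probabilities from a large-sample oracle of the same model:
  # P(max >= 0.5 | alpha = 0.1) ~ 0.88, P(max <= 0.3 | alpha = 100) ~ 0.87
  expect_gte(mean(max_frac(0.1) >= 0.5), 0.8)   # mono/oligoclonal regime
  expect_gte(mean(max_frac(100) <= 0.3), 0.8)   # polyclonal regime
  expect_error(draw_clonal_counts(10L, 5L, 0), "alpha")
})

test_that("+/+ samples are dominated while wild-type samples stay polyclonal", {
  coh <- simulate_cohort(sim_config(seed = 21))
  tr <- coh$truth$clones
  top <- tapply(tr$clone_fraction,
                list(paste(tr$mouse_id, tr$tissue), tr$genotype), max)
  pp <- stats::na.omit(top[, "+/+"])
  wt <- stats::na.omit(top[, "-/-"])
  expect_gte(mean(pp >= 0.5), 0.7)
  expect_lte(mean(wt >= 0.5), 0.2)
})

test_that("planted stereotypes surface as a cross-mouse set", {
  coh <- simulate_cohort(sim_config(seed = 31))
  expect_gte(coh$truth$n_stereotype_mice, 2L)
  tr <- coh$truth$clones
  carriers <- unique(tr$mouse_id[tr$cdr3_aa == coh$truth$stereotype_cdr3 &
                                   !is.na(tr$cdr3_aa) &
                                   !grepl("F1$", tr$mouse_id)])
  expect_gte(length(carriers), 2L)
})

test_that("a cohort writes and reloads through the standard formats", {
  coh <- simulate_cohort(small_cfg(seed = 13))
  dir <- tempfile()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("clones.fasta", "sample_sheet.tsv", "germline_V.fasta",
      "germline_D.fasta", "germline_J.fasta", "truth.json")))))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  clones <- read_clone_fasta(file.path(dir, "clones.fasta"), sheet)
  expect_equal(nrow(clones), nrow(coh$clones))
  expect_setequal(clones$sequence, coh$clones$sequence)
  v <- read_germline_fasta(file.path(dir, "germline_V.fasta"), "V")
  expect_setequal(v$name, coh$germline$name[coh$germline$segment_type == "V"])
})
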