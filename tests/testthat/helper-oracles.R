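# Independent oracles and small fixtures shared across tests. Each oracle is
# a deliberately naive reimplementation (grid search, regex scan, exhaustive
# tally) kept separate from the package's code paths.

# --- isoelectric point: fine-grid root finding over the same charge model ---

pi_grid_oracle <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  nres <- length(res)
  nterm <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
             E = 7.70)
  pos_pka <- c(R = 12, K = 10, H = 5.98)
  neg_pka <- c(D = 4.05, E = 4.45, C = 9, Y = 10)
  pos <- unname(nterm[res[1]])
  if (is.na(pos)) pos <- 7.50
  neg <- 3.55
  for (i in seq_len(nres)) {
    a <- res[i]
    if (a %in% names(pos_pka)) pos <- c(pos, pos_pka[[a]])
    if (a %in% names(neg_pka)) {
      pk <- neg_pka[[a]]
      if (i == nres && a == "D") pk <- 4.55
      if (i == nres && a == "E") pk <- 4.75
      neg <- c(neg, pk)
    }
  }
  ph <- seq(0, 14, by = 1e-3)
  net <- rowSums(vapply(pos, function(pk) 1 / (1 + 10^(ph - pk)),
                        numeric(length(ph)))) -
    rowSums(vapply(neg, function(pk) 1 / (1 + 10^(pk - ph)),
                   numeric(length(ph))))
  i <- which(net <= 0)[1]
  # linear interpolation across the sign change
  root <- ph[i - 1] + (ph[i] - ph[i - 1]) * net[i - 1] / (net[i - 1] - net[i])
  round(root, 2)
}

# --- IUPAC primer matching: brute-force window scan over expansion sets ---

primer_scan_oracle <- function(sequence, primer, max_mismatch = 0L) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  revcomp_chr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  seq_chars <- strsplit(sequence, "")[[1]]
  scan_one <- function(p, strand) {
    allowed <- expand[strsplit(p, "")[[1]]]
    k <- length(allowed)
    n <- length(seq_chars)
    if (k > n) return(NULL)
    hits <- list()
    for (s in seq_len(n - k + 1L)) {
      mm <- 0L
      for (j in seq_len(k)) {
        if (!seq_chars[s + j - 1L] %in% allowed[[j]]) mm <- mm + 1L
      }
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <- data.frame(position = s,
                                                mismatches = mm,
                                                strand = strand)
      }
    }
    if (length(hits) > 0) do.call(rbind, hits) else NULL
  }
  out <- rbind(scan_one(primer, "+"), scan_one(revcomp_chr(primer), "-"))
  if (is.null(out)) {
    return(data.frame(position = integer(), mismatches = integer(),
                      strand = character()))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

# --- SSP calling: exhaustive tally over all (position, nt) mismatches ---

ssp_brute_oracle <- function(group, min_fraction = 0.5, min_mice = 2L) {
  n_group <- nrow(group)
  tally <- list()
  for (i in seq_len(n_group)) {
    m <- group$v_mismatches[[i]]
    for (r in seq_len(nrow(m))) {
      key <- paste(m$position[r], m$observed_nt[r])
      if (is.null(tally[[key]])) {
        tally[[key]] <- list(support = 0L, mice = character())
      }
      tally[[key]]$support <- tally[[key]]$support + 1L
      tally[[key]]$mice <- union(tally[[key]]$mice, group$mouse_id[i])
    }
  }
  keys <- names(tally)
  keep <- vapply(keys, function(k) {
    tally[[k]]$support > min_fraction * n_group &&
      length(tally[[k]]$mice) >= min_mice
  }, logical(1))
  sort(keys[keep])
}

# --- small simulated cohorts for unit tests ---

small_cfg <- function(seed = 1L, ...) {
  sim_config(
    n_mice_per_genotype = c(`-/-` = 1L, `+/-` = 1L, `-/+` = 1L, `+/+` = 3L),
    colonies_per_sample = c(5L, 8L),
    seed = seed,
    ...
  )
}

# annotated rearrangement rows (not aligned; used for dedup/stats tests)
toy_rearrangement <- function() {
  tibble::tibble(
    sequence_id = paste0("r", 1:6),
    mouse_id = c("a", "a", "a", "bF1", "c", "c"),
    genotype = "+/+",
    tissue = c("spleen", "blood", "spleen", "node", "spleen", "spleen"),
    cdr3_aa = c("ARGGDY", "ARGGDY", "ASYAFAY", "ASYAFAY", "ARGGDY", "GRDDGY"),
    v_call = c("V1", "V1", "V2", "V2", "V1", "V3"),
    d_call = "D1", j_call = "J1",
    mutation_status = c("UM", "UM", "M", "M", "UM", "UM"),
    colony_count = c(6L, 7L, 4L, 9L, 2L, 8L),
    sample_total = c(10L, 10L, 10L, 10L, 10L, 10L),
    is_allotransplant = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    parental_mouse_id = c(NA, NA, NA, "a", NA, NA)
  )
}
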