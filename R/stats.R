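# Gene-usage frequency tables and the statistical battery: Pearson
# chi-square and likelihood-ratio (G) tests with a seeded Monte Carlo
# correction, one-sample proportion tests against background rearrangement
# frequencies, two-sample t-tests for HCDR3 length and pI, and grouped
# summaries.

#' Frequency table of segment usage
#'
#' Counts and percentages of gene or subgroup usage, optionally split by a
#' grouping column (e.g. genotype). Subgroups are taken from a
#' `<segment>_subgroup` column when present, otherwise derived from the gene
#' name prefix (before the first `-`, `.` or `*`).
#'
#' @param clones Tibble of (typically canonical) clones carrying
#'   `v_call`/`d_call`/`j_call` and optionally `v_subgroup` etc.
#' @param segment One of `"V"`, `"D"`, `"J"`.
#' @param level `"gene"` or `"subgroup"`.
#' @param group_by Optional column name to split by (e.g. `"genotype"`).
#' @return A tibble: `category`, (`group`,) `n`, `percent` (1 decimal,
#'   percentages within each group sum to 100 up to rounding).
#' @export
frequency_table <- function(clones, segment = c("V", "D", "J"),
                            level = c("gene", "subgroup"), group_by = NULL) {
  segment <- match.arg(segment)
  level <- match.arg(level)
  call_col <- paste0(tolower(segment), "_call")
  if (!call_col %in% names(clones)) {
    stop_ighrep("clones are missing column ", call_col)
  }
  cat_vals <- clones[[call_col]]
  if (level == "subgroup") {
    sub_col <- paste0(tolower(segment), "_subgroup")
    cat_vals <- if (sub_col %in% names(clones)) {
      clones[[sub_col]]
    } else {
      segment_subgroup(cat_vals)
    }
  }
  df <- tibble(category = cat_vals)
  if (!is.null(group_by)) {
    if (!group_by %in% names(clones)) {
      stop_ighrep("clones are missing grouping column ", group_by)
    }
    df$group <- clones[[group_by]]
  } else {
    df$group <- "all"
  }
  df <- df[!is.na(df$category), ]
  out <- df %>%
    count(.data$group, .data$category, name = "n") %>%
    group_by(.data$group) %>%
    mutate(percent = round(100 * .data$n / sum(.data$n), 1)) %>%
    ungroup() %>%
    arrange(.data$group, desc(.data$n), .data$category)
  if (is.null(group_by)) out$group <- NULL
  out
}

#' Pearson chi-square and likelihood-ratio tests with Monte Carlo correction
#'
#' For an r x c contingency table: Pearson X^2 = sum (O - E)^2 / E and the
#' likelihood-ratio statistic G = 2 sum O log(O/E) (0 log 0 = 0), with
#' asymptotic p from the chi-square distribution on (r-1)(c-1) degrees of
#' freedom. The Monte Carlo p resamples tables with the grand total fixed,
#' cell probabilities given by the independence model (row x column margin
#' products / N), and applies the add-one convention
#' p = (1 + #\{statistic >= observed\}) / (reps + 1).
#'
#' @param table Integer matrix of counts, at least 2 x 2, no zero margins.
#' @param mc_reps Monte Carlo replicates (0 disables the correction).
#' @param seed Integer seed for the resampling.
#' @return A tibble with one row per test (`pearson`, `likelihood_ratio`):
#'   `statistic`, `df`, `p_asymptotic`, `p_monte_carlo`, `mc_reps`, `seed`.
#' @export
chi_square_tests <- function(table, mc_reps = 10000L, seed = 1L) {
  O <- as.matrix(table)
  if (nrow(O) < 2L || ncol(O) < 2L) stop_ighrep("table must be at least 2 x 2")
  if (any(O < 0)) stop_ighrep("counts must be non-negative")
  rs <- rowSums(O)
  cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) {
    stop_ighrep("degenerate table: zero row or column margin")
  }
  N <- sum(O)
  E <- outer(rs, cs) / N
  pearson <- function(o) sum((o - as.vector(E))^2 / as.vector(E))
  gstat <- function(o) {
    e <- as.vector(E)
    terms <- ifelse(o == 0, 0, o * log(o / e))
    2 * sum(terms)
  }
  x2_obs <- pearson(as.vector(O))
  g_obs <- gstat(as.vector(O))
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  p_x2 <- pchisq(x2_obs, df, lower.tail = FALSE)
  p_g <- pchisq(g_obs, df, lower.tail = FALSE)
  p_mc <- c(NA_real_, NA_real_)
  if (mc_reps > 0L) {
    withr::local_seed(seed)
    sims <- rmultinom(mc_reps, N, as.vector(E) / N)
    r <- nrow(O)
    # each simulated table is scored against its own margin-estimated
    # expectations, as the statistics are defined (cells in zero margins
    # contribute nothing)
    sim_stats <- vapply(seq_len(mc_reps), function(k) {
      Ok <- matrix(sims[, k], nrow = r)
      Ek <- outer(rowSums(Ok), colSums(Ok)) / N
      nz <- Ek > 0
      x2 <- sum((Ok[nz] - Ek[nz])^2 / Ek[nz])
      g <- 2 * sum(ifelse(Ok[nz] == 0, 0, Ok[nz] * log(Ok[nz] / Ek[nz])))
      c(x2, g)
    }, numeric(2))
    tol <- 1e-9
    p_mc <- c(
      (1 + sum(sim_stats[1L, ] >= x2_obs - tol)) / (mc_reps + 1),
      (1 + sum(sim_stats[2L, ] >= g_obs - tol)) / (mc_reps + 1)
    )
  }
  tibble(
    test = c("pearson", "likelihood_ratio"),
    statistic = c(x2_obs, g_obs),
    df = df,
    p_asymptotic = c(p_x2, p_g),
    p_monte_carlo = p_mc,
    mc_reps = as.integer(mc_reps),
    seed = as.integer(seed)
  )
}

#' One-sample proportion test against a background frequency
#'
#' Two-sided z-test of an observed usage frequency `k/n` against a background
#' rearrangement proportion `p0`:
#' z = (k/n - p0) / sqrt(p0 (1 - p0) / n). With `exact = TRUE` the two-sided
#' exact binomial p is reported instead.
#'
#' @param k Successes (clones using the gene).
#' @param n Trials (clones examined), > 0.
#' @param p0 Background proportion in (0, 1).
#' @param exact Use the exact binomial test.
#' @return A tibble: `statistic` (z, `NA` for exact), `p`, `method`.
#' @export
proportion_test <- function(k, n, p0, exact = FALSE) {
  if (n <= 0L) stop_ighrep("n must be > 0")
  if (k < 0L || k > n) stop_ighrep("k must be within [0, n]")
  if (p0 <= 0 || p0 >= 1) stop_ighrep("p0 must be in (0, 1)")
  if (exact) {
    p <- stats::binom.test(k, n, p0)$p.value
    return(tibble(statistic = NA_real_, p = p, method = "exact_binomial"))
  }
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  tibble(statistic = z, p = 2 * pnorm(-abs(z)), method = "z_normal")
}

#' Two-sample t-test for HCDR3 length or pI
#'
#' Student's pooled-variance t-test by default; Welch optional. When both
#' samples have zero variance the test is degenerate: p = 1 if the means are
#' equal, p = 0 otherwise.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) test.
#' @return A tibble: `statistic`, `df`, `p`, `method`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_ighrep("both samples must have at least 2 values")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(statistic = if (equal) 0 else Inf * sign(mean(x) - mean(y)),
                  df = NA_real_, p = if (equal) 1 else 0,
                  method = "degenerate"))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, method = if (welch) "welch" else "student_pooled")
}

#' Grouped mean and SD of an HCDR3 feature
#'
#' Sample SD (n - 1 denominator); length summaries are reported to 1 decimal
#' and pI summaries to 2 decimals, the conventions used for repertoire
#' reports. SD is `NA` for singleton groups.
#'
#' @param clones Tibble with the feature column.
#' @param field `"length"` or `"pI"` (column name in `clones`).
#' @param group Optional grouping column name.
#' @return A tibble: (`group`,) `mean`, `sd`, `n`.
#' @export
summarize_features <- function(clones, field = c("length", "pI"),
                               group = NULL) {
  field <- match.arg(field)
  if (!field %in% names(clones)) {
    stop_ighrep("clones are missing column ", field)
  }
  digits <- if (field == "length") 1L else 2L
  df <- tibble(value = clones[[field]])
  df$group <- if (is.null(group)) "all" else clones[[group]]
  out <- df %>%
    group_by(.data$group) %>%
    summarise(
      mean = round(mean(.data$value), digits),
      sd = if (n() >= 2L) round(sd(.data$value), digits) else NA_real_,
      n = n(),
      .groups = "drop"
    )
  if (is.null(group)) out$group <- NULL
  out
}
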