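---
title: "Methods: heavy-chain repertoire analysis of mouse CLL/SLL clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heavy-chain repertoire analysis of mouse CLL/SLL clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighrep)
```

## The problem

B-cell clones expanded in mouse models of chronic lymphocytic leukemia /
small lymphocytic lymphoma (CLL/SLL) are characterised through their
immunoglobulin heavy-chain V-D-J rearrangements: which germline genes they
use, how far their IGHV region has diverged from the germline (somatic
hypermutation, SHM), and what their HCDR3 loop looks like (length,
isoelectric point, composition, and whether the same HCDR3 recurs in
unrelated animals — stereotypy). Two practical complications drive the
design of this package:

1. **Strain polymorphism masquerades as SHM.** When the sequenced mice are
   hybrids of strains that are poorly represented in germline databases
   (here FVB/N x BALB/c, compared against predominantly C57BL/6
   references), inherited strain-specific polymorphisms (SSPs) inflate the
   apparent mutation load. The package implements the cross-individual
   correction: clones sharing an IGHV gene are compared across mice, and a
   mismatch showing the *same substituted nucleotide at the same position*
   in most clones from several animals is attributed to the strain, not to
   SHM. The logic rests on SHM introducing any of the four nucleotides
   essentially at random, so somatic recurrence of one specific
   substitution across individuals is improbable.
2. **Colony-level sequencing requires explicit clonotype accounting.**
   Each sample yields 5-15 sequenced colonies; identical clones recur
   across tissues of one mouse and reappear in allotransplanted recipients.
   All frequency statistics therefore run on *canonical clones*: one entry
   per (parental mouse, HCDR3), with per-sample colony fractions retained
   for expansion calls.

## Pipeline stages

`simulate_cohort()` (optional) → `annotate_clones()` → `call_mutations()` →
`canonicalize_clones()` → `hcdr3_features()` / `detect_stereotypes()` /
`frequency_table()` and the test battery. `run_full_analysis()` chains the
stages and writes a manifest with the seed and a configuration hash; a
pre-annotated mode accepts an existing rearrangement table (for example the
packaged clone table, which has no raw nucleotide sequences) and runs only
the downstream accounting.

## Germline assignment and HCDR3 extraction

V and J calls maximise an end-gap-free (overlap) pairwise alignment score
(match +1, mismatch −1, gap open −4, gap extend −1), ties broken by higher
identity and then name. Overlap alignment is used because RT-PCR amplicons
primed with a degenerate FR1 primer may truncate the germline V 5' end. The
D call is the D gene with the longest exact contiguous match of at least
`d_min_len` (default 5) nucleotides inside the junction between the V and J
alignments — short D remnants cannot be assigned reliably, and 5 nt is the
conventional floor against chance matches.

The junction is translated in the germline V reading frame from the
conserved 2nd-CYS (located as the last in-frame cysteine of the germline V)
through the tryptophan of the first in-frame W-G-x-G motif contributed by
the J. The reported HCDR3 strips both anchor residues, matching how such
loops are printed in clone tables. A clone is productive when both anchors
are found in frame and the junction is stop-free.

Mismatches and divergence are quantified on the V region **through the Cys
codon only**: 3' of it, junction trimming and N-additions make germline
attribution ambiguous, and an overlap alignment that happens to extend a
few nucleotides into the junction would otherwise contribute spurious
"mutations". The SHM percent denominator is the clone's aligned V length
under the same convention (the published per-clone anchors — one residual
mismatch ↔ 0.35%, 24 polymorphisms ↔ 9.375% — imply aligned lengths of
about 286 and 256 nt, i.e. the aligned V region rather than a fixed
full-length gene).

Isotype is called from the constant-region reverse-primer sites (IgM / IgG
/ IgA), searched on both strands under IUPAC expansion with zero mismatches
by default; ties and absent sites yield `unknown` rather than an error.

## SSP/SHM discrimination

For every IGHV gene with at least 3 clones (across all genotypes and mice),
a (position, observed nucleotide) mismatch is an SSP iff it occurs in more
than `min_fraction` (default 0.5, strict majority) of the gene's clones
*and* in at least `min_mice` (default 2) distinct mice. Both knobs are
exposed because the underlying report describes the criterion qualitatively
("conserved in most clones from different individuals"); the defaults are
our operationalisation, and the multi-mouse requirement is what prevents a
clonally expanded SHM within one animal from being promoted to a
polymorphism. Corrected counts satisfy `ssp_count + shm_count =
raw_mismatches` by construction. Clones of ineligible genes (< 3 clones)
are classified from uncorrected counts and flagged `ssp_uncorrected`;
their UM/M label retains the strain-divergence bias, which is exactly the
situation the correction exists to fix.

Unmutated (UM) means ≥ 98% germline identity after correction, i.e.
`shm_percent <= 2.0` with the boundary on the UM side; above 2% is mutated
(M).

## Isoelectric point

`compute_pi()` implements the Bjellqvist charge model used by the standard
pI calculators: positive groups are the N-terminal amine (residue-specific
pKa: A 7.59, M 7.00, S 6.93, P 8.36, T 6.82, V 7.44, E 7.70, otherwise
7.50) and R/K/H side chains (12.00 / 10.00 / 5.98); negative groups are the
C-terminal carboxyl (3.55) and D/E/C/Y side chains (4.05 / 4.45 / 9.00 /
10.00), with C-terminal D/E side chains shifted to 4.55 / 4.75. The net
charge is strictly decreasing in pH, so the root is found by bisection on
[0, 14] to |net charge| < 1e-4 and reported to 2 decimals. The test suite
checks the solver against an independent fine-grid root-finding oracle over
the same model and against the full set of printed clone-table values.

## Synthetic repertoires and what they do (not) show

The generator is the package's test bed and emulates the study conditions:

* **Cohort layout.** 5 / 4 / 3 / 8 mice for the four genotypes (wild-type,
  single-transgenics, double-transgenic), one spleen sample each, a second
  (blood) sample for a quarter of the `+/+` mice, an allotransplanted F1
  recipient for a quarter of the `+/+` mice, and 5-15 colonies per sample.
* **Strain germline.** Each V gene receives Binomial(n, 0.0254)
  substitutions — the reported average strain divergence of 2.54%, whose
  printed per-gene range (1 substitution = 0.35% up to 24 = 9.375%) the
  binomial spread covers. All clones of a cohort share the one strain
  germline; that sharing is what makes SSPs conserved. Substituted
  positions stay 5' of the conserved Cys codon: the 2nd-CYS is invariant in
  functional V genes, and a polymorphism there would make every clone of
  the gene non-annotatable, which is not a condition the analysis is meant
  to face.
* **Rearrangement.** `V[1..len−t1] + N1 + D[t5+1..len−t3] + N2 + J[t4+1..]`
  with trims ≤ 3 nt per side, N-inserts ≤ 6 nt, at least 8 nt of D
  retained, and the second N-insert adjusted so the J tryptophan stays in
  the V reading frame (junctions are re-drawn rather than emitted with
  stops or a premature W-G-x-G). D segments are whole non-stop codons so
  untrimmed concatenations stay open in frame.
* **SHM.** Founders are unmutated with probability 0.85, drawing a per-site
  rate uniformly from 0-2%, otherwise from 2-5% (the cohort's observed
  85/15 UM/M split). Substitutions are uniform (no AID hotspot bias — the
  SSP criterion relies only on SHM randomness across clones, which uniform
  substitution satisfies), restricted to the V region 5' of the Cys codon,
  and never collide with the gene's SSP positions. The ground-truth UM/M
  label is computed from the *realized* substitution count under the same
  denominator convention as the pipeline, so the recovery tests measure
  SSP-correction fidelity rather than binomial sampling noise around the
  2% boundary.
* **Clonal expansion.** Colony counts are Dirichlet-multinomial: symmetric
  Dirichlet weights with concentration 0.1 for `+/+` samples
  (mono/oligoclonal dominance) and 10 elsewhere (polyclonal). Large-sample
  reference values of this model: with 10 colonies, the top clone reaches
  ≥ 50% in ~88% of alpha = 0.1 samples and stays ≤ 30% in ~87% of
  alpha = 100 samples.
* **Stereotypy.** A configurable fraction (default 0.3) of `+/+` mice share
  one planted founder junction, giving the stereotypy detector a known
  positive.

What passing these tests shows: the annotation inverts the generative model
essentially perfectly at low SHM, planted SSPs are recovered with precision
and recall ≥ 0.9 under the study conditions, and the UM/M label matches the
planted truth. What it does not show: robustness to indel SHM, AID hotspot
spectra, allele-level V distinctions, class-switched repertoires, or
sequencing error — none of which the generator emulates (and the first
three of which the method's own assumptions exclude).

## Statistics

* Pearson X² and the likelihood-ratio statistic G are computed from their
  definitions with asymptotic chi-square p-values. The Monte Carlo
  correction (seeded, add-one convention) resamples tables with the grand
  total fixed and cell probabilities from the independence model, and
  re-estimates each simulated table's expectations from its own margins —
  the statistic's null distribution is otherwise inflated from
  (r−1)(c−1) to rc−1 degrees of freedom. On dense tables the MC and
  asymptotic p agree within Monte Carlo error; on small tables (n ≈ 100 in
  a 2×2) the exact null's discreteness shifts the MC p by a few MC standard
  errors, which is a property of the table, not a defect of either p.
* The one-sample proportion test is the normal-approximation z-test
  (z = (k/n − p0) / sqrt(p0(1−p0)/n), two-sided), with an exact binomial
  option, for comparing a gene's usage frequency against its background
  rearrangement frequency.
* HCDR3 length and pI comparisons use Student's pooled t-test by default
  (Welch optional) with a p = 1 convention for degenerate zero-variance
  equal-mean inputs. Summaries report mean ± sample SD (n−1), 1 decimal for
  lengths and 2 for pI.

## Numerical and design choices

* Expansion threshold: ≥ 2 colonies **and** ≥ 20% of a sample (the smallest
  expanded fraction printed in the source clone table is 22.2%);
  configurable.
* Stereotypy: exact identity of anchor-stripped HCDR3 across ≥ 2 parental
  mice; an optional Hamming-distance ≤ 1 single-linkage mode (off by
  default) merges near-identical loops of equal length.
* Similarity search against an annotated HCDR3 reference set uses global
  alignment (match +1, BLOSUM62-positive mismatch +0.5, other mismatch 0,
  gap −1) with percent similarity = identities / alignment columns;
  reporting threshold 75%. Queries of 6-17 residues do not warrant
  heuristic database search, and externally published homology percentages
  against public databases are out of scope.
* Rearrangement tables are tab-separated with the AIRR-style column set
  plus `is_allotransplant` / `parental_mouse_id`, which the dedup rules
  need; absent D calls travel as empty strings.
* Tie-breaking is deterministic everywhere (score, then identity, then
  lexicographic name), and every stochastic stage takes an explicit seed;
  a cohort is a pure function of its configuration.

## Problem sizes used in the checks

The packaged clone table (27 records → 20 canonical clones) exercises the
accounting and feature stages at the exact published values. Synthetic
checks run full-size default cohorts (~100-130 clone records over 20 mice)
for SSP recovery and round-trip fidelity, 1,000 random peptides for the pI
oracle, and 10,000 Monte Carlo replicates for the chi-square comparison;
unit tests use smaller 6-mouse cohorts where the full cohort adds nothing.

## Known limitations

* No indel handling in SHM calling; an indel-containing V alignment is
  flagged and its junction is not extracted.
* SSP calling does not phase polymorphisms into haplotypes and does not
  emit novel germline alleles beyond the SSP table.
* The mutated/unmutated boundary is a hard 2% threshold; clones whose true
  divergence sits at the boundary are sensitive to the aligned-length
  denominator.
* Cross-genotype usage tests are exercised on synthetic cohorts only; the
  published per-genotype clone lists behind such comparisons are not
  packaged.
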