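---
title: "Off-target-minimized dsRNA design and knockdown quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-target-minimized dsRNA design and knockdown quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dstile)
```

## The problem

A long dsRNA injected into an insect is diced into short siRNAs, each of
which can load RISC and silence any transcript carrying a close match. When
the trigger is made from an arbitrary stretch of the target cDNA, paralogous
or repetitive stretches shared with other genes produce unintended
knockdowns that confound loss-of-function phenotypes. The screen implemented
here chooses the synthesis amplicon *within* the target so that as few as
possible of its constituent k-mers have credible matches elsewhere in the
transcriptome.

## The off-target model

The unit of risk is the k-mer fragment (default k = 19 nt, the canonical
siRNA core). A fragment is *flagged* when some non-target transcript has an
alignment to it satisfying, jointly:

* alignment length ≥ 18 columns ("longer than 17 nucleotides"),
* identity strictly greater than 90 % — identical columns over all alignment
  columns, gap columns included in the denominator (BLAST `pident`),
* at most 2 gapped columns ("fewer than 3 gaps") — total gap length, not
  openings, the stricter of the two readings,
* subject not among the declared target ids (self-hits are design signal,
  not risk).

`N` never counts as a match. Alignments are *match-bounded*: they begin and
end on an identical column, exactly as score-maximal local alignments
reported by BLAST-like tools do (a terminal mismatch or gap always lowers
the score, so no reported HSP carries one). This matters at the boundary: a
19-mer whose first and last bases both mismatch supports at best a 17-column
HSP, which the length rule rejects.

Both strands are screened by default, because a dsRNA trigger silences
through both of its strands and BLASTn searches both; minus-strand hits are
reported on forward-strand coordinates with a strand flag.

### Two search routes, one acceptance rule

`scan_offtargets()` implements a seed-and-extend matcher: exact
`seed_len`-mers of every non-target transcript are indexed; each seed match
nominates an alignment diagonal; a banded dynamic program (band = max gaps)
around each diagonal enumerates every match-bounded alignment passing the
rule, tracking gap columns and mismatches exactly rather than through a
substitution score. `scan_offtargets_bruteforce()` is the independent
oracle: an unseeded, unbanded DP over every (fragment, transcript, strand)
triple, quadratic by construction. The test suite requires exact hit-set
equality between the two on planted-homology instances.

The seed length default is 7, not the `floor(18/2) = 9` a mismatch-only
pigeonhole argument would give: at the default thresholds an acceptable
alignment can carry one mismatch *or* up to two gap columns, and a 19-match
alignment interrupted by two subject insertions can limit the longest exact
co-diagonal run to `ceil(19/3) = 7`. With `seed_len ≤ 7` every acceptable
alignment contains a nominating seed, so seeding loses nothing; larger
values trade completeness for speed and are exposed as a parameter.

Overlapping alignments of one fragment to one subject and strand are
collapsed to a single reported hit (highest identity, then longest, then
leftmost, then shortest). One caveat is documented rather than solved: both
routes emit the maximal-match alignment per end-cell and state, so an
adversarial tandem near-repeat could in principle make the collapse
representative tie-dependent. This never arises in the seeded property tests
(random backgrounds with single planted blocks), and the downstream risk
profile consumes only flag/subject information, which is unaffected.

### Risk profile and window selection

Accepted hits are tallied per fragment start. The amplicon of requested
length A (the study regime is a few hundred bp, e.g. 564 bp; there is no
principled default, so A is a required argument) is chosen by evaluating
every start `0 .. L − A` and minimizing the number of flagged fragments
*fully contained* in the window — a dsRNA can only be diced into siRNAs
lying wholly within itself. Partial-overlap counting is available as an
option for conservative designs. The load metric is the count of flagged
fragments, not the sum of hit counts: one fragment with five paralog hits is
one bad siRNA, not five. Ties break by fewest distinct off-target subjects,
then leftmost start — the leftmost rule is a repository convention, not an
inference about the original analysis. Optimality is by exhaustive
enumeration and is cross-checked in tests against an independent naive
recount.

`make_t7_templates()` prepends the T7 promoter to each primer. The canonical
minimal class III promoter `TAATACGACTCACTATAG` is the default; protocols
differ in how many initiating G's they append, so the sequence is a
parameter and is recorded in the JSON report.

## Quantification model

Per biological replicate, `dCt = Cq_gene − Cq_reference` cancels template
input; `ddCt = dCt − mean(dCt over the calibrator group)` scales the
calibrator to 1; the per-replicate fold is `2^−ddCt`. When per-primer
amplification factors are supplied (from `fit_standard_curve()`:
`E = 10^(−1/slope)` of the OLS fit of Cq on log10 template), the
Pfaffl-corrected ratio `E_gene^(ΔCq_gene) / E_ref^(ΔCq_ref)` is used, each
ΔCq taken against the calibrator-group mean Cq of that gene; at E = 2 for
both genes this reduces exactly to `2^−ddCt`.

**Geometric versus arithmetic summary.** Under Gaussian cycle noise the
per-replicate fold is log-normal. The geometric mean (equivalently
`2^−mean(ddCt)`) is the summary reported as `mean_fold` and
`percent_of_control`: it makes the calibrator group's own mean fold exactly
1 for any input, and it is unbiased for the true fold on the log scale,
which the parameter-recovery tests verify at knockdowns of 90/50/12/6 % of
control under σ ∈ {0, 0.2, 0.5} cycles. The arithmetic mean of folds —
what bar plots usually draw — carries a multiplicative bias of roughly
`exp((ln 2)² σ²_ddCt / 2)` and is reported alongside with its SEM. The 95 %
CI is a Student-t interval with n − 1 df computed on log2 folds and
back-transformed, so it is symmetric on the scale where the model is
Gaussian and always contains `mean_fold`; whether the original analysis used
t-based or normal intervals is not stated anywhere, so this is a repository
decision. Similarly, "percent of control" can be read as mean-of-ratios or
ratio-of-means; both are computed, with mean-of-ratios (consistent with
per-replicate ddCt) as the default field.

Technical replicates (duplicate Cq rows per sample, gene and replicate) are
averaged before dCt. Each replicate — in the emulated design, one pool of
three fat bodies — is one statistical unit; no nesting model is attempted.

**Group comparison.** Shapiro–Wilk on each group; if both retain normality
at α = 0.05, an unpaired, equal-variance, two-sided Student's t-test;
otherwise a two-sided Mann–Whitney U. The source study's caption describes
its non-normal groups as having Shapiro–Wilk "p > 0.05", which is internally
inconsistent with standard usage; the standard direction (reject normality
when p < 0.05) is implemented. A constant group, for which Shapiro–Wilk is
undefined, falls through to Mann–Whitney and is flagged as degenerate.

## What the synthetic generators state, and what a green test shows

`make_transcriptome()` draws i.i.d. bases at a tunable GC fraction —
deliberately structureless, so that any accepted hit in a planted instance
is attributable to the plant (background hits at ≥ 18 matched columns are
vanishingly rare in random sequence, and the zero-hit test on unrelated
transcriptomes confirms this). `plant_offtarget()` splices a mutated copy
of a target block into a host transcript: substitutions to a different base
at a per-base rate, and length-1 indels, matching the ≤ 2-gap acceptance
regime under test. The truth record lists the fragment starts *guaranteed*
to be flagged at zero mutation — every k-mer sharing at least 18 nt with the
block — plus the fully-contained subset; flanking host bases can extend an
alignment and flag one or two additional edge fragments, so tests assert
containment, not equality.

`simulate_cq()` encodes a true fold f as a cycle shift `−log_E(f)` on the
target gene plus `Normal(0, σ)` noise on every measurement, with the
defaults stating the emulated world: n = 5 replicates, σ = 0.2 cycles
(typical qPCR repeatability), baseline Cq 22 for assayed genes and 16 for
the abundant reference, E = 2. `default_cq_design()` mirrors the emulated
experiment: two dsRNA arms × two bacterial challenges plus a buffer
calibrator, target knocked down to 12 % of control and AMP readouts at
47–55 %, the regime the source study reports. What these generators do
*not* emulate: transcript abundance, amplification stochasticity at low
copy number, inter-plate effects, reference-gene instability, or realistic
transcriptome repeat structure. A green recovery test therefore establishes
correctness of the estimator under the stated noise model, not robustness
to qPCR pathology.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; BLAST tabular (1-based
  inclusive, minus-strand as reversed coordinates) is converted at import,
  and every report states its convention.
* The 12-column BLAST format carries gap openings, not total gap length;
  imported `gap_count` is the `gapopen` value and rows where it disagrees
  with the recomputable total `2·length − qspan − sspan` are flagged
  `gap_unverifiable` rather than silently corrected.
* Identity comparisons use `100·matches > min_identity·columns` so that the
  90.0 boundary (e.g. 18/20) rejects exactly, without floating-point
  division.
* Flat standard curves: |slope| < 1e-9 is an error (lm returns rounding
  noise, not exact zero); a positive slope is flagged invalid rather than
  erroring, since the fit itself is well-defined; efficiencies outside
  (1, 2.5] are flagged.
* Stride > 1 tiling always appends a final fragment ending at L so the 3'
  end is covered; stride 1 (every register, since Dicer products can arise
  in any frame) is the default and the published description does not state
  which was used.
* Seeds are threaded explicitly through every generator; identical seeds
  give byte-identical FASTA/CSV outputs and CLI reports.

## Known limitations

* No thermodynamic or seed-region (positions 2–8) siRNA efficacy model —
  risk is purely match-based, as in the emulated screen.
* Single reference gene; no geNorm/NormFinder multi-reference
  normalization.
* The brute-force oracle is quadratic and intended for testing scales
  (≲ 50 kb transcriptomes), not production screens; the seeded matcher
  handles production scales but its completeness guarantee is specific to
  threshold regimes with ≤ 2 gaps and ≤ 1 mismatch acceptable.
* Amplicon choice ignores primer design quality; primers are supplied by
  the user from dedicated tools and only tagged here.
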