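---
title: "Sequence statistics for behavioral syllables: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence statistics for behavioral syllables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SyllableSeq)
```

## The analysis problem

Unsupervised segmentation of depth video (motion sequencing) decomposes
rodent open-field behavior into a sequence of brief, stereotyped motifs
("syllables"), emitting one integer label per video frame, typically at
30 fps for 15-minute sessions (~27,000 frames). Downstream questions are
statistical: does a mutant genotype use syllables at different rates than
wildtype; does it *order* them differently (bigrams/trigrams of
consecutive syllables); and does a drug move the mutant's sequence
statistics back toward wildtype in a dose-dependent way?

SyllableSeq implements that downstream layer: representation
(`FrameLabels`, `RunSeq`), usage and n-gram probability tables
(`computeUsage`, `ngramTable`), resampling inference (`usageZTest`,
`mcAboveChance`, `scaledRescueStatistic`), the classical behavioral
endpoints run alongside (`discriminationIndex`, `freezingPercent`,
`anovaTwoWay`, ...), and a semi-Markov cohort generator
(`simulationParams`, `simulateCohort`) that makes every stage testable
without any recorded data.

## Representation: frames, runs, transitions

A syllable bout occupies several consecutive frames, so the frame stream
is run-length encoded and **transitions are defined between runs**.
Counting transitions at the frame level would be dominated by
self-transitions (a 10-frame bout would contribute nine i-to-i
"transitions"), which is why self-transitions are impossible by
construction here. Bigram probability is the number of i-to-j run
transitions divided by the total number of transitions; trigrams are
overlapping (stride-1) windows of three run labels. Windows never cross
animal boundaries.

Syllables enter the analysis when their usage — the fraction of total
frames, unassigned frames included in the denominator — pooled over all
animals exceeds 1% (strictly), minus any explicitly flagged noise
syllables; survivors are renumbered 0..k−1 by descending pooled usage
with ties broken by ascending original ID. When a run of an excluded
syllable is deleted from a sequence, flanking runs of equal label are
merged, treating the excluded bout as unobserved; tuples therefore never
contain excluded labels or equal adjacent labels.

Two choices here were genuinely open. Group tables **pool counts across
animals** before normalizing (rather than averaging per-animal
probabilities); pooling matches the one-probability-per-group-
per-condition presentation this analysis feeds and weights animals by
their transition counts. And trigram windows **overlap** rather than
tile; overlapping is the standard n-gram convention and uses all the
data. Only the first trial of each session is analyzed by default (later
trials are less reliable under repeated handling); this is configurable.

## Resampling inference

**Bootstrap unit = animal.** Animals are the independent units of a
cohort; frames and runs within an animal are strongly dependent. All
bootstrap operations resample animals with replacement and recompute the
pooled statistic, with 95% percentile intervals (no BCa refinement — the
percentile interval is the minimal reading, and the statistics here are
smooth functionals of pooled counts). 1000 replicates by default; tests
and quick runs use a reduced profile of 200.

**Usage z-test.** Per syllable, z = (ūA − ūB)/√(v̂A + v̂B) with each v̂ the
bootstrap variance of the pooled group usage, two-sided normal p-values,
Benjamini–Hochberg correction across the included syllables, and flags at
q < 0.05. If both bootstrap variances are zero with unequal means
(possible only in degenerate fixtures), the syllable is reported as an
infinite-z sentinel with p = 0 and a `degenerate` flag plus a warning.

**Above-chance n-grams.** "Expressed more than chance" must mean beyond
what usage alone predicts, so the Monte Carlo null permutes each animal's
run-label order — preserving per-animal usage, destroying sequence — and
rebuilds the pooled table. A raw permutation can place equal labels
adjacently, which a run sequence cannot, so permuted labels are re-merged
before windowing; without this the null would be biased against
sequences' built-in no-repeat structure, and even a structureless
two-syllable alternation would be flagged. One-sided p-values use +1
smoothing, p(g) = (#{P_null(g) ≥ P_obs(g)} + 1)/(n_rand + 1), so the
floor 1/(n_rand + 1) must be below alpha (`mcNullSpec` enforces this).
Defaults are 50,000 randomizations at p < 5e-5 for bigrams and 100,000
at p < 2e-5 for trigrams; the reduced profile (2,000 at 0.005) is used
throughout the test suite.

**Group comparisons.** The union of each group's above-chance n-grams is
compared by bootstrap: an n-gram differs significantly between groups
when the two 95% CIs are disjoint (strictly — touching intervals
overlap). The **summed-difference statistic** for a condition is
Σ_g |P_A(g) − P_B(g)| over a fixed differential set, with missing tuples
contributing 0. All conditions are scaled to the reference comparison
(untreated mutant vs wildtype), whose scaled point estimate is exactly 1
by construction. Bootstrap replicates are paired by replicate index
across conditions, each condition's groups resampled independently
within a replicate — the pairing convention is a documented choice, since
only the p-value formula
p = (#{value for A < value for B} + 1)/n_boot
is fixed; ties count as "not less than". Per-comparison p-values are
Bonferroni-corrected over the non-reference conditions.

Note a property of the summed absolute difference: it is positively
biased in finite samples, so even two groups drawn from identical
dynamics produce a positive value (the "noise floor"). Full rescue is
therefore assessed as indistinguishability from an all-wildtype
comparison, not as a literal zero.

**Multiple testing.** BH and Bonferroni are delegated to
`stats::p.adjust`; Holm–Šidák (step-down, adjusted_(i) = max_{j≤i}
1 − (1 − p_(j))^(m−j+1)) is implemented here since `p.adjust` offers only
plain Holm. All three are cross-checked against textbook-definition
oracles in the test suite.

## The synthetic cohort generator

The generator defines the conditions under which the pipeline is
validated. It is a **semi-Markov** chain: an embedded transition matrix
with zero diagonal chooses the next syllable, and geometric dwell times
give each bout a duration — frame-level Markov chains would make run
statistics degenerate. Defaults, chosen once as plausible stand-ins for
real ethograms (the source distributions are unpublished):

- 35 syllables, 27,000 frames/session (15 min at 30 fps); the test suite
  scales to 20 syllables x 5,000 frames to keep runs fast.
- power-law-like usage profile (rank^−0.85), so top syllables dominate;
- dwell means spread over 3–15 frames (0.1–0.5 s at 30 fps);
- base transitions attracted to target usage with a mild banded
  structure, so wildtype sequences carry genuine above-chance n-grams,
  as real behavior does;
- per-animal heterogeneity by Dirichlet jitter of transition rows,
  concentration 200 (mild);
- group sizes defaulting to the study design (15/12/27/14/18/11).

**Genotype effects** are multiplicative odds factors. An n-gram effect
multiplies its consecutive transition entries and renormalizes. A
syllable effect shifts that syllable's stationary **usage odds** by the
factor; because row renormalization couples syllables, the required
incoming-column multiplier is found by a short fixed-point iteration on
the semi-Markov stationary usage (naively multiplying the column
undershoots the intended usage shift). **Rescue** interpolates the mutant
matrix elementwise toward wildtype, (1−λ)·del + λ·wt, under a dose→λ map
defaulting to {0: 0, 0.25: 0.3, 0.5: 0.7, 1.0: 1.0} — a test fixture, not
an empirical dose-response claim. At the generative level the perturbed
entries are exactly monotone in λ, and λ = 1 restores wildtype exactly.

Synthetic endpoints mirror the classical tasks: gamma-distributed total
exploration with Beta-distributed novel-object preference (wildtype 0.7,
untreated mutant 0.5 = chance, treated mutant interpolated by λ),
Bernoulli 2-s freezing epochs, and Poisson 5-min activity bins.

What passing tests on these cohorts do **not** show: real syllable
sequences have longer-range dependencies than a semi-Markov chain,
session-level nonstationarity (habituation), and label noise from the
upstream segmentation; power and calibration measured here transfer to
real data only to the extent those features are negligible at the group
level.

## Classical endpoints

The endpoint rules are implemented exactly as printed, with boundary
strictness read literally: discrimination index 100·tB/(tA+tB); animals
excluded when total exploration is **strictly below** 3 s in either
phase (exactly 3 s is kept); outliers excluded when **strictly beyond**
±2 SD of their genotype-by-treatment group (sample SD, single pass, on
the full group including candidates — the iteration question is
undecidable from the printed rule, so the minimal single-shot reading is
used and the operator is exposed for re-running); freezing scored per 2-s
epoch; center-time percent 100·center/total; activity binned into
half-open [start, end) 5-minute windows, so an event exactly on a
boundary belongs to the later bin. Low-exploration exclusion runs before
outlier exclusion by default. The two-way genotype x treatment ANOVA
uses type III sums of squares with sum-to-zero contrasts (matching the
commercial packages these endpoints are usually analyzed in — the choice
matters once exclusions unbalance cells), with Welch post-hoc t-tests
adjusted by Holm–Šidák over exactly the requested comparison family.

## Numerical and reproducibility choices

- Every stochastic operation takes a seed, saves and restores the
  caller's RNG state, and is bit-reproducible; per-animal and per-stage
  seeds are derived deterministically from the master seed.
- Probabilities are exact count ratios; table invariants (sum to 1,
  count/total identity) are asserted to 1e-12.
- Degenerate inputs error early with named rows/cells: empty sequences,
  non-contiguous frame indices, empty ANOVA cells, all-zero transition
  rows, reference comparisons with zero summed difference.
- Usage-rank ties break by ascending original ID; n-gram sets order
  lexicographically by numeric ID.
- The CLI (`cliMain`; subcommands `simulate`, `usage-test`, `ngram-test`,
  `rescue`, `endpoints`) writes a manifest with every seed and parameter;
  identical inputs and seeds give byte-identical result files, and the
  manifest alone suffices to regenerate a run.

## A small worked example

```{r example}
p <- simulationParams(nSyllables = 10L, framesPerSession = 3000L,
                      seed = 1L,
                      genotypeEffect = list(list(target = 3L, odds = 1.5)))
design <- makeCohortDesign(data.frame(genotype = c("wt", "del"),
                                      dose = 0, n = 8L))
cohort <- simulateCohort(p, design)
usages <- lapply(cohort$sequences, computeUsage)
sset <- selectSyllables(usages, threshold = 0.01)
sset
res <- usageZTest(usages[cohort$meta$genotype == "wt"],
                  usages[cohort$meta$genotype == "del"],
                  sset, nBoot = 200L, seed = 2L)
res[res$significant, ]
```

## Known limitations

- The Monte Carlo null conditions on per-animal usage only; nulls
  preserving higher-order structure (block shuffles, Markov-preserving
  rewiring) are out of scope.
- The bootstrap treats animals as exchangeable within group; litter or
  cage structure is carried in metadata but not modeled.
- Scaled rescue values are ratios of positively biased quantities and
  should be read against the reference and a null comparison, not as
  absolute effect fractions.
- The generator's dose→λ map and dwell/usage profiles are plausible
  defaults, not estimates.
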