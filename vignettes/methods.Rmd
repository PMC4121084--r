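---
title: "Methods: cross-species stage-transition profiling of preimplantation expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species stage-transition profiling of preimplantation expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preimplantr)
```

## The analytical problem

During preimplantation development the embryo's transcriptome is rebuilt
twice: maternally loaded mRNAs are degraded during cleavage, and the
embryo's own genome starts transcribing at zygotic genome activation (ZGA)
— around the 4- to 8-cell stage in human and the 1- to 2-cell stage in
mouse. Expression studies of this window therefore revolve around three
canonical temporal profiles: genes switched on at ZGA that stay on
("Up"), genes switched on at ZGA and off again by the blastocyst
("Up-down"), and maternal transcripts that only decay ("Down").

`preimplantr` implements the complete analysis chain for comparing these
profiles between human and mouse across three platforms: two-channel-free
Affymetrix-style arrays (probe-level intensities), TaqMan qPCR cards (Ct
values), and RNA-seq RPKM matrices. Because the species differ in both
stages and platforms, every step is explicit about its stage design, its
significance convention and its missing-data policy.

## Stage designs and data layout

A `stage_design()` fixes the ordered stages, replicate counts and species;
samples are addressed as `"<stage>_<replicate>"`. Comparisons always use
the declared developmental order, never lexical order, and positional
column inference is refused: a file must name every `(stage, replicate)`
in its header. Expression tables are wide tibbles (`feature_id` + one
column per sample); qPCR tables are tidy long tables with one row per
reaction and an explicit `detected` flag. Expression matrices must be
complete — missingness is a qPCR concept, modelled only through detection
flags, because array and RPKM matrices arrive complete.

## Array preprocessing

Between-array normalisation uses the rank-invariant-set method: probes
whose proportional rank difference between target and reference stays
below a threshold (default 0.05, iterated to a fixed point, at most 10
rounds) anchor a non-decreasing piecewise-linear map from target onto
reference intensities, linearly extrapolated beyond the invariant range.
The defaults are conventions of this package: the reference array is the
one whose median equals the grand median of the per-array medians (ties
to the first in input order), and arrays are afterwards rescaled so all
medians agree (`rescale_to_common_median()`).

Probe sets are summarised with the model-based expression index:
`value[i,j] = phi[i] * theta[j]` (probe affinity times per-array
expression), fitted by alternating least squares under the
identifiability constraint `sum(phi^2) = n_probes`. We deliberately omit
the classic probe/array outlier-rejection loop: at the scale of these
designs (a handful of arrays per stage) outlier pruning is statistically
unverifiable and the plain least-squares fit is transparent; the residual
trace is exposed and tested to be non-increasing. On noiseless rank-1
input the fit is exact (tested to `1e-18` residual), and on noisy input
it agrees with the SVD rank-1 approximation.

## Stage-transition differential expression

For every consecutive stage pair, each feature is tested with a two-sided
two-sample t-test on log-scale values. Two variants are provided:

* **Student** — pooled variance, the test named for the qPCR analysis;
  Welch is available behind a flag for unequal variances.
* **Moderated** — empirical-Bayes variance moderation: per-feature
  variances are shrunk toward a prior `s0^2` with prior degrees of
  freedom `d0`, both estimated by method of moments on `log(s^2)`
  (digamma/trigamma matching), and the t-statistic gains `d0` degrees of
  freedom. `d0` above `1e6` is treated as infinite; when the sample
  variances have no spread the fit returns the exact degenerate limit
  (`d0 = Inf`, complete shrinkage). The fit is cross-checked in the test
  suite against `limma::squeezeVar`, which implements the same moments
  estimator, but the package's own fit is always the one used.

Features with fewer than two usable replicates in either stage are
reported `skipped` and carry no statistics — the rule the qPCR analysis
states, applied uniformly.

Multiple testing uses the Benjamini–Hochberg step-up, implemented
directly (`bh_fdr()`) and verified against a brute-force evaluation of
the definition and against `stats::p.adjust`. The FDR family is one
stage pair across all features; the alternative (one global family
across all transitions) is a single argument away since the tests return
per-pair tables. Two significance conventions coexist deliberately,
mirroring platform practice: arrays call significance at `q <= 0.05`,
qPCR and RPKM at raw `p <= 0.05`. No fold-change cut-off is applied
anywhere in the transition tests.

## Profile classification

`classify_profiles()` reduces a feature's transition calls to one of
`UP`, `UP_DOWN`, `DOWN`, `UNCLASSIFIED`:

* `UP_DOWN` — a significant increase into a ZGA-window stage followed by
  a later significant decrease into a late-window stage;
* `UP` — a significant increase into a ZGA-window stage with no later
  significant decrease;
* `DOWN` — at least one significant decrease, with no earlier
  significant increase.

Precedence is `UP_DOWN > UP > DOWN` because up-down is the only class
requiring both signals. The `DOWN` rule accepts a decrease at *any*
transition rather than only into the late window: the maternal class is
defined cumulatively ("down by" the late stages), and a maternal
transcript whose decay completes at ZGA would otherwise be
unclassifiable. Windows default to 4-/8-cell (ZGA) and the last two
stages (late) for human designs, and 1-/2-cell for mouse, and are
configurable per dataset so a design starting at the 1-cell stage needs
no code changes.

Two-dataset consensus (`intersect_datasets()`) keeps a feature only when
both datasets assign the same non-trivial class. This is deliberately the
looser of two readings (same class, not same significant transition);
requiring the identical transition would be stricter than the cluster
definitions themselves. Probe-to-gene collapse gives a gene a class when
at least one probe carries it; genes with probes in conflicting classes
are flagged ambiguous and excluded from counts rather than resolved by
majority — conflicts are surfaced, not hidden.

## The qPCR −ΔCt pipeline

`neg_delta_ct()` computes `-dCt = -(Ct_gene - mean(Ct_controls))` per
sample against endogenous controls (Hprt1 and Psmb6 in the mouse
designs). Three explicit policies govern undetected reactions:

1. **Arithmetic** — undetected reactions enter the calculation at the
   detection-limit Ct of 40.0 cycles.
2. **Imputation** — every undetected cell is floored at the lowest
   calculated −ΔCt among detected, non-control reactions of the same
   protocol (`impute_undetected()`); the floor is a per-protocol
   quantity, which is why the protocol label is a required table
   attribute. Controls are excluded from the floor because they sit near
   0 by construction.
3. **Averaging vs testing** — plotting averages use detected replicates
   only (falling back to the floor when every replicate is undetected),
   while stage-pair t-tests *include* imputed values but are only run
   when both stages have at least two detected replicates. These are two
   different policies on purpose, implemented exactly as stated.

## RPKM screens

`fold_change_filter()` adds a pseudocount of 0.1 to every RPKM value,
computes the late/early ratio of stage means and a pooled t-test on the
pseudocounted replicates, and passes genes with ratio strictly greater
than 5 and `p <= 0.05`. "More than 5 times" is read strictly (`>`, not
`>=`). The plotting transform is `ln(RPKM + 1)` — a distinct constant
(1, natural log) from the filtering pseudocount (0.1), never conflated.
The test behind the published RPKM p-values is not named in the source
methods; the pooled two-sample t is the package default for consistency
with the rest of the chain, with Welch optional — benchmark reproduction
depends on this choice, so it is a prominent, logged argument.
Same-stage columns (cells or embryos) are treated as independent
replicates, as the stage-mean comparisons imply.

## Cross-species concordance

Human gene-level calls are joined to mouse orthologs from a two-column
map (one verdict per pair; one-to-many maps are never aggregated to the
human gene). `classify_concordance()` then reads the mouse transition
evidence over MII → 1-cell → 2-cell → 8-cell at raw `p <= 0.05`:

* human `UP`: similar iff significantly up 1-cell → 2-cell (the mouse
  ZGA transition);
* human `UP_DOWN`: similar iff significantly up 1-cell → 2-cell *and*
  significantly down 2-cell → 8-cell; `relax_updown = TRUE` waives the
  decrease (a relaxation observed for a single ortholog in published
  data) and defaults off;
* human `DOWN`: similar iff at least one significant decrease and no
  significant increase across the course. The alternative reading — a
  direct MII vs 8-cell test — is narrower; the chosen rule uses all
  transitions and is configurable in spirit via the returned evidence
  counts.

Pairs failing their rule are `DIFFERENT_MATERNAL` when any significant
decrease exists (the maternal signature), else `UNCLASSIFIED`. A
`SIMILAR` verdict for a human `UP` gene is impossible when the
1-cell → 2-cell transition is skipped or non-significant, and this is
asserted as a property test. Whether `UNCLASSIFIED` pairs count as
"different" is a reporting decision, not a classification one, so both
tallies (with and without them) are derivable from the verdict table.

Stage-matched Pearson correlations (`pearson_stage_correlation()`) and
agglomerative clustering (`hierarchical_cluster()`, Euclidean distance,
complete linkage — the defaults of the common heatmap routine, and
configurable) support the comparison figures. Zero-variance vectors
yield a missing correlation with a warning rather than an error.

## The synthetic-data generator

`simulate_study()` plants ground truth for every downstream stage. Each
gene draws a baseline abundance (log2 Normal, mean 5, sd 1.5) and one of
four archetype templates with a step of `effect_log2` (default 2):
`up` steps up at the ZGA stage and persists, `up_down` returns to
baseline at the final stage, `down` is high through the maternal stages
and steps down at ZGA, `flat` is constant. Replicates add Normal noise
(`noise_sd_log2`, default 0.25). The simulated datasets are:

* two human probe-level arrays (stages MII/4-cell/8-cell/blastocyst and
  1-cell/4-cell/8-cell/blastocyst, 3 replicates), with 1–3 probes per
  gene and fixed per-probe affinity offsets (sd 0.3 log2) to exercise
  probe collapsing;
* a mouse TaqMan card (MII/1-cell/2-cell/8-cell with 2/2/3/3
  replicates — the replicate structure of the 12 ng random-hexamer
  protocol) including two flat control assays, converted to Ct by
  `ct = 38 - log2(expression)` with a 40-cycle detection limit;
* human (six stages to the blastocyst) and mouse RPKM-like matrices,
  `max(2^log2expr - 1, 0)`, guaranteeing non-negativity.

A planted fraction of mouse orthologs is concordant with the human
archetype. The fraction is allocated exactly (`round(f * n)` per
archetype) rather than by Bernoulli draws, so recovery tests measure
classification error, not binomial sampling noise. Divergent orthologs
of `up`/`up_down` genes take the maternal `down` template — the
divergence mode actually observed in cross-species comparisons. For
divergent orthologs of `down` genes the maternal template would itself
be concordant, so they take the `up_down` template instead (a transcript
that rises at ZGA and falls again), which the concordance rules classify
as different; without this asymmetry a planted concordant fraction would
be unrecoverable by construction. Orthologs of `flat` genes carry no
concordance label. The default concordant fraction is 0.7, the order of
the overall cross-species agreement reported for curated gene panels.

One master seed drives everything; per-matrix substreams are drawn once
from the seeded master stream so adding a dataset type cannot shift the
others. What the generator does **not** emulate: count-based sequencing
noise (negative binomial, library size), qPCR amplification-efficiency
variation, probe cross-hybridisation, and stage-timing heterogeneity
between embryos. Passing recovery tests therefore demonstrate that the
chain is correct under Gaussian log-scale noise with known designs — not
that real arrays or cards would reach the same accuracy.

## Numerical and design choices

* Zero-variance t-tests: identical groups give `t = 0, p = 1`; a pure
  shift with zero variance gives `p = 0`.
* The trigamma inverse is solved by Newton iteration (50 steps,
  relative tolerance `1e-10`), with asymptotic starts at both extremes.
* Ties in the invariant-set map: tied target values average their
  reference values, then the map is made non-decreasing (running
  maximum) so normalisation can never invert an ordering.
* The hierarchical clustering leaf order is deterministic; ties resolve
  by input index through the distance computation.
* `sim_config()` validates all variances, fractions and counts before
  any simulation.

## Verification scale

The test suite runs the recovery study at 400 genes per archetype
(effect 2.0 log2, noise 0.25, 3 replicates), the null calibration at
10,000 flat genes, the BH oracle on 1,000 random vectors, and the
concordance recovery at 300 pairs with a planted fraction of 0.6 — sizes
at which every check completes in seconds while leaving binomial noise
well inside the asserted bounds. `scripts/acceptance.R` recomputes the
same quantities from scratch for any seed.

## Known limitations

* The published probe counts of the original two-array comparison
  (hundreds to thousands of probes per cluster) depend on the raw
  ArrayExpress arrays and the original model fit; they are external
  benchmarks, not package tests, and the corresponding checks run only
  when a user supplies the converted tables (see
  `tests/testthat/test-acceptance.R`).
* The moderated test assumes exchangeable variances across features
  within a stage-pair family; strong mean–variance trends would call
  for a trended prior, which is not implemented.
* The `DOWN`/concordance rules are threshold classifiers on per-pair
  tests; they inherit the per-transition error rates and do not model
  the profile jointly.
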