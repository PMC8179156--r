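---
title: "Screening isotopologue pairs and tracer co-behavior in untargeted LC-MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening isotopologue pairs and tracer co-behavior in untargeted LC-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerscreen)
```

## The screening problem

Feeding a plant a stable-isotope-labeled precursor — for example a
glucosinolate carrying five deuterium atoms on its side chain — turns
every downstream processing intermediate into a *pair* of LC–MS
features: the unlabeled metabolite from the ordinary precursor and its
heavy isotopologue, co-eluting and separated by a fixed mass shift.
`tracerscreen` finds such pairs in aligned untargeted feature tables,
and additionally finds features whose abundance responds to the
precursor *regardless* of the label (for example glutathione depletion
while conjugates form, or accumulation of a terminal catabolite such
as raphanusamic acid), which the pair screen by construction cannot
see.

The expected experimental design is three treatments — solvent
control, unlabeled tracer, labeled tracer — crossed with time points
(3, 9, 24, 48 h by default) and replicates (3), measured in positive
and negative ion mode.

## Preprocessing

Two steps, in this order, mirroring standard untargeted practice:

1. **Noise flooring** (`floor_noise()`): every intensity below the
   noise floor (default 500 area units) and every missing cell is set
   to exactly the floor. Missing cells are kept distinct from zero up
   to this point so the raw table can be audited.
2. **Internal-standard normalization**
   (`normalize_internal_standard()`): within each ion mode, each
   sample column is divided by that sample's internal-standard
   intensity (lidocaine, *m/z* 235.1805, positive mode;
   10-camphorsulfonic acid, *m/z* 231.0697, negative mode; located by
   an *m/z* match within 0.01 Da). The pre-normalization matrix is
   retained on the table.

The intensity criterion below is stated in raw units ("twice the
noise level"), so it is evaluated on the retained pre-normalization
matrix by default; a `use_normalized` switch supports sensitivity
analysis.

## The pair screen

`screen_pairs()` applies four criteria per ion mode:

1. **Intensity**: the maximum over (treatment, time) group means is
   strictly greater than twice the noise floor, for both members.
2. **Mass shift**: the *m/z* difference matches the incorporation of
   2, 3, 5 or 10 deuterium atoms — shift table 2.0126, 3.0189,
   5.0314, 10.0628 Da — within ±20 ppm of the query (lighter
   member's) *m/z*. The tabulated shifts are used verbatim by
   default; `deuterium_shift(printed = FALSE)` switches to computed
   per-atom products (they agree within 20 ppm; the 3-atom value
   differs in the fourth decimal, and the tabulated value wins by
   default). A sulfur-34 specification (`sulfur34_shift()`, +2/+4 Da)
   is provided for ^34^S tracers.
3. **Co-elution**: retention times agree within ±0.05 min, boundary
   inclusive (with a 10^-9^ min guard so the printed boundary is
   robust to binary floating-point representation of decimal RTs).
4. **Treatment response**: the unlabeled member attains its maximal
   group mean exclusively under the unlabeled tracer, and the labeled
   member exclusively under the labeled tracer.

On tie handling in criterion 4 (and 5 below): the extremum must be
attained *only* by groups of the qualifying treatment class. A flat,
floored profile ties across all groups including controls and is
rejected as noise; a tie confined to the qualifying treatment(s) —
which arises in noise-free data when both tracer treatments share a
profile — still qualifies. This is the only reading under which the
two screens treat degenerate profiles consistently.

A feature may head several candidate pairs; reduction to one pair per
metabolite is deliberately deferred to consolidation.

## Consolidation across adducts and modes

One neutral metabolite can appear as [M+H]^+^, [2M+H]^+^ and
[M−H]^−^ features. `consolidate_records()` converts each record's
*m/z* to neutral-mass hypotheses under those adducts, links two
records when any hypotheses agree within 0.01 Da *and* retention
times agree within 0.05 min, and merges connected components,
keeping the most intense member as representative (ties broken by
lower *m/z*, then id). Connected components are used because
transitive merging is the only order-independent interpretation;
0.01 Da reuses the annotation tolerance, as no separate consolidation
tolerance is conventional; RT gating applies across ion modes since
both modes come from the same chromatographic run. For pair records
the linkage is evaluated on the unlabeled member
(`consolidate_pairs()`), and the labeled members of a merged
component are checked for consistent merging (warning otherwise).

## The co-behavior screen

`screen_cobehavior()` applies the intensity criterion plus:

5. **Extremum**: the global maximum or minimum of group means is
   attained only in tracer groups (either tracer; the direction
   records which extremum qualified, with the maximum taking
   precedence when both do).
6. **Correlation**: the Spearman rank correlation between the
   unlabeled-tracer and labeled-tracer sample vectors is strictly
   greater than 0.4, while both correlations of control against each
   tracer are at or below 0.2.

Criterion 6 correlates replicate-level vectors, pairing samples
positionally by (time point, replicate) — 12-point vectors under the
default design. A four-point group-mean variant is available
(`vector_mode = "group_mean"`), but a rank correlation on four points
takes only the coarse values {±1, ±0.8, ...}, which interacts poorly
with thresholds of 0.4 and 0.2; the replicate-level default is the
only variant for which the thresholds are meaningfully graded. The
replicate pairing itself is arbitrary (replicates are exchangeable),
which is why recovery on noisy data is a property of the profile
ranks across time, not of any particular replicate matching.

Two degenerate-input rules: a constant vector has no defined rank
correlation, and such features are rejected rather than erroring the
screen; constancy is assessed on the **pre-normalization** floored
intensities. The second clause matters: a feature flat at the noise
floor throughout a treatment carries no rank information of its own,
but dividing it by a per-sample internal standard manufactures
variation — the standard's own noise — which would then be rank-
correlated identically for *every* such feature. Assessing constancy
before normalization removes this artifact.

## Annotation

`annotate_mz()` matches observed *m/z* against theoretical precursor
ions ([M+H]^+^ positive, [M−H]^−^ negative) of a compound library
within an absolute 0.01 Da tolerance, sorted by error. A small
curated library ships with the package (the isothiocyanate processing
intermediates — SFN-GSH, SFN-γEC, SFN-Cys, the amine, raphanusamic
acid, glutathione — plus common glucosinolates); any user CSV with
`name,formula` columns is accepted. Monoisotopic masses come from an
embedded CIAAW/AME-derived atomic mass table (≥6 decimals) so results
are platform-independent. Only singly charged adducts are supported.

## Isotope budget arithmetic

`labeled_fraction(i_mono, i_labeled)` is the heavy-channel share of
the summed channel intensities, with no natural-abundance
correction — the convention here is that the two intensities are the
designated fragment-ion channels as measured. `dose_per_plant()`
(µM × mL / plants = nmol) and `recovery_percent()` express how much
of a supplied tracer is recovered in measured pools; for instance a
150 µM dose in 2 mL shared by 10 plants supplies 30 nmol per plant,
and recovered pools of 0.076 and 0.150 nmol are 0.753 % of that dose.

## The synthetic study generator

`simulate_feature_table()` emits a feature table with exact planted
ground truth, emulating the reference design: 1,200 positive and 800
negative features, 36 samples, noise floor 500, internal standards in
both modes, 20 planted pairs, 15 co-behaving features (8
accumulating, 7 transiently depleted), and 200 decoys in three
classes, each violating exactly one criterion (mass shift off by 2-4x
the tolerance; RT off by 0.2-0.5 min; labeled member peaking in
control). Baselines are log-normal with multiplicative noise
(multiplicative error is the standard MS intensity model), planted
time profiles follow the qualitative shapes seen for processing
intermediates (peak at 24 h, late accumulation, early transient, a
dip at 9 h, monotone rise), and deuterated partners co-elute with
their unlabeled forms up to jitter (label-induced RT shifts are
ignored - a documented simplification).

Three constructions make the ground truth exact rather than merely
likely, and they are the main things to keep in mind when reading
test results:

* **Placement hygiene**: feature *m/z* values are rejected if they
  would create an unintended co-eluting label-shift window (3x ppm
  margin, 4x RT margin) with any existing feature, so no background
  pair can satisfy criteria 2-3 by coincidence.
* **Correlation guards**: background (and internal-standard) noise
  draws are resampled until the tracer-tracer rank correlation of the
  floored (and IS-normalized) row is at most 0.2 — comfortably below
  the 0.4 threshold — so no background feature passes criterion 6 by
  luck. Without this, roughly one in ten flat features would exceed
  0.4 on 12-point vectors.
* **Opposed control drift**: controls of planted co-behaving features
  drift mildly in the opposite rank order of the tracer profile. A
  perfectly flat control with independent noise would have a ~25%
  chance per tracer of exceeding the 0.2 control-correlation bound,
  making recovery of a planted feature a coin flip rather than a
  guarantee.

Consequently, passing tests demonstrate that the screens implement
their criteria exactly (verified independently against O(n²)
brute-force enumeration), and that planted signal of the designed
effect size is recovered completely with no decoy leakage. They do
not demonstrate performance on real data, where control profiles are
not opposed by construction, backgrounds are not guarded, ion
suppression correlates features, and the boundary between "responds
to treatment" and "drifts" is not planted. The reproduction harness
(`reproduce_funnel()`) exists for that step: given the deposited
aligned matrix it reports the stage counts of all four declared
analysis variants (intensity criterion in raw vs normalized units x
replicate vs group-mean correlation vectors) next to the published
funnel (1,378/792 features, 42/13 pairs, 26 consolidated, 50/31
co-behavior records, 67 consolidated) with residuals, asserting
nothing.

## Numerical choices and limitations

* Thresholds are implemented exactly as stated: strict ">" for the
  intensity multiple and the tracer-tracer correlation, inclusive
  bounds for RT and the control correlations.
* The ppm window is scaled to the lighter (query) member's *m/z*.
* Problem sizes in the test suite: module tests run a 250-feature
  simulation; the acceptance suite runs the full 2,000-feature
  default and its brute-force cross-check, which completes in a few
  seconds.
* Out of scope: raw spectra and peak picking (the pipeline starts
  from an aligned matrix), isotope fine structure and natural-
  abundance envelopes, charge states beyond ±1, multi-label mixtures
  in one pass, significance testing of the correlations, and batch
  or RT-drift correction.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_feature_table(simulation_config(seed = 5))
res <- run_pipeline(table = sim$table)
res$summary
# planted truth is recovered exactly:
setequal(paste(res$pairs$unlabeled_id, res$pairs$labeled_id),
         paste(sim$truth$pairs$unlabeled_id, sim$truth$pairs$labeled_id))
```
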