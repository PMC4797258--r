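---
title: "Models and methods behind transdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind transdecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transdecon)
```

`transdecon` supports mapping-by-replacement genetics: identifying which
of several sequenced mutations causes a screened phenotype by replacing
each candidate with wild-type sequence co-transduced with a nearby
selectable marker, then re-screening the transductants. This vignette
records the models, the tunable parameters and their defaults, the
numerical conventions, and the design choices made where more than one
reasonable option existed.

## The co-transduction linkage model

Generalized transduction by phage P1 packages roughly 100 kb of donor
chromosome; after injection, a double crossover integrates a contiguous
segment around the selected marker into the recipient. The probability
that a locus at distance $d$ from the marker is co-inherited with it is
modelled by the classical mapping function

$$f(d) = \left(1 - \frac{d}{L}\right)^3, \qquad 0 \le d < L,$$

and $f(d) = 0$ for $d \ge L$, with $L$ the transducing-segment length
(default 100,000 bp, the accepted value for P1). The cubic form has the
anchor points one expects of a replacement process — $f(0) = 1$, strictly
decreasing, $f(L) = 0$ — and fixes all the derived statistics the package
reports. In particular, for two mutations on the same side of a marker at
distances $d_1 \le d_2$, a transduction separates them (replaces the near
one but not the far one) with probability $f(d_1) - f(d_2)$, because a
contiguous replaced segment that reaches $d_2$ must cover $d_1$. Under
this model mutations 10 kb apart within 30 kb of a marker are separated
with 17–22% probability, 5 kb apart within 25 kb with about 10%, and 1 kb
apart with at most about 3% — the resolution limit of the method.

Distances are shortest-arc distances on the circular chromosome.
Reference points follow the marker kind: an intergenic insertion occupies
a 2-bp (occasionally wider) interval and is measured from its midpoint,
which may be half-integral; a gene-replacement cassette spans the deleted
gene and is measured from whichever edge is nearer the query locus.
Coordinates are 1-based and inclusive throughout. Output tables round
distances to integer bp and percentages half-up to integers; the
underlying probabilities are always carried at full precision alongside.

## Library coverage and design

On a circular genome the worst-covered point is the midpoint of the
widest gap between adjacent marker reference points, where the distance
to the nearest marker is half the gap; `coverage_summary()` computes this
analytically rather than by scanning. For the packaged 94-insertion
intergenic library the widest gap is 62,574 bp (between insertions i-4
and i-5), giving a minimum co-transduction frequency of 0.324. Note that
a commonly quoted coverage floor for ~50 kb-spaced libraries is ~35%;
whether that figure reflects a second library used jointly or a different
distance convention is not derivable from the marker table alone, so
`validate_library()` treats the floor as a configurable parameter
(default 0.35) and the packaged library fails it narrowly in four gaps —
an honest property of the midpoint convention used here.

`place_markers()` designs new libraries by a greedy grid-and-snap rule:
ideal sites every `target_spacing_bp` (default 50,000 bp, half the
transducing segment, so adjacent markers always back each other up), each
snapped to the nearest intergenic point, ties to the lower coordinate. A
global optimizer (e.g. dynamic programming minimizing the maximum gap)
could shave the worst gap slightly but would obscure the correspondence
between grid index and genomic neighbourhood; the greedy rule matches how
such libraries are laid out in practice and is deterministic and
idempotent. Sites with no intergenic point within $L/2$ are reported as
unplaceable rather than raising an error, because a partially placeable
annotation is still useful. Overlapping genes are merged into opaque
blocks before region extraction (no convention exists for insertions
between overlapping ORFs), and region orientation is classified from the
flanking strands: `(+,-)` convergent, `(-,+)` divergent, equal strands
codirectional. No margin from gene boundaries is enforced by default;
real designs wanting promoter clearance can add one by pre-expanding
gene intervals.

## Experiment planning

For each candidate variant the planner reports the nearest marker, the
predicted frequency $f$, and the number of transductants to pick:
the smallest $n$ with $1-(1-f)^n \ge$ `confidence` (default 0.99), capped
at `max_picks` (default 22, a convenient robot-picked plate format). At
the packaged library's worst point ($f = 0.324$) the uncapped requirement
is 12 picks, and 11 at $f = 0.35$, so 22 picks carry a comfortable
margin. Variants sharing a nearest marker are cross-annotated with their
separation probability, since a revertant for one may still carry the
other; a variant whose two nearest markers are within 1 kb in distance
gets the runner-up recorded, which is useful when an independent
verification transduction is wanted.

Plate scoring works on log relative fluorescence (fluorescence / OD600):
the ratio is multiplicative, and control dispersions are closer to
symmetric on the log scale. A well is called reverted when it is closer
to the wild-type reference mean than to the mutant reference mean by at
least $g$ pooled standard deviations (default $g = 1$), mutant-like in
the mirror case, intermediate otherwise. Degenerate references (zero
dispersion) degrade to a nearest-mean rule with a warning. A transduction
group qualifies as causative with at least $m$ reverted wells (default
$m = 2$, guarding against single-well outliers; configurable down to 1).
Exactly one qualifying group yields a `full` call; none, but exactly one
group with $\ge m$ intermediate wells, yields `partial` — the signature
of a replacement that only partly restores the wild-type phenotype, as
when a second, uncalled mutation also contributes; multiple qualifying
groups yield `ambiguous`. No numeric reversion threshold is inherited
from any particular instrument; the margin rule is this package's
declared convention and is validated on synthetic plates only.

## The stochastic replaced-fragment model

The simulator needs per-pick replacement events, not just marginal
frequencies. Rather than modelling fragment packaging and double
crossovers mechanistically, the replacement around the marker extends
independently to each side by a random length $X$ with survival function
$P(X \ge d) = (1 - d/L)^3$ on $[0, L]$, sampled by inversion as
$X = L(1 - U^{1/3})$. This construction reproduces the marginal
co-replacement probability $f(d)$ exactly, and makes same-side
replacement nested by construction, so the pair-separation probability
$f(d_1) - f(d_2)$ also holds exactly; both identities are verified
empirically in the test suite at $10^5$ draws. Loci on opposite sides of
the marker are replaced independently — a model extrapolation, since
same-interval statistics say nothing about straddling pairs; plans flag
such configurations rather than quantifying them.

## Dose model and the end-to-end simulation

Mutation counts per genome are Poisson($\lambda$); the probabilities of
0, 1, and more than one mutation are $e^{-\lambda}$,
$\lambda e^{-\lambda}$, and the remainder, and the dose needed so that a
fraction $q$ of clones carries at least one mutation is
$\lambda = -\ln(1-q)$. The default $\lambda = 6$ reflects a realistic
screening dose at which almost every clone is mutated ($P_0 = 0.0025$)
but genomes still carry few enough mutations to deconvolute. Mutation
positions are i.i.d. uniform on the circle and each mutation is
independently causative with probability `causative_fraction` — the
simplest model adequate for validating the planner; gene-network
structure and mutational spectra (e.g. the transition bias of alkylating
mutagens) are deliberately not modelled.

`run_deconvolution_sim()` runs the whole loop per repetition: draw a
screened mutant (rejection sampling on carrying a causative mutation),
thin its mutations by `detection_sensitivity` (sequencing pipelines miss
real variants; a rep whose causative mutations are all missed is tallied
`causative_undetected_by_WGS`), build the plan, simulate `n_picks`
transductants per planned marker against the *full* mutation set
(undetected mutations still exist in the cell), synthesize plate readings
as log-normal around the wild-type level for reverted picks and the
mutant level otherwise, classify, and call. Success means a `full` call
naming a truly causative variant; everything else lands in exactly one
failure-mode tally, so tallies always sum to the repetition count. The
success rate is reported with a Wilson 95% interval.

Two regimes deserve distinction. Under the full model, a genome can carry
two causative mutations (which no single transduction can jointly
revert), and a non-causative variant's marker can itself be linked to the
causative mutation, producing revertants in a second group and hence an
`ambiguous` call. These are genuine properties of the method at high dose
and are exactly what the failure-mode tallies expose. The closed-form
prediction $1-(1-f)^n$ per repetition applies only when the phenotype
traces to a single mutation with no co-linked confounders; the config
switch `single_causative = TRUE` conditions each repetition on a
single-mutation causative genome for exactly that validation setting, in
which simulated screens over a fully covering library (uniform 50 kb
spacing, $f \ge 0.42$ everywhere, 22 picks, perfect detection, noiseless
plates) succeed in essentially every repetition, matching the analytic
bound of about $10^{-4}$ failures per rep.

## Synthetic data

`generate_fixtures()` writes a self-consistent fixture set: a circular
annotation with log-normal gene lengths (mean 1 kb, log-SD 0.4, matching
typical bacterial gene-length dispersion) and exponential intergenic gaps
sized for a target intergenic fraction (default 0.2, roughly bacterial);
strands are fair coins, so region orientations converge to 25% convergent
/ 50% codirectional / 25% divergent; a marker library designed by
`place_markers()`; an ENU-style variant set (Poisson count at
$\lambda = 6$, uniform positions, SNVs only); and one simulated re-screen
plate with control wells. The default toy genome is 500 kb — large enough
for ten 50 kb-spaced markers, small enough that everything regenerates in
well under a second. What the generator does *not* emulate: real operon
structure, mutational hotspots and spectra, copy-number artifacts in
plate readings, or linkage between neighbouring genes' strands — so
passing tests demonstrate internal consistency of the models, not
fidelity to any particular real screen.

Determinism is a contract: every stochastic entry point takes or requires
a seed, all draws come from the single seeded R stream in documented call
order, and all writers emit LF-terminated, fixed-format text, so the same
seed yields byte-identical files. Monte-Carlo test assertions use
3-standard-error bands at their stated sample sizes ($10^4$–$10^5$ draws,
chosen so the suite runs in about a minute); the end-to-end validation
uses 10,000 repetitions.

## Known limitations

* The linkage curve is used as-is; no empirical recalibration from
  observed transduction counts, and no modelling of packaging-site (pac)
  bias or restriction effects.
* Pairs straddling a marker are handled under a declared independence
  assumption, not a fitted one.
* Only single-contig circular (or linear) replicons; multi-contig input
  is rejected loudly.
* Variant handling is positional only — no sequence context, no FASTA.
* The plate classifier assumes two reasonably separated reference
  distributions; phenotypes with overlapping wild-type and mutant
  fluorescence distributions need a screen-specific rule.
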