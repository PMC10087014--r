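---
title: "Modelling, estimating and drawing tumor clonal evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling, estimating and drawing tumor clonal evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneviz)
```

## The data model

cloneviz works on clone-level summaries of tumor evolution. A
`clonal_evolution` object holds

* an `n × m` matrix of cancer cell fractions (CCFs) in percent — one row
  per clone, one column per time point;
* a parental relation for every clone: another clone, or `NORMAL` for
  clones arising directly from normal cells (founders / stemlines);
* strictly increasing numeric time coordinates (arbitrary non-negative
  units, typically days) with display labels, and a per-time-point tag
  `measured` / `interpolated` / `therapy`.

A clone's CCF includes all of its descendants. The derived *unique CCF*
`ccf'(c, t) = ccf(c, t) − Σ_{j ∈ children(c)} ccf(j, t)` counts only cells
belonging to exactly clone `c`; `ccf_from_unique()` inverts the
relationship by leaf-to-root accumulation. The *nested level* of a clone
is its depth in the phylogeny (founders are level 0). Throughout the
package, clones of the same nested level are assumed to have developed at
approximately the same time, and a higher nested level indicates
development at a later time.

Two representation decisions deserve a note:

* **Percent, not fractions.** The 100%-rule for founders only makes sense
  on the percent scale. Tables whose values are all ≤ 1 are rejected with
  a hint rather than silently rescaled — a table of uniformly tiny CCFs is
  more likely a unit mistake than a real tumor.
* **Missing cells are errors.** In the validity rules, "absent" (CCF 0)
  is semantically loaded — an extinct clone must not reappear. Allowing
  `NA` to mean 0 would let unit mistakes slip through silently.

## The validity check

`check_validity()` evaluates four rules and returns a structured report
(rule id, clone, time point, message) rather than a bare boolean:

* **V1** children-clones cannot exceed their parents;
* **V2** clones developing from normal cells cannot add up to more than
  100% at any time point;
* **V3** a clone cannot reappear;
* **V4** a parent-clone thoroughly replaced by its children cannot
  reappear (the same rule on `ccf'`).

All comparisons use an absolute tolerance (default `1e-9` percent,
configurable): large enough to absorb floating-point error from the
reconstruction pipelines that produce CCF tables, far too small to mask a
real violation. "Zero" in V3/V4 means `≤ tolerance`.

V3/V4 are implemented as the general rule — once a trajectory has been
positive and then dropped to zero, it must stay zero. A literal
consecutive-triple scan (`v[i] > 0 & v[i+1] == 0 & v[i+2] > 0`) would
tolerate patterns such as `5, 0, 0, 5`, which plainly *are*
reappearances; since we cannot know whether that leniency was ever
intended, the triple scan is available behind
`check_validity(..., reappearance = "triple")` for compatibility, and the
general rule is the default. Structural problems (unresolvable parents,
cycles) are reported as rule `"S"` and preempt V1–V4.

## Exploring alternative trees

With `n` clones there are `n^n` conceivable parent vectors (each clone:
normal cells or one of the `n − 1` other clones). `enumerate_trees()`
prunes this space with two sound pre-filters before running the full
validity check:

1. clone `c` cannot parent clone `j` if `ccf(c, t) < ccf(j, t)` at any
   time point — for a single child this is exactly rule V1;
2. if clone `j`'s parent can *only* be `c`, another clone `k` can only
   branch from `c` if `ccf(c, t) − ccf(j, t) ≥ ccf(k, t)` at every `t`.

Because the CCF filters never remove `NORMAL` from a candidate set, a
singleton non-normal candidate set — the trigger of filter 2 — can only
arise from explicit user constraints (the `known` argument). Filter 2 is
iterated to a fixpoint: a single pass is ambiguous when one removal
enables another, and fixpoint iteration only removes provably impossible
parents. Comparisons mirror the strict `<` with the tolerance.

Surviving vectors are checked for forest-ness (cycle exclusion must come
first — children sets are undefined on a cyclic relation) and then passed
through the validity check. If the filtered Cartesian product exceeds
`max_permutations` (default 20,000) the enumeration *aborts* with an
error carrying the product size and the cap: silently truncating would
misrepresent the promise that all valid parental relations are reported.
The cap is applied to the filtered product before cycle exclusion — the
conservative reading, since counting post-cycle-check would require
enumerating anyway.

## Time point interpolation

`interpolate_all()` composes two operations, both fully automatic — the
number of inserted points is a function of the phylogeny, not a user
knob. Inserted points are evenly spaced by default; explicit fractional
positions support skewed events.

**Before the first measurement** (`interpolate_initial()`): the clones
present at `t_1` are introduced backwards by nested level. The number of
inserted points equals the maximum nested level among initial clones.
Walking backwards from `t_1`, the clones of the currently highest
remaining level are zeroed while the others keep their unique CCF from
`t_1` and have their CCFs rebuilt. Holding `ccf'` constant is a
compromise: a clone may well have been larger before being pushed away by
its children, or smaller while still expanding; with no evidence either
way, the `t_1` value is used, which may under- or overestimate the true
course. Since the axis carries no data before `t_1`, inserted coordinates
step leftwards by the smallest gap between measured time points (1.0 when
only one measurement exists) — keeping the prefix visually commensurate
with the data; they may be negative.

**Between two measurements** (`interpolate_between()`): clones present at
`t_i` develop linearly — in the absence of therapy the overall tumor load
is assumed never to decrease, and linear CCF development is the simplest
trajectory consistent with both endpoints. Newly appearing clones start
staggered: with `u` unique nested levels among them, `u − 1` points are
inserted, and a new clone preceded by `z` lower new levels stays at zero
for the first `z` inserted points, then grows linearly to its value at
`t_{i+1}`. If this combination transiently drives a unique CCF below zero
at an inserted point (it cannot at measured points), the unique CCF is
floored at 0 and parents rebuilt, with a warning — rendering requires
nesting, and only inserted values are ever adjusted. Measured columns are
never modified by any operation in the package.

## Therapy effect estimation

Between two measurements spanning a therapy, linear interpolation is the
wrong model: the tumor may have collapsed and regrown. `apply_therapy()`
inserts a single estimated end-of-therapy point where every clone present
at `t_i` takes `ccf'(c) = min(ccf'(c, t_i), ccf'(c, t_{i+1}))` — any
observed decrease in unique CCF is attributed to the therapy, any
increase to post-therapy expansion of a resistant clone. Clones absent at
`t_i` are assumed to have developed after therapy (CCF 0 at the estimated
point). The min-rule is a heuristic: it overestimates the effect in some
cases and underestimates it in others, and no calibration is attempted.

For the post-therapy re-expansion, nested levels are *recalculated*
ignoring clones that survived therapy: a clone whose ancestors are all
present at the therapy point is only "one step" away, whatever its
absolute depth. `max(recalculated levels)` points are inserted between
the therapy point and `t_{i+1}`; a new clone with recalculated level `z`
stays at zero for the first `z` points, then grows linearly if childless,
or holds `ccf' = ccf'(c, t_{i+1})` if it has children (its CCF then grows
with them). For clones already present at the therapy point the
algorithm's source leaves `ccf'` at the inserted points unspecified; this
implementation interpolates their `ccf'` linearly from the therapy point
to `t_{i+1}`, consistent with the surrounding machinery operating on
unique CCFs.

By default the therapy point and the `k` post-therapy points divide the
interval into `k + 2` equal parts (the midpoint when `k = 0`); the
position is user-definable as a fraction of the interval. Extra
interpolation defaults to on exactly when new clones appear in the
window. One known limitation, inherited from the algorithm itself: when a
parent is *exactly* fully replaced by a new child across the window
(`ccf'` 0 at one flank while its CCF stays positive at both), the
min-rule forces the parent's CCF to 0 at the therapy point, which the
validity check then rejects as a reappearance. Real CCF tables virtually
never contain exact replacements; the constructor surfaces the conflict
as an error rather than silently repairing it.

## Phylogeny-aware color coding

`assign_colors()` works in HSL space under four rules: darker with
nested level; similar hue within a branch; similar-but-diverging hues for
branches sharing an ancestor; maximally different hues for independent
branches. Concretely: founders are spread evenly over the hue wheel
(2 founders → 180° apart); each founder's subtree owns a hue sector;
sibling branches subdivide 40% of their parent's sector proportionally to
subtree leaf counts (proportionality keeps unbalanced trees separable);
lightness runs from 0.75 down to 0.35 in steps of
`0.4 / (max nested level + 1)`. The 40% spread is deliberate: it keeps
the hue variation inside any founder subtree strictly smaller than the
hue gap between different founders' subtrees, making the "maximum
difference" rule a provable invariant rather than a tendency.

At most 25 independent clones are supported (a hard capacity, matching
the palette's resolution limits); related clones are unlimited — sectors
subdivide recursively, with a warning once a sector drops below 1°. Where
recursive subdivision collapses below 8-bit RGB resolution, residual hex
duplicates are separated by stepping saturation down — saturation is the
one channel carrying no phylogenetic meaning. The exact hue anchors and
lightness endpoints are implementation constants (documented in
`palette_config()`), not a published palette, and identical inputs always
yield identical colors.

## Plot geometries

All three layouts are renderer-independent geometry; `render_plot()`
materializes them as deterministic SVG (byte-stable for identical input)
or PNG from the same coordinates.

**Shark plots** are the raw phylogeny: nodes at `x = nested level`,
edges for parental relations, independent founders as disconnected
components. An optional strip shows per-time-point bubbles with
`radius = sqrt(ccf)` — zero exactly for CCF 0, strictly increasing
otherwise.

**Dolphin plots** are stacked-band (fish) plots: band thickness equals
CCF at every measured time point, children's bands nest strictly inside
their parent's. In centered mode the parent's unique CCF is split into
equal gaps around and between its children (siblings ordered by first
appearance, then label — determinism demands a rule); in bottom mode the
clones lie on the x-axis and, within each clone, the branch of greatest
subtree depth hugs the lower edge (ties broken by first appearance, then
label). A clone first appearing at `t_f` is drawn from
`x(t_{f-1}) + birth_offset` (default 0.1 time-axis units — axis-unit
dependent and configurable; clamped to half of very narrow intervals)
with zero thickness, which smooths band births. Spline shape uses
*monotone* cubic interpolation through the same support points; ordinary
cubic splines can overshoot and make children's boundaries cross their
parents', so they were rejected. `separate_independent` inserts a fixed
gap (default 2 height-percent) between founder stacks.

**Plaice plots** address biallelic events: the upper half is a
bottom-mode dolphin plot of the clonal evolution; the lower half is its
exact mirror across the x-axis and shows the loss of healthy alleles of
a gene of interest. By default lower bands are unfilled (100% healthy
alleles). A clone carrying a second hit that completes a first hit in an
ancestor (e.g. a 17p deletion overlapping a point-mutated *TP53* allele)
is filled in the hue of the clone carrying the first hit, linking the
completed biallelic event to its origin; hits on the same allele warrant
no fill at all, since a healthy copy remains. Hemizygous variants (X/Y
in males) are annotated the same way, a clone naming itself as color
source.

## Synthetic data

`simulate_evolution()` generates valid-by-construction evolutions for
property tests and stress cases: a forest drawn per evolution model
(linear / branched dependent / branched independent / mixed, up to 25
founders), birth time points increasing down the tree, unique-CCF
trajectories as positive random walks (start 5–40%, steps N(0, 8),
floored at 0.5% while alive), absorbing extinction (probability 0.1 per
clone, only after all its children are born), and per-column rescaling of
founder sums to ≤ 99%. Validity follows from the construction: CCFs are
accumulated from non-negative unique CCFs (V1), rescaled (V2), and walks
are strictly positive until extinction and zero after (V3/V4).

What it does *not* emulate: biologically calibrated growth dynamics,
measurement noise, clone-calling uncertainty, or correlated sampling
times. A green property test therefore establishes that the algorithms
honor their structural contracts on the full variety of valid inputs —
not that estimates match any particular tumor's biology. The generator is
deterministic per seed and restores the caller's RNG state.

## Numerical choices and degenerate inputs

* All inequality checks share one absolute tolerance (default `1e-9`
  percent).
* A single time point is fully supported (the common single-biopsy case);
  between-interpolation and therapy estimation then have no interval to
  work on and are rejected with a usage error.
* All-zero clones are accepted (they carry information for tree
  enumeration), get colors, and contribute no geometry.
* Ties in sibling and founder ordering are broken by first appearance,
  then label — layouts and SVG output are pure functions of their inputs.
* The CCF table writer emits 6 significant digits, fixed column order and
  a `#kind` header row; write–read round trips preserve values to that
  precision and tags exactly.

## Known limitations

* The therapy min-rule and the constant-`ccf'` initial interpolation are
  uncalibrated heuristics (see above); both can under- or overestimate.
* Exact full replacement of a parent across a therapy window conflicts
  with the reappearance rule (detailed above).
* Spline rendering interpolates the support points exactly but is only
  shape-preserving per boundary; nesting between dense samples is not
  separately enforced (it is at every support point).
* Colorblind-safe palettes are not attempted.
* No variant-level input: clustering variants into clones, and CCF
  estimation itself, happen upstream — the CCF table is the contract.
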