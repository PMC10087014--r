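# cloneviz

Visualization and estimation toolkit for tumor clonal evolution in R.

Tumors evolve as hierarchies of clones — cell populations defined by shared
somatic variants, related by a phylogeny rooted in normal cells. Analyses
of clonal evolution usually arrive as a **CCF table**: for every clone, the
cancer cell fraction (CCF, in percent) at every sampled time point, plus
the parental relation of each clone. cloneviz is built for the people who
work with such tables — cancer genomics researchers, hematologists,
bioinformaticians — and covers the steps between "I have a CCF table" and
"I can see and reason about the tumor's history":

* a validated data model (`clonal_evolution()`) enforcing the logic of
  clonal evolution — children cannot exceed parents, clones arising from
  normal cells cannot sum above 100%, extinct clones cannot reappear
  (neither in CCF nor in unique CCF);
* a structured validity check (`check_validity()`) reporting every violated
  rule with the clone and time point involved;
* exhaustive enumeration of alternative phylogenies compatible with a CCF
  table (`enumerate_trees()`), with CCF-based pre-filters and a 20,000
  permutation cap;
* fully automatic time-point interpolation (`interpolate_all()`) and
  therapy-effect estimation (`apply_therapy()`);
* phylogeny-aware color coding (`assign_colors()`), up to 25 independent
  clones;
* three plot geometries with deterministic SVG/PNG rendering: **shark**
  (phylogeny graph), **dolphin** (fish-plot style stacked bands), and
  **plaice** (mirrored, allele-aware plot for biallelic events);
* a seeded simulator of valid clonal evolutions and a file-based CLI.

## The model in brief

For clone `c` at time point `t_i`, `ccf(c, t_i)` is its cancer cell
fraction (including all descendants). The *unique CCF* is

    ccf'(c, t_i) = ccf(c, t_i) - Σ_{j ∈ children(c)} ccf(j, t_i)

the fraction of cells in exactly clone `c`. Interpolation before the first
measurement fixes `ccf'` at its `t_1` value and introduces clones
backwards by nested level (depth in the phylogeny); interpolation between
measurements assumes linear CCF development for present clones and
staggered starts for new ones. Therapy-effect estimation inserts a time
point where each surviving clone takes
`ccf'(c) = min(ccf'(c, t_i), ccf'(c, t_{i+1}))` — in the presence of
therapy, any drop in unique CCF is attributed to the therapy.

## Worked example

Using the packaged example table (4 clones, branched dependent plus an
independent founder, 3 time points at days 0/50/100):

```r
library(cloneviz)
path <- system.file("extdata", "example_ccf.csv", package = "cloneviz")
evo <- read_evolution(path)
evo
#> <clonal_evolution> 4 clone(s) x 3 time point(s)
#>   time points: t0 (m), t50 (m), t100 (m)
#>   founders: A, D

unique_ccf(evo)
#>   t0 t50 t100
#> A 40  25   30
#> B 20  35   20
#> C  0  10   40
#> D 10   5    0
```

Clone A's unique CCF is its CCF minus that of its child B (60 − 20 = 40 at
day 0). How many other phylogenies could explain the same table?

```r
attr(enumerate_trees(evo$ccf), "counts")
#>    n_total n_filtered    n_valid
#>        256         18          3
```

Of the 4^4 = 256 possible parent vectors, the CCF pre-filters leave 18,
and 3 survive the full validity check — the measured tree among them.

A therapy was applied between day 0 and day 50. Estimating its effect and
interpolating the remaining gaps:

```r
evo2 <- interpolate_all(apply_therapy(evo, therapy_window(1)))
round(evo2$ccf, 1)
#>   t-25 t0 t25 t50 t100
#> A   40 60  45  70   90
#> B    0 20  20  45   60
#> C    0  0   0  10   40
#> D   10 10   5   5    0
evo2$timepoint_kind
#> [1] "interpolated" "measured"     "therapy"      "measured"     "measured"
```

At the estimated end of therapy (day 25) every surviving clone holds the
minimum of its flanking unique CCFs — A drops to 45 (= 25 + 20), D to 5 —
and the interpolated point at day −25 shows the tumor before B existed
(A at its unique CCF of 40). Colors and plots:

```r
assign_colors(evo)
#>   clone hue saturation lightness     hex
#> 1     A   0       0.65 0.7500000 #E99696
#> 2     B   0       0.65 0.6166667 #DD5E5E
#> 3     C   0       0.65 0.4833333 #CB2B2B
#> 4     D 180       0.65 0.7500000 #96E9E9
```

The two independent founders A and D sit 180° apart on the hue wheel;
A's descendants share its hue, darkening with nested level. Rendering:

```r
render_plot(dolphin_layout(evo2), path = "dolphin.svg")
pl <- plaice_layout(evo2, annotations = c(C = "B"))  # C completes B's first hit
render_plot(pl, path = "plaice.svg")
render_plot(shark_layout(evo), assign_colors(evo), path = "shark.svg")
```

In the plaice plot the lower, mirrored half shows the loss of healthy
alleles: clone C's lower band is filled in clone B's hue, marking the
biallelic event completed in C.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/cloneviz check --input ccf.csv
Rscript inst/cli/cloneviz therapy --input ccf.csv --interval 1 --out therapy.csv
Rscript inst/cli/cloneviz plot plaice --input therapy.csv --annotations ann.csv --out plaice.svg
```

## Further reading

The methods vignette (`vignettes/clonal-evolution.Rmd`) documents the
algorithms, their assumptions, the tunable parameters, what the synthetic
data generator does and does not emulate, and known limitations.
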