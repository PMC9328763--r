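---
title: "Measuring DNA replication dynamics from single-molecule fiber data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring DNA replication dynamics from single-molecule fiber data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replidyn)
```

## The measurement problem

In cell-free egg-extract replication systems, sperm-derived nuclei enter a
synchronous S phase and incorporate a nucleotide label into nascent DNA.
Stretching individual DNA molecules on glass (DNA combing) turns the
replication state of each molecule into a geometric object: a fiber of known
length carrying labeled tracts where DNA has been replicated. From these
tracts one can estimate how far replication has progressed (replicated
fraction), how many replication forks are active per unit DNA (fork
density), how far apart origins fired (eye-to-eye distances, ETED), and how
long individual replication eyes have grown (eye lengths, EL). Immunodepleting
a candidate regulator and comparing depleted versus mock extracts turns these
geometric summaries into a functional readout: a factor that limits origin
firing shows up as an increased fork density and replicated fraction in the
depleted condition, concentrated in the part of S phase where that factor
normally acts.

`replidyn` implements this entire quantitative chain: a stochastic
single-fiber simulator that plays the role of the wet experiment, the combing
measurement calculus, incorporation-kinetics binning, nucleus fluorescence
quantification, and the depleted/mock ratio statistics.

## The combing calculus

Measurements on a fiber of length $L$ with labeled tracts are scored with
four rules, applied in this order:

1. **Gap merging.** An unlabeled stretch shorter than `min_gap_kb`
   (default 1 kb) is not a credible gap at combing resolution; the flanking
   tracts are fused. Merging is applied first because a discontinuous label
   only defines the tract once false gaps are removed.
2. **Size filtering.** A surviving tract shorter than `min_eye_kb`
   (default 1 kb) is discarded as detection noise. We apply this to
   extremity-touching tracts too; leaving sub-kb specks at fiber ends while
   filtering them elsewhere would bias fork counts at the ends.
3. **Terminal classification.** A tract touching exactly one fiber
   extremity (within `terminal_tolerance_kb`, default 0) is a terminal
   track: one of its forks has run off the visible molecule, so it counts
   one fork and is not an eye. A tract spanning the whole fiber counts zero
   on-fiber forks but still counts as replicated DNA.
4. **Eye scoring.** Every remaining interior tract is a replication eye with
   two diverging forks. Eye midpoints are the origin estimates; ETEDs are
   distances between midpoints of adjacent eyes; ELs are eye lengths.

Pooled statistics are length-weighted, not per-fiber averages: the replicated
fraction is $\sum \text{replicated kb} / \sum \text{fiber kb}$ and fork
density is $100 \cdot \sum \text{forks} / \sum \text{fiber kb}$ per 100 kb.
Length-weighting matches the definition of replication extent as a property
of the pooled DNA; per-fiber values are nevertheless kept (in
`combing_stats$per_fiber`) for scatter plots and dispersion checks. The
percentage of unreplicated fibers uses the post-filtering replicated length,
so a fiber carrying only sub-threshold specks counts as unreplicated —
consistent with how such a fiber would be scored by eye.

```{r}
fa <- fiber("A", 100, list(c(10, 12), c(12.5, 13.2), c(40, 45), c(99.5, 100)))
fiber_summary(call_eyes(fa))
```

One caveat worth knowing: fork counts are *not* monotone in `min_gap_kb`
when `min_eye_kb` is positive. Un-merging a small gap can split a surviving
tract into two fragments that each fall below `min_eye_kb` and are then both
discarded. Monotonicity holds in `min_eye_kb` at fixed gap threshold, and in
`min_gap_kb` when the size filter is off; the test suite checks exactly
those two properties.

## The simulator

The generator is a 1-D nucleation-and-growth process with three biological
ingredients:

* **Licensing.** Potential origins are a homogeneous Poisson process with
  mean spacing `lic_spacing_kb` (default 3 kb). Licensed origins are in
  excess; passive replication thins them out so that *activated* origins end
  up 5–15 kb apart, as observed in this system.
* **Timing domains.** The fiber alternates between early- and late-firing
  domains with exponentially distributed lengths (mean
  `cluster_mean_length_kb`, default 150 kb). Domain means are scaled so the
  long-run fraction of DNA in late domains equals `late_cluster_fraction`
  (default 0.5) while the average domain length stays at the stated mean.
  Early-domain origins fire with exponential waiting times at rate
  `firing_rate_per_origin_per_min` ($I_0$, default 0.01/min); late-domain
  origins fire at $I_0 \cdot s$, where the suppression multiplier $s$ is
  `suppression_mock` (default 0.1) or `suppression_depleted` (default 1).
  Depletion of a late-firing brake is thus modeled purely as derepression
  of late domains.
* **Fork progression.** Forks move bidirectionally at
  `fork_speed_kb_per_min` ($v$, default 0.5 kb/min). An origin overtaken
  before its firing time is passively replicated and fires nothing. With a
  single fork speed this bookkeeping never changes the replicated set (a
  passive origin's would-be eye is always inside the eye that covered it) —
  a property the test suite exploits as a consistency check — but it keeps
  the event record biologically meaningful.

The extract has no fixed genome: each sampling time is a fresh aliquot, so
fibers at different times are independent molecules, not the same molecule
observed twice. Defaults for $v$ and $I_0$ are not measured quantities for
this system; they were chosen once so that early S phase spans tens of
minutes, matching the sampling windows of the assays emulated, and the
default sampling grid (10, 20, 30, 40 min) covers very early to late S
phase under those rates.

Reproducibility: each fiber draws from a substream seeded deterministically
from `(seed, condition, time index, fiber index)`, so a dataset is
byte-identical for a given `sim_params()` regardless of call order, and the
session RNG state is left untouched.

### Closed-form validation

With no late domains and licensing spacing far below the typical eye
length, the simulator approaches the classical 1-D
nucleation-growth (KJMA) regime with nucleation rate
$I = I_0 / \text{spacing}$ per kb per min, for which

$$f(t) = 1 - e^{-I v t^2}, \qquad \rho(t) = 2 I t\, e^{-I v t^2}$$

give the replicated fraction and fork density. `kjma_fraction()` and
`kjma_fork_density()` evaluate these, and the acceptance test compares the
simulator against them at $t = 10, 20, 30$ min with $I = 0.001$/kb/min,
$v = 0.5$ kb/min over 500 fibers of 1,000 kb per time point. Two small,
deliberate departures from the ideal limit exist: the licensed-origin pool
depletes (the effective nucleation rate decays like $e^{-I_0 t}$, a ~1%
relative deficit by $t = 30$), and finite fibers lose fork ends at their
extremities. Both are properties of real molecules rather than bugs; at the
tested problem size they stay within three Monte-Carlo standard errors of
the closed form.

## Incorporation kinetics

Different extracts replicate with different absolute kinetics, so raw
incorporation values are comparable only within a series. Each series is
scaled to its own maximum (`normalize_to_max()`, max = 100%), and the
normalized mock percentage — the reference kinetics — assigns each shared
time point to one of four S-phase bins: `[0, 25]` early, `(25, 50]` mid,
`(50, 75]` late, `(75, 100]` very late (boundary values go to the lower
bin). Ratios are raw depleted over raw mock at shared time points (the two
conditions share the label mix, so raw values divide out), and each bin is
tested against the null ratio 1 with a two-tailed Wilcoxon signed-rank
test. Time points where the mock value is zero are skipped with a warning
rather than propagating infinities.

## Nucleus fluorescence

Per-nucleus incorporation is quantified as corrected total fluorescence,

$$\mathrm{CTF} = \text{integrated density} - \text{area} \times
\text{mean slide background},$$

with one background value per slide. Negative CTFs (dim nuclei on bright
slides) are retained in condition means — truncating them would bias the
depleted/mock ratio upward — but flagged in the output. "Positive" nuclei
are those with CTF above a configurable threshold, 0 by default, since the
assay itself defines positivity only as signal above background. Fold
changes are ratios of condition *means* per experiment, tested across
experiments with a one-sample t against 1.

`simulate_nucleus_table()` generates log-normal per-nucleus signal with a
multiplicative condition effect, log-normal areas, and additive slide
background, which is the structure the CTF formula inverts exactly; it is a
parameter-recovery fixture, not an image model.

## Statistics

All tests are two-tailed and reported against $\alpha = 0.05$, with no
multiple-testing correction (none is standard for these per-figure
comparisons). The Mann–Whitney test uses the exact null distribution when
the smaller group has at most 8 observations and there are no ties; the
Wilcoxon signed-rank test vs 1 is exact up to n = 25 tie-free values
(values equal to 1 are dropped). Beyond those branch points both fall back
to the normal approximation with continuity (and tie) correction. The
branch points are feasibility choices; the exact branches are verified
against full enumeration oracles in the test suite, and the signed-rank
test's attained size under null simulations is checked against binomial
bounds.

The co-IP enrichment filter keeps proteins at least 3-fold enriched in
target versus control immunoprecipitation; a protein absent from the
control is infinitely enriched and is kept when its target abundance
reaches `min_target_abundance` (a guard against one-peptide artifacts; the
choice of that floor is the user's). The replication-foci pattern ratio
`(mid + late) / early` is undefined for a retina with no early-pattern
nuclei; such records are excluded with a warning rather than mapped to
infinity.

## What the simulator does and does not establish

The generator reproduces the *statistical structure* the measurement chain
assumes: Poisson licensing, clustered firing times, continuous labeling
from S-phase start, independent fibers per time point. It deliberately
omits replication checkpoints, fork stalling and re-replication, origin
interference beyond passive replication, fiber breakage and stretching
error, and any sequence or 3-D nuclear structure. Passing the
parameter-recovery and KJMA tests therefore shows the measurement calculus
and statistics are correct on data satisfying the model's assumptions — it
does not validate the biological realism of any particular parameter set,
nor the image-analysis steps upstream of the tract tables.

## Numerical conventions

* Coordinates are kb, 0-based, half-open; tract tables are written with
  3-decimal fixed point, and abutting tracts are merged at construction
  (overlaps are an error naming the fiber).
* Interval comparisons use a 1e-9 kb tolerance so that written-then-read
  coordinates and exact-threshold cases (a gap of exactly 1 kb, an eye of
  exactly 1 kb) land on the intended side of each rule: threshold-equal
  gaps are real gaps, threshold-equal tracts are kept.
* Problem sizes in the shipped tests — 1,000 oracle fibers, 500 fibers ×
  1,000 kb per KJMA time point, 20 replicate depletion experiments, 10,000
  null Wilcoxon replicates — were chosen to give stable Monte-Carlo
  comparisons at three standard errors.
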