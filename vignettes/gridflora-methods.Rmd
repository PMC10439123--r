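---
title: "Methods: building gridded species-richness data sets with gridflora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building gridded species-richness data sets with gridflora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridflora)
```

## The data-production model

`gridflora` turns two occurrence sources — an atlas table of
(square, taxon) records and a long-format table of georeferenced
vegetation plots — into a per-square richness data set on a 10 × 10 km
cartogram grid. The pipeline is deterministic given its inputs and every
stage is a pure function, so any intermediate can be inspected or rerun.

The stages, and the assumptions each one makes:

1. **Grid** (`grid_spec`, `build_grid`, `assign_point`). Cells are
   half-open rectangles, closed on their lower-left edges, which
   guarantees that a point on a shared edge is assigned to exactly one
   cell — per-square counts of any point set are conserved. Plot
   coordinates arrive as WGS 84 longitude/latitude and are projected with
   a local equirectangular projection (`local_crs`): metres east/north of
   a reference point, scale fixed at the reference latitude. Over a
   country-sized extent this keeps area distortions small; the package
   deliberately does not re-derive the georeferencing of any real
   national grid, whose square codes it treats as opaque keys.
2. **Harmonization** (`harmonize`). Name matching is exact on a
   normalized key (whitespace collapsed, hybrid sign unified); there is
   no fuzzy matching, because a near-match heuristic can invent
   occurrences. Unmatched names are counted in the report and dropped
   from the presence table — the package cannot adjudicate nomenclature.
   Cultivars, ephemerophytes and extinct taxa are removed with logged
   reasons. OTU collapse applies a fixed precedence: genus on the
   collapse list > membership in a defined aggregate / *sensu lato*
   group > infraspecific fold into the parent species > singleton. The
   precedence matters where a microspecies genus also has defined
   aggregates: the genus is collapsed wholesale, so the genus rule must
   win. Hybrids resolve into an existing group only when both parents
   are members of that same group; otherwise they are excluded with
   reason `hybrid_unresolved`. Source merge is a union with provenance —
   one confirmed locality in either source fills the square.
3. **Classification** (`classify_otus`). See the rules below.
4. **Flags**. `CBS = 1` iff strictly more than `cbs.threshold` (default
   0.80) of the square's area lies inside the territory polygon; the
   strict inequality follows the "more than 80%" wording such data sets
   use. Area fractions are computed exactly by clipping the territory
   polygon against each rectangular cell (Sutherland–Hodgman against a
   convex window) and applying the shoelace formula; no external
   geometry engine is needed for axis-aligned cells. `SB` comes from the
   benchmark-species detector.
5. **Statistics** (`compute_square_stats`, `summarize_subset`). Every
   square of the grid is reported, including empty ones (`JSR = 0`, all
   percentages missing). Percentages are kept at full precision
   internally and rounded to one decimal only at serialization, so a
   reader can always reconstruct them from the count columns to within
   0.05. Subset means are additionally reported rounded half-up to an
   integer, the convention overview tables use for whole numbers.

## Classification rules for mixed OTUs

Members of an aggregate or *sensu lato* group can disagree in status or
conservation value. The rules, applied per OTU with tolerance
`tol = 0.05`:

* unanimous members decide directly;
* the **dominant category** is the one whose members jointly occupy the
  most squares (union, not sum, so duplicated coverage is not
  double-counted);
* a minority is **ignored** when it comprises no more than `tol` of the
  members *or* occupies strictly less than `tol` of all squares where
  the OTU was found (the two criteria are alternatives; the count
  comparison is inclusive "no more than", the square comparison strict
  "less than", following the wording of the rule set);
* a native-side/neophyte split whose minority exceeds the tolerance on
  *both* criteria makes the OTU unclassifiable:
  `verdict = EXCLUDED_CONFLICT`, and the OTU is removed from richness
  computation;
* the same machinery applies independently to the Red-List and apophyte
  flags, with `FALSE` as the outcome for non-ignorable mixtures — a unit
  is only flagged when the rules clearly say so.

Three situations the rule set leaves open were decided as follows.
Non-ignorable conflicts *within* the native side (native vs archeophyte)
resolve to the dominant category rather than exclusion: archeophytes
count as native in all downstream statistics, so such a split does not
hinder the native/alien categorization that exclusion exists to protect.
Exact 50/50 dominance ties (same square union and same member count)
are treated conservatively: exclusion for status, `FALSE` for boolean
flags. And frequency classes are assigned to every kept OTU from its
occupied-square count over the **full grid** — not the cleaned subset —
because the class definitions are phrased against the total number of
squares; whether conflict-excluded OTUs are removed before or after
frequency assignment does not affect kept OTUs under this definition.

With `tol = 0` the rules reduce to strict unanimity; the test suite
verifies this, and checks the whole procedure against an independently
written enumeration oracle over all small member configurations.

## The undersampling detector

The `k = 20` most frequent OTUs form the wish list (ties at the boundary
broken lexicographically, for determinism). A square missing `m = 3` or
more of them is flagged `SB = 0`. The premise is empirical: in a
well-surveyed national data set the top-20 species occur essentially
everywhere, so their absence measures effort, not ecology. The expert
screening such studies apply to wish-list candidates (excluding species
whose range genuinely avoids part of the territory) is represented by an
optional user-supplied exclusion list, not computed — that step is
judgment, not algorithm. Wish-list frequencies are computed over all
squares including cross-boundary ones, and `SB` is emitted for every
square; downstream filters combine `SB` with `CBS`.

## What the synthetic generator emulates

`sim_config()` defaults define the desk-scale study conditions used
throughout the tests: a 20 × 20 grid of 10-km cells, 300 base species,
two microspecies genera of 25 species collapsed at genus level, ten
aggregate/*sensu lato* definitions, six hybrids (half resolvable), a 10%
synonym rate, 5% subspecies, status mix 70/15/15
native/archeophyte/neophyte, Red-List rate 0.15, apophyte rate 0.30,
cultivar/ephemerophyte/extinct rates 3/3/2%, a plot source with
Poisson(3) plots per square and detection 0.5 per plot, and 20 injected
low-effort squares retaining 40% of their records.

* **Abundance and occupancy.** Species abundances follow a Fisher
  log-series (`sad_shape = 0.999`), the canonical macroecological
  abundance model. Occupancy saturates with abundance
  (`t = N(1 - e^{-n/(0.15 N)})`), so the most abundant species are
  near-ubiquitous — the wish-list premise — while the log-series tail
  stays rare. Each species gets a uniform range centre and a Gaussian
  range kernel whose radius is solved (by `uniroot` on log-radius, an
  increasing function of expected occupancy) to match its target; the
  kernel ceiling `p_max = 1` reflects that at the 10-km scale a species
  is treated as present wherever its range overlaps, with all
  observation noise modelled in the sampling layers.
* **Sources.** The atlas reports every recorded (square, species) pair —
  one locality fills a square. Plots are placed uniformly within their
  square, listed species drawn per plot with the detection probability,
  years uniform on 1925–2020.
* **Undersampling** is record-level loss shared by both sources: each
  true pair in an injected square survives into the observed pool with
  probability `undersampling_retention`, and atlas and plots both sample
  from that pool. A species never recorded in a poorly surveyed square
  is absent from every data stream derived from it; modelling the loss
  per source independently would let one source rescue the other, which
  is not how low survey effort behaves.
* **Territory.** An irregular polygon whose boundary wanders through the
  outer cell ring, giving edge squares inside-area fractions on both
  sides of the 80% threshold.
* **Reproducibility.** One master seed; each stage draws from its own
  deterministically derived sub-stream, so regenerating any stage in
  isolation reproduces it exactly.

What the generator does **not** emulate: real biogeography (gradients,
climate, dispersal autocorrelation beyond the range kernel), temporal
turnover or extinction, geocoding error in plot positions, and
non-random placement of survey effort. Passing end-to-end tests
therefore shows that the *pipeline* is correct and that the detector
recovers effort gaps of the modelled kind; it does not certify detector
performance against spatially structured or temporally drifting bias in
real data.

## Numerical choices and degenerate inputs

* Half-open cells with the lower-left edge closed; points outside the
  grid assign to `NA` and are excluded from square statistics.
* Strict `>` at the CBS threshold; inside fractions clamped to [0, 1]
  against floating-point residue from the polygon clipping.
* Percentage round-trip comparisons use a tolerance of 0.05 plus a
  10⁻⁹ epsilon, because a value stored at an exact half-rounding
  boundary (e.g. 6.25 → 6.2) differs from its recomputation by exactly
  0.05 up to float representation.
* Empty subsets produce an explicit empty-summary marker, never an
  error; empty member sets in classification are an error, since a
  verdict would be meaningless.
* The wish list warns and returns everything when fewer than `k` OTUs
  exist.
* Checklists with a raw name mapped to conflicting accepted names are
  rejected outright; so are OTU definitions assigning one name to two
  groups.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
8 × 8 grids with 80 species for unit-level checks, the 20 × 20 / 300
species default for end-to-end checks, ten seeds for the detector
recovery experiment, and an exhaustive enumeration (about 2,900 member
configurations at three tolerances) for the classification oracle. These
sizes were chosen as the smallest at which every rule is exercised with
comfortable statistical margins.

## Known limitations

* Geospatial I/O is GeoJSON only; ESRI Shapefile and xlsx are not
  written or read, and territory polygons with holes are not supported
  (multipolygon outer rings are).
* The equirectangular local projection is adequate for synthetic
  territories but is not a substitute for a national projection when
  real coordinates matter at sub-cell precision.
* Status, Red-List and apophyte information is input data; the package
  propagates it but cannot check it against the world.
* The deposit validator checks internal consistency and user-supplied
  expected values; it cannot verify a deposit against the raw sources
  from which that deposit was built.
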