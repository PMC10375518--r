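---
title: "Consensus change-point labelling for EHR data-quality time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus change-point labelling for EHR data-quality time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdcp)
```

## The problem

Routinely collected health-record data contain *change points*: moments
where the distribution of recorded values shifts abruptly because of a
computer-system migration, a new test method, a coding change — anything
but the patients themselves. An analyst who pools data across such a break
can reach the wrong conclusion. Screening for these artefacts is usually
manual: plot many summary series, look for jumps. `crowdcp` implements a
complete pipeline for doing this screening at scale with crowdsourced
visual inspection, and for quantifying how well the crowd's consensus
matches an expert:

1. **Aggregation** — turn a typed record extract into data-quality time
   series (completeness, conformance, plausibility summaries per day,
   week, and month).
2. **Rendering** — draw each series on a fixed-geometry image and own the
   affine pixel-to-date mapping.
3. **Cleaning** — reduce raw annotation lines to one first attempt per
   person per image and merge a person's near-coincident lines.
4. **Consensus** — cluster line positions with one-dimensional
   density-based clustering with noise; each cluster's mean position is a
   consensus change-point label.
5. **Evaluation** — score labels against expert lines with an
   interval-based confusion-matrix approximation, Wilson confidence
   intervals, and Matthews-correlation-coefficient (MCC) grid search for
   the clustering parameters.
6. **Synthetic data** — generate extracts with known injected change
   points and simulate volunteer behaviour, so the entire pipeline is
   testable without a live crowdsourcing campaign.

## Aggregation model

Each extract designates exactly one **timepoint** field; records with a
missing or unparseable timepoint are excluded (they cannot be binned), and
exact duplicate rows are removed with per-day removal counts retained.
Records are binned by day (midnight to midnight), week (Monday to
Sunday), and calendar month, over a gap-free index spanning the extract's
full date range.

Each field type gets a fixed set of per-bin summary functions — counts
and percentages of missing values, nonconformant values (non-numeric text
in a numeric field, non-date text in a date field), value summaries
(min/max/mean/median), string-length summaries for identifiers, distinct
and per-subcategory counts for categoricals, and midnight-value counts for
fields with a time element. Empty bins score 0 for the number-of-values
function `n` (an empty day genuinely has zero values) and `NA` for every
other function (no summary can be computed). Percentage denominators are
chosen for internal consistency: `missing_perc` uses all records in the
bin, so `missing_n + n` always equals the bin's record count, and
`nonconformant_perc` uses the values present, so conformant and
nonconformant values partition its denominator. Per-subcategory series are
only produced for fields with fewer than 20 distinct values; the limit is
configurable because real extracts occasionally warrant exceptions (one
published field with 23 categories was kept for consistency with its
neighbours). Datetime min/max series are expressed as days since
1970-01-01 so that every series is numeric. The percentage of duplicated
records is computed as removed duplicates over pre-deduplication rows per
bin — the simplest reading of "percentage of records that had been
duplicated"; the denominator is not pinned down by the published
description, so it is a documented package choice.

For freetext and all other fields, an empty string counts as missing: in
EHR exports an empty cell and an absent value are rarely distinguishable.

## Rendering geometry

All images share one canvas: 1,000 × 666 px at 96 dpi, with the plot area
spanning x-pixels 24–976 (952 px wide). The 952 px width is a derived
constant rather than a published one: the published evaluation counts
(492 TP, 90 FP, 120 FN, 38,194 TN over 286 images) imply exactly 136
seven-pixel intervals per image, and 136 × 7 = 952. Both the width and
the 136-interval budget are exposed in configuration.

Count-valued series are drawn with the y-axis starting at zero and ending
no earlier than 10; percentages always on a 0–100 axis; subcategory counts
share the y-scale of their field's whole-count series (`y_max_override`).
`NA` values are rendered as absent points, so presence gaps are visible.
The date-to-pixel map is affine and strictly increasing; its inverse
snaps to the nearest timepoint-interval start at the series' granularity,
so a label always indexes a real timepoint (the snapping is configurable
via `round = FALSE`).

## Cleaning rules

Serving platforms can show the same image to a person twice and can
collect more classifications than the retirement threshold. Cleaning
therefore keeps, per image and person, only the lines of the earliest
classification (ties broken by classification id, for determinism), and
then only the earliest 41 distinct people per image. The published rule
says only "up to a maximum of 41 different people"; earliest-by-time is
the package's deterministic reading.

Within one person's lines on one image, lines strictly closer than the
7 px minimum-distance cutoff are considered the same change point and are
merged at their unweighted mean; if any contributor was green (certain),
the merged line is green. Merging is transitive over connected components
of the closer-than-cutoff graph — the only order-independent
interpretation of "combined into a single line" when chains occur. Note
the deliberate asymmetry in comparisons: the merge cutoff is *exclusive*
(two lines exactly 7 px apart are distinct change points) while the
clustering epsilon below is *inclusive* (eps is the maximum distance
between two lines in a cluster).

## Consensus clustering

`dbscan_1d()` is a native one-dimensional implementation of density-based
spatial clustering with noise: a position is a core point when at least
`min_pts` positions (itself included — the standard counting convention)
lie within `eps_px`; clusters are connected components of core points
under the within-eps relation plus border points; everything else is
noise and ignored. A border point reachable from two clusters joins the
nearest core point's cluster, ties to the lower cluster id — the published
method does not state this case, so the package fixes a deterministic
rule. In one dimension the algorithm reduces to a sorted sweep
(`findInterval` neighbour counts, gap-based chaining), which the test
suite verifies against an independent quadratic brute-force reference on
a thousand random instances.

Each cluster's unweighted mean position becomes one consensus label with
its contributor count; labels convert to dates through the image's
recorded plot coordinates. The default parameters are the tuned values:
exclude yellow (uncertain) lines, `min_pts = 5`, `eps_px = 3`.

## Evaluation

Accuracy against expert lines is approximated as a binary classifier per
image, with a strict-`<` cutoff distance of 7 px:

* **TP** — expert lines with at least one label within the cutoff (many
  labels near one expert line count once, never as false positives);
* **FN** — expert lines with none;
* **FP** — labels with no expert line within the cutoff (one label near
  two expert lines yields two TPs and no FN);
* **TN** — estimated per image as 136 (the number of cutoff-width
  intervals across the plot, i.e. the maximum number of distinguishable
  change points) minus TP + FP + FN, summed over images.

Expert lines receive the same same-person merging as volunteers, for
consistency, and uncertain expert lines count as expert lines when
matching. Sensitivity, specificity, PPV and NPV come with Wilson score
95% intervals — the Wilson interval is the package's (inferred) choice
because it reproduces all eight published CI bounds exactly from the
published counts. MCC uses the standard formula; it is defined as 0 when
any marginal sum is zero, and metrics with a zero denominator are `NA`.

Tuning crosses include/exclude-yellow with `min_pts` 2–20 and integer
`eps_px` 1–7 px — 266 combinations, with counts pooled across images
before computing MCC (pooling matches how the final performance counts
are reported; a per-image average is the other reading). Ties in the
ranking break deterministically: smaller `min_pts`, smaller `eps_px`,
exclude-yellow first. The 70/30 tuning/test split is stratified by
extract with per-stratum rounding to nearest; with the validated
extracts' daily-series counts (401, 167, 184, 204 — their published
series totals divided by the three granularities) it yields exactly
670 tuning and 286 test images.

## Synthetic data: what it emulates and what it does not

The generator exists so every downstream stage has known ground truth.
Records are drawn per day from simple baselines (normal values for
numeric fields, uniform categories, random identifiers), and each
injected change point perturbs generation from its date onward: a level
shift of `magnitude` baseline SDs, a trend break of `magnitude` SDs per
30 days, a variability change multiplying the SD, a presence gap of
configurable length (whole records or a single field), or a single-day
outlier. Magnitudes are expressed in baseline SDs because the published
material describes artefact *kinds*, not a generative model; effect sizes
in SD units are the natural dimensionless choice.

Volunteers are i.i.d. — per-truth detection probability, Gaussian pixel
jitter, a fixed probability of drawing yellow, Poisson spurious lines
uniform over the plot, and a repeat-classification probability — because
the consensus method aggregates by counting and never models individual
skill. Default behaviour parameters (41 volunteers, detection 0.8, jitter
2 px, uncertainty 0.1, noise 0.3 lines/volunteer/image, repeat 0.05) are
plausible for an engaged citizen-science crowd; no published per-volunteer
statistics exist to calibrate them further, which is precisely why they
are fixed once and not tuned. What the generator does *not* emulate:
realistic clinical value distributions, secular trends and seasonality,
volunteer skill heterogeneity, or the serving platform's scheduling. A
passing pipeline on synthetic data therefore demonstrates correctness of
the mechanics and recoverability under calibrated noise — not performance
on real hospital extracts.

## Numerical and design choices

* Dates are ISO-8601 throughout; CSVs are UTF-8 with headers and `NA` as
  the empty string.
* First-attempt ordering ties break by classification id; clustering ids
  increase with pixel position; grid ranking ties break as above — every
  ordering in the package is deterministic.
* All seeds are explicit arguments; identical seeds reproduce extracts,
  annotation sets and pipeline CSV artefacts byte for byte.
* Degenerate inputs: an extract whose rows all lack valid timepoints is
  an error; an image whose line count is below `min_pts` yields zero
  labels; a negative per-image TN (interval budget too small for the
  image's line density) is a configuration error rather than a silent
  clamp.
* Problem sizes in the tests are chosen for fast, stable checks: record
  extracts of 15–200 rows/day over 40–120 days, 200–500 simulation
  replicates, 300–1,000 random instances per property. The level-shift
  recovery test uses 200 records/day so the two-sample standard error is
  small relative to the injected 10-SD shift.

## Known limitations

The evaluation's true-negative count is an interval-based estimate, not a
count of observed negatives, so specificity and NPV inherit its
granularity assumptions. The grid search treats images as exchangeable;
clustering of errors within images is not modelled in the CIs. And the
synthetic volunteer model is intentionally simple — parameter recovery
results on it bound what the pipeline can do under its assumptions, not
under real crowd behaviour.
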