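---
title: "Methods: repertoire annotation, funnel calibration and epitope binning"
author: "rabscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire annotation, funnel calibration and epitope binning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rabscreen)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the order a campaign uses them. It states no
empirical result beyond what the test suite and the acceptance script
compute themselves.

## 1. Repertoire annotation

**Closest germline.** Each VH (or VL) query is aligned globally against
every reference of its chain (`assign_germline()`), and the reference
with the fewest amino-acid replacements — alignment mismatch columns —
wins; ties break deterministically by reference order. Alignment scores
default to match +1, mismatch −1, gap open −5, gap extend −1 and are
configurable; rabbit V regions are close enough to their germlines that
the assignment is insensitive to the exact scores, and the suite checks
it against an exhaustive Hamming argmin oracle.

**Region delineation** (`delineate_regions()`) is anchored purely in
sequence: CDR3 consists of the residues strictly between the last Cys
preceding the chain's J motif (exclusive) and the motif's first residue
(W of W-G-x-G for heavy, F of F-G-x-G for kappa, exclusive); FR4 is the
motif onward. CDR1/CDR2 use fixed Kabat-style offsets (heavy 26–35 and
49–65, kappa 23–34 and 49–56, 0-based half-open), overridable per
germline reference. Which CDR numbering the original campaign workbook
used is not recoverable, so these offsets are a documented stand-in
chosen to be reproducible without external numbering servers. All
coordinates are 0-based half-open internally; only printed reports are
1-based. Sequences missing either anchor are *flagged*, never silently
dropped: they stay in the table with `annotation_ok = FALSE` and are
excluded from region statistics only.

**Replacement counting** (`count_replacements()`) counts substitutions
at aligned positions; indel columns contribute nothing, because the
campaign's mutation statistic is *replacement* mutations. FR totals
cover FR1–FR3 and CDR totals CDR1–CDR3; FR4 is J-segment-encoded and
excluded. The annotation table additionally exposes `*_repl_v`
(FR1–FR3 + CDR1/2): the CDR3 loop is junction-encoded rather than
germline-templated, so V-segment maturation analyses — including the
generator-recovery tests — use this column, while the full total keeps
the CDR1–CDR3 definition above.

## 2. Clonotype clustering

Two clones belong to one clonotype when their CDR-H3 *and* CDR-L3 are
identical or nearly so: equal loop lengths on both chains and at most
`threshold = 2` mismatches per chain. Unequal lengths make a pair
*incomparable* — "replacements" are substitutions, not indels. Clusters
are the single-linkage transitive closure of this relation (implemented
as connected components of the pair graph); a complete-linkage variant
(`linkage = "complete"`) is available for users who want every pair in a
cluster within threshold. Single linkage is the default because cluster
*membership* — not a linkage criterion — is what defines a clonotype
lineage descended through somatic mutation from one founder.

`categorize()` reproduces campaign-style accounting per (animal, bleed):
clone counts, unique/clustered split, and counts of clones sharing an
identical CDR-H3, CDR-L3, CDR-H3+L3, VH, VL or VH+VL with another clone
of the same group. Percent unique is rounded half-up to an integer in
these tables (1-decimal half-up in funnel reports); the original
reports' rounding convention is not perfectly consistent, so the package
documents and applies its own rule rather than reverse-engineering.
Clusters spanning several bleeds of one animal, or several animals, are
reported as attributes.

## 3. Diversity statistics

CDR-H3 length and replacement histograms conserve counts by
construction. Standard deviations default to the *population* form
(n denominator) with the sample form alongside, since the source
convention is unstated; strata with fewer than two clones print their sd
as `nd`. Hydropathy uses the Kyte–Doolittle scale (the canonical choice
where none is named); the scale is a configurable table.

## 4. Screening-funnel calibration

Positivity thresholds per OD channel follow a three-step procedure
(`calibrate_threshold()`):

1. **Outlier trimming** (`remove_outliers()`): points above
   `median + k · mad` (`k = 6`, `mad()` with the 1.4826 consistency
   constant) are removed and the rule re-evaluated once. Only the upper
   tail is trimmed — positives can only inflate ODs. A zero-MAD guard
   leaves degenerate inputs untouched. The rule is deliberately crude:
   its only job is to delete wells that *obviously stick out* before the
   background is modelled, and both `k` and the rule's audit trail are
   exposed.
2. **Johnson SU fit** (`fit_johnson_su()`): the four-parameter
   transformed-normal family $X = \xi + \lambda\sinh((Z-\gamma)/\delta)$
   is fitted by maximum likelihood (Nelder–Mead over
   $(\gamma, \log\delta, \xi, \log\lambda)$ from quantile-matching
   starts, then a BFGS polish). The SU family accommodates the skewed,
   heavy-tailed OD backgrounds of plate assays, and contains the normal
   as a limit.
3. **Threshold**: the fitted 99 % quantile,
   $\xi + \lambda\sinh((z_{0.99}-\gamma)/\delta)$.

One numerical choice matters here. The MAD trim imposes a hard upper
cut-off on the retained sample, and for heavy-tailed backgrounds that
cut-off can sit near the 99.5th percentile — a plain MLE on the trimmed
sample then systematically underestimates the tail and the threshold.
Because the cut-off is *known*, `calibrate_threshold()` fits the
retained sample with the right-truncated likelihood (each density term
divided by $P(X \le \text{cutoff})$), which restores the full-law
quantile; the suite verifies recovery of closed-form 99 % quantiles
within 2 % on clean backgrounds of $10^5$ wells, and within 5 % with 5 %
strong positives injected. The sorted-sample plot
(`plot(calibrate_threshold(...))`) lets the user confirm the threshold
sits at the kink where positives leave the background.

**Gating** (`apply_funnel()`) applies the ordered gates — IgG > 0.013
µg/ml, Fc-counterscreen ≤ OD 0.125 (binders excluded), human antigen
> OD 0.195, cynomolgus > 0.184, murine > 0.164, biochemical inhibition
≥ 40 %, and a 0.02 µg/ml IgG floor for PCR eligibility — with counts and
percentages of the conventional denominators (IgG⁺ wells for binding and
counterscreen, human binders for inhibition). Every percentage's
numerator and denominator are emitted for audit, and the function also
accepts pre-tabulated gate counts so printed reports can be re-derived
exactly. Percent inhibition is $100\,(P - s)/(P - N)$ from the plate's
positive/negative controls and is left unclipped; the ≥ 40 % gate is
applied afterwards. `threshold_correlation()` reports the squared
Pearson correlation of paired inhibition readouts above a cut-off; it is
sign-blind by construction.

## 5. Epitope binning

Entry $(i, j)$ of a cross-competition matrix is the detection signal
with antibody $i$ captured first and antibody $j$ pre-complexed with the
antigen: low signal means competition. How raw ODs were normalised in
the original workflow is unstated, so the package makes its choice
explicit: each row is scaled to $[0, 1]$ by its no-competition reference
(row maximum by default, an explicit control column if available).

Rows (first-captured antibodies) are then clustered under **Ward's
minimum-variance criterion**, implemented directly via the
Lance–Williams recurrence on squared Euclidean distances, with merge
heights $h(A,B) = \sqrt{2 n_A n_B/(n_A+n_B)}\,\lVert c_A - c_B\rVert$
(two singletons merge at their Euclidean distance; heights are monotone
because Ward admits no inversions on Euclidean input). Ties break by the
smallest involved leaf index. The implementation is verified against a
brute-force agglomerator that recomputes the Ward objective from the raw
points at every step, and against `hclust(..., "ward.D2")`.

The group count is chosen where dendrogram inspection would cut:
`select_k()` takes the largest *relative* gap between successive merge
heights, $(h_{m+1}-h_m)/h_m$, giving $k = n - m$; if no gap exceeds
`min_gap = 0.1` the convention is a single cluster, and a manual `k` can
always be supplied — the automated rule is a reproducible stand-in for
by-eye selection. The grouping is confirmed by centred PCA of the
profiles (three components, explained-variance shares, a
between/within-centroid separation score) and by clustering the
*transposed* matrix at matched $k$ (adjusted Rand index between row and
column partitions). `detect_asymmetry()` flags ordered pairs whose
normalised signals differ by more than `margin = 0.3` — antibodies whose
competition depends on which partner was pre-complexed with the antigen.
Because the original campaign's raw competition ODs are not available,
the specific published grouping cannot be re-derived; the procedure is
instead validated on planted-structure simulations (below).

## 6. The synthetic-data generators

Every stage is testable offline because the generators emulate the
statistical structure the analyses assume — with ground-truth labels
carried alongside, since all recovery tests are label-based.

**Repertoires** (`generate_repertoire()`). Germline references are
random domains with the anchors planted at the canonical offsets; clones
are built from them by swapping in a clone-defining CDR3 pair and
applying $\mathrm{Poisson}(\text{shm\_rate})$ substitutions uniformly
over germline-templated positions. Defaults are the campaign scale: 227
clones, 3 animals × 4 bleeds, 13 expected replacements per chain, CDR-H3
lengths from a truncated discrete Gaussian on 4–19 with mean 11.4 and sd
2.7 (CDR-L3: mean 9, sd 1.5 on 5–14, reflecting the shorter, less
variable kappa loop), and a quarter of clones in multi-member lineages
whose members differ from their founder by ≤ 2 CDR3 replacements per
chain — lineages never span animals. Simplifications a user should know
about: non-anchor positions draw from an 18-letter alphabet without Cys
and Gly, so anchors stay unique and annotation is always well-posed;
mutations are placed uniformly (no per-position mutability profile, no
hotspots); there are no indels, no nucleotide-level processes and no
sequencing error. Passing tests therefore demonstrate correctness of the
analysis logic, not robustness to badly behaved real sequences.

**Panels** (`generate_panel()`). Negative-well ODs follow a Johnson SU
background whose default 99 % quantile sits near OD 0.19; binder wells
add a log-normal shift. Label rates default to the observed campaign
(12.8 % IgG⁺; of those 22.5 % binders and 14.2 % Fc binders; of binders
91 % / 25 % cyno/murine cross-reactive and 16.4 % inhibitory). IgG
concentrations of secreting wells are log-normal with mean ≈ 0.9 µg/ml.
Cellular inhibition tracks biochemical inhibition tightly only above
90 % (sd 1 percentage point) and loosely below (slope 0.45, sd 18),
emulating a biochemical primary screen that is highly predictive of the
cell assay only for strong inhibitors. ODs are clipped at 0 after noise
(physical non-negativity).

**Competition matrices** (`generate_competition()`). 16 antibodies in 6
planted groups (sizes as equal as possible); same-group ordered pairs
draw around a low-OD competition mean (0.15), different-group pairs
around a high mean (1.0), with Gaussian noise (sd 0.15 — under a quarter
of the signal separation) and optional one-directional overrides for
planted asymmetric binders.

## 7. Problem sizes, determinism and limitations

All generators take explicit integer seeds and are bit-reproducible;
`run_campaign()` derives stage seeds from one master seed and is
idempotent. The validation suite uses $10^5$ draws for quantile-recovery
checks, 20 seeds for planted-partition recovery, repertoires of 50–227
clones (5000 for the distribution-law test), and brute-force oracles up
to $n = 50$ pairs (clonotypes) and $n = 10$ leaves (Ward) — sizes chosen
so each property is measured with comfortable statistical margin.

Known limitations: CDR1/CDR2 placement is offset-based, not a full
numbering scheme, so unusually long CDR1/2 indel variants would need
germline-specific offsets; the Ward implementation is $O(n^3)$ and meant
for panel-sized matrices (tens of antibodies), not repertoire-scale
input; the outlier rule assumes positives inflate the signal; and the
funnel assumes channel-wise independent thresholds — no plate-effect
normalisation is attempted.
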