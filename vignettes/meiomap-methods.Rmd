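---
title: "meiomap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meiomap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meiomap studies how meiotic crossovers distribute along chromosomes in F2
mapping populations, and how their two mechanistic pathways respond to
interhomolog polymorphism. The package is organised as an analysis
workflow: the numbered scripts under `analysis/` are thin narrative
drivers, and every computation they perform lives in package functions so
the same code is exercised by the test suite and the acceptance script.
This vignette documents the underlying models, the estimators, the
numerical choices, and what the simulation-based checks do and do not
establish.

## The meiosis model

Crossovers form by two pathways. Class I events (the ZMM pathway) show
interference — a crossover suppresses further crossovers nearby — and are
modelled as a stationary gamma-renewal process on the cumulative genetic
scale of the bivalent. Inter-event distances are gamma distributed with
shape $\nu$ and mean one (in units of expected events); $\nu = 1$
recovers a Poisson process with no interference, and larger $\nu$
regularises event spacing. Class II events (MUS81-dependent) do not
interfere and are superposed as an independent inhomogeneous Poisson
process. Both processes are simulated at the bivalent level and each
event is retained with probability 1/2, because any single chromatid is
involved in a given crossover with that probability. This
"thin-by-a-half" step is what makes gamete-level interference appear
weaker than bivalent-level interference, as in real data.

For integer $\nu$ the renewal process is drawn by the classical counting
construction — a Poisson process of rate $\nu$ in which every $\nu$-th
point is kept, with a uniformly random phase, which is exactly
stationary. For non-integer $\nu$ the first event is drawn from the
closed-form equilibrium (forward-recurrence) distribution
$F_e(t) = t\,(1 - F_{\nu,\nu}(t)) + F_{\nu+1,\nu}(t)$, inverted
numerically, and subsequent gaps are ordinary gamma draws.

Genetic positions are mapped to physical coordinates through the
piecewise-constant intensity tracks (cM/Mb) produced by
`build_intensity_profiles()`. Intensity is defined genome-wide: crossovers
also occur in homozygous blocks, where no marker can reveal them. This is
deliberate — it lets the tests measure caller blindness instead of hiding
it.

An obligate-crossover option redraws event-free bivalents. It is off by
default because rejection sampling distorts the map length slightly; when
on, that distortion is the user's explicit choice.

## Polymorphism responses

The local crossover rate responds to interhomolog polymorphism through
two configurable multipliers:

* `classI_poly_response(snps_per_kb, boundary_dist)` scales the Class I
  rate. The bundled `boundary_stimulation_response(A, L)` implements
  $1 + A e^{-d/L}$ around HET/HOM block junctions, a minimal emulation of
  the elevated Class I activity seen where a heterozygous block adjoins a
  homozygous one (the juxtaposition effect). It is illustrative, not
  fitted: no quantitative form for this response is established, so the
  defaults ($A = 1$, $L = 0.5$ Mb) were chosen once as a visible but
  moderate effect and are not tuned further.
* `classII_poly_response(snps_per_kb)` scales Class II in $[0, 1]$. The
  bundled `density_suppression_response(gamma)` implements
  $1/(1 + \gamma d)$, a saturating inhibition of the Class II pathway at
  polymorphic sites.

The `msh2_active` switch models loss of mismatch recognition: with
`msh2_active = FALSE` both responses become neutral, except a residual
MSH2-independent Class II inhibition term that stays in place. The
interhomolog SNP density seen by the responses is the model's density
track inside heterozygous blocks and zero elsewhere.

## Fluorescence estimators

**Seed system.** A coupling-phase F1 hemizygous for two linked seed
fluorophores (green, red) produces gametes GR, G, R and ∅ with
probabilities $(1-r)/2, r/2, r/2, (1-r)/2$. Selfing gives seed-class
probabilities, with $q = 1 - r$:

$$P(\text{green only}) = P(\text{red only}) = \tfrac{1-q^2}{4},\quad
  P(\text{both}) = \tfrac{2+q^2}{4},\quad
  P(\text{neither}) = \tfrac{q^2}{4}.$$

The single-colour fraction $f = (N_G + N_R)/N_T$ therefore equals
$(1-q^2)/2$, and inverting it gives the estimator implemented by
`seed_cm()`:

$$\mathrm{cM} = 100\,\bigl(1 - \sqrt{1 - 2f}\bigr).$$

The square-root form is the exact inverse of the selfing algebra; a
linear reading of the formula is not, and fails even the boundary cases
($f = 1/2$ must map to 100 cM). Counts with $f > 1/2$ are reported as an
infeasibility error rather than clamped. The standard error is
delta-method propagation of the binomial variance of $f$:
$\mathrm{SE} = 100\,(1-2f)^{-1/2}\sqrt{f(1-f)/N_T}$.

Seed classification from two-channel intensities uses fixed,
user-supplied thresholds, mirroring the manual histogram thresholding
practice; `suggest_threshold()` offers a density-valley heuristic but is
never applied implicitly.

**Pollen system.** For a two-colour interval scored as R, Y, RY and N
classes, `pollen_cm_two_color()` computes
$\mathrm{cM} = 100\,Y/(Y + RY)$ within the tester-selected pool. For the
three-fluorophore system, `i3bc_interference()` computes interval
distances $d_b$, $d_c$ as 100 times the recombinant fractions, the
expected double-crossover count under independence
$(d_b/100)(d_c/100)\,N$, and the coefficient of coincidence. The verbal
convention "ratio between expected and observed" is ambiguous; only
$\mathrm{CoC} = \text{observed}/\text{expected}$ makes
$\text{interference} = 1 - \mathrm{CoC}$ lie in $[0, 1]$ with complete
interference at 1, so that direction is implemented and documented here.
Fluorophore-to-position mapping is positional (`m1`, `m2`, `m3` ordered
by genomic coordinate); which colour sits where is a configuration
concern, not hard-coded.

`compare_groups()` deliberately delegates to the standard tests (Welch's
t, one-way ANOVA with Tukey HSD, Kruskal–Wallis with pairwise
Mann–Whitney U and Bonferroni correction): replicate-level inference is
not this package's contribution.

## The crossover caller

The caller consumes per-individual allele-count tables and proceeds in
four explicit, documented steps (a deliberately transparent replacement
for an HMM-based segmenter):

1. **Filtering** (`filter_markers()`). Three independent predicates:
   site quality strictly greater than 100; per-site read depth strictly
   greater than 2.5 (i.e. at least 3 reads covering the site in that
   library); libraries with total reads strictly below 100,000 dropped
   whole. Because each rule is a row- or library-level predicate on the
   input, the rules commute — filter order cannot change the result.
2. **Genotyping** (`call_genotypes()`). With alt fraction $a$ at nonzero
   depth: AA if $a \le 0.1$, BB if $a \ge 0.9$, AB if
   $0.3 \le a \le 0.7$, otherwise missing. The bands are asymmetric by
   design: fractions like 0.2 are genuinely ambiguous at GBS depths and
   are better treated as missing than guessed. The attached score is the
   binomial log-likelihood ratio of the best versus second-best state.
3. **Segmentation** (`segment_track()`). A $k$-site sliding-window
   majority vote over informative sites (ties keep the site's own call),
   followed by merging of runs shorter than `min_support` sites into the
   larger flanking run (ties merge left). Isolated miscalls are erased
   by construction.
4. **Calling** (`call_crossovers()`). One call per adjacent segment
   pair, flanked by the last informative site on the left and the first
   on the right, placed at `floor((left + right)/2)` (clamped one base
   right of the left marker when the flanks are adjacent base pairs).
   Direct AA↔BB switches are kept but flagged `suspect`, since in an F2
   they require a double crossover between adjacent markers or an
   artefact.

Smoothing strength must match the noise level, and the defaults
($k = 5$, `min_support` 3) suit mid-range conditions. Two regimes
bracket the choices used in the tests and the acceptance script:

* *Noise-free oracle runs* (30× depth, zero error, ~1 marker / 10 kb,
  `anchor_ends = TRUE`): genotypes are effectively deterministic, so
  $k = 3$, `min_support = 1` preserves single-marker terminal segments —
  a larger window can never let a one-site segment at the chromosome end
  win a truncated vote, silently hiding real distal crossovers.
* *Degraded runs* (2.5× depth, 0.5% error): heterozygous sites miscall
  as homozygous whenever sampling happens to draw one allele, so runs of
  same-state miscalls appear and $k = 13$, `min_support = 7` is needed
  to keep the population mean count unbiased to within a few percent.

The `anchor_ends` option of the GBS simulator places one marker at each
end of every heterozygous block. Without it, crossovers distal to the
outermost random marker are invisible to *any* caller; anchoring
separates "the caller is wrong" from "no marker could have seen it" in
oracle-equivalence comparisons.

## Landscape analysis

`bin_crossovers()` tiles chromosomes with half-open fixed-width windows
from position zero, assigns calls by midpoint, and normalises per F2
individual. The trailing partial window is retained at its true length
by default (`drop_partial` switches this off); with it retained, window
totals conserve the call count exactly. `scaled_arm_profile()` maps each
arm to [0, 1] from telomere to centromere and aggregates over arms, and
`profile_correlation()` compares populations by Spearman rank correlation
over identical grids.

For the polymorphism analysis, 100-kb windows are ranked by SNPs/kb
(ties broken by chromosome then start, so grouping is invariant to input
row order) and cut into consecutive complete groups of $k = 12$; with
1191 windows this yields 99 groups and a remainder of 3. The remainder
is taken from the high-density tail — which end to trim is not
established, so the choice is fixed, reported in the grouping object,
and easy to audit. Per-group crossover frequency is
$100 \cdot \text{count} / (2\,n\,k)$ — crossovers per gamete per 100-kb
window, in cM — and `delta_cm()` subtracts one population's curve from
another's over identical groups. Trends use `stats::loess` (degree 2,
tricube weights, span 0.75 — the common default of that implementation)
and rank correlations use `stats::cor.test` with average ranks for ties.

## Synthetic-data conditions

The generator's defaults are the package's fixed study conditions, chosen
once to emulate a plant F2 GBS experiment at desk scale:

* Two chromosomes (20 and 15 Mb) with metacentric centromeres; the
  landscape experiments use a sinusoidal SNP-density track spanning
  0–12 SNPs/kb so that density groups cover the full range.
* Class I base rate 3 cM/Mb with $\nu = 5$; Class II base rate 0.5
  cM/Mb (2 cM/Mb in the differential-landscape experiments, where the
  Class II signal is the object of study). Per-F2 crossover counts then
  fall in the low single digits per chromosome pair, as in real
  populations.
* Marker density 50–100 sites/Mb, mean depth 2.5–30× depending on the
  regime under study, 0–0.5% allele error, 5% of sites drawn from a
  low-quality mixture component so the quality filter is exercised
  (the quality scale itself is arbitrary). Library totals are the summed
  on-marker depth times 50, representing off-marker GBS reads.
* Estimator experiments: 2,500 seeds per replicate, 30,000 pollen
  grains, 200 replicates; caller experiments: 150–200 F2; landscape
  experiments: 500 F2 per population, 30,000 gametes for coincidence
  estimation. These sizes give Monte-Carlo errors comfortably inside the
  tolerances asserted in the tests and complete in minutes on one core.

All randomness flows from a single root seed (`set.seed` by the caller or
the `seed` field of the pipeline config); identical seed and
configuration reproduce outputs bit for bit.

What the simulator does *not* emulate: read-level artefacts (mapping
bias, PCR duplicates), segregation distortion, marker ascertainment bias,
variable per-individual library quality beyond Poisson depth, and any
fitted form of the polymorphism responses. Passing simulation tests
therefore demonstrates internal consistency of estimator, caller and
landscape code under the stated generative model — not that the
qualitative response shapes are those of any real genotype.

## Known limitations

* The majority-vote segmenter is transparent but weaker than an HMM at
  very low coverage; graceful degradation is quantified (population mean
  within 5% at 2.5×/0.5% error) rather than hidden.
* Crossovers distal to the outermost informative marker, or pairs within
  a single marker interval, are undetectable in principle; the simulator
  records them so their cost is measurable.
* The coincidence estimator treats an interval as recombinant if it
  contains at least one crossover; at 10-cM intervals the distinction
  from odd-count recombination is negligible but grows with interval
  size.
* Window counts near chromosome ends sit in a shorter partial window;
  per-kb quantities use the true window length, but users comparing
  populations should keep the same partial-window policy on both sides.
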