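---
title: "Scoring colony-size genetic interaction screens with pemscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring colony-size genetic interaction screens with pemscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemscreen)
```

## The screen and its statistical model

In a pombe epistasis mapper (PEM) or synthetic genetic array (SGA) screen,
a query mutant is crossed to an arrayed gene-deletion library and double
mutants are selected on drug-containing ("test") plates, while plates
without the selecting drug provide the matched single-mutant ("control")
measurements. Colony size is the quantitative phenotypic readout: a gene
deletion whose double mutant grows reproducibly worse than its single
mutant is synthetic sick with the query mutation; one that restores growth
of a temperature-sensitive query at its nonpermissive temperature is a
suppressor (rescue).

Colony sizes carry two dominant systematic effects that must be removed
before any statistics are meaningful:

* **Edge effect.** Colonies in the outermost two rows and two columns of a
  plate grow larger because they face less competition for nutrients.
* **Plate effect.** Each plate is a batch: agar thickness, incubation
  position and pinning pressure scale all colonies on a plate together.

`normalizePlates()` corrects both in two multiplicative steps. With
$m_p$ the mean colony size of plate $p$'s *middle* (everything outside the
two-deep edge ring) and $e_p$ its edge mean, every edge spot is first
multiplied by $f_p = m_p / e_p$, which maps the edge ring onto the plate
middle mean while leaving middle spots untouched. Then every spot on plate
$p$ is multiplied by $g_p = M / m_p$, where $M$ is the median of the
middle means over all plates, so that after normalization every plate's
middle mean equals the same fixed number $M$. The order of the two steps
is immaterial for the middle means (the edge step does not change $m_p$)
but is fixed for reproducibility. Because both steps are per-plate
multiplications, the procedure is idempotent and scale-equivariant, which
the test-suite asserts to $10^{-9}$ relative tolerance.

Two readings of "the edge is normalized to the plate middle mean" are
possible: one factor for the whole two-deep ring, or one per ring. The
single-factor reading is the default; `perRing = TRUE` applies separate
factors to the outermost and second rings. On data generated with a single
multiplicative edge boost the two agree.

**Dead spots.** A colony of size 0 is data, not a missing value: dead
spots stay in $e_p$ and $m_p$ (a dead middle colony genuinely lowers the
plate's growth estimate). A plate whose middle is entirely dead cannot be
normalized: it is excluded from $M$, flagged in the report, and its spots
are set to `NA`.

## Interaction statistics

For each gene, `scoreScreen()` forms paired differences
$d_i = \text{control}_i - \text{test}_i$ over replicate spots matched by
grid position, and computes the paired t-statistic

$$ t = \frac{\bar d}{s_d / \sqrt{n}}, \qquad \text{df} = n - 1, $$

two-sided by default (the direction is enforced later, at call time, via
the sign of $\bar d$). When a screen was performed twice, per-experiment
p-values are combined by Fisher's method,
$X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$, and a single pooled
t-statistic over all pairs is reported alongside. Genes whose
per-experiment t-statistics disagree in sign are never called: two
opposite-direction experiments must not combine into a hit.

Combined p-values are adjusted by Benjamini–Hochberg over the genes that
survive linkage filtering (Bonferroni is available by option). A gene is
called **sick** when its adjusted p-value is below `alpha` (default 0.05)
and its mean difference exceeds `diffThreshold` (default 25, in the same
arbitrary area units as the normalized sizes, whose scale is set by the
plate-middle target $M \approx 100$ under the generator defaults), and
**rescue** symmetrically for differences below `-diffThreshold`. The
rescue criterion mirrors the sick criterion because no separate
quantitative rescue rule is established for such screens; it is a stated
package choice. Temperature is carried as spot metadata so rescue screens
run at the nonpermissive temperature use the same machinery unchanged.

**Degenerate cases.** All-identical differences make $t$ undefined: the
result is flagged `degenerate` with p = 1 when $\bar d = 0$ (no
information, no effect) and p = 0 otherwise (a constant nonzero shift over
several replicates is unambiguous). Genes with fewer than two valid pairs
are reported with `insufficient` status, never silently dropped. Pairs
whose *control* spot is dead are excluded — a single mutant that failed to
grow says nothing about the interaction — while dead *test* spots are
retained, because a synthetic-lethal double mutant legitimately produces
size-0 test colonies and dropping them would discard exactly the strongest
hits.

## Linkage filtering

Genes physically near the query locus (or near a marker used by the
selection scheme) cannot recombine away from the query mutation during
the cross, so their double mutants are under-recovered regardless of any
genetic interaction. `flagLinked()` removes this bias with a fixed
physical window: a gene is flagged when it lies on a window's chromosome
and the minimum distance from the window center to any point of the gene
interval is at most 500 kb (boundary inclusive). Distance-to-interval
rather than distance-to-midpoint avoids long genes escaping the window on
a technicality. Flagged genes are still scored — the record stays
auditable — but they are excluded from the adjustment universe and can
never appear in a hit list.

## Gene-set overrepresentation and phenotype statistics

`hypergeometricEnrich()` tests hit lists for overrepresentation of gene
sets (GMT input) with the hypergeometric upper tail,
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, BH-adjusted across
sets. The universe is the set of genes scored after linkage filtering —
enrichment must be conditioned on what could have been a hit, not on the
whole genome. Only overrepresentation is tested, and no ontology-graph
propagation is performed: sets arrive flat.

`fisherExact2x2()` and `rateSummary()` cover the cytological side of such
studies: comparing, say, the percentage of anaphases with lagging
chromosomes between strains. The two-sided Fisher exact p-value uses the
minimum-likelihood convention (all tables with fixed margins no more
probable than the observed one), which is the most common convention and
the one `stats::fisher.test()` implements; percentages come with exact
Clopper–Pearson intervals. The module consumes raw counts — published
figures typically print only percentages, which do not determine the
p-values without the denominators.

## What the synthetic generator emulates

`simulateScreen()` produces screens with exactly the structure the
pipeline assumes, plus planted ground truth:

* an arrayed library on 384-format plates (16 × 24 by default), where
  each replicate is a complete pinned copy of the library arrangement on
  its own plate — so a gene sits at the same grid position on every
  replicate plate and on the matched control/test plates, as pinned
  libraries do;
* a multiplicative model for expected spot size:
  baseline × interaction effect × plate effect × edge factor, with
  mean-one lognormal spot noise at a configured coefficient of variation
  (sizes are positive and effects compound, which makes lognormal the
  natural noise family);
* independent mean-one lognormal plate effects for every physical plate —
  control and test plates do *not* share batch effects;
* an edge boost (default 1.3) on the outermost two rows/columns,
  mirroring the normalization's definition of the edge;
* random dropout (`missingRate`, default 1%) encoded as size 0;
* planted sick (default 5% of genes at effect 0.5×) and rescue (2% at
  1.5×) interactions applied to test plates only;
* a three-chromosome genome of realistic fission-yeast proportions
  (5.6, 4.5 and 2.5 Mb), genes placed uniformly, with one gene forced
  into the 500 kb window around each query locus so the linkage filter
  always has work to do;
* gene sets with planted enrichment: one set containing half of the
  planted sick genes (diluted 1:1 with null genes) among 20 random
  decoys.

Defaults follow the screen design the pipeline targets: 4 or 12 replicate
spots per gene, one or two experiments, baseline size 100. The replicate
count, plate format and the spatial arrangement of replicates are
configurable because published screen descriptions typically fix only the
replicate count.

When the library does not fill an integer number of plates, the last
plate of each replicate copy is padded with `"blank"` filler spots that
grow at baseline and are never scored — mirroring the border/filler
positions of real arrayed collections.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: spatial gradients within a plate beyond
the edge/middle dichotomy, row/column streaks, pinning-order artifacts,
competition between neighboring colonies, batch drift across days, or
image-segmentation noise. The generator validates the statistical
machinery under its stated assumptions; it cannot validate those
assumptions against a real screen.

## Calibration under the study conditions

At the default conditions (500 genes, 12 replicate pairs, two
experiments, noise CV 0.1), the acceptance suite measures a raw
per-experiment type-I rate slightly below nominal (about 0.046 at the
0.05 level, pooled over 20 simulated null screens). Two small, understood
mechanisms account for the gap: (i) each gene's spots contribute about
1/120 of their own plate's middle mean, so normalization regresses every
gene slightly toward its plate average; (ii) random dropout on test
plates turns a fraction of null genes into outlier-bearing samples whose
inflated variance makes the t-test conservative. Both are properties of
the published procedure itself, not implementation artifacts, and neither
costs detectable power: planted 0.5× effects at these settings are
recovered with sensitivity ≥ 0.95 and realized FDR at or near zero.
Recovery is assessed over the post-linkage analysis universe, since
linked genes are excluded from calling by design.

## Problem sizes and numerical choices

The test suite and acceptance script run simulations at 200–500 genes
with 4–12 replicates and 10–20 seeds per property — sizes chosen so each
statistical property is measured with a Monte-Carlo standard error well
below its acceptance margin. Normalization identities are asserted to
1e-9 relative tolerance and closed-form statistics to 1e-12 against
independent oracles (direct enumeration for hypergeometric and Fisher
exact tails, the explicit step-up construction for BH, the
$e^{-x/2}(1+x/2)$ survival for Fisher combination at $k = 2$). Fisher
combination clamps p = 0 to the smallest positive double with a warning.
All coordinate handling is 0-based half-open at the BED boundary and
1-based closed (Bioconductor convention) internally.

## A worked example

```{r example, eval = FALSE}
out <- runScreenPipeline(SimulationConfig(nGenes = 500, seed = 11))
table(out$results$call)
head(as.data.frame(out$enrichment), 3)
```

The pipeline can also be driven stage by stage from the shell via the
script in `system.file("scripts", "pemscreen.R", package = "pemscreen")`;
with a fixed seed every stage's output table is byte-identical across
reruns.
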