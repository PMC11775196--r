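---
title: "Scoring, filtering and integrating transcription-factor interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, filtering and integrating transcription-factor interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxiscore)
library(dplyr)
```

## The problem

Affinity purification (AP-MS) and proximity labeling (BioID/UltraID) both
report a bait protein's partners as spectral counts — peptide-spectrum
matches (PSMs) — across replicate runs, but raw count tables are dominated by
sticky background proteins. Calling a bait–prey pair a *high-confidence
interaction* (HCI) therefore needs three things: a statistical score that
asks whether the prey is enriched over negative controls, a false-discovery
estimate across the whole ranked list, and a contaminant ledger that uses
how often each prey shows up in control pulldowns. `proxiscore` implements
that pipeline for multi-bait screens (the motivating case is the four NFI
transcription factors profiled at two biotinylation times), then carries the
HCI lists into comparative analyses and into ChIP-seq targetome integration.

## The scoring model

For a pair with replicate counts $x_1,\dots,x_r$ and a control-library mean
$\mu_0$ for the same prey, each replicate's interaction probability is the
posterior of a two-component Poisson mixture with equal priors,

$$p_i = \frac{f_1(x_i)}{f_0(x_i) + f_1(x_i)},\qquad
f_0 = \mathrm{Pois}(\max(\mu_0, c_0)),\quad
f_1 = \mathrm{Pois}(\max(\bar{x}, \mu_0, c_0)),$$

and the pair's score is $\bar p$, the replicate mean. Clamping the signal
mean $\mu_1$ from below by $\mu_0$ makes the test one-sided: only enrichment
over control counts as evidence, a depleted prey is not an interaction. The
pseudo-floor $c_0$ (default 0.1 PSM) keeps $f_0$ proper for preys never seen
in controls. This scorer is deliberately transparent — every probability can
be recomputed from two Poisson densities — and reproduces the qualitative
behaviour expected of spectral-count scorers (probability increases with
count excess over controls); the downstream filter ledger does not depend on
which scorer produced the probabilities.

The Bayesian FDR is the cumulative mean of $1-\bar p$ down the
$\bar p$-ranked list, forced monotone with a running maximum. Ties are broken
by higher average spectral count, then prey identifier, so ranking is fully
reproducible. Each (assay, labeling-time) stratum is ranked separately, with
baits pooled inside a stratum; the two labeling times are treated as
independent experiments throughout.

## The HCI filter ledger

Four rules run in a fixed order, with boundary semantics taken literally
from their wording:

1. **Primary BFDR cut** — BFDR $\le$ 0.01 for BioID, $\le$ 0.05 for AP-MS
   (inclusive at the threshold).
2. **Cross-bait rescue** (BioID only) — a pair failing the cut is kept when
   the same prey passed with any other bait in the same stratum *and* the
   failing bait detected the prey at all (`avg_spec > 0`). Rescue never
   crosses time points and never manufactures an interaction from absence.
3. **Contaminant frequency** — preys detected in *over* 20% of control runs
   are removed, *unless* the record's average count is *over* 3 times the
   prey's library mean; exactly 20% frequency and exactly 3-fold both
   survive on the wrong side of "over".
4. **Minimum count** — average spectral count strictly below 3 is removed;
   exactly 3 survives ("less than three").

The "library average" in rule 3 is the prey's mean count over *all* control
runs, zeros included. The alternative (mean over detecting runs only) would
make the override harder for rarely-detected contaminants; the all-runs mean
is what the control-library container defines and keeps frequency and
abundance on the same denominator. Rescue is ordered before the abundance
rules so that a rescued pair still has to clear the contaminant and
minimum-count filters; since rules 3 and 4 both depend only on per-record
abundance, their mutual order does not change the surviving set (the test
suite asserts this commutativity).

Every record ends in exactly one terminal state (`none`, `bfdr`,
`contaminant`, `min_count`), recorded in an audit table, so HCI totals and
the known/novel bookkeeping (`known + novel = total`, checked against
reference interaction lists in both pair directions, case-normalized) are
reproducible from any run.

## What the simulators emulate — and what they do not

`simulate_interactome()` draws spectral counts from a negative binomial
(mean $\lambda_1$ = 50 for planted true pairs, $\lambda_0$ = 0.5 for
background, size 2). Overdispersion is the reason for the NB choice —
replicate PSM counts vary more than Poisson — and Poisson is recovered as
the size parameter grows. True dispersion of PSM data is not identifiable
from published tables, so size 2 is a deliberately conservative default and
is exposed in the configuration. Four baits are profiled in biological
triplicate at two labeling times against six GFP-style control runs; the
defaults place 30 true interactors per bait at the short time, a quarter of
them drawn from a family-shared core, with the true set expanding by 20% at
the long time while the bait's own PSM drops (200 vs 100 expected self-PSM)
— the qualitative time-course structure of proximity labeling, where longer
exposure biotinylates a broader but more dilute neighbourhood.

Contaminants (5% of preys) follow one sticky process in every run, control
or test, regardless of bait: present with probability 0.5 at mean 6 PSM.
Modelling them identically on both sides matters: it is exactly what makes
the frequency filter, rather than the score, the rule that removes them,
because their test abundance matches their library average and the 3-fold
override correctly refuses to fire. Controls are otherwise ordinary
background — the same NB process with no true pairs.

What the generator does **not** emulate: protein length and detectability
biases, shared-peptide ambiguity, batch effects between replicate blocks,
correlated contaminant co-occurrence, and interactors whose abundance sits
near the background. Passing recovery tests on this synthetic data therefore
demonstrates that the ledger implements its rules correctly and has the
intended operating characteristics under its stated model — not that those
characteristics transfer to any particular real dataset.

At the defaults, pooled over ten simulated screens, the full ledger recovers
planted pairs with sensitivity above 0.9 at an empirical FDR below 0.05, and
on null screens (nothing planted) essentially no pair reaches BFDR
$\le$ 0.01; both are recomputed by the test suite and the acceptance script,
not quoted from anywhere.

## Isoform differential analysis

`differential_isoform()` compares a full-length and a short-isoform bait per
prey with a Welch two-sample t-test on $\log_2(\mathrm{count}+1)$ across
replicates, a fold change $\log_2\frac{\bar x_\mathrm{short}+1}
{\bar x_\mathrm{full}+1}$ on the raw means, and Benjamini–Hochberg
adjustment over all tested preys. The +1 pseudocount exists because zeros
are ubiquitous in spectral counts; the Welch test is a simple
replicate-respecting default. The calling thresholds
default to $|\log_2\mathrm{FC}| \ge 1$ with adjusted $p < 0.5$ — the
published volcano's printed thresholds, kept as printed even though 0.5 is
an unusually permissive FDR level; both are arguments, so a stricter
analysis is one call away. When a prey's counts are constant across all
replicates of both baits the t-statistic is undefined; such preys get
$p = 1$ when the two means agree and $p = 0$ when they differ
deterministically, the only assignment consistent with the evidence in that
degenerate case.

## Stability scores

For baits profiled by both assays, the per-prey bait-normalized PSM (prey
count over bait self-count, averaged per assay) gives a bounded stability
score $s = n_\mathrm{AP\text{-}MS}/(n_\mathrm{AP\text{-}MS} +
n_\mathrm{BioID}) \in [0,1]$: near 1, a stable core-complex partner; near 0,
a proximal or transient neighbour. Preys seen in only one assay are pinned
to the boundary and flagged `one_sided`. This is a ratio formulation built
for boundedness and scale invariance (rescaling one assay's bait and prey
counts jointly cancels); it is a stand-in for interaction-distance metrics
defined in MAC-tag workflows, whose exact supplementary formula is not
reproduced here, and should not be reported as that metric.

## ChIP-seq integration choices

*Overlap.* Two peaks overlap when they share at least one base; coordinates
are BED-style 0-based half-open everywhere, so touching intervals do not
overlap. Multi-set Venn counting groups peaks by connected components of the
overlap graph: each maximal physical region is counted once, in the region
named by the set labels it contains. Pairwise counting conventions can
differ on chained overlaps; the component convention is fixed and documented
here, and is asserted against a quadratic brute-force oracle in the tests.

*Annotation.* Nearest TSS to the peak center (`floor((start+end)/2)`), ties
to the lexicographically smallest gene id. This replaces feature-hierarchy
annotators deliberately: for building targetome *sets* the nearest-TSS rule
is deterministic, order-free and sufficient.

*Targetomes.* Top-N peaks by score (ties by coordinate, so constant scores
still give a deterministic set), annotated, deduplicated. N defaults to 500.

*Signal matrices.* Coverage is integrated exactly per bin from the bedGraph
step function via a cumulative-integral interpolant (gaps count as zero),
across ±5 kb around peak centers in 50 bp bins by default. Rows order by
their own mean signal unless a reference sample's ordering is supplied, the
convention used when displaying a second condition against a reference
panel.

*Motif scanning.* The NFI site TTGGC(N$_k$)GCCAA is scanned as two
half-sites with a fully degenerate spacer, $k \in 3..7$ by default
(canonical spacer 5), with a per-half mismatch budget (default 1) rather
than a PWM — position weights are not tabulated for this family's variants,
so consensus-with-mismatch is the implementable and testable reading. `N` in
the genome never matches. The consensus is its own reverse complement, so
exact hits coincide on both strands and are merged keeping the plus-strand
record; mismatched hits are reported per strand. The scanner is verified
against exhaustive per-position enumeration.

*Occurrence enrichment.* The fraction of peaks containing a hit is compared
against uniform re-placement of equal-length intervals per chromosome, with
the add-one empirical p-value $(1 + \#\{\mathrm{shuffles} \ge
\mathrm{obs}\})/(1 + n)$.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
(`stats::phyper`) with BH adjustment across terms. The universe defaults to
all genes appearing in the gene-set collection — external annotation
services keep their backgrounds internal and irreproducible, so the
collection itself is the only defensible default; any explicit background
can be passed instead. Plain BH is used and reported as such (service
"Benjamini" columns can differ subtly).

## Pipeline reproducibility

`run_pipeline()` executes simulate → score → filter → compare → chip
(→ enrich) with one master seed fanned out to per-stage seeds by stable
string hashing of stage names, so toggling one stage never shifts another's
random stream. Every output file is checksummed into a JSON manifest;
identical configuration and seed reproduce identical checksums end to end.

## Problem sizes

The shipped defaults are desk-scale by design: 200 preys × 4 baits × 2
times in triplicate for interactome simulations, 100 peaks per bait on a
0.4 Mb two-chromosome toy genome, 100 kb genomes for scanner verification.
These sizes give stable recovery estimates (thousands of scored pairs per
run) while keeping a full test-and-acceptance cycle in minutes; every size
is a configuration argument for larger studies.

## Known limitations

* The scorer is a two-component Poisson posterior with equal priors, not a
  reimplementation of published SAINT internals; absolute probabilities are
  not comparable across scorers, though rankings behave alike.
* Replicate counts are treated as exchangeable; no protein-length or
  run-order normalization is applied.
* Nearest-TSS annotation ignores gene bodies, enhancer assignment and
  chromatin domains.
* The motif scanner is consensus-based; it will not capture half-site
  affinity differences a PWM would.
* The stability score is a bounded stand-in, not a calibrated physical
  distance.
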