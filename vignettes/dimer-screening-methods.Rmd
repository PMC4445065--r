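---
title: "Composite-motif screening and EMSA cooperativity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-motif screening and EMSA cooperativity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerscreen)
```

Some transcription factors, notably the SOXE group (SOX8, SOX9, SOX10),
bind DNA as dimers on *composite motifs*: two half-sites (e.g. `ACAAAG`
and its reverse complement `CTTTGT`) separated by a short spacer. This
package provides the two quantitative procedures such a study needs:

1. a **spacing-resolved enrichment screen** that asks, for every
   (half-site pair, orientation, spacer) configuration, whether composite
   instances occur in a foreground set of open-chromatin regions more
   often than a control set would predict; and
2. an **equilibrium two-site binding model** that turns quantified
   electrophoretic mobility shift assay (EMSA) band fractions into an
   estimate of the dimerization cooperativity factor ω.

A synthetic-data module generates region sets with planted composites,
noisy titration lane tables, and block-correlated expression matrices, so
every stage can be exercised against known ground truth.

## Motif model and scanning

Motifs are position weight matrices (PWMs) over A/C/G/T with an explicit
background distribution. They can be built from a consensus string
(`consensus_to_pwm()`, one-hot columns smoothed by a pseudocount spread
according to the background) or parsed from TRANSFAC-format count
matrices (`parse_transfac()`; counts in each row are converted to
probabilities as `(count + pc·b) / (total + pc)`).

Scanning (`scan_sequence()`) scores every window on both strands with
the log-odds score in bits, `sum log2(P(base)/background(base))`, and
reports matches in plus-strand 0-based half-open coordinates. Two
numerical choices matter:

* **Probability floor.** Zero entries (pseudocount 0) are floored at
  `1e-4` before the log, so a single mismatch against a consensus PWM
  costs ≈ 13 bits rather than producing `-Inf`. Ambiguity characters
  (`N` etc.) make a window non-matching rather than raising an error.
* **Threshold.** No match cutoff is published for these motif sets; the
  default is 80% of the motif's maximum attainable score
  (`default_threshold()`). For a pseudocount-free consensus PWM this
  admits exact matches only, which keeps planted-motif recall at 1 while
  remaining overridable for softer matrices.

## Composite configurations and the enrichment screen

A composite configuration is (half-site pair, orientation class, spacer),
where the spacer counts the bases between the end of the first half-site
and the start of the second. Orientation classes are defined as
*reverse-complement equivalence classes* of strand arrangements — for a
self-pair: direct/tandem {`++`, `--`}, inverted/head-to-head {`+-`},
everted/tail-to-tail {`-+`}. Defining classes this way makes every count
invariant under reverse-complementing the input sequences, which is the
property a strand-agnostic screen must have; it also means a self-pair
contributes exactly 3 classes per spacer (e.g. 153 configurations for one
half-site at spacers 0–50).

The screen (`run_enrichment_workflow()`) counts, per configuration, the
number of regions containing ≥ 1 instance — region-level indicators, not
instance totals, so long regions do not dominate — and tests enrichment
of foreground versus control with the one-sided hypergeometric (Fisher)
exact test on the pooled 2×2 margins. The statistic is exact,
assumption-light and desk-verifiable by enumeration; instance totals are
still reported as a column. p-values are Bonferroni-corrected with the
number of configurations actually screened in the run (printed in the
output header for transparency), a conservative choice that mirrors
correcting over all complexes one could have formed.

The control set is taken as given (no GC- or length-matched resampling);
the expectation shown per spacer is simply the control hit rate scaled to
the foreground size.

## The two-site equilibrium model

A probe with two protein-binding sites has four microstates. With
`q1 = K1·p` and `q2 = K2·p` (`p` = free protein, `K` = per-site
association constants), the statistical weights are 1, `q1`, `q2` and
`ω·q1·q2`; the partition function is `Z = 1 + q1 + q2 + ω·q1·q2`. The
two singly-bound microstates co-migrate as one gel band, giving band
fractions

* `f0 = 1/Z` (free probe),
* `f1 = (q1 + q2)/Z` (monomer band),
* `f2 = ω·q1·q2/Z` (dimer band).

ω is the cooperativity factor: ω > 1 cooperative, ≈ 1 additive, < 1
competitive. The additive band defaults to (0.5, 2.0), a configurable
operationalisation of "about 1".

Because EMSA probe concentrations (tens of nM) are comparable to the
protein, `solve_equilibrium()` imposes full mass balance
`P_total = p + D_total·(f1 + 2·f2)` and finds `p` by bracketed bisection
on `[0, P_total]` (the bound term is monotone in `p`, so the root is
unique); the conservation residual is checked to `1e-9` relative.

**Estimators.** Two are provided side by side, since either aggregation
is defensible:

* the per-lane ratio `ω̂ = 4·f2·f0/f1²`, exact for a symmetric probe at
  any free-protein concentration and independent of K — verified to
  `1e-6` relative error across a (K, ω, q) grid;
* a global least-squares fit of (log10 K, log10 ω) over all lanes
  against the mass-balance predictions, with Nelder–Mead multi-start
  over a log-spaced grid of initial values (unweighted residuals are the
  maximum-likelihood choice under homoscedastic fraction noise).

Singly-bound bands are pooled throughout; an asymmetric model
(`K1 ≠ K2`) would need resolved monomer bands and is therefore not
fitted.

**The "infinite ω" rule.** When the monomer band never reaches 2% of the
lane signal, ω cannot be separated from K and the fit is flagged
`unreliable/infinite omega` rather than given a number; the 2% bound is
the per-lane reliability threshold used when quantifying gels. Under the
model the monomer band peaks at `1/(1 + sqrt(ω))`, so ω = 10⁴ keeps it
below 1% — inside the flagged regime — across any titration. Note the
interaction with noise: densitometry error of ±2% can push a truly ~1%
band above the threshold in individual lanes, in which case the fit
proceeds but the returned ω is dominated by noise; the per-lane ratios
reported alongside make this visible.

## Heterodimer mixtures

`mixture_fractions()` extends the weights to two proteins: monomers get
two site assignments each (`2·K·p`), homodimers `ω_aa·(K_a·p_a)²`, and
the heterodimer `2·ω_ab·K_a·p_a·K_b·p_b` because AB and BA co-migrate.
Two limits pin the model down: `ω_ab = 0` abolishes the heterodimer
band, and a fully symmetric mixture shows the heterodimer at exactly
twice each homodimer band — the multiplicity signature of efficient
cross-dimerization. Heterodimer claims are exercised through these
band-order properties; no ω_ab is fitted from mixtures.

## Co-expression networks

`pairwise_r2()` computes squared Pearson correlations between gene
expression profiles, on `log(1+x)` values by default (expression data
are strongly right-skewed; the untransformed scale is available behind a
flag). Zero-variance genes are dropped with a note. `build_network()`
draws strong edges at r² > 0.4 and weak edges at r² > 0.1; heatmap
ordering, when wanted, is average-linkage clustering on 1 − r²
(`coexpression_order()`), kept separate because ordering is cosmetic.

## Synthetic data: what it emulates and what it does not

`simulate_region_sets()` draws i.i.d. background sequence (uniform base
composition by default) and plants, in a chosen fraction of foreground
regions, exactly one composite instance sampled from the configuration's
PWMs at a uniform admissible offset, replacing bases so lengths are
preserved; the strand arrangement is drawn uniformly within the
orientation class so planted data have no strand bias. Control regions
are never planted. Plant records carry the ground-truth coordinates, so
recall (≥ 0.99 required at the default threshold) and end-to-end
significance can be checked mechanically.

This emulates the *statistical* structure of a foreground/control screen
— not real chromatin: no GC heterogeneity, no repeat structure, no
clustering of sites, no length variation. Passing tests therefore show
the statistic and the scanner are correct and calibrated under the null,
not that any particular genomic claim replicates.

`simulate_titration()` perturbs mass-balance band fractions with
truncated Gaussian noise (default study conditions: 50 nM probe, 8
lanes, noise sd 0.02 in fraction units) and renormalises each lane to
sum 1. `simulate_expression()` mixes a per-block latent factor into
otherwise independent log-scale profiles so the expected within-block
correlation equals `within_r`, then exponentiates.

## Lane placement

Where lanes sit controls what a titration can measure.
`titration_design()` locates the protein concentration at which the
dimer band reaches half its plateau (under mass balance) and log-spaces
the lanes from `mid/span` to `mid·span`. The default `span = 3` comes
from a closed-form window: the monomer fraction
`f1 = 2q/(1 + 2q + ω·q²)` exceeds half its own maximum only while
`u = q·sqrt(ω)` satisfies `u + 1/u ≤ 4`, i.e. within `2 + sqrt(3) ≈ 3.7`
fold of the midpoint. Since the monomer band is the only signal
separating ω from K, schedules that overshoot this window (for example
long serial dilutions that saturate half the gel) leave ω poorly
determined at high cooperativity even though the least-squares optimum
is found; the transition-spanning default keeps the median relative
error of ω̂ below 25% at noise sd 0.02 for ω up to 500.

## Problem sizes and reproducibility

The standard demonstration (the `analysis/` drivers and the acceptance
script) uses 200 foreground and 2000 control regions of 300 bp with
plant rate 0.5, one half-site self-pair screened over spacers 0–10 in
all three orientation classes (33 configurations), 8-lane titrations at
50 nM probe, and 100-replicate recovery simulations — sizes at which the
planted configuration is unambiguous and every run completes in minutes
on a laptop. All randomness flows from one explicit seed per generator
call; every output table carries a header with the package version, the
seed and the generating parameters, so identical configurations
reproduce byte-identical files.

## Known limitations

* Enrichment uses a fixed control set; matched-control resampling (GC,
  length) is out of scope, so real-data runs inherit whatever
  composition bias the control set has.
* The exact test is conservative on very sparse counts (discreteness),
  which is the safe direction for a screen with Bonferroni correction.
* The binding model is equilibrium-only (no kinetics, no gel-caging
  effects) and pools the singly-bound microstates; probes with strongly
  asymmetric half-sites need resolved monomer bands that pooled lane
  tables cannot provide.
* ω estimates above ~10³ are reported but sit in the unreliable regime
  by the 2% monomer rule; treat them as "very cooperative" rather than
  as numbers.
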