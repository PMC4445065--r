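# dimerscreen

Transcription factors of the SOX family can assemble as dimers on
*composite DNA motifs*: two half-sites (such as `ACAAAG` and its reverse
complement `CTTTGT`) separated by a short spacer. Whether a factor
dimerizes on a given element — and how strongly — is captured by two
complementary measurements: the **enrichment** of a spacing/orientation
configuration in open-chromatin regions of a cell type versus a control
set, and the **cooperativity factor ω** measured by electrophoretic
mobility shift assays (EMSAs).

`dimerscreen` implements both ends of that workflow for R users
(regulatory genomicists and quantitative biochemists alike):

* **Motif handling** — PWMs from consensus strings or TRANSFAC-format
  count matrices; double-strand log-odds scanning in 0-based half-open
  coordinates.
* **Spacing-resolved enrichment** — enumerate all (pair, orientation,
  spacer) configurations up to a maximum spacer, count regions carrying
  at least one instance, and test foreground against control with the
  one-sided Fisher/hypergeometric exact test, Bonferroni-corrected over
  every configuration screened.
* **EMSA cooperativity** — the equilibrium two-site statistical-weight
  model `Z = 1 + q1 + q2 + ω·q1·q2` with full mass balance; the
  symmetric-probe per-lane estimator `ω̂ = 4·f2·f0/f1²`; a global
  least-squares fit of (K, ω); the per-lane 2% monomer-band rule that
  flags ω as `unreliable/infinite`; and the binding-mode classification
  (cooperative / additive / competitive).
* **Heterodimer band prediction** — mixture statistical weights for two
  proteins, with the 2:1 heterodimer:homodimer multiplicity signature.
* **Co-expression networks** — squared Pearson correlation matrices with
  strong (r² > 0.4) and weak (r² > 0.1) edges.
* **Synthetic data** — region sets with planted composites (ground-truth
  plant records included), noisy titration lane tables, and
  block-correlated expression matrices, so the whole pipeline can be
  validated without external downloads.

## Worked example

Plant an inverted-repeat 4-bp-spacer SOX palindrome in half of 200
synthetic foreground regions, screen spacers 0–10 in all three
orientation classes against 2000 unplanted controls:

```r
library(dimerscreen)

half <- consensus_to_pwm("ACAAAG", name = "SOX_ACAAAG")
cfg  <- dimer_config(half, orientation = "inverted", spacer = 4)
sim  <- simulate_region_sets(200, 2000, length = 300, config = cfg,
                             plant_rate = 0.5, seed = 1)
screen <- run_enrichment_workflow(sim$foreground, sim$control,
                                  list(half), max_spacer = 10)
print(screen)
#> enrichment screen: 33 configurations (Bonferroni factor 33)
#> top configurations:
#>      motif_a    motif_b orientation spacer k_fg expected_fg         p_raw         p_adj
#> 1 SOX_ACAAAG SOX_ACAAAG    inverted      4   94           0 3.351354e-109 1.105947e-107
#> 2 SOX_ACAAAG SOX_ACAAAG     everted      6    1           0  9.090909e-02  1.000000e+00
#> 3 SOX_ACAAAG SOX_ACAAAG      direct      0    0           0  1.000000e+00  1.000000e+00
```

The planted configuration (inverted, 4 bp) is found in 94 of 200
foreground regions, never in the controls (expectation 0), and is the
only configuration surviving Bonferroni correction — corrected
p ≈ 1.1·10⁻¹⁰⁷ versus ≥ 1 for everything else.

Estimating cooperativity from a quantified titration:

```r
m    <- two_site_model(1e7, omega = 100)      # K = 1e7 /M, omega = 100
conc <- titration_design(m, dna_total = 50)   # lanes spanning the transition
tit  <- simulate_titration(m, conc, dna_total = 50, noise_sd = 0.02, seed = 2)
fit  <- fit_titration(tit)
c(K = fit$K, omega = fit$omega)
#>            K        omega
#> 1.225903e+07 9.335756e+01
classify_binding(fit$omega)
#> [1] "cooperative"
omega_from_lane(c(0.25, 0.5, 0.25))$omega     # independent sites
#> [1] 1
```

The fit recovers ω within 7% at this noise level (the true values were
K = 10⁷ /M, ω = 100); `omega_from_lane()` returns exactly 1 on
independent-site fractions, the additive anchor.

The numbered drivers under `analysis/` run the full narrative —
region simulation, enrichment screen, cooperativity fits across spacer
scenarios, heterodimer band prediction, co-expression network — and
write their tables under `results/`.

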