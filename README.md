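# dualtf

Inference of **dual-function transcription factors** — TFs that activate
some cis-regulatory modules (CRMs) and repress others — from a
thermodynamic model of CRM-driven expression, in the setting of the
*Drosophila* developmental (gap-gene) network: a panel of TFs with known
binding motifs and concentration gradients along the anterior–posterior
(AP) axis, and CRMs with measured expression profiles.

For whom: computational/regulatory genomicists who want a tested,
reusable implementation of the whole analysis — PWM scanning,
thermodynamic forward model, simulated-annealing fitting, per-TF role
inference with an ensemble of three methods, dual-function retraining,
enrichment-p-value classification and SUMO-consensus protein scanning —
plus a synthetic-data generator so every stage runs with no downloads.

## The model

A CRM's sites are the PWM windows scoring ≥ *t* bits (default 9, both
strands), each with normalized affinity *q* = score / *s*<sub>max</sub>.
Given a role configuration ϕ = ⟨r<sub>1</sub>,…,r<sub>n</sub>⟩
(r<sub>i</sub> = +1 activator, −1 repressor), expression at AP position
*x* is

- occupancy  f<sub>i</sub>(x) = K·v(x)·q<sub>i</sub> / (1 + K·v(x)·q<sub>i</sub>)
- activation  Σ(x) = Σ<sub>act i</sub> E<sub>act</sub>·f<sub>i</sub> ·
  Π<sub>rep j : |c<sub>i</sub>−c<sub>j</sub>| ≤ d</sub> (1 − E<sub>rep</sub>·f<sub>j</sub>)
  (short-range quenching within *d* bp)
- rate  R(x) = R<sub>0</sub> / (1 + exp(−(Σ(x) − G<sub>0</sub>)))

with 2*n* + 2 free parameters (K and E per TF, G<sub>0</sub>,
R<sub>0</sub>), plus one per dual-function TF (split
E<sub>activator</sub>/E<sub>repressor</sub>). Fit quality is the Pearson
correlation (CC) with the observed profile. Parameters are fitted by
simulated annealing (1000 iterations, best of 5 repeats, geometric
cooling, fully seeded). Training every CRM–configuration pair gives a
CRMs × 2<sup>n</sup> CC matrix from which three methods call per-CRM
roles — SMALLEST-OPTIMAL (exact minimum set cover of per-CRM optima),
BEST-N (exact best n-subset of configurations, n ≤ 4) and SENSITIVITY
(largest CC change when one TF's role flips) — and a majority-vote
ensemble labels each TF `+`, `-` or `s` (switcher). See
`vignettes/dual-function-tfs.Rmd` for assumptions, parameter meanings
and design choices.

## Worked example

Desk-scale synthetic world: 4 TFs (two broad activators, two localized
repressors; "Mid" is planted dual-functioning — activator for CRMs 1–4,
repressor for 5–8), 8 CRMs × 500 bp, 50 AP positions, noise SD 0.05.

```r
library(dualtf)

spec <- generator_spec(seed = 1)
sdat <- make_synthetic_dataset(spec)
ds   <- as_crm_dataset(sdat)          # rescans sequences with the PWMs
ds$sites
#> tfbs_map: 8 CRM(s), 32 site(s) total (4.0 per CRM)

sch <- sa_schedule(iterations = 400, repeats = 2, seed = 7)  # quick demo
ccm <- build_cc_matrix(ds, sch)       # 8 x 16 CC matrix (~20 s)
se  <- sensitivity(ccm)
ensemble_vote(lapply(list(smallest_optimal(ccm), best_n(ccm, 4), se),
                     summarize_tf_roles))
#> role_summary (+ activator, - repressor, s switch):
#>     tf role confidence
#> 1  Ant    +         24
#> 2 Post    +         22
#> 3  Mid    s         24
#> 4 Tail    -         21

run_dual_experiment(ds, se, list("Mid"), sch)
#> variant_report:
#>    variant n_configs n_params mean_cc   se_cc best_cc
#> 1 baseline         1       10  0.6283 0.10388  0.7322
#> 2  MidDual         2       11  0.8636 0.04346  0.9071
```

Reading the output: the ensemble recovers the planted labels — both
activators `+`, the fixed repressor `-`, and the planted dual TF `s`
(confidence = strong supporting per-CRM calls across the three
methods).  Allowing Mid to take its per-CRM SENSITIVITY role raises the
simultaneous-fit mean CC from 0.63 to 0.86 at the cost of a single
extra parameter (11 vs 10 = 2·4+2) — the dual-function signature the
package is built to detect.  With the full default schedule
(`sa_schedule()`) the same experiment gives baseline ≈ 0.75 vs dual
≈ 0.93.  For the 8-TF panel the accounting gives
`count_free_parameters("reinitz", 8)` = 18, 19 with one dual TF, 20
with two (and 2^8 = 256 configurations).

A command-line interface wraps the same stages
(`simulate`, `scan`, `ccmatrix`, `roles`, `dualfit`, `sumoscan`,
`enrich-call`, `run-all`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","dualtf.R",package="dualtf"))')" \
    simulate --seed 3 --out sim/
```

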