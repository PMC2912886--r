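---
title: "Inferring dual-function transcription factors with a thermodynamic CRM model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dual-function transcription factors with a thermodynamic CRM model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtf)
```

## The problem

Quantitative models of transcription usually assume that each
transcription factor (TF) is either an activator or a repressor for every
gene it regulates.  In the early *Drosophila* embryo, eight well-studied
TFs (Bcd, Cad, Hb, Tll, Gt, Kr, Kni, TorRE) jointly control dozens of
developmental cis-regulatory modules (CRMs), and there is experimental
evidence that some of them — Hunchback is the classic example — activate
some CRMs while repressing others.  `dualtf` asks, for a panel of TFs
and a set of CRMs with measured expression along the anterior–posterior
(AP) axis: which role assignment ("configuration") fits each CRM best,
which TFs switch roles between CRMs, and how much does allowing such
dual function improve a single model fitted to all CRMs simultaneously?

## The forward model

For each CRM we scan its sequence with per-TF position weight matrices
(log-odds in bits, both strands, threshold `t = 9` bits by default) and
keep the discrete high-scoring sites, each with a normalized affinity
`q = score / s_max` in (0, 1], where `s_max` is the sum of the largest
log-odds entry in every motif column.  Given TF concentrations `v(x)`
along the AP axis and a role vector `r` (+1 activator, −1 repressor),
expression is predicted position by position:

* **Occupancy** of site `i` of TF `a`:
  `f_i(x) = K_a v_a(x) q_i / (1 + K_a v_a(x) q_i)` —
  a single-site binding isotherm with per-TF association constant `K_a`.
* **Short-range quenching**: each activator site's contribution
  `E_act(a) f_i` is multiplied by `(1 − E_rep(b) f_j)` for every occupied
  repressor site `j` whose centre lies within `d` base pairs (default
  100 bp).  Setting `d` beyond the CRM length recovers whole-CRM
  repression, the behaviour of models without a distance rule.
* **Transcription gate**: the summed, quenched activation Σ(x) drives a
  logistic switch `R(x) = R0 / (1 + exp(−(Σ(x) − G0)))` with activation
  threshold `G0` and maximal rate `R0`.

The model family this parameterization follows is cited in the
literature but its rate equations are not printed alongside the
parameter list; the three formulas above are this package's declared
concrete choice.  They are the minimal standard forms consistent with
every stated property of that model: the free-parameter inventory
(`K` and `E` per TF, plus `G0` and `R0`, i.e. `2n + 2` for `n` TFs, one
more per dual-function TF), distance-dependent repression, and the
absence of TF–TF synergy.  Goodness of fit is the Pearson correlation
(CC) between observed and predicted profiles; a zero-variance profile is
defined to have CC 0, since a constant prediction carries no shape
information (this also makes "all effectiveness zero" fits score 0
rather than propagating numerical noise).

## Fitting

Parameters are fitted by Metropolis simulated annealing maximizing the
mean CC over the training CRMs: 1000 iterations per repeat, best of 5
independent repeats (per-repeat bests are also averaged and reported
with their standard error).  Proposals pick one free parameter uniformly
at random; rate-like parameters (`K`, `E`, `R0`) take multiplicative
log-normal steps, `G0` additive Gaussian steps, both reflected at the
bounds.  The cooling constants are not dictated by the protocol we
follow, so they are package choices: `T0 = 0.1`, geometric factor
`alpha = 0.99` and step size `sigma = 0.5`.  They were chosen by
measuring convergence on noise-free synthetic data, where the attainable
CC is known (≈ 0.97): with the softer `T0 = 1`, `alpha = 0.995`,
`sigma = 0.2` the sampler spends half its budget accepting nearly every
move (temperatures far above the ~0.1 CC scale of the objective) and
plateaus around CC 0.87; the adopted schedule reaches ≈ 0.96–0.98.
Every repeat derives its own seed from the master seed, so all fits are
exactly reproducible.

## Role inference

For `n` TFs there are `2^n` configurations.  Training one model per
CRM–configuration pair (desk scale: 8 CRMs × 16 configurations) gives
the CC matrix that all three role-determining methods consume:

* **SMALLEST-OPTIMAL** — per CRM, the configurations tied (within
  `1e-9`) with the row maximum are "optimal"; an exact minimum set cover
  (branch and bound, lexicographically smallest on ties) picks the
  smallest configuration set containing an optimal configuration for
  every CRM.  A TF's role on a CRM is read off the assigned
  configuration, but set to `NA` when no configuration pair differing
  only in that TF changes the CC by at least `epsilon = 0.1`.
* **BEST-N** — the exact `n`-subset of configurations (n ≤ 4)
  maximizing the total CC when each CRM picks its best in-subset
  configuration.  The search is exhaustive-equivalent
  (branch and bound with suffix-maximum pruning) and every call is
  "strong" by construction.  The source text describing this method
  once says the total CC is *minimized*; every surrounding statement
  (and the accompanying figure) refers to best overall accuracy, so
  maximization is implemented.
* **SENSITIVITY** — per CRM and TF, the pair of configurations
  differing only in that TF with the largest absolute CC difference;
  the sign assigns the role, differences ≤ 0.1 give `NA`, and calls
  with |ΔCC| > 0.1 are "strong".

Each method's per-CRM calls are condensed per TF: more than θ = 2/3 of
non-`NA` calls on one side declares a single role, otherwise the TF is a
switcher ("s").  (The published description leaves the exact fraction
unreadable in the available text; 2/3 is this package's configurable
default.)  A majority vote over the three methods gives the final label,
with three-way disagreement also mapped to "s".  The reported
confidence — the count of strong per-CRM calls supporting the final
label, summed over methods — is a declared substitute for the original
confidence figure, whose definition is not given.

Dual-function retraining then fixes every TF at its literature role
except the declared dual TFs, which take their SENSITIVITY role per CRM
(`NA` falls back to the literature role); their sites are tagged so only
the appropriate version of the TF binds, concentrations are shared, and
the fit gains one extra effectiveness parameter per dual TF
(`E_activator` and `E_repressor` both free).  All variants use the same
schedule and master seed, so differences reflect model structure rather
than search luck.

## Enrichment classification and SUMO scanning

Motif-enrichment p-values (computed externally, e.g. by CLOVER, against
activator-set vs repressor-set CRM sequences) are classified with fixed
thresholds: over-represented below 0.01, under-represented above 0.99,
background otherwise; a TF is differentially enriched iff exactly one
set is over-represented, the other is not, and the p-values differ by
more than 0.2.  Untested (blank) cells never support a differential
call.  A Bonferroni helper (`p × m`, capped at 1) covers the worked
76-motif correction.

Protein sequences are scanned for the SUMOylation acceptor consensus
Ψ-K-x-E (Ψ ∈ {I, L, V}, x arbitrary) with a sliding window; overlapping
matches count separately (a conservative superset that leaves
presence/absence unchanged).  The second reported motif, Φ-C-x-I, is
implemented with its residue class exactly as printed — Φ = {K, L, Y} —
even though lysine in a "hydrophobic" class is chemically odd; the class
is an argument, so users can correct it.

## The synthetic stated world

The real gap-gene dataset (8 TFs, 44 CRMs, reporter mRNA profiles) is
not redistributable here, so the generator emulates its *structure* at
desk scale: 4 TFs (16 configurations), 8 CRMs of 500 bp, 50 AP
positions, expression = forward model + Gaussian noise (SD 0.05,
clipped at 0), one planted dual-function TF acting as activator in half
the CRMs.  Choices a reader should know about, and why:

* **Gradients**: two broad activator gradients (anterior/posterior
  exponentials, λ = 35 %EL) and two localized repressor bumps
  (Gaussians at 30 and 70 %EL, σ = 8 %EL).  This is the classic
  broad-activation / short-range-repression geometry: repressors carve
  interior valleys that no activator-only model can mimic, so every
  TF's role is consequential and recoverable.  Two rejected designs
  illustrate the constraint: with steep activators and mid-axis bumps,
  wrong-role fits could silence the TF (effectiveness → 0) and absorb
  its dip into a monotone profile, making roles nearly unidentifiable;
  and with ground-truth parameters that saturate the logistic gate the
  profiles go flat and noise dominates the CC.
* **Ground truth parameters**: `K = 8`, `E_act = 5`, `E_rep = 0.9`,
  `G0 = 5`, `R0 = 1`, `d = 100` bp — chosen once so that Σ(x) straddles
  `G0` (profiles span most of (0, R0)) and occupied repressors quench
  ~80% of an activator's contribution.
* **Site placement**: each CRM carries one exact-consensus site per TF,
  planted as a compact cluster spanning at most `d` (= 100 bp) at a
  random offset, sites ≥ 5 bp apart on random strands.  Spreading sites
  uniformly instead leaves repressor sites outside quench range of any
  activator in many CRMs, making the repressor inert there and its role
  undecidable — an instructive failure, not a usable default.
  Sequences are rejection-sampled until a scan at the default threshold
  recovers exactly the planted sites, so scanner truth and generator
  truth coincide by construction.
* **Proteins**: dual-labelled TFs receive planted Ψ-K-x-E instances;
  single-role TFs are rejection-sampled to contain none.

What a green synthetic run does **not** establish: recovery of the
published real-data CC values (they require the real dataset), realistic
stripe geometry, temporal dynamics, PWM uncertainty, or correlated
measurement noise.  The synthetic world shows that the pipeline's
inferences are correct *when the model's own assumptions hold*.

## Numerical choices and edge cases

* Coordinates are 0-based, half-open; quench distances are measured
  between site centres.
* Both strands are scanned (the source protocol does not say; it is
  standard scanner behaviour and required to find reverse-strand planted
  sites); a minus-strand site's start is its leftmost forward-strand
  base.
* Zero PWM probabilities are floored at 1e-3 before log-odds so scores
  stay finite.
* Two background models are provided: uniform, and the printed
  D. melanogaster composition (A/T 0.297, C/G 0.203).
* Row-maximum ties in the CC matrix use an absolute tolerance of 1e-9;
  minimum-set-cover and best-n ties resolve to the lexicographically
  smallest configuration-index set; `max.col` ties take the first
  column.
* An exactly constant profile (e.g. a CRM with no sites) is detected
  via max = min, not via a variance threshold, and scores CC 0 with a
  warning at the user-facing level.
* Configuration indices put TF `i` of the panel at bit `i − 1`
  (bit set = activator), so tables are stable under panel reordering
  only together with their panel.

## Known limitations

* The SA optimizer is a global heuristic; per-cell CC-matrix values
  carry optimization noise of a few hundredths, which is why the role
  methods' `epsilon`/strong thresholds (0.1) matter.
* `best_n` beyond n = 4 is deliberately unsupported (exactness would
  become expensive), matching the protocol it reproduces.
* The enrichment module classifies supplied p-values; it does not
  compute motif enrichment itself.
* Only the parameter count of the richer alternative model (the
  `3n + 3|W| + |C|` accounting) is implemented; its likelihood machinery
  is out of scope.
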