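---
title: "Models and design decisions behind hlaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions behind hlaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaflow)
```

# Scope

`hlaflow` models the quantitative layer of a registry-scale amplicon HLA
genotyping operation: how reads are generated and corrupted, how artefacts are
recognised, when a typing is repeated, how pooling is normalised without
quantification, and how fast novel alleles keep appearing. It deliberately
does **not** reproduce a production genotyping algorithm, flow-cell physics,
machine-learning plausibility checks, or locus-specific logic for KIR/blood
group markers; those are out of scope by design.

# The synthetic registry: a stated world

The generator's defaults are the operating conditions reported for a large
European registry laboratory, fixed once and not tuned to test outcomes.

## DNA concentrations

Per-provenance buccal-swab concentrations are log-normal. The printed
calibration triples (median, 5% and 95% quantiles, ng/μl) are DE
(26.5, 4.8, 83.7), PL (33.5, 5.5, 101.0) and UK (18.7, 3.9, 62.7). For a
log-normal, `mu = log(median)` reproduces the median exactly; `sigma` is the
least-squares fit to the two log quantiles, which reduces to
`sigma = (log(hi) - log(lo)) / (2 z_0.95)`. The printed ranges are not exactly
log-symmetric, so the fitted 5%/95% quantiles carry a residual misfit (UK:
fitted 4.7/75.0 vs printed 3.9/62.7); the two-parameter family cannot do
better and the median — the quantity the acceptance property checks — is
exact. The second swab is drawn with correlation `r = 0.79` on the log scale,
reflecting that a donor's swabbing technique, not chance, drives yield.

## Workflow routing and the primer-dimer model

Routing is threshold-based and strict: `C < 2` ng/μl rejected, `C < 18`
ng/μl to the 384-well 2-PCR 2-primer workflow, else the nanofluidic 1-PCR
4-primer workflow. The PD fraction is piecewise linear with a knee at
30 ng/μl:

```
pd(C) = baseline + slope * max(0, 30 - C),   clipped to [0, 1]
```

with baselines 3.25% (nanofluidic) and 0.9% (384-well) and slopes 3.4 and 2.7
percentage points per ng/μl less DNA — the operational estimates from the
low-concentration stratum. A caveat stated here once: extrapolating the
384-well slope from the knee down to 2 ng/μl yields PD fractions far above
what that workflow shows in production (its observed rates stay near 1%); the
package keeps the specified linear-knee form because the slope round-trip
property is defined on it, but users modelling the 384-well workflow
realistically should set its slope near zero. For read emission the fraction
is additionally capped at 0.99 so the compensating Poisson total stays finite.

A PD read is a random 16–24 nt primer followed by the read-through adapter and
a low-quality runoff tail (Q2–Q15); on-target bases sit at Q33–Q40. This is
the minimal quality model that reproduces the one constrained behaviour: %Q30
falls monotonically as the PD fraction rises. No per-base quality model is
asserted beyond that direction.

## Read yield, chimeras, errors, dropout

Total on-target reads per sample follow `R = C/(C + K_m) R_max` with a
Poisson draw about the mean, split over amplicons with mildly uneven
deterministic weights (mirroring primer-efficiency imbalance). The defaults
`K_m = 10` ng/μl, `R_max = 60000` reads are package choices — no published
estimates exist — sized so a median sample yields a few tens of thousands of
reads, as in production.

Heterozygous amplicons emit single-crossover chimeras at a per-amplicon rate
(default 15.2% for HLA-C exon 3, the consistently worst amplicon; 0.1% for
the near-invariant class II exon 3 amplicons; 5% otherwise). The breakpoint
is uniform over positions with at least one discriminating site on each side;
multi-breakpoint products are not modelled, as they are not quantified
anywhere. Every emitted base mutates independently at `error_rate` (default
1e-3, a typical Illumina amplicon substitution load; PCR and sequencing error
are not separated).

Allelic dropout is logistic in concentration,
`p(C) = p_max / (1 + exp((C - c50)/scale))`, per allele per locus, with
`p_max = 0.10, c50 = 5, scale = 2` on the nanofluidic workflow and
`p_max = 0.01` on plates. The functional form is a package choice (only the
direction — dropout worsens at low concentration on nanofluidics — is
documented operationally); it is flagged as such in the configuration help
and the logistic's smoothness is not load-bearing for any test.

Allele panels are synthetic: no real reference sequences are shipped. Each
allele differs from every other allele at one deterministic marker position
per amplicon span plus ~15–20 random substitutions (~7% divergence), giving
random pairs ~30 informative sites per span — the hyperpolymorphism that
makes chimera detection meaningful. Frequencies follow a rank power law
(exponent 1.5) with a small configurable mass (default 0.2%) on hidden novel
alleles.

## What the generator does not emulate

Index hopping, cluster-density physics, PF-read yield, contamination,
co-amplification of paralogues (DRB3/4/5, HLA-H), quality degradation along
the read, and batch effects are absent. A green round-trip test therefore
establishes that the *detectors recover the generator's structure*, not that
they would perform identically on production data; the oracle-equivalence
tests (brute-force sliding-window scan, exhaustive breakpoint search, closed
form accumulation) are generator-independent and carry that part of the
burden.

# Artefact detection

Primer-dimer detection scans both mates for a 12-base adapter prefix with at
most one mismatch and reports the leftmost in-bounds offset (0-based).
Amplicon assignment uses a shared 15-mer vote against all allele span
sequences with Hamming-identity confirmation (≥80%) — full alignment is
unnecessary because synthetic amplicons are frame-aligned; ties break
lexicographically by amplicon id.

Chimera detection evaluates every breakpoint in both parent orders and
requires the best split to beat the best pure parent by `margin = 2`
mismatches with at least `min_flank` informative positions on each side. The
packaged default is `min_flank = 3`, a deliberate deviation from the
originally drafted 10: with breakpoints uniform over informative intervals, a
flank requirement of 10 makes every breakpoint outside the 10th…(n−9)th
informative site structurally undetectable, and recovery of a 15.2% true
chimera rate within ±3 percentage points is then impossible for realistic
divergence (n ≈ 30–40). With `min_flank = 3` the detector still never fires
on pure-parent reads carrying ≤2 errors (the margin dominates) and the
recovery target is met. Per amplicon, the two most abundant exact sequences
act as parents and calls are kept only while each parent count ≥
`parent_ratio ×` the chimera count (`parent_ratio = 1`; the production
criterion "not significantly outnumbered" is nowhere quantified, so the
neutral ratio is declared, not inherited).

# Genotype calling

Clustering is exact-sequence after discarding reads with any base < Q10;
clusters under 10% of the amplicon's reads are dropped — at a 1e-3 error rate
over 250 nt, ~22% of reads carry errors but scatter across many singleton
sequences, so true clusters stand far above the filter. Calling matches the
top ≤2 clusters per amplicon exactly against the panel and searches allele
pairs consistent across exons; an unmatched consensus becomes a novel
placeholder that wildcards on the other exon (a novel allele's second exon
is unknown). Ties prefer full-coverage pairs, then higher summed panel
frequency, then lexicographic order. Flags: depth < 100× (the operational
sufficiency threshold), on-target rate < 50%, minor/major balance < 0.25
(the "heavy imbalance" bound is unquantified; 0.25 is the declared default),
>2 surviving clusters, no consistent pair, novel signature. Dropout of one
allele yields a clean homozygous call by construction — the caller is
*required* to fall into that trap so the QC layer's role is visible.

# QC policy

"Fails to produce credible results" is operationalised as "any
repeat-triggering flag". Only the six HLA loci count toward the
more-than-four rule (whether other markers count is unstated; they do not
here). Novel-allele confirmation requires byte-identical consensus from an
independent PCR — any tolerance would blur the artefact/novel boundary the
error-rate arithmetic rests on. Analyst-discretion repeats enter through an
explicit override hook rather than a model.

# Michaelis-Menten fitting

`fit_mm` minimises raw-read squared error. For fixed `K_m` the optimum
`R_max` is linear least squares in closed form, so the problem reduces to 1-D
minimisation over `log K_m` (golden-section, tolerance 1e-10), bracketing the
data-driven initial guess (95th percentile of reads; concentration at half
that by interpolation). This profiled approach is exact on noiseless data,
where `nls()` fails outright with zero residuals — the reason `nls()` is not
used. After the first fit, the top and bottom 0.5% of residuals are trimmed
and the model refitted once (soft outlier control; the production fitting
procedure is unspecified). Degenerate designs — fewer than 10 points, less
than a 4-fold concentration range, or constant concentration — are rejected.

Pooling factors are `clamp(R_ref / predicted, 1, 4)`: the reference is the
90%-of-saturation point (`9 K_m`), an arbitrary anchor that only shifts all
factors jointly before clamping; the cap of 4 reflects that physical pool
volumes cannot grow unboundedly. Samples under 5 ng/μl are flagged as not
fully compensable.

# Discovery forecasting

`discovery_curve` permutes samples without replacement, partitions them into
consecutive bins, and counts first occurrences per bin, averaging over 30
permutations. The estimator is unbiased for the iid expectation
`Σ_j (1 − (1 − p_j)^{mn})`; in the validation tests the comparison uses the
binomial variance of per-bin first occurrences as the error scale, because
replicates share one realised ledger and the rep-to-rep SD alone understates
the total uncertainty.

`fit_decay` fits `r(n) = c + a e^{−bn}` — the canonical 3-parameter
exponential-decay family; the nonzero asymptote `c` is what lets class II
projections keep growing linearly at long horizons. `(a, c)` are profiled out
by constrained linear least squares and `b` optimised on the log scale; bin
midpoints are the abscissae (edges would shift `b` slightly; midpoints are
declared). Whether production fits used midpoints or bin indices, and whether
projections summed discrete bins or integrated, is unknowable from the
outside: both abscissa conventions are exposed
(`abscissa = "samples" | "bin_index"`), and projection integrates the fitted
rate in closed form, an `O(bin)` difference from discrete summation.
Non-decaying curves degrade to `a = 0` with a warning rather than chasing a
negative amplitude.

Desk-scale validation uses 14,000-sample ledgers (a 100× scale-down of the
production horizon) with a power-law hidden-allele spectrum (1,000 alleles,
exponent 1.5, total draw mass 1% — inflated ~10× over the production flagged
rate so that a 14-bin curve is estimable from hundreds rather than tens of
events; stated here once). The acceptance property asserts projection at 2×
the horizon within 15% of the analytic truth in the median over 50
replicates. The printed production projections at 3/6/9 M samples are *not*
reproduced: they require the real 1.43 M-donor ledger, which does not exist
publicly.

# Reporting and rounding

All accounting is integer arithmetic until final rounding, which is
half-away-from-zero at the printed precision (three decimals for the flagged
rate — 0.0805…% prints as 0.081% — one for class fractions, two for the
error rate). The recomputed confirmed fraction is 26.6% (3,674/13,835);
contemporaneous reports quoted 26.4%, which is not reproducible from the
printed counts, so the summary reports the recomputed value and carries the
discrepancy as a footnote rather than matching the quote. The masking
probability implements the stated collision argument
`error_rate / (L (A−1))` with every input echoed; the order-of-magnitude
"one in five million" folklore figure is deliberately not asserted anywhere,
as its exact derivation is not stated.

# Known limitations

* The PD linear-knee model overstates 384-well PD rates at very low
  concentrations (see above).
* Exact-sequence clustering cannot merge true clusters split by systematic
  errors; it is adequate at the simulator's error rate but would undercall at
  error rates an order of magnitude higher.
* Chimera detection is restricted to the two most abundant parents per
  amplicon; target/off-target chimeras (paralogue co-amplification) are
  acknowledged as especially challenging and excluded by default.
* Forecasts assume a stationary donor population; a shift in ethnic
  composition changes the hidden spectrum and invalidates the decay fit.
* Acceptance criteria at production scale (repeat-rate time series, printed
  3/6/9 M projections) are replaced by property-based desk-scale checks; a
  green suite shows internal consistency and oracle agreement, not
  reproduction of the operational history.
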