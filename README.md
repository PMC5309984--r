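# hlaflow

Simulation and quality-control machinery for registry-scale amplicon HLA
genotyping.

Large stem-cell donor registries type millions of donors per year for the six
classical HLA loci (HLA-A, -B, -C, -DRB1, -DQB1, -DPB1) by short-amplicon
next-generation sequencing of the core exons 2 and 3. At that scale the
workflow's failure modes — primer dimers, PCR-mediated chimeras, allelic
dropout at low DNA concentration, uneven read yield — become quantifiable and
must be managed by explicit policy. `hlaflow` re-implements that quantitative
machinery as a tested, reusable R package for people who develop or audit such
pipelines:

* **`synthetic_registry`** — a generator of donor samples, allele panels with
  hidden novel alleles, and paired-end amplicon FASTQ reads carrying the
  statistical structure of real registry data: per-provenance log-normal DNA
  concentrations, saturation-shaped read yield, concentration- and
  workflow-dependent primer-dimer rates, per-amplicon chimera rates, PCR point
  errors and allelic dropout.
* **`artefact_detection`** — per-read classification (primer dimer / on-target /
  chimera / off-target) and run metrics (%Q30, PD rate, per-amplicon chimera
  rate).
* **`genotyping`** — a simplified consensus caller with novel-allele signature
  detection.
* **`qc_policy`** — the routing, repeat-typing and novel-allele verification
  rules as a pure decision engine.
* **`normalisation`** — Michaelis-Menten read-yield modelling and
  quantification-free post-PCR pooling volumes.
* **`discovery_forecast`** — binned-resampling discovery curves, 3-parameter
  exponential-decay fitting and projection of distinct novel alleles, with an
  analytic accumulation oracle.
* **`reporting`** — novel-allele accounting (ships the published per-locus
  counts as a fixture), maximum PCR error rate, masking probability and the
  PD-vs-concentration slope.

## The models at the core

**Read yield.** Final reads per sample saturate with input DNA concentration
`C` following a Michaelis-Menten law

```
R = C / (C + K_m) * R_max
```

with half-saturation constant `K_m` (ng/μl) and maximum achievable read number
`R_max`. Fitting `(K_m, R_max)` lets the lab predict relative yield from `C`
alone and equalise coverage by scaling per-sample pool volumes
(`pooling_volumes()`), skipping per-product quantification entirely. Samples
below 5 ng/μl cannot be fully compensated and are flagged.

**Primer dimers.** PD inserts are shorter than the read, so the sequencer runs
off into the adapter and produces a low-quality tail: detection is an adapter
scan (`detect_primer_dimer()`), and %Q30 falls as the PD fraction rises. The
simulated PD fraction is `baseline + slope * max(0, 30 - C)` per workflow,
with slopes of 3.4 (nanofluidic) and 2.7 (384-well) percentage points per
ng/μl less DNA.

**Chimeras.** A single-crossover recombinant of the two alleles of a
heterozygote. `detect_chimera()` minimises over every breakpoint `k` the split
score `mm(read[0:k], A) + mm(read[k:], B)` (both orders) and calls a chimera
only when the split beats the best single parent by a margin; calls are
suppressed when the parents are outnumbered by the recombinants, as in
production filters.

**Repeat policy.** Samples below 2 ng/μl are rejected to a second extraction;
below 18 ng/μl they move to the 384-well workflow. A locus is repeated iff any
quality flag is raised; a full sample repeat is triggered below 2 ng/μl or
when more than 4 of the 6 HLA loci fail. Potential novel alleles are confirmed
only by a byte-identical consensus from an independent PCR.

**Discovery forecasting.** Novel-allele events are resampled into consecutive
bins of 10^5 samples (30 random orderings); the per-bin discovery rate is
fitted with `r(n) = c + a exp(-b n)` and integrated in closed form to project
distinct-allele counts at 3, 6 and 9 million samples. The analytic oracle
`E[distinct] = Σ_j (1 - (1 - p_j)^(m n))` validates both steps.

## Worked example

```r
library(hlaflow)

panels <- default_panel_set(n_known = 10, n_novel = 2, seed = 7)
cfg    <- registry_config(mm_truth = list(km = 10, rmax = 12000), seed = 7)
panel  <- panels[["HLA-C"]]

donor <- list(id = "S000001", conc = 9.5, workflow = route_workflow(9.5),
              genotype = list("HLA-C" = panel$alleles$allele[c(1, 4)]))
donor$workflow
#> [1] "plate384"

sim <- simulate_reads(donor, panels["HLA-C"], cfg, seed = 11)
res <- classify_run(sim, panels["HLA-C"])
res$metrics
#> run metrics over 13612 read pairs
#>   on-target 0.426 | primer dimer 0.562 | off-target 0.012
#>   chimera rate (of on-target+chimera): 0.000
#>   %Q30: 55.7%

gt <- genotype_sample(res, sim, panels["HLA-C"])
gt[["HLA-C"]]
#> HLA-C: C*k001 / C*k001
#>   depth: 2634,1843 | balance: 1.00 | flags: low_on_target

locus_repeat_decision(gt[["HLA-C"]])
#> repeat [locus] reasons: low_on_target (loci: HLA-C)
```

At 9.5 ng/μl the PD model puts more than half of the reads into primer dimers,
dragging %Q30 to 55.7% and the on-target rate below the 50% threshold — the
locus is sent to repeat typing. The example also shows the *silent dropout*
hazard: the donor is truly heterozygous (`C*k001/C*k004`), but allele `C*k004`
dropped out during amplification (`sim$dropouts`), so the caller returns a
perfectly balanced homozygous call. Nothing in the reads distinguishes it from
a real homozygote; only the repeat triggered by the independent quality flags
can catch it.

```r
# Michaelis-Menten normalisation
set.seed(7)
conc  <- exp(runif(400, log(2), log(150)))
reads <- rpois(400, predict_reads(list(km = 10, rmax = 60000), conc))
fit_mm(conc, reads)
#> Michaelis-Menten read-yield model (n = 396)
#>   K_m   = 10.02 ng/ul
#>   R_max = 60049.7 reads
#>   residual SD = 190.8

pooling_volumes(c(4, 12, 40, 90), fit_mm(conc, reads))
#>   conc predicted   factor compensable
#> 1    4  17135.75 3.153915       FALSE
#> 2   12  32728.48 1.651305        TRUE
#> 3   40  48023.02 1.125391        TRUE
#> 4   90  54035.30 1.000174        TRUE

# discovery forecasting at desk scale (14,000 samples, bins of 1,000)
p   <- power_law_spectrum(1000, 1.5, total_mass = 0.01)
led <- simulate_novel_ledger(14000, p, m = 2, seed = 7)
cur <- discovery_curve(led, bin_size = 1000, n_reps = 30, seed = 7)
fit <- fit_decay(cur)
fit
#> exponential decay r(n) = 2.41 + 11.02 * exp(-0.0008087 n)  [per 1000-sample bin, n in samples]

project_discoveries(fit, cur$observed_distinct, 14000, c(28000, 42000))
#>   target_n  expected expected_rounded
#> 1    28000  80.73686               81
#> 2    42000 114.47356              114
```

47 distinct alleles were observed in 14,000 samples; the decay model projects
81 at twice the horizon, against an analytic truth of 83.2 — within 3%.

The reporting module recomputes the published novel-allele accounting from the
raw per-locus fixture: 3,674 confirmed novel alleles (858 class I vs 2,816
class II) representing 1,919 distinct sequences, a flagged-typing rate of
0.081% of 17,184,548 typed alleles, and a maximum PCR error rate of 0.06%:

```r
print(novel_allele_summary())
```

## Command line

A thin CLI wraps the same functions (`simulate`, `classify`, `normalise`,
`forecast`, `report`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hlaflow", package = "hlaflow"))')
Rscript "$CLI" report --fixture table2 --out report.json
Rscript "$CLI" simulate --out-dir sim/ --seed 1
```

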