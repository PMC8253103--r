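# hlabench

Consensus benchmarking of in-silico HLA genotyping tools, per-tool error
profiling, ensemble genotype calling, and the downstream immuno-survival
analysis that links HLA supertypes, tumor mutation burden and immune
cytolytic activity to overall survival.

## The problem

In-silico HLA genotyping from whole-exome reads is performed by many tools
(POLYSOLVER, OptiType, xHLA, HLA-HD, ...), and they disagree — with no
per-sample gold standard available for large cohorts, none of them can be
scored directly. `hlabench` takes the ensemble view: every tool is treated
as an expert voter, each called allele copy is one vote, and for every
sample and gene the most concordant alleles with **at least two votes from
at least two tools** form a *benchmark genotype*. Each tool is then scored
against that benchmark, its systematic confusions are quantified, and a
top-ranked subset of tools is integrated into a single ensemble genotype
that outperforms any constituent.

For two-field alleles (e.g. `A*25:01`), with calls classified per allele
copy as right (matched by the benchmark, as a multiset), wrong (emitted
but not in the benchmark) or uncalled (not emitted):

```
recall   = right / (right + wrong)
accuracy = right / (right + wrong + uncalled)
```

Per-tool error patterns use allelic counts (a homozygote counts twice):

```
general error rate(i)      = miscalled copies of allele i / benchmark copies of allele i
specific error rate(i, j)  = miscalls of i emitted as j   / all miscalled copies of i
```

Downstream, the package computes per-sample immune covariates and tests
the "Gun-Bullet" model — an HLA supertype is the gun, mutations are the
bullets, and their joint presence drives the immune response:

* **CYT** = `sqrt((GZMA + 0.01) * (PRF1 + 0.01))`, the offset geometric
  mean of the two cytolysis effector transcripts (TPM);
* **TMB** = nonsynonymous somatic mutations (13-keyword
  `One_Consequence` filter) per Mb of coding sequence;
* **supertype presence** from class I benchmark alleles, optionally
  demoted by allele-level loss of heterozygosity (LOH);
* median splits of CYT/TMB within each cancer condition
  (type x early/advanced stage), the four presence-by-TMB Gun-Bullet
  cells, and Kaplan-Meier / log-rank / Cox proportional-hazards
  comparisons between them.

A seeded synthetic-cohort generator (`sim_config()`, `simulate_cohort()`)
emulates multi-tool calls with tool-specific confusion pairs and dropout,
expression with a strong-supertype-by-high-TMB interaction, and
CYT-driven proportional-hazards survival, so the full pipeline is
testable without controlled-access cohort data.

## Worked example

```r
library(hlabench)

cfg  <- sim_config(seed = 7, n_samples = 300)   # 8 simulated tools, genes A/B/C
coh  <- simulate_cohort(cfg)
bench <- build_benchmark(coh$calls)
bench$report
#>   gene  complete partial unresolved
#> 1 A          300       0          0
#> 2 B          300       0          0
#> 3 C          300       0          0

ev <- evaluate_tool(subset(coh$calls, tool == "tool1"), bench, tool = "tool1")
ev$metrics
#>   class genes right wrong uncalled recall accuracy
#> 1 I     A,B,C  1722    78        0  0.957    0.957
head(ev$general_errors, 3)
#>   allele  benchmark_allelic_count miscalls   rate
#> 1 A*25:01                      27       21 0.778      # tool1's planted confusion
#> 2 B*58:01                      23        3 0.130
#> 3 B*51:01                      38        3 0.0789

ee <- evaluate_ensemble(coh$calls, bench,
                        ensemble_config(c("tool1", "tool2", "tool3"),
                                        genes = c("A", "B", "C")))
ee$metrics[c("tool", "class", "recall", "accuracy")]
#>   tool     class recall accuracy
#> 1 tool1    I      0.957    0.957
#> 2 tool2    I      0.963    0.963
#> 3 tool3    I      0.933    0.933
#> 4 ensemble I      0.993    0.993   # the vote-plus-fallback ensemble beats all three

rec <- immuno_table(bench, coh$phenotypes$expression, coh$phenotypes$maf,
                    coh$phenotypes$clinical, cfg$supertype_map, "B44")
rec$group <- as.character(rec$gun_bullet)
compare_survival(rec, c("present&high", "absent&low"))
#>   n_a n_b deaths_a deaths_b median_a median_b logrank_p        hr
#>    79  73       23       48       NA    799.8   1.96e-06  0.316
```

Read as: tool1 calls 95.7% of benchmark allele copies correctly but
miscalls 78% of its `A*25:01` copies (its planted signature confusion);
the top-3 ensemble lifts accuracy to 0.993; and under the planted
Gun-Bullet interaction, B44-present/high-TMB patients never reach median
follow-up mortality while absent/low patients have a median OS of 800
days (hazard ratio 0.32).

The interpretation of each knob, the voting and pairing rules, and the
generator's assumptions are documented in
`vignettes/hla-benchmarking.Rmd`.

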