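---
title: "Consensus HLA benchmarking and the Gun-Bullet survival model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus HLA benchmarking and the Gun-Bullet survival model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlabench)
```

This vignette is the package's account of its methods: the consensus
model and its assumptions, the exact decision rules where the informal
description leaves room, the parameters that matter, what the synthetic
cohorts do and do not emulate, and the known limits of each piece.

## 1. Allele nomenclature

All comparisons happen at two-field ("4-digit", protein-level)
resolution. `parse_hla()` accepts the dialects genotyping tools actually
emit — with or without the `HLA-` prefix and the `*` separator, one to
four colon-separated numeric fields — and `hla_normalize()` truncates to
the first two fields (`A01:01:03` becomes `A*01:01`). Three deliberate
rules:

* **Fields are text, left-padded to two digits.** `A2:1` and `A02:01`
  are the same allele; fields longer than two digits (`C*06:103`) are
  preserved verbatim. Numeric comparison would silently merge distinct
  alleles with leading zeros.
* **A one-field call is never equal to a two-field allele.** A tool
  emitting `B58` against a benchmark `B*58:01` has made a miscall, not a
  partial hit: evaluation counts it wrong, and the specific-error
  machinery can report the pair (`B*58:01` -> `B*58`) like any other
  confusion. Crediting low-resolution output would reward tools for
  refusing to commit.
* **Supertypes apply to class I only.** The presence analysis depends on
  peptide-binding-pocket sharing, which is defined for A/B/C molecules;
  querying a class II allele is a domain error, and class I alleles
  absent from the map are `"unclassified"` rather than an error, because
  every cohort contains rare alleles outside any published scheme. The
  map ships as an editable TSV
  (`inst/extdata/supertype_map.tsv`, twelve labels seeded from the
  Sidney-style functional classification); it is data, not code, because
  the classification itself evolves.

## 2. Consensus ("benchmark") genotypes by allelic voting

For one sample and gene, each tool contributes one vote per called
allele copy — a homozygous call casts two votes. Per-copy voting is what
keeps the benchmark's allelic counts (homozygote = 2) consistent with
the denominator of the general error rate later; voting per tool-mention
instead would make the two bookkeeping systems disagree on homozygotes.

A slot of the benchmark genotype is filled by the highest-voted allele
with **at least two votes from at least two distinct tools**; the second
slot takes the next-highest distinct such allele. The two-tool
requirement means a single tool's homozygous call (two votes from one
voter) can never establish consensus on its own. A homozygous benchmark
(same allele in both slots) additionally requires **two tools calling
that allele homozygous** — otherwise one tool's double vote plus an
unrelated heterozygous vote could fabricate homozygosity. Pairs that
fill both slots are `complete`; one slot, `partial`; none, `unresolved`.
Only `complete` genotypes serve as truth in evaluation — scoring a tool
against a consensus that does not exist is meaningless — and
`unresolved` pairs are excluded from the evaluation denominators.

Exact vote ties for the last open slot are broken lexicographically and
flagged `ambiguous`. The tie rule is arbitrary by necessity; what
matters is that it is deterministic (reruns are byte-identical) and
auditable (the flag survives into the output table).

Population summaries expose both counting conventions: the *population
count* (samples carrying the allele at least once) and the *allelic
count* (benchmark slots, homozygotes twice). Population frequency
divides by the samples with any resolved genotype in the allele's class
— class I and class II denominators differ because tools differ in
class support. Because the corresponding "allelic frequency" denominator
is genuinely ambiguous (all slots of the class, or of the gene?),
`allele_frequency_table()` reports both (`allelic_frequency_class`,
`allelic_frequency_gene`) rather than guessing.

## 3. Scoring a tool

Each evaluated (sample, gene) pair contributes exactly two slots.
Predicted alleles are matched against the benchmark as **multisets**
(order never matters; a homozygous prediction can consume at most the
benchmark's copies). Matched predictions are right; unmatched
predictions are wrong; slots the tool did not emit are uncalled. A gene
entirely absent from a tool's output is two uncalled slots per sample —
this is what separates recall from accuracy, and reproduces the
field-familiar pattern of a tool that cannot call one gene of a class:
recall stays high while accuracy drops by the gene's share of slots. The
gene scope is an argument, so "accuracy on supported genes only" is the
same call with a restricted scope.

The miscalls of allele *i* — its benchmark copies the tool failed to
match while still reporting the gene — feed Eq.-style rates:

* `general_error_rate(i) = miscalls(i) / benchmark_allelic_count(i)`;
* `specific_error_rate(i, j) = miscalls of i paired with prediction j /
  miscalls(i)`.

Pairing wrong predictions with missed benchmark alleles is
underdetermined when both slots are missed. The package pairs by
maximal shared field prefix (same first field wins), then
lexicographically, and flags pairings that were settled
lexicographically — real confusion pairs overwhelmingly share the first
field (`C*03:03`->`C*03:04`), so the prefix heuristic recovers the
intended pair and the flag marks the rest. When the tool emitted only
one (wrong) allele, the second missed benchmark copy still counts
toward the general error rate but contributes no pair: general and
specific numerators stay mutually consistent, and the specific rates of
an allele sum to at most 1, with equality whenever every miss is
pairable.

Rates are stored at full precision. `as_percent()` renders half-up to
two decimals only in reports, matching how such tables are printed.

## 4. The ensemble rule

Given tools ranked by standalone accuracy, the ensemble accepts any
allele with two per-copy votes from two roster tools; remaining slots
fall back to the highest-ranked tool that reported the gene, consuming
its call as a multiset (so a homozygous rank-1 call can fill both
slots, and a concordant allele consumes the matching copy before the
fallback is read). Two edge rules the informal description leaves open:
if three or more alleles reach two votes (possible with homozygous
calls), the two with most votes win, ties preferring the rank-1 tool's
own alleles, then lexicographic order; and when one slot is concordant
but the rank-1 tool disagrees with it entirely, the concordant allele
stays and only the remaining slot is filled from rank 1 — concordance
outranks any single tool by construction.

The ensemble's advantage rests on **error independence**: the tests
demonstrate both the success mode (three independent 5–10% tools,
ensemble accuracy above every constituent in 19/20 seeds) and the
documented failure mode (a confusion pair shared by all three tools
passes the vote and survives in the ensemble untouched).

## 5. Immune covariates

* **CYT** `= sqrt((GZMA + 0.01)(PRF1 + 0.01))`, TPM in, no log
  transform, no renormalization. The 0.01 offset keeps the score
  defined at zero expression (floor 0.01); the geometric mean is
  symmetric and strictly monotone in both transcripts.
* **TMB** counts `One_Consequence` values in the 13-keyword
  nonsynonymous set and divides by the coding length in Mb. The coding
  length is a parameter defaulting to **38 Mb**, a conventional
  whole-exome coding footprint; since published cohort medians depend
  on the exact footprint used, TMB values are comparable within a run,
  not across pipelines, and every output table records the value used.
* **Median splits** are within cancer condition (type x early/advanced
  stage): strictly above the condition median is `high`, at or below is
  `low`. The tie-goes-low rule is stated and tested; with continuous
  scores ties have measure zero, but mutation counts are discrete and
  need a rule. Conditions with fewer than two values are skipped with a
  warning; an all-tied condition degenerates to all-`low` and warns.
* **Stage** normalizes free text: sub-stage suffixes are stripped
  (`stage iiib` -> `iii`); 0/i/ii are early, iii/iv/x advanced;
  anything else is excluded with a warning rather than guessed.
* **Overall survival**: alive -> censored at `days_to_last_follow_up`;
  dead -> event at `days_to_death`; a dead record without
  `days_to_death` is rejected (not silently rescued from the follow-up
  field), and rejections are returned as an attribute.
* **Supertype presence** is carried by any mapped class I allele; with
  an LOH table (allele-level events at p <= 0.05 coverage imbalance),
  a lost allele no longer confers presence. LOH can only demote —
  a property the tests assert — because losing an allele can remove a
  peptide-presentation route but never add one. Presence is computed
  from whatever resolved class I slots a sample has; a sample with no
  resolved class I genotype is reported `absent`-by-default only if it
  appears in the benchmark at all, otherwise it is simply missing from
  the table.
* **Gun-Bullet cells** cross presence with the TMB group; the three
  contrasts of interest are presence vs absence, the concordant
  extremes (`present&high` vs `absent&low`) and the discordant cells
  (`present&low` vs `absent&high`).

## 6. Survival machinery

Kaplan–Meier curves, the two-group log-rank test and Cox
proportional-hazards fits are delegated to the `survival` package —
these are standard estimators, and reimplementing them would add risk
without adding science. Three contracts are pinned down on top:

* **Median survival** is the earliest time with S(t) <= 0.5. At an
  exact 0.5 plateau `survival::survfit` averages the plateau endpoints;
  the package computes the median from the curve instead, so the
  convention is uniform.
* **Ties** use the Breslow approximation — the simplest defensible
  choice, and the one the test oracle (a grid search over the Breslow
  partial likelihood) checks to 1e-4 on small fixtures.
* **Degenerate designs** are reported, not crashed on: a constant
  covariate yields coefficient 0 / HR 1 with a `degenerate` flag
  without entering the fit; suspected monotone likelihood (perfect
  separation) is flagged `separation`.

Wald confidence intervals default to 95%. Age dichotomization at 60 is
a convention of the cohort tables this mirrors, passed as an ordinary
covariate rather than hard-coded.

## 7. What the synthetic cohorts emulate — and what they do not

`simulate_truth()` draws two allele copies per gene independently from
a per-gene frequency pool (Hardy–Weinberg sampling).
`simulate_tool_calls()` miscalls each copy independently with the
tool's per-allele rate; a miscall lands on the tool's dominant
confusion partner with probability `dominant_mass` (default 0.9) and
otherwise uniformly on another pool allele of the gene; whole
(tool, gene, sample) calls drop out with a per-gene probability. The
default roster of eight tools mirrors the qualitative error anatomy of
real genotypers: one tool with a catastrophic rate on a single rare
allele, one emitting a low-resolution truncation (`B*58:01` -> `B58`),
one that never calls a gene, baseline errors of 2–12% elsewhere.

`simulate_phenotypes()` plants the Gun-Bullet structure: TMB is
log-normal per condition (default median 9.5 mutations/Mb, a
melanoma-like burden, realized as MAF rows with ~40% synonymous
decoys); GZMA and PRF1 are log-normal (baseline median 20 TPM, log-sd
0.5) with the means multiplied by `interaction_multiplier` (default
2.5) exactly when the strong supertype is present **and** TMB is above
the condition median; survival is exponential with hazard
`baseline_hazard * exp(beta_cyt * z)` where `z` is CYT z-scored within
condition (defaults 1/1500 per day and -0.8, i.e. protective CYT),
under independent uniform censoring on [0, 3000] days. Everything is
reproducible from one integer seed; the three generators use
`seed`, `seed + 1`, `seed + 2` so that truth is unchanged when only the
downstream stages are regenerated.

What this deliberately does **not** emulate: linkage disequilibrium
between HLA genes, ambiguity structure of real read alignment,
correlated errors between tools (available as an explicit failure-mode
configuration, not a default), nonexponential baseline hazards, and
informative censoring. Passing tests on these cohorts therefore
demonstrate that the pipeline's logic is correct under its stated
assumptions — not that any particular real cohort satisfies those
assumptions.

## 8. Problem sizes and numerical checks in the test suite

The suite recomputes the published worked examples exactly (for
instance 371/435 -> 85.29% and 343/371 -> 92.45% through the full
voting-plus-evaluation path, and the 4400/10479 -> 41.99% population
frequency on a full-size voted benchmark); checks the metric identities
on a 1000-pair generated cohort; recovers planted general rates within
±0.03 and dominant confusion masses within ±0.05 on a 3000-sample,
8-tool cohort in which each planted allele exceeds ~2000 copies (pool
design matters here: with only two alleles per gene, independent
baseline errors all land on the same alternative and can vote spurious
slots into the benchmark, so the fixture uses five-allele pools);
verifies ensemble superiority over 20 seeds at 250 samples; checks the
Cox fit against a grid-search Breslow oracle to 1e-4, hazard-ratio
recovery (true HR 2, n = 500, 20 seeds, ±15%) and log-rank type-I
control over 200 null draws; and exercises the Gun-Bullet closure at
600 samples (planted) and 40 x 300 samples (null, judged by rejection
rates rather than a single three-test draw). These sizes keep the full
suite around two minutes on one CPU while leaving each statistical
assertion multiple standard errors of slack.

## 9. Known limitations

* The benchmark is a consensus, not truth: alleles that every tool
  miscalls the same way are invisible to it, and per-tool error rates
  against the benchmark are accordingly *lower bounds* near such
  correlated failures.
* G-group/P-group equivalences and novel-allele discovery are out of
  scope; nomenclature handling is purely syntactic.
* The supertype map is a snapshot; users with a newer classification
  should replace the TSV, not patch code.
* TMB depends linearly on the assumed coding footprint; only the
  keyword filter, not the footprint, is canonical.
* `coxph` here is the `survival` package's fit with Breslow ties; exotic
  designs (time-varying covariates, competing risks) are not exposed.
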