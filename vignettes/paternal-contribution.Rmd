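---
title: "Quantifying the paternal RNA cargo and its phthalate response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the paternal RNA cargo and its phthalate response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paternalRE)
```

## The scientific problem

Mature sperm deliver a defined cargo of RNAs to the oocyte at fertilization.
Because the zygote has not yet activated its own genome, every transcript
present there must have come from one of the two gametes. Working at the
level of RNA elements (REs) — exon-sized RNA fragments identified by a
genomic interval `chrom_start_end` and quantified in RPKM — this package
asks two questions:

1. Which zygotic REs are *paternally provided*, i.e. attributable to the
   sperm rather than the oocyte?
2. Of those, which respond to preconception dibutyl-phthalate (DBP)
   exposure in a crossover–crossback trial, and what biology do they touch?

## The contribution model

For an RE with zygote abundance $Z$, sperm abundance $s$ and oocyte
abundance $o$ (all RPKM, medians across biological replicates), the
paternal contribution is

$$Pc = Z - \frac{Z}{1 + s/o} = Z\,\frac{s}{s+o}, \qquad Mc = Z - Pc,$$

valid when $Z \le s + o$. When the zygote abundance exceeds what the two
gametes jointly supplied ($Z > s + o$) the decomposition is capped at the
gamete abundances themselves: $Pc = s$, $Mc = o$. Two edge cases are fixed
by the model rather than left to floating point:

* $o = 0$: the formula's limit assigns the whole zygote paternally,
  $Pc = Z$ (meaningful only on the uncapped branch, $Z \le s$). It is
  handled as the analytic limit, not by special-casing into the cap.
* $Z > 0$ with $s = o = 0$ has no defined decomposition and is an error in
  `compute_contribution()`; the classifier excludes such REs with reason
  `"undefined_contribution"` instead of aborting a whole run.

On the uncapped branch the decomposition conserves abundance
($Pc + Mc = Z$), is scale-equivariant, and $Pc$ is monotone in $s$ — all
verified to $10^{-9}$ by the test suite.

## Threshold classifiers

All thresholds are strict inequalities exactly as published, collected in
`re_thresholds()` so each is visible and overridable:

| rule | default |
|---|---|
| fivefold paternal: sperm median | > 25 RPKM |
| fivefold paternal: oocyte median | < 5 RPKM |
| zygote presence gate (both classes) | > 10 RPKM |
| twofold paternal: contribution ratio | $Pc > 2\,Mc$ |
| oocyte presence floor (sperm-specific) | < 2 RPKM |
| twofold presence-floor clause: sperm window | 2–25 RPKM |
| gene-level (RE-RNA) presence | > 5 RPKM |

The twofold class is evaluated only on REs outside the fivefold set and
outside any supplied prior maternal set (the classifier computes the
fivefold set itself when no prior list is given, so the two classes are
disjoint by construction). The twofold rule is the disjunction of the
contribution-ratio clause and the presence-floor clause (oocyte below
2 RPKM with sperm strictly between 2 and 25 RPKM) — the published
definition states them with an "or", and we follow that reading. The
sperm-specific flag marks any classified RE whose oocyte median sits below
the 2 RPKM floor, the level at which RE presence cannot be distinguished
from experimental noise.

Aggregation across biological replicates uses the median (configurable to
the mean): the fivefold rule is defined on medians, and we apply the same
aggregate to the twofold inputs for consistency. Gene-level rollup labels
an RE-RNA with a class if at least one of its REs carries it, so a gene
can legitimately appear in both class lists.

## Sample QC: the transcript integrity index

RNA degradation inflates 3' bias and erodes coverage. The TII guards
against this using a user-supplied panel of stable sperm transcripts
(22 in the intended panel; the package hard-codes none). A panel
transcript passes in a sample when at least 50% of its exon bases are
covered at ≥ 5 RPM; both comparisons are `>=`, reading "at least" as
inclusive at the threshold. The sample's TII score is the fraction of
panel transcripts passing. Samples scoring strictly below the 25th
percentile of all scores (linear-interpolation percentile,
`stats::quantile()` type 7) are assigned quartile 4 and excluded; ties at
the percentile are kept, so a run of identical scores removes nobody. The
sample-level aggregate and the quartile estimator are package choices —
the original TII literature defines the per-transcript statistic but not
this aggregate — and both are documented and configurable for that reason.

## Full-length integrity calls

The published integrity assessment was visual (genome-browser
inspection). The programmatic stand-in calls a transcript `FULL_LENGTH`
when every sample's coverage clears 5 RPKM at every exon base, `PARTIAL`
when some but not all samples do (rendered "Full-length (≥ 1 < n
samples)"), and `FAIL` when none does. The strict every-base default is
the most conservative reading of "covered across all exons"; because a
human eye tolerates small gaps, `min_fraction` relaxes the per-sample rule
to a fraction of bases. Borderline gap tolerance is unknowable from a
visual protocol; that uncertainty lives in this one parameter.

## Overlap statistics

Overlap between a DBP-responsive gene list (size $n_1$) and the paternally
provided list (size $n_2$) in a universe of $N$ genes is summarized by the
representation factor $x / (n_1 n_2 / N)$ — observed over expected under
the hypergeometric null — with one-sided over- and under-representation
probabilities. `p_over` includes the observed count ($P[X \ge x]$); the
two one-sided tails are reported separately, never doubled. The exact
tails come from the hypergeometric distribution; the normal approximation
uses the hypergeometric mean and variance with a ±0.5 continuity
correction (disable with `continuity = FALSE`).

The approximation has a validity domain: with the expected overlap below
roughly ten the hypergeometric is visibly skewed and no continuity-corrected
normal tracks it to 0.01. The validation suite therefore checks the 0.01
agreement band on universes of 5,000–10,000 with both list fractions at
10–50% of the universe (expected overlap ≥ 50), where the measured worst
deviation is below 0.007, and we recommend the exact method whenever the
expected overlap is small — it is never expensive at gene-list scale.

The universe is an explicit argument everywhere. The pipeline default is
every gene with at least one detected (non-zero) RE in the zygote input,
because an overlap question about zygotic REs is only meaningful against
genes that could have been observed there. Published overlap p-values are
not reproducible without knowing the universe their calculator assumed;
ours is always stated in the result object.

## Stratified over-representation analysis

DBP-responsive RE lists carry empirical (bootstrapped) p-values in
(0, 0.05]. To keep each enrichment query under the 500 recognized-gene cap
of gene-set services, entries are partitioned into six groups at the cut
points 0.013, 0.023, 0.032, 0.041, 0.045, 0.05. Group 1 is open on the
right (p < 0.013); the remaining intervals are left-open/right-closed, a
choice the published "between" phrasing leaves open — `partition_by_pvalue()`
documents it and takes the boundaries as an argument. A group exceeding
the cap is an error naming the group, never a silent truncation.

`ora()` is a local replacement for the web-service enrichment step:
hypergeometric upper-tail p per set against a user-supplied GMT
collection, Benjamini–Hochberg q within each collection separately
(collections are never pooled), reporting sets with at least a two-gene
overlap and q < 0.05, at most 100 rows, sorted by p. "Recognized genes"
means the intersection with the supplied symbol universe; symbol matching
uppercases both sides. The five-process assignment (cellular stress, cell
cycle, apoptosis, DNA damage response, gene regulation) was curatorial in
origin; `categorize()` reconstructs it as an explicit ordered keyword map
(`default_category_map()`) that users can edit — the shipped map is a
documented approximation, not data.

## Movement patterns and consistent responders

The crossover–crossback design yields two comparisons per study arm:
baseline → crossover and crossover → crossback. An RE's movement pattern
renders each segment as Up/Down only if that segment is flagged
significant — membership in the segment's DBP-responsive list, not a
re-test — and the visit means actually differ; otherwise Same. A
significant segment with exactly equal means is an error, since its
direction would be arbitrary. Labels render capitalized-first
("Down—same"), and the classification is invariant to shifting all three
means by a constant.

A gene is a *consistent responder* when, across the segments where it is
significant, it moves one way under every DBP-addition segment (B1H, BH2)
and the opposite way under every withdrawal segment (H1B, HB2), with at
least one observation under each condition. Single-condition genes and
genes with any internal contradiction are excluded.

## The synthetic-data generator

`simulate_abundances()` and its companions generate every input the
pipeline consumes, with planted truth, so the whole analysis is testable
without sequencing data. What it emulates, and how:

* **Study conditions.** 7 sperm samples (the paternal characterization
  used 7 non-IBD semen samples) and 3 oocyte / 3 zygote replicates (the
  external datasets are small; odd counts make the median an order
  statistic). 1,000 REs over 250 genes by default; the planted-recovery
  validation uses 5,000 REs.
* **Abundances.** Log-normal per-sample variation (σ = 0.25 on the log
  scale) around a planted per-tissue median, chosen because RPKM is
  strictly positive with a heavy right tail. The noise multipliers are
  re-centred so the realised sample median equals the planted median
  exactly — the margins below are then guarantees, not probabilities.
* **Planted classes at margin δ** (default 0.2): each planted median sits
  a relative distance δ on the correct side of every threshold it must
  clear or avoid — e.g. fivefold REs have sperm median ≥ 25(1+δ), oocyte
  ≤ 5(1−δ), zygote ≥ 10(1+δ); background REs with a passing zygote gate
  keep their contribution ratio below 2(1−δ). At δ = 0.2 classification of
  planted labels is exact; as δ → 0 only boundary REs can flip.
* **The capping branch.** A twofold RE must clear the 10 RPKM zygote gate
  while its sperm abundance stays below the 25 RPKM fivefold bound; at
  wide margins the required zygote median can exceed s + o, which is
  exactly the capped branch of the contribution model. The generator
  allows this, and additionally inflates a 5% `cap_rate` fraction of
  paternal REs above s + o, so both branches are exercised in every run.
* **DBP lists.** 120 responsive REs per segment with empirical p ~
  Uniform(0, 0.05]; 80% of entries drawn from the paternal gene list. The
  planted overlap fraction deliberately exceeds the paternal share of the
  simulated universe so the lists are genuinely over-represented, matching
  the direction of the real finding; with the 10%+10% planted class
  fractions the paternal list is a large minority of the small simulated
  gene pool, so a low overlap fraction would invert the enrichment.
  A planted subset of overlapping genes appears in all four segments with
  opposite directions under addition vs withdrawal; every other gene
  carries one fixed direction everywhere, so it can never satisfy the
  consistency rule and the planted consistent responders are recovered
  exactly.
* **Coverage.** A 22-transcript panel; good samples cover every base at
  ≥ 5(1+δ) RPM; planted poor-quality samples have 75% of panel transcripts
  decayed below threshold over 60% of their bases (5'→3' linear decay), so
  those transcripts fail the 50% rule exactly as designed and the sample's
  TII drops to 1 − 0.75.
* **GMT.** 50 sets of 10–40 genes from a 2,000-gene universe with one
  planted set whose members seed the query in validation runs.

Everything is a pure function of the seed; the same configuration is
byte-identical across runs.

What the generator does **not** emulate: read-level sampling noise,
library-size and gene-length biases, batch effects, correlated REs within
a transcript, and annotation ambiguity. Passing tests demonstrate that the
decision rules, statistics and bookkeeping are implemented exactly — not
that the thresholds themselves are robust to the messiness of real
sequencing data.

## Validation problem sizes

The shipped validation suites run at sizes chosen to be decisive yet
quick: the contribution suite on 2,000 random triples; planted-truth
recovery on 5,000 REs at δ = 0.2; exact-tail equivalence by full
enumeration of every feasible configuration up to a universe of 60;
normal-approximation agreement on universes of 5,000 and 10,000;
ORA planted-set recovery over 100–200 seeded replicates against a
2,000-gene universe; movement labels against the six published table rows
whose significance flags are unambiguous.

## Known limitations

* The p-value group boundaries' endpoint handling and the TII quartile
  estimator are documented conventions where the source protocols are
  silent; both are configurable.
* Gene-symbol recognition is plain uppercase matching against the supplied
  universe; no alias resolution is attempted, so recognized counts on real
  data will differ from any service that resolves aliases.
* The full-length call approximates a visual protocol; its gap tolerance
  is a free parameter, not an inferred quantity.
* Overlap p-values depend on the chosen universe; comparisons across
  universes are not meaningful.
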