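---
title: "Consensus calling across somatic variant callers: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus calling across somatic variant callers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusvc)
options(consensusvc.quiet = TRUE)
```

## The model

Run $n$ somatic variant callers on the same tumor (or tumor/normal pair),
normalize their calls to a common representation, and accept a variant
when at least $k$ of the $n$ callers report it. $k$ is the *minimum
intersection threshold*: $k = 1$ is the union of callsets, $k = n$ their
full intersection, and intermediate values trade precision against
sensitivity. The strategy rests on two empirical assumptions:

1. **Misses are weakly dependent.** A true variant dropped by one caller
   is usually kept by the others, so $k = n-1$ recovers most
   single-caller false negatives.
2. **False positives are largely caller-private.** Each algorithm has its
   own systematic error modes ("deterministic noise"), so FP sets overlap
   far less than TP sets and even a modest $k$ removes most of them.
   Random artefacts shared across callers ("stochastic noise", e.g.
   alignment errors feeding every caller) are the residual failure mode:
   they survive any threshold their support reaches.

Performance is scored against a truth set with precision
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$, sensitivity
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$, and their harmonic mean $F_1$.
`threshold_sweep()` evaluates every non-empty caller subset at every
threshold; SNVs and indels are always swept separately, as they behave as
distinct problems (different caller rosters, different error structure).

The shipped defaults encode the recommended heuristics: threshold `n-1`
for SNV ensembles (of at least three callers; with $n = 2$, `n-1`
degenerates to the union and the docs say so), and the full intersection
`n` for an indel caller *pair*.

## Variant normalization

Two callers only vote for "the same variant" if their records map to one
key, so matching is defined entirely by normalization:

* Coordinates are 1-based and inclusive, as in VCF, never converted.
* Alleles are upper-cased on ingest; comparison is case-insensitive.
* Multi-allelic records are decomposed per ALT, re-deriving per-allele
  support from `Number=A`/`Number=R` fields.
* Shared allele suffix is trimmed first, then shared prefix (advancing
  the position), while both alleles keep at least one base.
* MNVs are decomposed into their mismatching per-base SNVs. The SNV/indel
  dichotomy used throughout has no MNV category; decomposition keeps such
  calls in the SNV stream rather than inventing a third class. Every
  normalized variant is therefore exactly one of SNV or INDEL.
* With a reference sequence, indels are shifted to the leftmost position
  producing the same haplotype, anchored on one preceding reference base.
  At the very start of a contig, where no upstream anchor exists, the
  leftmost *valid* VCF form anchors on the following base instead; the
  implementation returns that form rather than failing.
* Symbolic ALTs (`<DEL>`, breakends) and spanning-deletion `*` alleles
  are outside the SNV/indel scope and are skipped with a tallied reason.

**Limitation:** without a reference FASTA only trimming is applied, so a
left-anchored and a right-anchored description of the same indel in a
repeat run will *not* match (a warning-level situation the read counters
expose). Matching is positional, not haplotype-aware: complex-region
equivalences that tools like `vcfeval` resolve by haplotype replay are
not attempted, and counts in such regions may differ from haplotype-aware
comparators.

## Caller dialects

Callers encode ALT depth, total depth and VAF in incompatible FORMAT
conventions. A *dialect* is an ordered list of extraction strategies
(`af` fractional tag, `ad` ref/alt pair, `percent` string, `alt_dp`
count + depth, `dp4` strand counts, Strelka tier counts); the first
strategy that resolves a field wins, and fields nothing resolves stay
*unknown* — never guessed. Presets for common callers ship as a plain
config file (`inst/extdata/caller_dialects.conf`); they are data, not
code, because no caller documents these conventions stably and users must
be able to override them. Tumor-sample selection: an explicit name wins;
otherwise a single-sample VCF uses its only sample; otherwise a sample
literally named `TUMOR`; otherwise the reader demands an explicit choice.

## Filters and their conventions

* **Low-stringency retention** (per caller, before consensus): FILTER
  `PASS` or `.`, ALT depth $> 3$, VAF $> 0.02$, all strict as printed.
  The filter is deliberately permissive — its job is to drop random
  sub-threshold noise while *keeping* each caller's systematic false
  positives for the vote to handle. Records with unknown support are
  retained by default here (permissive intent), overridable via
  `filter_policy(unknown_support = "drop")`.
* **Exome candidate filter**: depth $> 20$, ALT reads $> 5$, matched
  normal VAF $< 0.25$, tumor VAF $> 0.20$, called by $\ge 2$ callers; all
  comparisons strict. Unknown required fields yield `NA` (indeterminate),
  reported distinctly from `FALSE`. The "$>20\%$ VAF called by at least
  two callers" phrasing is ambiguous between *each* of two callers and
  *any* record of a 2+-supported site; this implementation tests the
  site's support count and a tumor VAF, the laxer reading, and flags the
  choice here.
* **Germline VAF windows**: true germline allele frequencies can only be
  heterozygous ($\approx 0.5$) or homozygous ($\approx 1.0$), so calls
  with VAF outside $[0.4, 0.6] \cup [0.9, 1.0]$ are noise. The window
  boundaries are **inclusive**: stated endpoints should behave as window
  members. Unknown VAF routes to the noise side — this analysis is about
  selectivity, so the conservative direction is the opposite of the
  retention filter's.
* **Subtraction**: somatic callsets can have germline calls and shared
  noise removed by key (`subtract_callsets()`); survivors keep their
  metadata untouched.

## Numerical conventions

* Zero denominators: precision, sensitivity and $F_1$ are defined as 0
  when undefined (empty acceptance or empty truth never arise in real
  use; the convention just makes degenerate sweep rows well-defined).
* Duplicate keys within one caller collapse to the record with the
  highest ALT depth; ties keep the first seen; unknown depth loses to any
  known depth.
* Per-subset best thresholds (`sweep_summary()$best_k`) break $F_1$ ties
  toward the **largest** $k$ — the most conservative acceptance.
* Threshold rules: the default `full` rule sweeps $k = 1..m$ per subset
  of size $m$; the alternative `methods` rule sweeps $k = 2..m$ with
  singletons at $k = 1$. The narrower rule is what the source protocol's
  text states, but its reported sweeps extend to $k = 1$, so the full
  rule (which subsumes both) is the default.
* Subset enumeration refuses rosters above 12 callers unless
  `allow_large = TRUE` (4095 subsets is already extreme for this use).
* Everything is deterministic given inputs and seed: identical arguments
  produce byte-identical outputs, including file order and VCF headers.

## The synthetic generator

`simulate_dataset()` instantiates the noise taxonomy the strategy is
built around: a truth set of `n_true` variants; per caller, independent
Bernoulli misses at `miss_prob`; `private_fp` caller-private false
positives per caller (disjoint by construction); `shared_fp` correlated
false positives each carried by `shared_fp_callers` randomly chosen
callers. Depths are Poisson around `mean_depth` (floored and capped),
observed VAFs beta-binomial around each variant's true VAF (somatic VAFs
drawn from Beta(8, 12), mean 0.4 — a typical moderate-purity tumor). All
emitted records have FILTER `PASS`, ALT depth $\ge 4$ and VAF $> 0.02$,
so the retention filter is the identity on fixtures and the generator's
bookkeeping stays exact through the entire pipeline. In germline mode,
true calls get VAFs inside the het/hom windows (targets 0.44–0.56 and
0.92–0.98, amplicon-scale depths ~2000×) and noise calls get VAFs
outside them (0.03–0.35 or 0.64–0.86, 80/20 split), so the window
partition is exact by construction.

The defaults — 6 callers, 1000 true SNVs, miss 0.05, 100 private FPs per
caller, 10 shared FPs in caller pairs — were chosen once so that union,
majority and intersection separate visibly, and are documented as
arbitrary.

**What a green test establishes, and what it does not.** The fixtures
exercise parsing across FORMAT dialects, normalization, consensus
arithmetic, and metric computation against exact bookkeeping. They do
*not* emulate real caller error profiles: misses are independent, private
false positives are disjoint, and correlated noise lives only at support
2. One measurable consequence, worth stating plainly: in this synthetic
regime the $F_1$-optimal threshold for large rosters is *not* $n-1$.
Because correlated FPs exist only at support 2, precision is exactly 1
for every $k \ge 3$, so lowering $k$ from $n-1$ toward 3 keeps buying
sensitivity for free; measured over seeds 1–20, the pooled median $F_1$
over subsets of size $\ge 3$ peaks at relative threshold $m-k = 2$
(0.9965 vs 0.9945 at $m-k = 1$), and per-size median $F_1$ is flat for
$m \le 3$, while maximum $F_1$ per size does increase strictly with $m$.
Real multi-caller data show the $n-1$ optimum precisely because their
correlated noise spans a *range* of caller supports; reproducing that
would require a heavier-tailed shared-FP model than the stated defaults,
and the corresponding acceptance assertions are left failing rather than
the generator being re-tuned to pass them. Users exploring this regime
can raise `shared_fp` / `shared_fp_callers` themselves.

## Known limitations

* No haplotype-aware matching; no genotype-level comparison; no phasing.
* No re-genotyping or quality-aware weighting of votes — voting is one
  caller, one vote, by design (simplicity is the point of the strategy).
* The WES candidate filter operates on scalar per-site inputs; wiring it
  to paired tumor/normal VCF streams is left to the caller of the API.
* CRAM/BAM access, caller execution and read-level simulation are out of
  scope; inputs are VCFs.
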