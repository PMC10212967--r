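# consensusvc

Multi-caller consensus for somatic variant calls.

## The problem

Somatic variant callers disagree. Benchmarks rank them inconsistently, and
performance depends on the data, the parameters, and the metric; no single
caller is a safe default. A simple and robust remedy is to run several
callers and vote: accept a variant when at least *k* of the *n* callers
report it (the **minimum intersection threshold**). Accepting variants
called by *n − 1* callers keeps true positives that any single caller
misses while discarding caller-private false positives; for indels, where
callers diverge more sharply, the full intersection of a well-chosen pair
works better than larger ensembles.

`consensusvc` implements this strategy end to end for anyone who runs
two or more somatic callers on the same sample:

* **Normalization & matching** — allele trimming, reference-based
  left-alignment, multi-allelic and MNV decomposition, so the same allele
  change matches across callers (`normalize_variants()`, `make_key()`).
* **Dialect-aware VCF reading** — per-caller FORMAT conventions for ALT
  depth / total depth / VAF (fractional `AF`, `AD` pairs, VarScan percent
  strings, SomaticSniper `DP4`, Strelka tier counts), as editable config,
  not code (`read_caller_vcf()`, `dialect_presets()`).
* **Filtering** — the low-stringency retention rule (FILTER `PASS`/`.`,
  ALT depth > 3, VAF > 0.02), an exome tumor/normal candidate filter, and
  germline VAF-window noise partitioning ([0.4, 0.6] ∪ [0.9, 1.0]) for
  amplicon panels.
* **Consensus** — k-of-n voting with symbolic thresholds (`n-1`,
  `majority`), support histograms, subset enumeration
  (`combine_at_threshold()`).
* **Benchmarking** — precision = TP/(TP+FP), sensitivity = TP/(TP+FN) and
  their harmonic mean F1 for every caller subset at every threshold
  against a truth set (`threshold_sweep()`), plus per-sample germline
  noise tables (`noise_table()`).
* **Synthetic data** — a generator that emulates shared truth, per-caller
  misses, caller-private ("deterministic") and correlated ("stochastic")
  false positives, with exact bookkeeping (`simulate_dataset()`).

## Worked example

Simulate four callers over 200 true SNVs (5% independent miss rate, 25
private false positives per caller, 8 false positives shared by caller
pairs), write them as VCFs in four different FORMAT dialects, read them
back, and combine:

```r
library(consensusvc)

cfg <- simulation_config(seed = 7, n_callers = 4, n_true = 200,
                         private_fp = 25, shared_fp = 8)
ds    <- simulate_dataset(cfg)
files <- write_fixture_vcfs(ds, "fixtures")

callsets <- lapply(names(files$caller_vcfs), function(cid)
  read_caller_vcf(files$caller_vcfs[[cid]], dialect = files$dialects[[cid]],
                  caller_id = cid))
callsets <- lapply(callsets, low_stringency_filter)

support_histogram(callsets)
#>   1   2   3   4
#> 100  12  32 164
```

100 keys are caller-private (mostly false positives), 164 are called by
all four callers. Combine at the recommended SNV threshold `n-1` and
evaluate against the truth set:

```r
ct <- combine_at_threshold(callsets, "n-1")
ct
#> ConsensusTable: 4 callers (caller1, caller2, caller3, caller4), k=3
#>   308 distinct keys, 196 accepted at k=3

truth <- read_caller_vcf(files$truth_vcf, caller_id = "truth")
evaluate_consensus(ct, truth)
#>    tp fp fn precision sensitivity       f1
#> 1 196  0  4         1        0.98 0.989899

write_consensus_vcf(ct, "consensus.vcf")
```

At `k = 3` every private and pair-shared false positive is voted out
(precision 1) and only 4 of 200 true variants — those missed by two or
more callers — are lost. The full sweep shows the whole trade-off for the
4-caller roster:

```r
sw <- threshold_sweep(callsets, truth)
sweep_summary(sw)$by_threshold[m == 4]
#>    variant_class     m     k median_f1    max_f1 n_subsets   rel
#> 1:           SNV     4     1 0.7874016 0.7874016         1     3
#> 2:           SNV     4     2 0.9803922 0.9803922         1     2
#> 3:           SNV     4     3 0.9898990 0.9898990         1     1
#> 4:           SNV     4     4 0.9010989 0.9010989         1     0
```

The union (`k = 1`) pays in precision, the full intersection (`k = 4`)
pays in sensitivity, and `k = n − 1` is the sweet spot here.

## Command line

The same pipeline is scriptable via `exec/consensusvc` (or
`cvc_run()` from R):

```sh
consensusvc simulate -o fixtures --seed 7 --n-callers 4
consensusvc combine  --vcf a.vcf --vcf b.vcf --vcf c.vcf \
                     --threshold n-1 -o consensus.vcf
consensusvc sweep    --vcf a.vcf --vcf b.vcf --vcf c.vcf \
                     --truth truth.vcf -o sweep.tsv
consensusvc noise    --sample-dir GL1 --sample-dir GL2 -o noise.tsv
```

Exit codes: 0 success, 1 usage/configuration error, 2 data/format error.

## Documentation

The methods vignette (`vignettes/consensus-strategy.Rmd`) describes the
model and its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, numerical conventions, and known
limitations.
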