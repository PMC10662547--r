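---
title: "Selecting minimal SNP panels for sample discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting minimal SNP panels for sample discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcore)
```

## The model

`snpcore` treats marker selection as a discrimination problem over
multilocus genotype labels. Given a panel of $n$ samples typed at $p$
biallelic SNPs, each candidate marker subset $S$ induces a labelling of
the samples: sample $i$'s label is the tuple of its genotype codes over
$S$. A subset *discriminates* the panel when all labels are distinct.
The greedy objective is the Shannon index of the label frequencies,

$$H(S) = -\sum_i P_i \ln P_i,$$

which is maximised by many small, evenly sized label classes and so
rewards markers that split the current classes most evenly. Each round
adds the $H$-maximising marker; candidates that do not increase the
number of distinct labels are skipped before any $H$ evaluation, which
both speeds the search and encodes the real goal (label count, with $H$
ranking the count-increasing candidates).

Two properties follow directly and are asserted as tests: the label
count is non-decreasing in $|S|$ and bounded by $\min(n, 2^{|S|})$, so
$\lceil \log_2 n \rceil$ markers is a hard lower bound on any
discriminating panel; and greedy selection carries no optimality
guarantee, so the test suite compares it against exhaustive subset
enumeration on small instances (greedy $\ge$ optimum always; equality on
the packaged toy fixture).

### Assumptions

The genotype model is three-valued: reference homozygote, alternate
homozygote, missing. Heterozygous calls are masked to missing on ingest.
This matches inbred crop germplasm, where residual heterozygosity is
rare and often reflects genotyping artefacts; the package deliberately
offers no fourth heterozygote state, and asking `read_vcf()` to keep
heterozygotes raises an error rather than silently recoding them.

### Missing data and the recovery pass

Missing calls are imputed with the marker's major homozygote so the
greedy pass can run on a complete matrix, but an imputed call is a
guess: two samples separated only at imputed cells may in truth be
identical. The package therefore keeps an imputation mask and, after the
primary pass, rebuilds the pair ledger on *observed* genotypes. Pairs
with fewer than $m$ observed differences over the panel are collected
and markers are added greedily — each step the marker observed and
differing in the most still-unresolved pairs, a set-cover step — until
every pair with at least $m$ observed differences *somewhere* in the
input is resolved at level $m$. This termination argument is exact: an
unresolved-but-resolvable pair always retains at least one unused
separating marker, so each step makes progress. Pairs below the $m$
threshold genome-wide (IBS = 1 duplicates at $m = 1$) are reported as
unresolved and never looped on.

The recovery step's "most unresolved pairs covered" criterion is the
package's reading of frequency-based rescue: it is the only reading we
found that guarantees termination at complete differentiation, and ties
are broken by higher MAF and then genome order to keep runs
deterministic.

## Tunable parameters

| knob | default | meaning |
|------|---------|---------|
| `m` | 1 | minimum observed marker differences per pair; 2 buffers against single genotyping errors |
| `c` | 1 | independent repetitions (seeds `seed`, `seed+1`, …); best = smallest final panel |
| `x` | 1 | candidate extensions reported per round; the main path always follows the top-ranked one (no beam search) |
| `ld_prune_r2` | 0.8 | r² at or above which a marker near a selected one becomes ineligible |
| `ld_prune_window_bp` | 1 Mb | "nearby" window for that exclusion |
| sample / marker missing-rate filters | 0.5 / 0.2 | removal thresholds, samples first, `>=` comparison, marker rates recomputed on retained samples |

The linked-marker exclusion needs both a distance and a correlation
scale; neither is canonical, so both are exposed. The defaults (1 Mb,
r² ≥ 0.8) drop near-redundant neighbours — which could never add label
classes beyond what their partner adds — without touching weakly linked
markers. Because recovery is not subject to LD pruning, the
discrimination guarantee is unaffected by these knobs.

Ties among equal-Shannon candidates are broken uniformly at random under
the run's seed (equality tested at an absolute $10^{-12}$ tolerance);
repeated runs with one seed are byte-identical, and `c > 1` explores the
tie structure rather than re-rolling the same path.

## Numerical and degenerate-input choices

* Imputation ties (equal homozygote counts) fill with the reference
  homozygote: deterministic and stable under re-coding of the alternate
  allele.
* A matrix with no polymorphic marker (e.g. all samples identical)
  yields an *empty* panel with every pair unresolved — a meaningful
  answer, not an error. An eligible set emptied by the user's exclude
  list, by contrast, is a configuration error.
* Frequency vectors must sum to 1 within $10^{-8}$; zero frequencies
  contribute zero to $H$.
* `ld_r2` on a monomorphic marker is an error (the correlation is
  undefined), and the r²-pruning step simply skips monomorphic columns.
* Mantel p-values use the one-sided permutation convention with the
  add-one correction, $p = (1 + \#\{r^\ast \ge r\})/(1 + B)$; a
  zero-variance distance matrix is an error rather than a NaN.
* Chromosome arms for the random baseline default to the chromosome
  midpoint (mean of the lowest and highest marker position) because true
  centromere positions are unknown to the tool; a two-column
  `chrom, pos` table overrides this.

## What the synthetic generator emulates — and what it does not

`simulate_genotypes()` produces the statistical structure the method is
sensitive to: a configurable MAF spectrum, per-cell missing and
residual-heterozygote rates, LD blocks (each block has a founder column;
other columns copy it with probability $\rho$ and are redrawn at the
block's allele frequency otherwise, making founder–copy correlation
exactly $\rho$ in expectation), and planted duplicate or near-duplicate
samples whose differing cells are protected from the missing-data
sprinkle so that ground truth stays observable. The ground-truth
manifest (planted pairs, block map, true MAF) lets tests assert exact
recovery: planted duplicates must be precisely the IBS = 1 pairs and
precisely the unresolved pairs.

The generator does **not** emulate population structure, realistic LD
decay with distance, genotyping-platform ascertainment bias, or
chromosome-scale recombination maps. Passing tests therefore demonstrate
the algorithmic guarantees (discrimination, recovery, reproducibility,
greedy-vs-random efficiency) under controlled conditions; they do not
certify panel sizes on any real crop dataset, where diversity, IBS
structure and missingness drive the final count.

## Problem sizes used by the test suite

Unit tests run on matrices up to 50 × 200; the end-to-end discrimination
checks use 200 samples × 2,000 markers with three planted duplicate
pairs; the greedy-versus-random comparison uses twenty 120 × 700 panels
with 10-marker LD blocks at $\rho = 0.8$; exhaustive-enumeration oracles
are applied at ≤ 10 samples × ≤ 12 markers where full subset search is
cheap. These sizes were chosen so each property is exercised well inside
the regime where its asymptotics are visible.

## Known limitations

* Greedy selection is locally optimal per round only; globally minimal
  panels are not guaranteed (and are NP-hard in general — the problem
  contains set cover).
* `x > 1` reports per-round alternatives for downstream assay design but
  does not perform beam search.
* LD r² is genotype-based (0/1 homozygote coding); with heterozygotes
  masked there is no phase information, so haplotype-phase r² is out of
  scope.
* The simplified and full PIC formulas are defined for biallelic loci
  with allele frequency equal to the observed homozygote frequency;
  there is no heterozygosity-aware PIC for three-state genotypes.
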