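---
title: "Domain-based localization prediction and Mutual-Rank co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-based localization prediction and Mutual-Rank co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfantom)
library(tibble)
```

## The model and its assumptions

`pfantom` predicts a protein's subcellular compartment from the Pfam
domains it carries. The training signal is a set of GO cellular-component
annotations restricted to experimental evidence: by default only IDA
("inferred from direct assay") records are kept, discarding annotations
transferred by similarity or computation. Each surviving protein
contributes its distinct domains to the compartments it is annotated to,
giving per-domain counts and the **localization ratio**
`r(d, c) = count(d, c) / total(d)` — a row-stochastic table with one row
per domain summing to 1.

A query protein with domains `d1..dk` is scored per compartment by the
geometric mean `s(c) = (prod_i r(d_i, c))^(1/k)` and called at the argmax.
The geometric mean is deliberate: it requires *consensus* across domains —
a single domain never observed in a compartment vetoes it (a zero factor
annihilates the product), whereas an arithmetic mean would let one strong
domain carry a compartment the others contradict.

The method's core assumptions:

* domain content is informative about location (true for families such as
  glycosyltransferases or receptor kinases; weak for promiscuous domains);
* the experimentally annotated training set samples each domain's
  compartment distribution without strong assay bias;
* compartments are taken from a fixed eleven-term vocabulary; annotations
  to other terms are dropped and counted, with no ontology-graph
  propagation. Matching is exact by GO id; an optional user-supplied
  expansion table can fold descendant terms into the vocabulary, which
  keeps training reproducible without an ontology snapshot.

Counting is **protein-weighted**: a protein annotated to the same
compartment by five assays counts once, and a domain repeated within one
protein counts once. This avoids over-weighting heavily studied proteins;
the alternative (annotation-weighted counting) would tie ratios to assay
counts rather than to the protein population.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `evidence` | `"IDA"` | GO evidence codes admitted to training |
| `threshold` | 0 | minimum top score to call; 0 reproduces plain argmax reporting, non-zero values are used by the ROC sweep |
| `tie_tolerance` | 1e-9 | scores within this distance of the maximum are co-called; the default admits exact ties only, which yields joint "50/50"-style calls for domains split evenly between two compartments |
| `smoothing` | 0 | optional additive pseudo-ratio; off by default so that the bare geometric mean (and its zero-veto) is the model |
| ROC `step` | 0.01 | threshold grid spacing |
| MR `cutoff` | 70 | Pfam groups are retained when at least one member gene's average MR is strictly below this |

Scores are fractions internally; `format_percent()` renders the
one-decimal percentages used in reports (e.g. "80.9").

## Call semantics and degenerate inputs

A batch call has one of five statuses: `predicted` (unique argmax), `tie`
(two or more compartments within tolerance of the top score), `no_pfam`
(the protein carries no domains), `no_data` (it carries domains, but none
occur in the trained table), and `below_threshold`. Domains missing from
the table are *excluded* from the geometric mean rather than zeroing the
protein: a partially covered multi-domain protein is still predicted from
its covered domains, and only a protein with zero covered domains abstains
as `no_data`. This keeps coverage interpretable — abstentions are reported
separately from wrong calls.

Evaluation is one-vs-rest per compartment. Ground truth is multi-label (a
protein may genuinely reside in several compartments); a call for
compartment c is a true positive iff c is in the protein's true set.
Proteins with `no_pfam`/`no_data` are excluded from
sensitivity/specificity denominators by default and reported as coverage
(`include_uncovered = TRUE` counts them as all-negative calls). Zero
denominators yield `NA`, never a silent 0. "Cell plate" is retained in the
training vocabulary but excluded from default performance reports — it is
annotated to only a handful of proteins and its one-vs-rest tallies are
uninformative.

The ROC sweep calls a protein for compartment c at threshold t iff
`s(c) >= t` *and* c is among the protein's tied-argmax compartments; the
argmax gate matches how the predictor is actually used (one call per
protein), so the curve measures the calling rule, not a free-standing
score ranking. AUC is computed by the trapezoid rule on (FPR, TPR) sorted
by FPR, anchored at (0,0) and (1,1).

## Co-expression analysis

Ranked lists of co-expressed genes (one per bait, scored by Mutual Rank)
are consumed as published — the package never recomputes MR from
expression data, and never re-derives the top-300 cut. A gene present in
every bait list gets an **average MR**: the geometric mean of its per-bait
MRs, computed in log space. The geometric mean is the natural average for
a rank-product-style statistic: it is the exponent of the mean log rank,
so a gene must be consistently well ranked across baits to score well.

Intersections are computed on exact normalized identifiers (AGI loci
uppercased, splice suffixes stripped; rice RAP ids preserved). Bait genes
found in all lists are included in the shared set and flagged in an
`is_bait` column, so conventions with and without baits are both
recoverable; shared-gene percentages are reported against both the list
length and the union size, since the two denominators give different
figures. Cross-species comparison happens at the level of Pfam families:
each species' shared set is grouped by the *joint* domain set of each gene
(a three-domain protein groups under its full set, not under each domain
separately), and a group is retained when its best member's average MR is
strictly below the cutoff.

## The synthetic-data generators

Two seeded generators make every pipeline stage testable without
downloads; a single integer seed makes each output byte-reproducible.

`simulate_annotation_corpus()` draws, per protein, a domain count
(defaults 0/1/2/3 with probabilities 0.1/0.6/0.2/0.1, mimicking the
predominance of single-domain annotations in genome-wide Pfam tables),
distinct domains uniformly from the inventory, and one true compartment
per domain from a user-supplied conditional table p(compartment | pfam).
Evidence codes are drawn independently of the compartment (default 70%
IDA, 20% IMP, 10% ISS), so IDA filtering thins training uniformly without
biasing ratios. Multi-domain proteins can acquire several true
compartments, deliberately exercising multi-label evaluation — and also
*contaminating* single-domain ratio estimates, since a protein's
compartments come from all its domains. Parameter-recovery checks
therefore use single-domain corpora, where the trained ratio for each
domain is a binomial estimate of its conditional row.

What the corpus generator does *not* emulate: correlated domain
co-occurrence, assay bias toward abundant compartments, annotation errors,
and the heavy-tailed popularity of real Pfam families. Passing tests show
the estimator and evaluator are correct under the stated sampling model,
not that real-genome accuracy will match.

`simulate_mr_lists()` constructs bait lists whose pairwise and k-way
intersections equal a designed Venn structure exactly, by populating a
common core, pair-exclusive regions, and per-bait unique genes (designs
violating `kway <= pairwise <= length` are rejected with the violated
inequality). MR values are jittered ranks — position × 1.2 plus Gaussian
noise (sd 5), re-sorted and floored at 1 — so a 300-gene list tops out
near MR 360, in the range published top-300 lists reach. Bait genes are
placed in the common core by default, as real baits retrieve each other.
The canonical fixture design (pairwise 165/121/123, three-way 83, length
300) mirrors the rice glycosyltransferase bait triple; an
Arabidopsis-style design uses a three-way core of 124.

## Numerical choices

* Geometric means are computed as `exp(mean(log(x)))`; a zero ratio gives
  `-Inf` in log space and an exact 0 score, with no smoothing unless asked.
* Ratio tables round-trip through TSV bit-exactly: ratios are written at
  full precision and recomputed as `count/total` on read.
* Ties in ranked lists are kept in stable (file) order.
* The ratio-table invariant (rows sum to 1 within 1e-9) is asserted on
  every build.

## Problem sizes used in the test suite

Property tests run at the scale their statistics need: parameter recovery
uses 10,000 single-domain proteins (binomial se ≈ 0.008 at p = 0.7, well
inside the ±0.02 band); label-permutation ROC uses 1,000 proteins (AUC
within 0.05 of chance); oracle-agreement checks use corpora of up to 50
proteins and 100 random feasible Venn designs, where brute-force
enumeration is fast and exact.

## Known limitations

* Training-set evaluation is optimistic; the evaluator supports any
  calls-vs-truth pairing, but no cross-validation driver is built in.
* Exact GO-term matching ignores ontology descendants unless an expansion
  table is supplied.
* Single-compartment scoring ignores inter-domain dependence; domains are
  treated as independent evidence sources.
* No ortholog mapping: cross-species comparison is by Pfam group, not by
  gene identity.
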