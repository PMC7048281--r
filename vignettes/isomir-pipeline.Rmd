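---
title: "isomiR-resolved small RNA-seq analysis with isomiRpipe"
author: "isomiRpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isomiR-resolved small RNA-seq analysis with isomiRpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRpipe)
```

## Scope and model

isomiRpipe analyses single-end small RNA-seq libraries at the resolution of
miRNA sequence isoforms (isomiRs).  It was designed for dietary
extracellular-vesicle (EV) transfer studies — for example, asking whether
miRNAs packaged in colostrum EVs appear in a calf's circulating EVs after
the first feeding — where isomiR-level profiles are the fingerprint that
distinguishes transferred cargo from endogenous expression.  The same
machinery applies to any two-group, multi-time-point small RNA design.

The pipeline has five computational stages:

1. **Reference enumeration.**  From a miRBase-style mature + hairpin FASTA
   pair, every isomiR reachable from a canonical mature by trimming up to
   `maxTrim` nucleotides or adding up to `maxAdd` nucleotides on the 5'
   and/or 3' end is generated; variants shorter than `minLen` are pruned.
   Additions are *templated* by default: the added bases are read off the
   flanking hairpin sequence, modelling alternative DROSHA/DICER cleavage.
   A variant is identified by its signed end offsets `(e5, e3)`; `(0, 0)`
   is the canonical mature.  Identical sequences arising from different
   (miRNA, e5, e3) origins collapse into one variant carrying all parent
   annotations, with the lexicographically smallest parent id as the
   canonical parent.
2. **Preprocessing.**  3' adapters are trimmed with a two-stage rule
   (exact match of the adapter's first 10 nt anywhere in the read, else a
   3'-terminal overlap of at least `minOverlap` bases with at most one
   mismatch).  Inserts shorter than `minLen` are discarded as *Short*;
   inserts contained (with at most one mismatch) in an rRNA, tRNA, snRNA
   or snoRNA reference are discarded as contaminants, in that fixed
   priority order.  Every raw read receives exactly one terminal class, so
   the classes partition the library — the basis of the RNA species
   distribution table.
3. **Quantification.**  Retained inserts are assigned to variants by an
   ungapped, length-preserving, best-stratum matcher: exact matches
   (stratum 0) always beat single-substitution matches (stratum 1), and
   ties within a stratum are broken deterministically (smallest
   `|e5|+|e3|` over parent annotations, then smallest variant id).  The
   count key combines the variant with the mismatch descriptor, so a
   "polymorphic" isomiR (one internal substitution) is a distinct feature
   from its template — counting is effectively per unique read sequence.
   Canonical miRNA counts are obtained by summing all keys of a canonical
   parent.
4. **Differential expression.**  Median-of-ratios size factors, a
   per-feature method-of-moments negative-binomial dispersion (floored at
   `1e-8`), an NB log-linear model with size-factor offsets fitted per
   feature, a two-sided Wald test on the group coefficient, and
   Benjamini–Hochberg adjustment across tested features.  Features are
   called significant with the conservative inclusive filter
   `padj <= 0.05`, `|log2FC| >= 1`, `baseMean >= 50`.
5. **Profiling and enrichment.**  Species distribution percentages; PCA of
   the top-500-variance features and Ward (Ward.D2) clustering, both on
   `log2(normalized + 1)` counts; the overlap between a reference group's
   top-100 most abundant features and the up-regulated sets per time
   point; and gene-level hypergeometric pathway over-representation where
   the query is the *union* of the significant miRNAs' target genes, so a
   gene targeted by many miRNAs is counted once.

## A worked example on synthetic data

The synthetic-data generator is a first-class module: it draws a random
reference, an expression program per sample group, and reads with
adapters, contaminants and sequencing errors, together with per-read
ground-truth labels.

```{r example, eval = FALSE}
refDir <- file.path(tempdir(), "ref"); expDir <- file.path(tempdir(), "exp")
sr <- simulateReference(nMirnas = 20, seed = 1, dir = refDir)
design <- simulationDesign(timePoints = c("0h", "1h", "3h"),
                           replicates = 3, depth = 5e4, seed = 2)
v <- as.data.frame(variantAnnotation(sr$space))
planted <- v$variant_id[v$e5 == 0 & v$e3 == 0][1:6]
design$plantedEffects <- postprandialEffects(planted, design, log2FC = 3)
ex <- simulateExperiment(sr, design, dir = expDir)

res <- runPipeline(file.path(refDir, "mature.fa"),
                   file.path(refDir, "hairpin.fa"),
                   file.path(refDir, "contaminants.fa"),
                   file.path(expDir, "sample_sheet.tsv"),
                   outDir = file.path(tempdir(), "out"))
res$de[["calf_EV_3h_vs_0h"]]$up          # planted features resurface here
res$overlap$overlaps                     # top-100 overlap per time point
```

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `maxTrim` / `maxAdd` | 6 / 3 | nt | end-variant search space of the mapping reference |
| `minLen` | 16 | nt | inserts and variants below this cannot be assigned reliably; shorter variants could never be matched, so pruning them changes no result |
| adapter `minOverlap` | 6 | nt | shortest 3'-terminal overlap accepted as adapter evidence |
| `maxAdapterMismatch` | 1 | substitutions | tolerance in the terminal-overlap stage |
| contaminant mismatches | 1 | substitutions | same stringency as read assignment |
| `alpha` / `minAbsLfc` / `minBaseMean` | 0.05 / 1 / 50 | — / log2 / normalized counts | conservative significance filter; all thresholds inclusive |
| PCA `k` | 500 | features | top-variance subset for sample-level ordination |
| overlap `nTop` | 100 | features | abundance set of the reference group |

Simulation defaults: depth `1e5` reads per library, NB dispersion `0.1`,
substitution error rate `0.001` per base, contaminant / short / adapterless
read fractions `0.10 / 0.02 / 0.05`, read length 50 nt, three replicates
per group and time point, and ~70% of each miRNA's expression on its
canonical variant.  These emulate a plausible HiSeq-class small RNA
library; the planted-effect helper applies a log2 fold change that grows
linearly across post-feeding time points, mimicking a time-dependent
uptake signal.

## Design decisions and numerical choices

* **Templated additions by default.**  A mapping reference requires
  concrete bases for end additions, and the hairpin flanks are the only
  principled source.  An optional `nontemplated_AU` mode appends all A/U
  mono- to tri-nucleotide tails instead, for users interested in 3'
  tailing; it is off by default because tailing variants inflate the
  reference without hairpin support.
* **Deterministic "best" assignment.**  Short-read aligners typically
  break multi-mapping ties pseudo-randomly.  Here the tie-break is
  deterministic (offset magnitude, then variant id) so repeated runs and
  tests are reproducible; on genuinely ambiguous reads this can differ
  from any randomized aligner.
* **Simplified NB-Wald testing.**  The DE stage is a deliberately compact
  negative-binomial procedure: no Cox–Reid dispersion adjustment, no
  fold-change shrinkage, no independent filtering, no outlier replacement.
  Its operating characteristics are validated by simulation (null
  false-call rate under 1% after filtering; planted log2FC = 2 effects at
  `baseMean >= 200` recovered with median estimate within [1.7, 2.3] and
  sensitivity above 80%).  Fitted fold changes are reported from the model
  without pseudo-counts; a descriptive fold change with pseudo-count 0.5
  is carried alongside for display on low-count features.
* **Size factors.**  Median-of-ratios over features expressed in every
  sample; with sparse isomiR-level matrices where no feature satisfies
  that, a positive-count (poscounts-style) geometric mean reference with
  per-sample medians over expressed features is available
  (`pseudoReference = TRUE`), and the pipeline falls back to it
  automatically.
* **`log2(normalized + 1)` in place of a regularized log.**  Clustering
  and PCA conclusions at this package's scale are qualitative; the simple
  transform preserves the variance ranking and distance structure of
  abundant features without a fitted shrinkage model.
* **Ward variant fixed to Ward.D2** (merges minimize the increase of
  within-cluster variance on squared euclidean distances) and recorded in
  the output.
* **Enrichment universe** = genes present in the target map *and* in at
  least one pathway; query and pathways are restricted to it.  The
  hypergeometric upper tail is computed at the observed overlap.
* **Coordinates are 0-based half-open** everywhere (mature-in-hairpin,
  mismatch positions in reads).
* **Internal alphabet is DNA** (U normalized to T on input) so FASTQ reads
  and FASTA references compare directly.
* **Degenerate inputs.**  All-zero features are excluded from testing and
  reported with missing p-values; empty libraries yield all-zero species
  rows flagged and excluded from group means; a single sample gets size
  factor 1 by convention; abundance ties rank by feature id.

## What the simulator does and does not emulate

The generator reproduces the *structure* of a feeding-study data set:
adapterized 50-nt reads, a skewed isomiR mixture per miRNA, NB-dispersed
counts, group-specific expression programs, planted time-dependent
effects, contaminant fragments, short degradation products, and
adapterless reads.  It deliberately omits quality-score realism, GC and
ligation bias, PCR duplicates, and indel sequencing errors (the matcher is
substitution-only, so indel errors would surface as unmapped reads rather
than misassignments).  Passing tests therefore demonstrate correctness of
the algorithms under a controlled generative model — not robustness to
every artefact of real libraries.  Contaminant references are
rejection-sampled to stay at Hamming distance greater than 1 from every
enumerated variant, so contaminant filtering cannot steal miRNA reads by
construction; in real data, contaminant and miRNA sequences can be closer.

## Problem sizes used by the test suite

The packaged checks run on references of 20–50 miRNAs (roughly 1500–4000
variants), libraries of 1e5 reads for quantifier accuracy, an 18-library
end-to-end study at 5e4 reads each, and DE simulations of 2000 features at
3 vs 3 replicates — sizes chosen so the full suite exercises every code
path at realistic per-library composition while remaining quick on a
laptop.

## Known limitations

* Multi-factor designs, continuous covariates and shrinkage estimators
  are out of scope; contrasts are two-group.
* Assignment is ungapped and length-preserving; indels are representable
  only through the enumerated trim/extension variants.
* The enrichment stage takes user-supplied target maps and GMT files; no
  database access is built in, and the bovine-to-human homologue mapping
  is a plain translation table (identity by default).
* Reported isomiR keys depend on the enumeration bounds; reads from true
  variants outside the `[-6, +3]` offset grid are counted as unmapped.
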