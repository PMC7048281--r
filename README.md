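# isomiRpipe

IsomiR-resolved analysis of single-end small RNA-seq libraries, built for
dietary extracellular-vesicle (EV) miRNA transfer studies — the archetype
being postprandial profiling of calf plasma EVs after the first colostrum
feeding, where isomiR fingerprints separate transferred colostral cargo
from endogenous expression.  The package is aimed at transcriptomics
researchers who need a reproducible, fully testable pipeline from raw
FASTQ to differential isomiR tables without external services.

## What it computes

* **IsomiR reference enumeration.**  From mature + hairpin FASTA files,
  all end variants with signed offsets (e5, e3) ∈ [−maxTrim, +maxAdd]²
  (defaults −6…+3), additions templated from the hairpin flanks, pruned at
  a 16-nt minimum; identical sequences collapse into one variant with all
  parent annotations.
* **Preprocessing.**  Two-stage 3' adapter trimming (exact 10-mer seed,
  else ≥6-nt 3'-terminal overlap with ≤1 mismatch), a <16-nt length
  filter, and rRNA/tRNA/snRNA/snoRNA contaminant removal by substring
  containment with ≤1 mismatch.  Every read receives exactly one class:
  No-Adaptor, Short, a contaminant class, Mapped or Unmapped — the classes
  partition each library.
* **Quantification.**  An exact/one-mismatch, ungapped, best-stratum
  matcher with a deterministic tie-break assigns each insert to a variant;
  the count key is (variant, mismatch descriptor), so polymorphic isomiRs
  are separate features ("the sum of each individual sequence").  Keys
  roll up to canonical miRNA counts by parent.
* **Differential expression.**  Median-of-ratios size factors
  s_j = median_i (k_ij / (∏_j k_ij)^(1/n)), per-feature method-of-moments
  NB dispersion, an NB log-linear Wald test per feature with size-factor
  offsets, BH adjustment, and the conservative inclusive filter
  padj ≤ 0.05, |log2FC| ≥ 1, baseMean ≥ 50.
* **Profiling & enrichment.**  RNA species distribution; PCA of the
  top-500-variance isomiRs and Ward.D2 clustering of
  log2(normalized + 1) counts; overlap of a reference group's top-100
  most-abundant isomiRs with up-regulated sets per time point; gene-level
  hypergeometric KEGG-style enrichment on the union of the significant
  miRNAs' targets (a gene targeted by many miRNAs counts once).
* **Synthetic studies.**  A seeded generator produces a random reference,
  contaminants screened to Hamming distance > 1 from every variant,
  NB-dispersed per-sample counts with planted time-dependent log2 fold
  changes, and 50-nt adapterized reads with per-read ground-truth labels.

## Worked example

```r
library(isomiRpipe)

refDir <- "ref"; expDir <- "exp"
sr <- simulateReference(nMirnas = 12, seed = 11, dir = refDir)
sr$space
#> IsomirSpace with 911 unique variants (maxTrim=6, maxAdd=3, minLen=16, templated additions)
#>   parent annotations: 911

design <- simulationDesign(timePoints = c("0h", "1h", "3h"),
                           replicates = 3, depth = 2e4, seed = 12)
v <- as.data.frame(variantAnnotation(sr$space))
planted <- v$variant_id[v$e5 == 0 & v$e3 == 0][1:4]
design$plantedEffects <- postprandialEffects(planted, design, log2FC = 3)
ex <- simulateExperiment(sr, design, dir = expDir)

res <- runPipeline(file.path(refDir, "mature.fa"),
                   file.path(refDir, "hairpin.fa"),
                   file.path(refDir, "contaminants.fa"),
                   file.path(expDir, "sample_sheet.tsv"), outDir = "out")

round(res$speciesDistribution$groupMeans, 2)
#>              NO_ADAPTOR SHORT RRNA TRNA SNRNA SNORNA MAPPED UNMAPPED
#> calf_EV            5.07  2.05 2.64 2.55  2.73   2.60  82.29     0.06
#> colostrum_EV       4.86  2.02 2.52 2.46  2.57   2.51  83.01     0.05
```

Per sample group, the mean percentage of each library falling into each
read class: ~83% of reads map to isomiRs, ~10% are contaminants, ~5%
carry no detectable adapter — matching the simulation's design fractions.

```r
res$de[["calf_EV_3h_vs_0h"]]$up[, c("feature_id", "baseMean", "log2FC", "padj")]
#>                   feature_id baseMean log2FC     padj
#> 737  syn-miR-005|e5:+0|e3:+0     2434   2.40 1.00e-03
#> 1060 syn-miR-007|e5:+0|e3:+0     2264   2.59 4.52e-02
#> 1318 syn-miR-009|e5:+0|e3:+0     8950   2.81 1.06e-73
#> 1918 syn-miR-012|e5:+0|e3:+0      535   2.49 2.19e-64
```

All four planted canonical isomiRs pass the significance filter at the
last post-feeding time point; the 3 h samples carry the full planted
log2FC = 3, and the fitted estimates land between 2.4 and 2.8 after
normalization absorbs part of the planted shift.

```r
res$overlap$overlaps
#>   time_point n_top overlap_count overlap_percent
#> 1         1h   100             2               2
#> 2         3h   100             4               4
```

Of the colostrum-EV group's 100 most abundant isomiRs, 4 are re-discovered
as significantly up-regulated in calf EVs at 3 h — exactly the planted
overlap, since all four planted features rank inside the reference
top-100 here.

A thin command-line front end with `simulate`, `build-ref`, `preprocess`,
`quantify`, `diffexp`, `profile`, `enrich` and `run-all` subcommands lives
at `inst/scripts/isomir_pipeline.R`; `run-all` also accepts a YAML config.
Pointing the sample sheet at real FASTQ files and a miRBase mature/hairpin
pair runs the identical analysis on real data.

## Methods

See the methods vignette (`vignettes/isomir-pipeline.Rmd`) for the model,
parameter rationale, numerical choices, what the synthetic generator does
and does not emulate, and known limitations.
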