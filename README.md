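# tissueqc

Biological quality control for tissue-specific bulk RNA-seq of dissected
tissue from transgenic knockdown strains.

## The problem

Profiling the transcriptome of a small dissected tissue — for example the
larval central nervous system of a GAL4/UAS shRNA knockdown fly strain —
means pooling hundreds of delicate dissections per library. Two kinds of
artifact routinely corrupt such datasets on top of ordinary read-level
noise:

* **Tissue contamination.** Fragments of physically adjacent tissue
  (imaginal discs next to the CNS) end up in some pools and not others,
  so replicate libraries stop correlating with their own genotype and
  differential expression collapses.
* **Signal dilution.** When a ubiquitously expressed gene is knocked down
  in only one cell type (a neuron-restricted driver), the bulk
  measurement mixes knocked-down and unaffected cells. With neuron
  fraction *φ* and residual expression *r* in the targeted cells, the
  bulk fold change is only

  > FC = φ·r + (1 − φ)

  — e.g. 0.6 for φ = 0.5, r = 0.2 — and contamination at fraction *c*
  attenuates every cell-type-restricted effect by a further (1 − c).

`tissueqc` implements the analysis pipeline around these two ideas:

* read QC: filters for unknown bases, homopolymer runs ≥ 50 nt and mean
  Phred < 30; per-cycle nucleotide-composition profiling; 5′ trimming of
  the biased first 10 cycles (random-hexamer priming bias) with a
  before/after comparison;
* PCR-duplicate removal on the paired fragment signature (reference,
  both fragment ends, orientation) and a duplicate-rate vs cDNA-input
  diagnostic;
* union-mode gene-level fragment counting with a mapping-quality floor,
  and FPKM;
* median-of-ratios size factors, method-of-moments NB dispersions with a
  robust mean trend, a Wald NB test with BH adjustment, and
  correlation / clustering / PCA concordance diagnostics;
* a **marker-gene panel** (neuron marker, glia marker, driver transgene,
  contaminant-tissue marker, ubiquitous control) that flags contaminated
  and weak-driver libraries, scores contamination, and estimates the
  contaminant fraction by inverting the linear mixing model;
* an **shRNA interference audit**: coverage along the target gene, a
  targeted-region enrichment ratio between knockdown and control
  libraries, and differential expression restricted to the non-targeted
  5′ region, whose only possible origin is the endogenous gene;
* tissue-class enrichment of DE lists with the two-proportion z-test and
  the hypergeometric overlap test;
* a **synthetic mixed-tissue generator** that emits annotation (GTF),
  ground-truth alignments (SAM), and artifact-laden paired FASTQ
  (5′ composition bias, input-dependent PCR duplicates, QC-failing read
  classes, optional shRNA transgene reads) so every stage is testable
  against known truth.

## Worked example

Simulate a six-library experiment (3 control, 3 neuron-restricted
knockdown at r = 0.2, one control library contaminated at c = 0.6) and
run the full pipeline:

```r
library(tissueqc)

cfg <- simulation_config(
  n_genes = 30, library_size = 8000, seed = 42,
  libraries = local({
    l <- sim_libraries(n_wt = 3, n_kd = 3, cdna_input = c(2, 4, 6, 3, 5, 6))
    l$contamination <- c(0.6, 0, 0, 0, 0, 0)
    l
  }))
report <- run_pipeline(cfg, "example_run")
report
#> Pipeline run report
#>   libraries: 6; selected after panel QC: WT_2, WT_3, KD_1, KD_2, KD_3
#>   duplicate rate vs input: r = -0.996 (flag: TRUE)
#>   DE: 31 tested, 1 significant (0 up, 1 down)
#>   interference audit: R = 0.92 (no interference)

read.delim("example_run/verdicts.tsv")
#>   library contaminated low_transgene  pass     score
#> 1    WT_1         TRUE         FALSE FALSE  0.193062
#> 2    WT_2        FALSE         FALSE  TRUE -7.592069
#> 3    WT_3        FALSE         FALSE  TRUE -6.810801
#> 4    KD_1        FALSE         FALSE  TRUE -7.565631
#> 5    KD_2        FALSE         FALSE  TRUE -6.228991
#> 6    KD_3        FALSE         FALSE  TRUE -7.126357
```

Reading the output: the marker panel flags exactly the contaminated
library (contaminant marker far above, CNS markers far below their
target-tissue references; its contamination score sits ~7 log2 units
above the clean libraries) and the five passing libraries proceed to the
NB test. Duplicate rates correlate strongly and negatively with nominal
cDNA input (r = −0.996), the classic signature of input-limited library
amplification. The interference ratio R ≈ 1 says reads from the shRNA
transgene are not inflating the targeted 3′ region of the knockdown
target, so its quantification is trustworthy; the one significantly
*down* gene is the knockdown target itself, at the diluted bulk fold
change. Per-library tables (filter tallies, counts, FPKM, DE, trimming
comparison) are written under `example_run/`.

A command-line entry point wrapping the same stages is installed at
`inst/scripts/tissueqc` (subcommands `simulate`, `readqc`, `dedup`,
`count`, `panel`, `de`, `audit-target`, `enrich`, `run`).

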