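---
title: "Methods: quality control and signal dilution in tissue-specific bulk RNA-seq"
author: "tissueqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and signal dilution in tissue-specific bulk RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and the design
choices behind them. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The mixture model

The object of study is a bulk library prepared from a dissected target
tissue made of two cell types — neuron-like cells at fraction $\varphi$
and glia-like cells at $1-\varphi$ — with an admixture, at
library-specific fraction $c$, of a physically adjacent contaminant
tissue. A driver-restricted shRNA knocks one ubiquitously expressed
target gene down to a residual fraction $r$ in neuron-like cells only
(or in every compartment, for the somatic-deficiency comparison). The
expected abundance of gene $g$ is

$$a(g) = (1-c)\,\bigl[\varphi\,n(g)\,k(g) + (1-\varphi)\,l(g)\bigr] + c\,m(g),$$

with $n, l, m$ the per-cell abundances in neurons, glia and the
contaminant tissue and $k(g)=r$ for the target, 1 otherwise. Two
consequences drive the whole package:

* **Signal dilution.** For a ubiquitous target with $n(g)=l(g)$ and
  $c=0$, the bulk fold change under knockdown is exactly
  $\varphi r + (1-\varphi)$ — e.g. 0.6 at $\varphi=0.5$, $r=0.2$. A
  strong cell-type-restricted knockdown is thus a modest bulk effect,
  and contamination attenuates it by a further $(1-c)$.
* **Linear marker mixing.** A marker's expected FPKM interpolates
  linearly between its target-tissue and contaminant-tissue reference
  values, so the contaminant fraction is estimable as
  $\hat c = \mathrm{clamp}_{0}^{1}\,
  (\text{obs}-\text{ref}_T)/(\text{ref}_C-\text{ref}_T)$.

$\varphi$ defaults to 0.5. The true neuron:glia ratio of the tissue is
not something the package asserts; $\varphi$ is a free configuration
parameter, and every quantity that depends on it says so.

## What the generator emulates

`simulation_config()` + `simulate_experiment()` produce annotation
(GTF), ground-truth alignments (a minimal text SAM dialect), and paired
FASTQ with the artifact structure the analysis is designed to catch:

* **Counts** are negative binomial with mean
  $\mu_g = N\,a_g/\sum a$ and variance $\mu_g + \alpha\mu_g^2$. The
  default dispersion $\alpha = 0.02$ (CV $\approx 14\%$) reflects
  libraries pooled from hundreds of dissected animals, which averages
  away most biological variability; calibration tests that probe the NB
  test at $\alpha = 0.1$ pass that value explicitly.
* **Fragments** are placed uniformly on the spliced transcript, lengths
  uniform on 200–400 bp (mean 300, matching random-primed fragmentation),
  mate orientation random (unstranded protocol). Because the truth SAM
  uses single-block alignments, both mates are constrained to lie within
  single exons; placement is uniform over the valid set by rejection
  sampling, with a guaranteed fallback inside the longest exon. This
  constraint makes placement on short multi-exon genes only
  approximately uniform, so the designated knockdown target is pinned to
  a dedicated single-exon 2 kb gene — there placement is exactly uniform
  and the coverage audit has a clean baseline. Sampling distinct
  (start, length) pairs makes genuine signature collisions rare, so the
  injected duplicate rate is recoverable.
* **PCR duplicates** are whole-pair copies injected at rate
  $d = d_{\max} e^{-\lambda\,\text{input}}$; the defaults
  $d_{\max}=0.986$, $\lambda=0.15$ place nominal inputs of 2–6 ng at
  duplicate rates of about 0.73–0.40, the range a pilot sequencing round
  of low-input libraries shows, so the duplicate-vs-input diagnostic is
  exercised on realistic numbers.
* **5′ composition bias**: the first 10 cycles of each freshly sequenced
  mate are re-drawn from a per-position skewed base composition
  (multiplicative profile, amplitude 0.5 by default, 0 = unbiased).
  Duplicates copy their source pair byte for byte — same molecule, same
  priming.
* **QC-failing classes** are injected as *extra* pairs with fresh
  placements and deterministic patterns, so filter tests are exact: an
  'N' at one position; a 60 nt homopolymer; all-25 qualities (mean
  Phred 25 < 30); and a "qual5p" class whose first 10 cycles have
  quality 2 over a 32 baseline (mean 29 < 30 untrimmed, 32 after
  trimming 10 nt) — the class that 5′ trimming rescues. Its default rate
  of 0.08 makes the trimming arm recover about 8% more counted
  fragments, the size of gain the procedure is meant to surface. Clean
  reads have baseline quality 35–39, so they can never fail the mean
  rule.
* **shRNA transgene reads** (optional, knockdown libraries only) are
  drawn in both orientations from the 3′ targeted half of the target
  gene — the worst case for unstranded quantification.
* **Responder genes.** A configurable fraction (default 0.3) of
  non-marker genes shift by $\pm 1$ log2 unit at full knockdown, only in
  compartments where the knockdown is active. The mixture formula above
  covers the target itself; without downstream responders there would be
  nothing for differential expression to find, no PCA group structure,
  and no class-enrichment contrast between neuron-restricted and somatic
  knockdowns. Responder effects scale with knockdown depth as
  $2^{\beta(1-r)}$, so $r=1$ is exactly the wild type.
* **Markers**: one neuron-restricted, one glia-restricted, one
  contaminant-tissue gene (expressed 100× lower in the target tissue),
  one ubiquitous control, the single-exon ubiquitous knockdown target,
  and a driver transgene expressed only in neuron-like cells on its own
  reference sequence — so zero transgene counts are a meaningful
  measurement, not missing data. The transgene abundance sits at the
  90th percentile of gene abundances (a strong pan-neuronal driver);
  cell-type-restricted abundance blocks are scaled to a common total so
  compartments carry comparable signal mass while ubiquitous genes keep
  identical per-cell abundance everywhere (which is what makes the
  dilution formula exact).

What the generator does **not** emulate: sequencing-error substitutions,
splice isoforms, GC or positional coverage bias beyond the 5′
composition effect, polyA-selection artifacts, and real genome sequence.
Tests passing on this generator therefore certify the pipeline's logic
and statistics, not robustness to alignment ambiguity or isoform
complexity in real data.

## Read QC

Filtering drops a *pair* when either mate fails any rule, reporting the
first failing rule in the order unknown-nucleotide (any 'N' by default),
homopolymer (a maximal single-base run ≥ 50 nt anywhere in the mate; 'N'
never extends a run), low quality (arithmetic mean Phred strictly below
30, per mate). Trimming removes the first `trim5` bases *and* quality
scores of each mate and is applied before filtering; `trim(a)` then
`trim(b)` equals `trim(a+b)`. The composition-bias score is the maximum,
over the first $m$ positions, of the total-variation distance between
that position's base distribution and the pooled distribution of
positions $m+1..P$ — 0 for unbiased reads, 0.75 for a position fixed at
one base against a uniform tail.

## Duplicates and counting

The duplicate signature is (reference, leftmost fragment start,
rightmost fragment end, orientation) — both ends, not start only,
matching whole-pair PCR duplication; the kept representative is the pair
with the highest summed base quality, ties to first occurrence, making
deduplication idempotent. Counting is union mode at fragment level: the
feature set of a pair is the union of genes whose exons overlap either
mate, strand ignored (unstranded libraries); exactly one gene counts,
two or more are `ambiguous`, none `no_feature`, and a mate below the
mapping-quality floor (default 10) makes the fragment `low_quality`
first. The four categories partition the fragment total by construction.
FPKM divides by union-exon kilobases and *counted* fragments (not raw
mapped reads) in millions; the denominator choice is recorded in the
report so alternatives are auditable. Coordinates are 0-based half-open
internally, converted to 1-based SAM/GTF only at I/O boundaries.

## Normalization and the NB test

Size factors are the median across common-nonzero genes of the ratio to
the per-gene geometric mean (median-of-ratios; the test suite checks
agreement with the DESeq reference implementation to 1e-10). Dispersion
is estimated per gene by method of moments on normalized counts with
variances pooled within groups, $\hat\alpha_g = \max\{0,
(s^2_g-\bar\mu_g)/\bar\mu_g^2\}$, plus a trend from a robust (Huber)
linear fit of $\log\hat\alpha$ on $\log\bar\mu$; the working value is
$\max(\hat\alpha_g, \text{trend})$ — conservative at small replicate
numbers. The trend regression replaces a local regression: one fewer
smoothing knob, and the simulation-based calibration test is the
arbiter of adequacy. The two-group test is a Wald test on the
difference of log normalized group means with NB variance
$\mathrm{Var}(\hat q_k) = (q\sum_j 1/s_j + \alpha q^2 n_k)/n_k^2$, a
continuity term of half a normalized count guarding zero means, and BH
adjustment at 0.05. A Wald test was chosen over re-implementing the
exact conditioned NB test: simpler, and its type-I error is verified by
simulation (2,000 null genes, 3+3 replicates, $\alpha=0.1$) rather than
assumed. Genes with zero counts everywhere are excluded before
normalization and testing; single-replicate designs are refused unless a
pooled dispersion is supplied explicitly. The concordance transform is
$\log_2(\text{count}/s_j + 1)$ — a deliberate stand-in for a parametric
variance-stabilizing transform, monotone and size-factor-stable, feeding
Pearson correlations, average-linkage clustering on $1-r$, and PCA of
gene-centered values.

## The marker panel

A library is **contaminated** when every contaminant marker exceeds its
maximum threshold *and* at least one target-tissue marker falls below
its minimum — the joint pattern, so that a noisy single marker cannot
flag on its own. A non-contaminated library is **low-transgene** when
the driver transgene falls below its threshold, resolved at evaluation
time as half the median transgene FPKM of the non-contaminated
libraries; the two flags are distinct because a weak driver is a
different failure (and a different decision) than dissected-in
contaminant tissue. The contamination score is
$\log_2[(1+\overline{\text{contam}})/(1+\overline{\text{target}})]$,
monotone in $c$ by the mixing model.

Thresholds are relative and configurable. The defaults are: contaminant
marker max = 2× its (low) target-tissue reference; target marker min =
0.8× its reference. Under linear mixing a target marker falls to
$(1-c)$ of its reference, so a factor of 0.8 detects $c \ge 0.3$ with
margin: at $c=0.3$ the marker sits at 0.7× reference, about
$0.49\sigma$ below the threshold for a count CV of
$\sqrt{1/\mu+\alpha}\approx 0.145$, giving per-marker sensitivity
$\approx 0.69$ and $\approx 0.97$ for "any of two" markers, while the
false-positive rate stays negligible because the contaminant-marker
condition must fire jointly (its reference is ~1% of the contaminant
level, so exceeding 2× it at $c=0$ is a multi-sigma event for any
well-expressed marker). A factor of 0.5 would only detect $c \gtrsim
0.5$, inconsistent with flagging moderately contaminated libraries, so
0.8 is the shipped default. Selection refuses to leave any group with
fewer than two libraries, and logs every exclusion with flag and score.

## The interference audit

Coverage profiles bin the gene's exonic span in transcript coordinates;
a fragment increments every bin it overlaps, so bin sums can exceed the
fragment count unless bins are wider than fragments. For the
interference statistic, a fragment belongs to the region containing its
*midpoint*, so the control-group fraction in the targeted region equals
the region's length share (exactly 0.5 for the default 3′-half partition
of the single-exon target) and the knockdown/control ratio $R$ has a
clean null of 1. Assignment by any-overlap would inflate the baseline by
the fragment length and compress the achievable ratio. With heavy
transgene expression (shRNA pairs ~9× the gene's own fragments) the
targeted fraction saturates near 0.95 and $R$ approaches 1.9–2; the
default flag threshold is 1.5. The 5′-restricted estimator counts only
fragments overlapping the non-targeted region and not touching the
targeted one — sequences that can only come from the endogenous gene —
and reruns the NB test with the *global* size factors, so it stays
unbiased for the diluted fold change $\varphi r + (1-\varphi)$ whether or
not transgene reads are present. A zero-width targeted interval
degenerates gracefully: restricted counts equal the gene's fragments.

## Enrichment statistics

DE lists are classified against disjoint neuronal/glial/ubiquitous sets
(genes in several lists are dropped from all, with a recorded count);
percentages are rounded half away from zero to one decimal, matching how
such tables are printed. Proportions between two DE lists are compared
with the pooled two-proportion z-test, $p = 2\Phi(-|z|)$, degenerate
pooled proportions returning $p=1$ by convention; gene-list overlap uses
the upper-tail hypergeometric probability evaluated on the log scale,
with the universe defaulting to the genes tested for DE. Both are
cross-checked in the tests against `prop.test(correct = FALSE)` and
exhaustive enumeration on universes ≤ 25.

## Numerical and problem-size choices

Ties in deduplication break by first occurrence; percentage rounding is
half-up; the silhouette of a singleton group is 0; correlations of
constant libraries are reported as undefined rather than imputed. The
test suite and the acceptance script run everything at desk scale —
20–120 genes, 1,500–60,000 fragments per library, 6–20 libraries,
~50,000 read pairs for the filter checks and ~20,000 for duplicate-rate
recovery, 2,000 genes for NB calibration — sizes chosen so each
statistical check has the precision its tolerance needs (e.g. 10
replicates per group put the NB noise of the fold-change recovery well
inside ±0.05). All randomness flows from a single integer seed;
simulation emission is byte-reproducible given the configuration.

## Known limitations

The aligner is out of scope: the pipeline consumes ground-truth
alignments (or any minimal SAM), so mapping ambiguity, soft-clipping and
multi-mappers are unmodeled, and the 5′-trimming comparison quantifies
the *rescue of quality-failing reads*, not remapping gains. The Wald NB
test is slightly liberal at 2–3 replicates compared to exact tests —
calibrated by simulation, not proven. Marker thresholds assume the
linear mixing of well-expressed markers; panels built from weakly
expressed markers need wider margins. The contamination estimator
assumes a single contaminant tissue with a known reference level. The
region audit assumes the shRNA-homologous interval is known in
transcript coordinates.
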