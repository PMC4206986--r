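---
title: "Consensus motif discovery and intersection-zone selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus motif discovery and intersection-zone selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifzone)
```

## The problem

Transcription factors (TFs) that regulate, or are regulated by, a signalling
pathway leave a footprint in the promoters of the pathway's genes: short
binding sites (TFBSs) that motif-discovery programs can detect. Individual
programs disagree substantially, so a practical strategy is an ensemble:
accept a motif only when several independent per-sequence programs find it
*and* at least one dataset-wide enrichment program corroborates the factor.
motifzone implements that strategy end to end for TSS-anchored promoter
sets — by convention 5,000 bp upstream to 500 bp downstream of the
transcription start site — in a human–mouse orthologous design, with the
mTOR pathway's gene set as the motivating use case.

The pipeline's stages are:

1. **Scanning.** Each promoter is scanned on both strands with per-TF
   position weight matrices (PWMs) under a log-odds model. An ensemble of
   "main" tools reports positional hits per sequence; "supportive" tools
   report enriched TFs over the whole dataset.
2. **Consensus.** A motif occurrence of TF $t$ in gene $g$ is *accepted*
   only when all main tools present identify $t$ in $g$'s promoter
   (configurable to $\ge m$ tools) and at least one supportive tool lists
   $t$ (configurable). Accepted occurrences populate a gene × TF count
   matrix.
3. **Gene threshold.** The dataset mean of accepted motifs per gene,
   $\bar{c} = \tfrac{1}{N}\sum_g c_g$, defines the gene threshold; genes
   with $c_g > \lfloor\bar{c}\rfloor$ (strictly more than the floored
   mean) are the co-regulated set.
4. **TF threshold.** TFs seen in the selected genes are ranked by the
   number of selected genes they hit, then by total occurrences, then by
   symbol; the top 40% (floored) are kept.
5. **Intersection zone.** The selected-genes × selected-TFs count
   submatrix — the analysis's headline artifact.
6. **Cross-species comparison and classification.** Zone TF lists of the
   two species are intersected (case-insensitive symbol identity by
   default), and each zone TF is classified by pathway scope, binding
   affinity, and literature-annotated regulatory direction.

## Scoring model

A PWM is a column-stochastic $4 \times L$ matrix $p$ of per-position base
probabilities. A window $w$ scores

$$S(w) = \sum_{j=1}^{L} \log_2 \frac{p'_j(w_j)}{b(w_j)} \quad \text{bits},$$

where $b$ is the background base distribution (uniform by default,
overridable with observed promoter composition) and $p'$ is the column
after adding a pseudocount (default 0.01 per cell) and renormalizing — the
standard guard against $-\infty$ scores from sparse count matrices.
`N` bases contribute zero at their position, so ambiguous sequence is
score-neutral rather than disqualifying. Minus-strand hits are scored as
the reverse complement of the window read against the forward model.

Hits at or above the threshold are **de-overlapped greedily** per
(gene, TF): the best-scoring hit is kept and every hit overlapping it by
at least one bp is discarded, repeating down the score order (ties: smaller
start, then + strand). This is what makes "number of occurrences per
promoter" well defined — e.g. a factor with seven discrete copies in one
promoter.

**Virtual tools.** Since the ensemble's external programs are web services
with unpublished internals, the package supplies stand-ins that preserve
the ensemble's *report structure* without reproducing any specific
program: five virtual main tools are the same scanner at five
relative-score thresholds (defaults 0.75–0.95 of each PWM's maximal
score), and four virtual supportive tools call a TF enriched when its
dataset-wide hit total at that tool's threshold has Poisson upper-tail
$p \le \alpha$ (default 0.05) against the *exact* background expectation.
That expectation is computed by dynamic-programming convolution of the
per-column score distribution under the background model (scores
discretized to $10^{-3}$ bits), not by Monte Carlo, so it is deterministic
and exact to the grid. The threshold ladder is a free parameter: no
published per-tool thresholds exist to calibrate against, and the defaults
were fixed once as a plausible spread from permissive to stringent.

## Counting conventions

Two count-matrix modes coexist because the field mixes two conventions:

- `pooled` (default): the sum over main tools of each tool's de-overlapped
  hit count — five tools reporting one site count 5. This is the
  convention under which a dataset total divided by gene count gives a
  mean-motifs-per-gene threshold.
- `consensus_sites`: overlapping same-strand hits from different tools are
  single-linkage clustered, and clusters supported by at least `min_main`
  distinct tools count 1. This gives discrete per-promoter occurrence
  numbers.

Thresholding and selection run on the configured mode (default `pooled`);
the **high-affinity classification — strictly more than three occurrences
in a single promoter — always uses consensus-site counts**, because "three
occurrences" is a statement about discrete sites, not about pooled tool
reports.

## Thresholds and tie-breaks

- Gene selection is strictly `>` the integer cutoff
  $\lfloor\bar{c}\rfloor$, and the cutoff floors the *unrounded* mean.
- The reported mean and SD are rounded half-up to 2 decimals (base R's
  half-to-even would misreport borderline values).
- The SD of per-gene totals is population ($\div N$) by default — the
  dataset is the entire study population, not a sample — with a
  `sample` option for comparison.
- TF ranking: descending gene coverage, then descending total occurrences,
  then lexicographic symbol. The coverage-first key follows how ensemble
  studies describe their rankings (the top factor "found in most genes",
  the last one "found in 12 genes with single occurrence").
- The top-fraction count is floored: 61 candidates at 40% give 24.
- `select_top_tfs` clips (with a warning) when asked for more TFs than
  exist; `select_genes` may legitimately return an empty set, and the
  pipeline then skips zone construction for that species.

## The synthetic-data generator

Because the original promoter sets and web-tool outputs are not
retrievable, every downstream stage is validated on synthetic data whose
defaults mirror the study conditions: 49 human genes, 43 of them with
mouse orthologs, −5000/+500 windows, five main and four supportive tools.
The generator:

- samples i.i.d. background sequence at configurable GC content (default
  0.45, typical of promoter regions);
- plants TFBS copies per an explicit gene → TF → copies table at random
  non-overlapping positions and strands, drawing each site from the TF's
  PWM; the default study-shaped table is tiered (5 ubiquitous factors in
  ~40 of 49 genes, the top one with a seven-copy promoter; 10
  mid-frequency; 15 rare);
- derives mouse promoters by i.i.d. per-bp substitution (default 0.15,
  roughly the promoter-wide divergence scale of human–mouse alignments)
  with planted sites re-inserted unchanged, i.e. motif conservation is an
  assumption of the design, not an inference;
- emulates tool noise as an independent Bernoulli detection per true site
  per main tool (default sensitivity 0.9) plus Poisson false hits (default
  0.2/kb), and, for supportive tools, a sampled dataset-count threshold
  (tool $j$ draws Poisson($j-1$), so the first tool's threshold is always
  zero) plus a small false-TF rate (default 0.05). The published ensemble
  studies report no inter-tool disagreement statistics, so these defaults
  are illustrative, fixed once, and not calibrated to any target.

What the generator deliberately does **not** model: repeat structure, CpG
islands, dinucleotide/Markov background, indels or phylogenetically
realistic evolution, motif similarity between different TFs, and
alternative TSSs. Passing tests therefore demonstrate the pipeline's
*logic* (the consensus rule, thresholds, and classification behave as
specified, and signal survives a realistic noise channel) — not that the
scanner would match any particular program's calls on real promoters.

**Determinism.** One master seed drives everything. Child seeds are
derived as `set.seed(master); sample.int(2^31 - 2, n)` at fixed stream
indices, so each stage has its own reproducible stream and adding a stage
never shifts the others. Generator functions restore the caller's RNG
state on exit. Two runs with the same config are byte-identical.

## Design choices that were genuinely open

- **"Some supportive programs" → `min_supportive = 1`.** The source
  procedure never quantifies "some"; one corroboration is the weakest
  reading and is exposed as a parameter.
- **Main-tool unanimity relaxes to the tools present** unless
  `strict_main = TRUE`, so partial panels remain usable.
- **Pooled totalling as the threshold default** is inferred from the
  arithmetic of the motivating study (its dataset total divided by its
  gene count reproduces its printed mean only if per-tool counts are
  summed, not unioned).
- **Regulatory direction is annotation-only.** The regulating/regulated
  status of a TF comes from curated literature, so the package ships an
  editable YAML lookup (`inst/extdata/mtor_tf_direction.yaml`) and never
  infers direction from motif data. Module membership of the mTOR genes
  ships the same way (`mtor_modules.yaml`); simulated datasets carry their
  own generated module labels.
- **Orthologous TF matching is case-insensitive symbol identity**
  (SP1 ↔ Sp1), overridable with an explicit, injective name map.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
built at call time: unit fixtures of 4–50 genes and promoters of 0.3–2.5
kb; the scanner-vs-enumeration oracle on 50 random promoters up to 2 kb
against 10 random PWMs; recovery experiments on a 20-gene × 12-TF
two-tier design, noiseless and over 20 noisy replicates; and one
study-shaped run (49 + 43 genes, 30 TFs). These sizes were chosen so each
property is exercised well away from trivial edge cases while the whole
suite stays interactive.

## Known limitations

- The scanner is a generic PWM log-odds scanner; it is a structural
  stand-in for the published ensemble, not a re-implementation, and
  per-tool thresholds are free parameters.
- Near-identical motifs of different TFs (GC-box families, for instance)
  are not merged before counting; a real dataset will double-count such
  factors exactly as the original multi-tool procedure would.
- The Poisson background model for supportive calls assumes independent
  windows; clustered repeats violate this and inflate enrichment.
- No statistical significance is attached to the intersection zone
  itself — it is a descriptive selection, faithfully reproducing the
  thresholding procedure it implements.
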