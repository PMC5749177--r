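---
title: "PWM-anchored networks for cross-cell-type chromatin accessibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PWM-anchored networks for cross-cell-type chromatin accessibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pwmnet predicts, from DNA sequence alone, in which of three cell types
(iPSC, LCL, iPSC-derived cardiomyocyte) a 500-bp regulatory window is
accessible, and then interrogates the trained model: which transcription
factor explains each locus, how every possible point mutation would change
the prediction, and what effect a candidate causal caQTL SNP is predicted
to have on chromatin accessibility in each cell type. This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the synthetic benchmark does and does not
establish.

## The accessibility label

Accessibility across the three cell types is encoded as a single
categorical outcome $O \in \{1,\dots,7\}$ over the non-empty subsets of
cell types: 1 = open in iPSC-CM alone, 2 = LCL alone, 3 = iPSC-CM and LCL,
4 = iPSC alone, 5 = iPSC and iPSC-CM, 6 = iPSC and LCL, 7 = all three. A
locus open in no cell type is not a valid training example and is
rejected. `assign_category()` and `category_flags()` implement the mapping
and its inverse.

Training loci are built from per-sample ATAC-seq peak calls
(narrowPeak): peaks below a 15-fold enrichment over background are
discarded, survivors are merged by interval union per cell type
(`merge_peaks()`), the three merged sets are unioned across cell types,
and each union locus is flagged open in cell type $t$ if it overlaps any
merged peak of $t$ by at least one base (`build_dataset()`; a
minimum-overlap fraction is configurable, default 0, because no overlap
rule is canonical). One 500-bp window is extracted at the center
$c = \lfloor (start + end)/2 \rfloor$ of each union locus, regardless of
locus length; windows that would overhang a chromosome end are dropped
with a logged count rather than silently clipped.

## The network

The model is a four-layer convolutional network over the one-hot encoded
window (a 500 x 4 binary matrix; non-ACGT bases are all-zero rows, keeping
the input strictly binary):

1. **Frozen PWM convolution.** Each transcription-factor PWM is converted
   to a log2-odds filter
   $w_{jb} = \log_2\!\big((p_{jb} + \varepsilon)/(q_b + \varepsilon)\big)$
   against a background $q$ (default uniform, pseudocount
   $\varepsilon = 10^{-3}$), zero-padded on the right to the maximum motif
   width $W_{max}$, and — under the default `rc_max` strand policy —
   paired with its reverse complement, the two strands reduced by a
   positionwise maximum. The convolution is "valid", so the layer emits
   $500 - W_{max} + 1$ positions per TF. These weights are never trained;
   a checksum recorded at training time allows frozen-layer integrity to
   be verified afterwards.
2. **ReLU + max-pooling** of width/stride 8 (non-overlapping).
3. **Learnable convolution** (64 filters of width 8 across all TF
   channels), ReLU, and a global max-pool per filter.
4. **Dense layer** (128 units, ReLU) and an output layer of independent
   sigmoid units, one per category.

The sigmoid head models the categorical output as seven independent
Bernoulli scores trained with per-unit cross-entropy against the one-hot
category; scores are renormalized at prediction time. A softmax head is
available (`pwmnet_config(head = "softmax")`) since a mutually exclusive
7-way outcome is equally defensible; the sigmoid form is the default.
Per-cell-type open probabilities marginalize the category scores:
$p_t = \sum_{O \ni t} s_O / \sum_O s_O$. This marginalization is the
package's own construction — something of the kind is required to score a
single cell type from a 7-way head.

Training uses ADADELTA (decay 0.95, epsilon 1e-6, learning-rate
multiplier 1.0 — the algorithm's original settings), batches of 64, 15
epochs by default. All randomness (weight initialization, epoch
shuffling) derives from one integer seed recorded in the model, and
training is exactly reproducible given that seed. Because the first layer
is frozen, its pooled activations are computed once per window and cached,
which is what makes desk-scale training (~14,000 loci in about a minute
per 10 epochs on one CPU) practical in pure R.

Accuracy is evaluated per cell type as the rank-sum (Mann–Whitney) AUC of
$p_t$ against the binary open flag of $t$; `evaluate_auc()` also reports
every cross pairing (score of cell type $t$ against labels of $t'$),
which is the package's protocol for showing that a model for one cell
type transfers poorly to another.

## Attribution

`deeplift_scores()` implements DeepLIFT with the Rescale rule,
propagating contributions from a chosen output down to the post-ReLU
activations of the frozen first layer — one score per TF per scan
position. Design choices the method text leaves open:

* **Reference input.** Default is the background-frequency input (every
  row equal to the background vector), making "no sequence information"
  the baseline; all-zero and shuffled (seeded permutation of the window's
  own bases, preserving composition but not dinucleotide structure)
  references are selectable.
* **Max-pool multipliers.** Through each max unit the output delta is
  routed to the argmax of the *actual* input; if that position's delta
  vanishes while the output delta does not, the delta is distributed over
  the non-zero input deltas proportionally. This preserves
  summation-to-delta exactly by construction:
  $\sum_{f,j} C_{fj} = f(x) - f(\text{reference})$ holds to floating-point
  accuracy, and is asserted at 1e-4 relative tolerance in the tests.
* **Targets.** For a category target the attributed scalar is that
  category's sigmoid score. For a cell-type target it is the
  *unnormalized* sum of the scores of the categories containing the cell
  type, which keeps the output head linear in the sigmoid units so the
  multiplier algebra stays exact. (Saturation mutagenesis, which is pure
  forward differencing, uses the renormalized $p_t$ instead.)
* **Per-locus key TF.** Contributions are aggregated per TF as the sum of
  positive scores over positions (a max-over-positions variant is
  available); the TF with the highest aggregate is the locus's key TF,
  with exact ties broken lexicographically by `tf_id` and logged. Only
  loci whose predicted category equals their true category enter the
  per-category aggregation, and loci where no TF has positive aggregate
  are counted in the denominator but explain nothing, so fractions sum to
  at most 1.

DeepLIFT propagation is implemented for the sigmoid head only; the
softmax head couples output units and is not supported for attribution.

`saturation_mutagenesis()` computes
$\Delta\text{pred}(p, b) = f(x^{p \to b}) - f(x)$ for all 1,500 single
substitutions of a 500-bp window. The implementation recomputes only the
convolution offsets and pool bins a mutation can reach and batches the
learnable layers, but the result is bit-for-bit the same as 1,500
independent forward passes, which the tests assert against literal
recomputation. The delta at each position's reference base is exactly
zero; all-zero (masked) rows are mutated against the zero row and
flagged.

## Predicted caQTL effects

Candidate causal SNPs arrive with posterior probabilities $\pi_l$ (locus
is a caQTL) and $\pi_s$ (SNP is causal given the locus is a caQTL) from an
external fine-mapping step; `select_causal()` keeps records with
$\pi_l > 0.99$ **and** $\pi_s > 0.99$, strictly, matching the printed
filter. For each retained SNP, `build_haplotypes()` constructs the 500-bp
window centered on the SNP for every phased haplotype in the panel,
substituting *all* phased in-window SNVs of that haplotype (a
`focal_only` flag restricts to the focal SNP; indels and multiallelic
records are skipped with a warning because the window length must stay
500). `haplotype_effect()` then scores every haplotype and reports, per
cell type, the difference in median predicted activity between the
alternate- and reference-allele groups.

Activity is measured on the log-odds scale of $p_t$ by default. The
probability scale compresses differences near 0 and 1 — a strong motif
disruption at a confidently open locus would register almost nothing —
whereas the log-odds scale is the conventional unbounded effect-size
scale and keeps the response approximately proportional to the underlying
filter-score change. `scale = "response"` restores probability
differences. Allele-swap antisymmetry is exact on either scale.

`compare_to_imbalance()` correlates predicted effects with observed
allelic imbalance (alternate-allele fraction, centered at 0.5 by default;
raw and logit transforms selectable since the axis convention is not
fixed), reporting Pearson (default) or Spearman correlation with its
p-value and the matched scatter table.

## The synthetic benchmark

The generator (`sim_config()`, `simulate_pwms()`, `simulate_dataset()`,
`simulate_caqtl_panel()`) stands in for the study's real inputs — ATAC-seq
peaks across three cell types, curated PWM collections, a phased
reference panel, and read-level allelic imbalance — so that every stage
runs and is testable offline. Its defaults are the package's study
conditions:

* **Motifs.** Seven TFs: two specific to each cell type plus one shared
  by all three. Widths are drawn uniformly in 8–12 bp. Each PWM column
  puts probability $s \sim U(0.85, 0.97)$ on a consensus base. This range
  was calibrated so that a matched-filter detector built directly from
  the generating PWMs separates the planted classes with AUC clearly
  above 0.9 — i.e. the benchmark conditions make recovery possible in
  principle, so the network's held-out accuracy measures the
  implementation rather than an information floor. The spread of column
  strengths also varies the log-odds cost of disrupting a motif position,
  giving the caQTL panel a range of effect sizes.
* **Loci.** 2,286 loci per category (~16k total; an eighth held out gives
  the ~14,000/2,000 train/test split used in the acceptance runs), each
  an i.i.d. background sequence (GC 0.41, human-like) carrying one
  sampled instance of every motif assigned to its open cell types plus
  the shared motif, planted at uniform random non-overlapping positions
  on random strands. Labels follow the planting deterministically.
* **caQTL panel.** 200 true caQTLs: a window with a planted motif whose
  column $j$ sits at the window center; the reference base there is the
  motif consensus and the alternate allele is a random non-consensus
  base, so the SNP disrupts the motif by
  $m = \log_2\!\big((p_{j,ref}+\varepsilon)/(p_{j,alt}+\varepsilon)\big)$
  log-odds units. The planted allelic imbalance is
  $p_{\text{eff}} = \text{logis}(-0.3\,m)$, and observed counts are
  Binomial(depth 50, $p_{\text{eff}}$), clamped to keep both allele
  counts positive. A phased diploid panel of 40 individuals (80
  haplotypes) is drawn with allele frequency uniform in [0.1, 0.9], plus
  one neutral in-window SNV per locus so haplotype construction
  substitutes more than the focal SNP. 200 decoy background SNPs with
  $\pi_s < 0.5$ exercise the posterior filter.
* **Determinism.** Everything derives from the config seed; identical
  seeds give byte-identical FASTA/VCF/TSV output.

What the benchmark does *not* emulate: repeat structure, dinucleotide
composition, nucleosome or Tn5 bias, linkage disequilibrium beyond a
single window, overlapping or cooperative motifs, and the long-tailed
fold-enrichment distributions of real peak calls. Passing the synthetic
recovery tests therefore shows that the architecture, training loop,
attribution and variant scoring are implemented correctly and can recover
planted structure at realistic noise levels — not that comparable
accuracy would be reached on real chromatin data, which also requires the
full 1,320-TF PWM collection rather than seven simulated motifs.

## The variability statistic

For a phenotype matrix $\chi_{nl}$ (individuals $n = 1..N$, loci
$l = 1..L$) with per-locus means $\bar\chi_l$, the per-individual
variability is

$$V_n = \frac{N}{L\,(N-1)} \sum_{l=1}^{L}
        \frac{(\chi_{nl} - \bar\chi_l)^2}{\bar\chi_l^2},$$

reported alongside $\log_2 V_n$. The typeset source formula does not pin
down the placement of the constants; this reading is the only one that is
simultaneously an *average* (over $L$) squared relative distance and
carries the unbiased-variance correction $N/(N-1)$, and it makes mean
$V_n$ estimate the squared coefficient of variation under i.i.d. noise
(asserted empirically in the tests at $N = 50$, $L = 5000$). Zero-mean
loci are dropped with a message, not clamped; $V_n$ is invariant to
rescaling the whole matrix.

## Numerical notes and known limitations

* **Coordinates** are BED-convention 0-based half-open everywhere;
  window centers round down.
* **Padding.** Zero-padding filters to a common width means a narrower
  motif is not scanned over the final $W_{max} - W$ window positions.
  Strand-symmetry of per-TF maxima is therefore exact for equal-width
  filter banks and holds away from that trailing margin otherwise.
* **Ties.** Max-pool argmaxes take the first position; key-TF ties break
  lexicographically; both rules are deterministic and logged where they
  fire.
* **Clamps.** Log-odds activity clamps probabilities at $10^{-12}$;
  DeepLIFT Rescale falls back to the local derivative when an input delta
  is below $10^{-9}$.
* **Problem sizes.** The package's standard experiment — and what the
  acceptance script reruns — uses ~14,000 training loci, 2,000 held-out
  loci, 15 epochs, and a 200-caQTL/200-decoy panel with 80 haplotypes;
  unit tests use miniatures of the same generator.
* **Effect-size buffering.** Any max-score detector — this network, but
  equally a matched filter built from the generating PWM — responds to a
  point disruption only up to the margin between the disrupted site and
  the next-best match of the same TF in the window. The *direction* of a
  motif-disrupting variant is therefore recovered reliably, while the
  *magnitude* of the predicted effect is a buffered, locus-dependent
  transform of the column-level log-odds change. Correlations between
  predicted effect sizes and a generative effect defined purely at the
  disrupted column are bounded well below the generative
  signal-to-noise ceiling for this reason.
* The learnable stack is intentionally small and CPU-friendly; there is
  no dropout, no early stopping, and no hyperparameter search. The
  first-layer freeze is the architectural commitment; everything else is
  explicit configuration.
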